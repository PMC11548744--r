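#' @importFrom stats prcomp aov TukeyHSD pf
NULL

#' Principal component analysis of normalized expression
#'
#' Gene-centered (optionally variance-scaled) singular value decomposition
#' of the sample x gene matrix. Genes with any missing value in the analyzed
#' subset are dropped for that PCA only (no imputation); -ddCt values share
#' a common log2 scale, so variance scaling defaults off.
#'
#' @param qpcr a normalized \linkS4class{QpcrSet} (assay \code{"nddct"}).
#' @param subset optional logical or integer sample index (e.g. one time
#'   point), applied to columns.
#' @param assayName assay to analyze.
#' @param scale. variance-scale genes before the decomposition.
#' @param nComponents number of components to keep (truncated with a warning
#'   when more are requested than samples allow).
#' @return list with \code{scores} (sample x component), \code{loadings}
#'   (gene x component, orthonormal), \code{varianceExplained} (fraction per
#'   component), and \code{droppedGenes}.
#' @export
runPca <- function(qpcr, subset = NULL, assayName = "nddct",
                   scale. = FALSE, nComponents = Inf) {
  x <- assay(qpcr, assayName)
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 samples for PCA")
  complete <- rowSums(is.na(x)) == 0L
  dropped <- rownames(x)[!complete]
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 1L) stop("no genes without missing values in subset")
  p <- prcomp(t(x), center = TRUE, scale. = scale.)
  k_max <- ncol(p$rotation)
  k <- min(nComponents, k_max)
  if (is.finite(nComponents) && nComponents > k_max)
    warning("requested ", nComponents, " components, only ", k_max,
            " available; truncated")
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)],
       droppedGenes = dropped)
}

#' Top contributing genes of a principal component
#'
#' @param pca result of [runPca()].
#' @param component component index.
#' @param n genes per list.
#' @return list with \code{positive} and \code{negative} gene vectors: the
#'   \code{n} most positive and most negative loadings, sorted by signed
#'   loading (ties broken lexicographically by gene label).
#' @export
topLoadingGenes <- function(pca, component = 2L, n = 20L) {
  l <- pca$loadings[, component]
  stopifnot(n <= length(l))
  genes <- rownames(pca$loadings)
  pos <- genes[order(-l, genes)][seq_len(n)]
  neg <- genes[order(l, genes)][seq_len(n)]
  list(positive = pos, negative = neg)
}

## One balanced two-factor ANOVA with the degenerate-data convention:
## an effect whose sum of squares is (numerically) zero gets F = 0, p = 1.
.anova2 <- function(y, fa, fb, tukey = TRUE) {
  d <- data.frame(y = y, A = factor(fa), B = factor(fb))
  d <- d[!is.na(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$A)) < 2L || nlevels(droplevels(d$B)) < 2L)
    return(NULL)
  cells <- table(droplevels(d$A), droplevels(d$B))
  if (any(cells == 0L)) return(NULL)
  fit <- aov(y ~ A * B, data = d)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  eff <- function(i) {
    f <- tab[["F value"]][i]; p <- tab[["Pr(>F)"]][i]
    if (!is.finite(f) || ss[i] < 1e-12 * max(sum(ss), 1)) {
      f <- 0; p <- 1
    }
    c(F = f, p = p)
  }
  res <- list(A = eff(1L), B = eff(2L), AB = eff(3L),
              ss = c(A = ss[1L], B = ss[2L], AB = ss[3L],
                     error = ss[4L]))
  if (tukey)
    res$tukey <- tryCatch(TukeyHSD(fit), error = function(e) NULL)
  res$means <- tapply(d$y, list(d$A, d$B), mean)
  res$se <- tapply(d$y, list(d$A, d$B),
                   function(v) sd(v) / sqrt(length(v)))
  res
}

#' Per-gene two-factor ANOVA with Tukey HSD
#'
#' For every (organ, gene), fits the balanced two-way factorial model with
#' interaction (by default age x strain) on normalized expression and runs
#' Tukey Honest Significant Difference post hoc tests on the cell means with
#' pooled error. On a balanced design the sequential sums of squares equal
#' the type-II decomposition. Genes with empty design cells in an organ are
#' flagged and their statistics withheld.
#'
#' @param qpcr a normalized \linkS4class{QpcrSet}.
#' @param factors length-2 character, colData columns used as factors A and
#'   B (default \code{c("age_weeks", "strain")}).
#' @param assayName assay to analyze.
#' @param alpha significance level used for the significant-gene summary.
#' @return list with \code{stats} (data.frame: organ, gene, F and p for each
#'   factor and the interaction), \code{tukey} (nested list of
#'   \code{TukeyHSD} results per organ/gene), \code{flagged} (organ:gene
#'   labels with empty cells), and \code{significant} (rows of \code{stats}
#'   with any effect p < alpha).
#' @export
twoWayAnova <- function(qpcr, factors = c("age_weeks", "strain"),
                        assayName = "nddct", alpha = 0.05) {
  x <- assay(qpcr, assayName)
  meta <- colData(qpcr)
  fa_all <- meta[[factors[1L]]]
  fb_all <- meta[[factors[2L]]]
  rows <- list(); tukeys <- list(); flagged <- character(0)
  for (org in unique(as.character(meta$organ))) {
    idx <- meta$organ == org
    for (g in rownames(x)) {
      res <- .anova2(x[g, idx], fa_all[idx], fb_all[idx])
      if (is.null(res)) {
        flagged <- c(flagged, paste(org, g, sep = ":"))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, gene = g,
        F_A = res$A[["F"]], p_A = res$A[["p"]],
        F_B = res$B[["F"]], p_B = res$B[["p"]],
        F_AB = res$AB[["F"]], p_AB = res$AB[["p"]])
      tukeys[[org]][[g]] <- res$tukey
    }
  }
  stats <- do.call(rbind, rows)
  names(stats)[3:8] <- c(
    paste0(c("F_", "p_"), factors[1L]),
    paste0(c("F_", "p_"), factors[2L]),
    "F_interaction", "p_interaction")
  sig <- stats[stats[[4L]] < alpha | stats[[6L]] < alpha |
                 stats[[8L]] < alpha, , drop = FALSE]
  list(stats = stats, tukey = tukeys, flagged = flagged,
       significant = sig, factors = factors, alpha = alpha)
}

#' Cross-sex contrast of strain differences
#'
#' Restricts two single-sex datasets to their shared genes, organs and ages,
#' forms per-animal strain differences (each hypertensive-strain replicate
#' minus the matched normotensive cell mean), and contrasts them across
#' sexes with a two-way ANOVA using age and sex as interacting factors plus
#' Tukey HSD post hoc tests, per (organ, gene).
#'
#' @param qpcrF,qpcrM normalized \linkS4class{QpcrSet} objects for the two
#'   sexes (each containing both strains).
#' @param caseStrain,controlStrain strain labels of the hypertensive model
#'   and its control.
#' @param assayName assay to analyze.
#' @return list with \code{deltas} (data.frame organ, gene, age_weeks, sex,
#'   delta), \code{stats} (per organ/gene F and p for age, sex,
#'   interaction), \code{tukey}, \code{sharedGenes}, \code{sharedAges},
#'   \code{sharedOrgans}, \code{excludedGenes}.
#' @export
sexContrast <- function(qpcrF, qpcrM, caseStrain = "SHR",
                        controlStrain = "WKY", assayName = "nddct") {
  shared_genes <- intersect(rownames(qpcrF), rownames(qpcrM))
  shared_organs <- intersect(unique(colData(qpcrF)$organ),
                             unique(colData(qpcrM)$organ))
  shared_ages <- intersect(unique(colData(qpcrF)$age_weeks),
                           unique(colData(qpcrM)$age_weeks))
  excluded <- union(setdiff(rownames(qpcrF), shared_genes),
                    setdiff(rownames(qpcrM), shared_genes))
  if (length(shared_genes) == 0) stop("no shared genes between panels")
  per_sex <- function(q, sex) {
    x <- assay(q, assayName)
    meta <- colData(q)
    out <- list()
    for (org in shared_organs) for (a in shared_ages) {
      case_idx <- meta$organ == org & meta$age_weeks == a &
        meta$strain == caseStrain
      ctrl_idx <- meta$organ == org & meta$age_weeks == a &
        meta$strain == controlStrain
      if (!any(case_idx) || !any(ctrl_idx)) next
      for (g in shared_genes) {
        ctrl_mean <- mean(x[g, ctrl_idx], na.rm = TRUE)
        dv <- x[g, case_idx] - ctrl_mean
        dv <- dv[!is.na(dv)]
        if (length(dv) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          organ = org, gene = g, age_weeks = a, sex = sex, delta = dv)
      }
    }
    do.call(rbind, out)
  }
  deltas <- rbind(per_sex(qpcrF, "F"), per_sex(qpcrM, "M"))
  rows <- list(); tukeys <- list()
  for (org in shared_organs) for (g in shared_genes) {
    d <- deltas[deltas$organ == org & deltas$gene == g, ]
    res <- .anova2(d$delta, d$age_weeks, d$sex)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      organ = org, gene = g,
      F_age = res$A[["F"]], p_age = res$A[["p"]],
      F_sex = res$B[["F"]], p_sex = res$B[["p"]],
      F_interaction = res$AB[["F"]], p_interaction = res$AB[["p"]])
    tukeys[[org]][[g]] <- res$tukey
  }
  list(deltas = deltas, stats = do.call(rbind, rows), tukey = tukeys,
       sharedGenes = shared_genes, sharedAges = sort(shared_ages),
       sharedOrgans = shared_organs, excludedGenes = excluded)
}
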