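#' @importFrom SummarizedExperiment assays<-
#' @importFrom stats complete.cases
NULL

.present_fraction <- function(m, margin) {
  apply(!is.na(m), margin, mean)
}

.append_qc <- function(qpcr, name, record) {
  qc <- metadata(qpcr)$qc
  if (is.null(qc)) qc <- list()
  qc[[name]] <- record
  metadata(qpcr)$qc <- qc
  qpcr
}

#' Remove genes and samples with too little data
#'
#' Quality-control filter for qPCR matrices: genes observed in fewer than
#' \code{minPresent} of samples are removed first, then samples observed in
#' fewer than \code{minPresent} of the retained genes (one pass each, genes
#' before samples). The removed labels are recorded in the QC report
#' (\code{qcReport(x)$filter}).
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param minPresent minimum present fraction (default 0.6, i.e. the
#'   "at least 60% working reactions" rule).
#' @return the filtered \linkS4class{QpcrSet}.
#' @export
filterLowData <- function(qpcr, minPresent = 0.6) {
  stopifnot(minPresent > 0, minPresent <= 1)
  ct <- assay(qpcr, "ct")
  gene_frac <- .present_fraction(ct, 1L)
  drop_genes <- rownames(ct)[gene_frac < minPresent]
  keep_genes <- setdiff(rownames(ct), drop_genes)
  if (length(keep_genes) == 0)
    stop("empty matrix after QC: all genes below present fraction ",
         minPresent)
  sample_frac <- .present_fraction(ct[keep_genes, , drop = FALSE], 2L)
  drop_samples <- colnames(ct)[sample_frac < minPresent]
  keep_samples <- setdiff(colnames(ct), drop_samples)
  if (length(keep_samples) == 0)
    stop("empty matrix after QC: all samples below present fraction ",
         minPresent)
  out <- qpcr[keep_genes, keep_samples]
  .append_qc(out, "filter",
             list(minPresent = minPresent, removedGenes = drop_genes,
                  removedSamples = drop_samples))
}

## Agreement between two technical replicates: slope of the zero-intercept
## regression of replicate-2 Ct on replicate-1 Ct over co-present genes.
.replicate_slope <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * y[ok]) / sum(x[ok]^2)
}

#' Reconcile duplicate-chip technical replicates
#'
#' Samples run on two chips are identified by identical
#' (\code{animal_id}, \code{organ}, \code{age_weeks}) with distinct
#' \code{chip_id}. For each pair, the agreement statistic is the slope of
#' the zero-intercept regression of the second replicate's Ct on the first
#' over co-present genes; pairs whose slope lies within \code{band} are
#' replaced by the per-gene mean (over present values), otherwise the
#' replicate with more present reactions is kept and the exclusion logged.
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param band numeric length-2 agreement interval (inclusive), default
#'   \code{c(0.85, 1.15)}.
#' @return a \linkS4class{QpcrSet} with one column per biological sample.
#' @export
mergeChipReplicates <- function(qpcr, band = c(0.85, 1.15)) {
  ct <- assay(qpcr, "ct")
  meta <- colData(qpcr)
  key <- paste(meta$animal_id, meta$organ, meta$age_weeks, sep = "||")
  groups <- split(seq_len(ncol(ct)), key)
  sizes <- lengths(groups)
  if (any(sizes > 2L))
    stop("unsupported replicate multiplicity: ", sum(sizes > 2L),
         " sample group(s) with >2 chip replicates")
  merges <- list()
  exclusions <- list()
  keep <- logical(ncol(ct))
  for (idx in groups) {
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
      next
    }
    i1 <- idx[1L]; i2 <- idx[2L]
    slope <- .replicate_slope(ct[, i1], ct[, i2])
    if (!is.na(slope) && slope >= band[1L] && slope <= band[2L]) {
      merged <- rowMeans(ct[, c(i1, i2)], na.rm = TRUE)
      merged[is.nan(merged)] <- NA_real_
      ct[, i1] <- merged
      keep[i1] <- TRUE
      merges[[length(merges) + 1L]] <-
        list(kept = colnames(ct)[i1], merged_with = colnames(ct)[i2],
             slope = slope)
    } else {
      n1 <- sum(!is.na(ct[, i1])); n2 <- sum(!is.na(ct[, i2]))
      win <- if (n2 > n1) i2 else i1
      keep[win] <- TRUE
      exclusions[[length(exclusions) + 1L]] <-
        list(kept = colnames(ct)[win],
             excluded = colnames(ct)[setdiff(c(i1, i2), win)],
             slope = slope)
    }
  }
  out <- qpcr[, keep]
  assays(out)$ct <- ct[, keep, drop = FALSE]
  .append_qc(out, "replicates",
             list(band = band, merges = merges, exclusions = exclusions))
}

.organ_split <- function(qpcr) {
  split(seq_len(ncol(qpcr)), as.character(colData(qpcr)$organ))
}

#' Median-reference delta-Ct normalization
#'
#' Within each organ partition, the per-sample reference is the median Ct of
#' the organ's robust genes (genes with present fraction above
#' \code{robustMinPresent} within that organ), and
#' \eqn{\Delta Ct_{g,s} = Ct_{g,s} - \mathrm{median}_{robust}(Ct_{\cdot,s})}.
#' Missing entries propagate. The per-organ robust gene subsets are recorded
#' in the QC report.
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param robustMinPresent robust-gene present-fraction cutoff (strict
#'   \code{>}), default 0.6.
#' @return the \linkS4class{QpcrSet} with assay \code{"dct"} added.
#' @export
deltaCt <- function(qpcr, robustMinPresent = 0.6) {
  ct <- assay(qpcr, "ct")
  dct <- matrix(NA_real_, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  refs <- list()
  for (org in names(.organ_split(qpcr))) {
    idx <- .organ_split(qpcr)[[org]]
    sub <- ct[, idx, drop = FALSE]
    robust <- rownames(sub)[.present_fraction(sub, 1L) > robustMinPresent]
    if (length(robust) == 0)
      stop("no reference subset: organ '", org,
           "' has no genes above present fraction ", robustMinPresent)
    ref <- apply(sub[robust, , drop = FALSE], 2L, median, na.rm = TRUE)
    dct[, idx] <- sweep(sub, 2L, ref, "-")
    refs[[org]] <- robust
  }
  assays(qpcr, withDimnames = FALSE)$dct <- dct
  .append_qc(qpcr, "reference",
             list(robustMinPresent = robustMinPresent, robustGenes = refs))
}

#' Cross-sample median centering (-ddCt)
#'
#' Rescales delta-Ct values to \eqn{-\Delta\Delta Ct}: within each organ,
#' each gene is centered by its median over present samples and negated, so
#' positive values mean above-median (higher) expression. Genes present in
#' fewer than 2 samples of an organ are set missing and logged.
#'
#' @param qpcr a \linkS4class{QpcrSet} carrying assay \code{"dct"}.
#' @return the \linkS4class{QpcrSet} with assay \code{"nddct"} added.
#' @export
negDeltaDeltaCt <- function(qpcr) {
  if (!"dct" %in% assayNames(qpcr))
    stop("run deltaCt() first: assay 'dct' not found")
  dct <- assay(qpcr, "dct")
  nddct <- matrix(NA_real_, nrow(dct), ncol(dct), dimnames = dimnames(dct))
  sparse_genes <- list()
  for (org in names(.organ_split(qpcr))) {
    idx <- .organ_split(qpcr)[[org]]
    sub <- dct[, idx, drop = FALSE]
    n_present <- rowSums(!is.na(sub))
    med <- apply(sub, 1L, median, na.rm = TRUE)
    centered <- -sweep(sub, 1L, med, "-")
    centered[n_present < 2L, ] <- NA_real_
    nddct[, idx] <- centered
    if (any(n_present < 2L))
      sparse_genes[[org]] <- rownames(sub)[n_present < 2L]
  }
  assays(qpcr, withDimnames = FALSE)$nddct <- nddct
  .append_qc(qpcr, "centering", list(tooSparseGenes = sparse_genes))
}

#' Full QC + normalization pipeline
#'
#' Convenience wrapper: [filterLowData()] then [mergeChipReplicates()] then
#' [deltaCt()] then [negDeltaDeltaCt()].
#'
#' @param qpcr a \linkS4class{QpcrSet} with raw Ct values.
#' @param minPresent present-fraction QC cutoff.
#' @param band replicate agreement band.
#' @param robustMinPresent robust reference-gene cutoff.
#' @return a normalized \linkS4class{QpcrSet} with assays \code{ct},
#'   \code{dct}, \code{nddct} and a full QC report in
#'   \code{qcReport(x)}.
#' @export
normalizeQpcr <- function(qpcr, minPresent = 0.6, band = c(0.85, 1.15),
                          robustMinPresent = 0.6) {
  qpcr <- filterLowData(qpcr, minPresent = minPresent)
  qpcr <- mergeChipReplicates(qpcr, band = band)
  qpcr <- deltaCt(qpcr, robustMinPresent = robustMinPresent)
  negDeltaDeltaCt(qpcr)
}

#' Rank reference-gene stability
#'
#' Pairwise-variation stability ranking in the spirit of geNorm: for each
#' candidate gene, the stability score is the mean over partner genes of the
#' standard deviation across samples of the pairwise Ct difference (Ct is
#' already a log2 quantity, so differences are log-ratios). Lower scores are
#' more stable. Used to document the choice of the median-vector reference;
#' requires at least three candidates fully observed in the selected
#' partition.
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param organ optional organ label restricting the partition; default all
#'   samples.
#' @return data.frame with columns \code{gene}, \code{stability}, ascending
#'   by score.
#' @export
rankReferenceStability <- function(qpcr, organ = NULL) {
  ct <- assay(qpcr, "ct")
  if (!is.null(organ))
    ct <- ct[, colData(qpcr)$organ == organ, drop = FALSE]
  full <- rownames(ct)[rowSums(is.na(ct)) == 0L]
  if (length(full) < 3L)
    stop("insufficient candidates: need >= 3 fully observed genes, have ",
         length(full))
  m <- ct[full, , drop = FALSE]
  score <- vapply(seq_along(full), function(j) {
    partners <- setdiff(seq_along(full), j)
    mean(vapply(partners,
                function(k) sd(m[j, ] - m[k, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = full, stability = score)
  out[order(out$stability, out$gene), , drop = FALSE]
}
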