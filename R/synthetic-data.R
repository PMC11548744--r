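#' @importFrom stats rnorm runif median sd setNames
NULL

## Run expr with a locally seeded RNG, restoring global RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

.rlaplace <- function(n, scale) {
  u <- runif(n, -0.5, 0.5)
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Construct a study design
#'
#' @param organs character vector of organ labels.
#' @param strains character vector of strain labels.
#' @param agesWeeks strictly increasing ages in weeks.
#' @param replicatesPerCell animals per (strain, organ, age) cell.
#' @param genes character vector of gene labels, or a data.frame/DataFrame
#'   with columns \code{gene} and \code{pathway}.
#' @param sex cohort sex, \code{"F"} or \code{"M"}.
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- studyDesign(organs = c("adrenal", "kidney"), strains = c("SHR", "WKY"),
#'                  agesWeeks = c(8, 12, 16), replicatesPerCell = 3,
#'                  genes = c("Th", "Ren", "Il1b"))
#' d
#' @export
studyDesign <- function(organs, strains, agesWeeks, replicatesPerCell = 3L,
                        genes, sex = "F") {
  if (is.character(genes))
    genes <- DataFrame(gene = genes, pathway = rep("other", length(genes)))
  else
    genes <- as(as.data.frame(genes), "DataFrame")
  new("StudyDesign", organs = organs, strains = strains,
      agesWeeks = as.numeric(agesWeeks),
      replicatesPerCell = as.integer(replicatesPerCell),
      genes = genes, sex = sex)
}

#' Default gene panel
#'
#' A 96-assay panel patterned on multi-pathway hypertension profiling:
#' named sympathetic/catecholaminergic, renin-angiotensin, inflammation,
#' metabolism and fibrosis genes, padded with synthetic placeholder assays
#' (\code{gXX}) to the requested size.
#'
#' @param n panel size (default 96, the capacity of a 96x96 dynamic array).
#' @return \code{DataFrame} with columns \code{gene}, \code{pathway}.
#' @export
defaultGenePanel <- function(n = 96L) {
  core <- rbind(
    data.frame(gene = c("Th", "Nts", "Adra1a", "Adra1b", "Adrb1", "Adrb2",
                        "Hcrtr1", "Npy", "Dbh", "Chga"),
               pathway = "sympathetic"),
    data.frame(gene = c("Ren", "Renbp", "Agt", "Ace", "Agtr1a", "Agtrap"),
               pathway = "RAS"),
    data.frame(gene = c("Il1b", "Il6", "Il10", "Il1rn", "Tnf", "Tlr3", "Tlr4",
                        "Bcl6", "Ccr1", "Ccr5", "Ccl5", "Ltb4r", "Hmgb1",
                        "Hif1a", "Ephx2", "Esr1", "Nfkb1", "Ptgs2"),
               pathway = "inflammation"),
    data.frame(gene = c("Cd36", "Arg2", "Cyp19a1", "Sod2", "Nos3", "Pparg",
                        "Lepr", "Insr"),
               pathway = "metabolism"),
    data.frame(gene = c("Tgfb1", "Thbs1", "Scx", "Col1a1", "Col3a1", "Mmp2",
                        "Mmp9", "Timp1", "Rhoa", "Apln", "Gja1", "Fn1"),
               pathway = "fibrosis")
  )
  if (n <= nrow(core)) return(as(core[seq_len(n), ], "DataFrame"))
  extra <- n - nrow(core)
  filler <- data.frame(gene = sprintf("g%02d", seq_len(extra)),
                       pathway = "other")
  as(rbind(core, filler), "DataFrame")
}

#' Default study design
#'
#' The factorial design of the emulated study: 2 strains (SHR, WKY) x 5 ages
#' (8, 10, 12, 16, 24 weeks) x 5 organs (adrenal, kidney, liver, lung,
#' spleen) x 3 female animals per cell, with a 96-gene panel -- 150 samples
#' and 14,400 measurements before QC. Brainstem autonomic regions (RVLM,
#' CVLM, NTS) can be appended via \code{brainstem = TRUE}.
#'
#' @param nGenes panel size.
#' @param brainstem include the three brainstem regions as additional organs.
#' @return a \linkS4class{StudyDesign}.
#' @export
defaultStudyDesign <- function(nGenes = 96L, brainstem = FALSE) {
  organs <- c("adrenal", "kidney", "liver", "lung", "spleen")
  if (brainstem) organs <- c(organs, "RVLM", "CVLM", "NTS")
  studyDesign(organs = organs, strains = c("SHR", "WKY"),
              agesWeeks = c(8, 10, 12, 16, 24), replicatesPerCell = 3L,
              genes = defaultGenePanel(nGenes), sex = "F")
}

#' Generate a sparse stable ground-truth network
#'
#' Draws a random sparse interaction matrix K over all (organ, gene) nodes of
#' a design. Off-diagonal support is chosen uniformly at random at the given
#' density; nonzero magnitudes are Laplace(0, \code{coeffScale}) distributed
#' (heavy-tailed, sparsity-realistic). The diagonal is set to
#' \code{stabilityBound - margin_i - sum(|off-diagonal|)} per row, with
#' per-node margins drawn from \code{marginRange}, which by Gershgorin's
#' theorem bounds every eigenvalue's real part by \code{stabilityBound}, so
#' trajectories of \eqn{dE/dt = K E} are bounded (decaying for a negative
#' bound).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param density fraction of off-diagonal entries that are nonzero.
#' @param coeffScale Laplace scale of nonzero coefficients (1/week).
#' @param stabilityBound upper bound on the spectral abscissa (1/week,
#'   usually negative).
#' @param marginRange range of per-node decay margins (1/week) added to the
#'   stabilizing diagonal. Distinct margins give every node a distinct
#'   relaxation rate; identical rates would make edge-free nodes evolve as
#'   exactly proportional exponentials, leaving the network structurally
#'   unidentifiable from its trajectories.
#' @param seed integer seed (reproducible draw).
#' @return an \linkS4class{InteractionNetwork} with generation diagnostics
#'   (density, edge count, spectral abscissa).
#' @examples
#' d <- studyDesign("adrenal", "SHR", c(8, 12, 16), 3, c("Th", "Ren"))
#' net <- generateGroundTruthNetwork(d, density = 1, seed = 1)
#' interactionMatrix(net)
#' @export
generateGroundTruthNetwork <- function(design, density = 0.05,
                                       coeffScale = 0.1,
                                       stabilityBound = -0.05,
                                       marginRange = c(0.02, 0.3),
                                       seed = NULL) {
  stopifnot(density >= 0, density <= 1, coeffScale > 0)
  nodeData <- DataFrame(
    organ = rep(organs(design), each = nrow(genePanel(design))),
    gene = rep(genePanel(design)$gene, times = length(organs(design)))
  )
  n <- nrow(nodeData)
  n_off <- n * (n - 1L)
  m <- round(density * n_off)
  if (density > 0 && m == 0)
    stop("empty network: density ", density, " yields no edges on ",
         n, " nodes")
  K <- matrix(0, n, n)
  .with_seed(seed, {
    if (m > 0) {
      off_idx <- which(row(K) != col(K))
      support <- sample(off_idx, m)
      K[support] <- .rlaplace(m, coeffScale)
    }
    margins <- runif(n, marginRange[1L], marginRange[2L])
    diag(K) <- stabilityBound - margins - rowSums(abs(K))
  })
  labels <- .node_labels(nodeData)
  dimnames(K) <- list(labels, labels)
  new("InteractionNetwork", K = K, nodeData = nodeData,
      diagnostics = list(
        kind = "ground_truth", density = density, nEdges = m,
        coeffScale = coeffScale, stabilityBound = stabilityBound,
        spectralAbscissa = max(Re(eigen(K, only.values = TRUE)$values)),
        seed = seed))
}

#' Simulate trajectories of a linear network
#'
#' Integrates \eqn{dE/dt = K E} from the state \code{E0} at the first grid
#' time, using the exact matrix-exponential propagator between consecutive
#' grid times (a single propagator reused on uniform grids).
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param tGrid increasing times (weeks); output states at these times.
#' @param E0 initial state, one value per node.
#' @param guard overflow guard; any state exceeding it in magnitude aborts
#'   with an "unstable simulation" error.
#' @return a \linkS4class{TrajectorySet}.
#' @examples
#' d <- studyDesign("adrenal", "SHR", c(8, 12, 16), 3, "Th")
#' net <- generateGroundTruthNetwork(d, density = 0, seed = 1)
#' tr <- simulateTrajectories(net, tGrid = 0:8, E0 = 1)
#' trajectoryMatrix(tr)
#' @export
simulateTrajectories <- function(network, tGrid, E0, guard = 1e6) {
  K <- interactionMatrix(network)
  n <- nrow(K)
  stopifnot(length(E0) == n, length(tGrid) >= 1, all(diff(tGrid) > 0))
  values <- matrix(NA_real_, n, length(tGrid),
                   dimnames = list(rownames(K), NULL))
  state <- as.numeric(E0)
  values[, 1L] <- state
  dts <- diff(tGrid)
  uniform <- length(dts) > 0 &&
    all(abs(dts - dts[1L]) < 1e-9 * max(dts[1L], 1))
  if (uniform && length(dts) > 0) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(K * dts[1L])))
    for (i in seq_along(dts)) {
      state <- P %*% state
      if (any(!is.finite(state)) || max(abs(state)) > guard)
        stop("unstable simulation: state exceeded guard at t = ",
             tGrid[i + 1L])
      values[, i + 1L] <- state
    }
  } else {
    for (i in seq_along(dts)) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(K * dts[i])))
      state <- P %*% state
      if (any(!is.finite(state)) || max(abs(state)) > guard)
        stop("unstable simulation: state exceeded guard at t = ",
             tGrid[i + 1L])
      values[, i + 1L] <- state
    }
  }
  new("TrajectorySet", values = values, times = as.numeric(tGrid),
      nodeData = network@nodeData,
      scaling = DataFrame(min = numeric(0), max = numeric(0)))
}

#' Sample a replicated Ct-scale dataset from trajectories
#'
#' Emulates a high-throughput qPCR readout of the given noiseless
#' trajectories under the factorial study design: for every
#' (strain, organ, age, animal) cell a sample is drawn with
#' \code{Ct = ctOffset - log2(expression)} plus Gaussian replicate noise on
#' the Ct (cycle) scale; a fraction of reactions is set missing; a fraction
#' of samples is duplicated on a second chip with independent noise.
#'
#' With \code{trajScale = "log2"} (the default) the trajectory state is the
#' log2-scale relative expression -- the same quantity the downstream
#' normalization recovers and the network model is fitted on -- so
#' expression is \code{2^E} and \code{Ct = ctOffset - E} exactly. With
#' \code{trajScale = "linear"} the state is linear-scale expression;
#' nonpositive values are clipped to \code{exprFloor} before the log (with
#' a warning), keeping Ct finite.
#'
#' Trajectory times are matched to design ages as \code{age - min(age)}, so
#' the trajectory grid must contain every design age offset.
#'
#' @param traj \linkS4class{TrajectorySet} of noiseless expression (nodes =
#'   design organs x genes).
#' @param design \linkS4class{StudyDesign}.
#' @param ctOffset Ct of unit expression (cycles).
#' @param noiseSd replicate noise SD on the Ct scale (cycles).
#' @param missingRate fraction of reactions set missing at random.
#' @param chipReplicateFraction fraction of samples duplicated as
#'   second-chip technical replicates.
#' @param trajScale \code{"log2"} (trajectory state = log2 relative
#'   expression) or \code{"linear"} (state = linear expression).
#' @param exprFloor positive floor applied to linear expression before log2.
#' @param seed integer seed.
#' @return a \linkS4class{QpcrSet} (assay \code{"ct"}).
#' @seealso [simulateStudyDataset()] for the one-call generator.
#' @export
sampleQpcrDataset <- function(traj, design, ctOffset = 25, noiseSd = 0.15,
                              missingRate = 0, chipReplicateFraction = 0,
                              trajScale = c("log2", "linear"),
                              exprFloor = 1e-6, seed = NULL) {
  trajScale <- match.arg(trajScale)
  stopifnot(noiseSd >= 0, missingRate >= 0, missingRate < 1,
            chipReplicateFraction >= 0, chipReplicateFraction <= 1)
  ages <- agesWeeks(design)
  t_off <- ages - min(ages)
  idx_t <- match(round(t_off, 9), round(trajectoryTimes(traj), 9))
  if (anyNA(idx_t))
    stop("trajectory grid lacks design ages (offsets ",
         paste(t_off[is.na(idx_t)], collapse = ", "), ")")
  genes <- genePanel(design)$gene
  node_lab <- nodeLabels(traj)

  grid <- expand.grid(animal = seq_len(design@replicatesPerCell),
                      age = ages, organ = organs(design),
                      strain = strains(design),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- DataFrame(
    strain = grid$strain, sex = design@sex, organ = grid$organ,
    age_weeks = grid$age,
    animal_id = sprintf("%s_%s_%02dw_a%d", grid$strain, grid$organ,
                        grid$age, grid$animal),
    chip_id = "chip1")
  sample_id <- sprintf("%s_c1", meta$animal_id)

  tv <- trajectoryMatrix(traj)
  if (trajScale == "linear") {
    n_clipped <- sum(tv[, idx_t] < exprFloor)
    if (n_clipped > 0)
      warning(n_clipped, " nonpositive expression value(s) clipped to ",
              "floor ", exprFloor, " before log2", call. = FALSE)
  }
  expected_ct <- function(organ, age) {
    nodes <- match(paste(organ, genes, sep = ":"), node_lab)
    E <- tv[nodes, idx_t[match(age, ages)]]
    if (trajScale == "log2") ctOffset - E
    else ctOffset - log2(pmax(E, exprFloor))
  }

  draw_ct <- function(i) {
    mu <- expected_ct(meta$organ[i], meta$age_weeks[i])
    if (noiseSd > 0) mu + rnorm(length(mu), 0, noiseSd) else mu
  }
  out <- .with_seed(seed, {
    base <- matrix(vapply(seq_len(nrow(meta)), draw_ct,
                          numeric(length(genes))),
                   nrow = length(genes))
    dimnames(base) <- list(genes, sample_id)
    if (missingRate > 0)
      base[runif(length(base)) < missingRate] <- NA_real_
    meta_all <- meta
    n_dup <- round(chipReplicateFraction * ncol(base))
    if (n_dup > 0) {
      dup_idx <- sample(ncol(base), n_dup)
      dup <- matrix(vapply(dup_idx, draw_ct, numeric(length(genes))),
                    nrow = length(genes))
      dimnames(dup) <- list(genes, sprintf("%s_c2", meta$animal_id[dup_idx]))
      if (missingRate > 0)
        dup[runif(length(dup)) < missingRate] <- NA_real_
      meta_dup <- meta[dup_idx, ]
      meta_dup$chip_id <- "chip2"
      meta_all <- rbind(meta, meta_dup)
      base <- cbind(base, dup)
    }
    list(ct = base, meta = meta_all)
  })
  rownames(out$meta) <- colnames(out$ct)
  QpcrSet(out$ct, out$meta)
}

#' Construct a QpcrSet from a Ct matrix and sample metadata
#'
#' @param ct gene x sample numeric matrix of Ct values (\code{NA} = failed
#'   reaction), with row and column names.
#' @param meta data.frame/DataFrame of per-sample factors with columns
#'   \code{strain}, \code{sex}, \code{organ}, \code{age_weeks},
#'   \code{animal_id}, \code{chip_id}; rows match the columns of \code{ct}.
#' @return a \linkS4class{QpcrSet}.
#' @export
QpcrSet <- function(ct, meta) {
  meta <- as(as.data.frame(meta), "DataFrame")
  se <- SummarizedExperiment(assays = list(ct = ct), colData = meta)
  new("QpcrSet", se)
}

#' Inject structured missingness into a QpcrSet
#'
#' Deterministically (given the seed) blanks a stated fraction of reactions
#' for targeted genes (across random samples) and targeted samples (across
#' the non-targeted genes), used to build QC fixtures in which specific genes
#' and samples fail the present-fraction filter.
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param genes gene labels to degrade.
#' @param samples sample labels to degrade.
#' @param geneMissingFrac fraction of samples blanked for each targeted gene.
#' @param sampleMissingFrac fraction of non-targeted genes blanked for each
#'   targeted sample.
#' @param seed integer seed.
#' @return the modified \linkS4class{QpcrSet}.
#' @export
injectStructuredMissingness <- function(qpcr, genes = character(0),
                                        samples = character(0),
                                        geneMissingFrac = 0.5,
                                        sampleMissingFrac = 0.5,
                                        seed = NULL) {
  ct <- assay(qpcr, "ct")
  .with_seed(seed, {
    for (g in genes) {
      idx <- sample(ncol(ct), ceiling(geneMissingFrac * ncol(ct)))
      ct[g, idx] <- NA_real_
    }
    other <- setdiff(rownames(ct), genes)
    for (s in samples) {
      idx <- sample(other, ceiling(sampleMissingFrac * length(other)))
      ct[idx, s] <- NA_real_
    }
  })
  assays(qpcr)$ct <- ct
  qpcr
}

#' One-call synthetic study generator
#'
#' Chains ground-truth network generation, forward simulation at the design
#' ages (initial states uniform on (0.2, 1) so downstream min-max scaling is
#' non-degenerate), and Ct-scale sampling into a complete synthetic dataset
#' carrying its own ground truth.
#'
#' @param design \linkS4class{StudyDesign} (default: the emulated study).
#' @param density,coeffScale,stabilityBound see
#'   [generateGroundTruthNetwork()].
#' @param ctOffset,noiseSd,missingRate,chipReplicateFraction,exprFloor see
#'   [sampleQpcrDataset()].
#' @param seed integer master seed; sub-draws (network, initial state,
#'   noise) are derived from it.
#' @return a \linkS4class{SyntheticQpcrDataset}.
#' @examples
#' ds <- simulateStudyDataset(defaultStudyDesign(nGenes = 8), seed = 1)
#' ds
#' @export
simulateStudyDataset <- function(design = defaultStudyDesign(),
                                 density = 0.05, coeffScale = 0.1,
                                 stabilityBound = -0.05, ctOffset = 25,
                                 noiseSd = 0.15, missingRate = 0,
                                 chipReplicateFraction = 0,
                                 exprFloor = 1e-6, seed = 1L) {
  seeds <- deriveStageSeeds(seed, c("network", "init", "sampling"))
  net <- generateGroundTruthNetwork(design, density = density,
                                    coeffScale = coeffScale,
                                    stabilityBound = stabilityBound,
                                    seed = seeds[["network"]])
  n <- nrow(interactionMatrix(net))
  E0 <- .with_seed(seeds[["init"]], runif(n, 0.2, 1.0))
  tGrid <- agesWeeks(design) - min(agesWeeks(design))
  traj <- simulateTrajectories(net, tGrid, E0)
  qpcr <- sampleQpcrDataset(traj, design, ctOffset = ctOffset,
                            noiseSd = noiseSd, missingRate = missingRate,
                            chipReplicateFraction = chipReplicateFraction,
                            exprFloor = exprFloor,
                            seed = seeds[["sampling"]])
  new("SyntheticQpcrDataset", qpcr = qpcr, design = design, truth = net,
      trueTrajectories = traj, seed = as.integer(seed))
}

#' Synthetic fixture mirroring the study's QC arithmetic
#'
#' Builds the full factorial dataset (150 samples x 96 genes = 14,400
#' reactions) and then injects structured missingness so that exactly 4
#' genes and 4 samples fail the 60% present-fraction filter, leaving a
#' 92-gene x 146-sample matrix after QC. Entirely synthetic: the counts are
#' reproduced by construction, not by re-deriving the deposited data.
#'
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticQpcrDataset} whose \code{qpcr} slot has
#'   the structured missingness applied.
#' @export
studyMimicDataset <- function(seed = 1L) {
  ds <- simulateStudyDataset(defaultStudyDesign(), seed = seed)
  genes <- as.character(genePanel(ds@design)$gene)
  samp <- colnames(ds@qpcr)
  seeds <- deriveStageSeeds(seed, c("targets", "inject"))
  tg <- .with_seed(seeds[["targets"]], list(
    genes = sample(genes, 4),
    samples = sample(samp, 4)))
  ds@qpcr <- injectStructuredMissingness(
    ds@qpcr, genes = tg$genes, samples = tg$samples,
    geneMissingFrac = 0.5, sampleMissingFrac = 0.45,
    seed = seeds[["inject"]])
  ds
}
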