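#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assayNames
NULL

#' Factorial study design for a multi-organ qPCR time course
#'
#' Describes the sampling design of a multi-organ expression study: which
#' organs and strains are profiled, at which ages (weeks), with how many
#' animals per (strain, organ, age) cell, and the gene panel with its pathway
#' annotation (inflammation, RAS, sympathetic, metabolism, fibrosis, other).
#'
#' @slot organs character vector of organ labels.
#' @slot strains character vector of strain labels (e.g. \code{"SHR"},
#'   \code{"WKY"}).
#' @slot agesWeeks strictly increasing numeric vector of sampling ages in
#'   weeks.
#' @slot replicatesPerCell integer, animals per (strain, organ, age) cell.
#' @slot genes \code{DataFrame} with columns \code{gene} (unique labels) and
#'   \code{pathway}.
#' @slot sex single character, sex of the cohort (\code{"F"} or \code{"M"}).
#'
#' @seealso [studyDesign()] for the user-facing constructor and
#'   [defaultStudyDesign()] for the design mirroring the hypertensive-rat
#'   study (2 strains x 5 ages x 5 organs x 3 animals, 96 genes).
#' @export
setClass("StudyDesign",
  representation(
    organs = "character",
    strains = "character",
    agesWeeks = "numeric",
    replicatesPerCell = "integer",
    genes = "DataFrame",
    sex = "character"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- NULL
  if (length(object@agesWeeks) < 1 || any(diff(object@agesWeeks) <= 0))
    msg <- c(msg, "agesWeeks must be non-empty and strictly increasing")
  if (object@replicatesPerCell < 1L)
    msg <- c(msg, "replicatesPerCell must be >= 1")
  if (!all(c("gene", "pathway") %in% colnames(object@genes)))
    msg <- c(msg, "genes must have columns 'gene' and 'pathway'")
  else if (anyDuplicated(object@genes$gene))
    msg <- c(msg, "gene labels must be unique")
  if (length(object@organs) < 1 || anyDuplicated(object@organs))
    msg <- c(msg, "organs must be non-empty and unique")
  if (length(object@strains) < 1 || anyDuplicated(object@strains))
    msg <- c(msg, "strains must be non-empty and unique")
  if (is.null(msg)) TRUE else msg
})

#' qPCR expression container
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a gene x sample
#' matrix of qPCR measurements. The raw assay is \code{"ct"} (quantification
#' cycles, \code{NA} = failed reaction); normalization adds assays
#' \code{"dct"} (median-reference delta-Ct) and \code{"nddct"}
#' (\eqn{-\Delta\Delta Ct}, log2-scale relative expression). Sample factors
#' (strain, sex, organ, age_weeks, animal_id, chip_id) live in
#' \code{colData}; QC provenance (removed genes/samples, replicate merges,
#' per-organ reference gene subsets) accumulates in \code{metadata()$qc}.
#'
#' @seealso [QpcrSet()], [filterLowData()], [normalizeQpcr()]
#' @export
setClass("QpcrSet", contains = "SummarizedExperiment")

.qpcr_required_cols <- c("strain", "sex", "organ", "age_weeks",
                         "animal_id", "chip_id")

setValidity("QpcrSet", function(object) {
  msg <- NULL
  if (!"ct" %in% assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  missing_cols <- setdiff(.qpcr_required_cols, colnames(colData(object)))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene labels must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample labels must be unique")
  if ("ct" %in% assayNames(object) &&
      any(is.infinite(assay(object, "ct"))))
    msg <- c(msg, "Ct values must be finite where present")
  if (is.null(msg)) TRUE else msg
})

#' Per-node expression trajectories
#'
#' Expression of each network node -- an (organ, gene) pair -- as a function
#' of time: replicate means at the sampled ages, spline-interpolated dense
#' grids, or forward simulations of a fitted model. Values are stored as a
#' node x time matrix.
#'
#' @slot values numeric matrix, nodes x times; rownames are
#'   \code{"organ:gene"} labels.
#' @slot times numeric vector of times in weeks (increasing).
#' @slot nodeData \code{DataFrame} with columns \code{organ} and \code{gene},
#'   one row per node.
#' @slot scaling \code{DataFrame} with per-node \code{min} and \code{max} used
#'   by min-max scaling (zero rows when unscaled).
#' @export
setClass("TrajectorySet",
  representation(
    values = "matrix",
    times = "numeric",
    nodeData = "DataFrame",
    scaling = "DataFrame"
  )
)

setValidity("TrajectorySet", function(object) {
  msg <- NULL
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "ncol(values) must equal length(times)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@values) != nrow(object@nodeData))
    msg <- c(msg, "nodeData must have one row per node")
  if (!all(c("organ", "gene") %in% colnames(object@nodeData)))
    msg <- c(msg, "nodeData needs columns 'organ' and 'gene'")
  if (is.null(msg)) TRUE else msg
})

#' Interaction matrix of a linear gene regulatory network
#'
#' The square matrix K of the continuous-time linear model
#' \eqn{dE/dt = K E}, where entry K[target, regulator] is the interaction
#' coefficient (1/week) with which the regulator node drives the rate of
#' change of the target node. Nodes are (organ, gene) pairs. For fitted
#' networks, \code{diagnostics} records the penalty grid, the whole-model
#' simulation RMSE per penalty, and the selected penalty; for generated
#' ground-truth networks it records density and stability information.
#'
#' @slot K numeric node x node matrix (rows = targets, columns = regulators).
#' @slot nodeData \code{DataFrame} with columns \code{organ}, \code{gene}.
#' @slot diagnostics list of fit or generation diagnostics.
#' @seealso [estimateNetwork()], [generateGroundTruthNetwork()]
#' @export
setClass("InteractionNetwork",
  representation(
    K = "matrix",
    nodeData = "DataFrame",
    diagnostics = "list"
  )
)

setValidity("InteractionNetwork", function(object) {
  msg <- NULL
  n <- nrow(object@nodeData)
  if (nrow(object@K) != n || ncol(object@K) != n)
    msg <- c(msg, "K must be square with one row/column per node")
  if (!all(c("organ", "gene") %in% colnames(object@nodeData)))
    msg <- c(msg, "nodeData needs columns 'organ' and 'gene'")
  if (is.null(msg)) TRUE else msg
})

#' Thresholded directed edge set
#'
#' Directed regulatory edges surviving a thresholding rule applied to an
#' \linkS4class{InteractionNetwork}: each edge runs from a regulator
#' (organ, gene) to a target (organ, gene) and carries the interaction
#' coefficient as weight. \code{provenance} records the rule and its
#' parameters.
#'
#' @slot edges data.frame with columns \code{src_organ}, \code{src_gene},
#'   \code{dst_organ}, \code{dst_gene}, \code{weight}, \code{sign}.
#' @slot provenance list describing the generating threshold rule.
#' @seealso [thresholdBySd()], [thresholdByMaxFraction()], [exportNetwork()]
#' @export
setClass("NetworkEdgeSet",
  representation(edges = "data.frame", provenance = "list")
)

.edge_cols <- c("src_organ", "src_gene", "dst_organ", "dst_gene",
                "weight", "sign")

setValidity("NetworkEdgeSet", function(object) {
  msg <- NULL
  if (!all(.edge_cols %in% colnames(object@edges)))
    msg <- c(msg, paste0("edges must have columns: ",
                         paste(.edge_cols, collapse = ", ")))
  else {
    key <- paste(object@edges$src_organ, object@edges$src_gene,
                 object@edges$dst_organ, object@edges$dst_gene)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (regulator, target) pairs")
  }
  if (is.null(msg)) TRUE else msg
})

#' Synthetic multi-organ qPCR dataset with known ground truth
#'
#' Bundles a simulated Ct-scale dataset (with the factorial study design,
#' replicate noise, missing reactions and duplicate-chip replicates) together
#' with the sparse stable network and noiseless trajectories it was generated
#' from, so downstream stages can be validated against ground truth.
#'
#' @slot qpcr \linkS4class{QpcrSet} of simulated Ct values.
#' @slot design \linkS4class{StudyDesign} used for generation.
#' @slot truth \linkS4class{InteractionNetwork}, the generating network.
#' @slot trueTrajectories \linkS4class{TrajectorySet}, noiseless node
#'   trajectories at the design ages.
#' @slot seed integer seed the dataset was generated under.
#' @seealso [sampleQpcrDataset()]
#' @export
setClass("SyntheticQpcrDataset",
  representation(
    qpcr = "QpcrSet",
    design = "StudyDesign",
    truth = "InteractionNetwork",
    trueTrajectories = "TrajectorySet",
    seed = "integer"
  )
)
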