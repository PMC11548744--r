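#' Accessors for HartleyNet classes
#'
#' Small accessor layer: \code{interactionMatrix} returns the K matrix of an
#' \linkS4class{InteractionNetwork}; \code{nodeInfo} the per-node
#' (organ, gene) \code{DataFrame}; \code{nodeLabels} the \code{"organ:gene"}
#' labels; \code{edgeTable} the edge data.frame of a
#' \linkS4class{NetworkEdgeSet}; \code{trajectoryMatrix} /
#' \code{trajectoryTimes} the value matrix and time grid of a
#' \linkS4class{TrajectorySet}; \code{fitDiagnostics} the fit diagnostics
#' list; \code{organs}, \code{strains}, \code{agesWeeks}, \code{genePanel}
#' the \linkS4class{StudyDesign} components; \code{qcReport} the accumulated
#' QC provenance of a \linkS4class{QpcrSet}.
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#' @name accessors
#' @aliases interactionMatrix nodeInfo nodeLabels edgeTable trajectoryMatrix
#'   trajectoryTimes fitDiagnostics organs strains agesWeeks genePanel
#'   qcReport
NULL

.node_labels <- function(nodeData) {
  paste(nodeData$organ, nodeData$gene, sep = ":")
}

#' @rdname accessors
#' @export
setMethod("interactionMatrix", "InteractionNetwork", function(x) x@K)

#' @rdname accessors
#' @export
setMethod("nodeInfo", "InteractionNetwork", function(x) x@nodeData)

#' @rdname accessors
#' @export
setMethod("nodeInfo", "TrajectorySet", function(x) x@nodeData)

#' @rdname accessors
#' @export
setMethod("nodeLabels", "InteractionNetwork",
          function(x) .node_labels(x@nodeData))

#' @rdname accessors
#' @export
setMethod("nodeLabels", "TrajectorySet",
          function(x) .node_labels(x@nodeData))

#' @rdname accessors
#' @export
setMethod("edgeTable", "NetworkEdgeSet", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("trajectoryMatrix", "TrajectorySet", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trajectoryTimes", "TrajectorySet", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("fitDiagnostics", "InteractionNetwork", function(x) x@diagnostics)

#' @rdname accessors
#' @export
setMethod("organs", "StudyDesign", function(x) x@organs)

#' @rdname accessors
#' @export
setMethod("strains", "StudyDesign", function(x) x@strains)

#' @rdname accessors
#' @export
setMethod("agesWeeks", "StudyDesign", function(x) x@agesWeeks)

#' @rdname accessors
#' @export
setMethod("genePanel", "StudyDesign", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("qcReport", "QpcrSet", function(x) {
  qc <- metadata(x)$qc
  if (is.null(qc)) list() else qc
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@strains), "strain(s) x",
      length(object@agesWeeks), "age(s) x", length(object@organs),
      "organ(s) x", object@replicatesPerCell, "animal(s),",
      nrow(object@genes), "genes, sex =", object@sex, "\n")
  cat("  ages (weeks):", paste(object@agesWeeks, collapse = ", "), "\n")
  cat("  organs:", paste(object@organs, collapse = ", "), "\n")
})

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", nrow(object@values), "node(s) x",
      length(object@times), "time(s) over [",
      min(object@times), ",", max(object@times), "] weeks",
      if (nrow(object@scaling)) "(min-max scaled)" else "", "\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  n <- nrow(object@K)
  nz <- sum(object@K[row(object@K) != col(object@K)] != 0)
  cat("InteractionNetwork:", n, "node(s) (",
      length(unique(object@nodeData$organ)), "organ(s) x",
      length(unique(object@nodeData$gene)), "gene(s) ),",
      nz, "nonzero off-diagonal coefficient(s)\n")
  if (!is.null(object@diagnostics$selectedPenalty))
    cat("  selected penalty:", object@diagnostics$selectedPenalty,
        " simulation RMSE:", object@diagnostics$selectedRmse, "\n")
})

setMethod("show", "NetworkEdgeSet", function(object) {
  cat("NetworkEdgeSet:", nrow(object@edges), "directed edge(s)")
  if (!is.null(object@provenance$rule))
    cat(" [rule:", object@provenance$rule, "]")
  cat("\n")
})

setMethod("show", "SyntheticQpcrDataset", function(object) {
  cat("SyntheticQpcrDataset (seed ", object@seed, ")\n", sep = "")
  cat("  qpcr: ", nrow(object@qpcr), " genes x ", ncol(object@qpcr),
      " samples\n", sep = "")
  cat("  truth: ", nrow(object@truth@K), " node network\n", sep = "")
})
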