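#' @importFrom utils read.csv write.csv
#' @importFrom jsonlite write_json read_json
NULL

#' Read a long-format Ct table and sample metadata
#'
#' The long Ct table has columns \code{sample_id}, \code{gene}, \code{Ct}
#' (empty/NA = failed reaction); the metadata table has one row per sample
#' with columns \code{sample_id}, \code{strain}, \code{sex}, \code{organ},
#' \code{age_weeks}, \code{animal_id}, \code{chip_id}.
#'
#' @param ctPath path to the long-format Ct CSV.
#' @param metaPath path to the metadata CSV.
#' @return a \linkS4class{QpcrSet}.
#' @export
readQpcrTables <- function(ctPath, metaPath) {
  long <- read.csv(ctPath, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "gene", "Ct") %in% colnames(long)))
  meta <- read.csv(metaPath, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% colnames(meta))
  genes <- unique(long$gene)
  samples <- meta$sample_id
  ct <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  ct[cbind(match(long$gene, genes), match(long$sample_id, samples))] <-
    long$Ct
  rownames(meta) <- meta$sample_id
  QpcrSet(ct, meta[, setdiff(colnames(meta), "sample_id"), drop = FALSE])
}

#' Write a QpcrSet as long-format Ct + metadata CSVs
#'
#' @param qpcr a \linkS4class{QpcrSet}.
#' @param ctPath,metaPath output paths.
#' @return invisibly, the two paths.
#' @export
writeQpcrTables <- function(qpcr, ctPath, metaPath) {
  ct <- assay(qpcr, "ct")
  long <- data.frame(
    sample_id = rep(colnames(ct), each = nrow(ct)),
    gene = rep(rownames(ct), times = ncol(ct)),
    Ct = as.vector(ct))
  write.csv(long, ctPath, row.names = FALSE)
  meta <- as.data.frame(colData(qpcr))
  meta <- cbind(sample_id = rownames(meta), meta)
  write.csv(meta, metaPath, row.names = FALSE)
  invisible(c(ctPath, metaPath))
}

#' Write per-organ normalized matrices
#'
#' One CSV per organ (genes x samples, header row of sample ids) of the
#' requested assay.
#'
#' @param qpcr a normalized \linkS4class{QpcrSet}.
#' @param dir output directory (created if needed).
#' @param assayName assay to write.
#' @return invisibly, the written paths.
#' @export
writeNormalizedMatrices <- function(qpcr, dir, assayName = "nddct") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  x <- assay(qpcr, assayName)
  paths <- character(0)
  for (org in unique(as.character(colData(qpcr)$organ))) {
    idx <- colData(qpcr)$organ == org
    p <- file.path(dir, paste0(assayName, "_", org, ".csv"))
    write.csv(x[, idx, drop = FALSE], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the QC report as JSON
#'
#' @param qpcr a \linkS4class{QpcrSet} that has been through QC.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeQcReport <- function(qpcr, path) {
  write_json(qcReport(qpcr), path, auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(path)
}

#' Write / read a labeled interaction matrix CSV
#'
#' Rows are targets, columns regulators, both labeled \code{organ:gene}.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path CSV path.
#' @return invisibly the path (write); an
#'   \linkS4class{InteractionNetwork} (read).
#' @export
writeInteractionMatrix <- function(net, path) {
  write.csv(interactionMatrix(net), path)
  invisible(path)
}

#' @rdname writeInteractionMatrix
#' @export
readInteractionMatrix <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
  labels <- rownames(m)
  nodeData <- DataFrame(organ = sub(":.*$", "", labels),
                        gene = sub("^[^:]*:", "", labels))
  new("InteractionNetwork", K = m, nodeData = nodeData,
      diagnostics = list(kind = "imported", path = path))
}
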