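#' @importFrom utils write.table read.delim
#' @importFrom igraph graph_from_data_frame write_graph read_graph
#'   as_data_frame vertex_attr
NULL

.edge_set <- function(net, idx, rule, params) {
  K <- interactionMatrix(net)
  nd <- nodeInfo(net)
  ri <- row(K)[idx]   # row = target
  ci <- col(K)[idx]   # column = regulator
  w <- K[idx]
  edges <- data.frame(
    src_organ = as.character(nd$organ[ci]),
    src_gene = as.character(nd$gene[ci]),
    dst_organ = as.character(nd$organ[ri]),
    dst_gene = as.character(nd$gene[ri]),
    weight = w,
    sign = sign(w))
  new("NetworkEdgeSet", edges = edges,
      provenance = c(list(rule = rule), params))
}

#' Threshold interaction coefficients by standard deviations from the mean
#'
#' Keeps the coefficients lying more than \code{factor} standard deviations
#' from the mean, where mean and SD are computed over all entries of the
#' matrix (elastic-net zeros included; set \code{population = "nonzero"} to
#' restrict the reference population to nonzero entries).
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param factor SD multiplier (default 2).
#' @param population \code{"all"} or \code{"nonzero"}.
#' @return a \linkS4class{NetworkEdgeSet} (empty, with a warning, when the
#'   SD is zero).
#' @export
thresholdBySd <- function(net, factor = 2, population = c("all", "nonzero")) {
  population <- match.arg(population)
  K <- interactionMatrix(net)
  if (length(K) == 0) stop("empty interaction matrix")
  pop <- if (population == "all") as.numeric(K) else K[K != 0]
  mu <- mean(pop)
  s <- sd(pop)
  params <- list(factor = factor, population = population,
                 mean = mu, sd = s)
  if (!is.finite(s) || s == 0) {
    warning("zero SD of interaction coefficients; empty edge set")
    return(.edge_set(net, integer(0), "sd_from_mean", params))
  }
  idx <- which(abs(K - mu) > factor * s)
  .edge_set(net, idx, "sd_from_mean", params)
}

#' Threshold by fraction of the maximum coefficient magnitude
#'
#' Within the scope (optionally restricted to blocks between given organs),
#' keeps coefficients with \eqn{|k| > frac \cdot \max|k|}.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param frac fraction of the maximum magnitude, in (0, 1).
#' @param scopeOrgans optional organ labels; both regulator and target must
#'   belong to them (e.g. \code{c("adrenal", "kidney")} for the
#'   adrenal-kidney block).
#' @return a \linkS4class{NetworkEdgeSet}.
#' @export
thresholdByMaxFraction <- function(net, frac, scopeOrgans = NULL) {
  stopifnot(frac > 0, frac < 1)
  K <- interactionMatrix(net)
  nd <- nodeInfo(net)
  in_scope <- matrix(TRUE, nrow(K), ncol(K))
  if (!is.null(scopeOrgans)) {
    node_in <- nd$organ %in% scopeOrgans
    in_scope <- outer(node_in, node_in, "&")
  }
  if (!any(in_scope)) stop("empty scope")
  vals <- abs(K)[in_scope]
  cutoff <- frac * max(vals)
  idx <- which(in_scope & abs(K) > cutoff)
  .edge_set(net, idx, "max_fraction",
            list(frac = frac, scopeOrgans = scopeOrgans,
                 maxAbs = max(vals)))
}

#' Organ-level edge count matrix
#'
#' Entry (source organ, target organ) counts the edges from any gene of the
#' source organ to any gene of the target organ -- the edge weights of the
#' organ-level network diagram.
#'
#' @param edges a \linkS4class{NetworkEdgeSet}.
#' @param organLevels optional organ labels fixing the matrix dimensions.
#' @return integer matrix, source organs x target organs.
#' @export
organEdgeCounts <- function(edges, organLevels = NULL) {
  e <- edgeTable(edges)
  if (is.null(organLevels))
    organLevels <- sort(unique(c(e$src_organ, e$dst_organ)))
  out <- table(factor(e$src_organ, levels = organLevels),
               factor(e$dst_organ, levels = organLevels))
  m <- matrix(as.integer(out), nrow = length(organLevels),
              dimnames = list(source = organLevels, target = organLevels))
  m
}

#' Compare regulator gene sets of one organ across two networks
#'
#' The regulators of an organ are the genes of that organ appearing as edge
#' sources. Returns the three-way partition between two thresholded edge
#' sets (e.g. the hypertensive and control networks).
#'
#' @param edgesA,edgesB \linkS4class{NetworkEdgeSet} objects.
#' @param organ organ label.
#' @return list with gene vectors \code{onlyA}, \code{common}, \code{onlyB}
#'   and the integer vector \code{counts} (nOnlyA, nCommon, nOnlyB).
#' @export
regulatorSets <- function(edgesA, edgesB, organ) {
  regs <- function(es) {
    e <- edgeTable(es)
    unique(e$src_gene[e$src_organ == organ])
  }
  a <- regs(edgesA); b <- regs(edgesB)
  out <- list(onlyA = sort(setdiff(a, b)), common = sort(intersect(a, b)),
              onlyB = sort(setdiff(b, a)))
  out$counts <- c(onlyA = length(out$onlyA), common = length(out$common),
                  onlyB = length(out$onlyB))
  out
}

#' Order nodes by time of peak expression
#'
#' For each node of a simulated (or interpolated) trajectory set, finds the
#' time at which expression is maximal (first grid time on ties, so a
#' constant trajectory peaks at the window start) and sorts nodes by that
#' time, breaking ties by organ then gene label. This is the ordering used
#' to display the multi-organ activation cascade.
#'
#' @param traj a \linkS4class{TrajectorySet} on a common grid.
#' @return data.frame with \code{organ}, \code{gene}, \code{peakTime}
#'   (weeks), sorted ascending.
#' @export
peakOrder <- function(traj) {
  v <- trajectoryMatrix(traj)
  times <- trajectoryTimes(traj)
  peak <- times[apply(v, 1L, which.max)]
  nd <- nodeInfo(traj)
  out <- data.frame(organ = as.character(nd$organ),
                    gene = as.character(nd$gene),
                    peakTime = peak)
  out[order(out$peakTime, out$organ, out$gene), , drop = FALSE]
}

#' Export a thresholded network
#'
#' Writes the edge set as a tab-separated edge list (weights at 17
#' significant digits, so a read round-trip preserves them to full double
#' precision) or as GraphML with node attributes \code{organ} and
#' \code{gene} and edge attribute \code{weight}.
#'
#' @param edges a \linkS4class{NetworkEdgeSet}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @seealso [readNetworkEdges()]
#' @export
exportNetwork <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  e <- edgeTable(edges)
  if (format == "tsv") {
    out <- e
    out$weight <- sprintf("%.17g", out$weight)
    out$sign <- as.integer(out$sign)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    src <- paste(e$src_organ, e$src_gene, sep = ":")
    dst <- paste(e$dst_organ, e$dst_gene, sep = ":")
    nodes <- unique(c(src, dst))
    vdf <- data.frame(name = nodes,
                      organ = sub(":.*$", "", nodes),
                      gene = sub("^[^:]*:", "", nodes))
    g <- graph_from_data_frame(
      data.frame(from = src, to = dst, weight = e$weight),
      directed = TRUE, vertices = vdf)
    write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge set written by [exportNetwork()]
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @return a \linkS4class{NetworkEdgeSet}.
#' @export
readNetworkEdges <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    e <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(rep("character", 4L),
                                   "numeric", "integer"))
  } else {
    g <- read_graph(path, format = "graphml")
    ig <- igraph::as_data_frame(g, what = "both")
    v <- ig$vertices
    lookup <- function(name, col) v[[col]][match(name, v$name)]
    e <- data.frame(
      src_organ = lookup(ig$edges$from, "organ"),
      src_gene = lookup(ig$edges$from, "gene"),
      dst_organ = lookup(ig$edges$to, "organ"),
      dst_gene = lookup(ig$edges$to, "gene"),
      weight = ig$edges$weight,
      sign = sign(ig$edges$weight))
  }
  new("NetworkEdgeSet", edges = e,
      provenance = list(rule = "imported", path = path, format = format))
}
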