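#' @importFrom glmnet glmnet
NULL

#' Default configuration for network identification
#'
#' Tunables of the Hartley-modulating-function fit: basis size \code{M} = 8
#' and order \code{N} = 3 (M at least the number of sampled ages, N >= 3 so
#' basis functions vanish at the window ends to second order); dense grid of
#' 257 points; elastic-net mixing \code{l1Ratio} = 0.5 with a logarithmic
#' penalty grid over 1e-4..10 (20 points); simulation span 8-24 weeks.
#'
#' @param ... overrides for individual entries.
#' @return named list of configuration values.
#' @export
defaultHmfConfig <- function(...) {
  cfg <- list(M = 8L, N = 3L, nGrid = 257L, l1Ratio = 0.5,
              penaltyGrid = 10^seq(-4, 1, length.out = 20L),
              tSpan = c(8, 24), nOut = 101L)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

#' Replicate-mean trajectories per (organ, gene)
#'
#' Collapses a normalized dataset to one trajectory per network node for one
#' strain: the mean of present replicate values at each age. Nodes with
#' fewer than two ages observed are excluded (and reported via the
#' \code{"excluded"} attribute). The model describes group-level
#' trajectories; animals are cross-sectional, so replicate means (not
#' individual animals) feed the fit.
#'
#' @param qpcr a normalized \linkS4class{QpcrSet}.
#' @param strain strain label to extract.
#' @param assayName assay to summarize.
#' @return a \linkS4class{TrajectorySet} with times = sampled ages (weeks);
#'   missing (node, age) means are NA.
#' @export
summarizeReplicates <- function(qpcr, strain, assayName = "nddct") {
  x <- assay(qpcr, assayName)
  meta <- colData(qpcr)
  sel <- meta$strain == strain
  x <- x[, sel, drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  ages <- sort(unique(meta$age_weeks))
  orgs <- unique(as.character(meta$organ))
  nodeData <- DataFrame(organ = rep(orgs, each = nrow(x)),
                        gene = rep(rownames(x), times = length(orgs)))
  values <- matrix(NA_real_, nrow(nodeData), length(ages),
                   dimnames = list(.node_labels(nodeData), NULL))
  for (oi in seq_along(orgs)) {
    for (ai in seq_along(ages)) {
      idx <- meta$organ == orgs[oi] & meta$age_weeks == ages[ai]
      if (!any(idx)) next
      mu <- rowMeans(x[, idx, drop = FALSE], na.rm = TRUE)
      rows <- (oi - 1L) * nrow(x) + seq_len(nrow(x))
      values[rows, ai] <- ifelse(is.nan(mu), NA_real_, mu)
    }
  }
  n_ages <- rowSums(!is.na(values))
  keep <- n_ages >= 2L
  excluded <- rownames(values)[!keep]
  out <- new("TrajectorySet", values = values[keep, , drop = FALSE],
             times = as.numeric(ages),
             nodeData = nodeData[keep, , drop = FALSE],
             scaling = DataFrame(min = numeric(0), max = numeric(0)))
  attr(out, "excluded") <- excluded
  out
}

#' Assemble the modulating-function regression for one target node
#'
#' For target node \eqn{(r, g)}, the linear model projected onto the basis
#' reads \eqn{b_m = \sum_{(i,j)} A_{m,(i,j)} k_{ij}^{(rg)}} with
#' \eqn{b_m = \int \varphi_m \, dE_{rg}/dt \; dt} (the target's derivative
#' moments) and \eqn{A_{m,(i,j)} = \int \varphi_m E_{ij} \, dt} (every
#' candidate regulator's moments, the target itself included --
#' self-regulation is allowed).
#'
#' @param projections result of [projectTrajectory()] over all nodes.
#' @param target node label (\code{"organ:gene"}) or column index.
#' @return list with \code{A} (M x nodes), \code{b} (length M),
#'   \code{target}, \code{rank}, and logical flags \code{underdetermined}
#'   (M < nodes) and \code{rankDeficient}.
#' @export
assembleRegression <- function(projections, target) {
  A <- projections$moments
  if (is.character(target)) target <- match(target, colnames(A))
  stopifnot(!is.na(target), target >= 1, target <= ncol(A))
  b <- projections$derivativeMoments[, target]
  r <- qr(A)$rank
  list(A = A, b = b, target = colnames(A)[target], rank = r,
       underdetermined = nrow(A) < ncol(A),
       rankDeficient = r < min(dim(A)))
}

## Scalar elastic net (closed form) for single-regulator systems, matching
## the glmnet objective 1/(2n)||b - x beta||^2 + lambda(alpha|beta| +
## (1-alpha)/2 beta^2).
.enet_scalar <- function(x, b, alpha, lambda) {
  n <- length(b)
  rho <- sum(x * b) / n
  z <- sum(x * x) / n
  soft <- sign(rho) * pmax(abs(rho) - lambda * alpha, 0)
  soft / (z + lambda * (1 - alpha))
}

#' Elastic-net solution of one regression system over a penalty grid
#'
#' Solves the modulating-function regression of \code{b} on the columns of
#' \code{A} for every penalty in the grid, with columns scaled to unit root
#' mean square before penalization and coefficients returned on the
#' original scale. A penalty of exactly zero is solved by QR least squares,
#' so the zero-penalty fit is the ordinary least-squares solution on
#' well-posed systems. The procedure is deterministic.
#'
#' @param system result of [assembleRegression()].
#' @param l1Ratio elastic-net mixing (1 = lasso, 0 = ridge).
#' @param penaltyGrid non-empty numeric vector of penalties.
#' @return list with \code{coefficients} (nodes x penalties matrix) and
#'   \code{penaltyGrid}.
#' @export
fitElasticNet <- function(system, l1Ratio = 0.5,
                          penaltyGrid = defaultHmfConfig()$penaltyGrid) {
  stopifnot(length(penaltyGrid) >= 1)
  A <- system$A
  b <- system$b
  p <- ncol(A)
  scales <- sqrt(colMeans(A^2))
  live <- scales > 0
  coefs <- matrix(0, p, length(penaltyGrid),
                  dimnames = list(colnames(A), NULL))
  if (!any(live)) {
    warning("all-zero design for target ", system$target,
            "; returning zero coefficients")
    return(list(coefficients = coefs, penaltyGrid = penaltyGrid))
  }
  As <- sweep(A[, live, drop = FALSE], 2L, scales[live], "/")
  pos_pen <- penaltyGrid[penaltyGrid > 0]
  if (length(pos_pen) > 0) {
    if (ncol(As) >= 2L) {
      lam <- sort(unique(pos_pen), decreasing = TRUE)
      fit <- glmnet(As, b, family = "gaussian", alpha = l1Ratio,
                    lambda = lam, standardize = FALSE, intercept = FALSE,
                    thresh = 1e-12, maxit = 2e5)
      beta <- as.matrix(fit$beta)
      for (j in which(penaltyGrid > 0)) {
        col <- which.min(abs(fit$lambda - penaltyGrid[j]))
        coefs[live, j] <- beta[, col] / scales[live]
      }
    } else {
      for (j in which(penaltyGrid > 0))
        coefs[live, j] <- .enet_scalar(As[, 1L], b, l1Ratio,
                                       penaltyGrid[j]) / scales[live]
    }
  }
  zero_j <- which(penaltyGrid == 0)
  if (length(zero_j) > 0) {
    ls <- qr.coef(qr(As), b)
    ls[is.na(ls)] <- 0
    for (j in zero_j) coefs[live, j] <- ls / scales[live]
  }
  list(coefficients = coefs, penaltyGrid = penaltyGrid)
}

.traj_from_K <- function(K, nodeData, diagnostics = list()) {
  new("InteractionNetwork", K = K, nodeData = nodeData,
      diagnostics = diagnostics)
}

#' Identify the interaction matrix from trajectories
#'
#' Core of the network identification: (optionally min-max scaled)
#' trajectories are spline-interpolated onto a dense grid, projected onto
#' the Hartley modulating function basis, and each target node's coefficient
#' row is estimated by elastic-net regression over the penalty grid. The
#' winning penalty is the one whose assembled matrix, simulated forward
#' from the first observed state, has the lowest root-mean-square error
#' against the (scaled) data at the observed ages -- a single penalty chosen
#' jointly for the whole model, not per row.
#'
#' @param traj a \linkS4class{TrajectorySet} of per-node observations.
#' @param config list as from [defaultHmfConfig()].
#' @param rescale min-max scale nodes to (0, 1) first (set \code{FALSE} when
#'   the trajectories are already in model coordinates).
#' @return an \linkS4class{InteractionNetwork}; diagnostics carry the
#'   penalty grid, per-penalty simulation RMSE, selected penalty, and
#'   assembly flags.
#' @export
estimateNetworkFromTrajectories <- function(traj, config = defaultHmfConfig(),
                                            rescale = TRUE) {
  times <- trajectoryTimes(traj)
  if (length(times) < 3L) stop("need >= 3 distinct ages to fit")
  scaled <- if (rescale) minmaxScale(traj) else traj
  dense <- interpolateDense(scaled, nGrid = config$nGrid, clip = rescale)
  basis <- hmfBasis(M = config$M, N = config$N, T = diff(range(times)),
                    nGrid = config$nGrid)
  proj <- projectTrajectory(basis, dense)
  p <- nrow(trajectoryMatrix(scaled))
  L <- length(config$penaltyGrid)
  Ks <- array(0, dim = c(p, p, L))
  flags <- list()
  for (tg in seq_len(p)) {
    system <- assembleRegression(proj, tg)
    fit <- fitElasticNet(system, l1Ratio = config$l1Ratio,
                         penaltyGrid = config$penaltyGrid)
    Ks[tg, , ] <- fit$coefficients
    if (tg == 1L)
      flags <- list(underdetermined = system$underdetermined,
                    rank = system$rank)
  }
  obs <- trajectoryMatrix(scaled)
  labels <- rownames(obs)
  E0 <- obs[, 1L]
  E0[is.na(E0)] <- 0.5   # missing first-age mean: neutral mid-scale start
  rmse <- vapply(seq_len(L), function(l) {
    K <- Ks[, , l]
    sim <- tryCatch(
      simulateTrajectories(.traj_from_K(K, scaled@nodeData), times, E0),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    sqrt(mean((trajectoryMatrix(sim) - obs)^2, na.rm = TRUE))
  }, numeric(1))
  win <- which.min(rmse)
  K <- Ks[, , win]
  dimnames(K) <- list(labels, labels)
  new("InteractionNetwork", K = K, nodeData = scaled@nodeData,
      diagnostics = list(kind = "hmf_fit",
                         penaltyGrid = config$penaltyGrid,
                         rmsePath = rmse,
                         selectedPenalty = config$penaltyGrid[win],
                         selectedRmse = rmse[win],
                         l1Ratio = config$l1Ratio,
                         M = config$M, N = config$N,
                         flags = flags,
                         scaling = scaled@scaling))
}

#' Identify a multi-organ network for one strain
#'
#' End-to-end identification from a normalized dataset: replicate means per
#' (organ, gene) for the chosen strain, min-max scaling, dense
#' interpolation, basis projection, per-target elastic-net fits, and joint
#' penalty selection by simulation fit (see
#' [estimateNetworkFromTrajectories()]). One network per strain (and per
#' sex, when both are profiled) is the intended use.
#'
#' @param qpcr a normalized \linkS4class{QpcrSet}.
#' @param strain strain label.
#' @param config list as from [defaultHmfConfig()].
#' @param assayName assay holding normalized expression.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
estimateNetwork <- function(qpcr, strain, config = defaultHmfConfig(),
                            assayName = "nddct") {
  traj <- summarizeReplicates(qpcr, strain, assayName = assayName)
  estimateNetworkFromTrajectories(traj, config = config, rescale = TRUE)
}

#' Simulate a fitted network model forward
#'
#' Integrates the fitted linear model from an initial state at the first
#' age over the requested span (by default 8 to 24 weeks), returning
#' evenly spaced states. Shares the matrix-exponential integrator (and the
#' instability guard) with [simulateTrajectories()].
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param E0 state at the first age, one value per node (typically the
#'   scaled data at the earliest age).
#' @param tSpan length-2 numeric, simulation span in weeks.
#' @param nOut number of evenly spaced output times.
#' @return a \linkS4class{TrajectorySet} with times on the age axis.
#' @export
simulateFittedModel <- function(network, E0, tSpan = c(8, 24), nOut = 101L) {
  grid <- seq(tSpan[1L], tSpan[2L], length.out = nOut)
  sim <- simulateTrajectories(network, grid - grid[1L], E0)
  new("TrajectorySet", values = trajectoryMatrix(sim), times = grid,
      nodeData = network@nodeData,
      scaling = DataFrame(min = numeric(0), max = numeric(0)))
}
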