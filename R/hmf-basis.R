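#' @importFrom stats spline mvfft
NULL

#' The cas kernel of the Hartley transform
#'
#' \code{cas(x) = cos(x) + sin(x)}.
#'
#' @param x numeric.
#' @return numeric of the same length.
#' @export
cas <- function(x) cos(x) + sin(x)

#' Hartley modulating function basis
#'
#' Builds the family of modulating functions
#' \deqn{\varphi_m(t) = \sum_{k=0}^{N} (-1)^k \binom{N}{k}
#'   \mathrm{cas}((m+k)\,\omega_0 t), \qquad m = 1, \dots, M,}
#' with fundamental frequency \eqn{\omega_0 = 2\pi/T}, sampled with its
#' analytic derivative on a uniform grid over \eqn{[0, T]}. The alternating
#' binomial identities \eqn{\sum_k (-1)^k \binom{N}{k} (m+k)^j = 0} for
#' \eqn{j < N} make \eqn{\varphi_m} and (for \eqn{N \ge 2}) its derivative
#' vanish at both window ends, so inner products with a signal's derivative
#' can be moved onto the known \eqn{\varphi_m'} by integration by parts --
#' no numerical differentiation of noisy data is ever needed.
#'
#' @param M number of modulating functions.
#' @param N order (>= 2 for vanishing end derivatives; >= 3 keeps the
#'   second derivative zero at the ends too, which sharpens the trapezoid
#'   quadrature).
#' @param T window length (weeks).
#' @param nGrid grid size (points, including both endpoints).
#' @return object of class \code{"HMFBasis"}: list with \code{M}, \code{N},
#'   \code{T}, \code{omega0}, \code{tGrid}, and the \code{M x nGrid}
#'   matrices \code{phi} and \code{dphi}.
#' @examples
#' b <- hmfBasis(M = 4, N = 3, T = 16)
#' max(abs(b$phi[, c(1, ncol(b$phi))]))   # boundary values ~ 0
#' @export
hmfBasis <- function(M = 8L, N = 3L, T, nGrid = 257L) {
  stopifnot(N >= 2L, M >= 1L, T > 0, nGrid >= 2L)
  omega0 <- 2 * pi / T
  tGrid <- seq(0, T, length.out = nGrid)
  phi <- matrix(0, M, nGrid)
  dphi <- matrix(0, M, nGrid)
  for (m in seq_len(M)) {
    for (k in 0:N) {
      cfk <- (-1)^k * choose(N, k)
      a <- (m + k) * omega0
      phi[m, ] <- phi[m, ] + cfk * cas(a * tGrid)
      dphi[m, ] <- dphi[m, ] + cfk * a * (cos(a * tGrid) - sin(a * tGrid))
    }
  }
  structure(list(M = M, N = N, T = T, omega0 = omega0, tGrid = tGrid,
                 phi = phi, dphi = dphi),
            class = "HMFBasis")
}

#' Min-max scale trajectories to (0, 1)
#'
#' Affinely maps each node's values to [0, 1] using the node's min and max
#' over its observed time points. Constant nodes (max = min) are mapped to
#' the constant 0.5 and flagged -- they carry no dynamic information for
#' fitting.
#'
#' @param traj a \linkS4class{TrajectorySet}.
#' @return the scaled \linkS4class{TrajectorySet}; per-node \code{min},
#'   \code{max} and a \code{degenerate} flag are stored in the
#'   \code{scaling} slot.
#' @export
minmaxScale <- function(traj) {
  v <- trajectoryMatrix(traj)
  mn <- apply(v, 1L, min, na.rm = TRUE)
  mx <- apply(v, 1L, max, na.rm = TRUE)
  degen <- mx - mn <= 0
  rng <- ifelse(degen, 1, mx - mn)
  scaled <- (v - mn) / rng
  scaled[degen, ] <- 0.5
  new("TrajectorySet", values = scaled, times = traj@times,
      nodeData = traj@nodeData,
      scaling = DataFrame(min = mn, max = mx, degenerate = degen))
}

#' Interpolate trajectories onto a dense uniform grid
#'
#' Natural cubic spline through each node's observed time-point values,
#' evaluated on a uniform grid spanning the observation window. Values are
#' optionally clipped to [0, 1] (the scaled-data convention).
#'
#' @param traj a \linkS4class{TrajectorySet} (typically min-max scaled).
#' @param nGrid grid size; must be at least the number of time points.
#' @param clip clip interpolated values to [0, 1].
#' @return a dense \linkS4class{TrajectorySet} on the uniform grid.
#' @export
interpolateDense <- function(traj, nGrid = 257L, clip = TRUE) {
  times <- trajectoryTimes(traj)
  stopifnot(nGrid >= length(times))
  grid <- seq(min(times), max(times), length.out = nGrid)
  v <- trajectoryMatrix(traj)
  dense <- t(apply(v, 1L, function(y) {
    ok <- !is.na(y)
    spline(times[ok], y[ok], xout = grid, method = "natural")$y
  }))
  if (clip) dense <- pmin(pmax(dense, 0), 1)
  rownames(dense) <- rownames(v)
  new("TrajectorySet", values = dense, times = grid,
      nodeData = traj@nodeData, scaling = traj@scaling)
}

.trapezoid_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

#' Project trajectories onto the modulating-function basis
#'
#' Computes, for every node \eqn{j} and modulating function \eqn{m}, the
#' moment \eqn{\int_0^T \varphi_m E_j\,dt} and the derivative moment
#' \eqn{\int_0^T \varphi_m E_j'\,dt = -\int_0^T \varphi_m' E_j\,dt} (the
#' boundary terms of the integration by parts vanish by the basis
#' construction). Two independent quadrature routes are provided: composite
#' trapezoid sums on the dense grid, and a spectral route that assembles the
#' same integrals from discrete Hartley transform components of each
#' trajectory (with endpoint correction), used as a cross-check.
#'
#' @param basis an \code{"HMFBasis"}.
#' @param dense a dense \linkS4class{TrajectorySet} on the basis grid (same
#'   length and window).
#' @param method \code{"trapezoid"} or \code{"hartley"}.
#' @return list with matrices \code{moments} and \code{derivativeMoments}
#'   (both M x nodes).
#' @export
projectTrajectory <- function(basis, dense,
                              method = c("trapezoid", "hartley")) {
  method <- match.arg(method)
  times <- trajectoryTimes(dense)
  n <- length(times)
  if (n != length(basis$tGrid) ||
      abs(diff(range(times)) - basis$T) > 1e-8 * max(basis$T, 1))
    stop("grid mismatch between basis and trajectories")
  v <- trajectoryMatrix(dense)
  h <- basis$T / (n - 1L)
  if (method == "trapezoid") {
    w <- .trapezoid_weights(n, h)
    vw <- t(v) * w                     # n x nodes
    moments <- basis$phi %*% vw
    dmoments <- -(basis$dphi %*% vw)
  } else {
    ## Hartley route: integrals of cas(a w0 t) * E and (cos - sin)(a w0 t) * E
    ## from the DFT of E over the periodic part of the grid (last point
    ## dropped), plus the trapezoid endpoint correction h*(E(T) - E(0))/2
    ## (cas and cos - sin are both 1 at t = 0 and t = T for harmonics).
    Np <- n - 1L
    freq_max <- basis$M + basis$N
    stopifnot(freq_max < Np / 2)
    X <- mvfft(t(v[, seq_len(Np), drop = FALSE]))   # Np x nodes
    endc <- h * (v[, n] - v[, 1L]) / 2
    casI <- matrix(0, freq_max, ncol(X))
    cmsI <- matrix(0, freq_max, ncol(X))
    for (a in seq_len(freq_max)) {
      Xa <- X[a + 1L, ]
      casI[a, ] <- h * (Re(Xa) - Im(Xa)) + endc
      cmsI[a, ] <- h * (Re(Xa) + Im(Xa)) + endc
    }
    moments <- matrix(0, basis$M, nrow(v))
    dmoments <- matrix(0, basis$M, nrow(v))
    for (m in seq_len(basis$M)) {
      for (k in 0:basis$N) {
        cfk <- (-1)^k * choose(basis$N, k)
        a <- m + k
        moments[m, ] <- moments[m, ] + cfk * casI[a, ]
        dmoments[m, ] <- dmoments[m, ] -
          cfk * a * basis$omega0 * cmsI[a, ]
      }
    }
  }
  colnames(moments) <- colnames(dmoments) <- rownames(v)
  list(moments = moments, derivativeMoments = dmoments)
}
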