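#' Equilibrium biomass densities
#'
#' Solves the Lotka-Volterra equilibrium condition `A %*% N = K` for the
#' biomass-density vector `N` by a linear solve (never an explicit inverse).
#' A reciprocal-condition-number guard rejects near-singular matrices.
#'
#' @param A Square interaction matrix (or a `"community"` object).
#' @param K Carrying-capacity vector, same length as `nrow(A)`.
#' @param cond_threshold Condition-number threshold above which the solve is
#'   refused; default 1e12.
#' @return Equilibrium vector `N`.
#' @export
equilibrium <- function(A, K, cond_threshold = 1e12) {
  A <- as_interaction_matrix(A)
  if (length(K) != nrow(A)) stop("K must have length nrow(A)")
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / cond_threshold)
    stop(sprintf(
      "interaction matrix is numerically singular (rcond = %.3e)", rc))
  drop(solve(A, K))
}

as_interaction_matrix <- function(A) {
  if (inherits(A, "community")) A <- A$A
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix or a community object")
  A
}

#' Feasibility of a carrying-capacity direction
#'
#' A community is *feasible* for a given `K` when the equilibrium
#' `N = solve(A, K)` is strictly positive — the necessary condition for
#' coexistence.  Feasibility depends only on the direction of `K`:
#' rescaling `K` by any positive scalar leaves the answer unchanged.
#' Components in `(0, boundary_tol]` are flagged as boundary cases via the
#' `"boundary"` attribute (a direction on the edge of the feasibility cone,
#' e.g. `K` equal to a column of `A`, is not strictly interior).
#'
#' @inheritParams equilibrium
#' @param tol Strict positivity tolerance; default 0.
#' @param boundary_tol Width of the boundary band; default 1e-12.
#' @return Logical; attribute `"boundary"` is `TRUE` when the minimum
#'   component lies within the boundary band.
#' @export
is_feasible <- function(A, K, tol = 0, boundary_tol = 1e-12) {
  N <- equilibrium(A, K)
  ans <- min(N) > tol
  attr(ans, "boundary") <- ans && min(N) <= boundary_tol
  ans
}

#' Centroid of the feasibility domain
#'
#' The feasibility domain of an interaction matrix `A` is the convex cone
#' spanned by its column vectors; its centroid is the arithmetic mean of
#' those columns, `(a_1 + ... + a_S) / S`.  It represents the average
#' distribution of carrying capacities across feasible environments, and it
#' is the unique direction at which all equilibrium biomass densities are
#' equal.  By default the raw (unnormalized) columns are averaged — only
#' then is the equal-abundance solution `solve(A, centroid(A)) = 1/S` an
#' exact identity; set `normalize = TRUE` for the unit-column variant used
#' in parts of the structuralist literature.
#'
#' @param A Square interaction matrix with positive columns (or a
#'   `"community"` object).
#' @param normalize Average unit-norm columns instead of raw columns;
#'   default `FALSE`.
#' @return Centroid vector of length `nrow(A)`.
#' @export
centroid <- function(A, normalize = FALSE) {
  A <- as_interaction_matrix(A)
  if (any(A < 0)) stop("A must have nonnegative entries")
  if (normalize)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  rowMeans(A)
}

#' Equal equilibrium biomass density at the centroid
#'
#' At the centroid direction every population has the same equilibrium
#' biomass density `h`.  With the raw-column centroid this constant is
#' exactly `1/S`.  The function solves for the equilibrium, verifies
#' uniformity, and returns `h`.
#'
#' @inheritParams centroid
#' @param tol Maximum allowed spread (max - min) of the equilibrium
#'   components; default 1e-8.
#' @return The scalar `h`.
#' @export
equal_biomass_constant <- function(A, tol = 1e-8) {
  A <- as_interaction_matrix(A)
  N <- equilibrium(A, centroid(A))
  if (diff(range(N)) > tol)
    warning("equilibrium at the centroid is not uniform to tolerance")
  mean(N)
}

#' Angular distance between carrying-capacity directions
#'
#' The angle, in degrees, between a carrying-capacity vector `K` and a
#' reference direction `Kc` (typically the feasibility-domain centroid):
#' `acos(<K, Kc> / (|K| |Kc|)) * 180 / pi`.  For nonnegative vectors the
#' distance lies in `[0, 90]`.  Internally the numerically equivalent
#' two-argument arctangent form
#' `2 * atan2(|K |Kc| - Kc |K||, |K |Kc| + Kc |K||)` is used: unlike a
#' clamped `acos` it stays fully precise near collinearity and returns an
#' exact zero for positively proportional vectors.
#'
#' @param K,Kc Nonzero nonnegative vectors of equal length.
#' @return Angle in degrees.
#' @export
angular_distance <- function(K, Kc) {
  if (length(K) != length(Kc)) stop("K and Kc must have the same length")
  nK <- sqrt(sum(K^2)); nC <- sqrt(sum(Kc^2))
  if (nK == 0 || nC == 0) stop("angular distance undefined for zero vectors")
  u <- K * nC
  v <- Kc * nK
  2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2))) * 180 / pi
}

#' Sample random carrying-capacity directions and label feasibility
#'
#' Draws `n` random directions in the positive orthant (absolute values of
#' standard normals, normalized) and labels each by [is_feasible()].  Used
#' as a sampling probe of the feasibility cone.
#'
#' @inheritParams equilibrium
#' @param n Number of directions to draw (>= 1).
#' @return A data frame with one row per direction: columns `feasible`
#'   (logical), `distance_deg` (angle to the centroid), and a matrix column
#'   `K` of the sampled unit directions.
#' @export
sample_feasible_directions <- function(A, n = 100) {
  A <- as_interaction_matrix(A)
  S <- nrow(A)
  Kc <- centroid(A)
  K <- abs(matrix(stats::rnorm(n * S), n, S))
  K <- K / sqrt(rowSums(K^2))
  feasible <- logical(n)
  dist_deg <- numeric(n)
  for (i in seq_len(n)) {
    feasible[i] <- as.logical(is_feasible(A, K[i, ]))
    dist_deg[i] <- angular_distance(K[i, ], Kc)
  }
  out <- data.frame(feasible = feasible, distance_deg = dist_deg)
  out$K <- K
  out
}

#' Assess feasibility of a community under a carrying-capacity direction
#'
#' Convenience wrapper combining the equilibrium solve, the feasibility
#' test and the angular distance to the centroid.
#'
#' @param community A `"community"` object (see
#'   [build_interaction_matrix()]).
#' @param K Carrying-capacity vector; defaults to the centroid direction.
#' @return An object of class `"feasibility_assessment"`: list with
#'   `N_star`, `feasible`, `distance_deg`.
#' @export
assess_feasibility <- function(community, K = NULL) {
  A <- as_interaction_matrix(community)
  Kc <- centroid(A)
  if (is.null(K)) K <- Kc
  N <- equilibrium(A, K)
  structure(list(N_star = N,
                 feasible = all(N > 0),
                 distance_deg = angular_distance(K, Kc)),
            class = "feasibility_assessment")
}

#' @export
print.feasibility_assessment <- function(x, ...) {
  cat(sprintf("Feasibility assessment (S = %d):\n", length(x$N_star)))
  cat(sprintf("  feasible: %s; angular distance to centroid: %.4g deg\n",
              x$feasible, x$distance_deg))
  cat(sprintf("  equilibrium biomass density range [%.4g, %.4g]\n",
              min(x$N_star), max(x$N_star)))
  invisible(x)
}
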