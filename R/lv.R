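#' Lotka-Volterra competition parameters
#'
#' Parameter set for the generalized Lotka-Volterra competition model in
#' carrying-capacity form:
#' `dN_i/dt = N_i * (r_i / K_i) * (K_i - sum_j a_ij N_j)`.
#'
#' @param r Vector of maximum intrinsic growth rates (> 0, time^-1).
#' @param K Vector of carrying capacities of biomass density (> 0).
#' @param A Interaction matrix (dimensionless, unit diagonal) or a
#'   `"community"` object.
#' @return An object of class `"lv_params"`.
#' @export
lv_params <- function(r, K, A) {
  A <- as_interaction_matrix(A)
  S <- nrow(A)
  if (length(r) == 1) r <- rep(r, S)
  if (length(K) == 1) K <- rep(K, S)
  if (length(r) != S || length(K) != S)
    stop("r and K must have length nrow(A)")
  if (any(r <= 0)) stop("growth rates r must be positive")
  if (any(K <= 0)) stop("carrying capacities K must be positive")
  structure(list(r = r, K = K, A = A, S = S), class = "lv_params")
}

#' Right-hand side of the Lotka-Volterra competition model
#'
#' Per-population growth `N_i * (r_i/K_i) * (K_i - sum_j a_ij N_j)`.
#' Exact zeros are preserved: an extinct population stays extinct.
#'
#' @param N Biomass-density state vector (>= 0).
#' @param params An [lv_params()] object.
#' @return Vector of time derivatives.
#' @export
lv_rhs <- function(N, params) {
  if (length(N) != params$S) stop("state N must have length S")
  N * (params$r / params$K) * (params$K - drop(params$A %*% N))
}

#' Analytic Jacobian of the Lotka-Volterra model
#'
#' Jacobian of [lv_rhs()] at state `N`.  At an interior equilibrium the
#' `(i, j)` entry reduces to `-(r_i/K_i) * N_i * a_ij`, so local stability
#' there is governed by the scaled interaction matrix.
#'
#' @inheritParams lv_rhs
#' @return The `S x S` Jacobian matrix.
#' @export
jacobian_at <- function(N, params) {
  if (length(N) != params$S) stop("state N must have length S")
  g <- params$r / params$K
  growth <- g * (params$K - drop(params$A %*% N))   # per-capita rates
  J <- -(g * N) * params$A                          # row-scaled interaction
  diag(J) <- diag(J) + growth
  J
}

#' Integrate the Lotka-Volterra competition dynamics
#'
#' Numerically integrates [lv_rhs()] with a stiff-capable adaptive solver
#' (`deSolve::ode`, method `"lsoda"`).  Wide body-mass ranges produce wide
#' spreads of `r_i/K_i`, so stiffness is expected.  States falling below
#' the extinction threshold are clipped to exactly zero; extinction is
#' absorbing.  Feasibility alone does not guarantee attraction to the
#' interior equilibrium — convergence should only be expected when the
#' Jacobian there is stable (see [jacobian_at()]).
#'
#' @param N0 Initial biomass densities (>= 0).
#' @param params An [lv_params()] object.
#' @param t_end Duration of integration.
#' @param n_steps Number of output time points; default 200.
#' @param rtol,atol Solver tolerances; defaults 1e-8 and 1e-10.
#' @param extinction_threshold States below this are clipped to zero;
#'   default 1e-12.
#' @return A data frame of class `"lv_trajectory"` in long form: columns
#'   `time`, `population`, `biomass_density`.  The final state is attached
#'   as attribute `"final_state"`.
#' @export
simulate_lv <- function(N0, params, t_end, n_steps = 200,
                        rtol = 1e-8, atol = 1e-10,
                        extinction_threshold = 1e-12) {
  if (length(N0) != params$S) stop("N0 must have length S")
  if (any(N0 < 0)) stop("initial densities must be nonnegative")
  times <- seq(0, t_end, length.out = n_steps + 1)
  deriv <- function(t, N, p) {
    N <- pmax(N, 0)
    list(lv_rhs(N, p))
  }
  sol <- deSolve::ode(y = N0, times = times, func = deriv,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("Lotka-Volterra integration failed (see deSolve diagnostics)")
  states <- unname(sol[, -1, drop = FALSE])
  states[states < extinction_threshold] <- 0
  traj <- data.frame(
    time = rep(sol[, 1], times = params$S),
    population = rep(seq_len(params$S), each = nrow(sol)),
    biomass_density = as.vector(states))
  class(traj) <- c("lv_trajectory", "data.frame")
  attr(traj, "final_state") <- states[nrow(states), ]
  traj
}

#' Final state of a simulated trajectory
#'
#' @param trajectory An object returned by [simulate_lv()].
#' @return Numeric vector of biomass densities at `t_end`.
#' @export
final_state <- function(trajectory) {
  attr(trajectory, "final_state")
}
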