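#' Sweep the carrying-capacity scaling exponent over a community ensemble
#'
#' The core numerical experiment.  For each of `cfg$n_communities`
#' communities: draw a lognormal body-mass vector, build the metabolically
#' generated competition matrix, and compute the centroid of its
#' feasibility domain.  Then, for every exponent `beta` on the grid,
#' measure the angular distance between the candidate carrying-capacity
#' direction `M^beta` and the centroid.  The distance is recorded for every
#' sampled community, feasible or not: the angular distance is defined for
#' any positive direction, so no feasibility filter is applied.  Ensemble
#' mean and SD are reported per `beta`, together with the grid argmin.
#'
#' @param cfg An [ensemble_config()].
#' @param beta_grid Ordered vector of exponents; default
#'   `seq(-2, 2, by = 0.05)`.
#' @return An object of class `"beta_sweep"`: list with a `summary` data
#'   frame (`beta`, `mean_distance_deg`, `sd_distance_deg`, `n`),
#'   `argmin_beta`, `n_communities`, `n_skipped`, `seed`, and `config`.
#' @examples
#' bs <- beta_sweep(ensemble_config(S = 10, n_communities = 50, seed = 1),
#'                  beta_grid = seq(-2, 2, by = 0.5))
#' bs$argmin_beta
#' @export
beta_sweep <- function(cfg = ensemble_config(),
                       beta_grid = seq(-2, 2, by = 0.05)) {
  if (!inherits(cfg, "ensemble_config")) stop("cfg must be an ensemble_config")
  if (length(beta_grid) == 0 || is.unsorted(beta_grid))
    stop("beta_grid must be a nonempty increasing vector")
  n <- cfg$n_communities
  seeds <- substream_seeds(cfg$seed, n)
  D <- matrix(NA_real_, n, length(beta_grid))
  skipped <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- sample_masses(cfg, seed = seeds[i])
      com <- build_interaction_matrix(m, alpha = cfg$alpha,
                                      a0_rule = cfg$a0_rule)
      Kc <- centroid(com$A)
      vapply(beta_grid,
             function(b) angular_distance(metabolic_K_vector(m, b), Kc),
             numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L else D[i, ] <- res
  }
  ok <- stats::complete.cases(D)
  if (!any(ok)) stop("every community in the ensemble failed")
  D <- D[ok, , drop = FALSE]
  summary <- data.frame(
    beta = beta_grid,
    mean_distance_deg = colMeans(D),
    sd_distance_deg = apply(D, 2, stats::sd),
    n = nrow(D))
  structure(list(summary = summary,
                 argmin_beta = beta_grid[which.min(summary$mean_distance_deg)],
                 n_communities = nrow(D),
                 n_skipped = skipped,
                 seed = cfg$seed,
                 config = cfg),
            class = "beta_sweep")
}

#' @export
print.beta_sweep <- function(x, ...) {
  cat(sprintf(
    "Carrying-capacity exponent sweep: %d communities of S = %d\n",
    x$n_communities, x$config$S))
  cat(sprintf("  grid [%g, %g] (%d values); argmin beta = %g (%.3f deg)\n",
              min(x$summary$beta), max(x$summary$beta), nrow(x$summary),
              x$argmin_beta, min(x$summary$mean_distance_deg)))
  if (x$n_skipped > 0)
    cat(sprintf("  %d communities skipped after numerical failure\n",
                x$n_skipped))
  invisible(x)
}

#' Mean centroid distance as a function of community size
#'
#' Measures, for each community size in `S_values`, the ensemble mean
#' angular distance between `M^beta` and the feasibility-domain centroid.
#' At `beta = 1/4` the distance decreases toward an asymptote as the
#' community grows: the quarter-power carrying-capacity law approaches the
#' centroid in large communities.  The same master seed drives every
#' community size (matched-seed protocol).
#'
#' @param S_values Vector of community sizes (each >= 2).
#' @param cfg An [ensemble_config()]; its `S` field is overridden by each
#'   element of `S_values` in turn.
#' @param beta Carrying-capacity exponent; default 1/4.
#' @return A data frame: `S`, `mean_distance_deg`, `sd_distance_deg`, `n`.
#' @export
size_scaling <- function(S_values, cfg = ensemble_config(), beta = 1/4) {
  if (any(S_values < 2)) stop("all community sizes must be >= 2")
  rows <- lapply(S_values, function(S) {
    cfg_S <- cfg
    cfg_S$S <- as.integer(S)
    bs <- beta_sweep(cfg_S, beta_grid = beta)
    data.frame(S = S,
               mean_distance_deg = bs$summary$mean_distance_deg,
               sd_distance_deg = bs$summary$sd_distance_deg,
               n = bs$summary$n)
  })
  do.call(rbind, rows)
}

#' Abundance densities at the centroid and their mass scaling
#'
#' At the centroid of the feasibility domain all populations share the same
#' equilibrium biomass density `h`, independent of body size.  Dividing by
#' body mass gives the abundance density (individuals per area)
#' `I_i = h / M_i`, so log abundance density is exactly linear in log mass
#' with slope -1 — the community-level inverse size-abundance law.  The
#' slope does not depend on the consumption exponent used to build the
#' interaction matrix.
#'
#' @param community A `"community"` object.
#' @return List with `abundance` (the vector `N*/M`), `slope` (fitted
#'   log-log slope), and `h` (the common biomass density).
#' @export
abundance_at_centroid <- function(community) {
  A <- as_interaction_matrix(community)
  N <- equilibrium(A, centroid(A))
  I <- N / community$masses
  fit <- stats::lm(log(I) ~ log(community$masses))
  list(abundance = I,
       slope = unname(stats::coef(fit)[2]),
       h = mean(N))
}
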