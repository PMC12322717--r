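#' Configuration of a Monte-Carlo community ensemble
#'
#' @param S Community size (number of populations, >= 2).
#' @param n_communities Ensemble size (>= 1).  The headline experiment uses
#'   large ensembles; tests use a few hundred.
#' @param log_mu Mean of log body mass; default 0.
#' @param log_sigma SD of log body mass; default 2, i.e. masses spanning
#'   several orders of magnitude.
#' @param a0_rule Off-diagonal interaction normalization: `"sqrt_S"` (the
#'   weak-interaction convention `a0 = S^(-1/2)`), or a positive scalar.
#' @param alpha Interaction scaling exponent; default -1/4.
#' @param seed Master RNG seed (integer).  All randomness in an ensemble
#'   flows from this one seed via deterministic per-community substreams.
#'
#' @return An object of class `"ensemble_config"`.
#' @export
ensemble_config <- function(S = 50, n_communities = 1e4,
                            log_mu = 0, log_sigma = 2,
                            a0_rule = "sqrt_S", alpha = -1/4,
                            seed = 1L) {
  if (!is.numeric(S) || length(S) != 1 || S < 2 || S != round(S))
    stop("S must be a single integer >= 2")
  if (!is.numeric(n_communities) || n_communities < 1)
    stop("n_communities must be >= 1")
  if (!is.numeric(log_sigma) || log_sigma < 0)
    stop("log_sigma must be >= 0")
  if (is.numeric(a0_rule)) {
    if (length(a0_rule) != 1 || a0_rule <= 0)
      stop("a numeric a0_rule must be a single positive scalar")
  } else if (!identical(a0_rule, "sqrt_S")) {
    stop("a0_rule must be \"sqrt_S\" or a positive scalar")
  }
  structure(list(S = as.integer(S),
                 n_communities = as.integer(n_communities),
                 log_mu = log_mu, log_sigma = log_sigma,
                 a0_rule = a0_rule, alpha = alpha,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

resolve_a0 <- function(a0_rule, S) {
  if (is.numeric(a0_rule)) a0_rule else S^(-1/2)
}

# Deterministic substream seeds: one master seed yields one 31-bit seed per
# community, so ensembles reproduce regardless of evaluation order.
substream_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Sample a body-mass vector
#'
#' Draws `cfg$S` independent body masses from a lognormal distribution with
#' log-mean `cfg$log_mu` and log-SD `cfg$log_sigma`.
#'
#' @param cfg An [ensemble_config()].
#' @param seed Optional seed overriding `cfg$seed` (used internally for
#'   per-community substreams).
#' @return Numeric vector of `cfg$S` positive masses.
#' @export
sample_masses <- function(cfg = ensemble_config(), seed = cfg$seed) {
  if (!inherits(cfg, "ensemble_config")) stop("cfg must be an ensemble_config")
  set.seed(seed)
  stats::rlnorm(cfg$S, meanlog = cfg$log_mu, sdlog = cfg$log_sigma)
}

#' Assemble the metabolically generated competition matrix
#'
#' Builds the `S x S` interaction matrix with entries
#' `A[i, j] = a0 * (M_j / M_i)^alpha` for `i != j` and `A[i, i] = 1`
#' (self-regulation is the unit of the per-capita effect).  The default
#' normalization `a0 = S^(-1/2)` encodes the convention that interspecific
#' effects are weak relative to self-regulation in large communities.
#'
#' @param masses Vector of positive body masses (length >= 2).
#' @param alpha Interaction scaling exponent; default -1/4.
#' @param a0_rule `"sqrt_S"` or a positive scalar (see [ensemble_config()]).
#' @return An object of class `"community"`: a list with elements `masses`,
#'   `A`, `S`, `a0`, `alpha`.
#' @examples
#' com <- build_interaction_matrix(c(1, 16))
#' com$A  # off-diagonals 2^(-1/2) * c(0.5, 2)
#' @export
build_interaction_matrix <- function(masses, alpha = -1/4,
                                     a0_rule = "sqrt_S") {
  check_mass(masses)
  S <- length(masses)
  if (S < 2) stop("a community needs at least 2 populations")
  a0 <- resolve_a0(a0_rule, S)
  ma <- masses^alpha
  A <- a0 * outer(1 / ma, ma)   # A[i, j] = a0 * (M_j/M_i)^alpha
  diag(A) <- 1
  structure(list(masses = masses, A = A, S = S, a0 = a0, alpha = alpha),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("Competition community: S = %d populations\n", x$S))
  cat(sprintf("  body-mass range [%.4g, %.4g], a0 = %.4g, alpha = %g\n",
              min(x$masses), max(x$masses), x$a0, x$alpha))
  invisible(x)
}

#' Carrying-capacity direction for a scaling exponent
#'
#' Returns the vector with components `M_i^beta`, the direction of the
#' carrying capacities of biomass density under the allometric law
#' `K = K0 * M^beta`.  The normalization `K0` affects only the magnitude,
#' never the direction, and is omitted.
#'
#' @param masses Vector of positive body masses.
#' @param beta Scaling exponent of carrying capacity on body mass.
#' @return Numeric vector, same length as `masses`.
#' @export
metabolic_K_vector <- function(masses, beta) {
  check_mass(masses)
  masses^beta
}

#' Read a body-mass vector from a one-column text file
#'
#' Accepts plain text (one mass per line) or single-column CSV with an
#' optional header.
#'
#' @param path File path.
#' @return Numeric vector of positive masses.
#' @export
read_mass_vector <- function(path) {
  raw <- utils::read.csv(path, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  m <- suppressWarnings(as.numeric(raw))
  m <- m[!is.na(m)]   # drop a header line if present
  check_mass(m)
  m
}
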