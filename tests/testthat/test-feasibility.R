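A22 <- matrix(c(1, 2, 2, 1), 2)   # strong symmetric competition

test_that("equilibrium is the linear solve of A N = K", {
  expect_equal(equilibrium(diag(2), c(1, 1)), c(1, 1))
  # 2x2 inversions done by hand: A^(-1) = -1/3 [[1,-2],[-2,1]]
  expect_equal(equilibrium(A22, c(1, 1)), c(1/3, 1/3))
  expect_equal(equilibrium(A22, c(1, 5)), c(3, -1))
  expect_error(equilibrium(matrix(1, 2, 2), c(1, 1)), "singular")
  expect_error(equilibrium(A22, 1:3), "length")
})

test_that("feasibility means a strictly positive equilibrium", {
  expect_true(as.logical(is_feasible(A22, c(1, 1))))
  expect_false(as.logical(is_feasible(A22, c(1, 5))))
  # K equal to a column of A puts the equilibrium on a basis vector:
  # feasible only up to the boundary band
  f <- is_feasible(A22, A22[, 1], tol = -1e-15)
  expect_true(attr(f, "boundary"))
  # scale invariance: only the direction of K matters
  com <- make_community(S = 15, seed = 5)
  K <- metabolic_K_vector(com$masses, 1/4)
  for (lambda in c(1e-6, 1, 1e6))
    expect_equal(as.logical(is_feasible(com$A, lambda * K)),
                 as.logical(is_feasible(com$A, K)))
})

test_that("centroid is the mean of the spanning columns", {
  expect_equal(centroid(diag(2)), c(0.5, 0.5))
  # masses (1, 16): columns are (1, sqrt(2)) and (sqrt(2)/4, 1)
  com2 <- build_interaction_matrix(c(1, 16))
  expect_equal(centroid(com2), c(0.6767766953, 1.2071067812),
               tolerance = 1e-9)
  # normalized-column variant averages unit vectors instead
  expect_equal(centroid(diag(2) * 5, normalize = TRUE), c(0.5, 0.5))
})

test_that("equilibrium at the centroid is uniform with value 1/S", {
  for (S in c(2, 10, 50)) {
    com <- make_community(S = S, seed = S)
    N <- equilibrium(com$A, centroid(com$A))
    expect_lt(diff(range(N)), 1e-10)
    expect_equal(equal_biomass_constant(com$A), 1 / S, tolerance = 1e-12)
  }
})

test_that("angular distance is the arccos cosine similarity in degrees", {
  expect_equal(angular_distance(c(1, 1), c(2, 2)), 0)
  expect_equal(angular_distance(c(1, 0), c(1, 1)), 45)
  # two-species worked example: d((1,2), centroid) for masses (1,16)
  com2 <- build_interaction_matrix(c(1, 16))
  expect_equal(angular_distance(c(1, 2), centroid(com2)), 2.7125620133,
               tolerance = 1e-8)
  expect_error(angular_distance(c(0, 0), c(1, 1)), "zero")
  # bounds and scale invariance on random positive pairs
  set.seed(8)
  for (i in 1:50) {
    u <- rexp(6); v <- rexp(6)
    d <- angular_distance(u, v)
    expect_gte(d, 0); expect_lte(d, 90)
    expect_equal(angular_distance(1e6 * u, v), d)
    expect_equal(angular_distance(u / 1e6, v), d)
  }
})

test_that("two-species feasibility matches the analytic angular test", {
  # for S = 2 the feasibility cone is the set of directions strictly
  # between the two column directions; compare against that oracle
  set.seed(21)
  for (i in 1:25) {
    com <- build_interaction_matrix(rlnorm(2, 0, 2))
    ang <- function(v) atan2(v[2], v[1])
    a1 <- ang(com$A[, 1]); a2 <- ang(com$A[, 2])
    lo <- min(a1, a2); hi <- max(a1, a2)
    K <- abs(rnorm(2))
    inside <- ang(K) > lo && ang(K) < hi
    expect_equal(as.logical(is_feasible(com$A, K)), inside)
  }
})

test_that("sampled feasible directions lie inside the spanning cone", {
  set.seed(4)
  # identity matrix: the whole positive orthant is feasible
  labels <- sample_feasible_directions(diag(3), n = 40)
  expect_true(all(labels$feasible))
  # metabolically generated matrix: the centroid direction is feasible,
  # the negation of a column is not
  com <- make_community(S = 6, seed = 13)
  expect_true(as.logical(is_feasible(com$A, centroid(com$A))))
  expect_false(as.logical(is_feasible(com$A, -com$A[, 1])))
  probe <- sample_feasible_directions(com, n = 60)
  # every feasible label is certified by its positive solve
  for (i in which(probe$feasible))
    expect_true(all(solve(com$A, probe$K[i, ]) > 0))
  expect_true(all(probe$distance_deg >= 0 & probe$distance_deg <= 90))
})

test_that("assess_feasibility bundles equilibrium, flag and distance", {
  com <- make_community(S = 5, seed = 30)
  fa <- assess_feasibility(com)          # defaults to the centroid
  expect_true(fa$feasible)
  expect_equal(fa$N_star, rep(1 / 5, 5), tolerance = 1e-10)
  expect_equal(fa$distance_deg, 0)
  fa2 <- assess_feasibility(com, metabolic_K_vector(com$masses, 1/4))
  expect_gte(fa2$distance_deg, 0)
})
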