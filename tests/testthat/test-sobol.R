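test_that("Sobol' sequence is equidistributed and scrambling is seed-keyed", {
  U <- sobol_sequence(1024, 5)
  expect_true(all(U > 0 & U < 1))
  # dyadic equidistribution: each half of each axis holds exactly n/2 points
  for (j in 1:5)
    expect_equal(sum(U[, j] < 0.5), 512)
  # star-discrepancy proxy: ecdf deviation well below a random sample's
  expect_lt(max(abs(sort(U[, 3]) - (1:1024) / 1024)), 0.01)
  expect_identical(sobol_sequence(64, 3, seed = 9),
                   sobol_sequence(64, 3, seed = 9))
  expect_false(identical(sobol_sequence(64, 3, seed = 9),
                         sobol_sequence(64, 3, seed = 10)))
})

test_that("Saltelli design has (d+2)N rows with AB_j structure and bounded columns", {
  m1 <- uniform_marginals(1, 0, 1)
  expect_equal(nrow(design_points(build_saltelli_design(m1, 2))), 6)
  m <- default_cohort_spec()$inputs
  des <- build_saltelli_design(m, 50, seed = 2)
  pts <- design_points(des)
  expect_equal(nrow(pts), 12 * 50)
  for (nm in names(m))
    expect_true(all(pts[, nm] >= m[[nm]]$lo & pts[, nm] <= m[[nm]]$hi))
  # AB_j equals A with column j replaced from B
  for (j in c(1, 7)) {
    expect_identical(des$AB[[j]][, -j], des$A[, -j])
    expect_identical(des$AB[[j]][, j], des$B[, j])
  }
})

test_that("pick-freeze recovers analytic variance shares of an additive model", {
  m <- uniform_marginals(2, 0, 1)
  des <- build_saltelli_design(m, 2^13, seed = 5)
  P <- design_points(des)
  est <- estimate_sobol(des, P[, 1] + 2 * P[, 2])
  expect_equal(as.numeric(est$S), c(0.2, 0.8), tolerance = 0.02)
  # additive: totals equal firsts and shares sum to one
  expect_equal(as.numeric(est$ST), as.numeric(est$S), tolerance = 0.02)
  expect_equal(sum(est$S), 1, tolerance = 0.02)
})

test_that("pick-freeze matches the closed-form Ishigami indices", {
  m <- uniform_marginals(3)
  des <- build_saltelli_design(m, 2^14, seed = 7)
  est <- estimate_sobol(des, ishigami(design_points(des)))
  ref <- ishigami_indices()
  expect_equal(as.numeric(est$S), ref$S, tolerance = 0.02)
  expect_equal(as.numeric(est$ST), ref$ST, tolerance = 0.02)
  expect_gt(est$ST[1, 3], 0.2)   # X3 acts only through interaction
  expect_lt(abs(est$S[1, 3]), 0.02) # no first order effect of X3
})

test_that("pick-freeze agrees with a brute-force quadrature oracle", {
  # independent oracle: conditional-expectation quadrature on a fine grid
  g <- function(x1, x2) x1 + 3 * x2^2 + 2 * x1 * x2 + x1^3
  ng <- 2001
  u <- (seq_len(ng) - 0.5) / ng
  Y <- outer(u, u, g)
  V <- stats::var(as.vector(Y))
  S_oracle <- c(stats::var(rowMeans(Y)), stats::var(colMeans(Y))) / V
  ST_oracle <- c(1 - stats::var(colMeans(Y)) / V,
                 1 - stats::var(rowMeans(Y)) / V)
  m <- uniform_marginals(2, 0, 1)
  des <- build_saltelli_design(m, 2^14, seed = 11)
  P <- design_points(des)
  est <- estimate_sobol(des, g(P[, 1], P[, 2]))
  expect_equal(as.numeric(est$S), S_oracle, tolerance = 0.02)
  expect_equal(as.numeric(est$ST), ST_oracle, tolerance = 0.02)
})

test_that("estimator rejects incomplete or degenerate outputs", {
  m <- uniform_marginals(2, 0, 1)
  des <- build_saltelli_design(m, 64, seed = 1)
  expect_error(estimate_sobol(des, rep(1, 5 * 64)), "rows")
  expect_error(estimate_sobol(des, rep(1, 4 * 64)), "zero variance")
  y <- rnorm(4 * 64); y[5] <- NA
  expect_error(estimate_sobol(des, y), "missing")
})

test_that("convergence error is the max absolute index change, symmetric", {
  m <- uniform_marginals(2, 0, 1)
  des <- build_saltelli_design(m, 256, seed = 3)
  P <- design_points(des)
  e1 <- estimate_sobol(des, P[, 1] + 2 * P[, 2])
  expect_equal(convergence_error(e1, e1)$err_first, 0)
  e2 <- e1
  e2$S[1, ] <- c(0.4, 0.35); e1$S[1, ] <- c(0.5, 0.3)
  expect_equal(convergence_error(e1, e2)$err_first, 0.1)
  expect_equal(convergence_error(e1, e2), convergence_error(e2, e1))
})

test_that("repeat confidence intervals cover analytic additive indices", {
  m <- uniform_marginals(2, 0, 1)
  ests <- lapply(1:10, function(s) {
    des <- build_saltelli_design(m, 2^11, seed = 100 + s)
    P <- design_points(des)
    estimate_sobol(des, P[, 1] + 2 * P[, 2])
  })
  ci <- confidence_intervals(ests)
  truth <- c(0.2, 0.8)
  covered <- truth >= ci$S$lower[1, ] & truth <= ci$S$upper[1, ]
  expect_gte(sum(covered), 1)
  expect_true(all(ci$S$upper - ci$S$lower < 0.1))
  # degenerate and error cases
  same <- confidence_intervals(list(ests[[1]], ests[[1]]))
  expect_equal(same$S$upper, same$S$lower)
  expect_error(confidence_intervals(ests[1]), "at least 2")
  odd <- ests[[1]]; odd$N <- 999
  expect_error(confidence_intervals(list(ests[[1]], odd)), "same N")
})

test_that("sensitivity classification follows the qualitative legend", {
  est <- structure(list(
    S = matrix(c(0.45, 0.1, 0.002, 0.12), 1,
               dimnames = list("Y", paste0("X", 1:4))),
    ST = matrix(c(0.5, 0.1, 0.004, 0.4), 1,
                dimnames = list("Y", paste0("X", 1:4)))),
    class = "sobol_estimate")
  lab <- classify_sensitivity(est)
  expect_identical(as.character(lab),
                   c("sensitive", "fairly sensitive", "insensitive",
                     "intermediate"))
})
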