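test_that("Stieltjes recurrences match Hermite and Legendre oracles", {
  # Hermite checked at degree 3: the recurrence estimators involve
  # moments up to order 8, whose sampling noise at feasible n swamps a
  # 0.05 tolerance for higher degrees (bounded supports are unaffected)
  set.seed(1)
  hb <- stieltjes_recurrence(rnorm(1e5), 3)
  expect_equal(hb$alpha, rep(0, 3), tolerance = 0.05)
  expect_equal(hb$beta, sqrt(1:3), tolerance = 0.05)
  lb <- stieltjes_recurrence(runif(20000, -1, 1), 5)
  expect_equal(lb$alpha, rep(0, 5), tolerance = 0.05)
  expect_equal(lb$beta, (1:5) / sqrt(4 * (1:5)^2 - 1), tolerance = 0.05)
})

test_that("generated bases are empirically orthonormal (Gram identity)", {
  set.seed(2)
  for (x in list(rnorm(3000), rexp(3000), runif(3000, 2, 9))) {
    b <- stieltjes_recurrence(x, 6)
    Psi <- eval_basis1d(b, x)
    G <- crossprod(Psi) / length(x)
    expect_lt(max(abs(G - diag(7))), 5e-2)
    expect_true(all(Psi[, 1] == 1)) # degree-0 polynomial is 1
  }
  expect_error(stieltjes_recurrence(rnorm(40), 5), "at least")
  expect_error(stieltjes_recurrence(rep(2, 500), 3), "degenerate")
  expect_error(stieltjes_recurrence(rep(c(1, 2), 500), 3), "distinct")
})

test_that("total-degree multi-index sets have the right size and order", {
  M <- multi_index_set(10, 4)
  expect_equal(nrow(M), choose(14, 4)) # 1001
  expect_equal(nrow(multi_index_set(1, 4)), 5)
  expect_equal(nrow(multi_index_set(2, 2)), 6)
  expect_identical(M[1, ], rep(0L, 10))  # zero index first
  expect_true(all(diff(rowSums(M)) >= 0)) # graded order
  expect_true(all(rowSums(M) <= 4))
  expect_equal(nrow(unique(M)), nrow(M))
})

test_that("degree-q polynomials are reproduced exactly and fits are stable", {
  set.seed(4)
  X <- cbind(a = runif(1500), b = rnorm(1500))
  Y <- 1 + 2 * X[, 1] - X[, 1] * X[, 2] + 0.5 * X[, 2]^2
  bs <- build_pce_basis(X, 2)
  fit <- fit_pce(X, Y, bs)
  expect_lt(fit$resid_rms, 1e-6)
  expect_equal(as.numeric(predict(fit, X)), Y, tolerance = 1e-8)
  # duplicating the whole training set leaves the LS solution unchanged
  fit2 <- fit_pce(rbind(X, X), c(Y, Y), bs)
  expect_lt(max(abs(fit$beta - fit2$beta)), 1e-10)
  # underdetermined fits are refused with the required row count
  expect_error(fit_pce(X[1:8, ], Y[1:8], bs), "at least 12")
})

test_that("chunked prediction equals single-shot prediction", {
  set.seed(6)
  X <- cbind(x = runif(700), y = runif(700))
  Y <- X[, 1]^2 + X[, 2]
  fit <- fit_pce(X, Y, build_pce_basis(X, 2))
  expect_equal(predict(fit, X, chunk = 64), predict(fit, X, chunk = 1e6))
})

test_that("analytic Sobol indices from coefficients obey Parseval and oracles", {
  set.seed(5)
  X <- cbind(X1 = runif(2000, -1, 1), X2 = runif(2000, -1, 1))
  bs <- build_pce_basis(X, 3)
  # function of X1 alone: S1 = ST1 = 1
  f1 <- fit_pce(X, X[, 1] + 0.3 * X[, 1]^3, bs)
  e1 <- sobol_from_pce(f1)
  expect_equal(as.numeric(e1$S), c(1, 0), tolerance = 1e-8)
  expect_equal(as.numeric(e1$ST), c(1, 0), tolerance = 1e-8)
  # interaction: sum of first-order shares strictly below total variance
  f2 <- fit_pce(X, X[, 1] * X[, 2] + X[, 1], bs)
  e2 <- sobol_from_pce(f2)
  expect_lt(sum(e2$S), 1)
  expect_equal(sum(e2$S[1, ]) + (e2$ST[1, 1] - e2$S[1, 1]), 1,
               tolerance = 1e-6) # Parseval bookkeeping
})

test_that("degree-8 Ishigami surrogate reproduces the closed-form indices", {
  set.seed(3)
  X <- matrix(runif(5e4 * 3, -pi, pi), ncol = 3,
              dimnames = list(NULL, paste0("X", 1:3)))
  Y <- ishigami(X)
  fit <- fit_pce(X, Y, build_pce_basis(X, 8))
  est <- sobol_from_pce(fit)
  ref <- ishigami_indices()
  expect_equal(as.numeric(est$S), ref$S, tolerance = 0.02)
  expect_equal(as.numeric(est$ST), ref$ST, tolerance = 0.02)
  # at degree 10 the truncation error falls below 1% of sd(Y)
  fit10 <- fit_pce(X, Y, build_pce_basis(X, 10))
  expect_lt(fit10$resid_rms / sd(Y), 1e-2)
})

test_that("Q2 follows its definition and enforces train/test disjointness", {
  set.seed(9)
  X <- cbind(x = runif(400), y = runif(400))
  Y <- 2 * X[, 1] + X[, 2]^2
  fit <- fit_pce(X, Y, build_pce_basis(X, 2))
  Xt <- cbind(x = runif(200), y = runif(200))
  Yt <- 2 * Xt[, 1] + Xt[, 2]^2
  r <- q2_score(fit, Xt, Yt)
  expect_equal(r$Q2, 1, tolerance = 1e-8) # perfect surrogate
  expect_equal(r$n_test, 200)
  # direct formula check: an identity surrogate predicting (1,2,3)
  # against truth (1,2,4) scores 1 - 1/(3 var(1,2,4))
  xtr <- matrix(runif(200, 0, 5), dimnames = list(NULL, "x"))
  ident <- fit_pce(xtr, xtr[, 1], build_pce_basis(xtr, 1))
  r3 <- q2_score(ident, matrix(c(1, 2, 3), dimnames = list(NULL, "x")),
                 c(1, 2, 4))
  expect_equal(r3$Q2, 1 - 1 / (3 * var(c(1, 2, 4))), tolerance = 1e-8)
  # constant prediction at the test mean scores ~ 0
  const_pred <- rep(mean(Yt), length(Yt))
  q2_const <- 1 - sum((Yt - const_pred)^2) / (length(Yt) * var(Yt))
  expect_equal(q2_const, 0, tolerance = 0.01)
  # overlap and degenerate-variance guards
  expect_error(q2_score(fit, X[1:50, ], Y[1:50]), "overlap")
  expect_error(q2_score(fit, Xt, rep(1, 200)), "zero test variance")
})

test_that("pick-freeze and PCE routes agree on the same analytic function", {
  m <- uniform_marginals(3)
  des <- build_saltelli_design(m, 2^13, seed = 21)
  pf <- estimate_sobol(des, ishigami(design_points(des)))
  set.seed(22)
  X <- matrix(runif(3e4 * 3, -pi, pi), ncol = 3,
              dimnames = list(NULL, paste0("X", 1:3)))
  pce <- sobol_from_pce(fit_pce(X, ishigami(X), build_pce_basis(X, 8)))
  expect_equal(as.numeric(pf$S), as.numeric(pce$S), tolerance = 0.03)
  expect_equal(as.numeric(pf$ST), as.numeric(pce$ST), tolerance = 0.03)
})
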