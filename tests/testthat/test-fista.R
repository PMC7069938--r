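test_that("soft threshold is the l1 proximal map", {
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-2.5, 1), -1.5)
  v <- c(-3, -0.2, 0, 0.7, 4)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(v, 1), c(-2, 0, 0, 0, 3))
})

test_that("power iteration matches the dense decomposition", {
  expect_equal(lipschitz_estimate(diag(4)), 1, tolerance = 1e-6)
  expect_equal(lipschitz_estimate(diag(c(3, 1))), 9, tolerance = 1e-6)
  set.seed(2)
  A <- matrix(stats::rnorm(50 * 20), 50, 20)
  expect_rel_equal(lipschitz_estimate(A, tol = 1e-10), max(svd(A)$d)^2, 1e-6)
})

test_that("FISTA solves unregularized least squares exactly", {
  set.seed(3)
  A <- qr.Q(qr(matrix(stats::rnorm(30 * 10), 30, 10))) # orthonormal columns
  T0 <- stats::rnorm(10)
  S <- as.vector(A %*% T0)
  rec <- fista_solve(A, S, solver_config(0, max_iters = 5000,
                                         tolerance = 1e-14))
  expect_equal(rec$T_hat, T0, tolerance = 1e-6)
  expect_lt(rec$residual_norm, 1e-6)
})

test_that("FISTA matches an independent LASSO solver on small instances", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  for (i in 1:4) {
    m <- sample(20:50, 1)
    n <- sample(10:40, 1)
    A <- matrix(stats::rnorm(m * n), m, n)
    beta <- stats::rbinom(n, 1, 0.25) * stats::rnorm(n)
    S <- as.vector(A %*% beta + 0.1 * stats::rnorm(m))
    a2 <- 0.1 * 2 * max(abs(crossprod(A, S)))
    rec <- fista_solve(A, S, solver_config(sqrt(a2), max_iters = 30000,
                                           tolerance = 1e-15))
    obj_f <- utils::tail(rec$objective_trace, 1)
    # glmnet minimizes RSS/(2m) + lambda ||beta||_1
    g <- glmnet::glmnet(A, S, lambda = a2 / (2 * m), intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
    Tg <- as.vector(stats::coef(g))[-1]
    obj_g <- sum((S - A %*% Tg)^2) + a2 * sum(abs(Tg))
    expect_lt(abs(obj_f - obj_g) / obj_g, 1e-6)
  }
})

test_that("objective trace is non-increasing and optimality conditions hold", {
  set.seed(5)
  A <- matrix(stats::rnorm(40 * 25), 40, 25)
  S <- as.vector(A %*% (stats::rbinom(25, 1, 0.2) * 2) + 0.05 * stats::rnorm(40))
  a2 <- 0.05 * 2 * max(abs(crossprod(A, S)))
  rec <- fista_solve(A, S, solver_config(sqrt(a2), max_iters = 30000,
                                         tolerance = 1e-15))
  expect_true(all(diff(rec$objective_trace) <= 1e-9))

  grad <- as.vector(2 * crossprod(A, A %*% rec$T_hat - S))
  zero_set <- setdiff(seq_len(25), rec$support)
  tol <- 1e-5 * a2
  expect_true(all(abs(grad[zero_set]) <= a2 + tol))
  expect_true(all(abs(grad[rec$support] +
                        a2 * sign(rec$T_hat[rec$support])) <= tol + 1e-6))
})

test_that("solutions are homogeneous under joint scaling of S and alpha", {
  set.seed(6)
  A <- matrix(stats::rnorm(30 * 15), 30, 15)
  S <- as.vector(A %*% (stats::rbinom(15, 1, 0.3)) + 0.1 * stats::rnorm(30))
  a2 <- 0.1 * 2 * max(abs(crossprod(A, S)))
  cfg <- solver_config(sqrt(a2), max_iters = 20000, tolerance = 1e-15)
  rec1 <- fista_solve(A, S, cfg)
  cc <- 3.7
  cfg2 <- solver_config(sqrt(cc) * sqrt(a2), max_iters = 20000,
                        tolerance = 1e-15)
  rec2 <- fista_solve(A, cc * S, cfg2)
  expect_equal(rec2$T_hat, cc * rec1$T_hat, tolerance = 1e-5)
})

test_that("solver guards dimensions and supports nonnegativity", {
  A <- matrix(1:6, 3, 2)
  expect_error(fista_solve(A, c(1, 2), solver_config(1)),
               class = "sparsus_error_dimension")

  set.seed(7)
  B <- matrix(stats::rnorm(30 * 12), 30, 12)
  S <- as.vector(B %*% abs(stats::rnorm(12)))
  rec <- fista_solve(B, S, solver_config(0.5, max_iters = 5000,
                                         tolerance = 1e-12,
                                         nonnegativity = TRUE))
  expect_true(all(rec$T_hat >= 0))
})

test_that("alpha at or above alpha_max yields the all-zero solution", {
  set.seed(8)
  A <- matrix(stats::rnorm(30 * 12), 30, 12)
  S <- as.vector(A %*% stats::rbinom(12, 1, 0.4))
  a2max <- 2 * max(abs(crossprod(A, S)))
  rec <- fista_solve(A, S, solver_config(sqrt(a2max * 1.0001),
                                         max_iters = 500, tolerance = 1e-12))
  expect_length(rec$support, 0)

  # well below alpha_max the solution is nonempty
  rec2 <- fista_solve(A, S, solver_config(sqrt(a2max * 0.01),
                                          max_iters = 5000, tolerance = 1e-12))
  expect_gt(length(rec2$support), 0)
})

test_that("alpha scan reports the support/residual trade-off and a choice", {
  set.seed(9)
  A <- matrix(stats::rnorm(60 * 30), 60, 30)
  S <- as.vector(A %*% (stats::rbinom(30, 1, 0.15) * 3) +
                   0.05 * stats::rnorm(60))
  ca <- choose_alpha(A, S, support_budget = 10,
                     max_iters = 3000, tolerance = 1e-10)
  expect_s3_class(ca$scan, "tbl_df")
  expect_equal(nrow(ca$scan), 8)
  expect_true(ca$flag %in% c("ok", "all_above_budget", "all_empty"))
  if (ca$flag == "ok") {
    expect_lte(ca$scan$eff_support[ca$scan$alpha == ca$alpha], 10)
    picked <- ca$scan$eff_support > 0 & ca$scan$eff_support <= 10
    expect_equal(ca$alpha, min(ca$scan$alpha[picked]))
  }
  expect_true(all(ca$scan$eff_support <= ca$scan$support))
  # residuals shrink as alpha shrinks along the scan
  expect_true(all(diff(ca$scan$residual_norm) <= 1e-8))
})

test_that("tidy and glance summarize reconstructions", {
  set.seed(10)
  A <- matrix(stats::rnorm(30 * 12), 30, 12)
  S <- as.vector(A %*% stats::rbinom(12, 1, 0.4))
  rec <- fista_solve(A, S, solver_config(0.8, max_iters = 2000,
                                         tolerance = 1e-10))
  td <- tidy(rec)
  expect_named(td, c("point", "value"))
  expect_equal(td$value, rec$T_hat[rec$support])
  gl <- glance(rec)
  expect_equal(gl$support_size, length(rec$support))
  expect_equal(gl$alpha, 0.8)
})
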