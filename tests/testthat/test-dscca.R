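std_pair <- function(n = 80, p = 6, q = 7, rho = 0.8, seed = 2) {
  set.seed(seed)
  z <- rnorm(n)
  x <- cbind(z + rnorm(n, sd = 0.4), matrix(rnorm(n * (p - 1)), n))
  y <- cbind(z + rnorm(n, sd = 0.4), matrix(rnorm(n * (q - 1)), n))
  list(x = standardize(x), y = standardize(y))
}

test_that("soft thresholding satisfies the L1 subgradient optimality condition", {
  set.seed(3)
  for (i in 1:10) {
    z <- rnorm(20, sd = 2)
    lam <- runif(1, 0, 2)
    w <- soft_threshold(z, lam)
    # w minimizes 1/2 (w - z)^2 + lam |w|: check the subgradient conditions
    expect_true(all(abs(z[w == 0]) <= lam + 1e-12))
    nz <- w != 0
    expect_equal(w[nz], z[nz] - lam * sign(w[nz]), tolerance = 1e-12)
  }
})

test_that("identical single-column views give canonical correlation 1", {
  set.seed(4)
  x <- standardize(matrix(rnorm(30), 30, 1))
  fit <- dscca(x, x)
  expect_equal(fit$cor, 1, tolerance = 1e-8)
})

test_that("the objective trace is monotone nonincreasing", {
  d <- std_pair()
  for (lam in c(0, 0.05, 0.2)) {
    fit <- suppressWarnings(dscca(d$x, d$y, lambda1 = lam, lambda2 = lam))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
  pg <- to_laplacian(matrix(runif(80 * 80), 80, 80), level = "subject")
  fit <- dscca(d$x, d$y, lambda1 = 0.1, lambda2 = 0.1,
               beta1 = 0.5, beta2 = 0.5, prior = pg)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("with no penalties the solver recovers classical CCA", {
  set.seed(6)
  x <- standardize(matrix(rnorm(100 * 5), 100, 5))
  y <- standardize(x %*% matrix(rnorm(25), 5, 5) +
                     matrix(rnorm(500), 100, 5) * 2)
  fit <- dscca(x, y)   # beta = lambda = 0, gamma = 1
  expect_equal(fit$cor, cca_first_corr(x, y), tolerance = 1e-3)
})

test_that("the SCCA baseline is bit-identical to DSCCA with beta = 0", {
  d <- std_pair(seed = 7)
  f1 <- scca(d$x, d$y, lambda1 = 0.1, lambda2 = 0.1)
  f2 <- dscca(d$x, d$y, lambda1 = 0.1, lambda2 = 0.1, beta1 = 0, beta2 = 0)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("increasing lambda weakly decreases the support size", {
  d <- std_pair(n = 100, p = 10, q = 12, seed = 8)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(lam) {
    fit <- suppressWarnings(dscca(d$x, d$y, lambda1 = lam, lambda2 = lam))
    sum(fit$u != 0) + sum(fit$v != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("fits are deterministic and sign-standardized", {
  d <- std_pair(seed = 9)
  f1 <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05)
  f2 <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$u, f2$u)
  expect_gt(f1$u[which.max(abs(f1$u))], 0)
  r1 <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05,
              init = "random", seed = 11)
  r2 <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05,
              init = "random", seed = 11)
  expect_identical(r1$u, r2$u)
})

test_that("fitted composites have unit norm and graph penalties engage", {
  d <- std_pair(seed = 10)
  # informative subject graph: connect subjects with similar latent values
  fit <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05)
  expect_equal(sqrt(sum((d$x %*% fit$u)^2)), 1, tolerance = 1e-6)
  expect_equal(sqrt(sum((d$y %*% fit$v)^2)), 1, tolerance = 1e-6)
  W <- matrix(runif(80 * 80, 0, 0.2), 80, 80)
  pg <- to_laplacian(W, level = "subject")
  fitb <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05,
                beta1 = 2, beta2 = 2, prior = pg)
  # the penalized fit differs from the unpenalized one
  expect_gt(sum(abs(fitb$u - fit$u)), 1e-6)
  expect_error(dscca(d$x, d$y, prior = to_laplacian(matrix(0.1, 9, 9)),
                     beta1 = 1), "dimension")
})

test_that("over-thresholded fits warn and are flagged unusable", {
  d <- std_pair(seed = 12)
  w <- capture_warnings(fit <- dscca(d$x, d$y, lambda1 = 50, lambda2 = 50))
  expect_match(w, "lambda too large", all = FALSE)
  expect_false(fit$converged)
  expect_true(all(fit$u == 0) || all(fit$v == 0))
})

test_that("canonical_correlation behaves on edge cases", {
  d <- std_pair(seed = 13)
  fit <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05)
  r <- canonical_correlation(fit, d$x, d$y)
  expect_equal(r, fit$cor, tolerance = 1e-12)
  # elementwise-equal projections
  fit_id <- fit; fit_id$v <- numeric(length(fit$v))
  expect_warning(r0 <- canonical_correlation(fit_id, d$x, d$y), "constant")
  expect_equal(r0, 0)
  # sign flip of one side negates the correlation
  fit_neg <- fit; fit_neg$u <- -fit$u
  expect_equal(canonical_correlation(fit_neg, d$x, d$y), -r, tolerance = 1e-12)
})

test_that("predict, coef, summary and print work on fitted models", {
  d <- std_pair(seed = 14)
  fit <- dscca(d$x, d$y, lambda1 = 0.05, lambda2 = 0.05)
  pr <- predict(fit, d$x, d$y)
  expect_identical(names(pr), c("xu", "yv"))
  expect_equal(cor(pr$xu, pr$yv), fit$cor, tolerance = 1e-12)
  expect_identical(coef(fit, "u"), fit$u)
  expect_output(print(fit), "canonical correlation")
  expect_output(print(summary(fit)), "Top x-side")
})
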