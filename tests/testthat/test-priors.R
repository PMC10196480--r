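test_that("diagnosis network is a normalized block graph", {
  lab <- setNames(factor(c("A", "A", "A", "B", "B")), paste0("s", 1:5))
  pg <- diagnosis_network(lab)
  M <- pg$matrix
  # to_laplacian zeroes the diagonal of the stored matrix; check structure
  expect_equal(unname(M[1, 2:3]), c(0.25, 0.25))  # group of 3: 1/(2*(3-1))
  expect_equal(unname(M[4, 5]), 0.5)              # group of 2: 1/(2*1)
  expect_true(all(M[1:3, 4:5] == 0))              # exact block zeros
  # row sums of the pre-Laplacian graph (diag 1/2 restored) are exactly 1
  expect_equal(unname(rowSums(M) + 0.5), rep(1, 5))
  # literal variant divides by group size g instead
  pg_lit <- diagnosis_network(lab, literal = TRUE)
  expect_equal(unname(pg_lit$matrix[1, 2]), 1 / 6)
  expect_equal(unname(pg_lit$matrix[4, 5]), 1 / 4)
  expect_error(diagnosis_network(factor(c("A", "A", "B"))), "singleton.*B")
})

test_that("a single diagnosis group gives the complete-graph prior", {
  pg <- diagnosis_network(factor(rep("CN", 4)))
  off <- pg$matrix[upper.tri(pg$matrix)]
  expect_true(all(off == off[1]) && off[1] > 0)
  expect_equal(sum(pg$matrix[1, ] > 0), 3)  # connected to every other subject
})

test_that("laplacian construction is symmetric, zero-row-sum, PSD", {
  # 2-node graph with weight w
  w <- 0.7
  pg <- to_laplacian(matrix(c(0, w, w, 0), 2, 2), level = "feature")
  expect_equal(pg$laplacian, matrix(c(w, -w, -w, w), 2, 2))
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(runif(36), 6, 6)  # asymmetric, gets symmetrized
    pg <- to_laplacian(A, level = "subject")
    expect_equal(unname(rowSums(pg$laplacian)), rep(0, 6), tolerance = 1e-10)
    ev <- eigen(pg$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(to_laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("laplacian quadratic form equals the explicit edge double sum", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    pg <- to_laplacian(W, level = "subject")
    z <- rnorm(n)
    expect_equal(drop(crossprod(z, pg$laplacian %*% z)),
                 double_sum_penalty(W, z), tolerance = 1e-10)
  }
})

test_that("penalty_value handles both prior levels and degenerate inputs", {
  set.seed(12)
  X <- matrix(rnorm(40), 8, 5)
  u <- rnorm(5)
  # single-edge subject graph: penalty = w * ((Xu)_i - (Xu)_j)^2
  W <- matrix(0, 8, 8); W[2, 5] <- W[5, 2] <- 0.6
  pg <- to_laplacian(W, level = "subject")
  z <- drop(X %*% u)
  expect_equal(penalty_value(u, X, pg), 0.6 * (z[2] - z[5])^2,
               tolerance = 1e-12)
  expect_equal(penalty_value(u, X, pg), double_sum_penalty(W, z),
               tolerance = 1e-12)
  expect_equal(penalty_value(numeric(5), X, pg), 0)
  expect_equal(penalty_value(u, X, to_laplacian(matrix(0, 8, 8))), 0)
  # feature-level: acts on the weights directly
  Wf <- matrix(0, 5, 5); Wf[1, 2] <- Wf[2, 1] <- 1
  pf <- to_laplacian(Wf, level = "feature")
  expect_equal(penalty_value(u, X, pf), (u[1] - u[2])^2, tolerance = 1e-12)
  expect_error(penalty_value(u, X[, 1:3], pg), "weight length")
  expect_error(penalty_value(rnorm(8), X, pf), "feature-level")
})

test_that("co-expression network matches a direct partial-correlation oracle", {
  set.seed(21)
  ns <- 10; ng <- 5
  expr <- matrix(rnorm(ns * ng), ns, ng,
                 dimnames = list(paste0("samp", 1:ns), paste0("g", 1:ng)))
  roi <- rep(paste0("roi", 1:5), each = 2)
  pg <- coexpression_network(expr, roi)
  # oracle: ridge-regularized inverse covariance between samples,
  # scaled to partial correlations, aggregated blockwise by median
  C <- cov(t(expr))
  Th <- solve(C + diag(1e-3 * sum(diag(C)) / ns, ns))
  pc <- -Th / sqrt(outer(diag(Th), diag(Th)))
  rois <- sort(unique(roi))
  expected <- matrix(0, 5, 5)
  for (a in 1:5) for (b in 1:5) {
    ia <- which(roi == rois[a]); ib <- which(roi == rois[b])
    blk <- pc[ia, ib]
    expected[a, b] <- if (a == b) 0 else median(blk)
  }
  expected[expected < 0] <- 0
  expect_equal(unname(pg$matrix), expected, tolerance = 1e-8)
  expect_identical(pg$level, "feature")
  # identical profiles in two singleton regions give (up to the ridge
  # regularization, which damps the singular duplicate pair) an entry at
  # the top of the similarity scale
  expr2 <- expr; expr2[3, ] <- expr2[1, ]
  pg2 <- coexpression_network(expr2, paste0("r", 1:10))
  m <- pg2$matrix
  expect_gte(unname(m["r1", "r3"]), 0.95 * max(m))
  expect_equal(unname(diag(m)), rep(0, 10))  # singleton diagonal blocks
  expect_error(coexpression_network(expr, roi, gene_subset = c("g1", "nope")),
               "nope")
})
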