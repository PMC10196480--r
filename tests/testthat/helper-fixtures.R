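# Shared fixtures and independent oracles used across the test files.

# small standardized matrix with rownames, deterministic
rand_fm <- function(n, m, seed = 1, prefix = "s") {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                              sprintf("f%02d", seq_len(m))))
  x
}

# well-separated subject clusters in two modalities
clustered_cohort <- function(n_per = 10, m = 6, sep = 6, seed = 42, k = 3) {
  set.seed(seed)
  centers <- matrix(rnorm(k * m), k, m) * sep
  g <- rep(seq_len(k), each = n_per)
  mk <- function() centers[g, ] + matrix(rnorm(length(g) * m), ncol = m)
  x <- mk(); y <- mk()
  ids <- sprintf("s%02d", seq_along(g))
  dimnames(x) <- list(ids, sprintf("a%02d", 1:m))
  dimnames(y) <- list(ids, sprintf("b%02d", 1:m))
  list(x = x, y = y, groups = g, ids = ids)
}

# closed-form first canonical correlation via the generalized eigenproblem
# (independent of the package's iterative solver)
cca_first_corr <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  Sxx <- crossprod(X); Syy <- crossprod(Y); Sxy <- crossprod(X, Y)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(Re(eigen(M, only.values = TRUE)$values)))
}

# explicit Laplacian quadratic form: 1/2 sum_ij W_ij (z_i - z_j)^2
double_sum_penalty <- function(W, z) {
  n <- length(z)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + W[i, j] * (z[i] - z[j])^2
  acc / 2
}

# the Eq-(3)-style status renormalization, written independently
status_oracle <- function(M) {
  P <- M
  for (i in seq_len(nrow(M))) {
    s <- sum(M[i, -i])
    P[i, ] <- M[i, ] / (2 * s)
    P[i, i] <- 0.5
  }
  P
}

expect_row_stochastic <- function(P, tol = 1e-12) {
  expect_equal(unname(rowSums(as.matrix(P))), rep(1, nrow(P)), tolerance = tol)
}
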