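#' Soft-thresholding operator
#'
#' Proximal operator of the L1 norm, `sign(z) * max(|z| - lambda, 0)`; the
#' elementwise shrinkage step at the heart of the sparse CCA solver.
#'
#' @param z numeric vector.
#' @param lambda nonnegative threshold.
#' @export
soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# assemble one side's quadratic-term matrix in covariance (1/n) scale:
# gamma X'X/n + beta * prior penalty
penalty_matrix <- function(X, gamma, beta, prior) {
  n <- nrow(X)
  A <- gamma * crossprod(X) / n
  if (beta > 0 && !is.null(prior)) {
    if (is.null(prior$laplacian)) prior <- to_laplacian(prior)
    L <- prior$laplacian
    if (prior$level == "subject") {
      if (nrow(L) != nrow(X))
        stop("subject-level prior dimension ", nrow(L),
             " != number of subjects ", nrow(X))
      A <- A + beta * crossprod(X, L %*% X) / n
    } else {
      if (nrow(L) != ncol(X))
        stop("feature-level prior dimension ", nrow(L),
             " != number of features ", ncol(X))
      A <- A + beta * L
    }
  }
  A
}

resolve_priors <- function(prior, prior_v = NULL) {
  if (is.null(prior)) return(list(u = NULL, v = NULL))
  if (inherits(prior, "similarity_network")) prior <- to_laplacian(prior)
  if (inherits(prior, "prior_graph")) {
    if (prior$level == "subject") return(list(u = prior, v = prior))
    return(list(u = prior, v = prior_v))
  }
  if (is.list(prior)) return(list(u = prior$u, v = prior$v))
  stop("prior must be NULL, a prior_graph, a similarity_network, ",
       "or list(u =, v =)")
}

#' Discriminative sparse canonical correlation analysis
#'
#' Finds sparse weight vectors `u`, `v` associating two column-standardized
#' data views `x` (subjects x p, e.g. regional imaging traits) and `y`
#' (subjects x q, e.g. SNP dosages) by maximizing
#' \deqn{u^\top X^\top Y v - \tfrac{\gamma_1}{2}\|Xu\|_2^2 -
#'   \tfrac{\gamma_2}{2}\|Yv\|_2^2 - \tfrac{\beta_1}{2} P_1(u) -
#'   \tfrac{\beta_2}{2} P_2(v) - \lambda_1\|u\|_1 - \lambda_2\|v\|_1,}
#' the Lagrangian form of sparse CCA with discriminative graph penalties
#' \eqn{P_1(u) = u^\top X^\top L X u} (subject-level prior with Laplacian
#' \eqn{L}; see [to_laplacian()]) or \eqn{u^\top L u} (feature-level prior).
#' The problem is biconvex; each conditional problem is solved by
#' Nesterov-accelerated proximal gradient with L1 soft-thresholding, and the
#' two sides alternate until the objective changes by less than `stop_tol`.
#'
#' Internally all moment matrices are taken in covariance scale
#' (\eqn{X^\top Y/n} etc.) and after every update each weight vector is
#' renormalized to unit composite variance (\eqn{u^\top X^\top X u / n = 1})
#' — the scale constraint of the original two-view problem. The pinned
#' scale is what gives the L1 threshold a stable operating point: without
#' it the bilinear term can never outweigh the quadratic terms (for
#' canonical correlation < 1 the unconstrained optimum is \eqn{u = v = 0})
#' and the iteration collapses. `objective_trace` records the objective at
#' the normalized iterates and is nonincreasing by construction (a cycle
#' that fails to decrease it is rejected and the alternation stops).
#' The fitted weights are finally rescaled so the composites satisfy
#' \eqn{\|Xu\|_2 = \|Yv\|_2 = 1}, and signs are flipped so the
#' largest-magnitude entry of `u` is positive.
#'
#' @param x,y column-standardized numeric matrices with the same subjects in
#'   rows (see [standardize()]).
#' @param lambda1,lambda2 L1 sparsity penalties for `u` and `v`.
#' @param beta1,beta2 strengths of the graph prior penalty on each side.
#' @param gamma1,gamma2 weights of the variance terms; the method is
#'   insensitive to these and both default to 1.
#' @param prior `NULL` (plain sparse CCA), a subject-level [prior_graph()]
#'   or fused `similarity_network` shared by both sides, or
#'   `list(u = , v = )` of feature-level priors.
#' @param init `"svd"` (deterministic: leading singular pair of
#'   \eqn{X^\top Y}) or `"random"` (Gaussian, controlled by `seed`).
#' @param seed RNG seed used only for random initialization.
#' @param max_outer,stop_tol outer alternation limit and absolute
#'   objective-change stopping tolerance (defaults 100 and 1e-6).
#' @param max_inner,inner_tol per-side proximal-gradient limit and relative
#'   weight-change tolerance (defaults 1000 and 1e-8).
#' @return an object of class `"dscca"`: list with named weight vectors `u`,
#'   `v`, the canonical correlation `cor` on the training data,
#'   `objective_trace` (one value per outer iteration, nonincreasing),
#'   `converged`, `n_iter`, and the hyperparameters.
#' @seealso [scca()] for the no-prior baseline, [cv_dscca()] for tuned,
#'   cross-validated comparisons.
#' @examples
#' set.seed(1)
#' z <- rnorm(60)
#' x <- standardize(cbind(z + rnorm(60, sd = .3), matrix(rnorm(240), 60)))
#' y <- standardize(cbind(z + rnorm(60, sd = .3), matrix(rnorm(240), 60)))
#' fit <- dscca(x, y, lambda1 = .2, lambda2 = .2)
#' fit$cor
#' @export
dscca <- function(x, y, lambda1 = 0, lambda2 = 0, beta1 = 0, beta2 = 0,
                  gamma1 = 1, gamma2 = 1, prior = NULL,
                  init = c("svd", "random"), seed = NULL,
                  max_outer = 100, stop_tol = 1e-6,
                  max_inner = 1000, inner_tol = 1e-8) {
  init <- match.arg(init)
  X <- unclass(as.matrix(x)); Y <- unclass(as.matrix(y))
  if (nrow(X) != nrow(Y)) stop("x and y must have the same subjects")
  stopifnot(lambda1 >= 0, lambda2 >= 0, beta1 >= 0, beta2 >= 0,
            gamma1 >= 0, gamma2 >= 0)
  pr <- resolve_priors(prior)
  n <- nrow(X)
  C <- crossprod(X, Y) / n
  Sx <- crossprod(X) / n
  Sy <- crossprod(Y) / n
  A1 <- penalty_matrix(X, gamma1, beta1, pr$u)
  A2 <- penalty_matrix(Y, gamma2, beta2, pr$v)
  if (init == "svd") {
    sv <- svd(C, nu = 1, nv = 1)
    u0 <- sv$u[, 1]; v0 <- sv$v[, 1]
  } else {
    u0 <- with_seed(seed, rnorm(ncol(X)))
    v0 <- with_seed(if (is.null(seed)) NULL else seed + 1L, rnorm(ncol(Y)))
    u0 <- u0 / sqrt(sum(u0^2)); v0 <- v0 / sqrt(sum(v0^2))
  }
  sol <- dscca_solve_cpp(C, A1, A2, Sx, Sy, lambda1, lambda2, u0, v0,
                         as.integer(max_outer), stop_tol,
                         as.integer(max_inner), inner_tol)
  u <- drop(sol$u); v <- drop(sol$v)
  converged <- isTRUE(sol$converged)
  nu <- sqrt(sum((X %*% u)^2)); nv <- sqrt(sum((Y %*% v)^2))
  if (nu < 1e-12 || nv < 1e-12) {
    warning("all-zero weight vector after thresholding ",
            "(lambda too large); model not usable")
    converged <- FALSE
  } else {
    u <- u / nu; v <- v / nv
    s <- sign(u[which.max(abs(u))])
    if (s < 0) { u <- -u; v <- -v }
  }
  names(u) <- if (!is.null(colnames(X))) colnames(X)
              else paste0("x", seq_along(u))
  names(v) <- if (!is.null(colnames(Y))) colnames(Y)
              else paste0("y", seq_along(v))
  fit <- structure(list(
    u = u, v = v,
    cor = safe_cor(X %*% u, Y %*% v),
    hyperparams = list(lambda1 = lambda1, lambda2 = lambda2, beta1 = beta1,
                       beta2 = beta2, gamma1 = gamma1, gamma2 = gamma2),
    prior_level = if (!is.null(pr$u)) pr$u$level else NULL,
    prior_source = if (!is.null(pr$u)) pr$u$source else "none",
    objective_trace = drop(sol$objective_trace),
    converged = converged, n_iter = sol$n_iter,
    n = nrow(X), p = ncol(X), q = ncol(Y),
    call = match.call()), class = "dscca")
  fit
}

#' Sparse CCA baseline (no prior)
#'
#' The L1-penalized sparse CCA without any graph penalty — identical to
#' [dscca()] with `beta1 = beta2 = 0`, exposed as the comparison baseline.
#'
#' @inheritParams dscca
#' @param ... further arguments passed to [dscca()].
#' @return a `"dscca"` object.
#' @export
scca <- function(x, y, lambda1 = 0, lambda2 = 0, ...) {
  fit <- dscca(x, y, lambda1 = lambda1, lambda2 = lambda2,
               beta1 = 0, beta2 = 0, prior = NULL, ...)
  fit$call <- match.call()
  fit
}

safe_cor <- function(a, b, warn = TRUE) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    if (warn) warning("constant canonical composite; correlation set to 0")
    return(0)
  }
  drop(cor(a, b))
}

#' Canonical correlation of a fitted model on (new) data
#'
#' Pearson correlation between the composites `Xu` and `Yv`; the held-out
#' version of this is the test metric of the cross-validation reports.
#'
#' @param model a fitted `"dscca"` object.
#' @param x,y data matrices conforming to the training feature sets
#'   (standardize test data with the training statistics).
#' @return scalar correlation; 0 with a warning if either composite is
#'   constant (e.g. an all-zero weight vector).
#' @export
canonical_correlation <- function(model, x, y) {
  stopifnot(inherits(model, "dscca"))
  safe_cor(as.matrix(x) %*% model$u, as.matrix(y) %*% model$v)
}

#' @export
print.dscca <- function(x, ...) {
  h <- x$hyperparams
  cat("Sparse canonical correlation model",
      if (x$prior_source != "none")
        sprintf("(prior: %s, %s-level)", x$prior_source, x$prior_level)
      else "(no prior)", "\n")
  cat(sprintf("  n = %d subjects, p = %d x-features, q = %d y-features\n",
              x$n, x$p, x$q))
  cat(sprintf("  lambda = (%g, %g), beta = (%g, %g), gamma = (%g, %g)\n",
              h$lambda1, h$lambda2, h$beta1, h$beta2, h$gamma1, h$gamma2))
  cat(sprintf("  nonzero weights: |u| = %d / %d, |v| = %d / %d\n",
              sum(x$u != 0), x$p, sum(x$v != 0), x$q))
  cat(sprintf("  training canonical correlation: %.4f (%s in %d iterations)\n",
              x$cor, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' @export
coef.dscca <- function(object, side = c("both", "u", "v"), ...) {
  side <- match.arg(side)
  switch(side, u = object$u, v = object$v,
         both = list(u = object$u, v = object$v))
}

#' Project new data onto the canonical composites
#'
#' @param object a fitted `"dscca"` model.
#' @param x,y matrices conforming to the training feature sets.
#' @param ... unused.
#' @return data frame with columns `xu` and `yv` (one row per subject).
#' @export
predict.dscca <- function(object, x, y, ...) {
  data.frame(xu = drop(as.matrix(x) %*% object$u),
             yv = drop(as.matrix(y) %*% object$v))
}

#' @export
summary.dscca <- function(object, top = 10, ...) {
  pick <- function(w) {
    w <- w[w != 0]
    head(w[order(-abs(w), names(w))], top)
  }
  out <- list(fit = object, top_u = pick(object$u), top_v = pick(object$v))
  class(out) <- "summary.dscca"
  out
}

#' @export
print.summary.dscca <- function(x, ...) {
  print(x$fit)
  cat("\nTop x-side features (by |weight|):\n")
  print(round(x$top_u, 4))
  cat("\nTop y-side features (by |weight|):\n")
  print(round(x$top_v, 4))
  invisible(x)
}

#' @export
plot.dscca <- function(x, ...) {
  plot(seq_along(x$objective_trace) - 1L, x$objective_trace, type = "b",
       xlab = "outer iteration", ylab = "objective (minimization form)",
       main = "DSCCA objective trace", ...)
  invisible(x)
}
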