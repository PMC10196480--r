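#' Prior graph objects
#'
#' A prior graph wraps a square nonnegative similarity/affinity matrix with
#' the level at which it applies — `"subject"` (n x n, penalizing the
#' canonical composites across similar subjects) or `"feature"` (p x p or
#' q x q, penalizing the weight vectors directly) — and, once
#' [to_laplacian()] has run, the combinatorial graph Laplacian used as the
#' penalty in [dscca()].
#'
#' @param matrix square nonnegative numeric matrix.
#' @param level `"subject"` or `"feature"`.
#' @param source provenance tag: `"fused"`, `"diagnosis"`, `"coexpression"`
#'   or `"custom"`.
#' @return object of class `"prior_graph"` with fields `matrix`, `level`,
#'   `laplacian` (populated by [to_laplacian()]) and `source`.
#' @export
prior_graph <- function(matrix, level = c("subject", "feature"),
                        source = "custom") {
  level <- match.arg(level)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("prior graph matrix must be square")
  structure(list(matrix = m, level = level, laplacian = NULL, source = source),
            class = "prior_graph")
}

#' @export
print.prior_graph <- function(x, ...) {
  cat(sprintf("<prior_graph: %d nodes, level = %s, source = %s, laplacian %s>\n",
              nrow(x$matrix), x$level, x$source,
              if (is.null(x$laplacian)) "pending" else "ready"))
  invisible(x)
}

#' Diagnosis block network
#'
#' Complete graph within each diagnosis group, zero across groups, scaled so
#' self-similarity is 1/2. With the default `literal = FALSE`, within-group
#' off-diagonal entries are \eqn{1/(2(g-1))} for a group of size \eqn{g},
#' which makes every row sum to exactly 1 (the stated purpose of the
#' normalization). `literal = TRUE` uses the divisor \eqn{g} instead, giving
#' row sums \eqn{(2g-1)/(2g)}.
#'
#' @param labels factor (or coercible) of one diagnosis per subject,
#'   names taken as subject ids when present.
#' @param literal use the group-size divisor (see Details).
#' @return a subject-level [prior_graph()] with Laplacian populated.
#' @export
diagnosis_network <- function(labels, literal = FALSE) {
  f <- droplevels(as.factor(labels))
  n <- length(f)
  sizes <- table(f)
  if (any(sizes < 2))
    stop("singleton diagnosis group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  M <- matrix(0, n, n)
  for (g in levels(f)) {
    idx <- which(f == g)
    gsize <- length(idx)
    div <- if (literal) gsize else gsize - 1L
    M[idx, idx] <- 1 / (2 * div)
  }
  diag(M) <- 0.5
  ids <- names(labels)
  if (!is.null(ids)) dimnames(M) <- list(ids, ids)
  to_laplacian(prior_graph(M, "subject", source = "diagnosis"))
}

#' Feature-level co-expression network
#'
#' Builds a region-by-region similarity from a gene-expression matrix whose
#' samples map onto imaging regions. A sample-by-sample partial-correlation
#' matrix is computed on the selected genes (Gaussian graphical convention:
#' negated, scaled inverse of the ridge-regularized between-sample
#' covariance), then each region pair's block is aggregated by the median,
#' negative aggregates are clipped to 0 and the diagonal is zeroed.
#'
#' @param expr samples x genes numeric matrix (sample ids as row names).
#' @param sample_to_roi character/factor mapping each sample (by position or
#'   name) to a region id.
#' @param gene_subset optional gene ids to restrict to; an error lists any
#'   that are absent from `expr`.
#' @param ridge ridge regularization multiplier applied as
#'   `ridge * trace(C)/dim` on the between-sample covariance (default 1e-3),
#'   needed because few genes make the covariance singular.
#' @return a feature-level [prior_graph()] (regions as nodes) with Laplacian
#'   populated.
#' @export
coexpression_network <- function(expr, sample_to_roi, gene_subset = NULL,
                                 ridge = 1e-3) {
  X <- as.matrix(expr)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, colnames(X))
    if (length(missing))
      stop("gene(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    X <- X[, gene_subset, drop = FALSE]
  }
  ns <- nrow(X)
  roi <- as.character(sample_to_roi)
  if (length(roi) != ns) stop("sample_to_roi must map every expression sample")
  # covariance between sample profiles, taken across genes
  C <- stats::cov(t(X))
  eps <- ridge * sum(diag(C)) / ns
  Theta <- solve(C + diag(eps, ns))
  d <- sqrt(diag(Theta))
  pcor <- -Theta / outer(d, d)
  diag(pcor) <- 1
  rois <- sort(unique(roi))
  R <- matrix(0, length(rois), length(rois), dimnames = list(rois, rois))
  for (a in seq_along(rois)) for (b in seq_len(a)) {
    ia <- which(roi == rois[a]); ib <- which(roi == rois[b])
    block <- pcor[ia, ib, drop = FALSE]
    if (a == b) {
      off <- block[row(block) != col(block)]
      R[a, a] <- if (length(off)) median(off) else 0
    } else {
      R[a, b] <- R[b, a] <- median(block)
    }
  }
  R[R < 0] <- 0
  diag(R) <- 0
  to_laplacian(prior_graph(R, "feature", source = "coexpression"))
}

#' Populate the combinatorial Laplacian of a prior graph
#'
#' Symmetrizes the graph matrix as \eqn{(M + M^\top)/2}, zeroes its diagonal
#' and sets \eqn{L = D - M_{sym}} with \eqn{D} the degree diagonal. The
#' unnormalized Laplacian is positive semidefinite with zero row sums, and
#' its quadratic form is the weighted sum of squared differences across
#' edges — the quantity the discriminative penalty minimizes.
#'
#' @param graph a [prior_graph()], a `similarity_network` (treated as a
#'   subject-level prior) or a plain square matrix.
#' @param level level tag used when `graph` is not already a `prior_graph`.
#' @return the [prior_graph()] with `matrix` symmetrized and `laplacian`
#'   filled in.
#' @export
to_laplacian <- function(graph, level = "subject") {
  if (inherits(graph, "similarity_network")) {
    src <- if (identical(network_kind(graph), "fused")) "fused" else "custom"
    graph <- prior_graph(as.matrix(graph), "subject", source = src)
  } else if (!inherits(graph, "prior_graph")) {
    graph <- prior_graph(as.matrix(graph), level)
  }
  M <- (graph$matrix + t(graph$matrix)) / 2
  diag(M) <- 0
  if (any(M < 0))
    stop("negative edge weight(s) after symmetrization; clip upstream")
  L <- diag(rowSums(M)) - M
  dimnames(L) <- dimnames(M)
  graph$matrix <- M
  graph$laplacian <- L
  graph
}

#' Graph-Laplacian penalty value
#'
#' Evaluates the discriminative penalty for one weight vector. For a
#' subject-level prior the penalty is \eqn{w^\top X^\top L X w} — the
#' Laplacian quadratic form of the canonical composite \eqn{Xw} over the
#' subject graph; for a feature-level prior it is \eqn{w^\top L w} on the
#' weights directly.
#'
#' @param w weight vector.
#' @param data subjects x features matrix the weights apply to (used only
#'   for subject-level priors).
#' @param prior a [prior_graph()] with Laplacian populated (see
#'   [to_laplacian()]).
#' @return nonnegative scalar (up to numerical noise).
#' @export
penalty_value <- function(w, data, prior) {
  if (is.null(prior$laplacian)) prior <- to_laplacian(prior)
  L <- prior$laplacian
  if (prior$level == "subject") {
    if (nrow(L) != nrow(data))
      stop("subject-level prior: Laplacian dimension ", nrow(L),
           " != number of subjects ", nrow(data))
    if (length(w) != ncol(data)) stop("weight length != number of features")
    z <- as.vector(as.matrix(data) %*% w)
    drop(crossprod(z, L %*% z))
  } else {
    if (nrow(L) != length(w))
      stop("feature-level prior: Laplacian dimension ", nrow(L),
           " != weight length ", length(w))
    drop(crossprod(w, L %*% w))
  }
}
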