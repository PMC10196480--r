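#' Euclidean distance between subjects
#'
#' @param fm standardized feature matrix (subjects x features).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(fm) {
  x <- unclass(as.matrix(fm))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects (kernel scaling undefined below)")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

as_network <- function(m, kind, mu = NA_real_, K = NA_integer_) {
  attr(m, "kind") <- kind
  attr(m, "params") <- list(mu = mu, K = as.integer(K))
  class(m) <- c("similarity_network", class(m)[class(m) != "similarity_network"])
  m
}

network_kind <- function(x) attr(x, "kind")

#' @export
print.similarity_network <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<similarity_network: %d subjects, kind = %s (mu = %s, K = %s)>\n",
              nrow(x), attr(x, "kind"), format(p$mu), format(p$K)))
  invisible(x)
}

#' Scaled exponential similarity kernel
#'
#' Full subject-similarity kernel
#' \deqn{W(i,j) = \exp(-\rho^2(x_i,x_j) / (\mu\,\epsilon_{i,j}))}
#' with the local scale
#' \eqn{\epsilon_{i,j} = (\mathrm{mean}(\rho(x_i,N_i)) +
#' \mathrm{mean}(\rho(x_j,N_j)) + \rho(x_i,x_j))/3}, where \eqn{N_i} is the
#' set of the \eqn{K} nearest subjects to \eqn{i} *including* \eqn{i} itself
#' (so the self-distance 0 enters the mean). The result is symmetric with
#' unit diagonal and entries in (0, 1].
#'
#' @param dist symmetric distance matrix from [pairwise_distance()].
#' @param mu bandwidth multiplier; recommended range \[0.3, 0.8\],
#'   default 0.5 (a warning is emitted outside the range).
#' @param K self-inclusive neighborhood size used for the local scale,
#'   default 20.
#' @return a `similarity_network` of kind `"kernel_W"`.
#' @export
scaled_exponential_kernel <- function(dist, mu = 0.5, K = 20) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (K >= n) stop("K must be smaller than the number of subjects")
  if (K < 1) stop("K must be at least 1")
  if (mu < 0.3 || mu > 0.8)
    warning("mu = ", mu, " is outside the recommended range [0.3, 0.8]")
  # mean distance to the K nearest subjects, self included (self-distance 0)
  m <- apply(d, 1, function(row) mean(sort(row, partial = K)[seq_len(K)]))
  eps <- (outer(m, m, "+") + d) / 3
  if (any(eps[upper.tri(eps)] <= 0))
    stop("zero local scale: coincident subjects detected; ",
         "jitter or deduplicate the data")
  W <- exp(-(d^2) / (mu * eps))
  diag(W) <- 1
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(d)
  as_network(W, "kernel_W", mu = mu, K = K)
}

#' Row-normalized status matrix
#'
#' Normalizes a similarity kernel so that each subject's self-similarity is
#' exactly 1/2 and the remaining 1/2 of row mass is distributed over the
#' other subjects in proportion to W:
#' \deqn{P(i,j) = W(i,j) / (2\sum_{k\neq i} W(i,k)) \ (j \neq i), \quad
#'       P(i,i) = 1/2.}
#' Every row sums to 1; the operator is invariant to rescaling W.
#'
#' @param W square nonnegative similarity matrix.
#' @return a `similarity_network` of kind `"status_P"`.
#' @export
normalize_status <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  off <- rowSums(W) - diag(W)
  if (any(off <= 0))
    stop("row(s) with zero off-diagonal mass: ",
         paste(which(off <= 0), collapse = ", "))
  P <- W / (2 * off)
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  as_network(P, "status_P")
}

#' Sparse KNN local-affinity matrix
#'
#' Keeps, per row, only the K most similar other subjects and renormalizes:
#' \deqn{S(i,j) = W(i,j)/\sum_{k \in N_i} W(i,k) \ (j \in N_i), \quad 0
#' \text{ otherwise}.}
#' By default the neighbor set excludes the subject itself, so S has zero
#' diagonal and exactly K nonzeros per row (absent ties); set
#' `include_self = TRUE` for the self-inclusive variant. Ties at the K-th
#' neighbor are broken by ascending subject index.
#'
#' @param W a similarity kernel (`kernel_W`).
#' @param K number of neighbors, `1 <= K < n`.
#' @param include_self logical; include the subject in its own neighbor set.
#' @return a `similarity_network` of kind `"knn_S"`.
#' @export
knn_affinity <- function(W, K = 20, include_self = FALSE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (K >= n || K < 1) stop("K must satisfy 1 <= K < n")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    cand <- if (include_self) seq_len(n) else setdiff(seq_len(n), i)
    # most similar first; ties broken by ascending subject index
    nb <- cand[order(-w[cand], cand)][seq_len(K)]
    S[i, nb] <- w[nb] / sum(w[nb])
  }
  as_network(S, "knn_S", K = K)
}

#' One-call per-modality similarity network construction
#'
#' Convenience wrapper: standardized data -> distances -> scaled exponential
#' kernel, returning the full kernel together with its status and KNN forms.
#'
#' @param fm standardized feature matrix.
#' @inheritParams scaled_exponential_kernel
#' @return list with elements `W` (kernel), `P` (status), `S` (KNN affinity).
#' @export
similarity_network <- function(fm, mu = 0.5, K = 20) {
  W <- scaled_exponential_kernel(pairwise_distance(fm), mu = mu, K = K)
  list(W = W, P = normalize_status(W), S = knn_affinity(W, K = K))
}
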