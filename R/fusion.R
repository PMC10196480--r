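#' Similarity network fusion by iterative cross-diffusion
#'
#' Fuses the status matrices of two modalities into one subject network.
#' Each iteration diffuses one modality's global similarity through the
#' other's local KNN graph,
#' \deqn{P^{(1)}_{t+1} = S^{(1)} P^{(2)}_t S^{(1)\top}, \qquad
#'       P^{(2)}_{t+1} = S^{(2)} P^{(1)}_t S^{(2)\top},}
#' followed by the status renormalization of [normalize_status()], which
#' keeps each matrix row-stochastic with self-similarity pinned at 1/2.
#' Iteration stops when the larger of the two relative Frobenius changes
#' drops below `tol` or after `max_iter` sweeps. The returned network is the
#' symmetrized average of the two converged status matrices,
#' \eqn{(P^{(1)} + P^{(2)} + P^{(1)\top} + P^{(2)\top})/4}, renormalized
#' once more.
#'
#' @param P1,P2 status matrices (kind `"status_P"`) of the two modalities.
#' @param S1,S2 KNN affinity matrices (kind `"knn_S"`) of the two modalities.
#' @param max_iter maximum number of diffusion sweeps (default 20;
#'   cross-diffusion converges fast in practice).
#' @param tol relative Frobenius-change tolerance (default 1e-6).
#' @return a `similarity_network` of kind `"fused"` carrying the
#'   per-iteration change series in `attr(, "delta_trace")` and the number
#'   of sweeps in `attr(, "iterations")`.
#' @export
fuse_networks <- function(P1, P2, S1, S2, max_iter = 20, tol = 1e-6) {
  stopifnot(nrow(P1) == nrow(P2), nrow(P1) == nrow(S1), nrow(P1) == nrow(S2))
  if (!is.null(rownames(P1)) && !is.null(rownames(P2)) &&
      !identical(rownames(P1), rownames(P2)))
    stop("subject ordering differs between the two modalities")
  A1 <- as.matrix(P1); A2 <- as.matrix(P2)
  B1 <- as.matrix(S1); B2 <- as.matrix(S2)
  deltas <- numeric(0)
  for (t in seq_len(max_iter)) {
    N1 <- normalize_status(B1 %*% A2 %*% t(B1))
    N2 <- normalize_status(B2 %*% A1 %*% t(B2))
    d1 <- norm(N1 - A1, "F") / norm(A1, "F")
    d2 <- norm(N2 - A2, "F") / norm(A2, "F")
    deltas <- c(deltas, max(d1, d2))
    A1 <- as.matrix(N1); A2 <- as.matrix(N2)
    if (deltas[t] < tol) break
  }
  if (deltas[length(deltas)] >= tol && length(deltas) == max_iter)
    warning(sprintf(
      "fusion did not converge in %d iterations (last delta = %.3g)",
      max_iter, deltas[length(deltas)]))
  fused <- normalize_status((A1 + A2 + t(A1) + t(A2)) / 4)
  fused <- as_network(as.matrix(fused), "fused")
  dimnames(fused) <- dimnames(as.matrix(P1))
  attr(fused, "delta_trace") <- deltas
  attr(fused, "iterations") <- length(deltas)
  fused
}

#' Per-iteration convergence trace of a fused network
#'
#' @param fused result of [fuse_networks()].
#' @return numeric vector of relative-change deltas, one per sweep performed.
#' @export
fusion_trace <- function(fused) {
  tr <- attr(fused, "delta_trace")
  if (is.null(tr)) stop("no trace: object was not produced by fuse_networks()")
  tr
}

#' Fused subject network straight from two data matrices
#'
#' Convenience pipeline: standardize each modality, build its kernel, status
#' and KNN matrices, then cross-diffuse.
#'
#' @param x,y feature matrices (subjects aligned) — raw; standardized
#'   internally.
#' @inheritParams scaled_exponential_kernel
#' @inheritParams fuse_networks
#' @return a fused `similarity_network`.
#' @export
fused_network <- function(x, y, mu = 0.5, K = 20, max_iter = 20, tol = 1e-6) {
  K <- min(K, nrow(as.matrix(x)) - 1L)
  n1 <- similarity_network(standardize(x), mu = mu, K = K)
  n2 <- similarity_network(standardize(y), mu = mu, K = K)
  fuse_networks(n1$P, n2$P, n1$S, n2$S, max_iter = max_iter, tol = tol)
}
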