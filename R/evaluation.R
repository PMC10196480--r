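#' Stratified k-fold assignment
#'
#' Deterministically assigns subjects to `k` cross-validation folds. Fold
#' sizes differ by at most one; when `labels` are given the assignment is
#' stratified so each diagnosis group's members are spread across folds with
#' per-fold counts also differing by at most one. The assignment depends
#' only on the subject ids (when available), the labels and the seed — not
#' on the input order — so reordering subjects and regenerating folds maps
#' every subject to the same fold.
#'
#' @param n number of subjects, or a vector of subject ids.
#' @param labels optional factor of diagnosis labels (length n) for
#'   stratification.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return integer vector of fold indices in `1..k`, named by subject id
#'   when ids were supplied.
#' @export
make_folds <- function(n, labels = NULL, k = 5, seed = 1) {
  ids <- NULL
  if (length(n) > 1L || is.character(n)) { ids <- as.character(n); n <- length(ids) }
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("more folds than subjects")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal the number of subjects")
  # canonical subject order: by id when ids exist, else by position
  canon <- if (!is.null(ids)) order(ids) else seq_len(n)
  perm <- canon[with_seed(seed, sample(n))]
  fold <- integer(n)
  if (is.null(labels)) {
    fold[perm] <- rep_len(seq_len(k), n)
  } else {
    f <- droplevels(as.factor(labels))
    small <- table(f) < k
    if (any(small))
      stop("group(s) smaller than k folds: ",
           paste(names(table(f))[small], collapse = ", "))
    ptr <- 0L  # global round-robin pointer keeps overall fold sizes balanced
    for (g in levels(f)) {
      members <- perm[f[perm] == g]
      fold[members] <- (ptr + seq_along(members) - 1L) %% k + 1L
      ptr <- (ptr + length(members)) %% k
    }
  }
  if (!is.null(ids)) names(fold) <- ids
  fold
}

#' Hyperparameter grid for [cv_dscca()]
#'
#' Expands tied (lambda, beta) combinations: `lambda1 = lambda2 = lambda`
#' and `beta1 = beta2 = beta`. Pass any data frame with columns `lambda1`,
#' `lambda2`, `beta1`, `beta2` to [cv_dscca()] for untied grids.
#'
#' @param lambda L1 penalty values (default: 5 points, log-spaced
#'   10^-3 .. 10).
#' @param beta graph-penalty strengths (default 0: no prior term).
#' @return data frame with columns lambda1, lambda2, beta1, beta2.
#' @export
hyper_grid <- function(lambda = 10^seq(-3, 1, length.out = 5), beta = 0) {
  g <- expand.grid(lambda = lambda, beta = beta, KEEP.OUT.ATTRS = FALSE)
  data.frame(lambda1 = g$lambda, lambda2 = g$lambda,
             beta1 = g$beta, beta2 = g$beta)
}

# construct the prior for a given subject subset (training split)
build_fold_prior <- function(prior_type, x_raw, y_raw, labels, idx, prior,
                             mu, K, all_subjects_prior) {
  switch(prior_type,
    none = NULL,
    fused = {
      if (all_subjects_prior) {
        if (is.null(prior)) stop("all_subjects_prior needs a prebuilt prior")
        subset_prior(prior, idx)
      } else {
        to_laplacian(fused_network(x_raw[idx, , drop = FALSE],
                                   y_raw[idx, , drop = FALSE], mu = mu, K = K))
      }
    },
    diagnosis = {
      if (is.null(labels)) stop("diagnosis prior requires labels")
      if (all_subjects_prior) {
        if (is.null(prior)) stop("all_subjects_prior needs a prebuilt prior")
        subset_prior(prior, idx)
      } else diagnosis_network(labels[idx])
    },
    custom = {
      if (is.null(prior)) stop("custom prior_type requires `prior`")
      if (inherits(prior, "prior_graph") && prior$level == "subject")
        subset_prior(prior, idx)
      else prior  # feature-level priors are split-independent
    })
}

subset_prior <- function(prior, idx) {
  if (inherits(prior, "similarity_network")) prior <- to_laplacian(prior)
  stopifnot(inherits(prior, "prior_graph"), prior$level == "subject")
  to_laplacian(prior_graph(prior$matrix[idx, idx, drop = FALSE], "subject",
                           source = prior$source))
}

#' Nested cross-validated DSCCA / SCCA
#'
#' The full evaluation harness: stratified outer folds estimate held-out
#' canonical correlation while inner folds tune the hyperparameters on the
#' grid. Within every training split (outer and inner) the data are
#' re-standardized with that split's statistics and the subject-level prior
#' (fused or diagnosis network) is rebuilt from that split's subjects only,
#' so no test information leaks into training; set
#' `all_subjects_prior = TRUE` to instead subset a whole-cohort prior (the
#' leaky variant some studies use).
#'
#' @param x,y raw (unstandardized) aligned feature matrices.
#' @param labels optional diagnosis factor: enables stratification and the
#'   diagnosis prior.
#' @param prior_type `"none"` (plain SCCA), `"fused"`, `"diagnosis"` or
#'   `"custom"`.
#' @param prior prebuilt [prior_graph()] for `"custom"` (or for
#'   `all_subjects_prior = TRUE`).
#' @param grid hyperparameter data frame (see [hyper_grid()]); a single row
#'   degenerates to plain k-fold CV at that setting.
#' @param folds optional externally fixed fold assignment (integer vector),
#'   so competing methods share identical partitions.
#' @param k,inner_k outer and inner fold counts (defaults 5 and 5).
#' @param seed seed controlling fold assignment.
#' @param mu,K kernel parameters forwarded to the fused-network builder.
#' @param all_subjects_prior build the prior once from all subjects
#'   (leaky; off by default).
#' @param select `"best"` picks the grid row maximizing mean inner-test
#'   canonical correlation; `"1se"` picks the sparsest row (largest
#'   `lambda1 + lambda2`) within one standard error of the best — the usual
#'   choice when the goal is feature selection rather than prediction.
#' @param ... further arguments forwarded to [dscca()].
#' @return object of class `"dscca_cv"`: per-fold test correlations, their
#'   mean, chosen hyperparameters per fold, sign-aligned fold-averaged
#'   weights, and the per-fold fitted models.
#' @export
cv_dscca <- function(x, y, labels = NULL,
                     prior_type = c("none", "fused", "diagnosis", "custom"),
                     prior = NULL, grid = hyper_grid(), folds = NULL,
                     k = 5, inner_k = 5, seed = 1, mu = 0.5, K = 20,
                     all_subjects_prior = FALSE, select = c("best", "1se"),
                     ...) {
  prior_type <- match.arg(prior_type)
  select <- match.arg(select)
  x_raw <- unclass(as.matrix(x)); y_raw <- unclass(as.matrix(y))
  n <- nrow(x_raw)
  stopifnot(nrow(y_raw) == n)
  req <- c("lambda1", "lambda2", "beta1", "beta2")
  if (!all(req %in% names(grid))) stop("grid needs columns ", paste(req, collapse = ", "))
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (prior_type %in% c("fused", "diagnosis") && all_subjects_prior && is.null(prior)) {
    prior <- if (prior_type == "fused")
      to_laplacian(fused_network(x_raw, y_raw, mu = mu, K = K))
    else diagnosis_network(labels)
  }
  if (is.null(folds))
    folds <- make_folds(if (!is.null(rownames(x_raw))) rownames(x_raw) else n,
                        labels = labels, k = k, seed = seed)
  k <- max(folds)
  per_fold <- numeric(k)
  chosen <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    inner_ids <- if (!is.null(rownames(x_raw))) rownames(x_raw)[tr] else length(tr)
    inner_folds <- make_folds(inner_ids,
                              labels = if (!is.null(labels)) labels[tr],
                              k = inner_k, seed = seed + 7919L * f)
    best <- select_hyperparams(x_raw[tr, , drop = FALSE],
                               y_raw[tr, , drop = FALSE],
                               if (!is.null(labels)) droplevels(as.factor(labels[tr])),
                               prior_type, prior, grid, inner_folds,
                               mu, K, all_subjects_prior, select, ...)
    # refit on the full outer-training split at the selected setting
    Xtr <- standardize(x_raw[tr, , drop = FALSE])
    Ytr <- standardize(y_raw[tr, , drop = FALSE])
    pg <- build_fold_prior(prior_type, x_raw, y_raw, labels, tr, prior,
                           mu, K, all_subjects_prior)
    fit <- dscca(Xtr, Ytr, lambda1 = best$lambda1, lambda2 = best$lambda2,
                 beta1 = best$beta1, beta2 = best$beta2, prior = pg, ...)
    Xte <- standardize(x_raw[te, , drop = FALSE],
                       center = attr(Xtr, "center"), scale = attr(Xtr, "scale"))
    Yte <- standardize(y_raw[te, , drop = FALSE],
                       center = attr(Ytr, "center"), scale = attr(Ytr, "scale"))
    per_fold[f] <- canonical_correlation(fit, Xte, Yte)
    chosen[[f]] <- best
    models[[f]] <- fit
  }
  # sign-align folds to fold 1 before averaging (CCA is sign-ambiguous)
  U <- t(vapply(models, function(m) m$u, numeric(ncol(x_raw))))
  V <- t(vapply(models, function(m) m$v, numeric(ncol(y_raw))))
  for (f in seq_len(k)[-1]) {
    s <- sum(U[f, ] * U[1, ])
    if (s < 0) { U[f, ] <- -U[f, ]; V[f, ] <- -V[f, ] }
  }
  structure(list(
    method = if (prior_type == "none") "scca" else paste0("dscca_", prior_type),
    prior_type = prior_type,
    per_fold_test_corr = per_fold,
    mean_test_corr = mean(per_fold),
    chosen_hyperparams = do.call(rbind, chosen),
    averaged_u = setNames(colMeans(U), colnames(x_raw)),
    averaged_v = setNames(colMeans(V), colnames(y_raw)),
    folds = folds, seed = seed, models = models), class = "dscca_cv")
}

select_hyperparams <- function(x_raw, y_raw, labels, prior_type, prior, grid,
                               inner_folds, mu, K, all_subjects_prior,
                               select = "best", ...) {
  ki <- max(inner_folds)
  splits <- lapply(seq_len(ki), function(f) {
    tr <- which(inner_folds != f); te <- which(inner_folds == f)
    Xtr <- standardize(x_raw[tr, , drop = FALSE])
    Ytr <- standardize(y_raw[tr, , drop = FALSE])
    list(tr = tr, te = te, Xtr = Xtr, Ytr = Ytr,
         Xte = standardize(x_raw[te, , drop = FALSE],
                           center = attr(Xtr, "center"),
                           scale = attr(Xtr, "scale")),
         Yte = standardize(y_raw[te, , drop = FALSE],
                           center = attr(Ytr, "center"),
                           scale = attr(Ytr, "scale")),
         prior = build_fold_prior(prior_type, x_raw, y_raw, labels, tr, prior,
                                  mu, K, all_subjects_prior))
  })
  score <- numeric(nrow(grid))
  sem <- numeric(nrow(grid))
  alive <- logical(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, ]
    corrs <- vapply(splits, function(sp) {
      fit <- suppressWarnings(
        dscca(sp$Xtr, sp$Ytr, lambda1 = g$lambda1, lambda2 = g$lambda2,
              beta1 = g$beta1, beta2 = g$beta2, prior = sp$prior, ...))
      if (any(fit$u != 0) && any(fit$v != 0)) alive[gi] <<- TRUE
      suppressWarnings(canonical_correlation(fit, sp$Xte, sp$Yte))
    }, numeric(1))
    score[gi] <- mean(corrs)
    sem[gi] <- sd(corrs) / sqrt(length(corrs))
  }
  if (!any(alive))
    stop("every grid point produced all-zero weights; ",
         "use a smaller lambda range")
  score[!alive] <- -Inf
  best <- which.max(score)
  if (identical(select, "1se")) {
    ok <- which(alive & score >= score[best] - sem[best])
    sparsity <- grid$lambda1[ok] + grid$lambda2[ok]
    best <- ok[order(-sparsity)][1]
  }
  grid[best, , drop = FALSE]
}

#' Tune hyperparameters by k-fold cross-validation and refit
#'
#' Single-level counterpart of [cv_dscca()]: one stratified k-fold CV over
#' the grid chooses the hyperparameters, then the model is refit on the
#' full data at that setting. This is the workflow for feature selection on
#' a whole cohort (use [cv_dscca()] when an unbiased estimate of held-out
#' correlation is also needed).
#'
#' @inheritParams cv_dscca
#' @return a `"dscca"` fit on the full (standardized) data, with the chosen
#'   grid row in `$tuning`.
#' @export
tune_dscca <- function(x, y, labels = NULL,
                       prior_type = c("none", "fused", "diagnosis", "custom"),
                       prior = NULL, grid = hyper_grid(), k = 5, seed = 1,
                       mu = 0.5, K = 20, select = c("best", "1se"), ...) {
  prior_type <- match.arg(prior_type)
  select <- match.arg(select)
  x_raw <- unclass(as.matrix(x)); y_raw <- unclass(as.matrix(y))
  folds <- make_folds(if (!is.null(rownames(x_raw))) rownames(x_raw)
                      else nrow(x_raw), labels = labels, k = k, seed = seed)
  best <- select_hyperparams(x_raw, y_raw,
                             if (!is.null(labels)) droplevels(as.factor(labels)),
                             prior_type, prior, grid, folds, mu, K,
                             all_subjects_prior = FALSE, select = select, ...)
  Xs <- standardize(x_raw); Ys <- standardize(y_raw)
  pg <- build_fold_prior(prior_type, x_raw, y_raw, labels,
                         seq_len(nrow(x_raw)), prior, mu, K, FALSE)
  fit <- dscca(Xs, Ys, lambda1 = best$lambda1, lambda2 = best$lambda2,
               beta1 = best$beta1, beta2 = best$beta2, prior = pg, ...)
  fit$tuning <- best
  fit
}

#' Fold-averaged feature ranking
#'
#' Ranks features by the mean absolute weight across the sign-aligned fold
#' models, the selection rule used for reporting top regions and SNPs.
#' Zero-weight features are excluded; ties break by feature id.
#'
#' @param report a `"dscca_cv"` object.
#' @param top_k list length cap per side (default 10).
#' @return list of two data frames (`u`, `v`) with columns `feature` and
#'   `mean_abs_weight`, in rank order.
#' @export
rank_features <- function(report, top_k = 10) {
  stopifnot(inherits(report, "dscca_cv"))
  one <- function(w) {
    aw <- abs(w)[abs(w) > 0]
    if (length(aw) == 0)
      return(data.frame(feature = character(0), mean_abs_weight = numeric(0)))
    ord <- order(-aw, names(aw))
    out <- data.frame(feature = names(aw)[ord], mean_abs_weight = aw[ord],
                      row.names = NULL)
    head(out, top_k)
  }
  list(u = one(report$averaged_u), v = one(report$averaged_v))
}

#' @export
print.dscca_cv <- function(x, ...) {
  cat(sprintf("Nested cross-validation report: %s\n", x$method))
  cat("  per-fold test canonical correlation:\n    ")
  cat(sprintf("%.4f", x$per_fold_test_corr), sep = "  ")
  cat(sprintf("\n  mean: %.4f\n", x$mean_test_corr))
  invisible(x)
}

#' @export
summary.dscca_cv <- function(object, top = 10, ...) {
  print(object)
  cat("\nChosen hyperparameters per fold:\n")
  print(object$chosen_hyperparams)
  cat("\nTop features by fold-averaged |weight|:\n")
  rk <- rank_features(object, top)
  cat("  x side:\n"); print(rk$u)
  cat("  y side:\n"); print(rk$v)
  invisible(object)
}

#' @export
plot.dscca_cv <- function(x, ...) {
  bp <- barplot(x$per_fold_test_corr,
                names.arg = paste0("fold ", seq_along(x$per_fold_test_corr)),
                ylab = "held-out canonical correlation", main = x$method, ...)
  abline(h = x$mean_test_corr, lty = 2)
  invisible(bp)
}

#' Fold-by-method comparison table
#'
#' Assembles the familiar report layout — one row per method, one column per
#' fold plus the average — from a named list of [cv_dscca()] reports run on
#' identical fold assignments.
#'
#' @param reports named list of `"dscca_cv"` objects.
#' @return data frame with columns `method`, `fold_1..k`, `average`.
#' @export
cv_table <- function(reports) {
  stopifnot(length(reports) > 0)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    v <- c(r$per_fold_test_corr, r$mean_test_corr)
    setNames(as.data.frame(as.list(round(v, 4))),
             c(paste0("fold_", seq_along(r$per_fold_test_corr)), "average"))
  })
  cbind(method = names(reports), do.call(rbind, rows))
}

#' Serialize / restore a CV report
#'
#' JSON round-trip of everything in a `"dscca_cv"` object except the fitted
#' per-fold models (weights, correlations, folds and chosen hyperparameters
#' are preserved exactly).
#'
#' @param report a `"dscca_cv"` object.
#' @param path file path.
#' @export
write_cv_report <- function(report, path) {
  out <- report[setdiff(names(report), "models")]
  # named vectors must become objects (not arrays) to keep feature ids;
  # 17 significant digits make the double round trip exact
  out$averaged_u <- as.list(out$averaged_u)
  out$averaged_v <- as.list(out$averaged_v)
  out$folds <- as.list(out$folds)
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_fold_test_corr <- as.numeric(raw$per_fold_test_corr)
  raw$averaged_u <- unlist(raw$averaged_u)
  raw$averaged_v <- unlist(raw$averaged_v)
  raw$folds <- unlist(raw$folds)
  raw$models <- NULL
  structure(raw, class = "dscca_cv")
}
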