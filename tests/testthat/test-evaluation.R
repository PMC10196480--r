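test_that("fold assignment is balanced, stratified and deterministic", {
  f <- make_folds(10, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  lab <- factor(rep(c("A", "B"), each = 10))
  fs <- make_folds(20, labels = lab, k = 5, seed = 2)
  tab <- table(fs, lab)
  expect_true(all(tab == 2))          # 2 per group in every fold
  expect_identical(make_folds(20, labels = lab, k = 5, seed = 2), fs)
  expect_false(identical(make_folds(20, labels = lab, k = 5, seed = 3), fs))
  expect_error(make_folds(10, labels = factor(rep(c("A", "B"), c(8, 2))),
                          k = 5), "smaller than k")
  expect_error(make_folds(10, k = 1), "at least 2")
  # uneven n: fold sizes differ by at most one
  f13 <- make_folds(13, k = 5, seed = 4)
  expect_lte(diff(range(table(f13))), 1)
})

test_that("fold assignment follows subject ids, not input order", {
  ids <- sprintf("s%02d", 1:20)
  lab <- setNames(factor(rep(c("A", "B"), 10)), ids)
  f1 <- make_folds(ids, labels = lab, k = 4, seed = 9)
  set.seed(1); perm <- sample(20)
  f2 <- make_folds(ids[perm], labels = lab[perm], k = 4, seed = 9)
  expect_identical(f2[ids], f1[ids])
})

test_that("a single-row grid degenerates to plain k-fold CV", {
  co <- simulate_cohort(simulation_config(n = 60, p = 10, q = 12, seed = 2))
  grid1 <- data.frame(lambda1 = 0.15, lambda2 = 0.15, beta1 = 0, beta2 = 0)
  folds <- make_folds(rownames(co$X), labels = co$labels, k = 3, seed = 5)
  rep <- cv_dscca(co$X, co$Y, labels = co$labels, prior_type = "none",
                  grid = grid1, folds = folds, inner_k = 3, seed = 5)
  expect_true(all(rep$chosen_hyperparams$lambda1 == 0.15))
  # manual oracle for fold 1: standardize on train, fit, correlate on test
  tr <- which(folds != 1); te <- which(folds == 1)
  Xtr <- standardize(co$X[tr, ]); Ytr <- standardize(co$Y[tr, ])
  fit <- scca(Xtr, Ytr, lambda1 = 0.15, lambda2 = 0.15)
  Xte <- standardize(co$X[te, ], center = attr(Xtr, "center"),
                     scale = attr(Xtr, "scale"))
  Yte <- standardize(co$Y[te, ], center = attr(Ytr, "center"),
                     scale = attr(Ytr, "scale"))
  expect_equal(rep$per_fold_test_corr[1],
               canonical_correlation(fit, Xte, Yte), tolerance = 1e-12)
  expect_equal(rep$mean_test_corr, mean(rep$per_fold_test_corr))
})

test_that("cross-validation results are invariant to subject order", {
  co <- simulate_cohort(simulation_config(n = 50, p = 8, q = 10, seed = 3))
  grid1 <- data.frame(lambda1 = 0.1, lambda2 = 0.1, beta1 = 0, beta2 = 0)
  r1 <- cv_dscca(co$X, co$Y, labels = co$labels, prior_type = "none",
                 grid = grid1, k = 5, inner_k = 3, seed = 7)
  set.seed(4); perm <- sample(50)
  r2 <- cv_dscca(co$X[perm, ], co$Y[perm, ], labels = co$labels[perm],
                 prior_type = "none", grid = grid1, k = 5, inner_k = 3,
                 seed = 7)
  expect_equal(r2$mean_test_corr, r1$mean_test_corr, tolerance = 1e-10)
  expect_equal(r2$per_fold_test_corr, r1$per_fold_test_corr, tolerance = 1e-10)
})

test_that("feature ranking orders by mean |weight| with deterministic ties", {
  rep <- structure(list(
    averaged_u = c(roiA = 0.5, roiB = -0.8, roiC = 0, roiD = 0.5),
    averaged_v = c(snp1 = 0, snp2 = 0, snp3 = 0.1)), class = "dscca_cv")
  rk <- rank_features(rep, top_k = 10)
  expect_identical(rk$u$feature, c("roiB", "roiA", "roiD"))  # tie: id order
  expect_identical(rk$v$feature, "snp3")                     # zeros excluded
  rk2 <- rank_features(rep, top_k = 2)
  expect_identical(rk2$u$feature, c("roiB", "roiA"))
})

test_that("an all-shrinking grid raises the lambda-range error", {
  co <- simulate_cohort(simulation_config(n = 40, p = 6, q = 8, seed = 4))
  grid <- data.frame(lambda1 = 100, lambda2 = 100, beta1 = 0, beta2 = 0)
  expect_error(cv_dscca(co$X, co$Y, prior_type = "none", grid = grid,
                        k = 3, inner_k = 3, seed = 1),
               "smaller lambda")
})

test_that("cross-validation reports serialize and restore exactly", {
  co <- simulate_cohort(simulation_config(n = 40, p = 6, q = 8, seed = 6))
  grid1 <- data.frame(lambda1 = 0.1, lambda2 = 0.1, beta1 = 0, beta2 = 0)
  rep <- cv_dscca(co$X, co$Y, prior_type = "none", grid = grid1,
                  k = 3, inner_k = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, path)
  back <- read_cv_report(path)
  expect_equal(back$per_fold_test_corr, rep$per_fold_test_corr, tolerance = 0)
  expect_equal(back$mean_test_corr, rep$mean_test_corr, tolerance = 0)
  expect_equal(back$averaged_u, rep$averaged_u, tolerance = 0)
  expect_equal(back$averaged_v, rep$averaged_v, tolerance = 0)
  expect_identical(unname(unlist(back$folds)), unname(rep$folds))
})

test_that("tune_dscca refits on the full data at the selected setting", {
  co <- simulate_cohort(simulation_config(n = 60, p = 10, q = 12, seed = 9))
  grid <- hyper_grid(lambda = c(0.1, 0.2))
  fit <- tune_dscca(co$X, co$Y, labels = co$labels, prior_type = "none",
                    grid = grid, k = 3, seed = 3)
  expect_s3_class(fit, "dscca")
  expect_true(fit$tuning$lambda1 %in% c(0.1, 0.2))
  expect_equal(fit$n, 60)
})
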