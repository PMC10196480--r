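default_config <- function() {
  list(
    stages = c("simulate", "build_prior", "cv"),
    out = ".",
    seed = 1,
    inputs = list(x = NULL, y = NULL, labels = NULL,
                  x_dialect = "delimited", y_dialect = "delimited",
                  prior_file = NULL),
    simulate = list(n = 250, p = 100, q = 150, support_u = 1:5,
                    support_v = 1:5, latent_corr = 0.7, n_groups = 3,
                    group_effect = 1.5, noise_sd = 1,
                    maf_range = c(0.1, 0.5)),
    prior = list(type = "fused", level = "subject", mu = 0.5, K = 20,
                 fusion_iter = 20, fusion_tol = 1e-6),
    fit = list(model = "dscca", lambda1 = 0.1, lambda2 = 0.1,
               beta1 = 0.1, beta2 = 0.1, gamma1 = 1, gamma2 = 1),
    cv = list(folds = 5, inner_folds = 5,
              lambda = 10^seq(-3, 1, length.out = 5),
              beta = 10^seq(-3, 1, length.out = 5),
              all_subjects_prior = FALSE)
  )
}

merge_config <- function(user, defaults = default_config(), path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, "$", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

plog <- function(...) message(sprintf("[snfcca %s] ", format(Sys.time(), "%H:%M:%S")), ...)

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stage chain `simulate` -> `build_prior` -> `fit` / `cv`
#' from a single configuration (an R list or the path to a JSON file).
#' Unknown configuration keys are rejected; one seed fans out
#' deterministically to simulation, fold assignment and solver
#' initialization; a resolved-configuration snapshot is written next to the
#' outputs so every artifact is regenerable from it alone.
#'
#' Stages: `"simulate"` writes `X.tsv`, `Y.tsv`, `labels.tsv` and a truth
#' file; `"build_prior"` writes `prior_network.tsv` (type `fused`,
#' `diagnosis` or `custom`); `"fit"` writes weight tables for a single
#' model; `"cv"` writes a nested-CV report JSON and the fold-by-method
#' correlation table comparing the requested model with the SCCA baseline.
#'
#' @param config list or path to a JSON config file; see
#'   `snfcca:::default_config()` for the full key set and defaults.
#' @return invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(config)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  plog("stages: ", paste(cfg$stages, collapse = " -> "), "; seed = ", cfg$seed)

  labels <- NULL
  if ("simulate" %in% cfg$stages) {
    sc <- do.call(simulation_config, c(cfg$simulate, list(seed = cfg$seed)))
    cohort <- simulate_cohort(sc)
    X <- cohort$X; Y <- cohort$Y; labels <- cohort$labels
    artifacts$x <- write_feature_matrix(X, file.path(out, "X.tsv"))
    artifacts$y <- write_feature_matrix(Y, file.path(out, "Y.tsv"))
    lab_df <- data.frame(subject_id = names(labels), diagnosis = labels)
    write.table(lab_df, file.path(out, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts$labels <- file.path(out, "labels.tsv")
    jsonlite::write_json(cohort$truth[c("support_u", "support_v",
                                        "u_star", "v_star")],
                         file.path(out, "truth.json"), digits = NA)
    artifacts$truth <- file.path(out, "truth.json")
    plog("simulated cohort: n = ", nrow(X), ", p = ", ncol(X),
         ", q = ", ncol(Y))
  } else {
    if (is.null(cfg$inputs$x) || is.null(cfg$inputs$y))
      stop("inputs$x and inputs$y are required when not simulating")
    if (!file.exists(cfg$inputs$x)) stop("missing input file: ", cfg$inputs$x)
    if (!file.exists(cfg$inputs$y)) stop("missing input file: ", cfg$inputs$y)
    X <- read_feature_matrix(cfg$inputs$x, cfg$inputs$x_dialect, "imaging")
    Y <- read_feature_matrix(cfg$inputs$y, cfg$inputs$y_dialect, "genotype")
    if (!is.null(cfg$inputs$labels)) labels <- read_labels(cfg$inputs$labels)
    al <- align_subjects(X, Y, labels)
    X <- al$a; Y <- al$b; labels <- al$labels
    plog("loaded inputs: n = ", nrow(X), ", p = ", ncol(X), ", q = ", ncol(Y))
  }

  if (cfg$prior$type == "diagnosis" && is.null(labels))
    stop("prior type 'diagnosis' requires diagnosis labels")

  prior <- NULL
  if ("build_prior" %in% cfg$stages) {
    prior <- switch(cfg$prior$type,
      fused = to_laplacian(fused_network(X, Y, mu = cfg$prior$mu,
                                         K = cfg$prior$K,
                                         max_iter = cfg$prior$fusion_iter,
                                         tol = cfg$prior$fusion_tol)),
      diagnosis = diagnosis_network(labels),
      custom = {
        if (is.null(cfg$inputs$prior_file))
          stop("prior type 'custom' requires inputs$prior_file")
        to_laplacian(prior_graph(read_network(cfg$inputs$prior_file),
                                 cfg$prior$level))
      },
      none = NULL,
      stop("invalid prior type: ", cfg$prior$type))
    if (!is.null(prior)) {
      artifacts$prior <- write_network(prior$matrix,
                                       file.path(out, "prior_network.tsv"))
      plog("built ", cfg$prior$type, " prior (", nrow(prior$matrix), " nodes)")
    }
  }

  if ("fit" %in% cfg$stages) {
    f <- cfg$fit
    if (f$model == "dscca" && is.null(prior) && cfg$prior$type != "none")
      stop("fit stage with model 'dscca' needs the build_prior stage ",
           "(or prior type 'none' with model 'scca')")
    Xs <- standardize(X); Ys <- standardize(Y)
    fit <- if (f$model == "scca")
      scca(Xs, Ys, lambda1 = f$lambda1, lambda2 = f$lambda2, seed = cfg$seed)
    else dscca(Xs, Ys, lambda1 = f$lambda1, lambda2 = f$lambda2,
               beta1 = f$beta1, beta2 = f$beta2, gamma1 = f$gamma1,
               gamma2 = f$gamma2, prior = prior, seed = cfg$seed)
    for (side in c("u", "v")) {
      w <- coef(fit, side)
      tab <- data.frame(feature = names(w), weight = w)
      fn <- file.path(out, paste0("weights_", side, ".tsv"))
      write.table(tab, fn, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts[[paste0("weights_", side)]] <- fn
    }
    plog(sprintf("fitted %s: train corr %.4f, |u| = %d, |v| = %d",
                 f$model, fit$cor, sum(fit$u != 0), sum(fit$v != 0)))
  }

  if ("cv" %in% cfg$stages) {
    cvc <- cfg$cv
    grid_p <- hyper_grid(lambda = cvc$lambda, beta = cvc$beta)
    grid_0 <- hyper_grid(lambda = cvc$lambda, beta = 0)
    folds <- make_folds(rownames(X), labels = labels, k = cvc$folds,
                        seed = cfg$seed)
    reports <- list()
    if (cfg$prior$type != "none") {
      reports[[paste0("dscca_", cfg$prior$type)]] <-
        cv_dscca(X, Y, labels = labels, prior_type = cfg$prior$type,
                 prior = prior, grid = grid_p, folds = folds,
                 inner_k = cvc$inner_folds, seed = cfg$seed,
                 mu = cfg$prior$mu, K = cfg$prior$K,
                 all_subjects_prior = cvc$all_subjects_prior)
    }
    reports$scca <- cv_dscca(X, Y, labels = labels, prior_type = "none",
                             grid = grid_0, folds = folds,
                             inner_k = cvc$inner_folds, seed = cfg$seed)
    for (nm in names(reports)) {
      fn <- file.path(out, paste0("cv_report_", nm, ".json"))
      write_cv_report(reports[[nm]], fn)
      artifacts[[paste0("cv_", nm)]] <- fn
      plog(sprintf("cv %s: mean held-out corr %.4f", nm,
                   reports[[nm]]$mean_test_corr))
    }
    tab <- cv_table(reports)
    fn <- file.path(out, "cv_table.tsv")
    write.table(tab, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$cv_table <- fn
  }

  snap <- file.path(out, "resolved_config.json")
  jsonlite::write_json(cfg, snap, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  artifacts$config <- snap
  plog("done; resolved config snapshot at ", snap)
  invisible(artifacts)
}
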