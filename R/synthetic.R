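#' Simulation configuration
#'
#' Collects and validates the knobs of the synthetic imaging-genetics
#' cohort generator. Defaults are the package's benchmark world: 250
#' subjects, 100 imaging regions, 150 SNPs, planted supports of 5 features
#' per side, latent canonical correlation 0.7, three diagnosis groups with
#' mean severity spacing 1.5, unit imaging noise and minor-allele
#' frequencies uniform on \[0.1, 0.5\].
#'
#' @param n,p,q subjects, imaging features, SNP features.
#' @param support_u,support_v planted support index sets (within `1..p` /
#'   `1..q`).
#' @param latent_corr correlation in \[0, 1\] between the latent severity
#'   factor and the planted genetic score.
#' @param n_groups number of diagnosis groups.
#' @param group_effect spacing of the group-specific severity means.
#' @param noise_sd standard deviation of the imaging noise.
#' @param maf_range minor-allele-frequency interval, within (0, 0.5\].
#' @param seed RNG seed; the cohort is a deterministic function of the
#'   configuration.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 250, p = 100, q = 150,
                              support_u = 1:5, support_v = 1:5,
                              latent_corr = 0.7, n_groups = 3,
                              group_effect = 1.5, noise_sd = 1,
                              maf_range = c(0.1, 0.5), seed = 1) {
  stopifnot(n >= 4, p >= 1, q >= 1, n_groups >= 1, group_effect >= 0,
            noise_sd > 0, length(maf_range) == 2)
  if (latent_corr < 0 || latent_corr > 1)
    stop("latent_corr must lie in [0, 1]; attainable bound is 1")
  if (max(support_u) > p || min(support_u) < 1)
    stop("support_u must index into 1..p")
  if (max(support_v) > q || min(support_v) < 1)
    stop("support_v must index into 1..q")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  structure(list(n = n, p = p, q = q, support_u = support_u,
                 support_v = support_v, latent_corr = latent_corr,
                 n_groups = n_groups, group_effect = group_effect,
                 noise_sd = noise_sd, maf_range = maf_range, seed = seed),
            class = "simulation_config")
}

#' Simulate an imaging-genetics cohort with planted canonical structure
#'
#' Generates a genotype dosage matrix, an imaging quantitative-trait matrix
#' and diagnosis labels carrying a known sparse canonical association:
#'
#' 1. SNP dosages are drawn Binomial(2, MAF) with per-SNP MAFs uniform on
#'    `maf_range` (constant columns are redrawn so downstream
#'    standardization is well defined).
#' 2. The planted genetic score is the signed sum of centered dosages over
#'    `support_v`; the latent severity is
#'    `w = latent_corr * score + sqrt(1 - latent_corr^2) * noise`, with the
#'    noise orthogonalized in-sample so `cor(w, score) = latent_corr`
#'    exactly.
#' 3. Diagnosis groups are the `n_groups` severity quantile bins — disease
#'    stage reflects the same severity axis that links the two modalities —
#'    and the full latent factor adds the group separation:
#'    `z = w + group_effect * (bin - center)`.
#' 4. Imaging features load on `z` over `support_u` (alternating signs);
#'    non-support features receive a fixed alternating group-offset pattern
#'    of magnitude `group_effect/4`; Gaussian noise of sd `noise_sd` is
#'    added everywhere.
#'
#' Dosages therefore stay exactly in \{0, 1, 2\}, the latent correlation is
#' analytically controlled, and the diagnosis groups are visible in both
#' modalities (through severity) — giving the fused and diagnosis priors
#' real structure to exploit without letting the group pattern swamp the
#' planted sparse association.
#'
#' @param config a [simulation_config()] (or arguments passed on to it).
#' @param ... used to build a config when `config` is missing.
#' @return list of class `"synthetic_cohort"` with elements `X` (imaging
#'   [feature_matrix()]), `Y` (genotype), `labels` (factor named by subject
#'   id) and `truth` (planted `u_star`, `v_star`, supports, latent factors,
#'   group assignment and the realized composite correlation).
#' @export
simulate_cohort <- function(config = simulation_config(...), ...) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n; p <- cfg$p; q <- cfg$q
    ids <- sprintf("s%03d", seq_len(n))
    snp_ids <- sprintf("snp%04d", seq_len(q))
    roi_ids <- sprintf("roi%03d", seq_len(p))
    maf <- runif(q, cfg$maf_range[1], cfg$maf_range[2])
    Y <- vapply(seq_len(q), function(j) rbinom(n, 2, maf[j]), numeric(n))
    for (tries in 1:20) {             # redraw degenerate (constant) SNPs
      const <- apply(Y, 2, function(col) max(col) == min(col))
      if (!any(const)) break
      Y[, const] <- vapply(which(const),
                           function(j) rbinom(n, 2, maf[j]), numeric(n))
    }
    v_star <- numeric(q)
    v_star[cfg$support_v] <- rep_len(c(1, -1), length(cfg$support_v))
    score <- drop(scale(Y, center = 2 * maf, scale = FALSE) %*% v_star)
    if (sd(score) < 1e-12) stop("degenerate genetic score; increase n")
    score_s <- drop(scale(score))
    eta <- rnorm(n)
    # orthogonalize the noise so corr(w, score) = latent_corr exactly
    eta_perp <- eta - score_s * sum(eta * score_s) / sum(score_s^2)
    eta_perp <- drop(scale(eta_perp))
    r <- cfg$latent_corr
    w <- r * score_s + sqrt(1 - r^2) * eta_perp
    # diagnosis = severity stage: quantile bins of w, then extra separation
    G <- cfg$n_groups
    grp <- if (G == 1) rep(1L, n)
           else as.integer(cut(rank(w, ties.method = "first"),
                               breaks = round(seq(0, n, length.out = G + 1)),
                               labels = FALSE))
    mcent <- (seq_len(G) - (G + 1) / 2)
    z <- w + cfg$group_effect * mcent[grp]
    u_star <- numeric(p)
    u_star[cfg$support_u] <- rep_len(c(1, -1), length(cfg$support_u))
    # alternating +-1 offsets plant group structure in non-support regions
    hpat <- rep_len(c(1, -1), p)
    hpat[cfg$support_u] <- 0
    X <- outer(z, u_star) +
      outer(cfg$group_effect * mcent[grp] / 4, hpat) +
      matrix(rnorm(n * p, sd = cfg$noise_sd), n, p)
    dimnames(X) <- list(ids, roi_ids)
    dimnames(Y) <- list(ids, snp_ids)
    labels <- setNames(factor(paste0("G", grp)), ids)
    truth <- list(u_star = setNames(u_star, roi_ids),
                  v_star = setNames(v_star, snp_ids),
                  support_u = cfg$support_u, support_v = cfg$support_v,
                  z = z, w = w, score = score_s, groups = grp, maf = maf,
                  observed_composite_corr =
                    suppressWarnings(safe_cor(X %*% u_star, Y %*% v_star,
                                              warn = FALSE)))
    structure(list(X = feature_matrix(X, "imaging"),
                   Y = feature_matrix(Y, "genotype"),
                   labels = labels, truth = truth, config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<synthetic_cohort: n = %d, p = %d, q = %d, ",
                     "latent_corr = %g, %d groups, seed = %d>\n"),
              cfg$n, cfg$p, cfg$q, cfg$latent_corr, cfg$n_groups, cfg$seed))
  cat(sprintf("  realized corr(X u*, Y v*) = %.3f\n",
              x$truth$observed_composite_corr))
  invisible(x)
}

#' Score recovery of the planted canonical structure
#'
#' Compares a fitted model against the generator's ground truth: F1 overlap
#' between each side's nonzero set and the planted support, and the
#' absolute (sign-invariant) cosine similarity between the weight vectors.
#'
#' @param model a fitted `"dscca"` object (or any list with `u`, `v`).
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @return named numeric vector: `support_f1_u`, `support_f1_v`,
#'   `cosine_u`, `cosine_v`.
#' @export
score_recovery <- function(model, truth) {
  f1 <- function(sel, true) {
    tp <- length(intersect(sel, true))
    if (tp == 0) return(0)
    2 * tp / (2 * tp + length(setdiff(sel, true)) + length(setdiff(true, sel)))
  }
  abs_cos <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(0)
    abs(sum(a * b)) / (na * nb)
  }
  u <- model$u; v <- model$v
  stopifnot(length(u) == length(truth$u_star),
            length(v) == length(truth$v_star))
  c(support_f1_u = f1(which(u != 0), truth$support_u),
    support_f1_v = f1(which(v != 0), truth$support_v),
    cosine_u = abs_cos(u, truth$u_star),
    cosine_v = abs_cos(v, truth$v_star))
}
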