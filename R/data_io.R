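#' Construct a feature matrix
#'
#' A feature matrix is the basic data block of the package: a numeric
#' subjects-by-features matrix with unique subject identifiers as row names,
#' feature identifiers as column names, and a modality tag (`"imaging"` for
#' quantitative traits such as regional PET uptake, `"genotype"` for additive
#' SNP dosages coded 0/1/2).
#'
#' @param values numeric matrix, subjects in rows and features in columns;
#'   row and column names are required (or supplied via `subject_ids` /
#'   `feature_ids`).
#' @param modality `"imaging"` or `"genotype"`.
#' @param subject_ids,feature_ids optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return a numeric matrix of class `"feature_matrix"` with a `modality`
#'   attribute.
#' @export
feature_matrix <- function(values, modality = c("imaging", "genotype"),
                           subject_ids = rownames(values),
                           feature_ids = colnames(values)) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id(s): ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyNA(values))
    stop("feature matrix contains missing values; impute or remove upstream")
  if (modality == "genotype") {
    ok <- values >= 0 & values <= 2 & abs(values - round(values)) < 1e-8
    if (!all(ok))
      stop("genotype dosages must be 0, 1 or 2 before standardization")
  }
  dimnames(values) <- list(as.character(subject_ids), as.character(feature_ids))
  attr(values, "modality") <- modality
  class(values) <- c("feature_matrix", class(values))
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d subjects x %d features, modality = %s>\n",
              nrow(x), ncol(x), attr(x, "modality")))
  invisible(x)
}

modality_of <- function(fm) {
  m <- attr(fm, "modality")
  if (is.null(m)) "imaging" else m
}

detect_sep <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else if (grepl(",", line, fixed = TRUE)) "," else NA
}

#' Read a feature matrix from disk
#'
#' Two dialects are supported. `"delimited"`: a header row of feature ids
#' (optionally preceded by a subject-id column name), first column holding
#' subject ids, tab or comma separated (auto-detected from the header line).
#' `"plink-raw"`: the whitespace-separated PLINK `--recode A` additive format
#' with the six leading FID/IID/PAT/MAT/SEX/PHENOTYPE columns followed by
#' `SNP_allele` dosage columns; the IID column provides subject ids.
#'
#' Missing genotype dosages (`NA`) are imputed by the per-SNP mode;
#' constant-valued features are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"delimited"` or `"plink-raw"`.
#' @param modality modality tag for the result; `"plink-raw"` forces
#'   `"genotype"`.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path, dialect = c("delimited", "plink-raw"),
                                modality = c("imaging", "genotype")) {
  dialect <- match.arg(dialect)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plink-raw") {
    df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE, na.strings = c("NA", "-9"))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 7 || !identical(toupper(names(df)[1:6]), meta))
      stop("parse error at line 1: expected PLINK .raw header ",
           "FID IID PAT MAT SEX PHENOTYPE ...")
    ids <- as.character(df$IID)
    vals <- as.matrix(df[, -(1:6), drop = FALSE])
    storage.mode(vals) <- "double"
    vals <- apply(vals, 2, impute_mode)
    rownames(vals) <- ids
    return(drop_constant(feature_matrix(vals, "genotype")))
  }
  lines1 <- readLines(path, n = 1L)
  if (length(lines1) == 0L || !nzchar(lines1))
    stop("parse error at line 1: empty header")
  sep <- detect_sep(lines1)
  if (is.na(sep))
    stop("parse error at line 1: header is neither tab- nor comma-delimited")
  nf <- utils::count.fields(path, sep = sep, quote = "")
  header <- strsplit(lines1, sep, fixed = TRUE)[[1]]
  body_nf <- nf[-1]
  if (length(body_nf) == 0L) stop("parse error: no data rows in ", path)
  expect <- if (all(body_nf == length(header))) length(header)
            else if (all(body_nf == length(header) + 1L)) length(header) + 1L
            else stop("parse error at line ",
                      1L + which(body_nf != body_nf[1])[1],
                      ": inconsistent field count")
  feats <- if (expect == length(header)) header[-1] else header
  df <- read.table(path, header = FALSE, sep = sep, skip = 1L,
                   stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, feats)
  if (modality == "genotype") vals <- apply(vals, 2, impute_mode)
  rownames(vals) <- ids
  drop_constant(feature_matrix(vals, modality))
}

impute_mode <- function(x) {
  if (!anyNA(x)) return(x)
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) stop("feature with all values missing")
  tab <- table(obs)
  m <- as.numeric(names(tab)[which.max(tab)])
  x[is.na(x)] <- m
  x
}

drop_constant <- function(fm) {
  v <- apply(fm, 2, function(col) max(col) - min(col))
  keep <- v > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s): ",
            paste(colnames(fm)[!keep], collapse = ", "))
    fm <- feature_matrix(unclass(fm)[, keep, drop = FALSE], modality_of(fm))
  }
  fm
}

#' Write a feature matrix as tab-delimited text
#'
#' Inverse of the `"delimited"` dialect of [read_feature_matrix()]:
#' `write_feature_matrix()` then `read_feature_matrix()` reproduces the
#' values bit-exactly.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  vals <- format_full(unclass(fm))
  df <- data.frame(subject_id = rownames(fm), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision decimal rendering so numeric round trips are bit-exact
format_full <- function(m) {
  out <- vapply(as.vector(m), function(x) sprintf("%.17g", x), character(1))
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Column-standardize a feature matrix
#'
#' Centers each feature to mean zero and scales to unit sample standard
#' deviation, the normalization expected by the similarity kernels and the
#' CCA solver.
#'
#' @param fm a [feature_matrix()] or plain numeric matrix.
#' @param center,scale optional vectors of pre-computed means and standard
#'   deviations (used to apply training-fold statistics to test subjects).
#' @return standardized matrix with `"center"` and `"scale"` attributes.
#' @export
standardize <- function(fm, center = NULL, scale = NULL) {
  x <- unclass(as.matrix(fm))
  storage.mode(x) <- "double"
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, sd)
  if (any(scale < 1e-12))
    stop("constant feature(s) cannot be standardized: ",
         paste(colnames(x)[scale < 1e-12], collapse = ", "))
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Align two feature matrices (and optional labels) on shared subjects
#'
#' Restricts both matrices to the intersection of their subject ids, ordered
#' as in the first argument, and subsets the label vector to match.
#'
#' @param a,b feature matrices with subject ids as row names.
#' @param labels optional labels (named factor/character, names = subject ids).
#' @return list with elements `a`, `b` and (if given) `labels`.
#' @export
align_subjects <- function(a, b, labels = NULL) {
  ids <- intersect(rownames(a), rownames(b))
  if (length(ids) == 0L) stop("no subjects shared between the two matrices")
  a2 <- feature_matrix(unclass(a)[ids, , drop = FALSE], modality_of(a))
  b2 <- feature_matrix(unclass(b)[ids, , drop = FALSE], modality_of(b))
  out <- list(a = a2, b = b2)
  if (!is.null(labels)) {
    if (is.null(names(labels))) stop("labels must be named by subject id")
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("labels missing for subjects: ", paste(missing, collapse = ", "))
    out$labels <- droplevels(as.factor(labels[ids]))
  }
  out
}

#' Read a diagnosis label file
#'
#' Two delimited columns: subject id and diagnosis string (tab or comma,
#' auto-detected; a header line is optional and detected by non-repetition).
#'
#' @param path file path.
#' @return factor named by subject id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  l1 <- readLines(path, n = 1L)
  sep <- detect_sep(l1)
  if (is.na(sep)) sep <- ""
  df <- read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("labels file needs two columns: subject id, diagnosis")
  if (identical(tolower(df[1, 1]), "subject_id")) df <- df[-1, , drop = FALSE]
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject id(s) in labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(factor(df[[2]]), ids)
}

#' Read / write a square network file
#'
#' Delimited n x n matrix with matching id header and row labels; the format
#' used to exchange similarity networks and prior graphs.
#'
#' @param path file path.
#' @return square numeric matrix with matching dimnames.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(readLines(path, n = 1L))
  if (is.na(sep)) stop("parse error at line 1: undetectable delimiter")
  m <- as.matrix(read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, quote = ""))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("network file must be square with matching row/column ids")
  m
}

#' @rdname read_network
#' @param net square matrix with matching dimnames.
#' @export
write_network <- function(net, path) {
  df <- data.frame(id = rownames(net), format_full(as.matrix(net)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
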