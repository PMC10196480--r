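test_that("delimited feature matrices round-trip bit-exactly", {
  fm <- feature_matrix(rand_fm(3, 2), "imaging")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path, "delimited")
  expect_identical(dim(back), dim(fm))
  expect_identical(rownames(back), rownames(fm))
  expect_identical(colnames(back), colnames(fm))
  expect_identical(unclass(back)[, ], unclass(fm)[, ])
  # second round trip is also exact
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("comma and tab dialects are auto-detected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,f1,f2", "s1,1.5,2", "s2,3,4.25", "s3,0,1"), path)
  fm <- read_feature_matrix(path)
  expect_equal(dim(fm), c(3L, 2L))
  expect_equal(unname(fm["s2", "f2"]), 4.25)
})

test_that("plink-raw dosages are parsed and NA imputed by per-SNP mode", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
    "f1 s1 0 0 1 -9 0 2",
    "f2 s2 0 0 2 -9 0 1",
    "f3 s3 0 0 1 -9 1 0",
    "f4 s4 0 0 2 -9 NA 1"), path)
  fm <- read_feature_matrix(path, "plink-raw")
  expect_identical(attr(fm, "modality"), "genotype")
  expect_identical(rownames(fm), c("s1", "s2", "s3", "s4"))
  expect_equal(unname(fm["s4", "rs1_A"]), 0)  # mode of {0,0,1}
})

test_that("constant features are dropped with a warning", {
  x <- rand_fm(4, 3)
  x[, 2] <- 7
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(feature_matrix(x), path)
  expect_warning(fm <- read_feature_matrix(path), "constant")
  expect_equal(ncol(fm), 2L)
  expect_false("f02" %in% colnames(fm))
})

test_that("malformed and duplicate inputs raise informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tf1\tf2", "s1\t1\t2", "s2\t3"), path)
  expect_error(read_feature_matrix(path), "parse error")
  writeLines(c("id\tf1", "s1\t1", "s1\t2", "s2\t0"), path)
  expect_error(read_feature_matrix(path), "duplicate subject")
  expect_error(read_feature_matrix(tempfile()), "not found")
})

test_that("standardize gives exact z-scores and is idempotent", {
  fm <- feature_matrix(cbind(a = c(1, 2, 3), b = c(5, 1, 0)))
  s <- standardize(fm)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(s), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(s, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(standardize(s)[, ], s[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(standardize(cbind(c(5, 5, 5))), "constant")
})

test_that("align_subjects intersects, reorders, and is idempotent", {
  a <- feature_matrix(rand_fm(3, 2)[c("s01", "s02", "s03"), ])
  b <- feature_matrix(rand_fm(4, 2, seed = 2)[c("s02", "s03", "s04", "s01"), ])
  rownames(b) <- c("s02", "s03", "s04", "s05")
  al <- align_subjects(a, b)
  expect_identical(rownames(al$a), c("s02", "s03"))
  expect_identical(rownames(al$b), c("s02", "s03"))
  al2 <- align_subjects(al$a, al$b)
  expect_identical(unclass(al2$a)[, ], unclass(al$a)[, ])
  # same ids, different order: b is reordered to match a
  b2 <- feature_matrix(unclass(a)[c(3, 1, 2), ])
  expect_identical(rownames(align_subjects(a, b2)$b), rownames(a))
  # disjoint sets
  rownames(b2) <- c("x1", "x2", "x3")
  expect_error(align_subjects(a, b2), "no subjects shared")
  # labels subset and ordered
  lab <- setNames(factor(c("AD", "CN", "CN", "MCI")),
                  c("s03", "s01", "s02", "s99"))
  al3 <- align_subjects(a, feature_matrix(unclass(a)[, ]), lab)
  expect_identical(as.character(al3$labels), c("CN", "CN", "AD"))
})

test_that("square network files round-trip with matching ids", {
  W <- matrix(runif(9), 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(W, path)
  back <- read_network(path)
  expect_identical(dimnames(back), dimnames(W))
  expect_identical(back[, ], W[, ])
})

test_that("label files are read as named factors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tCN", "s2\tAD", "s3\tCN"), path)
  lab <- read_labels(path)
  expect_identical(names(lab), c("s1", "s2", "s3"))
  expect_identical(levels(lab), c("AD", "CN"))
})
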