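write_tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

test_that("mixture tables read with covariates, preserving row order", {
  set.seed(11)
  df <- data.frame(d13C = round(rnorm(10, -20), 3), d15N = round(rnorm(10, 8), 3),
                   Length = round(runif(10, 40, 300), 1),
                   Sex = rep(c("F", "M"), 5))
  f <- write_tmp_csv(df)
  mix <- read_mixture_table(f, c("d13C", "d15N"), factor_columns = "Sex",
                            continuous_columns = "Length")
  expect_s3_class(mix, "mixture_data")
  expect_equal(dim(mix$values), c(10L, 2L))
  expect_equal(mix$values[, "d13C"], df$d13C)
  expect_equal(mix$continuous_covariates$Length, df$Length)
  # first-appearance level order, not alphabetical
  expect_equal(levels(mix$fixed_factors$Sex), c("F", "M"))
})

test_that("schema and validation errors name the offender", {
  df <- data.frame(d13C = c(-20, -21), Sex = c("F", "F"))
  f <- write_tmp_csv(df)
  expect_error(read_mixture_table(f, c("d13C", "d15N")), "d15N")
  expect_error(read_mixture_table(f, "d13C", factor_columns = "Sex"),
               ">= 2 levels")
  df2 <- data.frame(d13C = c("-20", "oops", "-19"))
  f2 <- write_tmp_csv(df2)
  expect_error(read_mixture_table(f2, "d13C"), "row 2")
  # a 2-level factor cannot be declared random
  df3 <- data.frame(d13C = rnorm(6), Sex = rep(c("F", "M"), 3))
  f3 <- write_tmp_csv(df3)
  expect_error(read_mixture_table(f3, "d13C", factor_columns = "Sex",
                                  random_flags = TRUE), "fixed effect")
})

test_that("summary source tables read with concentrations and n", {
  df <- data.frame(Source = c("eggs", "fish", "inverts"),
                   Meand13C = c(-30, -20, -25), SDd13C = c(1, 2, 1.5),
                   Meand15N = c(5, 10, 8), SDd15N = c(1, 1, 1),
                   Concd13C = c(0.4, 0.5, 0.45), Concd15N = c(0.1, 0.12, 0.11),
                   n = c(30, 8, 25))
  f <- write_tmp_csv(df)
  src <- read_source_table(f, "summary", c("d13C", "d15N"))
  expect_equal(src$treatment, "summary")
  expect_equal(src$source_names, c("eggs", "fish", "inverts"))
  expect_equal(unname(src$means[, 1]), c(-30, -20, -25))
  expect_equal(src$sample_sizes, c(30L, 8L, 25L))
  expect_equal(unname(src$concentrations[2, ]), c(0.5, 0.12))
  expect_error(read_source_table(write_tmp_csv(df[-8]), "summary",
                                 c("d13C", "d15N")), "n")
  df_bad <- df; df_bad$SDd13C[1] <- 0
  expect_error(read_source_table(write_tmp_csv(df_bad), "summary",
                                 c("d13C", "d15N")), "SD")
})

test_that("raw source tables summarize to the externally computed statistics", {
  set.seed(12)
  raw <- data.frame(Source = rep(c("A", "B"), each = 20),
                    d13C = round(rnorm(40, rep(c(-25, -15), each = 20)), 6),
                    d15N = round(rnorm(40, rep(c(5, 12), each = 20)), 6))
  f <- write_tmp_csv(raw)
  src <- read_source_table(f, "raw", c("d13C", "d15N"))
  expect_equal(src$treatment, "raw")
  expect_equal(nrow(src$raw_samples$A), 20L)
  # internal summarization == external summary of the same samples
  ext_mean <- aggregate(cbind(d13C, d15N) ~ Source, raw, mean)
  ext_sd <- aggregate(cbind(d13C, d15N) ~ Source, raw, sd)
  expect_equal(unname(src$means), unname(as.matrix(ext_mean[, 2:3])),
               tolerance = 1e-12)
  expect_equal(unname(src$sds), unname(as.matrix(ext_sd[, 2:3])),
               tolerance = 1e-12)
})

test_that("as_fixed_sources freezes and is idempotent", {
  df <- data.frame(Source = c("A", "B"), Meanx = c(-20, -10), SDx = c(1, 2),
                   n = c(10, 10))
  src <- read_source_table(write_tmp_csv(df), "summary", "x")
  fx <- as_fixed_sources(src)
  expect_equal(fx$treatment, "fixed")
  expect_equal(fx$means, src$means)
  expect_equal(fx$sds, src$sds)
  expect_identical(as_fixed_sources(fx), fx)
  expect_null(fx$raw_samples)
})

test_that("round-trip write/read reproduces values bit-identically", {
  fx <- alligator_like_fixture(seed = 2, n_consumers = 20L)
  fmix <- tempfile(fileext = ".csv")
  write_mixture_table(fx$mix, fmix)
  back <- read_mixture_table(fmix, fx$mix$tracer_names,
                             factor_columns = names(fx$mix$fixed_factors),
                             continuous_columns = "Length")
  expect_identical(back$values, fx$mix$values)
  expect_identical(back$continuous_covariates$Length,
                   fx$mix$continuous_covariates$Length)
  fsrc <- tempfile(fileext = ".csv")
  write_source_table(fx$src, fsrc)
  src_back <- read_source_table(fsrc, "summary", fx$src$tracer_names)
  expect_identical(src_back$means, fx$src$means)
  expect_identical(src_back$sds, fx$src$sds)
  fdisc <- tempfile(fileext = ".csv")
  write_discrimination_table(fx$disc, fdisc)
  disc_back <- read_discrimination_table(fdisc, fx$src$tracer_names, fx$src)
  expect_identical(disc_back$means, fx$disc$means)
})

test_that("tab-delimited files auto-detect and missing discrimination is zero", {
  df <- data.frame(d13C = c(-20.5, -21.25), d15N = c(8, 9))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  mix <- read_mixture_table(f, c("d13C", "d15N"))
  expect_equal(mix$values[, 1], df$d13C)
  src <- source_data("summary", matrix(c(-20, -10), 2, 1),
                     matrix(1, 2, 1), c(5L, 5L), tracer_names = "d13C")
  disc <- read_discrimination_table(NULL, "d13C", src)
  expect_true(all(disc$means == 0) && all(disc$sds == 0))
})
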