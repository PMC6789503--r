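test_that("luminescence CSVs are read and validated", {
  path <- write_fixture_csv(luc = c(40, 80, 12, 30), ren = c(10, 20, 3, 10),
                            construct = c("p0", "p0", "p7", "p7"),
                            OHT = c("no", "no", "yes", "yes"),
                            Cytokine = c("IL3", "IL3", "GCSF", "GCSF"))
  tab <- read_luminescence_csv(path)
  expect_s3_class(tab, "luminescence_table")
  expect_equal(nrow(tab), 4)
  expect_identical(names(tab), c("Luc", "Ren", "Construct", "OHT", "Cytokine"))

  # header-only file: empty table, zero groups downstream
  empty <- tempfile(fileext = ".csv")
  writeLines("Luc,Ren,Construct,OHT", empty)
  tab0 <- read_luminescence_csv(empty)
  expect_equal(nrow(tab0), 0)
  expect_equal(nrow(calc_slopes_cis(tab0, ci_method = "none")), 0)

  # misnamed columns and bad cells are named in the error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("Luc,Renilla,Construct", "1,2,a"), bad)
  expect_error(read_luminescence_csv(bad), "'Luc', 'Ren', 'Construct'")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("Luc,Ren,Construct", "1,2,a", "x,3,a"), bad2)
  expect_error(read_luminescence_csv(bad2), "row 2")
  expect_error(read_luminescence_csv(tempfile()), "not found")
})

test_that("numeric-looking labels are treated as categorical levels", {
  path <- write_fixture_csv(luc = c(1, 2), ren = c(1, 1),
                            construct = c(0, 7))
  tab <- read_luminescence_csv(path)
  expect_type(tab$Construct, "character")
})

test_that("grouped estimation yields one row per observed combination, in file order", {
  set.seed(55)
  groups <- expand.grid(Construct = c("c0", "c7", "c7m1"),
                        Cytokine = c("IL3", "GCSF"), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    r <- runif(10, 2, 20)
    data.frame(Luc = (i + 1) * r + rnorm(10, sd = 0.5), Ren = r,
               Construct = groups$Construct[i], Cytokine = groups$Cytokine[i])
  }))
  res <- calc_slopes_cis(rows, method = "ols", ci_method = "boot",
                         n_boot = 99, seed = 1)
  expect_equal(nrow(res), 6)
  expect_true(all(res$n_replicates == 10))
  expect_identical(res$Construct, groups$Construct)  # file-appearance order
  expect_equal(res$slope, seq_len(6) + 1, tolerance = 0.1)
  expect_true(all(res$ci_lower <= res$slope & res$slope <= res$ci_upper))
})

test_that("collinear groups give the same slope for every estimator", {
  df <- data.frame(Luc = 4 * c(1, 2, 3), Ren = c(1, 2, 3), Construct = "c")
  for (m in c("ratio", "ols", "eiv", "reiv")) {
    res <- calc_slopes_cis(df, method = m, ci_method = "none")
    expect_equal(res$slope, 4, tolerance = 1e-9, label = m)
  }
})

test_that("a too-small group is marked failed without affecting the others", {
  df <- data.frame(Luc = c(5, 3, 6, 9), Ren = c(1, 1, 2, 3),
                   Construct = c("solo", "trio", "trio", "trio"))
  res <- calc_slopes_cis(df, method = "reiv", ci_method = "none")
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$slope[res$Construct == "solo"]))
  expect_match(res$error[res$Construct == "solo"], "at least 2")
  expect_false(is.na(res$slope[res$Construct == "trio"]))
})

test_that("results round-trip through CSV bit-exactly", {
  df <- data.frame(Luc = c(exp(1) * 7, pi * 11, 40, 80), Ren = c(7, 11, 10, 20),
                   Construct = c("a", "a", "b", "b"))
  res <- calc_slopes_cis(df, method = "eiv", ci_method = "boot",
                         n_boot = 99, seed = 2)
  out <- tempfile(fileext = ".csv")
  write_results_csv(res, out)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(back$slope, res$slope, tolerance = 1e-15)
  expect_equal(back$ci_lower, res$ci_lower, tolerance = 1e-15)
  # empty result table -> header-only file
  res0 <- res[0, ]
  out0 <- tempfile(fileext = ".csv")
  write_results_csv(res0, out0)
  expect_length(readLines(out0), 1)
})

test_that("simulated tables flow through I/O without numeric drift", {
  cfg <- simulation_config(true_activity = 10, n = 20, tbar = 0.75,
                           sigma11 = 1, sigma12 = 1)
  d <- simulate_experiment(cfg, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_luminescence_csv(d, path, construct = "sim")
  tab <- read_luminescence_csv(path)
  direct <- eiv_estimate(d)$activity
  via_io <- calc_slopes_cis(tab, method = "eiv", ci_method = "none")$slope
  expect_equal(via_io, direct, tolerance = 1e-12)
})

test_that("reference-construct normalization divides by the matching group", {
  df <- data.frame(Luc = c(2 * c(1, 2, 3), 6 * c(1, 2, 3)),
                   Ren = rep(c(1, 2, 3), 2),
                   Construct = rep(c("base", "enh"), each = 3))
  res <- calc_slopes_cis(df, method = "ols", ci_method = "none",
                         reference_construct = "base")
  expect_equal(res$relative_slope, c(1, 3), tolerance = 1e-12)
  expect_error(calc_slopes_cis(df, method = "ols", ci_method = "none",
                               reference_construct = "nope"), "not found")
})

test_that("the ignore set must keep Luc and Ren out of the grouping", {
  df <- data.frame(Luc = 1, Ren = 1, Construct = "a")
  expect_error(calc_slopes_cis(df, ignore = "Luc"), "Luc.*Ren")
})
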