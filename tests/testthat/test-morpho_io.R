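test_that("trait catalog has the 23 measured codes plus derived CS", {
  cat <- trait_catalog()
  expect_equal(nrow(cat), 24)
  expect_equal(sum(cat$kind == "measured"), 23)
  expect_true(all(c("CL", "CWb", "Cdep", "PSTI", "PPL", "CS") %in% cat$code))
  expect_false(anyDuplicated(cat$code) > 0)
  expect_setequal(setdiff(cat$code[cat$kind == "measured"],
                          analysis_traits()), c("Cdep", "PSTI"))
})

test_that("read_morpho_table parses, preserves metadata, blanks become NA", {
  df <- data.frame(specimen_id = c("A1", "A2"), nest_id = c("n1", "n2"),
                   CL = c(700, 710), CWb = c(600, NA),
                   locality = c("x", "y"))
  path <- write_csv_fixture(df)
  tab <- read_morpho_table(path)
  expect_s3_class(tab, "morpho_table")
  expect_equal(nrow(tab), 2)
  expect_setequal(trait_cols(tab), c("CL", "CWb"))
  expect_true("locality" %in% names(tab))   # unknown column preserved
  expect_true(is.na(tab$CWb[2]))            # blank -> absent, not zero
})

test_that("read_morpho_table rejects bad input naming the culprit", {
  df <- data.frame(specimen_id = c("A1", "A1"), nest_id = c("n1", "n2"),
                   CL = c(700, 710))
  expect_error(read_morpho_table(write_csv_fixture(df)), "A1")
  df2 <- data.frame(specimen_id = c("A1", "A2"), nest_id = c("n1", "n2"),
                    CL = c(700, -5))
  expect_error(read_morpho_table(write_csv_fixture(df2)), "CL")
  df3 <- data.frame(specimen_id = c("A1", "A2"), nest_id = c("n1", ""),
                    CL = c(700, 705))
  expect_error(read_morpho_table(write_csv_fixture(df3)), "nest_id")
  df4 <- data.frame(specimen_id = "A1", nest_id = "n1", CL = "seven")
  expect_error(read_morpho_table(write_csv_fixture(df4)), "non-numeric")
})

test_that("read -> write -> read round-trips bit-identically", {
  tab <- make_table(n = 8, nests = 4)
  p1 <- tempfile(fileext = ".csv")
  write_morpho_table(tab, p1)
  back <- read_morpho_table(p1)
  expect_identical(back$CL, tab$CL)
  expect_identical(back$CWb, tab$CWb)
  expect_identical(back$specimen_id, tab$specimen_id)
})

test_that("derive_cs computes the CL/CWb arithmetic mean", {
  tab <- as_morpho_table(data.frame(
    specimen_id = c("a", "b", "c"), nest_id = "n1",
    CL = c(700, 500, 946), CWb = c(600, 500, 850)))
  out <- derive_cs(tab)
  expect_equal(out$CS, c(650, 500, 898))   # identity case and printed extremes
  expect_equal(out$CL, tab$CL)             # other columns untouched
  tab$CWb[2] <- NA
  expect_error(derive_cs(as_morpho_table(as.data.frame(tab))), "b")
})

test_that("ratio_table produces dimensionless ratios with NA propagation", {
  tab <- as_morpho_table(data.frame(
    specimen_id = c("a", "b"), nest_id = "n1",
    SL = c(650, NA), CS = c(1000, 900), CL = c(1100, 980),
    CWb = c(900, 820)))
  rt <- ratio_table(tab, "CS", c("SL", "CS"))
  expect_equal(rt[["SL/CS"]], c(0.65, NA))
  expect_equal(rt[["CS/CS"]], c(1, 1))     # identity ratio exactly 1
  expect_error(ratio_table(tab, "CS", character(0)), "non-empty")
})

test_that("ratios are invariant under global rescaling of measurements", {
  sim <- small_sim(n_species = 2, nests = 3)
  tab <- sim$table
  scaled <- as.data.frame(tab)
  for (tc in trait_cols(tab)) scaled[[tc]] <- scaled[[tc]] * 3.7
  scaled <- derive_cs(as_morpho_table(scaled))
  r1 <- ratio_table(tab, "CS", c("SL", "ML"))
  r2 <- ratio_table(scaled, "CS", c("SL", "ML"))
  expect_equal(r1[["SL/CS"]], r2[["SL/CS"]], tolerance = 1e-12)
  expect_equal(r1[["ML/CS"]], r2[["ML/CS"]], tolerance = 1e-12)
})

test_that("synthetic ratios track their generator parameter", {
  sim <- simulate_dataset(table2_params()["angulatus"],
                          nests_per_species = 40, nest_size = 2, seed = 3)
  rt <- ratio_table(sim$table, "CS", "SL")
  expect_equal(mean(rt[["SL/CS"]]), 0.815, tolerance = 0.01)
})

test_that("correlation_screen: collinear traits score r = 1, unflagged", {
  set.seed(9)
  n <- 30
  df <- data.frame(specimen_id = sprintf("s%02d", 1:n),
                   nest_id = rep(c("n1", "n2", "n3"), each = 10),
                   CL = runif(n, 600, 700))
  df$CWb <- 2 * df$CL
  tab <- as_morpho_table(df)
  rep <- correlation_screen(tab, class_labels = df$nest_id)
  expect_equal(rep$mean_r, c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(any(rep$flagged))
})

test_that("correlation_screen flags a noise trait; pooled r matches a direct
           per-class oracle; invariant to row order", {
  set.seed(11)
  n <- 200
  classes <- rep(sprintf("c%d", 1:4), each = n / 4)
  size <- rnorm(n, 1000, 80)                  # common size factor
  df <- data.frame(specimen_id = sprintf("s%03d", 1:n), nest_id = classes,
                   CL = size * rnorm(n, 1, 0.02),
                   CWb = size * rnorm(n, 0.8, 0.02),
                   SL = size * rnorm(n, 0.6, 0.02),
                   PPL = rnorm(n, 200, 20))   # independent noise
  tab <- as_morpho_table(df)
  rep <- correlation_screen(tab, class_labels = classes)
  expect_identical(rep$trait[rep$flagged], "PPL")

  # oracle: pooled r for the CL-CWb pair, computed independently
  r_by_class <- vapply(unique(classes), function(cl)
    cor(df$CL[classes == cl], df$CWb[classes == cl]), numeric(1))
  w <- vapply(unique(classes), function(cl) sum(classes == cl) - 1, numeric(1))
  pooled <- attr(rep, "pooled_r")
  expect_equal(pooled["CL", "CWb"], sum(w * r_by_class) / sum(w),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pooled, t(pooled))             # symmetric in trait order

  perm <- sample(n)
  rep2 <- correlation_screen(as_morpho_table(df[perm, ]),
                             class_labels = classes[perm])
  expect_equal(rep$mean_r, rep2$mean_r, tolerance = 1e-12)
})

test_that("correlation_screen needs a usable class", {
  tab <- make_table(n = 4, nests = 4)   # every nest has 1 specimen
  expect_error(correlation_screen(tab), ">= 3 specimens")
})

test_that("standardize_columns yields mean 0 / sd 1 and is idempotent", {
  expect_equal(as.numeric(standardize_columns(cbind(a = c(1, 2, 3)))),
               c(-1, 0, 1))
  set.seed(5)
  m <- matrix(rnorm(500, 50, 9), 100, 5,
              dimnames = list(NULL, paste0("t", 1:5)))
  z <- standardize_columns(m)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  z2 <- standardize_columns(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  m[, 2] <- 7
  expect_error(standardize_columns(m), "t2")
})
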