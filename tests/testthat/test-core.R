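# Peak-table ingestion, internal-standard quantification and fractional
# abundances.

make_area_df <- function(n = 3, seed = 42) {
  set.seed(seed)
  df <- data.frame(sample_id = sprintf("s%d", seq_len(n)),
                   station = "KT1", dry_weight = runif(n, 2, 3),
                   is_mass = 100, toc = runif(n, 0.3, 1.2),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (cc in DETECTED11) df[[cc]] <- runif(n, 10, 1000)
  df[["Cren"]] <- runif(n, 1e4, 5e4)
  df[["C46-GTGT"]] <- runif(n, 500, 2000)
  df
}

test_that("peak tables round-trip through CSV with aliases resolved", {
  df <- make_area_df(3)
  names(df)[names(df) == ID_IIa6] <- "IIa'"   # ASCII apostrophe header
  pt <- read_peak_table(write_fixture_csv(df))
  expect_s3_class(pt, "gdgt_table")
  expect_equal(nrow(pt), 3L)
  expect_setequal(intersect(compounds(pt), brgdgt_ids()), DETECTED11)
  expect_true(ID_IIa6 %in% names(pt))          # alias mapped to prime form
  expect_true(all(c("Cren", "C46-GTGT") %in% compounds(pt)))
  # absent compounds are not invented as zero columns
  expect_false("IIIb" %in% names(pt))

  out <- tempfile(fileext = ".csv")
  write_gdgt_table(pt, out)
  back <- read_peak_table(out)
  expect_identical(back$sample_id, pt$sample_id)
  expect_identical(back$station, pt$station)
  for (cc in compounds(pt)) {
    expect_equal(back[[cc]], pt[[cc]], tolerance = 1e-12)
  }
})

test_that("explicit column mapping works and errors are informative", {
  df <- make_area_df(2)
  names(df)[names(df) == "Ia"] <- "peak_1022_first"
  pt <- read_peak_table(write_fixture_csv(df),
                        mapping = c("Ia" = "peak_1022_first"))
  expect_true("Ia" %in% compounds(pt))

  expect_error(read_peak_table(write_fixture_csv(df),
                               mapping = c("IVa" = "peak_1022_first")),
               "accepted ids")

  bad <- make_area_df(3)
  bad$IIa[2] <- -5
  expect_error(read_peak_table(write_fixture_csv(bad)),
               "negative peak area.*IIa.*row 2")
})

test_that("quantification follows the internal-standard ratio formula", {
  df <- data.frame(sample_id = "x", dry_weight = 2, is_mass = 100,
                   Ia = 500, IIa = 0, `C46-GTGT` = 500,
                   check.names = FALSE)
  ct <- quantify(read_peak_table(write_fixture_csv(df)))
  expect_equal(ct$Ia, 50)        # area ratio 1 x 100 ng / 2 g
  expect_equal(ct$IIa, 0)        # zero area stays zero

  # randomized records against independent hand computation
  df2 <- make_area_df(5, seed = 7)
  pt2 <- read_peak_table(write_fixture_csv(df2))
  ct2 <- quantify(pt2)
  for (i in seq_len(5)) {
    for (cc in DETECTED11) {
      expect_equal(ct2[[cc]][i],
                   (df2[[cc]][i] / df2[["C46-GTGT"]][i]) * df2$is_mass[i] /
                     df2$dry_weight[i],
                   tolerance = 1e-12)
    }
  }
  # TOC bookkeeping: ug per g TOC = (ng per g dws) / (10 * TOC%)
  tn <- attr(ct2, "toc_normalized")
  expect_equal(tn$Ia, ct2$Ia / (10 * df2$toc), tolerance = 1e-12)
})

test_that("quantification is linear in areas and inverse in the standard", {
  df <- make_area_df(4, seed = 11)
  pt <- read_peak_table(write_fixture_csv(df))
  base <- quantify(pt)

  df2 <- df
  for (cc in c(DETECTED11, "Cren")) df2[[cc]] <- 2 * df2[[cc]]
  doubled <- quantify(read_peak_table(write_fixture_csv(df2)))
  expect_equal(doubled$Ia, 2 * base$Ia, tolerance = 1e-12)

  df3 <- df
  df3[["C46-GTGT"]] <- 2 * df3[["C46-GTGT"]]
  halved <- quantify(read_peak_table(write_fixture_csv(df3)))
  expect_equal(halved$Ia, base$Ia / 2, tolerance = 1e-12)
})

test_that("quantification preconditions are enforced", {
  df <- make_area_df(2)
  df[["C46-GTGT"]][1] <- 0
  expect_error(quantify(read_peak_table(write_fixture_csv(df))),
               "quantification impossible")
  df2 <- make_area_df(2)
  df2[["C46-GTGT"]] <- NULL
  expect_error(quantify(read_peak_table(write_fixture_csv(df2))),
               "quantification impossible")
})

test_that("fractional abundances normalize over detected brGDGTs only", {
  # equal areas -> 1/11 each; crenarchaeol excluded from the sum
  df <- data.frame(sample_id = "e", check.names = FALSE)
  for (cc in DETECTED11) df[[cc]] <- 7
  df$Cren <- 100
  fa <- fractional_abundances(read_peak_table(write_fixture_csv(df)))
  for (cc in DETECTED11) expect_equal(fa[[cc]], 1 / 11, tolerance = 1e-12)

  solo <- data.frame(sample_id = "d", Ia = 42, IIa = 0, check.names = FALSE)
  fs <- fractional_abundances(read_peak_table(write_fixture_csv(solo)))
  expect_equal(fs$Ia, 1)

  # proportionality and unit sum on arbitrary areas
  df2 <- make_area_df(6, seed = 3)
  fa2 <- fractional_abundances(read_peak_table(write_fixture_csv(df2)))
  m <- as.matrix(as.data.frame(fa2)[DETECTED11])
  expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-9)
  expect_equal(m[, "Ia"] / m[, "IIa"], df2$Ia / df2$IIa, tolerance = 1e-12)

  zero <- data.frame(sample_id = "z", Ia = 0, IIa = 0, check.names = FALSE)
  expect_error(fractional_abundances(read_peak_table(write_fixture_csv(zero))),
               "empty composition")
})

test_that("fractional abundances are identical from areas and concentrations", {
  df <- make_area_df(4, seed = 19)
  pt <- read_peak_table(write_fixture_csv(df))
  fa_area <- fractional_abundances(pt)
  fa_conc <- fractional_abundances(quantify(pt))
  for (cc in DETECTED11) {
    expect_equal(fa_conc[[cc]], fa_area[[cc]], tolerance = 1e-12)
  }
  # and index values are scale-invariant across the two routes
  expect_equal(as.numeric(compute_imbt(fa_conc)),
               as.numeric(compute_imbt(pt)), tolerance = 1e-12)
})
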