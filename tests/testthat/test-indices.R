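# The proxy index suite: printed-formula cases, formula oracles on random
# compositions, monotonicity and flag behaviour.

test_that("IMBT matches direct substitution and handles zero cases", {
  eq <- setNames(rep(0.2, 5), c("IIIa", ID_IIIa6, "IIa", ID_IIa6, "Ia"))
  expect_equal(as.numeric(compute_imbt(eq)), -log10(0.4), tolerance = 1e-9)

  # zero 6-methyl numerator: undefined under the default policy
  no6 <- c(IIIa = 0.5, IIa = 0.3, Ia = 0.2)
  v <- compute_imbt(no6)
  expect_true(is.na(v))
  expect_true(attr(v, "undefined"))
  # ... but finite under the epsilon floor
  v2 <- compute_imbt(no6, zero_policy = "epsilon", epsilon = 1e-3)
  expect_true(is.finite(v2))
  expect_false(attr(v2, "undefined"))

  # all-6-methyl limit: ratio 1, IMBT = 0
  all6 <- setNames(c(0.6, 0.4), c(ID_IIIa6, ID_IIa6))
  expect_equal(as.numeric(compute_imbt(all6)), 0)
})

test_that("BIT, IR, MBT'5ME, CBT5ME and SIIIa/SIIa reproduce their formulas", {
  expect_equal(as.numeric(compute_bit(c(Ia = 1, IIa = 1, IIIa = 1,
                                        setNames(c(1, 1), c(ID_IIa6, ID_IIIa6)),
                                        Cren = 0))), 1)
  eqbit <- setNames(rep(1, 6),
                    c("Ia", "IIa", "IIIa", ID_IIa6, ID_IIIa6, "Cren"))
  expect_equal(as.numeric(compute_bit(eqbit)), 5 / 6, tolerance = 1e-12)

  only5 <- c(IIa = 0.5, IIIa = 0.5)
  expect_equal(as.numeric(compute_ir(only5)), 0)
  only6 <- setNames(c(0.5, 0.5), c(ID_IIa6, ID_IIIa6))
  expect_equal(as.numeric(compute_ir(only6)), 1)
  half <- setNames(c(0.5, 0.5), c("IIa", ID_IIa6))
  expect_equal(as.numeric(compute_ir(half)), 0.5)

  expect_equal(as.numeric(compute_mbt5me(c(Ia = 1))), 1)
  expect_equal(as.numeric(compute_mbt5me(c(IIIa = 1))), 0)
  expect_equal(as.numeric(compute_cbt5me(c(Ia = 0.25, Ib = 0.25,
                                           IIa = 0.25, IIb = 0.25))), 0)

  v <- setNames(c(0.3, 0.4, 0.2, 0.15),
                c("IIIa", ID_IIIa6, "IIa", ID_IIa6))
  expect_equal(as.numeric(compute_siiia_siia(v)), 2.0, tolerance = 1e-12)
  und <- compute_siiia_siia(c(IIIa = 0.5, Ia = 0.5))
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("ternary coordinates count series membership from the registry", {
  expect_equal(unname(ternary_coordinates(c(Ia = 1))[1, ]), c(1, 0, 0))
  eq11 <- setNames(rep(1 / 11, 11), DETECTED11)
  expect_equal(unname(ternary_coordinates(eq11)[1, ]),
               c(3 / 11, 6 / 11, 2 / 11), tolerance = 1e-12)
})

test_that("every index matches its hand-coded oracle on random compositions", {
  set.seed(101)
  fa <- random_compositions(500, ids = c(DETECTED11, "Cren"),
                            zero_prob = 0.05)
  imbt <- compute_imbt(fa)
  bit <- compute_bit(fa)
  ir <- compute_ir(fa)
  mbt <- compute_mbt5me(fa)
  cbt <- compute_cbt5me(fa)
  sr <- compute_siiia_siia(fa)
  tern <- ternary_coordinates(fa)
  for (i in seq_len(nrow(fa))) {
    row <- as.list(fa[i, ])
    expect_equal(as.numeric(imbt[i]), oracle_imbt(row), tolerance = 1e-12)
    expect_equal(as.numeric(bit[i]), oracle_bit(row), tolerance = 1e-12)
    expect_equal(as.numeric(ir[i]), oracle_ir(row), tolerance = 1e-12)
    expect_equal(as.numeric(mbt[i]), oracle_mbt5me(row), tolerance = 1e-12)
    expect_equal(as.numeric(cbt[i]), oracle_cbt5me(row), tolerance = 1e-12)
    expect_equal(as.numeric(sr[i]), oracle_siiia_siia(row),
                 tolerance = 1e-12)
    expect_equal(unname(tern[i, ]), unname(oracle_ternary(row)),
                 tolerance = 1e-12)
  }
})

test_that("indexes respond monotonically to isomer/methylation transfers", {
  base <- c(IIIa = 0.15, IIa = 0.2, Ia = 0.25)
  base[ID_IIIa6] <- 0.25
  base[ID_IIa6] <- 0.15
  # moving mass 6-methyl -> 5-methyl within the hexa series raises IMBT and
  # leaves SIIIa/SIIa unchanged
  shift <- base
  shift["IIIa"] <- shift["IIIa"] + 0.1
  shift[ID_IIIa6] <- shift[ID_IIIa6] - 0.1
  expect_gt(as.numeric(compute_imbt(shift)), as.numeric(compute_imbt(base)))
  expect_equal(as.numeric(compute_siiia_siia(shift)),
               as.numeric(compute_siiia_siia(base)), tolerance = 1e-12)
  # moving mass IIa' -> Ia raises both IMBT and MBT'5ME
  shift2 <- base
  shift2["Ia"] <- shift2["Ia"] + 0.1
  shift2[ID_IIa6] <- shift2[ID_IIa6] - 0.1
  expect_gt(as.numeric(compute_imbt(shift2)), as.numeric(compute_imbt(base)))
  expect_gt(as.numeric(compute_mbt5me(shift2)),
            as.numeric(compute_mbt5me(base)))
})

test_that("indexes depend on compound names, not column order", {
  set.seed(5)
  fa <- random_compositions(20, ids = c(DETECTED11, "Cren"))
  shuffled <- fa[, sample(ncol(fa))]
  for (f in list(compute_imbt, compute_bit, compute_ir, compute_mbt5me,
                 compute_cbt5me, compute_siiia_siia)) {
    expect_equal(as.numeric(f(shuffled)), as.numeric(f(fa)),
                 tolerance = 1e-12)
  }
})

test_that("undefined values are always flagged, incomplete inputs marked", {
  set.seed(77)
  fa <- random_compositions(2000, zero_prob = 0.25)
  idx <- compute_indices(fa)
  for (nm in c("imbt", "bit", "siiia_siia", "ir", "mbt5me", "cbt5me")) {
    expect_false(any(is.nan(idx[[nm]])))
    expect_true(all(is.na(idx[[nm]]) | is.finite(idx[[nm]])))
    # NA only where the _ok flag says undefined
    expect_true(all(!is.na(idx[[nm]]) | !idx[[paste0(nm, "_ok")]]))
  }
  # IIIb/IIIc series absent from the detected set: IR input is incomplete
  expect_true(attr(idx, "incomplete")[["ir"]])
  # BIT without a crenarchaeol column is likewise incomplete
  expect_true(attr(compute_bit(fa), "incomplete")[1])
})

test_that("user-registered indexes are computed alongside the suite", {
  register_index("acyclic_share",
                 function(x) {
                   m <- as.matrix(as.data.frame(x)[intersect(
                     c("Ia", "IIa", ID_IIa6, "IIIa", ID_IIIa6),
                     names(as.data.frame(x)))])
                   rowSums(m)
                 },
                 citation = "package example")
  on.exit(unregister_index("acyclic_share"))
  set.seed(9)
  fa <- random_compositions(5)
  idx <- compute_indices(fa)
  expect_true("acyclic_share" %in% names(idx))
  expect_true(all(idx$acyclic_share > 0 & idx$acyclic_share <= 1))
})
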