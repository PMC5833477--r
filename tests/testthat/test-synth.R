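test_that("intensity tables are deterministic, non-negative and label-conserving", {
  sp <- mixtureSpec(nCells = 10000L, highFraction = 0.05, seed = 7L)
  t1 <- genIntensityTable(sp)
  t2 <- genIntensityTable(sp)
  expect_identical(t1, t2)

  cells <- t1$cells
  expect_equal(nrow(cells), 10000L)
  expect_true(all(cells$intensity >= 0))
  expect_identical(t1$truth$nHigh + t1$truth$nLow, 10000L)
  expect_identical(sum(cells$label == "high"), t1$truth$nHigh)

  ## realized high count within the 3-sigma binomial bound of n * p
  bound <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(t1$truth$nHigh - 500), bound)

  ## degenerate mixture: no high cells at all
  t0 <- genIntensityTable(mixtureSpec(nCells = 500L, highFraction = 0,
                                      seed = 3L))
  expect_true(all(t0$cells$label == "low"))
  expect_identical(t0$truth$nHigh, 0L)
})

test_that("mixture spec validation names the offending field", {
  expect_error(mixtureSpec(nCells = 100, highFraction = 1.5), "highFraction")
  expect_error(mixtureSpec(nCells = 100, bgSd = 0), "bgSd")
  expect_error(mixtureSpec(nCells = 100, highShift = -1), "highShift")
  expect_error(mixtureSpec(nCells = -5), "nCells")
})

test_that("high and low populations barely overlap at shift 8", {
  t1 <- genIntensityTable(mixtureSpec(nCells = 100000L, highFraction = 0.3,
                                      highShift = 8, seed = 11L))
  lo <- t1$cells$intensity[t1$cells$label == "low"]
  hi <- t1$cells$intensity[t1$cells$label == "high"]
  overlap <- sum(hi < max(lo)) + sum(lo > min(hi))
  expect_lt(overlap / nrow(t1$cells), 0.001)
})

test_that("nuclei fields carry exact geometric ground truth", {
  sp <- fieldImageSpec(
    nNuclei = 50L, mixture = mixtureSpec(nCells = 50L, seed = 5L),
    nucleusRadiusSd = 1e-9, psfSigma = 0, noiseSd = 0
  )
  fld <- genNucleiField(sp)
  expect_equal(nrow(fld$truth), 50L)
  ## 6 um radius at 0.65 um/px -> 9.23 px
  expect_equal(fld$truth$radius_px, rep(6 / 0.65, 50), tolerance = 1e-6)
  ## noise-free nuclear mask has exactly 50 connected components
  lab <- EBImage::bwlabel(fld$image@nuclear > 0)
  expect_equal(max(lab), 50)
  ## pairwise separation respected
  d <- as.matrix(dist(fld$truth[, c("x", "y")])) * 0.65
  diag(d) <- Inf
  expect_true(all(d >= sp@minSeparation - 1e-9))

  ## empty field: noise-only channels, no truth rows
  blank <- genNucleiField(fieldImageSpec(
    nNuclei = 0L, mixture = mixtureSpec(nCells = 0L, seed = 1L)
  ))
  expect_equal(nrow(blank$truth), 0L)

  ## impossible packing is an error, not silent under-placement
  expect_error(
    genNucleiField(fieldImageSpec(
      nNuclei = 100L, mixture = mixtureSpec(nCells = 100L, seed = 1L),
      width = 128L, height = 128L, minSeparation = 40
    )),
    "could not place"
  )
})

test_that("plate generation honours roles, overrides, toxicity and substreams", {
  lay <- data.frame(
    well = c("A01", "A02", "B01", "B02", "C01"),
    role = c("dmso", "deab", "sample", "sample", "empty"),
    compound = c("DMSO", "DEAB", "CPD1", "CPD2", NA),
    dose_uM = c(0, 10, 10, 10, NA)
  )
  spec <- plateSpec(
    lay, baseMixture = mixtureSpec(nCells = 1000L, highFraction = 0.05),
    toxicity = c(B02 = 0.4), seed = 42L
  )
  ds1 <- genPlateDataset(spec)
  ds2 <- genPlateDataset(spec)
  expect_identical(ds1, ds2)

  tr <- ds1$truth
  expect_false("C01" %in% tr$well)                     # empty well skipped
  expect_equal(tr$n_cells[tr$well == "B02"], round(0.4 * 1000))
  expect_equal(tr$true_high_fraction[tr$well == "A02"], 0)  # deab forced
  expect_equal(tr$true_high_fraction[tr$well == "B01"], 0.05)
  ## per-well substreams: dropping a well does not change the others
  spec2 <- plateSpec(
    lay[lay$well != "A01", ], baseMixture = spec@baseMixture,
    toxicity = c(B02 = 0.4), seed = 42L
  )
  ds3 <- genPlateDataset(spec2)
  b1 <- ds1$cells[ds1$cells$well == "B01", ]
  b3 <- ds3$cells[ds3$cells$well == "B01", ]
  rownames(b1) <- rownames(b3) <- NULL
  expect_identical(b1, b3)
})

test_that("dose-response generator follows the 4PL closed form", {
  ## midpoint identity at x = IC50
  d <- genDoseResponse(doses = 2, top = 80, bottom = 20, ic50 = 2,
                       hill = 1.7, noiseSd = 0)
  expect_equal(d$data$effect, (80 + 20) / 2)
  ## closed form: 100 / (1 + 3) = 25
  d2 <- genDoseResponse(doses = 3, top = 100, bottom = 0, ic50 = 1,
                        hill = 1, noiseSd = 0)
  expect_equal(d2$data$effect, 25)
  ## steep-slope limit below the IC50 approaches the top asymptote
  d3 <- genDoseResponse(doses = 0.5, top = 100, bottom = 0, ic50 = 1,
                        hill = 50, noiseSd = 0)
  expect_equal(d3$data$effect, 100, tolerance = 1e-6)
  expect_error(genDoseResponse(doses = c(-1, 1)), "doses")
  expect_error(genDoseResponse(doses = 1, top = 0, bottom = 10), "bottom")
})
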