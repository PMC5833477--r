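test_that("toxicity masking uses a strict >50% cell-count reduction", {
  w <- toyWellTable(sampleFractions = c(0.1, 0.1, 0.1),
                    sampleCounts = c(49, 50, 100))
  m <- maskToxicWells(w)
  samp <- w$role == "sample"
  expect_identical(unname(m[samp]), c(TRUE, FALSE, FALSE))
  expect_false(any(m[!samp]))
  expect_error(
    maskToxicWells(w[w$role != "dmso", ]),
    "neutral"
  )
})

test_that("normalization anchors the controls at 0% and 100%", {
  w <- toyWellTable(sampleFractions = c(0.10, 0.00, 0.05),
                    sampleCounts = rep(100, 3))
  norm <- normalizeToControls(w)
  samp <- which(w$role == "sample")
  expect_equal(norm$normalized_effect[samp], c(0, 100, 50))
  expect_equal(norm$normalized_effect[w$role == "dmso"], rep(0, 3))
  expect_equal(norm$normalized_effect[w$role == "deab"], rep(100, 3))
  ## over-normalization allowed but flagged beyond +/-150
  w2 <- toyWellTable(sampleFractions = c(-0.08), sampleCounts = 100)
  n2 <- normalizeToControls(w2)
  expect_true(n2$normalized_effect[w2$role == "sample"] > 150)
  expect_true(n2$effect_flag[w2$role == "sample"])
  ## degenerate anchors are a QC error
  w3 <- toyWellTable(sampleFractions = 0.05, sampleCounts = 100,
                     dmsoFraction = 0.1, deabFraction = 0.1)
  expect_error(normalizeToControls(w3), "degenerate")
})

test_that("normalization is affine-invariant, reduction is scale-invariant", {
  set.seed(41)
  w <- toyWellTable(sampleFractions = runif(6, 0, 0.2),
                    sampleCounts = rep(100, 6))
  n0 <- normalizeToControls(w)$normalized_effect
  wShift <- w; wShift$fraction_high <- w$fraction_high + 0.37
  expect_equal(normalizeToControls(wShift)$normalized_effect, n0)
  r0 <- reductionVsNeutral(w)
  wScale <- w; wScale$fraction_high <- w$fraction_high * 4.2
  expect_equal(reductionVsNeutral(wScale), r0)
})

test_that("hits need a strict >25% reduction and an unmasked well", {
  ## dyadic anchor (0.125) so the 25% boundary is exact in floating point:
  ## reductions are 26%, exactly 25%, and 68% (masked)
  w <- toyWellTable(sampleFractions = c(0.0925, 0.09375, 0.040),
                    sampleCounts = c(100, 100, 40), dmsoFraction = 0.125)
  masked <- maskToxicWells(w)
  hits <- callHits(w, masked)
  samp <- which(w$role == "sample")
  expect_identical(unname(hits[samp]), c(TRUE, FALSE, FALSE))
  ## control wells are never hits
  expect_false(any(hits[-samp], na.rm = TRUE))
  ## zero neutral fraction: not evaluable
  w0 <- toyWellTable(sampleFractions = 0.05, sampleCounts = 100,
                     dmsoFraction = 0, deabFraction = 0.2)
  expect_warning(h0 <- callHits(w0, maskToxicWells(w0)), "undefined")
  expect_true(is.na(h0[w0$role == "sample"]))
})

test_that("fast-acting flag requires immediate effect plus rebound", {
  expect_true(flagFastActing(94, 5))
  expect_false(flagFastActing(10, 80))
  expect_false(flagFastActing(90, 90))   # persistent effect: no rebound
  expect_false(flagFastActing(50, 5))
  expect_true(is.na(flagFastActing(NA, 5)))
  expect_true(is.na(flagFastActing(94, NA)))
  ## vectorized over a follow-up table
  expect_identical(flagFastActing(c(94, 10, 90), c(5, 80, 90)),
                   c(TRUE, FALSE, FALSE))
})

test_that("robust Z-prime matches hand computation and a brute-force oracle", {
  expect_equal(robustZPrime(c(0, 0.1, 0.2), c(1.0, 1.1, 1.2)), 0.11044,
               tolerance = 1e-12)
  expect_identical(robustZPrime(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_warning(z <- robustZPrime(c(1, 1, 1), c(1, 1, 1)), "QC")
  expect_identical(z, -Inf)
  expect_error(robustZPrime(c(1, 2), c(1, 2, 3)), "at least 3")

  ## brute-force re-computation of the formula on random control sets
  bruteRZ <- function(p, n) {
    madS <- function(v) 1.4826 * median(abs(v - median(v)))
    1 - 3 * (madS(p) + madS(n)) / abs(median(p) - median(n))
  }
  set.seed(55)
  for (i in 1:100) {
    p <- rnorm(sample(3:12, 1), 0.02, 0.01)
    n <- rnorm(sample(3:12, 1), 0.2, 0.05)
    expect_equal(robustZPrime(p, n), bruteRZ(p, n), tolerance = 1e-12)
  }

  ## RZ' <= 1 and decreasing with control spread at fixed medians
  spread <- c(0.01, 0.02, 0.05, 0.1)
  z <- vapply(spread, function(s) {
    robustZPrime(c(0.2 - s, 0.2, 0.2 + s), c(0.8, 0.9, 1.0))
  }, numeric(1))
  expect_true(all(z <= 1))
  expect_true(all(diff(z) < 0))
})

test_that("signal-to-background divides the control aggregates", {
  expect_equal(signalToBackground(c(0.2, 0.2), c(0.1, 0.1)), 2)
  expect_equal(signalToBackground(c(0.3), c(0.3)), 1)
  expect_warning(sb <- signalToBackground(c(0.2), c(0)), "infinite")
  expect_identical(sb, Inf)
})

test_that("pipeline flags equal a brute-force oracle on a 24-well toy plate", {
  ## hand-enumerated plate: 3 DMSO (count anchor 100, dyadic fraction
  ## anchor 0.125 so the 25% boundary is floating-point exact), 3 DEAB,
  ## 18 samples including both rule boundaries
  fr <- c(0.0925, 0.09375, 0.040, 0.125, 0.15, 0.02, 0.0925, 0.09, 0.05,
          0.125, 0.091, 0.095, 0.00, 0.19, 0.0935, 0.094, 0.033, 0.125)
  ct <- c(100, 100, 40, 100, 100, 49, 50, 51, 100,
          100, 100, 100, 100, 100, 100, 100, 49, 50)
  w <- toyWellTable(sampleFractions = fr, sampleCounts = ct,
                    dmsoFraction = 0.125)
  res <- screenPlate(w)
  out <- screenWells(res)

  ## independent brute-force re-implementation of the three rules
  dmsoCount <- median(w$n_cells[w$role == "dmso"])
  dmsoFrac <- median(w$fraction_high[w$role == "dmso"])
  oracleMasked <- oracleHit <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    oracleMasked[i] <- w$n_cells[i] < 0.5 * dmsoCount
    reduction <- 100 * (dmsoFrac - w$fraction_high[i]) / dmsoFrac
    oracleHit[i] <- (!oracleMasked[i]) && reduction > 25 &&
      w$role[i] == "sample"
  }
  expect_identical(out$masked, oracleMasked)
  expect_identical(out$hit, oracleHit)
  ## boundary wells behave exactly as enumerated: count 50 unmasked,
  ## count 49 masked; reduction 25% not a hit, 26% a hit
  expect_false(out$masked[out$well == "G03"])   # count exactly 50
  expect_true(out$masked[out$well == "F03"])    # count 49
  expect_true(out$hit[out$well == "A03"])       # reduction 26%
  expect_false(out$hit[out$well == "B03"])      # reduction exactly 25%
})

test_that("screenPlate wires masking, QC and follow-up triage together", {
  w <- toyWellTable(sampleFractions = c(0.02, 0.003, 0.09),
                    sampleCounts = c(100, 100, 100))
  fu <- data.frame(compound = c("CPD01", "CPD02"),
                   effect_2h = c(5, 93), effect_washoff = c(70, 4))
  res <- screenPlate(w, followUp = fu)
  out <- screenWells(res)
  samp <- out$role == "sample"
  expect_identical(out$hit[samp], c(TRUE, TRUE, FALSE))
  ## only the DEAB-like compound is flagged fast-acting
  expect_identical(out$fast_acting[samp], c(FALSE, TRUE, NA))
  qc <- plateQC(res)
  expect_true(qc$rzPrime <= 1)
  expect_identical(qc$nHits, 2L)
})
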