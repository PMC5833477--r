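test_that("blank and constant fields segment to zero labels", {
  blank <- genNucleiField(fieldImageSpec(
    nNuclei = 0L, mixture = mixtureSpec(nCells = 0L, seed = 2L),
    width = 256L, height = 256L
  ))
  lab <- segmentNuclei(blank$image)
  expect_equal(max(lab), 0)
  expect_identical(measureCells(blank$image, lab)$cell_id, integer(0))

  flat <- fieldImage(matrix(7, 64, 64), matrix(0, 64, 64), 0.65)
  expect_warning(lab2 <- segmentNuclei(flat), "constant")
  expect_equal(max(lab2), 0)
})

test_that("well-separated nuclei are recovered with exact count", {
  sp <- fieldImageSpec(nNuclei = 50L,
                       mixture = mixtureSpec(nCells = 50L, seed = 9L))
  fld <- genNucleiField(sp)
  lab <- segmentNuclei(fld$image)
  expect_equal(max(lab), 50)   # recall and precision 1.0
})

test_that("touching nuclei are split by the watershed", {
  nuc <- matrix(0, 128L, 128L)
  r <- 9
  ## centres 1.75 r apart: overlap well under 30% of the radius
  nuc <- AldhScreen:::paintDisk(nuc, 56, 64, r, 1000)
  nuc <- AldhScreen:::paintDisk(nuc, 56 + 1.75 * r, 64, r, 1000)
  img <- fieldImage(nuc, matrix(0, 128L, 128L), 0.65)
  lab <- segmentNuclei(img)
  expect_equal(max(lab), 2)
})

test_that("painted intensities are recovered exactly on clean fields", {
  centres <- cbind(c(40, 100, 160, 220), c(50, 110, 170, 60))
  pf <- paintedField(centres, intensities = c(200, 400, 600, 800))
  lab <- segmentNuclei(pf$image)
  expect_equal(max(lab), 4)
  cells <- measureCells(pf$image, lab, well = "A01")
  idx <- matchToTruth(cells, pf$centres[, 1], pf$centres[, 2])
  expect_equal(cells$intensity, pf$intensities[idx], tolerance = 1e-9)
  ## uniform reporter value over the cell regions, zero background
  expect_true(all(cells$well == "A01"))
})

test_that("synthetic field ground truth is matched by the measurement path", {
  sp <- fieldImageSpec(nNuclei = 40L,
                       mixture = mixtureSpec(nCells = 40L, seed = 21L),
                       psfSigma = 0, noiseSd = 0)
  fld <- genNucleiField(sp)
  lab <- segmentNuclei(fld$image)
  cells <- measureCells(fld$image, lab)
  expect_equal(nrow(cells), 40L)
  idx <- matchToTruth(cells, fld$truth$x, fld$truth$y)
  expect_equal(cells$intensity, fld$truth$intensity[idx], tolerance = 1e-9)
})

test_that("measurement is permutation-invariant and conserves labeled area", {
  sp <- fieldImageSpec(nNuclei = 20L,
                       mixture = mixtureSpec(nCells = 20L, seed = 13L))
  fld <- genNucleiField(sp)
  lab <- segmentNuclei(fld$image)
  cells <- measureCells(fld$image, lab)
  ## total nuclear area conserved between segmentation and measurement
  expect_equal(sum(cells$nuc_area_px), sum(lab > 0))
  ## permute the label ids: same set of records
  perm <- sample(max(lab))
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  lab2[lab > 0] <- perm[lab[lab > 0]]
  cells2 <- measureCells(fld$image, lab2)
  o1 <- order(cells$x, cells$y)
  o2 <- order(cells2$x, cells2$y)
  expect_equal(cells$intensity[o1], cells2$intensity[o2])
  expect_equal(cells$nuc_area_px[o1], cells2$nuc_area_px[o2])
})

test_that("background estimation uses the median of non-cell pixels", {
  set.seed(31)
  rep_ch <- matrix(rnorm(200 * 200, 50, 5), 200, 200)
  img <- fieldImage(matrix(0, 200, 200), rep_ch, 0.65)
  bg <- estimateBackground(img, matrix(0L, 200, 200))
  expect_lt(abs(bg - 50), 0.5)

  zeros <- fieldImage(matrix(0, 64, 64), matrix(0, 64, 64), 0.65)
  expect_equal(estimateBackground(zeros, matrix(0L, 64, 64)), 0)

  ## painted background value is recovered exactly when cells exist
  pf <- paintedField(cbind(64, 64), dim = c(128L, 128L))
  pf$image@reporter[pf$image@reporter == 0] <- 100
  lab <- segmentNuclei(pf$image)
  expect_equal(estimateBackground(pf$image, lab), 100)
})

test_that("missing pixel size is a unit error", {
  img <- fieldImage(matrix(0, 32, 32), matrix(0, 32, 32), 1)
  img@pixelSize <- NA_real_
  expect_error(measureCells(img, matrix(0L, 32, 32)), "pixel size")
  expect_error(measureCells(fieldImage(matrix(0, 32, 32),
                                       matrix(0, 32, 32), 1),
                            matrix(0L, 16, 16)), "aligned")
})
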