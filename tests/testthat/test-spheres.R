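## Frozen cross-check values for the 4-direction Crofton perimeter,
## computed independently with scikit-image's perimeter_crofton on
## byte-identical rasters (dist <= r rule).
test_that("Crofton perimeter matches the independent reference values", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  expect_equal(croftonPerimeter(m), 2.681517061334488, tolerance = 1e-12)
  expect_equal(croftonPerimeter(m), pi / 4 * (2 + sqrt(2)), tolerance = 1e-12)

  sq <- matrix(0, 200, 200); sq[51:150, 51:150] <- 1
  expect_equal(croftonPerimeter(sq), 378.11305885286833, tolerance = 1e-9)

  x <- matrix(0:299, 300, 300); y <- t(x)
  circ <- ((x - 150)^2 + (y - 150)^2) <= 77^2
  expect_equal(croftonPerimeter(circ), 484.4998300483003, tolerance = 1e-9)
  ## rasterized ideal circle: shape factor within discretization of 1
  expect_equal(4 * pi * sum(circ) / croftonPerimeter(circ)^2, 1,
               tolerance = 0.05)

  ## a filled square has true circularity pi/4; discretization epsilon 0.1
  expect_lt(abs(4 * pi * sum(sq) / croftonPerimeter(sq)^2 - pi / 4), 0.1)
})

test_that("sphere field ground truth records diameters and shape factors", {
  sp <- data.frame(diameter_um = c(40, 100, 300), elongation = 1,
                   x_um = c(120, 330, 620), y_um = c(120, 330, 620))
  fld <- genSphereField(sphereImageSpec(sp, width = 700L, height = 700L,
                                        pixelSize = 1.3, seed = 4L))
  expect_equal(fld$truth$diameter_um, c(40, 100, 300))
  expect_equal(fld$truth$shape_factor, rep(1, 3), tolerance = 1e-6)

  ## strongly elongated ellipse at fixed area: shape factor < 0.5
  el <- data.frame(diameter_um = 100, elongation = 10, x_um = 400, y_um = 100)
  fe <- genSphereField(sphereImageSpec(el, width = 700L, height = 200L,
                                       pixelSize = 1.3, seed = 4L))
  expect_lt(fe$truth$shape_factor, 0.5)

  ## overlap is rejected by construction
  bad <- data.frame(diameter_um = c(100, 100), elongation = 1,
                    x_um = c(200, 260), y_um = c(200, 200))
  expect_error(sphereImageSpec(bad), "non-overlapping")
})

test_that("size and shape filters keep exactly the qualifying spheres", {
  sp <- rbind(
    data.frame(diameter_um = c(40, 100, 300), elongation = 1,
               x_um = c(120, 330, 620), y_um = c(150, 350, 620)),
    data.frame(diameter_um = 100, elongation = 10, x_um = 560, y_um = 120)
  )
  fld <- genSphereField(sphereImageSpec(sp, width = 700L, height = 700L,
                                        pixelSize = 1.3, debrisCount = 5L,
                                        seed = 8L))
  det <- detectSpheres(fld$image, fld$pixelSize)
  pass <- det[det$passes_filters, ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$equivalent_diameter_um, 100, tolerance = 0.02)
  expect_gt(pass$shape_factor, 0.9)
  ## debris stays below the size filter; the ellipse fails on shape
  expect_true(all(det$equivalent_diameter_um[!det$passes_filters] < 50 |
                  det$equivalent_diameter_um[!det$passes_filters] > 250 |
                  det$shape_factor[!det$passes_filters] < 0.5))

  expect_equal(nrow(detectSpheres(matrix(0, 64, 64), 1.3)), 0L)
})

test_that("border-touching objects are excluded", {
  sp <- data.frame(diameter_um = c(100, 100), elongation = 1,
                   x_um = c(30, 330), y_um = c(330, 330))  # first clipped
  fld <- genSphereField(sphereImageSpec(sp, width = 512L, height = 512L,
                                        pixelSize = 1.3, seed = 2L))
  det <- detectSpheres(fld$image, fld$pixelSize)
  expect_equal(nrow(det), 1L)
  expect_equal(det$equivalent_diameter_um, 100, tolerance = 0.02)
})

test_that("micrometre measurements are pixel-size invariant within 2%", {
  sp <- data.frame(diameter_um = 120, elongation = 2, x_um = 330, y_um = 330)
  coarse <- genSphereField(sphereImageSpec(sp, width = 512L, height = 512L,
                                           pixelSize = 1.3, seed = 3L))
  fine <- genSphereField(sphereImageSpec(sp, width = 1024L, height = 1024L,
                                         pixelSize = 0.65, seed = 3L))
  d1 <- detectSpheres(coarse$image, 1.3)
  d2 <- detectSpheres(fine$image, 0.65)
  expect_equal(d1$equivalent_diameter_um, d2$equivalent_diameter_um,
               tolerance = 0.02)
  expect_equal(d1$perimeter_um, d2$perimeter_um, tolerance = 0.02)
  expect_equal(d1$shape_factor, d2$shape_factor, tolerance = 0.02)
})

test_that("TFC is the passing count over the seeded count", {
  expect_equal(computeTFC(20, nSeeded = 200)$tfc, 0.10)
  expect_equal(computeTFC(0, nSeeded = 100)$tfc, 0)
  rel <- computeTFC(10, nSeeded = 200, referenceTfc = 0.10)
  expect_equal(rel$tfc_relative, 50)
  ## linear in the passing count at fixed seeding
  counts <- c(5, 10, 20, 40)
  tfcs <- vapply(counts, function(k) computeTFC(k, 200)$tfc, numeric(1))
  expect_equal(tfcs, counts / 200)
  expect_error(computeTFC(5, nSeeded = 0), "nSeeded")
  expect_warning(out <- computeTFC(5, 100, referenceTfc = 0), "undefined")
  expect_true(is.na(out$tfc_relative))

  ## data.frame input counts only filter-passing spheres
  df <- data.frame(passes_filters = c(TRUE, FALSE, TRUE))
  expect_equal(computeTFC(df, nSeeded = 100)$n_spheres_pass, 2L)
})
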