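## Synthetic-data generators. Every generator is seed-deterministic and
## returns its ground truth alongside the data so downstream stages can be
## validated without re-deriving truth from the generated artifacts.

#' Generate a single-cell intensity table from a two-population mixture
#'
#' Draws `nCells` cells; each cell is ALDH-high with probability
#' `highFraction`. Low cells are Normal(`bgMean`, `bgSd`), high cells
#' Normal(`bgMean + highShift * bgSd`, `highSd`); both truncated at 0 by
#' resampling. The per-cell labels are the ground truth.
#'
#' @param spec a [MixtureSpec-class].
#' @return A list with `cells` (data.frame `cell_id`, `intensity`,
#'   `label`) and `truth` (list with the realized `nHigh`, `nLow`, the
#'   realized `highFraction` and the nominal `trueHighFraction`).
#' @examples
#' tab <- genIntensityTable(mixtureSpec(nCells = 500, seed = 7))
#' table(tab$cells$label)
#' @export
genIntensityTable <- function(spec) {
  validObject(spec)
  n <- spec@nCells
  set.seed(spec@seed)
  if (n == 0L) {
    cells <- data.frame(cell_id = integer(0), intensity = numeric(0),
                        label = character(0), stringsAsFactors = FALSE)
    return(list(cells = cells,
                truth = list(nHigh = 0L, nLow = 0L, highFraction = NaN,
                             trueHighFraction = spec@highFraction)))
  }
  isHigh <- stats::runif(n) < spec@highFraction
  intensity <- numeric(n)
  if (any(!isHigh))
    intensity[!isHigh] <- rnormTrunc0(sum(!isHigh), spec@bgMean, spec@bgSd)
  if (any(isHigh))
    intensity[isHigh] <- rnormTrunc0(
      sum(isHigh), spec@bgMean + spec@highShift * spec@bgSd, spec@highSd
    )
  cells <- data.frame(
    cell_id = seq_len(n), intensity = intensity,
    label = ifelse(isHigh, "high", "low"), stringsAsFactors = FALSE
  )
  list(
    cells = cells,
    truth = list(
      nHigh = sum(isHigh), nLow = sum(!isHigh),
      highFraction = mean(isHigh), trueHighFraction = spec@highFraction
    )
  )
}

## Paint a filled disk (value `value`) into matrix `m` (x-by-y), centre in
## pixels, radius in pixels; returns the modified matrix.
paintDisk <- function(m, cx, cy, r, value) {
  W <- nrow(m); H <- ncol(m)
  xr <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  d2 <- outer((xr - cx)^2, (yr - cy)^2, "+")
  sub <- m[xr, yr, drop = FALSE]
  sub[d2 <= r^2] <- value
  m[xr, yr] <- sub
  m
}

## Axis-aligned filled ellipse with semi-axes a (x) and b (y), in pixels.
paintEllipse <- function(m, cx, cy, a, b, value) {
  W <- nrow(m); H <- ncol(m)
  xr <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
  yr <- max(1L, floor(cy - b)):min(H, ceiling(cy + b))
  d2 <- outer(((xr - cx) / a)^2, ((yr - cy) / b)^2, "+")
  sub <- m[xr, yr, drop = FALSE]
  sub[d2 <= 1] <- value
  m[xr, yr] <- sub
  m
}

#' Generate a synthetic two-channel nuclei field
#'
#' Places `nNuclei` non-overlapping nuclei by rejection sampling (at most
#' 10^4 attempts per nucleus; failure is an error, never silent
#' under-placement), paints disks into the nuclear channel and each cell's
#' mixture intensity over its footprint (nucleus dilated by the
#' measurement ring plus a three-pixel guard) into the reporter channel,
#' then applies Gaussian blur and non-negative additive noise.
#'
#' Centres are kept far enough from the border that the whole painted
#' footprint is inside the image.
#'
#' @param spec a [FieldImageSpec-class].
#' @param ringRadius measurement-ring width in um painted around each
#'   nucleus in the reporter channel (match [measureCells()]'s ring).
#'   The painted footprint carries a 3-pixel guard beyond the ring so
#'   that small segmentation-mask dilations stay inside the footprint.
#' @param nuclearLevel painted nuclear-stain intensity, a.u.
#' @return A list with `image` (a [FieldImage-class]) and `truth`
#'   (data.frame `cell_id`, `x`, `y`, `radius_px`, `nuc_area_px`,
#'   `intensity`, `label`).
#' @export
genNucleiField <- function(spec, ringRadius = 3, nuclearLevel = 1000) {
  validObject(spec)
  px <- spec@pixelSize
  W <- spec@width; H <- spec@height
  tab <- genIntensityTable(spec@mixture)  # seeds the stream
  cells <- tab$cells
  n <- spec@nNuclei
  nuc <- matrix(0, W, H)
  rep_ch <- matrix(0, W, H)
  truth <- data.frame(
    cell_id = integer(0), x = numeric(0), y = numeric(0),
    radius_px = numeric(0), nuc_area_px = integer(0),
    intensity = numeric(0), label = character(0), stringsAsFactors = FALSE
  )
  if (n > 0L) {
    rPx <- pmax(2, stats::rnorm(n, spec@nucleusRadiusMean / px,
                                spec@nucleusRadiusSd / px))
    ringPx <- ringRadius / px
    footPx <- rPx + ringPx + 3          # painted footprint radius, px
    minSepPx <- spec@minSeparation / px
    xs <- ys <- numeric(0)
    for (i in seq_len(n)) {
      m <- footPx[i] + 1
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        x <- stats::runif(1, m, W - m)
        y <- stats::runif(1, m, H - m)
        if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= minSepPx^2) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place nucleus ", i, " of ", n,
             " at minSeparation = ", spec@minSeparation,
             " um after 10000 attempts; reduce nNuclei or minSeparation")
    }
    areas <- integer(n)
    for (i in seq_len(n)) {
      before <- sum(nuc > 0)
      nuc <- paintDisk(nuc, xs[i], ys[i], rPx[i], nuclearLevel)
      areas[i] <- sum(nuc > 0) - before
      rep_ch <- paintDisk(rep_ch, xs[i], ys[i], footPx[i],
                          cells$intensity[i])
    }
    truth <- data.frame(
      cell_id = cells$cell_id, x = xs, y = ys, radius_px = rPx,
      nuc_area_px = areas, intensity = cells$intensity,
      label = cells$label, stringsAsFactors = FALSE
    )
  }
  if (spec@psfSigma > 0) {
    nuc <- as.matrix(EBImage::gblur(EBImage::Image(nuc),
                                    sigma = spec@psfSigma))
    rep_ch <- as.matrix(EBImage::gblur(EBImage::Image(rep_ch),
                                       sigma = spec@psfSigma))
  }
  if (spec@noiseSd > 0) {
    nuc <- pmax(nuc + matrix(stats::rnorm(W * H, 0, spec@noiseSd), W, H), 0)
    rep_ch <- pmax(rep_ch + matrix(stats::rnorm(W * H, 0, spec@noiseSd), W, H), 0)
  }
  list(image = fieldImage(nuc, rep_ch, px), truth = truth)
}

## Numeric perimeter of an axis-aligned ellipse with semi-axes a, b.
ellipsePerimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

#' Generate a synthetic tumorsphere image
#'
#' Renders each sphere as a filled axis-aligned ellipse with the requested
#' equivalent diameter `d` and elongation `e` (semi-axes `d/2 * sqrt(e)`
#' and `d/2 / sqrt(e)`, preserving area), plus `debrisCount` debris disks
#' with diameters drawn uniformly in 5-35 um (all below the 50 um filter).
#' The true shape factor recorded for each sphere is `4 * pi * A / P^2`
#' with the ellipse perimeter computed by numeric quadrature.
#'
#' @param spec a [SphereImageSpec-class].
#' @param level painted object intensity, a.u.
#' @return list with `image` (numeric matrix, a.u.), `pixelSize` (um/px)
#'   and `truth` (data.frame `sphere_id`, `x_um`, `y_um`, `diameter_um`,
#'   `elongation`, `shape_factor`).
#' @export
genSphereField <- function(spec, level = 1000) {
  validObject(spec)
  set.seed(spec@seed)
  px <- spec@pixelSize
  W <- spec@width; H <- spec@height
  img <- matrix(0, W, H)
  sp <- spec@spheres
  truth <- data.frame(
    sphere_id = seq_len(nrow(sp)), x_um = sp$x_um, y_um = sp$y_um,
    diameter_um = sp$diameter_um, elongation = sp$elongation,
    shape_factor = NA_real_
  )
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      a <- sp$diameter_um[i] / 2 * sqrt(sp$elongation[i])
      b <- sp$diameter_um[i] / 2 / sqrt(sp$elongation[i])
      img <- paintEllipse(img, sp$x_um[i] / px, sp$y_um[i] / px,
                          a / px, b / px, level)
      A <- pi * a * b
      truth$shape_factor[i] <- 4 * pi * A / ellipsePerimeter(a, b)^2
    }
  }
  if (spec@debrisCount > 0L) {
    aMax <- if (nrow(sp)) sp$diameter_um / 2 * sqrt(sp$elongation) else numeric(0)
    for (i in seq_len(spec@debrisCount)) {
      d <- stats::runif(1, 5, 35)
      for (attempt in seq_len(10000L)) {
        x <- stats::runif(1, d, W * px - d)
        y <- stats::runif(1, d, H * px - d)
        clear <- !nrow(sp) ||
          all(sqrt((sp$x_um - x)^2 + (sp$y_um - y)^2) > aMax + d / 2 + 2 * px)
        if (clear) break
      }
      img <- paintDisk(img, x / px, y / px, d / 2 / px, level)
    }
  }
  if (spec@noiseSd > 0)
    img <- pmax(img + matrix(stats::rnorm(W * H, 0, spec@noiseSd), W, H), 0)
  list(image = img, pixelSize = px, truth = truth)
}

#' Generate a full synthetic screening plate
#'
#' Generates one intensity table per non-empty layout well from the base
#' mixture (or its per-well override), with the well's seed taken from the
#' plate seed plus the row-major well index so each well is independently
#' reproducible. Wells with role `"deab"` are forced to
#' `highFraction = 0` (enzyme inhibition abolishes reporter retention);
#' toxicity multipliers shrink the generated cell count to
#' `round(multiplier * nCells)`.
#'
#' @param spec a [PlateSpec-class].
#' @return list with `cells` (data.frame `well`, `cell_id`, `intensity`,
#'   `label` for all wells), `platemap` (the layout) and `truth`
#'   (data.frame `well`, `n_cells`, `true_high_fraction`,
#'   `realized_high_fraction`, `toxicity`).
#' @export
genPlateDataset <- function(spec) {
  validObject(spec)
  lay <- spec@layout[spec@layout$role != "empty", , drop = FALSE]
  cellsList <- vector("list", nrow(lay))
  truth <- data.frame(
    well = lay$well, n_cells = NA_integer_, true_high_fraction = NA_real_,
    realized_high_fraction = NA_real_, toxicity = 1, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(lay))) {
    w <- lay$well[i]
    mx <- if (w %in% names(spec@overrides)) spec@overrides[[w]] else spec@baseMixture
    if (lay$role[i] == "deab") mx@highFraction <- 0
    tox <- if (w %in% names(spec@toxicity)) spec@toxicity[[w]] else 1
    mx@nCells <- as.integer(round(tox * mx@nCells))
    mx@seed <- wellSeed(spec@seed, wellIndex384(w))
    tab <- genIntensityTable(mx)
    if (nrow(tab$cells)) {
      cellsList[[i]] <- cbind(well = w, tab$cells, stringsAsFactors = FALSE)
    }
    truth$n_cells[i] <- nrow(tab$cells)
    truth$true_high_fraction[i] <- mx@highFraction
    truth$realized_high_fraction[i] <- tab$truth$highFraction
    truth$toxicity[i] <- tox
  }
  cells <- do.call(rbind, cellsList[!vapply(cellsList, is.null, logical(1))])
  rownames(cells) <- NULL
  list(cells = cells, platemap = spec@layout, truth = truth)
}

#' Evaluate the four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`; at `x = ic50`
#' the response is the midpoint `(top + bottom) / 2`.
#'
#' @param x dose(s), uM.
#' @param top,bottom asymptotes.
#' @param ic50 inflection dose, uM.
#' @param hill Hill slope.
#' @return Numeric response(s).
#' @export
fourParameterLogistic <- function(x, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Generate a noisy dose-response series with known 4PL parameters
#'
#' @param doses positive doses, uM.
#' @param top,bottom,ic50,hill true curve parameters.
#' @param noiseSd SD of additive Gaussian noise on the response.
#' @param seed integer seed.
#' @return list with `data` (data.frame `dose`, `effect`) and `truth`
#'   (list of the four true parameters).
#' @export
genDoseResponse <- function(doses, top = 100, bottom = 0, ic50 = 1,
                            hill = 1, noiseSd = 0, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be > 0")
  if (bottom > top) stop("bottom must be <= top")
  set.seed(as.integer(seed))
  y <- fourParameterLogistic(doses, top, bottom, ic50, hill)
  if (noiseSd > 0) y <- y + stats::rnorm(length(doses), 0, noiseSd)
  list(
    data = data.frame(dose = doses, effect = y),
    truth = list(top = top, bottom = bottom, ic50 = ic50, hill = hill)
  )
}
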