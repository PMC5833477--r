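## Tumorsphere detection and tumorsphere-formation-capacity (TFC)
## scoring. A sphere passes when its equivalent circular diameter lies in
## [dMin, dMax] um and its shape factor (circularity, 4*pi*A/P^2) is at
## least sfMin; boundaries inclusive. Perimeters use the 4-direction
## Crofton approximation, which is much closer to the continuous perimeter
## than boundary-pixel counting: an ideal rasterized circle scores a shape
## factor within ~0.01 of 1, a square within ~0.1 of pi/4 (the documented
## discretization epsilon is 0.1).

#' Crofton perimeter of a binary mask
#'
#' Four-direction Crofton estimate of the continuous boundary length of
#' the foreground of a binary image, computed from the histogram of 2x2
#' pixel configurations with the standard integral-geometry weight table.
#'
#' @param mask logical or 0/1 matrix; non-zero is foreground.
#' @return Total perimeter in pixels.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' croftonPerimeter(m)  # pi/4 * (2 + sqrt(2)) ~ 2.6815
#' @export
croftonPerimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 3L, ncol(mask) + 3L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0
  nr <- nrow(m); nc <- ncol(m)
  ## 2x2 configuration code at each offset position
  a <- m[-1, -1]; b <- m[-1, -nc]; c <- m[-nr, -1]; d <- m[-nr, -nc]
  code <- a + 4 * b + 2 * c + 8 * d
  h <- tabulate(code + 1L, nbins = 16L)
  isq <- 1 / sqrt(2)
  coefs <- c(
    0, pi / 4 * (1 + isq), pi / 4 * isq, pi / 2 * isq,
    0, pi / 4 * (1 + isq), 0, pi / 4 * isq,
    pi / 4, pi / 2, pi / 4 * isq, pi / 4 * isq,
    pi / 4, pi / 2, 0, 0
  )
  sum(coefs * h)
}

#' Detect tumorspheres and apply the size/shape filters
#'
#' Objects are segmented from the nuclear-stain image (Gaussian smooth,
#' Otsu threshold, hole filling, connected-component labelling), measured
#' (area, Crofton perimeter, equivalent circular diameter
#' `2 * sqrt(area / pi)` in um, shape factor `4 * pi * area / perimeter^2`),
#' and flagged. `passes_filters` is TRUE when
#' `dMin <= equivalent diameter <= dMax` and `shape factor >= sfMin`
#' (both boundaries inclusive). Objects touching the image border are
#' excluded: their area and perimeter are truncated.
#'
#' @param image numeric matrix (a.u.), the sphere-plate nuclear channel.
#' @param pixelSize um per pixel (> 0).
#' @param dMin,dMax diameter filter bounds, um (defaults 50 and 250).
#' @param sfMin minimum shape factor (default 0.5).
#' @param smoothSigma pre-smoothing sigma, pixels.
#' @return data.frame with one row per non-border object: `sphere_id`,
#'   `x`, `y` (centroid, px), `area_um2`, `perimeter_um`,
#'   `equivalent_diameter_um`, `shape_factor`, `passes_filters`.
#'   A blank image yields an empty data.frame.
#' @export
detectSpheres <- function(image, pixelSize, dMin = 50, dMax = 250,
                          sfMin = 0.5, smoothSigma = 2) {
  if (!is.finite(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be a positive number (um/pixel)")
  if (dMin >= dMax) stop("dMin must be < dMax")
  empty <- data.frame(
    sphere_id = integer(0), x = numeric(0), y = numeric(0),
    area_um2 = numeric(0), perimeter_um = numeric(0),
    equivalent_diameter_um = numeric(0), shape_factor = numeric(0),
    passes_filters = logical(0)
  )
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  norm <- (image - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smoothSigma)
  mask <- EBImage::fillHull(sm > EBImage::otsu(sm))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nLab <- max(lab)
  if (nLab == 0) return(empty)
  W <- nrow(lab); H <- ncol(lab)
  border <- unique(c(lab[1, ], lab[W, ], lab[, 1], lab[, H]))
  border <- border[border > 0]
  rows <- vector("list", nLab)
  keep <- 0L
  for (id in seq_len(nLab)) {
    if (id %in% border) next
    idx <- which(lab == id, arr.ind = TRUE)
    areaPx <- nrow(idx)
    ## measure on a cropped sub-mask for speed
    xr <- range(idx[, 1]); yr <- range(idx[, 2])
    sub <- lab[xr[1]:xr[2], yr[1]:yr[2], drop = FALSE] == id
    perPx <- croftonPerimeter(sub)
    areaUm2 <- areaPx * pixelSize^2
    perUm <- perPx * pixelSize
    eqd <- 2 * sqrt(areaUm2 / pi)
    sf <- 4 * pi * areaUm2 / perUm^2
    keep <- keep + 1L
    rows[[keep]] <- data.frame(
      sphere_id = keep, x = mean(idx[, 1]), y = mean(idx[, 2]),
      area_um2 = areaUm2, perimeter_um = perUm,
      equivalent_diameter_um = eqd, shape_factor = sf,
      passes_filters = (eqd >= dMin && eqd <= dMax && sf >= sfMin)
    )
  }
  if (keep == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(keep)])
  rownames(out) <- NULL
  out
}

#' Tumorsphere-formation capacity
#'
#' TFC is the number of filter-passing spheres divided by the number of
#' seeded single cells (from a Day-0 nuclear count or the declared
#' 100/200 cells per well). When a reference TFC is supplied (the DMSO or
#' lipid-only control), the relative TFC in percent of that reference is
#' reported too.
#'
#' @param spheres data.frame from [detectSpheres()] (needs
#'   `passes_filters`), or a single count of passing spheres.
#' @param nSeeded number of seeded cells (>= 1).
#' @param referenceTfc optional reference TFC fraction; 0 makes the
#'   relative value undefined (NA with a warning).
#' @return One-row data.frame: `n_spheres_pass`, `n_seeded`, `tfc`,
#'   `tfc_relative` (percent; NA when no reference).
#' @examples
#' computeTFC(20, nSeeded = 200)            # tfc 0.10
#' computeTFC(10, 200, referenceTfc = 0.1)  # 50% of reference
#' @export
computeTFC <- function(spheres, nSeeded, referenceTfc = NULL) {
  nPass <- if (is.data.frame(spheres)) {
    sum(spheres$passes_filters)
  } else {
    as.integer(spheres)
  }
  if (length(nSeeded) != 1L || !is.finite(nSeeded) || nSeeded < 1)
    stop("nSeeded must be a single count >= 1")
  tfc <- nPass / nSeeded
  rel <- NA_real_
  if (!is.null(referenceTfc)) {
    if (referenceTfc == 0) {
      warning("reference TFC is 0: relative TFC undefined")
    } else {
      rel <- 100 * tfc / referenceTfc
    }
  }
  data.frame(
    n_spheres_pass = nPass, n_seeded = nSeeded, tfc = tfc,
    tfc_relative = rel
  )
}
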