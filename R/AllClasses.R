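#' @import methods
#' @importFrom stats rnorm runif rbinom median mad sd quantile integrate setNames
#' @importFrom utils read.csv write.csv
NULL

## Role vocabulary used in platemaps. "deab" is the ALDH-inhibitor staining
## control that anchors the intensity gate; "lipid"/"sirna" are the
## transfection-control analogues used in knockdown experiments.
WELL_ROLES <- c("sample", "dmso", "deab", "lipid", "sirna", "empty")

#' MixtureSpec: two-population single-cell intensity mixture
#'
#' Describes a heterogeneous cell population as a mixture of a background
#' (ALDH-low) intensity component and a brighter ALDH-high component.
#' Intensities are in arbitrary fluorescence units (a.u.) and are
#' non-negative by construction (negative draws are redrawn, not clipped,
#' so moments stay close to nominal).
#'
#' @slot nCells number of cells to generate.
#' @slot bgMean mean background (ALDH-low) intensity, a.u.
#' @slot bgSd standard deviation of the background intensity, a.u. (> 0).
#' @slot highFraction fraction of ALDH-high cells, in \[0, 1\].
#' @slot highShift separation of the high population mode from the
#'   background mode, expressed in multiples of \code{bgSd} (>= 0).
#' @slot highSd standard deviation of the high population, a.u.
#' @slot seed integer seed; the same seed reproduces the table exactly.
#'
#' @export
setClass("MixtureSpec",
  representation(
    nCells = "integer", bgMean = "numeric", bgSd = "numeric",
    highFraction = "numeric", highShift = "numeric", highSd = "numeric",
    seed = "integer"
  )
)

setValidity("MixtureSpec", function(object) {
  msg <- character(0)
  if (length(object@nCells) != 1L || is.na(object@nCells) || object@nCells < 0L)
    msg <- c(msg, "nCells must be a single non-negative integer")
  if (length(object@bgSd) != 1L || !is.finite(object@bgSd) || object@bgSd <= 0)
    msg <- c(msg, "bgSd must be a single positive number")
  if (length(object@highFraction) != 1L || is.na(object@highFraction) ||
      object@highFraction < 0 || object@highFraction > 1)
    msg <- c(msg, "highFraction must lie in [0, 1]")
  if (length(object@highShift) != 1L || !is.finite(object@highShift) ||
      object@highShift < 0)
    msg <- c(msg, "highShift must be >= 0")
  if (length(object@highSd) != 1L || !is.finite(object@highSd) ||
      object@highSd <= 0)
    msg <- c(msg, "highSd must be a single positive number")
  if (length(object@bgMean) != 1L || !is.finite(object@bgMean) ||
      object@bgMean < 0)
    msg <- c(msg, "bgMean must be a single non-negative number")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureSpec
#'
#' Defaults model an Aldefluor-stained population at roughly 10% background
#' coefficient of variation with a clearly separated ALDH-high mode eight
#' background SDs above the background mean, and a tighter absolute spread
#' for the high population (half the background SD) so that a gate at
#' mean + 6 SD sits several high-population SDs below the high mode.
#'
#' @param nCells number of cells.
#' @param bgMean,bgSd background intensity mean and SD (a.u.).
#' @param highFraction fraction of ALDH-high cells.
#' @param highShift high-mode offset in multiples of `bgSd`.
#' @param highSd SD of the high population (a.u.).
#' @param seed integer seed.
#' @return A [MixtureSpec-class] object.
#' @examples
#' mixtureSpec(nCells = 1000, highFraction = 0.05, seed = 1)
#' @export
mixtureSpec <- function(nCells = 1000L, bgMean = 500, bgSd = 50,
                        highFraction = 0.05, highShift = 8,
                        highSd = bgSd / 2, seed = 1L) {
  new("MixtureSpec",
    nCells = as.integer(nCells), bgMean = as.numeric(bgMean),
    bgSd = as.numeric(bgSd), highFraction = as.numeric(highFraction),
    highShift = as.numeric(highShift), highSd = as.numeric(highSd),
    seed = as.integer(seed)
  )
}

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf(
    "MixtureSpec: %d cells, bg %.4g +/- %.4g a.u., %.2f%% high (shift %.3g SD, sd %.4g), seed %d\n",
    object@nCells, object@bgMean, object@bgSd, 100 * object@highFraction,
    object@highShift, object@highSd, object@seed
  ))
})

#' FieldImageSpec: synthetic two-channel microscopy field
#'
#' Layout of one synthetic imaging field: scattered non-overlapping nuclei
#' (channel 1, nuclear stain) and the Aldefluor reporter painted over each
#' cell footprint (channel 2) according to its mixture label. Randomness
#' (labels, intensities, radii, placement, noise) is driven entirely by the
#' seed of the embedded [MixtureSpec-class].
#'
#' @slot width,height image size in pixels.
#' @slot pixelSize pixel size, micrometres per pixel.
#' @slot nNuclei number of nuclei to place.
#' @slot nucleusRadiusMean,nucleusRadiusSd nuclear radius distribution, um.
#' @slot minSeparation minimum centre-to-centre distance between nuclei, um.
#' @slot psfSigma Gaussian blur sigma applied to both channels, pixels.
#' @slot noiseSd additive Gaussian noise SD, a.u.
#' @slot mixture a [MixtureSpec-class]; its `nCells` equals `nNuclei`.
#' @export
setClass("FieldImageSpec",
  representation(
    width = "integer", height = "integer", pixelSize = "numeric",
    nNuclei = "integer", nucleusRadiusMean = "numeric",
    nucleusRadiusSd = "numeric", minSeparation = "numeric",
    psfSigma = "numeric", noiseSd = "numeric", mixture = "MixtureSpec"
  )
)

setValidity("FieldImageSpec", function(object) {
  msg <- character(0)
  if (object@width < 16L || object@height < 16L)
    msg <- c(msg, "width/height must be at least 16 pixels")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive number (um/pixel)")
  if (object@nNuclei < 0L)
    msg <- c(msg, "nNuclei must be non-negative")
  if (object@nucleusRadiusMean <= 0)
    msg <- c(msg, "nucleusRadiusMean must be positive (um)")
  if (object@minSeparation < 0)
    msg <- c(msg, "minSeparation must be >= 0")
  if (object@mixture@nCells != object@nNuclei)
    msg <- c(msg, "mixture nCells must equal nNuclei")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldImageSpec
#'
#' Defaults emulate a 10x confocal field at 0.65 um/pixel with 6 um nuclei.
#' The minimum separation (24 um) keeps the painted cell footprints
#' (nucleus, measurement ring and guard margin) disjoint, so every
#' painted reporter value can be recovered exactly on noise-free fields.
#'
#' @param nNuclei number of nuclei.
#' @param mixture a [MixtureSpec-class]; its `nCells` is forced to `nNuclei`.
#' @param width,height image size, pixels.
#' @param pixelSize um per pixel.
#' @param nucleusRadiusMean,nucleusRadiusSd nuclear radius, um.
#' @param minSeparation minimum nucleus centre separation, um.
#' @param psfSigma blur sigma, pixels.
#' @param noiseSd additive noise SD, a.u.
#' @return A [FieldImageSpec-class].
#' @export
fieldImageSpec <- function(nNuclei = 120L,
                           mixture = mixtureSpec(nCells = nNuclei),
                           width = 640L, height = 640L, pixelSize = 0.65,
                           nucleusRadiusMean = 6, nucleusRadiusSd = 0.5,
                           minSeparation = 24, psfSigma = 1, noiseSd = 5) {
  mixture@nCells <- as.integer(nNuclei)
  validObject(mixture)
  new("FieldImageSpec",
    width = as.integer(width), height = as.integer(height),
    pixelSize = as.numeric(pixelSize), nNuclei = as.integer(nNuclei),
    nucleusRadiusMean = as.numeric(nucleusRadiusMean),
    nucleusRadiusSd = as.numeric(nucleusRadiusSd),
    minSeparation = as.numeric(minSeparation),
    psfSigma = as.numeric(psfSigma), noiseSd = as.numeric(noiseSd),
    mixture = mixture
  )
}

#' SphereImageSpec: synthetic tumorsphere field
#'
#' Describes a bright-nuclear-stain tumorsphere image: filled ellipses with
#' stated equivalent diameter and elongation (major/minor axis ratio),
#' plus optional sub-50-um debris. Spheres are non-overlapping by
#' construction (validity enforces it); ellipses are axis-aligned.
#'
#' @slot width,height image size in pixels.
#' @slot pixelSize um per pixel.
#' @slot spheres data.frame with columns `diameter_um`, `elongation`,
#'   `x_um`, `y_um` (centres in micrometres).
#' @slot debrisCount number of small (< 50 um) debris disks.
#' @slot noiseSd additive Gaussian noise SD, a.u.
#' @slot seed integer seed.
#' @export
setClass("SphereImageSpec",
  representation(
    width = "integer", height = "integer", pixelSize = "numeric",
    spheres = "data.frame", debrisCount = "integer", noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SphereImageSpec", function(object) {
  msg <- character(0)
  sp <- object@spheres
  need <- c("diameter_um", "elongation", "x_um", "y_um")
  if (!all(need %in% names(sp)))
    return(paste("spheres must have columns", paste(need, collapse = ", ")))
  if (nrow(sp)) {
    if (any(sp$diameter_um <= 0)) msg <- c(msg, "diameter_um must be > 0")
    if (any(sp$elongation < 1)) msg <- c(msg, "elongation must be >= 1")
    ## non-overlap: centre distance must exceed the sum of major semi-axes
    if (nrow(sp) > 1) {
      a <- sp$diameter_um / 2 * sqrt(sp$elongation)
      d <- as.matrix(stats::dist(sp[, c("x_um", "y_um")]))
      lim <- outer(a, a, "+")
      diag(d) <- Inf
      if (any(d <= lim)) msg <- c(msg, "spheres must be non-overlapping")
    }
  }
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (object@debrisCount < 0L) msg <- c(msg, "debrisCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SphereImageSpec
#'
#' @param spheres data.frame(`diameter_um`, `elongation`, `x_um`, `y_um`).
#' @param width,height image size, pixels.
#' @param pixelSize um per pixel; 1.3 matches a 10x widefield setup.
#' @param debrisCount number of sub-50-um debris disks to scatter.
#' @param noiseSd additive noise SD, a.u.
#' @param seed integer seed.
#' @return A [SphereImageSpec-class].
#' @export
sphereImageSpec <- function(spheres, width = 640L, height = 640L,
                            pixelSize = 1.3, debrisCount = 0L,
                            noiseSd = 0, seed = 1L) {
  new("SphereImageSpec",
    width = as.integer(width), height = as.integer(height),
    pixelSize = as.numeric(pixelSize),
    spheres = as.data.frame(spheres), debrisCount = as.integer(debrisCount),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
  )
}

#' PlateSpec: synthetic 384-well screening plate
#'
#' A full-plate layout (wells A01..P24) mapping wells to roles, compounds
#' and doses, with a shared base intensity mixture, optional per-well
#' mixture overrides, and a toxicity map of cell-count multipliers.
#' Wells with role "deab" (the ALDH-inhibitor staining control) are always
#' generated with `highFraction = 0`: enzyme inhibition abolishes reporter
#' retention regardless of the base mixture.
#'
#' @slot layout data.frame with columns `well`, `role`, `compound`,
#'   `dose_uM`; wells unique, roles from the platemap vocabulary.
#' @slot baseMixture the default [MixtureSpec-class] for every well.
#' @slot overrides named list (by well) of [MixtureSpec-class] overrides.
#' @slot toxicity named numeric (by well) of cell-count multipliers in
#'   (0, 1\]; generated cell count is `round(multiplier * nCells)`.
#' @slot seed integer; per-well substreams use seed + well index (row-major
#'   A01=1 .. P24=384), so each well is independently reproducible.
#' @export
setClass("PlateSpec",
  representation(
    layout = "data.frame", baseMixture = "MixtureSpec",
    overrides = "list", toxicity = "numeric", seed = "integer"
  )
)

setValidity("PlateSpec", function(object) {
  msg <- character(0)
  lay <- object@layout
  need <- c("well", "role", "compound", "dose_uM")
  if (!all(need %in% names(lay)))
    return(paste("layout must have columns", paste(need, collapse = ", ")))
  bad <- lay$well[!isValidWell384(lay$well)]
  if (length(bad))
    msg <- c(msg, paste("invalid 384-well ids:", paste(unique(bad), collapse = ", ")))
  if (anyDuplicated(lay$well))
    msg <- c(msg, "duplicate wells in layout")
  badrole <- setdiff(unique(lay$role), WELL_ROLES)
  if (length(badrole))
    msg <- c(msg, paste("unknown roles:", paste(badrole, collapse = ", ")))
  if (length(object@overrides)) {
    if (is.null(names(object@overrides)) ||
        !all(names(object@overrides) %in% lay$well))
      msg <- c(msg, "overrides must be named by wells present in the layout")
    if (!all(vapply(object@overrides, is, logical(1), "MixtureSpec")))
      msg <- c(msg, "overrides must be MixtureSpec objects")
  }
  if (length(object@toxicity)) {
    if (is.null(names(object@toxicity)) ||
        !all(names(object@toxicity) %in% lay$well))
      msg <- c(msg, "toxicity must be named by wells present in the layout")
    if (any(!is.finite(object@toxicity)) || any(object@toxicity <= 0))
      msg <- c(msg, "toxicity multipliers must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlateSpec
#'
#' @param layout data.frame(`well`, `role`, `compound`, `dose_uM`).
#' @param baseMixture default [MixtureSpec-class] for all wells.
#' @param overrides named list of per-well [MixtureSpec-class] overrides.
#' @param toxicity named numeric of per-well cell-count multipliers.
#' @param seed integer plate seed.
#' @return A [PlateSpec-class].
#' @export
plateSpec <- function(layout, baseMixture = mixtureSpec(),
                      overrides = list(), toxicity = numeric(0), seed = 1L) {
  layout <- as.data.frame(layout)
  layout$well <- as.character(layout$well)
  layout$role <- as.character(layout$role)
  layout$compound <- as.character(layout$compound)
  layout$dose_uM <- as.numeric(layout$dose_uM)
  new("PlateSpec",
    layout = layout, baseMixture = baseMixture,
    overrides = overrides, toxicity = toxicity, seed = as.integer(seed)
  )
}

#' FieldImage: a two-channel microscopy field
#'
#' Container for one field: nuclear-stain channel, Aldefluor reporter
#' channel (both numeric matrices in a.u., dimensions x-by-y as in
#' EBImage), and the pixel size in micrometres.
#'
#' @slot nuclear nuclear channel matrix, a.u.
#' @slot reporter reporter channel matrix, a.u.
#' @slot pixelSize um per pixel.
#' @export
setClass("FieldImage",
  representation(nuclear = "matrix", reporter = "matrix",
                 pixelSize = "numeric")
)

setValidity("FieldImage", function(object) {
  msg <- character(0)
  if (!identical(dim(object@nuclear), dim(object@reporter)))
    msg <- c(msg, "nuclear and reporter channels must have identical dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldImage
#' @param nuclear,reporter numeric matrices (same dimensions), a.u.
#' @param pixelSize um per pixel.
#' @return A [FieldImage-class].
#' @export
fieldImage <- function(nuclear, reporter, pixelSize) {
  new("FieldImage", nuclear = nuclear, reporter = reporter,
      pixelSize = as.numeric(pixelSize))
}

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@nuclear)
  cat(sprintf(
    "FieldImage: %d x %d px (%.3g um/px), nuclear range [%.3g, %.3g], reporter range [%.3g, %.3g]\n",
    d[1], d[2], object@pixelSize,
    min(object@nuclear), max(object@nuclear),
    min(object@reporter), max(object@reporter)
  ))
})

#' GateThreshold: the DEAB-anchored intensity gate
#'
#' The assay's core cutoff: cells whose background-corrected reporter
#' intensity exceeds `mean + k * SD` of the pooled ALDH-inhibitor (DEAB)
#' control cells are classified ALDH-high. The sample SD (n - 1
#' denominator) is used.
#'
#' @slot meanDeab mean intensity of the pooled control cells, a.u.
#' @slot sdDeab sample SD of the pooled control cells, a.u.
#' @slot k the multiplier (default 6).
#' @slot threshold `meanDeab + k * sdDeab`, a.u.
#' @slot nControlCells number of pooled control cells.
#' @slot sourceWells wells the control cells were pooled from.
#' @export
setClass("GateThreshold",
  representation(
    meanDeab = "numeric", sdDeab = "numeric", k = "numeric",
    threshold = "numeric", nControlCells = "integer",
    sourceWells = "character"
  )
)

setValidity("GateThreshold", function(object) {
  msg <- character(0)
  if (object@k >= 0 && object@threshold < object@meanDeab - 1e-12)
    msg <- c(msg, "threshold must be >= meanDeab when k >= 0")
  if (object@sdDeab < 0) msg <- c(msg, "sdDeab must be >= 0")
  if (object@nControlCells < 1L) msg <- c(msg, "nControlCells must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GateThreshold", function(object) {
  cat(sprintf(
    "GateThreshold: %.6g a.u. (control mean %.6g + %g x SD %.6g; %d cells",
    object@threshold, object@meanDeab, object@k, object@sdDeab,
    object@nControlCells
  ))
  if (length(object@sourceWells))
    cat(sprintf(" from %d well(s)", length(object@sourceWells)))
  cat(")\n")
})

#' DoseResponseFit: four-parameter logistic fit
#'
#' Result of fitting `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`
#' to a dose-response series by bounded least squares with the IC50
#' optimised on the log10 scale.
#'
#' @slot top,bottom asymptotes, percent effect.
#' @slot ic50 inflection dose, uM (NA when not converged).
#' @slot hill Hill slope (dimensionless).
#' @slot rss residual sum of squares of the best fit.
#' @slot converged whether an identifiable fit was obtained.
#' @slot nPoints number of dose points used.
#' @export
setClass("DoseResponseFit",
  representation(
    top = "numeric", bottom = "numeric", ic50 = "numeric",
    hill = "numeric", rss = "numeric", converged = "logical",
    nPoints = "integer"
  )
)

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cat(sprintf(
      "DoseResponseFit: IC50 %.4g uM, hill %.3g, top %.4g%%, bottom %.4g%% (RSS %.4g, n = %d)\n",
      object@ic50, object@hill, object@top, object@bottom, object@rss,
      object@nPoints
    ))
  } else {
    cat(sprintf("DoseResponseFit: not converged / non-identifiable (n = %d)\n",
                object@nPoints))
  }
})

#' ScreenResult: per-well screen analytics plus plate QC
#'
#' @slot wells data.frame with one row per analysed well: role, compound,
#'   dose, cell count, ALDH-high fraction, normalized effect (percent of
#'   control scale), reduction vs the neutral control, masked and hit
#'   flags.
#' @slot rzPrime robust Z-prime of the plate's control wells.
#' @slot signalToBackground neutral/full-effect control signal ratio
#'   (+Inf sentinel when the full-effect aggregate is 0).
#' @slot gate the [GateThreshold-class] used, when gating was run upstream.
#' @slot config the normalization / masking / hit-calling configuration
#'   echoed for auditability.
#' @export
setClass("ScreenResult",
  representation(
    wells = "data.frame", rzPrime = "numeric",
    signalToBackground = "numeric", gate = "ANY", config = "list"
  )
)

setMethod("show", "ScreenResult", function(object) {
  w <- object@wells
  cat(sprintf(
    "ScreenResult: %d wells | masked %d | hits %d | RZ' %.4f | S/B %s\n",
    nrow(w), sum(w$masked, na.rm = TRUE), sum(w$hit, na.rm = TRUE),
    object@rzPrime,
    if (is.finite(object@signalToBackground))
      sprintf("%.3f", object@signalToBackground) else "Inf"
  ))
})
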