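## Plate-level screening analytics: toxicity masking, control-anchored
## normalization, hit calling, fast-acting false-positive flagging and
## control-based QC. Control aggregation defaults to the per-plate median
## (robust to single outlier control wells); mean is available by config.

#' Screen analysis configuration
#'
#' Bundles the control roles and thresholds used by the screen statistics
#' and echoes them into every result for auditability. The defaults are
#' the compound-screen setup: DMSO solvent wells anchor 0% effect, DEAB
#' inhibitor wells anchor 100%. For siRNA screens use
#' `neutralRole = "lipid"`, `fullEffectRole = "sirna"`.
#'
#' @param neutralRole platemap role of the neutral (0% effect) control.
#' @param fullEffectRole role of the full-effect (100%) control.
#' @param aggregation "median" (default) or "mean" over control wells.
#' @param maskFraction wells with a cell count below this fraction of the
#'   neutral-control aggregate are masked (strict inequality: a reduction
#'   of exactly 50% is not masked).
#' @param hitThreshold minimum percent reduction of the ALDH-high fraction
#'   vs the neutral control for a hit (strict inequality; default 25).
#' @param tFast minimum 2 h effect (percent) for the fast-acting flag.
#' @param tRebound maximum post-wash-off effect (percent) for the
#'   fast-acting flag.
#' @return A named list of class `screenConfig`.
#' @export
screenConfig <- function(neutralRole = "dmso", fullEffectRole = "deab",
                         aggregation = c("median", "mean"),
                         maskFraction = 0.5, hitThreshold = 25,
                         tFast = 75, tRebound = 25) {
  structure(
    list(
      neutralRole = neutralRole, fullEffectRole = fullEffectRole,
      aggregation = match.arg(aggregation), maskFraction = maskFraction,
      hitThreshold = hitThreshold, tFast = tFast, tRebound = tRebound
    ),
    class = "screenConfig"
  )
}

#' Mask toxic / antiproliferative wells
#'
#' A well is masked when its cell count is reduced by strictly more than
#' `1 - maskFraction` (default 50%) relative to the neutral-control
#' aggregate, i.e. `n_cells < maskFraction * aggregate(neutral counts)`.
#' A reduction of exactly 50% is not masked.
#'
#' @param wells data.frame with `role` and `n_cells`.
#' @param config a [screenConfig()].
#' @return Logical vector of mask flags, one per well row.
#' @export
maskToxicWells <- function(wells, config = screenConfig()) {
  stopifnot(all(c("role", "n_cells") %in% names(wells)))
  neutral <- wells$n_cells[wells$role == config$neutralRole]
  if (!length(neutral))
    stop("no wells with neutral role '", config$neutralRole,
         "': cannot assess toxicity")
  ref <- aggFun(config$aggregation)(neutral)
  wells$n_cells < config$maskFraction * ref
}

#' Percent-of-control normalization of the ALDH-high fraction
#'
#' Linear rescaling anchoring the neutral control to 0% effect and the
#' full-effect control to 100%:
#' `effect = 100 * (f_neutral - f_well) / (f_neutral - f_full)`.
#' Values outside \[0, 100\] are permitted (over-normalization); values
#' beyond +/-150 are flagged.
#'
#' @param wells data.frame with `role` and `fraction_high`.
#' @param config a [screenConfig()].
#' @return data.frame with `normalized_effect` (percent) and
#'   `effect_flag` (TRUE beyond +/-150).
#' @export
normalizeToControls <- function(wells, config = screenConfig()) {
  stopifnot(all(c("role", "fraction_high") %in% names(wells)))
  f <- aggFun(config$aggregation)
  fn <- wells$fraction_high[wells$role == config$neutralRole]
  ff <- wells$fraction_high[wells$role == config$fullEffectRole]
  if (!length(fn) || !length(ff))
    stop("both control roles ('", config$neutralRole, "', '",
         config$fullEffectRole, "') must be present on the plate")
  fNeutral <- f(fn); fFull <- f(ff)
  if (fNeutral == fFull)
    stop("QC failure: degenerate anchors (neutral aggregate equals ",
         "full-effect aggregate, ", fNeutral, ")")
  eff <- 100 * (fNeutral - wells$fraction_high) / (fNeutral - fFull)
  data.frame(normalized_effect = eff, effect_flag = abs(eff) > 150)
}

#' Reduction of the ALDH-high fraction vs the neutral control
#'
#' `100 * (f_neutral - f_well) / f_neutral`, the DMSO-relative scale the
#' hit rule operates on. NA (not evaluable) when the neutral aggregate
#' is 0.
#'
#' @inheritParams normalizeToControls
#' @return Numeric vector of percent reductions.
#' @export
reductionVsNeutral <- function(wells, config = screenConfig()) {
  stopifnot(all(c("role", "fraction_high") %in% names(wells)))
  fn <- wells$fraction_high[wells$role == config$neutralRole]
  if (!length(fn))
    stop("no wells with neutral role '", config$neutralRole, "'")
  fNeutral <- aggFun(config$aggregation)(fn)
  if (fNeutral == 0) {
    warning("neutral-control ALDH-high fraction is 0: reduction undefined")
    return(rep(NA_real_, nrow(wells)))
  }
  100 * (fNeutral - wells$fraction_high) / fNeutral
}

#' Call screening hits
#'
#' A well is a hit when it is not masked and its reduction of the
#' ALDH-high fraction vs the neutral control is strictly greater than the
#' threshold (default 25%). Masking takes precedence over any reduction.
#' Only sample wells are eligible when a `role` column is present.
#'
#' @param wells data.frame with `role` and `fraction_high`.
#' @param masked logical vector from [maskToxicWells()].
#' @param config a [screenConfig()].
#' @return Logical hit flags (NA where the reduction is not evaluable).
#' @export
callHits <- function(wells, masked, config = screenConfig()) {
  red <- reductionVsNeutral(wells, config)
  hit <- !masked & red > config$hitThreshold
  if ("role" %in% names(wells)) hit <- hit & wells$role == "sample"
  hit[is.na(red) & !masked] <- NA
  hit[masked] <- FALSE
  hit
}

#' Flag fast-acting false positives
#'
#' A compound behaves like a direct ALDH enzyme inhibitor (a false
#' positive for stem-cell elimination) when it abolishes the reporter
#' signal within 2 h (`effect2h >= tFast`, default 75%) and the signal
#' rebounds after compound wash-off (`effectWashoff < tRebound`, default
#' 25%). The thresholds are configuration, defaulted from the DEAB
#' exemplar behaviour (~94% reduction at 2 h, full rebound).
#'
#' @param effect2h percent effect after 2 h co-incubation.
#' @param effectWashoff percent effect remaining after wash-off.
#' @param config a [screenConfig()].
#' @return Logical flags; NA where either measurement is missing.
#' @export
flagFastActing <- function(effect2h, effectWashoff,
                           config = screenConfig()) {
  flag <- effect2h >= config$tFast & effectWashoff < config$tRebound
  flag[is.na(effect2h) | is.na(effectWashoff)] <- NA
  flag
}

#' Robust Z-prime factor
#'
#' `RZ' = 1 - 3 * (1.4826 * MAD(pos) + 1.4826 * MAD(neg)) /
#' |median(pos) - median(neg)|` -- the median/scaled-MAD analogue of the
#' Z-prime assay-quality statistic. 1 is perfect separation; RZ' is
#' always <= 1.
#'
#' @param pos,neg control-well readouts (e.g. ALDH-high fractions) for
#'   the two control groups; at least 3 wells each.
#' @return The RZ' value; `-Inf` (with a warning) when the medians are
#'   equal, which is a QC failure.
#' @examples
#' robustZPrime(c(0, 0.1, 0.2), c(1.0, 1.1, 1.2))  # 0.11044
#' @export
robustZPrime <- function(pos, neg) {
  if (length(pos) < 3 || length(neg) < 3)
    stop("at least 3 wells per control group are required")
  sep <- abs(stats::median(pos) - stats::median(neg))
  if (sep == 0) {
    warning("QC failure: control medians are equal; RZ' is -Inf")
    return(-Inf)
  }
  1 - 3 * (stats::mad(pos) + stats::mad(neg)) / sep
}

#' Signal-to-background ratio of the assay controls
#'
#' Aggregate ALDH-high fraction of the neutral control divided by that of
#' the full-effect control.
#'
#' @param neutral,full control-well ALDH-high fractions.
#' @param aggregation "mean" (default) or "median".
#' @return The ratio; `+Inf` with a warning when the full-effect
#'   aggregate is 0.
#' @export
signalToBackground <- function(neutral, full,
                               aggregation = c("mean", "median")) {
  f <- aggFun(match.arg(aggregation))
  b <- f(full)
  if (b == 0) {
    warning("full-effect control aggregate is 0: signal-to-background infinite")
    return(Inf)
  }
  f(neutral) / b
}

#' Run the complete plate-level screen analysis
#'
#' Applies toxicity masking, percent-of-control normalization, the
#' neutral-relative reduction, hit calling and plate QC (robust Z-prime
#' and signal-to-background on the control wells) to a table of per-well
#' summaries; optionally merges per-compound 2 h / wash-off follow-up
#' measurements and flags fast-acting false positives among the hits.
#'
#' @param wells data.frame of per-well summaries (`well`, `role`,
#'   `compound`, `dose_uM`, `n_cells`, `fraction_high`), e.g. from
#'   [summarizePlate()].
#' @param config a [screenConfig()].
#' @param followUp optional data.frame (`compound`, `effect_2h`,
#'   `effect_washoff`) of follow-up measurements for nominated hits.
#' @param gate optional [GateThreshold-class] to echo into the result.
#' @return A [ScreenResult-class].
#' @export
screenPlate <- function(wells, config = screenConfig(), followUp = NULL,
                        gate = NULL) {
  stopifnot(is.data.frame(wells))
  masked <- maskToxicWells(wells, config)
  norm <- normalizeToControls(wells, config)
  red <- reductionVsNeutral(wells, config)
  hit <- callHits(wells, masked, config)
  out <- cbind(
    wells, norm,
    data.frame(reduction_vs_neutral = red, masked = masked, hit = hit)
  )
  out$fast_acting <- NA
  if (!is.null(followUp)) {
    idx <- match(out$compound, followUp$compound)
    fa <- flagFastActing(followUp$effect_2h[idx],
                         followUp$effect_washoff[idx], config)
    ## the fast-acting triage is only meaningful for nominated hits
    out$fast_acting <- ifelse(out$hit %in% TRUE, fa, NA)
  }
  pos <- wells$fraction_high[wells$role == config$fullEffectRole]
  neg <- wells$fraction_high[wells$role == config$neutralRole]
  rz <- if (length(pos) >= 3 && length(neg) >= 3) {
    robustZPrime(pos, neg)
  } else NA_real_
  sb <- suppressWarnings(signalToBackground(neg, pos))
  new("ScreenResult",
    wells = out, rzPrime = rz, signalToBackground = sb,
    gate = gate, config = unclass(config)
  )
}
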