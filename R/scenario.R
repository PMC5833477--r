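## A fully synthetic 384-well compound screen with known ground truth:
## neutral compounds, true CSC-suppressor compounds (lowered ALDH-high
## fraction), fast-acting enzyme mimics (DEAB-like: strong apparent
## reduction that reverses on wash-off), and toxic wells. This is the
## package's reference end-to-end validation scenario.

#' Build a synthetic 384-well screen scenario with planted ground truth
#'
#' Layout: column 1 = DMSO neutral controls (16 wells), column 2 = DEAB
#' inhibitor controls (16 wells), columns 3-24 = 352 sample wells, one
#' compound each at 10 uM. Among the sample compounds the scenario
#' plants, at seeded random positions: true suppressors (ALDH-high
#' fraction halved: 50% reduction), fast-acting enzyme mimics (DEAB-like
#' 94% apparent reduction) and toxic wells (cell count multiplied by
#' 0.4, i.e. masked under the >50% rule). Everything else carries the
#' base mixture (5% ALDH-high, 5000 cells/well -- roughly four imaged
#' fields at 10x).
#'
#' @param seed integer scenario seed.
#' @param nCellsPerWell cells per well.
#' @param nSuppressors,nMimics,nToxic planted counts (defaults 10/5/20).
#' @param baseFraction neutral ALDH-high fraction (default 0.05).
#' @param suppressorFraction ALDH-high fraction in suppressor wells.
#' @param mimicFraction apparent ALDH-high fraction in mimic wells.
#' @param toxicMultiplier cell-count multiplier for toxic wells.
#' @return list with `spec` (a [PlateSpec-class]) and `truth` (list:
#'   `suppressors`, `mimics` -- compound ids; `toxicWells`,
#'   `toxicCompounds`; plus the scenario parameters).
#' @export
screenScenario <- function(seed = 1L, nCellsPerWell = 5000L,
                           nSuppressors = 10L, nMimics = 5L, nToxic = 20L,
                           baseFraction = 0.05,
                           suppressorFraction = baseFraction / 2,
                           mimicFraction = 0.003,
                           toxicMultiplier = 0.4) {
  wells <- plateWells384()
  col <- as.integer(substr(wells, 2, 3))
  role <- rep("sample", length(wells))
  role[col == 1] <- "dmso"
  role[col == 2] <- "deab"
  compound <- rep(NA_character_, length(wells))
  sampleWells <- wells[role == "sample"]
  compound[role == "sample"] <- sprintf("CPD%04d", seq_along(sampleWells))
  compound[role == "dmso"] <- "DMSO"
  compound[role == "deab"] <- "DEAB"
  layout <- data.frame(
    well = wells, role = role, compound = compound,
    dose_uM = ifelse(role == "sample", 10, ifelse(role == "deab", 10, 0)),
    stringsAsFactors = FALSE
  )
  set.seed(as.integer(seed))
  planted <- sample(sampleWells, nSuppressors + nMimics + nToxic)
  supWells <- planted[seq_len(nSuppressors)]
  mimWells <- planted[nSuppressors + seq_len(nMimics)]
  toxWells <- planted[nSuppressors + nMimics + seq_len(nToxic)]
  base <- mixtureSpec(nCells = nCellsPerWell, highFraction = baseFraction)
  overrides <- c(
    setNames(lapply(supWells, function(w) {
      m <- base; m@highFraction <- suppressorFraction; m
    }), supWells),
    setNames(lapply(mimWells, function(w) {
      m <- base; m@highFraction <- mimicFraction; m
    }), mimWells)
  )
  spec <- plateSpec(
    layout = layout, baseMixture = base, overrides = overrides,
    toxicity = setNames(rep(toxicMultiplier, nToxic), toxWells),
    seed = seed
  )
  cpdOf <- function(w) layout$compound[match(w, layout$well)]
  list(
    spec = spec,
    truth = list(
      suppressors = cpdOf(supWells), mimics = cpdOf(mimWells),
      toxicWells = toxWells, toxicCompounds = cpdOf(toxWells),
      baseFraction = baseFraction,
      suppressorFraction = suppressorFraction,
      mimicFraction = mimicFraction, nCellsPerWell = nCellsPerWell,
      seed = as.integer(seed)
    )
  )
}

#' Generate 2 h / wash-off follow-up measurements for candidate hits
#'
#' Emulates the hit-triage experiment: candidate compounds are
#' co-incubated with the staining reagent for 2 h (enzyme mimics abolish
#' the signal immediately, like DEAB; maintenance suppressors need days
#' and show no 2 h effect), and separately washed off after a 72 h
#' treatment (the mimic signal rebounds to near baseline; the suppressor
#' effect persists). Each phase is generated as a small control-anchored
#' plate and analysed through the normal gating path; effects are percent
#' reductions vs that plate's DMSO wells.
#'
#' @param scenario a [screenScenario()] result.
#' @param compounds compound ids to profile (typically the nominated
#'   hits). Unknown compounds behave neutrally.
#' @param nCellsPerWell cells per follow-up well.
#' @return data.frame `compound`, `effect_2h`, `effect_washoff` (percent).
#' @export
followUpEffects <- function(scenario, compounds,
                            nCellsPerWell = scenario$truth$nCellsPerWell) {
  tr <- scenario$truth
  base <- tr$baseFraction
  phaseFraction <- function(cpd, phase) {
    if (cpd %in% tr$mimics) {
      ## immediate enzyme inhibition; signal reappears after wash-off
      if (phase == "2h") tr$mimicFraction else base * 0.95
    } else if (cpd %in% tr$suppressors) {
      ## maintenance inhibition: nothing at 2 h, persistent after wash-off
      if (phase == "2h") base else tr$suppressorFraction
    } else base
  }
  runPhase <- function(phase, phaseSeed) {
    n <- length(compounds)
    ctrl <- data.frame(
      well = c(sprintf("A%02d", 1:4), sprintf("B%02d", 1:4)),
      role = rep(c("dmso", "deab"), each = 4),
      compound = rep(c("DMSO", "DEAB"), each = 4), dose_uM = c(rep(0, 4), rep(10, 4)),
      stringsAsFactors = FALSE
    )
    rows <- LETTERS[3:16]
    sampleWells <- as.vector(t(outer(rows, sprintf("%02d", 1:24), paste0)))[seq_len(n)]
    lay <- rbind(ctrl, data.frame(
      well = sampleWells, role = "sample", compound = compounds,
      dose_uM = 10, stringsAsFactors = FALSE
    ))
    mx <- mixtureSpec(nCells = nCellsPerWell, highFraction = base)
    over <- setNames(lapply(compounds, function(cpd) {
      m <- mx; m@highFraction <- phaseFraction(cpd, phase); m
    }), sampleWells)
    ds <- genPlateDataset(plateSpec(lay, baseMixture = mx,
                                    overrides = over, seed = phaseSeed))
    sm <- summarizePlate(ds$cells, ds$platemap)
    red <- reductionVsNeutral(sm$wells)
    red[match(sampleWells, sm$wells$well)]
  }
  data.frame(
    compound = compounds,
    effect_2h = runPhase("2h", wellSeed(tr$seed, 100000L)),
    effect_washoff = runPhase("washoff", wellSeed(tr$seed, 200000L)),
    stringsAsFactors = FALSE
  )
}
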