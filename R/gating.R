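## DEAB-anchored intensity gating: the assay's core statistic. The
## threshold is mean + k * SD (sample SD) of the pooled ALDH-inhibitor
## control cells of the plate; a cell is ALDH-high when its intensity is
## strictly above the threshold (ties count as low; conservative).

#' Compute the DEAB-anchored gate threshold
#'
#' @param controlIntensities background-corrected intensities (a.u.) of
#'   cells pooled across all inhibitor-control (DEAB) wells of the plate.
#' @param k SD multiplier; default 6.
#' @param minCells QC floor for the control pool (default 200); fewer
#'   control cells is an error rather than a gate computed on noise.
#' @param sourceWells optional well ids the pool came from (audit trail).
#' @return A [GateThreshold-class] with `threshold = mean + k * sd`
#'   (sample SD, n - 1 denominator). Zero variance with n > 1 yields
#'   `threshold = mean` with a warning.
#' @examples
#' gateCutoff(computeGateThreshold(c(8, 10, 12), k = 6, minCells = 1))  # 22
#' @export
computeGateThreshold <- function(controlIntensities, k = 6, minCells = 200,
                                 sourceWells = character(0)) {
  if (!is.numeric(controlIntensities))
    stop("controlIntensities must be numeric")
  if (k <= 0) stop("k must be > 0")
  n <- length(controlIntensities)
  if (n < minCells)
    stop("QC failure: only ", n, " control cells pooled (minimum ", minCells,
         "); gate would be computed on noise")
  m <- mean(controlIntensities)
  s <- if (n > 1) stats::sd(controlIntensities) else 0
  if (s == 0 && n > 1)
    warning("zero variance in control intensities; threshold equals the mean")
  new("GateThreshold",
    meanDeab = m, sdDeab = s, k = as.numeric(k), threshold = m + k * s,
    nControlCells = as.integer(n), sourceWells = as.character(sourceWells)
  )
}

## Accept either a cell-record data.frame (with an `intensity` column) or
## a bare numeric vector of intensities.
cellIntensities <- function(cells) {
  if (is.data.frame(cells)) {
    if (!"intensity" %in% names(cells))
      stop("cell table must have an 'intensity' column")
    cells$intensity
  } else if (is.numeric(cells)) {
    cells
  } else stop("cells must be a data.frame or a numeric vector")
}

#' ALDH-high fraction of a well
#'
#' Counts cells whose intensity is strictly above the gate threshold and
#' reports the fraction of the total population.
#'
#' @param cells cell records (data.frame with `intensity`) or a numeric
#'   intensity vector.
#' @param gate a [GateThreshold-class].
#' @param well optional well id for the summary row.
#' @return A one-row data.frame: `well`, `n_cells`, `n_high`,
#'   `fraction_high`. An empty well is an explicit error: "no cells" is
#'   distinct from "0 percent high".
#' @export
gateFraction <- function(cells, gate, well = NA_character_) {
  stopifnot(is(gate, "GateThreshold"))
  int <- cellIntensities(cells)
  if (length(int) == 0)
    stop("empty well: no cells to gate (distinct from a 0% ALDH-high well)")
  nHigh <- sum(int > gate@threshold)
  data.frame(
    well = well, n_cells = length(int), n_high = nHigh,
    fraction_high = nHigh / length(int), stringsAsFactors = FALSE
  )
}

#' In-silico sort into ALDH-high and ALDH-low subsets
#'
#' Partitions cells by the gate, mirroring a FACS sort on the same
#' threshold. When ground-truth labels are available (synthetic data, a
#' `label` column), the report includes the purity of each sorted subset:
#' the fraction of true-high labels in the high set and true-low labels
#' in the low set.
#'
#' @param cells cell-record data.frame with `intensity` and optionally
#'   `label` ("high"/"low").
#' @param gate a [GateThreshold-class].
#' @return list with `high` and `low` (data.frames) and `purity` (list
#'   with `high` and `low` fractions, or NULL without labels; NA for an
#'   empty subset).
#' @export
inSilicoSort <- function(cells, gate) {
  stopifnot(is(gate, "GateThreshold"), is.data.frame(cells))
  int <- cellIntensities(cells)
  isHigh <- int > gate@threshold
  high <- cells[isHigh, , drop = FALSE]
  low <- cells[!isHigh, , drop = FALSE]
  purity <- NULL
  if ("label" %in% names(cells)) {
    purity <- list(
      high = if (nrow(high)) mean(high$label == "high") else NA_real_,
      low = if (nrow(low)) mean(low$label == "low") else NA_real_
    )
  }
  list(high = high, low = low, purity = purity)
}

#' Gate a whole plate of cell records
#'
#' Pools the intensities of all wells with the control role, computes the
#' plate gate, and gates every well on the plate (control-on-every-plate
#' practice: one threshold per plate from that plate's own inhibitor
#' wells). With `perWellGate = TRUE` each control well instead anchors
#' its own gate and sample wells use the pooled one; the pooled cell-level
#' statistic is the default.
#'
#' @param cells data.frame of cell records with `well` and `intensity`.
#' @param platemap data.frame with `well`, `role` (and typically
#'   `compound`, `dose_uM`), e.g. from [loadPlatemap()].
#' @param k SD multiplier for the gate.
#' @param controlRole role whose wells anchor the gate (default "deab";
#'   use "sirna" for the knockdown-control variant).
#' @param minCells control-pool QC floor passed to
#'   [computeGateThreshold()].
#' @return list with `wells` (data.frame: `well`, `role`, `compound`,
#'   `dose_uM`, `n_cells`, `n_high`, `fraction_high`) and `gate` (the
#'   [GateThreshold-class]).
#' @export
summarizePlate <- function(cells, platemap, k = 6, controlRole = "deab",
                           minCells = 200) {
  stopifnot(is.data.frame(cells), is.data.frame(platemap))
  if (!all(c("well", "intensity") %in% names(cells)))
    stop("cells must have 'well' and 'intensity' columns")
  ctrlWells <- platemap$well[platemap$role == controlRole]
  if (!length(ctrlWells))
    stop("no wells with control role '", controlRole, "' in the platemap")
  pool <- cells$intensity[cells$well %in% ctrlWells]
  gate <- computeGateThreshold(pool, k = k, minCells = minCells,
                               sourceWells = ctrlWells)
  byWell <- split(cells$intensity, cells$well)
  present <- intersect(platemap$well, names(byWell))
  rows <- lapply(present, function(w) gateFraction(byWell[[w]], gate, well = w))
  wells <- do.call(rbind, rows)
  meta <- platemap[match(wells$well, platemap$well),
                   intersect(c("role", "compound", "dose_uM"), names(platemap)),
                   drop = FALSE]
  wells <- cbind(wells[, "well", drop = FALSE], meta,
                 wells[, c("n_cells", "n_high", "fraction_high")])
  rownames(wells) <- NULL
  list(wells = wells, gate = gate)
}
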