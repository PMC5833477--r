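## Shared fixture builders. Everything is generated in code; no binary
## fixtures on disk.

## A hand-sized well-summary table for the screen statistics tests:
## 3 DMSO wells, 3 DEAB wells and a configurable set of sample wells.
toyWellTable <- function(sampleFractions, sampleCounts,
                         dmsoFraction = 0.10, deabFraction = 0,
                         dmsoCount = 100) {
  n <- length(sampleFractions)
  data.frame(
    well = c("A01", "B01", "C01", "A02", "B02", "C02",
             sprintf("%s03", LETTERS[seq_len(n)])),
    role = c(rep("dmso", 3), rep("deab", 3), rep("sample", n)),
    compound = c(rep("DMSO", 3), rep("DEAB", 3),
                 sprintf("CPD%02d", seq_len(n))),
    dose_uM = c(rep(0, 3), rep(10, 3), rep(10, n)),
    n_cells = c(rep(dmsoCount, 3), rep(dmsoCount, 3), sampleCounts),
    fraction_high = c(rep(dmsoFraction, 3), rep(deabFraction, 3),
                      sampleFractions),
    stringsAsFactors = FALSE
  )
}

## Two-channel field with nuclei painted as exact disks and the reporter
## painted over disjoint footprints; no blur, no noise. Returns the
## FieldImage plus the painted truth.
paintedField <- function(centres, radiusPx = 9, intensities = 500,
                         dim = c(256L, 256L), pixelSize = 0.65,
                         ringGuardPx = 8) {
  nuc <- matrix(0, dim[1], dim[2])
  rep_ch <- matrix(0, dim[1], dim[2])
  intensities <- rep_len(intensities, nrow(centres))
  radiusPx <- rep_len(radiusPx, nrow(centres))
  for (i in seq_len(nrow(centres))) {
    nuc <- AldhScreen:::paintDisk(nuc, centres[i, 1], centres[i, 2],
                                  radiusPx[i], 1000)
    rep_ch <- AldhScreen:::paintDisk(rep_ch, centres[i, 1], centres[i, 2],
                                     radiusPx[i] + ringGuardPx,
                                     intensities[i])
  }
  list(image = fieldImage(nuc, rep_ch, pixelSize),
       centres = centres, intensities = intensities)
}

## Match measured cell records to ground-truth entries by nearest centre.
matchToTruth <- function(cells, truthX, truthY) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truthX - cells$x[i])^2 + (truthY - cells$y[i])^2)
  }, integer(1))
}
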