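## File formats. CSV dialect everywhere: UTF-8, comma separator, '.'
## decimal, no thousands separators. Tables may carry '#'-prefixed
## metadata header lines (tool version, configuration fingerprint, gate
## parameters); readers skip them.

#' Load and validate a platemap
#'
#' Expects a CSV with header `well,role,compound,dose_uM`. Wells are
#' validated against the 384 format (A01..P24), duplicates and unknown
#' roles are rejected; every error message carries the offending line
#' number.
#'
#' @param path CSV file path.
#' @return data.frame `well`, `role`, `compound`, `dose_uM`.
#' @export
loadPlatemap <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("well", "role", "compound", "dose_uM")
  if (!identical(names(pm)[seq_along(need)], need))
    stop("platemap must have header 'well,role,compound,dose_uM', got '",
         paste(names(pm), collapse = ","), "'")
  line <- seq_len(nrow(pm)) + 1L   # header is line 1
  bad <- !isValidWell384(pm$well)
  if (any(bad))
    stop("malformed well id(s) outside the 384 format (A01..P24): ",
         paste(sprintf("'%s' (line %d)", pm$well[bad], line[bad]),
               collapse = ", "))
  dup <- duplicated(pm$well)
  if (any(dup))
    stop("duplicate well row(s): ",
         paste(sprintf("'%s' (line %d)", pm$well[dup], line[dup]),
               collapse = ", "))
  badRole <- !(pm$role %in% WELL_ROLES)
  if (any(badRole))
    stop("unknown role(s): ",
         paste(sprintf("'%s' (line %d)", pm$role[badRole], line[badRole]),
               collapse = ", "),
         "; expected one of ", paste(WELL_ROLES, collapse = ", "))
  pm$dose_uM <- as.numeric(pm$dose_uM)
  pm[, need]
}

#' Write a platemap CSV
#' @param platemap data.frame `well`, `role`, `compound`, `dose_uM`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePlatemap <- function(platemap, path) {
  utils::write.csv(platemap[, c("well", "role", "compound", "dose_uM")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Write a data.frame as CSV preceded by '#'-prefixed metadata lines.
writeCsvWithMeta <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a per-cell intensity table
#'
#' Canonical schema `well,cell_id,x,y,nuc_area_px,intensity,label`;
#' columns absent from the input (e.g. positions for table-only synthetic
#' data, labels for real data) are written as NA and restored as such.
#'
#' @param cells data.frame of cell records.
#' @param path CSV path.
#' @param meta optional named character vector written as `# key=value`
#'   header lines.
#' @return `writeCellTable`: the path, invisibly. `readCellTable`: the
#'   data.frame.
#' @export
writeCellTable <- function(cells, path, meta = character(0)) {
  cols <- c("well", "cell_id", "x", "y", "nuc_area_px", "intensity", "label")
  for (cl in setdiff(cols, names(cells))) cells[[cl]] <- NA
  writeCsvWithMeta(cells[, cols], path, meta)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write / read a two-channel field image as 16-bit TIFF plus sidecar
#'
#' The two channels (nuclear, reporter -- in that order) go into one
#' multi-directory 16-bit TIFF; intensities are stored as rounded a.u.
#' (1 digital number = 1 a.u., clipped at 65535). The pixel size and
#' channel order live in a JSON sidecar next to the TIFF
#' (`<path>.json`).
#'
#' @param img a [FieldImage-class].
#' @param path TIFF output path.
#' @return `writeFieldImage`: the path, invisibly. `readFieldImage`: the
#'   [FieldImage-class].
#' @export
writeFieldImage <- function(img, path) {
  stopifnot(is(img, "FieldImage"))
  toDn <- function(m) t(pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(list(toDn(img@nuclear), toDn(img@reporter)),
                  path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = img@pixelSize,
         channels = c("nuclear", "reporter"),
         intensity_scale = "1 DN = 1 a.u."),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeFieldImage
#' @export
readFieldImage <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("pixel-size sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ch <- tiff::readTIFF(path, all = TRUE)
  if (length(ch) < 2) stop("expected a two-channel TIFF (nuclear, reporter)")
  fromDn <- function(m) t(m * 65535)
  fieldImage(fromDn(ch[[1]]), fromDn(ch[[2]]),
             pixelSize = meta$pixel_size_um)
}
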