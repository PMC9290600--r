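# --- on-disk formats -----------------------------------------------------------

#' Write / read a multispectral field
#'
#' A field is stored as a multi-page TIFF (one page per channel) plus a JSON
#' sidecar carrying wavelength, channel kind, pixel size, exposure scale and
#' field index.
#'
#' @param field An \code{ms_field}.
#' @param path TIFF path; the sidecar takes the same path with a
#'   \code{.json} extension.
#' @return \code{read_field} returns the restored \code{ms_field}.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ms_field"))
  write_tiff(field$channels, path)
  side <- list(pixel_size_um = field$pixel_size,
               field_index = field$field_index,
               channels = field$channel_meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  channels <- read_tiff(path)
  side <- jsonlite::fromJSON(readLines(paste0(path, ".json")))
  structure(list(channels = channels,
                 pixel_size = side$pixel_size_um,
                 channel_meta = as.data.frame(side$channels),
                 field_index = side$field_index),
            class = "ms_field")
}

#' Write / read per-field ground truth as JSON
#'
#' @param truth A \code{field_truth}.
#' @param path JSON path.
#' @return \code{read_field_truth} returns the restored \code{field_truth}.
#' @export
write_field_truth <- function(truth, path) {
  stopifnot(inherits(truth, "field_truth"))
  obj <- list(field_index = truth$field_index,
              field_width = truth$field_width,
              field_height = truth$field_height,
              cells = truth$cells,
              overlap_pairs = truth$overlap_pairs)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_field_truth
#' @export
read_field_truth <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  ov <- obj$overlap_pairs
  if (is.null(ov) || !length(ov)) ov <- matrix(integer(0), 0, 2)
  structure(list(cells = as.data.frame(obj$cells),
                 overlap_pairs = matrix(as.integer(ov), ncol = 2),
                 field_index = obj$field_index,
                 field_width = obj$field_width,
                 field_height = obj$field_height),
            class = "field_truth")
}

#' Ground-truth cell roster as CSV
#'
#' One row per cell across all fields: field index, position, kind, class and
#' the per-cell truth values.
#'
#' @param fields List of \code{field_truth}.
#' @param path CSV path.
#' @return The roster data.frame, invisibly (write) / directly (read).
#' @export
write_truth_roster <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    if (!nrow(f$cells)) return(NULL)
    data.frame(field_index = f$field_index,
               uid = f$cells$uid, kind = f$cells$kind, class = f$cells$class,
               x = f$cells$x, y = f$cells$y, radius = f$cells$radius,
               volume_fl = f$cells$volume, hb_pg = f$cells$hb_mass,
               stringsAsFactors = FALSE)
  })
  roster <- do.call(rbind, rows)
  if (is.null(roster)) roster <- data.frame(
    field_index = integer(0), uid = integer(0), kind = character(0),
    class = character(0), x = numeric(0), y = numeric(0),
    radius = numeric(0), volume_fl = numeric(0), hb_pg = numeric(0))
  write.csv(roster, path, row.names = FALSE)
  invisible(roster)
}

#' Write / read an absorbance set as JSON
#'
#' @param absorbances An \code{hb_absorbance_set}.
#' @param path JSON path.
#' @return \code{read_absorbances} returns the restored set.
#' @export
write_absorbances <- function(absorbances, path) {
  obj <- list(wavelengths = absorbances$wavelengths,
              path_lengths = absorbances$path_lengths,
              noise_sd = absorbances$noise_sd,
              A = absorbances$A)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_absorbances
#' @export
read_absorbances <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  A <- matrix(unlist(obj$A), nrow = length(obj$wavelengths))
  dimnames(A) <- list(obj$wavelengths, obj$path_lengths)
  structure(list(A = A, wavelengths = obj$wavelengths,
                 path_lengths = obj$path_lengths, noise_sd = obj$noise_sd),
            class = "hb_absorbance_set")
}

# --- CSV schemas for the validation statistics ---------------------------------

check_cols <- function(d, need, what) {
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopf("%s: missing column(s) %s", what, paste(missing, collapse = ", "))
  d
}

#' Read validation-study CSV inputs
#'
#' Schemas: paired data (sample_id, analyte, x, y [, excluded, reason]);
#' replicates (sample_id, measurand, replicate_index, value [, range_label]);
#' nested design (site, device, day, run, replicate, level, measurand,
#' value); flagging adjudication (sample_id, truth, flagged) with
#' truth/flagged as 0/1 or logical.
#'
#' @param path CSV path.
#' @return data.frame validated against the schema.
#' @export
read_paired_csv <- function(path) {
  d <- check_cols(read.csv(path), c("sample_id", "analyte", "x", "y"),
                  "paired data")
  if (is.null(d$excluded)) d$excluded <- FALSE
  if (is.null(d$reason)) d$reason <- ""
  d$excluded <- as.logical(d$excluded)
  d
}

#' @rdname read_paired_csv
#' @export
read_replicates_csv <- function(path) {
  d <- check_cols(read.csv(path),
                  c("sample_id", "measurand", "replicate_index", "value"),
                  "replicate data")
  if (is.null(d$range_label)) d$range_label <- ""
  d
}

#' @rdname read_paired_csv
#' @export
read_nested_csv <- function(path) {
  check_cols(read.csv(path),
             c("site", "device", "day", "run", "replicate", "level",
               "measurand", "value"), "nested design data")
}

#' @rdname read_paired_csv
#' @export
read_flagging_csv <- function(path) {
  d <- check_cols(read.csv(path), c("sample_id", "truth", "flagged"),
                  "flagging data")
  ok01 <- function(v) is.logical(v) ||
    (is.numeric(v) && all(v %in% c(0, 1)))
  if (!ok01(d$truth) || !ok01(d$flagged))
    stopf("flagging data: truth/flagged must be 0/1 or logical")
  d$truth <- as.logical(d$truth)
  d$flagged <- as.logical(d$flagged)
  d
}
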