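# --- platelet pipeline -------------------------------------------------------

#' Detection thresholds for the platelet pipeline
#'
#' @param excess_k Detection threshold in units of the exposure-normalized
#'   background noise SD of the blue-excited channel.
#' @param min_area,max_area Accepted footprint area bounds, square pixels (at
#'   1 um/px the defaults span 1-15 px^2).
#' @param min_peak,max_peak Accepted peak excess bounds (exposure-normalized
#'   counts): the lower bound sits between the dim-speckle and platelet peak
#'   populations; the upper bound excludes the much brighter cytoplasm
#'   fragments of white cells.
#' @param max_violet_od Hemoglobin exclusion: mean violet OD over the object
#'   must stay below this (rules out red-cell fragments).
#' @param min_roundness Shape bound, applied to single-peak objects >= 6 px.
#' @param peak_split_min,peak_min_dist Local-maxima counting on the smoothed
#'   excess raster: two settled platelets whose masks touch are counted as
#'   two when both peaks exceed \code{peak_split_min} at separation
#'   \code{peak_min_dist} (um); the box smoothing makes a noise-induced
#'   second maximum within a single platelet effectively impossible.
#' @return List of thresholds.
#' @export
plt_thresholds <- function(excess_k = 4, min_area = 1, max_area = 15,
                           min_peak = 4, max_peak = 30,
                           max_violet_od = 0.05, min_roundness = 0.4,
                           peak_split_min = 4, peak_min_dist = 2.2) {
  list(excess_k = excess_k, min_area = min_area, max_area = max_area,
       min_peak = min_peak, max_peak = max_peak,
       max_violet_od = max_violet_od, min_roundness = min_roundness,
       peak_split_min = peak_split_min, peak_min_dist = peak_min_dist)
}

#' Detect platelet candidates
#'
#' Platelets carry little RNA, so their stain signal only stands above
#' background at the long exposure of the blue-excited channel. Candidates
#' are small connected components of exposure-normalized excess fluorescence,
#' combined with a brightfield absence-of-hemoglobin criterion so red-cell
#' fragments are not picked up.
#'
#' @param field An \code{ms_field} whose blue-excited channel carries
#'   exposure metadata.
#' @param thresholds See \code{\link{plt_thresholds}}.
#' @param ctx Optional precomputed \code{field_context} rasters.
#' @return data.frame of candidates: centroid (um), area_px, peak excess,
#'   mean violet OD, roundness, field index.
#' @export
detect_platelet_candidates <- function(field, thresholds = plt_thresholds(),
                                       ctx = NULL) {
  stopifnot(inherits(field, "ms_field"))
  meta <- field$channel_meta
  fl <- meta$wavelength_nm[meta$kind == "fluorescence"]
  if (!length(fl)) stopf("blue-excited fluorescence channel is missing")
  cyt <- if (!is.null(ctx)) ctx$cyt else fluor_excess(field, max(fl))
  px <- field$pixel_size
  vod <- (if (!is.null(ctx)) ctx$vod else violet_od(field))$od
  mask <- cyt$excess > thresholds$excess_k * cyt$sigma
  lab <- cpp_label(mask, 8L)
  nlab <- max(lab)
  if (nlab == 0)
    return(data.frame(cx = numeric(0), cy = numeric(0), area_px = numeric(0),
                      peak_excess = numeric(0), od_violet = numeric(0),
                      roundness = numeric(0), field_index = integer(0)))
  st <- cpp_label_stats(lab, cyt$excess, nlab)
  odst <- cpp_label_stats(lab, vod, nlab)
  # keep the small-object regime early to avoid measuring whole white cells
  area <- st[, 1]
  small <- which(area <= 4 * thresholds$max_area)
  rnd <- vapply(small, function(l) {
    if (area[l] < 6) return(1)
    sub <- lab[st[l, 7]:st[l, 8], st[l, 9]:st[l, 10], drop = FALSE] == l
    4 * pi * sum(sub) / mask_perimeter(sub)^2
  }, numeric(1))
  # touching platelets merge into one component; count them by the local
  # maxima of the box-smoothed excess inside each component
  sm <- box_smooth3(cyt$excess * mask)
  pk <- cpp_peaks(sm, min_val = thresholds$peak_split_min,
                  min_dist = thresholds$peak_min_dist / px)
  peak_lab <- if (nrow(pk)) lab[pk] else integer(0)
  n_peaks <- tabulate(peak_lab, nbins = nlab)
  # brightness maxima of a tight group can fuse under smoothing; for
  # components too large or too elongated to be one platelet, the distance
  # transform of the footprint still resolves the individuals
  for (l in small) {
    if (area[l] <= 9 || (n_peaks[l] < 2 && rnd[match(l, small)] >= 0.55))
      next
    sub <- lab[st[l, 7]:st[l, 8], st[l, 9]:st[l, 10], drop = FALSE] == l
    dpk <- cpp_peaks(cpp_edt(sub), min_val = 0.8,
                     min_dist = thresholds$peak_min_dist / px)
    n_peaks[l] <- max(n_peaks[l], nrow(dpk))
  }
  out <- data.frame(cx = (st[small, 5] / area[small] - 0.5) * px,
                    cy = (st[small, 4] / area[small] - 0.5) * px,
                    area_px = area[small] * px^2,
                    peak_excess = st[small, 11],
                    od_violet = odst[small, 2] / area[small],
                    roundness = rnd,
                    n_peaks = pmax(n_peaks[small], 1L),
                    field_index = field$field_index %||% NA_integer_)
  out[out$area_px <= 4 * thresholds$max_area &
        out$od_violet < thresholds$max_violet_od, , drop = FALSE]
}

# 3x3 box smoothing with zero padding (platelet peak counting).
box_smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
     p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] +
     p[2:(nr + 1), 3:(nc + 2)] +
     p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] +
     p[3:(nr + 2), 3:(nc + 2)]) / 9
}

#' Filter platelet candidates into accepted platelet records
#'
#' Rule mode: accept a candidate when its area, peak intensity and roundness
#' all lie within bounds (the morphological and intensity filtering stage).
#' An optional classifier mode accepts candidates with score >= 0.5 from a
#' supplied prediction function — a stand-in for the production networks.
#'
#' @param candidates data.frame from \code{\link{detect_platelet_candidates}}.
#' @param thresholds See \code{\link{plt_thresholds}}.
#' @param classifier Optional function(candidates) -> numeric scores in
#'   [0, 1]; when supplied, score >= 0.5 replaces the rule criteria.
#' @return The candidates with an \code{accepted} logical column.
#' @export
filter_platelets <- function(candidates, thresholds = plt_thresholds(),
                             classifier = NULL) {
  if (!nrow(candidates)) {
    candidates$accepted <- logical(0)
    return(candidates)
  }
  if (!is.null(classifier)) {
    candidates$accepted <- classifier(candidates) >= 0.5
    return(candidates)
  }
  np <- candidates$n_peaks %||% rep(1L, nrow(candidates))
  candidates$accepted <-
    candidates$area_px / np >= thresholds$min_area &
    candidates$area_px / np <= thresholds$max_area &
    candidates$peak_excess >= thresholds$min_peak &
    candidates$peak_excess <= thresholds$max_peak &
    candidates$od_violet < thresholds$max_violet_od &
    (np > 1 | candidates$roundness >= thresholds$min_roundness)
  candidates
}

#' Run the platelet pipeline on one field
#'
#' @param field An \code{ms_field}.
#' @param thresholds See \code{\link{plt_thresholds}}.
#' @param ctx Optional precomputed \code{field_context} rasters.
#' @return data.frame of accepted platelet records, one row per counted
#'   platelet (a merged pair of touching platelets yields two rows).
#' @export
plt_pipeline <- function(field, thresholds = plt_thresholds(), ctx = NULL) {
  cand <- detect_platelet_candidates(field, thresholds, ctx = ctx)
  out <- filter_platelets(cand, thresholds)
  out <- out[out$accepted, , drop = FALSE]
  if (nrow(out) && any(out$n_peaks > 1))
    out <- out[rep(seq_len(nrow(out)), out$n_peaks), , drop = FALSE]
  rownames(out) <- NULL
  out
}
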