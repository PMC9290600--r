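# --- channel access and background estimation -------------------------------

# Index of a channel by wavelength; violet = shortest brightfield wavelength.
channel_index <- function(field, wavelength = NULL, kind = NULL) {
  meta <- field$channel_meta
  idx <- seq_len(nrow(meta))
  if (!is.null(kind)) idx <- idx[meta$kind[idx] == kind]
  if (!is.null(wavelength)) idx <- idx[meta$wavelength_nm[idx] == wavelength]
  if (!length(idx)) stopf("no channel with wavelength %s / kind %s",
                          wavelength %||% "*", kind %||% "*")
  idx[1]
}

violet_channel <- function(field) {
  meta <- field$channel_meta
  bf <- which(meta$kind == "brightfield")
  if (!length(bf)) stopf("field has no brightfield channel")
  bf[which.min(meta$wavelength_nm[bf])]
}

# Robust background level and noise SD from the pixel population. Objects are
# darker than background in brightfield and brighter in fluorescence, so the
# median plus a one-sided MAD isolates the background mode; the final level is
# the mean of pixels within a few sigma of it.
estimate_background <- function(I, dark_objects = TRUE) {
  bg0 <- median(I)
  d <- I - bg0
  half <- if (dark_objects) d[d >= 0] else -d[d <= 0]
  s <- median(half) / 0.6745
  if (!is.finite(s) || s == 0) s <- max(mad(I), 1e-12)
  sel <- if (dark_objects) (I > bg0 - 2.5 * s & I < bg0 + 4 * s)
         else (I < bg0 + 2.5 * s & I > bg0 - 4 * s)
  list(level = mean(I[sel]), sigma = s)
}

# Violet-channel optical density raster and its noise scale.
violet_od <- function(field) {
  I <- field$channels[[violet_channel(field)]]
  bg <- estimate_background(I, dark_objects = TRUE)
  od <- -log10(pmax(I, 0.5) / bg$level)
  list(od = od, bg = bg$level, sigma_od = bg$sigma / (bg$level * log(10)))
}

# Shared per-field rasters (violet OD, fluorescence excesses): computed once
# and handed to all three pipelines when a whole field is analyzed.
field_context <- function(field) {
  meta <- field$channel_meta
  fl <- meta$wavelength_nm[meta$kind == "fluorescence"]
  list(vod = violet_od(field),
       nuc = if (length(fl) >= 2) fluor_excess(field, min(fl)) else NULL,
       cyt = if (length(fl) >= 1) fluor_excess(field, max(fl)) else NULL)
}

# --- RBC pipeline ------------------------------------------------------------

#' Detection thresholds for the red-cell pipeline
#'
#' @param od_k Threshold in units of the per-pixel OD noise SD.
#' @param min_od Absolute floor on the OD threshold.
#' @param min_area,max_area Candidate region area bounds, square micrometers.
#' @param split_trigger_area Regions larger than this are screened for
#'   overlaps and split, square micrometers.
#' @param split_min_dist Minimum seed separation for splitting, micrometers.
#' @param min_frag_area Minimum split-fragment area, square micrometers.
#' @param min_frag_roundness Minimum split-fragment roundness (4*pi*A/P^2).
#' @return List of thresholds.
#' @export
rbc_thresholds <- function(od_k = 4, min_od = 0.01,
                           min_area = 15, max_area = 3000,
                           split_trigger_area = 72, split_min_dist = 3.4,
                           min_frag_area = 12, min_frag_roundness = 0.4) {
  list(od_k = od_k, min_od = min_od, min_area = min_area, max_area = max_area,
       split_trigger_area = split_trigger_area,
       split_min_dist = split_min_dist, min_frag_area = min_frag_area,
       min_frag_roundness = min_frag_roundness)
}

#' Detect red-cell candidate regions in the violet brightfield channel
#'
#' Hemoglobin strongly absorbs violet light, so red cells appear as connected
#' regions of elevated optical density. Regions are thresholded at
#' \code{max(od_k * sigma_od, min_od)} and kept when their area lies within
#' the configured bounds; a region may still contain several touching cells
#' (see \code{\link{split_overlaps}}).
#'
#' @param field An \code{ms_field}.
#' @param optics The \code{\link{optics_config}} used to acquire it.
#' @param thresholds See \code{\link{rbc_thresholds}}.
#' @param ctx Optional precomputed \code{field_context} rasters.
#' @return Object of class \code{rbc_candidates}: \code{labels} (label
#'   raster), \code{regions} (data.frame: label, area_um2, od_sum, od2_sum,
#'   cx, cy in um, border flag, bounding box), plus the OD raster and noise
#'   scale.
#' @export
detect_rbc_candidates <- function(field, optics = NULL,
                                  thresholds = rbc_thresholds(), ctx = NULL) {
  stopifnot(inherits(field, "ms_field"))
  v <- if (!is.null(ctx)) ctx$vod else violet_od(field)
  px <- field$pixel_size
  thr <- max(thresholds$od_k * v$sigma_od, thresholds$min_od)
  mask <- v$od > thr
  lab <- cpp_label(mask, 4L)
  nlab <- max(lab)
  regions <- if (nlab > 0) {
    st <- cpp_label_stats(lab, v$od, nlab)
    data.frame(label = seq_len(nlab),
               area_um2 = st[, 1] * px^2,
               od_sum = st[, 2] * px^2,       # integrated OD x pixel area
               od2_sum = st[, 3] * px^2,
               cx = (st[, 5] / st[, 1] - 0.5) * px,
               cy = (st[, 4] / st[, 1] - 0.5) * px,
               border = st[, 6] > 0,
               rmin = st[, 7], rmax = st[, 8],
               cmin = st[, 9], cmax = st[, 10])
  } else {
    data.frame(label = integer(0), area_um2 = numeric(0), od_sum = numeric(0),
               od2_sum = numeric(0), cx = numeric(0), cy = numeric(0),
               border = logical(0), rmin = numeric(0), rmax = numeric(0),
               cmin = numeric(0), cmax = numeric(0))
  }
  keep <- regions$area_um2 >= thresholds$min_area &
    regions$area_um2 <= thresholds$max_area
  structure(list(labels = lab, regions = regions[keep, , drop = FALSE],
                 od = v$od, sigma_od = v$sigma_od, od_threshold = thr,
                 pixel_size = px),
            class = "rbc_candidates")
}

# Boundary length of a mask in pixel-edge units (count of exposed 4-edges).
mask_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- sum(mask[1, ]) + sum(mask[nr, ]) + sum(mask[, 1]) + sum(mask[, nc])
  p <- p + sum(mask[-1, ] != mask[-nr, ] & (mask[-1, ] | mask[-nr, ])) +
    sum(mask[, -1] != mask[, -nc] & (mask[, -1] | mask[, -nc]))
  # edges where exactly one side is inside
  p
}

#' Split a candidate region into single-cell masks
#'
#' Distance-transform watershed: seeds are local maxima of the Euclidean
#' distance transform separated by at least \code{split_min_dist}; markers
#' grow back over the region so that the fragment union reproduces the parent
#' mask exactly. The split is accepted only when every fragment satisfies the
#' area and roundness bounds; otherwise the region is returned unsplit (k = 1
#' is the no-split outcome).
#'
#' @param mask Logical matrix (the candidate region footprint).
#' @param pixel_size Micrometers per pixel.
#' @param thresholds See \code{\link{rbc_thresholds}}.
#' @return Integer matrix the shape of \code{mask}: 0 outside, fragment id
#'   1..k inside.
#' @export
split_overlaps <- function(mask, pixel_size = 1, thresholds = rbc_thresholds()) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dt <- cpp_edt(mask)
  pk <- cpp_peaks(dt, min_val = 1.4,
                  min_dist = thresholds$split_min_dist / pixel_size)
  one <- function() { m <- matrix(0L, nrow(mask), ncol(mask)); m[mask] <- 1L; m }
  if (nrow(pk) <= 1) return(one())
  markers <- matrix(0L, nrow(mask), ncol(mask))
  markers[cbind(pk[, 1], pk[, 2])] <- seq_len(nrow(pk))
  ws <- cpp_watershed(dt, markers, mask)
  # acceptance: every fragment must look like a cell
  for (k in seq_len(nrow(pk))) {
    fm <- ws == k
    a <- sum(fm) * pixel_size^2
    if (a < thresholds$min_frag_area) return(one())
    p <- mask_perimeter(fm) * pixel_size
    if (4 * pi * a / p^2 < thresholds$min_frag_roundness) return(one())
  }
  ws
}

#' Measure a single red cell
#'
#' Hemoglobin mass comes from the integrated violet optical density:
#' hb_pg = 0.01 * sum(OD) * pixel_area / eps(violet), the Beer-Lambert
#' inversion of the rendering model ((g/dl)*fl = 0.01 pg). Volume comes from
#' the effective footprint area A_eff = (sum OD)^2 / sum(OD^2), which for the
#' fixed biconcave profile is a shape constant times the true footprint area
#' and is insensitive to the exact threshold; the fixed area-to-volume mapping
#' is the profile's own isometric calibration and is documented as a stand-in
#' for the device's (unpublished) absolute volume measurement.
#'
#' @param od_sum Integrated OD over the mask times pixel area ((OD) um^2).
#' @param od2_sum Integrated squared OD times pixel area squared... supplied
#'   as sum(OD^2) * pixel_area (um^2) by the detector.
#' @param eps_violet Hemoglobin extinction at the violet wavelength,
#'   per (g/dl)*um.
#' @param pixel_size Micrometers per pixel.
#' @param saturated Any saturated pixels in the mask (measurement flagged).
#' @return data.frame row: hb_pg, volume_fl, a_eff_um2, saturated.
#' @export
measure_rbc <- function(od_sum, od2_sum, eps_violet, pixel_size = 1,
                        saturated = FALSE) {
  hb_pg <- 0.01 * od_sum / eps_violet
  # od_sum and od2_sum each carry one factor of pixel area, so the ratio has
  # units of area; for the fixed biconcave profile it is a shape constant
  # times footprint area, mapped to volume by the pixelization-aware
  # calibration below
  a_eff <- ifelse(od2_sum > 0, od_sum^2 / od2_sum, 0)
  cal <- rbc_volume_calibration(pixel_size)
  volume_fl <- stats::approx(cal$a_eff, cal$volume, xout = a_eff,
                             rule = 2)$y
  data.frame(hb_pg = pmax(hb_pg, 0), volume_fl = volume_fl,
             a_eff_um2 = a_eff, saturated = saturated)
}

# Effective-area -> volume calibration for the biconcave profile, computed on
# the renderer's own pixel sampling (2x2 subsamples per pixel) and averaged
# over subpixel center offsets, so finite-pixel smoothing of the profile does
# not bias the volume estimate. Memoised per pixel size.
.rbc_cal_cache <- new.env(parent = emptyenv())
rbc_volume_calibration <- function(pixel_size) {
  key <- sprintf("%.6g", pixel_size)
  hit <- .rbc_cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  radii <- seq(1.8, 6.5, by = 0.1)
  offs <- c(0.13, 0.38, 0.62, 0.87)
  aeff <- vapply(radii, function(r) {
    n <- ceiling(2 * r / pixel_size) + 2
    sub <- (seq_len(2 * n) - 0.5) / 2 * pixel_size   # painter subcenters
    mean(vapply(offs, function(o) {
      d <- sub - (n / 2 + o) * pixel_size
      u <- sqrt(outer(d^2, d^2, "+")) / r
      g <- matrix(biconcave_g(pmin(u, 1)), 2 * n, 2 * n)
      gp <- (g[seq(1, 2 * n, 2), ] + g[seq(2, 2 * n, 2), ])
      gp <- (gp[, seq(1, 2 * n, 2)] + gp[, seq(2, 2 * n, 2)]) / 4
      sum(gp)^2 / sum(gp^2) * pixel_size^2
    }, numeric(1)))
  }, numeric(1))
  cal <- list(a_eff = aeff, volume = 90 * (radii / 3.6)^3)
  .rbc_cal_cache[[key]] <- cal
  cal
}

#' Run the full red-cell pipeline on one field
#'
#' Detect candidates, split regions large enough to hold several touching
#' cells, and measure every resulting mask.
#'
#' @param field An \code{ms_field}.
#' @param optics The acquisition \code{\link{optics_config}}.
#' @param thresholds See \code{\link{rbc_thresholds}}.
#' @param ctx Optional precomputed \code{field_context} rasters.
#' @return data.frame of per-cell measurements: centroid (um), area,
#'   hb_pg, volume_fl, border and saturated flags, field index.
#' @export
rbc_pipeline <- function(field, optics, thresholds = rbc_thresholds(),
                         ctx = NULL) {
  det <- detect_rbc_candidates(field, optics, thresholds, ctx = ctx)
  px <- det$pixel_size
  eps <- optics$hb_extinction[[as.character(
    field$channel_meta$wavelength_nm[violet_channel(field)])]]
  sat <- field$channels[[violet_channel(field)]] >= optics$noise$sat_level
  reg <- det$regions
  out <- list()
  simple <- reg[reg$area_um2 <= thresholds$split_trigger_area, , drop = FALSE]
  if (nrow(simple)) {
    m <- measure_rbc(simple$od_sum, simple$od2_sum, eps, px)
    out$simple <- data.frame(cx = simple$cx, cy = simple$cy,
                             area_um2 = simple$area_um2,
                             hb_pg = m$hb_pg, volume_fl = m$volume_fl,
                             border = simple$border,
                             saturated = FALSE, split = FALSE)
  }
  big <- reg[reg$area_um2 > thresholds$split_trigger_area, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    lb <- big$label[i]
    r0 <- big$rmin[i]; r1 <- big$rmax[i]
    c0 <- big$cmin[i]; c1 <- big$cmax[i]
    sub <- det$labels[r0:r1, c0:c1, drop = FALSE] == lb
    ws <- split_overlaps(sub, px, thresholds)
    odc <- det$od[r0:r1, c0:c1, drop = FALSE]
    satc <- sat[r0:r1, c0:c1, drop = FALSE]
    nfrag <- max(ws)
    for (k in seq_len(nfrag)) {
      fm <- ws == k
      osum <- sum(odc[fm]) * px^2
      o2 <- sum(odc[fm]^2) * px^2
      m <- measure_rbc(osum, o2, eps, px, saturated = any(satc[fm]))
      ridx <- which(fm, arr.ind = TRUE)
      out[[paste0("b", i, "_", k)]] <- data.frame(
        cx = (mean(ridx[, 2]) + c0 - 1.5) * px,
        cy = (mean(ridx[, 1]) + r0 - 1.5) * px,
        area_um2 = sum(fm) * px^2, hb_pg = m$hb_pg,
        volume_fl = m$volume_fl, border = big$border[i],
        saturated = m$saturated, split = TRUE)
        # split = TRUE marks every overlap-screened region, including failed
        # splits, so per-cell indices use clean singles only
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cx = numeric(0), cy = numeric(0), area_um2 = numeric(0),
               hb_pg = numeric(0), volume_fl = numeric(0),
               border = logical(0), saturated = logical(0), split = logical(0))
  rownames(res) <- NULL
  res$field_index <- field$field_index %||% NA_integer_
  res
}

#' Aggregate per-cell red-cell measurements into population indices
#'
#' Concentration = cells counted / blood-equivalent volume imaged. Mean cell
#' volume, distribution width (RDW = 100 * sd/mean of volume) and mean cell
#' hemoglobin come from interior, unsaturated, unsplit cells only: clipped
#' border footprints and watershed fragments of touching cells still count,
#' but their distorted per-cell measurements would bias the indices.
#'
#' @param measurements data.frame from \code{\link{rbc_pipeline}} (possibly
#'   several fields).
#' @param geom,kit Chamber geometry and kit (for the counted volume).
#' @param n_fields Number of fields actually analyzed.
#' @return Object of class \code{rbc_indices}: rbc_conc (1e6/ul), mcv (fl),
#'   rdw (pct), mch (pg), n_cells_measured, n_cells_counted.
#' @export
aggregate_rbc <- function(measurements, geom, kit,
                          n_fields = geom$n_fields) {
  good <- measurements[!measurements$border & !measurements$saturated &
                         !measurements$split, , drop = FALSE]
  if (nrow(good) < 2)
    return(structure(list(rbc_conc = NA_real_, mcv = NA_real_,
                          rdw = NA_real_, mch = NA_real_,
                          n_cells_measured = nrow(good),
                          n_cells_counted = nrow(measurements)),
                     class = "rbc_indices"))
  vol_ul <- imaged_blood_volume(geom, kit, n_fields)
  mcv <- mean(good$volume_fl)
  structure(list(
    rbc_conc = nrow(measurements) / (vol_ul * 1e6),
    mcv = mcv,
    rdw = 100 * sd(good$volume_fl) / mcv,
    mch = mean(good$hb_pg),
    n_cells_measured = nrow(good),
    n_cells_counted = nrow(measurements)),
    class = "rbc_indices")
}
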