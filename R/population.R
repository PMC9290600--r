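#' Sample a ground-truth blood cell population
#'
#' Draws the cells contained in a given blood-equivalent volume: counts per
#' kind are Poisson(concentration x volume), red-cell volumes are lognormal
#' with the configured mean/SD, per-cell hemoglobin mass derives from a
#' normal per-cell hemoglobin concentration around the population MCHC
#' implied by \code{hgb / (rbc_conc * mcv_mean) * 1000} so that total
#' hemoglobin over total cell volume matches the configured MCHC up to
#' sampling error. White cells receive a class from the configured fractions
#' and per-cell geometry/stain draws from the class table.
#'
#' @param params A \code{\link{population_params}} object.
#' @param sampled_volume Blood-equivalent volume sampled, microliters.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return An object of class \code{ground_truth_sample}: list with
#'   \code{cells} (one row per cell), \code{params}, \code{sampled_volume},
#'   \code{seed}.
#' @export
sample_cell_population <- function(params, sampled_volume, seed = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (sampled_volume <= 0) stopf("sampled_volume must be positive")
  with_seed(seed, {
    n_rbc <- rpois(1, params$rbc_conc * 1e6 * sampled_volume)
    n_wbc <- rpois(1, params$wbc_conc * 1e3 * sampled_volume)
    n_plt <- rpois(1, params$plt_conc * 1e3 * sampled_volume)
    n_deb <- rpois(1, params$debris_conc * 1e3 * sampled_volume)

    cells <- list()
    if (n_rbc > 0) {
      # lognormal volumes with the requested arithmetic mean/sd
      s2 <- log(1 + (params$mcv_sd / params$mcv_mean)^2)
      vol <- rlnorm(n_rbc, log(params$mcv_mean) - s2 / 2, sqrt(s2))
      mchc_pop <- if (params$rbc_conc > 0)
        params$hgb / (params$rbc_conc * params$mcv_mean) * 1000 else 0
      mchc <- pmax(5, rnorm(n_rbc, mchc_pop, params$mchc_sd))
      cells$rbc <- data.frame(
        kind = "rbc", class = NA_character_, volume = vol,
        hb_mass = mchc * vol / 100,         # (g/dl)*fl -> pg
        radius = rbc_radius(vol), mchc = mchc,
        nuc_r = 0, n_lobes = 0L, nuc_aspect = 1,
        sig_nuc = 0, sig_cyt = 0, sig_cyt365 = 0,
        gran_ch = 0L, gran_n = 0L, gran_amp = 0,
        stringsAsFactors = FALSE)
    }
    if (n_wbc > 0) {
      tab <- params$class_table
      fr <- params$wbc_class_fractions[tab$class]
      if (sum(fr) <= 0) stopf("wbc_conc > 0 requires nonzero class fractions")
      ki <- sample.int(nrow(tab), n_wbc, replace = TRUE, prob = fr)
      jr <- rlnorm(n_wbc, -params$cv_radius^2 / 2, params$cv_radius)
      js <- rlnorm(n_wbc, -params$cv_signal^2 / 2, params$cv_signal)
      cls <- tab$class[ki]
      mchc_pop <- if (params$rbc_conc > 0)
        params$hgb / (params$rbc_conc * params$mcv_mean) * 1000 else 33
      cells$wbc <- data.frame(
        kind = "wbc", class = cls, volume = tab$volume_fl[ki] * jr^3,
        hb_mass = ifelse(cls == "nrbc", mchc_pop * 70 / 100 * jr^3, 0),
        radius = tab$r_cell[ki] * jr, mchc = ifelse(cls == "nrbc", mchc_pop, 0),
        nuc_r = tab$nuc_r[ki] * jr, n_lobes = tab$n_lobes[ki],
        nuc_aspect = tab$nuc_aspect[ki],
        sig_nuc = tab$sig_nuc[ki] * js, sig_cyt = tab$sig_cyt[ki] * js,
        sig_cyt365 = tab$sig_cyt365[ki] * js,
        gran_ch = tab$gran_ch[ki], gran_n = tab$gran_n[ki],
        gran_amp = tab$gran_amp[ki],
        stringsAsFactors = FALSE)
    }
    if (n_plt > 0) {
      jr <- rlnorm(n_plt, 0, 0.15)
      js <- rlnorm(n_plt, 0, 0.2)
      cells$plt <- data.frame(
        kind = "plt", class = NA_character_, volume = 8 * jr^3, hb_mass = 0,
        radius = 1.3 * jr, mchc = 0,
        nuc_r = 0, n_lobes = 0L, nuc_aspect = 1,
        sig_nuc = 0, sig_cyt = 12 * js, sig_cyt365 = 0,
        gran_ch = 0L, gran_n = 0L, gran_amp = 0,
        stringsAsFactors = FALSE)
    }
    if (n_deb > 0) {
      sub <- sample(c("nuclear_fragment", "speckle"), n_deb, replace = TRUE)
      jr <- rlnorm(n_deb, 0, 0.25)
      cells$debris <- data.frame(
        kind = "debris", class = sub, volume = 0, hb_mass = 0,
        radius = ifelse(sub == "nuclear_fragment", 1.6, 1.0) * jr, mchc = 0,
        nuc_r = 0, n_lobes = 0L, nuc_aspect = 1,
        sig_nuc = ifelse(sub == "nuclear_fragment", 220, 0) *
          rlnorm(n_deb, 0, 0.2),
        sig_cyt = ifelse(sub == "speckle", 4, 0) * rlnorm(n_deb, 0, 0.2),
        sig_cyt365 = 0, gran_ch = 0L, gran_n = 0L, gran_amp = 0,
        stringsAsFactors = FALSE)
    }
    cells <- if (length(cells)) do.call(rbind, cells) else empty_cells()
    rownames(cells) <- NULL
    if (nrow(cells)) cells$uid <- seq_len(nrow(cells)) else cells$uid <- integer(0)
    structure(list(cells = cells, params = params,
                   sampled_volume = sampled_volume, seed = seed),
              class = "ground_truth_sample")
  })
}

empty_cells <- function() {
  data.frame(kind = character(0), class = character(0), volume = numeric(0),
             hb_mass = numeric(0), radius = numeric(0), mchc = numeric(0),
             nuc_r = numeric(0), n_lobes = integer(0), nuc_aspect = numeric(0),
             sig_nuc = numeric(0), sig_cyt = numeric(0),
             sig_cyt365 = numeric(0), gran_ch = integer(0),
             gran_n = integer(0), gran_amp = numeric(0),
             stringsAsFactors = FALSE)
}

# Red-cell footprint radius (um) from volume (fl): isometric scaling around a
# 90 fl cell of radius 3.6 um. The same relation, inverted, is the area ->
# volume mapping used by the measurement pipeline.
rbc_radius <- function(volume_fl, r_ref = 3.6, v_ref = 90) {
  r_ref * (volume_fl / v_ref)^(1 / 3)
}

#' Blood-equivalent volume imaged by a scan
#'
#' The diluted suspension settles onto the chamber floor; the column above
#' one field of area A and height h holds A*h/dilution of blood equivalent.
#'
#' @param geom A \code{\link{chamber_geometry}}.
#' @param kit A \code{\link{kit_config}}.
#' @param n_fields Number of fields (defaults to the geometry's).
#' @return Volume in microliters.
#' @export
imaged_blood_volume <- function(geom, kit, n_fields = geom$n_fields) {
  n_fields * geom$field_width * geom$field_height * geom$chamber_height /
    kit$dilution_factor / 1e9
}

#' Settle a sampled population into imaging fields
#'
#' Cells are assigned to fields uniformly at random and placed by random
#' sequential (hard-core) settling: positions are drawn uniformly within the
#' field and redrawn while the footprint would overlap an already settled
#' cell; after \code{max_tries} failures the cell is placed anyway, so every
#' cell of the sample lands in exactly one field. This mirrors monolayer
#' settling, in which cells exclude each other on the chamber floor and, for
#' the most part, do not overlap. The overlap graph lists the remaining
#' footprint intersections.
#'
#' @param sample A \code{\link{ground_truth_sample}} generated for the
#'   blood-equivalent volume implied by \code{geom} and \code{kit}
#'   (see \code{\link{imaged_blood_volume}}).
#' @param geom A \code{\link{chamber_geometry}}.
#' @param kit A \code{\link{kit_config}}.
#' @param seed Integer seed.
#' @param n_fields Number of fields to settle into (defaults to geometry).
#' @param hard_gap Hard-core multiplier on the sum of footprint radii
#'   (> 1 leaves a visible gap between settled neighbours).
#' @param max_tries Redraws before a cell is force-placed.
#' @return List of \code{field_truth} objects: \code{cells} with positions
#'   x/y (um, origin top-left, x = column), \code{overlap_pairs} (2-column
#'   matrix of row indices into \code{cells}) and \code{field_index}.
#' @export
settle_fields <- function(sample, geom, kit, seed = NULL,
                          n_fields = geom$n_fields,
                          hard_gap = 1.08, max_tries = 120) {
  stopifnot(inherits(sample, "ground_truth_sample"),
            inherits(geom, "chamber_geometry"), inherits(kit, "kit_config"))
  if (geom$field_width * geom$field_height * n_fields > geom$chamber_floor_area)
    stopf("requested fields exceed the chamber floor area")
  cells <- sample$cells
  with_seed(seed, {
    fidx <- if (nrow(cells)) sample.int(n_fields, nrow(cells), replace = TRUE)
            else integer(0)
    lapply(seq_len(n_fields), function(f) {
      fc <- cells[fidx == f, , drop = FALSE]
      rownames(fc) <- NULL
      if (nrow(fc)) {
        # settle large cells first, as denser cells reach the floor sooner;
        # also makes hard-core placement of the big WBC footprints reliable
        ord <- order(-fc$radius)
        fc <- fc[ord, , drop = FALSE]
        pl <- cpp_place(geom$field_width, geom$field_height,
                        fc$radius * hard_gap, max_tries)
        fc$x <- pl$x; fc$y <- pl$y; fc$forced <- pl$forced
        ov <- cpp_overlap_pairs(fc$x, fc$y, fc$radius)
      } else {
        fc$x <- numeric(0); fc$y <- numeric(0); fc$forced <- logical(0)
        ov <- matrix(integer(0), 0, 2)
      }
      structure(list(cells = fc, overlap_pairs = ov, field_index = f,
                     field_width = geom$field_width,
                     field_height = geom$field_height),
                class = "field_truth")
    })
  })
}
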