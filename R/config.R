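#' Test-kit configuration
#'
#' Volumes of the single-use kit: total blood drawn, the undiluted aliquot
#' feeding the hemoglobin chamber, the aliquot that is diluted and stained for
#' the imaging chamber, and the dilution factor applied to the imaging
#' aliquot (ratio of diluted mixture volume to blood volume).
#'
#' @param total_blood_volume Total sample volume, microliters.
#' @param hb_chamber_volume Undiluted volume filling the hemoglobin chamber,
#'   microliters.
#' @param imaging_draw_volume Blood volume mixed with diluent and stains for
#'   imaging, microliters.
#' @param dilution_factor Dimensionless dilution of the imaging aliquot
#'   (must exceed 1). The default is a simulator choice, tuned so that the
#'   settled red-cell monolayer remains mostly non-overlapping at the top of
#'   the physiological range (8e6/ul); the device's true ratio is unpublished.
#' @return An object of class \code{kit_config}.
#' @export
kit_config <- function(total_blood_volume = 27,
                       hb_chamber_volume = 17,
                       imaging_draw_volume = 10,
                       dilution_factor = 300) {
  if (hb_chamber_volume + imaging_draw_volume != total_blood_volume)
    stopf("hb_chamber_volume + imaging_draw_volume must equal total_blood_volume (%g + %g != %g)",
          hb_chamber_volume, imaging_draw_volume, total_blood_volume)
  if (dilution_factor <= 1) stopf("dilution_factor must exceed 1")
  structure(list(total_blood_volume = total_blood_volume,
                 hb_chamber_volume = hb_chamber_volume,
                 imaging_draw_volume = imaging_draw_volume,
                 dilution_factor = dilution_factor),
            class = "kit_config")
}

#' Optical configuration of the multispectral microscope
#'
#' Five illumination channels: violet/green/red brightfield (405/517/633 nm)
#' and UV/blue fluorescence excitation (365/460 nm). The blue-excited channel
#' is acquired at a longer exposure so that dim platelets stand above the
#' background. Hemoglobin extinction applies to the brightfield channels and
#' must be strictly greatest in the violet.
#'
#' @param channel_wavelengths Wavelengths in nm (exactly 5).
#' @param channel_kind "brightfield" or "fluorescence" per channel.
#' @param pixel_size Micrometers per pixel.
#' @param exposure_scale Dimensionless exposure multiplier per channel.
#' @param hb_extinction Absorbance per (g/dl)*um at each brightfield channel,
#'   named by wavelength.
#' @param noise Camera noise model: list with \code{gain} (shot-noise
#'   variance per count), \code{read_sd} (additive read noise, counts),
#'   \code{bf_background} and \code{fl_background} (counts), and
#'   \code{sat_level}.
#' @return An object of class \code{optics_config}.
#' @export
optics_config <- function(channel_wavelengths = c(405, 517, 633, 365, 460),
                          channel_kind = c("brightfield", "brightfield",
                                           "brightfield", "fluorescence",
                                           "fluorescence"),
                          pixel_size = 1.0,
                          exposure_scale = c(1, 1, 1, 1, 8),
                          hb_extinction = c("405" = 8e-3, "517" = 9e-4,
                                            "633" = 6e-5),
                          noise = list(gain = 0.05, read_sd = 2,
                                       bf_background = 1000,
                                       fl_background = 20,
                                       sat_level = 4095)) {
  if (length(channel_wavelengths) != 5 || length(channel_kind) != 5 ||
      length(exposure_scale) != 5)
    stopf("exactly 5 channels are required")
  if (!all(channel_kind %in% c("brightfield", "fluorescence")))
    stopf("channel_kind must be 'brightfield' or 'fluorescence'")
  bf <- channel_wavelengths[channel_kind == "brightfield"]
  ext <- hb_extinction[as.character(bf)]
  if (anyNA(ext)) stopf("hb_extinction must be named by brightfield wavelength")
  violet <- as.character(min(bf))
  if (!all(hb_extinction[violet] > ext[names(ext) != violet]))
    stopf("violet hb extinction must be strictly greatest among brightfield channels")
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  structure(list(channel_wavelengths = channel_wavelengths,
                 channel_kind = channel_kind,
                 pixel_size = pixel_size,
                 exposure_scale = exposure_scale,
                 hb_extinction = hb_extinction,
                 noise = noise),
            class = "optics_config")
}

#' Imaging-chamber geometry
#'
#' @param chamber_height Height of the settling column, micrometers
#'   (order "a few hundred").
#' @param field_width,field_height Imaged field size, micrometers.
#' @param n_fields Number of non-overlapping fields scanned (device scans at
#'   least 200).
#' @param chamber_floor_area Floor area available for non-overlapping fields,
#'   square micrometers.
#' @return An object of class \code{chamber_geometry}.
#' @export
chamber_geometry <- function(chamber_height = 300,
                             field_width = 500, field_height = 500,
                             n_fields = 200,
                             chamber_floor_area = 1.44e8) {
  vals <- c(chamber_height, field_width, field_height, n_fields,
            chamber_floor_area)
  if (any(vals <= 0)) stopf("all geometry values must be positive")
  if (field_width * field_height * n_fields > chamber_floor_area)
    stopf("field area x n_fields (%.3g um^2) exceeds chamber floor area (%.3g um^2)",
          field_width * field_height * n_fields, chamber_floor_area)
  structure(list(chamber_height = chamber_height,
                 field_width = field_width, field_height = field_height,
                 n_fields = n_fields,
                 chamber_floor_area = chamber_floor_area),
            class = "chamber_geometry")
}

#' White-cell class geometry and stain-response table
#'
#' Per-class rendering model: cell footprint radius, nucleus radius (total
#' nuclear area is preserved when split into lobes), lobe count, nuclear
#' aspect ratio, mean stain responses in the UV-excited (nuclear DNA stain)
#' and blue-excited (DNA/RNA and acidic-organelle stain) channels, granule
#' painting (channel, count, amplitude) and a nominal cell volume. Radii in
#' micrometers, intensities in camera counts at unit exposure.
#'
#' @return data.frame keyed by class, rows in the fixed class order used for
#'   classifier tie-breaking.
#' @export
wbc_class_table <- function() {
  data.frame(
    class = c("neutrophil", "lymphocyte", "monocyte", "eosinophil",
              "basophil", "blast", "immature_granulocyte",
              "atypical_lymphocyte", "nrbc"),
    r_cell   = c(6.0, 4.5, 8.0, 6.5, 5.5, 8.5, 7.0, 6.5, 4.5),
    nuc_r    = c(3.4, 3.2, 4.0, 3.6, 3.2, 6.8, 4.4, 4.0, 2.8),
    n_lobes  = c(3L, 1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L),
    nuc_aspect = c(1.0, 1.0, 1.9, 1.0, 1.0, 1.05, 1.3, 1.1, 1.0),
    sig_nuc  = c(300, 400, 250, 300, 280, 350, 320, 380, 450),
    sig_cyt  = c(80, 60, 50, 150, 70, 45, 80, 140, 40),
    sig_cyt365 = c(0, 0, 0, 0, 90, 0, 0, 0, 0),
    gran_ch  = c(0L, 0L, 0L, 2L, 1L, 0L, 0L, 0L, 0L),
    gran_n   = c(0L, 0L, 0L, 14L, 10L, 0L, 0L, 0L, 0L),
    gran_amp = c(0, 0, 0, 160, 150, 0, 0, 0, 0),
    volume_fl = c(330, 220, 470, 360, 290, 520, 420, 350, 240),
    stringsAsFactors = FALSE
  )
}

#' Blood population parameters for the simulator
#'
#' The stated world of the generator. Concentration and index defaults are
#' the normal-range pooled means of the device's whole-blood repeatability
#' study (WBC 9.26e3/ul, RBC 5.04e6/ul, PLT 309e3/ul, HGB 14.81 g/dl,
#' MCV 85.28 fl, RDW 15%). Red-cell volumes are lognormal; per-cell
#' hemoglobin concentration is normal around the population MCHC implied by
#' hgb/(rbc_conc*mcv).
#'
#' @param rbc_conc Red cells, 1e6/ul (device range roughly 2-8).
#' @param wbc_conc White cells, 1e3/ul (0.5-80).
#' @param plt_conc Platelets, 1e3/ul (9-800).
#' @param hgb Total hemoglobin, g/dl.
#' @param mcv_mean,mcv_sd Red-cell volume mean and SD, fl (RDW = 100*sd/mean).
#' @param mchc_sd Per-cell hemoglobin-concentration SD, g/dl.
#' @param wbc_class_fractions Named fractions over the nine white-cell
#'   classes (five normal plus blast, immature granulocyte, atypical
#'   lymphocyte, nucleated RBC); must be non-negative and sum to 1.
#' @param debris_conc Debris objects (nuclear fragments, dim speckles),
#'   1e3/ul; provides true negatives for the candidate filters.
#' @param class_table Stain/geometry table, see \code{\link{wbc_class_table}}.
#' @param cv_radius,cv_signal Lognormal coefficients of variation applied per
#'   cell to class radii and stain responses.
#' @return An object of class \code{population_params}.
#' @export
population_params <- function(rbc_conc = 5.04, wbc_conc = 9.26,
                              plt_conc = 309, hgb = 14.81,
                              mcv_mean = 85.28, mcv_sd = 12.8,
                              mchc_sd = 1.2,
                              wbc_class_fractions = c(
                                neutrophil = 0.6683, lymphocyte = 0.2262,
                                monocyte = 0.0774, eosinophil = 0.0229,
                                basophil = 0.0052, blast = 0,
                                immature_granulocyte = 0,
                                atypical_lymphocyte = 0, nrbc = 0),
                              debris_conc = 2.0,
                              class_table = wbc_class_table(),
                              cv_radius = 0.06, cv_signal = 0.12) {
  if (any(c(rbc_conc, wbc_conc, plt_conc, hgb, debris_conc) < 0))
    stopf("concentrations must be non-negative")
  if (mcv_sd < 0) stopf("mcv_sd must be non-negative")
  fr <- wbc_class_fractions
  if (is.null(names(fr)) || !all(names(fr) %in% class_table$class))
    stopf("wbc_class_fractions must be named by white-cell class")
  if (any(fr < 0)) stopf("wbc_class_fractions must be non-negative")
  if (sum(fr) > 0 && abs(sum(fr) - 1) > 1e-9)
    stopf("wbc_class_fractions must sum to 1 (got %.12g)", sum(fr))
  full <- setNames(numeric(nrow(class_table)), class_table$class)
  full[names(fr)] <- fr
  structure(list(rbc_conc = rbc_conc, wbc_conc = wbc_conc,
                 plt_conc = plt_conc, hgb = hgb,
                 mcv_mean = mcv_mean, mcv_sd = mcv_sd, mchc_sd = mchc_sd,
                 wbc_class_fractions = full, debris_conc = debris_conc,
                 class_table = class_table,
                 cv_radius = cv_radius, cv_signal = cv_signal),
            class = "population_params")
}

#' Hemoglobin photometry configuration
#'
#' Four measurement wavelengths and at least two optical path lengths. The
#' absorbance model is A(lambda, L) = eps(lambda)*hgb*L + s_coef*s(lambda)*L
#' + offset(lambda): linear absorption plus a scattering term with a fixed
#' spectral basis, plus a path-independent offset (illumination and
#' manufacturing tolerances) that differential measurements cancel. The
#' device's actual wavelengths are unpublished; defaults are placeholders in
#' the green-red region where whole-blood absorbance stays in a measurable
#' range at these path lengths.
#'
#' @param wavelengths 4 wavelengths, nm.
#' @param path_lengths >= 2 distinct optical path lengths, micrometers.
#' @param epsilon Hemoglobin absorptivity per (g/dl)*um at each wavelength.
#' @param scattering Scattering spectral basis s(lambda), per um.
#' @param offset Path-independent absorbance offset per wavelength.
#' @param noise_sd Absorbance measurement noise SD.
#' @param cal_slope,cal_offset Linear calibration applied to the solved
#'   concentration.
#' @return An object of class \code{hb_photometry_config}.
#' @export
hb_photometry_config <- function(wavelengths = c(500, 570, 600, 660),
                                 path_lengths = c(50, 150),
                                 epsilon = c(9e-4, 6e-4, 3e-4, 8e-5),
                                 scattering = 1e-5 * (500 / wavelengths)^4,
                                 offset = c(0.05, 0.04, 0.03, 0.02),
                                 noise_sd = 0.01,
                                 cal_slope = 1, cal_offset = 0) {
  if (length(wavelengths) != 4) stopf("exactly 4 wavelengths are required")
  if (length(unique(path_lengths)) < 2)
    stopf("at least 2 distinct path lengths are required")
  if (length(epsilon) != 4 || length(scattering) != 4 || length(offset) != 4)
    stopf("epsilon, scattering and offset must have one value per wavelength")
  if (!any(epsilon > 0)) stopf("epsilon must be positive at >= 1 wavelength")
  structure(list(wavelengths = wavelengths,
                 path_lengths = sort(path_lengths),
                 epsilon = epsilon, scattering = scattering, offset = offset,
                 noise_sd = noise_sd,
                 cal_slope = cal_slope, cal_offset = cal_offset),
            class = "hb_photometry_config")
}

#' Flagging thresholds and distributional reference ranges
#'
#' A morphological flag (nrbc, blast, immature granulocyte, atypical
#' lymphocyte) is raised when at least \code{min_cells} cells of the class
#' are seen AND they make up at least \code{min_fraction} of classified white
#' cells. The distributional flag is raised when any five-part differential
#' percentage falls outside its reference range.
#'
#' @param min_cells Minimum abnormal-class cell count per flag.
#' @param min_fraction Minimum abnormal-class fraction (of classified WBC).
#' @param reference_ranges Named list of c(low, high) percentage ranges for
#'   NEUT/LYMPH/MONO/EOS/BASO percentages.
#' @return An object of class \code{flag_thresholds}.
#' @export
flag_thresholds <- function(min_cells = 10, min_fraction = 0.01,
                            reference_ranges = list(
                              NEUT = c(40, 75), LYMPH = c(20, 45),
                              MONO = c(2, 10), EOS = c(0, 6),
                              BASO = c(0, 2))) {
  if (min_cells < 0 || min_fraction < 0) stopf("thresholds must be >= 0")
  structure(list(min_cells = min_cells, min_fraction = min_fraction,
                 reference_ranges = reference_ranges),
            class = "flag_thresholds")
}

#' Failsafe validity rules
#'
#' Contract-level stand-ins for the device's internal validity system: the
#' run is invalid overall when too few fields were analyzed or the focus
#' proxy (median background sharpness) falls below a floor; individual
#' measurands are invalidated when too few events support them.
#'
#' @param min_fields Minimum analyzed fields for an overall-valid run.
#' @param min_focus Floor on the focus proxy (0 disables).
#' @param min_wbc_events Minimum classified WBC for any differential result.
#' @param min_class_events Minimum events for a subclass percentage/count.
#' @param min_rbc_events Minimum red cells measured for RBC-derived indices.
#' @param min_plt_events Minimum accepted platelets for PLT.
#' @return An object of class \code{failsafe_rules}.
#' @export
failsafe_rules <- function(min_fields = 100, min_focus = 0,
                           min_wbc_events = 50, min_class_events = 10,
                           min_rbc_events = 100, min_plt_events = 10) {
  structure(list(min_fields = min_fields, min_focus = min_focus,
                 min_wbc_events = min_wbc_events,
                 min_class_events = min_class_events,
                 min_rbc_events = min_rbc_events,
                 min_plt_events = min_plt_events),
            class = "failsafe_rules")
}
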