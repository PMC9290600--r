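# Shared fixtures: small geometries keep unit tests fast; acceptance tests
# use the package defaults.

small_geom <- function(n_fields = 4)
  chamber_geometry(field_width = 150, field_height = 150, n_fields = n_fields)

# Field truth built directly from a cell table (positions preset), bypassing
# the settler -- used to stage exact scenes for the pipelines.
manual_truth <- function(cells, width = 100, height = 100, index = 1) {
  structure(list(cells = cells, overlap_pairs = matrix(integer(0), 0, 2),
                 field_index = index, field_width = width,
                 field_height = height),
            class = "field_truth")
}

# One truth row per call; defaults are a generic red cell.
truth_row <- function(kind = "rbc", class = NA_character_, x = 50, y = 50,
                      volume = 90, hb_mass = 30, radius = NULL, mchc = NULL,
                      nuc_r = 0, n_lobes = 0L, nuc_aspect = 1,
                      sig_nuc = 0, sig_cyt = 0, sig_cyt365 = 0,
                      gran_ch = 0L, gran_n = 0L, gran_amp = 0, uid = 1L) {
  if (is.null(radius))
    radius <- if (kind == "rbc") cbcsim:::rbc_radius(volume) else 1.3
  if (is.null(mchc)) mchc <- if (kind == "rbc") 100 * hb_mass / volume else 0
  data.frame(kind = kind, class = class, volume = volume, hb_mass = hb_mass,
             radius = radius, mchc = mchc, nuc_r = nuc_r, n_lobes = n_lobes,
             nuc_aspect = nuc_aspect, sig_nuc = sig_nuc, sig_cyt = sig_cyt,
             sig_cyt365 = sig_cyt365, gran_ch = gran_ch, gran_n = gran_n,
             gran_amp = gran_amp, uid = uid, x = x, y = y, forced = FALSE,
             stringsAsFactors = FALSE)
}

wbc_truth_row <- function(class, x = 50, y = 50, uid = 1L, sig_scale = 1,
                          rad_scale = 1) {
  tab <- wbc_class_table()
  k <- match(class, tab$class)
  truth_row(kind = "wbc", class = class, x = x, y = y,
            volume = tab$volume_fl[k],
            hb_mass = if (class == "nrbc") 23 else 0,
            radius = tab$r_cell[k] * rad_scale,
            mchc = if (class == "nrbc") 33 else 0,
            nuc_r = tab$nuc_r[k] * rad_scale, n_lobes = tab$n_lobes[k],
            nuc_aspect = tab$nuc_aspect[k],
            sig_nuc = tab$sig_nuc[k] * sig_scale,
            sig_cyt = tab$sig_cyt[k] * sig_scale,
            sig_cyt365 = tab$sig_cyt365[k] * sig_scale,
            gran_ch = tab$gran_ch[k], gran_n = tab$gran_n[k],
            gran_amp = tab$gran_amp[k], uid = uid)
}

# A classifier shared across tests (training is the expensive step).
shared_classifier <- local({
  clf <- NULL
  function() {
    if (is.null(clf))
      clf <<- default_wbc_classifier(n = 360, seed = 42)
    clf
  }
})

# Draw physiologically linked population parameters for recovery sweeps:
# hgb co-varies with the red-cell mass so MCHC stays in range.
random_population <- function(seed) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    rbc <- runif(1, 2, 8)
    mcv <- runif(1, 75, 95)
    mchc <- runif(1, 31, 36)
    population_params(
      rbc_conc = rbc,
      wbc_conc = 10^runif(1, log10(0.5), log10(80)),
      plt_conc = runif(1, 20, 800),
      hgb = rbc * mcv * mchc / 1000,
      mcv_mean = mcv, mcv_sd = 0.15 * mcv)
  })
}
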