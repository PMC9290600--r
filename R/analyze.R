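# --- end-to-end simulation and analysis ---------------------------------------

#' Simulate one blood sample scan
#'
#' Draws the ground-truth population for the imaged blood-equivalent volume,
#' settles it into fields, and renders the hemoglobin-chamber absorbances.
#' Field micrographs are rendered lazily (per field, by
#' \code{\link{analyze_sample}} or \code{\link{render_field}}) so that a full
#' scan never holds all rasters in memory at once.
#'
#' @param params \code{\link{population_params}}.
#' @param geom \code{\link{chamber_geometry}}.
#' @param kit \code{\link{kit_config}}.
#' @param optics \code{\link{optics_config}}.
#' @param photometry \code{\link{hb_photometry_config}}.
#' @param seed Integer seed controlling population, settling, absorbance
#'   noise, and per-field render noise.
#' @param n_fields Number of fields (defaults to the geometry's).
#' @return Object of class \code{cbc_sim}: \code{sample}, \code{fields}
#'   (list of \code{field_truth}), \code{absorbances}, configs, seed.
#' @export
simulate_sample <- function(params = population_params(),
                            geom = chamber_geometry(),
                            kit = kit_config(),
                            optics = optics_config(),
                            photometry = hb_photometry_config(),
                            seed = 1, n_fields = geom$n_fields) {
  vol <- imaged_blood_volume(geom, kit, n_fields)
  sample <- sample_cell_population(params, vol, seed = child_seed(seed, 1))
  fields <- settle_fields(sample, geom, kit, seed = child_seed(seed, 2),
                          n_fields = n_fields)
  absorbances <- render_hb_chamber(params, photometry,
                                   seed = child_seed(seed, 3))
  structure(list(sample = sample, fields = fields, absorbances = absorbances,
                 params = params, geom = geom, kit = kit, optics = optics,
                 photometry = photometry, seed = seed, n_fields = n_fields),
            class = "cbc_sim")
}

# Focus proxy: RMS of the discrete Laplacian of the violet channel relative
# to its background level. In-focus fields carry sharp cell edges, so the
# statistic collapses when the render is blurred or empty of structure.
focus_proxy <- function(field) {
  I <- field$channels[[violet_channel(field)]]
  nr <- nrow(I); nc <- ncol(I)
  if (nr < 3 || nc < 3) return(0)
  core <- I[2:(nr - 1), 2:(nc - 1)]
  lap <- 4 * core - I[1:(nr - 2), 2:(nc - 1)] - I[3:nr, 2:(nc - 1)] -
    I[2:(nr - 1), 1:(nc - 2)] - I[2:(nr - 1), 3:nc]
  sqrt(mean(lap^2)) / median(I)
}

#' Analyze a simulated scan into a CBC report
#'
#' Renders each field under the scan seed and runs the three cell pipelines,
#' then the photometry inversion, and compiles the report with flags and
#' validity verdicts. Per-field rasters are discarded as soon as they are
#' measured.
#'
#' @param sim A \code{cbc_sim} from \code{\link{simulate_sample}}.
#' @param classifier A \code{wbc_classifier}; without one the white-cell
#'   pipeline reports candidates but no classes (and the report invalidates
#'   the differential).
#' @param rbc_thr,wbc_thr,plt_thr Pipeline thresholds.
#' @param flags,rules Flagging thresholds and validity rules.
#' @param keep_cells Keep the per-cell tables in the result (memory).
#' @return List of class \code{cbc_analysis}: \code{report},
#'   \code{rbc_indices}, \code{wbc_counts}, \code{plt_count}, \code{hgb},
#'   \code{n_fields}, and per-cell tables when requested.
#' @export
analyze_sample <- function(sim, classifier = NULL,
                           rbc_thr = rbc_thresholds(),
                           wbc_thr = wbc_thresholds(),
                           plt_thr = plt_thresholds(),
                           flags = flag_thresholds(),
                           rules = failsafe_rules(),
                           keep_cells = FALSE) {
  stopifnot(inherits(sim, "cbc_sim"))
  rbc_all <- list(); wbc_all <- list()
  plt_n <- 0L
  focus <- numeric(length(sim$fields))
  for (i in seq_along(sim$fields)) {
    fld <- render_field(sim$fields[[i]], sim$optics,
                        seed = child_seed(sim$seed, 100 + i))
    ctx <- field_context(fld)
    rbc_all[[i]] <- rbc_pipeline(fld, sim$optics, rbc_thr, ctx = ctx)
    wbc_all[[i]] <- wbc_pipeline(fld, classifier, wbc_thr, ctx = ctx)
    plt_n <- plt_n + nrow(plt_pipeline(fld, plt_thr, ctx = ctx))
    focus[i] <- focus_proxy(fld)
  }
  rbc_cells <- do.call(rbind, rbc_all)
  wbc_cells <- do.call(rbind, wbc_all)
  rbc_idx <- aggregate_rbc(rbc_cells, sim$geom, sim$kit,
                           n_fields = length(sim$fields))
  wbc_counts <- NULL
  if (!is.null(classifier)) {
    cls <- wbc_cells$class[!wbc_cells$rejected & !is.na(wbc_cells$class)]
    wbc_counts <- table(factor(cls, levels = c(wbc_normal_classes,
                                               wbc_abnormal_classes)))
    wbc_counts <- setNames(as.integer(wbc_counts), names(wbc_counts))
  }
  hgb <- estimate_hgb(sim$absorbances, sim$photometry)
  report <- compile_cbc(rbc = rbc_idx, wbc_counts = wbc_counts,
                        plt_count = plt_n, hgb = hgb,
                        geom = sim$geom, kit = sim$kit,
                        n_fields = length(sim$fields),
                        thresholds = flags, rules = rules,
                        focus = median(focus))
  out <- list(report = report, rbc_indices = rbc_idx,
              wbc_counts = wbc_counts, plt_count = plt_n, hgb = hgb,
              n_fields = length(sim$fields),
              n_wbc_candidates = nrow(wbc_cells))
  if (keep_cells) {
    out$rbc_cells <- rbc_cells
    out$wbc_cells <- wbc_cells
  }
  class(out) <- "cbc_analysis"
  out
}
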