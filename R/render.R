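#' Render a settled field into a five-channel micrograph
#'
#' Physics of the renderer: brightfield channels obey Beer-Lambert,
#' I = background * 10^(-OD), with per-pixel OD equal to the channel's
#' hemoglobin extinction times the hemoglobin optical path density along the
#' cell footprint (a biconcave radial profile for red cells, a flat footprint
#' for nucleated red cells). The UV-excited channel carries the nuclear DNA
#' stain; the blue-excited channel carries the cytoplasmic (DNA/RNA/organelle)
#' stain at a longer exposure, where platelets render dim because of their low
#' RNA content. Shot noise (Gaussian, variance = gain * signal) plus read
#' noise is added to every channel.
#'
#' @param truth A \code{field_truth} from \code{\link{settle_fields}}.
#' @param optics An \code{\link{optics_config}} (must match pixel geometry).
#' @param seed Integer seed; identical seeds give bit-identical rasters.
#' @param noise_free Disable all noise (calibration and oracle tests).
#' @return An object of class \code{ms_field}: \code{channels} (list of 5
#'   equal-shape matrices), \code{pixel_size}, \code{channel_meta}
#'   (wavelength, kind, exposure), \code{field_index}.
#' @export
render_field <- function(truth, optics, seed = NULL, noise_free = FALSE) {
  stopifnot(inherits(truth, "field_truth"), inherits(optics, "optics_config"))
  px <- optics$pixel_size
  ncol <- round(truth$field_width / px)
  nrow <- round(truth$field_height / px)
  with_seed(seed, {
    prim <- build_primitives(truth$cells)
    rast <- cpp_paint(nrow, ncol, px, prim$x, prim$y, prim$rx, prim$ry,
                      prim$theta, prim$channel, prim$amp, prim$profile, 2L)
    nm <- optics$noise
    channels <- vector("list", 5)
    for (k in 1:5) {
      wl <- optics$channel_wavelengths[k]
      if (optics$channel_kind[k] == "brightfield") {
        eps <- optics$hb_extinction[[as.character(wl)]]
        I <- nm$bf_background * optics$exposure_scale[k] * 10^(-eps * rast$hb)
      } else {
        sig <- if (wl < 420) rast$f365 else rast$f460
        I <- optics$exposure_scale[k] * (nm$fl_background + sig)
      }
      if (!noise_free)
        I <- I + rnorm(length(I)) * sqrt(nm$gain * pmax(I, 0) + nm$read_sd^2)
      I <- pmin(matrix(pmax(I, 0), nrow, ncol), nm$sat_level)
      channels[[k]] <- I
    }
    structure(list(channels = channels, pixel_size = px,
                   channel_meta = data.frame(
                     wavelength_nm = optics$channel_wavelengths,
                     kind = optics$channel_kind,
                     exposure_scale = optics$exposure_scale,
                     stringsAsFactors = FALSE),
                   field_index = truth$field_index),
              class = "ms_field")
  })
}

# Expand the per-cell truth table into paintable elliptical primitives.
# Channel codes: 0 hemoglobin path density, 1 UV-excited, 2 blue-excited.
# Profiles: 0 flat, 1 biconcave, 3 dome. Uses the RNG (lobe angles, granule
# positions); callers fix the seed. Vectorised per kind: fields hold many
# hundreds of red cells, so per-cell data.frame construction is avoided.
build_primitives <- function(cells) {
  xs <- list(); k <- 0L
  add <- function(x, y, rx, ry = rx, theta = 0, channel, amp, profile) {
    n <- length(x)
    if (!n) return(invisible())
    k <<- k + 1L
    xs[[k]] <<- list(x = x, y = y, rx = rx,
                     ry = if (length(ry) == n) ry else rep(ry, n),
                     theta = if (length(theta) == n) theta else rep(theta, n),
                     channel = rep_len(as.integer(channel), n),
                     amp = rep_len(amp, n),
                     profile = rep_len(as.integer(profile), n))
  }
  J <- .biconcave_const$J
  rbc <- cells[cells$kind == "rbc", , drop = FALSE]
  # optical path density integrates to mchc * volume = 100 * hb_mass
  add(rbc$x, rbc$y, rbc$radius, channel = 0L,
      amp = rbc$mchc * rbc$volume / (J * rbc$radius^2), profile = 1L)
  plt <- cells[cells$kind == "plt", , drop = FALSE]
  add(plt$x, plt$y, plt$radius, channel = 2L, amp = plt$sig_cyt, profile = 3L)
  deb <- cells[cells$kind == "debris", , drop = FALSE]
  dn <- deb[deb$sig_nuc > 0, , drop = FALSE]
  add(dn$x, dn$y, dn$radius, channel = 1L, amp = dn$sig_nuc, profile = 3L)
  dc <- deb[deb$sig_cyt > 0, , drop = FALSE]
  add(dc$x, dc$y, dc$radius, channel = 2L, amp = dc$sig_cyt, profile = 3L)
  wbc <- cells[cells$kind == "wbc", , drop = FALSE]
  for (i in seq_len(nrow(wbc))) {
    cl <- wbc[i, ]
    # cytoplasm: blue-excited stain over the whole-cell footprint
    add(cl$x, cl$y, cl$radius, channel = 2L, amp = cl$sig_cyt, profile = 3L)
    if (cl$sig_cyt365 > 0)   # basophil-like granules stain in UV channel
      add(cl$x, cl$y, cl$radius, channel = 1L, amp = cl$sig_cyt365,
          profile = 3L)
    # nucleus: one ellipse or several lobes of preserved total area; the
    # nuclear stain also appears (weaker) in the blue-excited channel
    if (cl$n_lobes <= 1) {
      asp <- sqrt(cl$nuc_aspect)
      th <- runif(1, 0, pi)
      add(cl$x, cl$y, cl$nuc_r * asp, cl$nuc_r / asp, th,
          channel = 1L, amp = cl$sig_nuc, profile = 3L)
      add(cl$x, cl$y, cl$nuc_r * asp, cl$nuc_r / asp, th,
          channel = 2L, amp = 0.35 * cl$sig_nuc, profile = 3L)
    } else {
      nl <- cl$n_lobes
      rl <- cl$nuc_r / sqrt(nl) * 1.15   # slight lobe overlap
      off <- min(0.42 * cl$radius, cl$radius - rl - 0.5)
      ang <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(nl) / nl +
        rnorm(nl, 0, 0.25)
      lx <- cl$x + off * cos(ang); ly <- cl$y + off * sin(ang)
      add(lx, ly, rep(rl, nl), channel = 1L, amp = cl$sig_nuc, profile = 3L)
      add(lx, ly, rep(rl, nl), channel = 2L, amp = 0.35 * cl$sig_nuc,
          profile = 3L)
    }
    if (cl$gran_n > 0) {     # granules scattered over the cytoplasm
      gr <- runif(cl$gran_n, 0.45, 0.92) * cl$radius
      ga <- runif(cl$gran_n, 0, 2 * pi)
      add(cl$x + gr * cos(ga), cl$y + gr * sin(ga), rep(0.6, cl$gran_n),
          channel = cl$gran_ch, amp = cl$gran_amp, profile = 3L)
    }
    if (cl$class %in% "nrbc" && cl$hb_mass > 0)  # hemoglobin-positive footprint
      add(cl$x, cl$y, cl$radius, channel = 0L,
          amp = 100 * cl$hb_mass / (pi * cl$radius^2), profile = 0L)
  }
  if (!k)
    return(list(x = numeric(0), y = numeric(0), rx = numeric(0),
                ry = numeric(0), theta = numeric(0),
                channel = integer(0), amp = numeric(0), profile = integer(0)))
  nm <- names(xs[[1]])
  setNames(lapply(nm, function(f) unlist(lapply(xs, `[[`, f),
                                        use.names = FALSE)), nm)
}

#' Render hemoglobin-chamber absorbances
#'
#' Absorbance at each photometry wavelength and optical path length:
#' A(lambda, L) = eps(lambda)*hgb*L + s(lambda)*L + offset(lambda) + noise.
#' The scattering term enters with unit coefficient; the estimator solves for
#' it jointly with the concentration.
#'
#' @param params A \code{\link{population_params}} (supplies \code{hgb}).
#' @param photometry A \code{\link{hb_photometry_config}}.
#' @param seed Integer seed for measurement noise.
#' @param noise_free Disable measurement noise.
#' @return Object of class \code{hb_absorbance_set}: matrix \code{A}
#'   (wavelengths x path lengths), \code{wavelengths}, \code{path_lengths},
#'   \code{noise_sd}.
#' @export
render_hb_chamber <- function(params, photometry, seed = NULL,
                              noise_free = FALSE) {
  stopifnot(inherits(photometry, "hb_photometry_config"))
  hgb <- if (inherits(params, "population_params")) params$hgb else params
  if (hgb < 0) stopf("hgb must be non-negative")
  if (length(photometry$path_lengths) < 2)
    stopf("at least 2 path lengths are required")
  with_seed(seed, {
    A <- outer(photometry$epsilon * hgb + photometry$scattering,
               photometry$path_lengths) + photometry$offset
    if (!noise_free)
      A <- A + rnorm(length(A), 0, photometry$noise_sd)
    A <- pmax(A, 0)
    dimnames(A) <- list(photometry$wavelengths, photometry$path_lengths)
    structure(list(A = A, wavelengths = photometry$wavelengths,
                   path_lengths = photometry$path_lengths,
                   noise_sd = photometry$noise_sd),
              class = "hb_absorbance_set")
  })
}

#' Render a labelled gallery of single white cells
#'
#' Small single-cell crops for classifier training and evaluation: each crop
#' holds exactly one white cell of a known class, rendered with the standard
#' field renderer on a quiet background. This is the package's stand-in for
#' the expert-labelled cell archives used to train production classifiers.
#'
#' @param n Number of cells.
#' @param params A \code{\link{population_params}} (class table and jitter).
#' @param optics An \code{\link{optics_config}}.
#' @param classes Classes to draw from (uniformly); default the five normal
#'   classes.
#' @param crop_um Crop side, micrometers.
#' @param seed Integer seed.
#' @return List with \code{fields} (list of \code{ms_field}) and
#'   \code{labels} (character vector).
#' @export
render_wbc_gallery <- function(n, params = population_params(),
                               optics = optics_config(),
                               classes = c("neutrophil", "lymphocyte",
                                           "monocyte", "eosinophil",
                                           "basophil"),
                               crop_um = 28, seed = NULL) {
  tab <- params$class_table
  stopifnot(all(classes %in% tab$class))
  with_seed(seed, {
    lab <- sample(classes, n, replace = TRUE)
    fields <- lapply(seq_len(n), function(i) {
      ki <- match(lab[i], tab$class)
      jr <- rlnorm(1, -params$cv_radius^2 / 2, params$cv_radius)
      js <- rlnorm(1, -params$cv_signal^2 / 2, params$cv_signal)
      cells <- empty_cells()
      cells[1, ] <- NA
      cells$kind <- "wbc"; cells$class <- lab[i]
      cells$volume <- tab$volume_fl[ki] * jr^3
      cells$hb_mass <- if (lab[i] == "nrbc") 23 * jr^3 else 0
      cells$radius <- tab$r_cell[ki] * jr
      cells$mchc <- if (lab[i] == "nrbc") 33 else 0
      cells$nuc_r <- tab$nuc_r[ki] * jr
      cells$n_lobes <- tab$n_lobes[ki]
      cells$nuc_aspect <- tab$nuc_aspect[ki]
      cells$sig_nuc <- tab$sig_nuc[ki] * js
      cells$sig_cyt <- tab$sig_cyt[ki] * js
      cells$sig_cyt365 <- tab$sig_cyt365[ki] * js
      cells$gran_ch <- tab$gran_ch[ki]; cells$gran_n <- tab$gran_n[ki]
      cells$gran_amp <- tab$gran_amp[ki]
      cells$uid <- i
      cells$x <- crop_um / 2; cells$y <- crop_um / 2; cells$forced <- FALSE
      truth <- structure(list(cells = cells,
                              overlap_pairs = matrix(integer(0), 0, 2),
                              field_index = i, field_width = crop_um,
                              field_height = crop_um),
                         class = "field_truth")
      render_field(truth, optics)
    })
    list(fields = fields, labels = lab)
  })
}
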