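#' Estimate total hemoglobin from chamber absorbances
#'
#' The hemoglobin chamber is filled with undiluted whole blood and read at
#' four wavelengths through measurement areas of different optical path
#' length. Differential absorbances between the longest and shortest path,
#' Delta A(lambda) = A(lambda, L2) - A(lambda, L1), cancel every
#' path-independent offset (illumination intensity, window losses,
#' manufacturing tolerances). The remaining model
#' Delta A(lambda) = (eps(lambda) * c + s_coef * s(lambda)) * Delta L
#' is solved for the concentration c and a scattering coefficient by least
#' squares over the four wavelengths; c is clipped at zero (with a warning)
#' and passed through the linear calibration.
#'
#' @param absorbances An \code{hb_absorbance_set} from
#'   \code{\link{render_hb_chamber}} (or a compatible list with \code{A},
#'   \code{wavelengths}, \code{path_lengths}).
#' @param config The \code{\link{hb_photometry_config}} describing the
#'   measurement.
#' @return Estimated hemoglobin concentration, g/dl.
#' @export
estimate_hgb <- function(absorbances, config) {
  stopifnot(inherits(config, "hb_photometry_config"))
  A <- absorbances$A
  if (!all(absorbances$wavelengths == config$wavelengths))
    stopf("absorbance wavelengths do not match the photometry config")
  L <- absorbances$path_lengths
  if (length(L) < 2) stopf("at least 2 path lengths are required")
  if (!all(L %in% config$path_lengths))
    stopf("absorbance path lengths do not match the photometry config")
  # collinear absorption and scattering spectra leave (c, s) unidentifiable
  e <- config$epsilon; s <- config$scattering
  if (sd(e) > 0 && sd(s) > 0 && abs(cor(e, s)) > 1 - 1e-10)
    stopf("singular design: scattering basis proportional to absorptivity")
  i1 <- which.min(L); i2 <- which.max(L)
  dA <- A[, i2] - A[, i1]
  dL <- L[i2] - L[i1]
  X <- cbind(hgb = e * dL, scatter = s * dL)
  beta <- qr.solve(X, dA)
  c_hat <- beta[["hgb"]]
  if (c_hat < 0) {
    warning("negative hemoglobin solution clipped to 0", call. = FALSE)
    c_hat <- 0
  }
  config$cal_slope * c_hat + config$cal_offset
}
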