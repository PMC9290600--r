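# --- WBC pipeline ------------------------------------------------------------

#' Detection thresholds for the white-cell pipeline
#'
#' @param nuc_min Minimum exposure-normalized excess over background in the
#'   UV-excited (nuclear stain) channel, counts.
#' @param cyt_min Same for the blue-excited (cytoplasmic stain) channel.
#' @param min_nuc_area Minimum nucleus area, square micrometers.
#' @param min_cell_area,max_cell_area Whole-cell area bounds ("filtered
#'   according to size"), square micrometers.
#' @param min_cyt_area Minimum cytoplasm area after segmentation.
#' @param min_roundness Shape bound on the whole-cell mask.
#' @return List of thresholds.
#' @export
wbc_thresholds <- function(nuc_min = 60, cyt_min = 12,
                           min_nuc_area = 4,
                           min_cell_area = 25, max_cell_area = 600,
                           min_cyt_area = 5, min_roundness = 0.25) {
  list(nuc_min = nuc_min, cyt_min = cyt_min, min_nuc_area = min_nuc_area,
       min_cell_area = min_cell_area, max_cell_area = max_cell_area,
       min_cyt_area = min_cyt_area, min_roundness = min_roundness)
}

# Exposure-normalized excess fluorescence over background for one channel.
fluor_excess <- function(field, wavelength) {
  k <- channel_index(field, wavelength = wavelength, kind = "fluorescence")
  ex <- field$channel_meta$exposure_scale[k]
  I <- field$channels[[k]] / ex
  bg <- estimate_background(I, dark_objects = FALSE)
  list(excess = I - bg$level, sigma = bg$sigma, index = k)
}

#' Detect white-cell candidates
#'
#' A white cell must show both its nucleus (UV-excited DNA stain) and its
#' cytoplasm (blue-excited stain): connected components of the combined
#' fluorescence mask are kept when they contain enough nuclear signal and
#' pass the size and shape filters. Anucleate objects (red cells, platelets,
#' dim speckles) and nuclear-only fragments fail one of the two requirements.
#'
#' @param field An \code{ms_field} with both fluorescence channels.
#' @param thresholds See \code{\link{wbc_thresholds}}.
#' @param ctx Optional precomputed \code{field_context} rasters.
#' @return Object of class \code{wbc_candidates}: label raster of candidate
#'   cells, per-candidate bounding boxes, the two excess rasters, and the
#'   number of raw components rejected by the size/shape filter.
#' @export
detect_wbc_candidates <- function(field, thresholds = wbc_thresholds(),
                                  ctx = NULL) {
  stopifnot(inherits(field, "ms_field"))
  meta <- field$channel_meta
  fl <- meta$wavelength_nm[meta$kind == "fluorescence"]
  if (length(fl) < 2) stopf("both fluorescence channels must be present")
  nuc <- if (!is.null(ctx)) ctx$nuc else fluor_excess(field, min(fl))
  cyt <- if (!is.null(ctx)) ctx$cyt else fluor_excess(field, max(fl))
  px <- field$pixel_size
  nuc_mask <- nuc$excess > thresholds$nuc_min
  cell_mask <- (cyt$excess > thresholds$cyt_min) | nuc_mask
  lab <- cpp_label(cell_mask, 8L)
  nlab <- max(lab)
  boxes <- list(); rejected <- 0L
  if (nlab > 0) {
    st <- cpp_label_stats(lab, nuc$excess * nuc_mask, nlab)
    nuc_area <- cpp_label_stats(lab, nuc_mask + 0, nlab)[, 2]
    for (l in seq_len(nlab)) {
      area <- st[l, 1] * px^2
      na <- nuc_area[l] * px^2
      if (area < thresholds$min_cell_area || area > thresholds$max_cell_area ||
          na < thresholds$min_nuc_area) {
        if (area >= 1) rejected <- rejected + 1L
        next
      }
      boxes[[length(boxes) + 1L]] <- c(label = l)
    }
  }
  labels_kept <- vapply(boxes, function(b) b[["label"]], numeric(1))
  # bounding boxes for kept labels
  bb <- NULL
  if (length(labels_kept)) {
    bb <- do.call(rbind, lapply(labels_kept, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(label = l, r0 = min(idx[, 1]), r1 = max(idx[, 1]),
        c0 = min(idx[, 2]), c1 = max(idx[, 2]))
    }))
  }
  structure(list(labels = lab, boxes = bb,
                 nuc_excess = nuc$excess, cyt_excess = cyt$excess,
                 nuc_sigma = nuc$sigma, cyt_sigma = cyt$sigma,
                 n_rejected = rejected, pixel_size = px,
                 thresholds = thresholds),
            class = "wbc_candidates")
}

#' Segment a white-cell candidate into nucleus and cytoplasm
#'
#' Nucleus = UV-excited threshold component within the cell mask; cytoplasm =
#' cell minus nucleus. Candidates whose nucleus or cytoplasm is empty after
#' segmentation are rejected (they count toward rejects, not classes).
#'
#' @param det A \code{wbc_candidates} object.
#' @param i Candidate index (row of \code{det$boxes}).
#' @return Object of class \code{wbc_candidate} with \code{cell}/\code{nucleus}/
#'   \code{cytoplasm} masks (cropped), the crop window, and \code{rejected}.
#' @export
segment_nucleus_cytoplasm <- function(det, i) {
  stopifnot(inherits(det, "wbc_candidates"))
  b <- det$boxes[i, ]
  win <- list(r0 = b[["r0"]], r1 = b[["r1"]], c0 = b[["c0"]], c1 = b[["c1"]])
  cell <- det$labels[win$r0:win$r1, win$c0:win$c1, drop = FALSE] == b[["label"]]
  nucx <- det$nuc_excess[win$r0:win$r1, win$c0:win$c1, drop = FALSE]
  nucleus <- cell & (nucx > det$thresholds$nuc_min)
  cytoplasm <- cell & !nucleus
  px <- det$pixel_size
  rejected <- sum(nucleus) * px^2 < det$thresholds$min_nuc_area ||
    sum(cytoplasm) * px^2 < det$thresholds$min_cyt_area
  structure(list(cell = cell, nucleus = nucleus, cytoplasm = cytoplasm,
                 window = win, label = b[["label"]], rejected = rejected,
                 pixel_size = px),
            class = "wbc_candidate")
}

# Eccentricity of a mask from its second central moments.
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(0)
  mu <- colMeans(idx)
  xr <- idx[, 1] - mu[1]; xc <- idx[, 2] - mu[2]
  m20 <- mean(xr^2); m02 <- mean(xc^2); m11 <- mean(xr * xc)
  tr <- m20 + m02
  det2 <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det2, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(pmax(1 - l2 / l1, 0))
}

#' Compute classification features for a white-cell candidate
#'
#' Morphology (areas, equivalent diameter, nucleus/cell ratio, nucleus
#' lobedness = P^2/(4*pi*A), eccentricity), intensity (mean fluorescence of
#' each stain over nucleus and cytoplasm, mean violet brightfield absorption
#' over the cell) and texture (SD of each fluorescence channel over nucleus
#' and cytoplasm).
#'
#' @param cand A \code{wbc_candidate} from
#'   \code{\link{segment_nucleus_cytoplasm}}.
#' @param det The parent \code{wbc_candidates}.
#' @param field The source \code{ms_field}.
#' @param vod Optional precomputed violet OD raster (whole field), to avoid
#'   recomputation when measuring many candidates.
#' @return One-row data.frame of features.
#' @export
compute_wbc_features <- function(cand, det, field, vod = NULL) {
  px <- cand$pixel_size
  win <- cand$window
  nucx <- det$nuc_excess[win$r0:win$r1, win$c0:win$c1, drop = FALSE]
  cytx <- det$cyt_excess[win$r0:win$r1, win$c0:win$c1, drop = FALSE]
  if (is.null(vod)) vod <- violet_od(field)$od
  vod <- vod[win$r0:win$r1, win$c0:win$c1, drop = FALSE]
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  a_cell <- sum(cand$cell) * px^2
  a_nuc <- sum(cand$nucleus) * px^2
  p_nuc <- mask_perimeter(cand$nucleus) * px
  data.frame(
    cell_area = a_cell,
    nucleus_area = a_nuc,
    eq_diameter = 2 * sqrt(a_cell / pi),
    nc_ratio = a_nuc / a_cell,
    nuc_mean_365 = mean(nucx[cand$nucleus]),
    nuc_sd_365 = sd0(nucx[cand$nucleus]),
    nuc_mean_460 = mean(cytx[cand$nucleus]),
    nuc_sd_460 = sd0(cytx[cand$nucleus]),
    cyt_mean_365 = if (any(cand$cytoplasm)) mean(nucx[cand$cytoplasm]) else 0,
    cyt_sd_365 = sd0(nucx[cand$cytoplasm]),
    cyt_mean_460 = if (any(cand$cytoplasm)) mean(cytx[cand$cytoplasm]) else 0,
    cyt_sd_460 = sd0(cytx[cand$cytoplasm]),
    bf_absorption = mean(vod[cand$cell]),
    lobedness = if (a_nuc > 0) p_nuc^2 / (4 * pi * a_nuc) else 0,
    eccentricity = mask_eccentricity(cand$nucleus))
}

wbc_feature_names <- function() {
  c("cell_area", "nucleus_area", "eq_diameter", "nc_ratio",
    "nuc_mean_365", "nuc_sd_365", "nuc_mean_460", "nuc_sd_460",
    "cyt_mean_365", "cyt_sd_365", "cyt_mean_460", "cyt_sd_460",
    "bf_absorption", "lobedness", "eccentricity")
}

#' Train the white-cell classifier
#'
#' A lightweight, seedable classical classifier over the feature schema:
#' linear discriminant analysis (default) or, with \code{method =
#' "multinom"}, an L2-regularised multinomial fit via glmnet. The production
#' device uses heavier machine-learning models trained on expert-labelled
#' archives; this interface is pluggable so such a model can be substituted.
#'
#' @param features data.frame containing the feature columns and a
#'   \code{class} column of labels.
#' @param method "lda" or "multinom".
#' @param seed Integer seed (the fits are deterministic; the seed fixes any
#'   internal randomness of the backend).
#' @return Object of class \code{wbc_classifier}.
#' @export
train_wbc_classifier <- function(features, method = c("lda", "multinom"),
                                 seed = 1) {
  method <- match.arg(method)
  fn <- wbc_feature_names()
  missing <- setdiff(c(fn, "class"), names(features))
  if (length(missing)) stopf("missing feature columns: %s",
                             paste(missing, collapse = ", "))
  cls <- unique(features$class)
  if (length(cls) < 2) stopf("training requires >= 2 classes")
  x <- as.matrix(features[, fn])
  if (any(!is.finite(x))) stopf("features must be finite")
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  # fixed class order for deterministic tie-breaking
  ord <- wbc_class_table()$class
  levels <- c(intersect(ord, cls), setdiff(sort(cls), ord))
  y <- factor(features$class, levels = levels)
  fit <- with_seed(seed, {
    if (method == "lda") {
      MASS::lda(xs, grouping = y)
    } else {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stopf("method 'multinom' requires the glmnet package")
      glmnet::glmnet(xs, y, family = "multinomial", lambda = 1e-3,
                     alpha = 0)
    }
  })
  structure(list(method = method, fit = fit, feature_names = fn,
                 levels = levels, center = ctr, scale = scl,
                 schema_version = 1L),
            class = "wbc_classifier")
}

#' Classify white-cell feature rows
#'
#' @param features data.frame with the trained feature schema.
#' @param model A \code{wbc_classifier}.
#' @param min_prob Reject threshold on the maximum posterior (default 0:
#'   always classify).
#' @return data.frame: \code{class}, \code{prob} (winning posterior),
#'   \code{rejected}, plus a \code{posterior} matrix attribute with one
#'   column per class (rows sum to 1).
#' @export
classify_wbc <- function(features, model, min_prob = 0) {
  stopifnot(inherits(model, "wbc_classifier"))
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) stopf("feature schema mismatch; missing: %s",
                             paste(missing, collapse = ", "))
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  xs <- scale(x, model$center, model$scale)
  post <- if (model$method == "lda") {
    predict(model$fit, xs)$posterior
  } else {
    p <- predict(model$fit, xs, type = "response")[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                     dimnames = list(NULL, names(p)))
    p
  }
  post <- post[, model$levels, drop = FALSE]
  post <- post / rowSums(post)
  win <- apply(post, 1, which.max)   # first max = fixed class-order tie-break
  prob <- post[cbind(seq_len(nrow(post)), win)]
  out <- data.frame(class = model$levels[win], prob = prob,
                    rejected = prob < min_prob, stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  out
}

#' Serialize / restore a trained classifier
#'
#' The artifact is JSON with a versioned schema header, so model files are
#' plain text and portable.
#'
#' @param model A \code{wbc_classifier}.
#' @param path File path.
#' @return \code{load_wbc_classifier} returns the restored model.
#' @export
save_wbc_classifier <- function(model, path) {
  stopifnot(inherits(model, "wbc_classifier"))
  obj <- list(schema_version = model$schema_version,
              feature_names = model$feature_names,
              method = model$method,
              payload = jsonlite::serializeJSON(model))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_wbc_classifier
#' @export
load_wbc_classifier <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (is.null(obj$schema_version)) stopf("not a classifier artifact: %s", path)
  jsonlite::unserializeJSON(obj$payload)
}

#' Run the white-cell pipeline on one field
#'
#' Detection, segmentation, feature computation and (when a model is given)
#' classification. Rejected candidates are returned with \code{rejected =
#' TRUE} and no class; rejects + classified = candidates.
#'
#' @param field An \code{ms_field}.
#' @param model Optional \code{wbc_classifier}.
#' @param thresholds See \code{\link{wbc_thresholds}}.
#' @return data.frame of per-candidate features with \code{class},
#'   \code{prob}, \code{rejected}, \code{field_index}.
#' @export
wbc_pipeline <- function(field, model = NULL, thresholds = wbc_thresholds(),
                         ctx = NULL) {
  det <- detect_wbc_candidates(field, thresholds, ctx = ctx)
  n <- if (is.null(det$boxes)) 0L else nrow(det$boxes)
  if (n == 0)
    return(cbind(stats::setNames(
      data.frame(matrix(numeric(0), 0, length(wbc_feature_names()))),
      wbc_feature_names()),
      data.frame(class = character(0), prob = numeric(0),
                 rejected = logical(0), field_index = integer(0))))
  vod <- (if (!is.null(ctx)) ctx$vod else violet_od(field))$od
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- segment_nucleus_cytoplasm(det, i)
    if (cand$rejected) {
      f <- as.data.frame(as.list(setNames(rep(NA_real_,
                                              length(wbc_feature_names())),
                                          wbc_feature_names())))
      f$rejected <- TRUE
    } else {
      f <- compute_wbc_features(cand, det, field, vod = vod)
      f$rejected <- FALSE
    }
    rows[[i]] <- f
  }
  out <- do.call(rbind, rows)
  out$class <- NA_character_
  out$prob <- NA_real_
  ok <- !out$rejected
  if (!is.null(model) && any(ok)) {
    cl <- classify_wbc(out[ok, , drop = FALSE], model)
    out$class[ok] <- cl$class
    out$prob[ok] <- cl$prob
    out$rejected[ok] <- cl$rejected
  }
  out$field_index <- field$field_index %||% NA_integer_
  rownames(out) <- NULL
  out
}

#' Train the default classifier from a rendered single-cell gallery
#'
#' Renders \code{n} labelled cells with \code{\link{render_wbc_gallery}},
#' runs the detection/segmentation/feature pipeline on each crop, and fits
#' the classifier on the recovered features, so that training and inference
#' see the same measurement process.
#'
#' @param params,optics Simulator configuration.
#' @param n Gallery size.
#' @param classes Classes to include (default: all nine).
#' @param method Classifier backend.
#' @param seed Integer seed.
#' @return A \code{wbc_classifier}.
#' @export
default_wbc_classifier <- function(params = population_params(),
                                   optics = optics_config(),
                                   n = 900,
                                   classes = wbc_class_table()$class,
                                   method = "lda", seed = 42) {
  gal <- render_wbc_gallery(n, params, optics, classes = classes,
                            seed = child_seed(seed, 1))
  feats <- gallery_features(gal)
  train_wbc_classifier(feats, method = method, seed = child_seed(seed, 2))
}

# Features + labels for every recoverable cell of a gallery.
gallery_features <- function(gal) {
  rows <- list()
  for (i in seq_along(gal$fields)) {
    f <- wbc_pipeline(gal$fields[[i]])
    f <- f[!f$rejected, , drop = FALSE]
    if (nrow(f) == 1) {
      f$class <- gal$labels[i]
      rows[[length(rows) + 1L]] <- f
    }
  }
  do.call(rbind, rows)
}
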