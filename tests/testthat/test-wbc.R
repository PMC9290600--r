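opt <- optics_config()

test_that("anucleate fields produce no white-cell candidates", {
  cells <- do.call(rbind, lapply(1:6, function(i)
    truth_row(x = 20 * i, y = 50, uid = i)))
  fld <- render_field(manual_truth(cells, 140, 100), opt, seed = 2)
  det <- detect_wbc_candidates(fld)
  expect_true(is.null(det$boxes) || nrow(det$boxes) == 0)
})

test_that("rendered white cells are all detected; nuclear-only debris is not", {
  tab <- wbc_class_table()
  cells <- do.call(rbind, lapply(1:9, function(i)
    wbc_truth_row(tab$class[i], x = 25 + 50 * ((i - 1) %% 3),
                  y = 25 + 50 * ((i - 1) %/% 3), uid = i)))
  # a nuclear-only fragment and a dim speckle among them
  cells <- rbind(cells,
                 truth_row(kind = "debris", class = "nuclear_fragment",
                           x = 10, y = 140, volume = 0, hb_mass = 0,
                           radius = 1.6, sig_nuc = 220, uid = 10L),
                 truth_row(kind = "debris", class = "speckle",
                           x = 140, y = 140, volume = 0, hb_mass = 0,
                           radius = 1, sig_cyt = 4, uid = 11L))
  fld <- render_field(manual_truth(cells, 150, 150), opt, seed = 3)
  det <- detect_wbc_candidates(fld)
  expect_equal(nrow(det$boxes), 9)
})

test_that("nucleus/cytoplasm segmentation recovers the truth geometry", {
  fld <- render_field(manual_truth(wbc_truth_row("lymphocyte")), opt,
                      noise_free = TRUE)
  det <- detect_wbc_candidates(fld)
  expect_equal(nrow(det$boxes), 1)
  cand <- segment_nucleus_cytoplasm(det, 1)
  expect_false(cand$rejected)
  expect_true(all(!(cand$nucleus & cand$cytoplasm)))     # disjoint
  expect_true(all(cand$nucleus | cand$cytoplasm | !cand$cell))
  tab <- wbc_class_table()
  truth_ratio <- (tab$nuc_r[tab$class == "lymphocyte"] /
                    tab$r_cell[tab$class == "lymphocyte"])^2
  f <- compute_wbc_features(cand, det, fld)
  expect_lt(abs(f$nc_ratio - truth_ratio), 0.05)
})

test_that("a nucleus filling the whole cell is rejected", {
  # unit-level check of the empty-cytoplasm rule: UV excess saturates the
  # entire cell mask, so cytoplasm = cell minus nucleus is empty
  n <- 20
  lab <- matrix(0L, n, n)
  lab[6:15, 6:15] <- 1L
  det <- structure(list(labels = lab,
                        boxes = rbind(c(label = 1, r0 = 6, r1 = 15,
                                        c0 = 6, c1 = 15)),
                        nuc_excess = matrix(500, n, n),
                        cyt_excess = matrix(50, n, n),
                        nuc_sigma = 1, cyt_sigma = 1, n_rejected = 0L,
                        pixel_size = 1, thresholds = wbc_thresholds()),
                   class = "wbc_candidates")
  cand <- segment_nucleus_cytoplasm(det, 1)
  expect_true(cand$rejected)
  expect_equal(sum(cand$cytoplasm), 0)
})

test_that("feature values follow the rendered geometry and intensities", {
  fld <- render_field(manual_truth(wbc_truth_row("lymphocyte")), opt,
                      noise_free = TRUE)
  det <- detect_wbc_candidates(fld)
  cand <- segment_nucleus_cytoplasm(det, 1)
  f <- compute_wbc_features(cand, det, fld)
  tab <- wbc_class_table()
  r_nuc <- tab$nuc_r[tab$class == "lymphocyte"]
  expect_lt(abs(2 * sqrt(f$nucleus_area / pi) - 2 * r_nuc), 1)
  # uniform nucleus rendered noise-free: texture SD tracks the dome shape
  # only; with camera noise it rises by about the noise SD
  f_noisy <- local({
    fldn <- render_field(manual_truth(wbc_truth_row("lymphocyte")), opt,
                         seed = 6)
    detn <- detect_wbc_candidates(fldn)
    compute_wbc_features(segment_nucleus_cytoplasm(detn, 1), detn, fldn)
  })
  expect_gt(f_noisy$nuc_sd_365, f$nuc_sd_365)
  # doubling the cytoplasm stain doubles the rendered excess exactly over a
  # fixed region (linearity); the feature itself moves with its own mask,
  # whose threshold boundary shifts, so it doubles only approximately
  bright <- wbc_truth_row("lymphocyte")
  bright$sig_cyt <- bright$sig_cyt * 2
  fld2 <- render_field(manual_truth(bright), opt, noise_free = TRUE)
  det2 <- detect_wbc_candidates(fld2)
  # fixed pixel band through the cytoplasm only: cell center (50, 50),
  # nucleus radius 3.2, cell radius 4.5; row 54 (y = 53.5) keeps every
  # subsample outside the nucleus but inside the cell for these columns
  ring <- matrix(FALSE, 100, 100)
  ring[54, 49:52] <- TRUE
  ex1 <- det$cyt_excess[ring]; ex2 <- det2$cyt_excess[ring]
  expect_true(all(ex1 > 1))
  expect_equal(ex2, 2 * ex1, tolerance = 1e-9)
  # the feature itself still moves up strongly (its own mask widens to
  # dimmer rim pixels, so the ratio sits below 2)
  f2 <- compute_wbc_features(segment_nucleus_cytoplasm(det2, 1), det2, fld2)
  expect_gt(f2$cyt_mean_460 / f$cyt_mean_460, 1.5)
})

test_that("a bilobed nucleus is more lobed than a round one", {
  lobed <- function(class) {
    fld <- render_field(manual_truth(wbc_truth_row(class)), opt, seed = 9)
    det <- detect_wbc_candidates(fld)
    compute_wbc_features(segment_nucleus_cytoplasm(det, 1), det, fld)$lobedness
  }
  expect_gt(lobed("neutrophil"), lobed("lymphocyte"))
})

test_that("classifier training and prediction behave on a separable toy set", {
  set.seed(11)
  n <- 60
  mk <- function(cls, shift) {
    f <- as.data.frame(matrix(rnorm(n * 15, shift), n, 15))
    names(f) <- cbcsim:::wbc_feature_names()
    f$class <- cls
    f
  }
  toy <- rbind(mk("lymphocyte", 0), mk("neutrophil", 6))
  m <- train_wbc_classifier(toy, seed = 1)
  pred <- classify_wbc(toy, m)
  expect_equal(mean(pred$class == toy$class), 1)       # training accuracy
  post <- attr(pred, "posterior")
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_error(train_wbc_classifier(mk("lymphocyte", 0)), ">= 2 classes")
  # schema mismatch is an input error
  expect_error(classify_wbc(toy[, 1:5], m), "schema")
  # the alternative multinomial backend fits the same interface
  if (requireNamespace("glmnet", quietly = TRUE)) {
    m2 <- train_wbc_classifier(toy, method = "multinom", seed = 1)
    p2 <- classify_wbc(toy, m2)
    expect_equal(mean(p2$class == toy$class), 1)
    expect_true(all(abs(rowSums(attr(p2, "posterior")) - 1) < 1e-9))
  }
})

test_that("label permutation drops held-out accuracy to chance", {
  gal <- render_wbc_gallery(150, seed = 13)
  feats <- cbcsim:::gallery_features(gal)
  set.seed(2)
  feats$class <- sample(feats$class)
  idx <- seq_len(100)
  m <- train_wbc_classifier(feats[idx, ], seed = 3)
  pred <- classify_wbc(feats[-idx, ], m)
  acc <- mean(pred$class == feats$class[-idx])
  expect_lt(acc, 0.45)            # ~1/5 expected; far below the trained level
})

test_that("classifier artifacts round-trip through JSON", {
  m <- shared_classifier()
  path <- tempfile(fileext = ".json")
  save_wbc_classifier(m, path)
  m2 <- load_wbc_classifier(path)
  gal <- render_wbc_gallery(20, seed = 17)
  f <- cbcsim:::gallery_features(gal)
  p1 <- classify_wbc(f, m)
  p2 <- classify_wbc(f, m2)
  expect_identical(p1$class, p2$class)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})

test_that("rejects and classified candidates partition the total", {
  sim <- simulate_sample(geom = small_geom(2), seed = 19, n_fields = 2)
  clf <- shared_classifier()
  out <- rbind(wbc_pipeline(render_field(sim$fields[[1]], opt, seed = 1),
                            clf),
               wbc_pipeline(render_field(sim$fields[[2]], opt, seed = 2),
                            clf))
  expect_equal(sum(out$rejected) + sum(!out$rejected & !is.na(out$class)),
               nrow(out))
})
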