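opt <- optics_config()

test_that("a blank field yields no red-cell candidates", {
  fld <- render_field(manual_truth(cbcsim:::empty_cells()[0, ]), opt,
                      seed = 1)
  det <- detect_rbc_candidates(fld, opt)
  expect_equal(nrow(det$regions), 0)
})

test_that("disjoint red cells are detected one-to-one with true centroids", {
  # 25 cells on a grid, noise-free; oracle = the truth footprints themselves
  gx <- as.vector(outer(seq(15, 135, by = 30), rep(1, 5)))
  gy <- as.vector(outer(rep(1, 5), seq(15, 135, by = 30)))
  cells <- do.call(rbind, lapply(1:25, function(i)
    truth_row(x = gx[i], y = gy[i], uid = i)))
  fld <- render_field(manual_truth(cells, 150, 150), opt, noise_free = TRUE)
  det <- detect_rbc_candidates(fld, opt)
  expect_equal(nrow(det$regions), 25)
  ord <- order(det$regions$cx + 1000 * round(det$regions$cy / 30))
  tord <- order(gx + 1000 * round(gy / 30))
  expect_true(all(abs(det$regions$cx[ord] - gx[tord]) <= 1))
  expect_true(all(abs(det$regions$cy[ord] - gy[tord]) <= 1))
})

test_that("two overlapping red cells merge into one candidate region", {
  cells <- rbind(truth_row(x = 47, y = 50, uid = 1),
                 truth_row(x = 52, y = 50, uid = 2))
  fld <- render_field(manual_truth(cells), opt, noise_free = TRUE)
  det <- detect_rbc_candidates(fld, opt)
  expect_equal(nrow(det$regions), 1)
  expect_gt(det$regions$area_um2, 60)
})

test_that("split_overlaps separates touching discs and preserves the union", {
  disc_mask <- function(centers, r = 4, n = 40) {
    m <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(centers)))
      m <- m | (outer((1:n - centers[k, 2])^2, (1:n - centers[k, 1])^2,
                      "+") <= r^2)
    m
  }
  # isolated disc: no split
  m1 <- disc_mask(cbind(20, 20))
  s1 <- split_overlaps(m1)
  expect_equal(max(s1), 1)
  expect_identical(s1 > 0, m1)
  # two discs 1.5 radii apart: 2 masks, centroids near truth
  m2 <- disc_mask(rbind(c(16, 20), c(28, 20)), r = 4)
  s2 <- split_overlaps(m2)
  expect_equal(max(s2), 2)
  expect_identical(s2 > 0, m2)                       # union preserved exactly
  for (k in 1:2) {
    idx <- which(s2 == k, arr.ind = TRUE)
    cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
    expect_lt(min(abs(cx - c(16, 28))), 2)
    expect_lt(abs(cy - 20), 2)
  }
  # chain of three touching discs: 3 masks
  m3 <- disc_mask(rbind(c(12, 20), c(20, 20), c(28, 20)), r = 4)
  s3 <- split_overlaps(m3)
  expect_equal(max(s3), 3)
  expect_identical(s3 > 0, m3)
})

test_that("per-cell hemoglobin and volume invert the render", {
  cells <- do.call(rbind, lapply(1:9, function(i)
    truth_row(x = 25 + 50 * ((i - 1) %% 3), y = 25 + 50 * ((i - 1) %/% 3),
              hb_mass = 30, volume = 90, uid = i)))
  fld <- render_field(manual_truth(cells, 150, 150), opt, noise_free = TRUE)
  m <- rbc_pipeline(fld, opt)
  m <- m[!m$border, ]
  expect_true(all(abs(m$hb_pg - 30) < 0.5))
  expect_true(all(abs(m$volume_fl - 90) / 90 < 0.05))
  # zero-absorption footprint measures zero hemoglobin
  z <- measure_rbc(0, 0, eps_violet = 0.008)
  expect_equal(z$hb_pg, 0)
  # two cells with 20 and 40 pg measure a 2.0 ratio within 5%
  two <- rbind(truth_row(x = 30, y = 50, hb_mass = 20, uid = 1),
               truth_row(x = 90, y = 50, hb_mass = 40, uid = 2))
  fld2 <- render_field(manual_truth(two, 120, 100), opt, noise_free = TRUE)
  m2 <- rbc_pipeline(fld2, opt)
  m2 <- m2[order(m2$cx), ]
  expect_lt(abs(m2$hb_pg[2] / m2$hb_pg[1] - 2), 0.1)
})

test_that("MCH recovery bias is below 2% on noise-free renders", {
  p <- population_params(wbc_conc = 0, plt_conc = 0, debris_conc = 0)
  geom <- small_geom(3)
  sim <- simulate_sample(p, geom = geom, seed = 21, n_fields = 3)
  out <- NULL
  for (i in 1:3) {
    fld <- render_field(sim$fields[[i]], opt, noise_free = TRUE)
    out <- rbind(out, rbc_pipeline(fld, opt))
  }
  g <- out[!out$border & !out$split, ]
  truth_mch <- mean(sim$sample$cells$hb_mass[sim$sample$cells$kind == "rbc"])
  expect_lt(abs(mean(g$hb_pg) - truth_mch) / truth_mch, 0.02)
})

test_that("aggregation reproduces sample statistics and counting rates", {
  # degenerate volumes: mcv equals the value, rdw is zero
  m <- data.frame(cx = 1:5, cy = 1:5, area_um2 = 40, hb_pg = 30,
                  volume_fl = 90, border = FALSE, saturated = FALSE,
                  split = FALSE, field_index = 1L)
  idx <- aggregate_rbc(m, small_geom(1), kit_config(), n_fields = 1)
  expect_equal(idx$mcv, 90)
  expect_equal(idx$rdw, 0)
  expect_equal(idx$mch, 30)
  # lognormal volumes: mcv and rdw track the sample oracle
  set.seed(4)
  s2 <- log(1 + (12 / 88)^2)
  vols <- rlnorm(4000, log(88) - s2 / 2, sqrt(s2))
  m2 <- data.frame(cx = 0, cy = 0, area_um2 = 40, hb_pg = 30,
                   volume_fl = vols, border = FALSE, saturated = FALSE,
                   split = FALSE, field_index = 1L)
  idx2 <- aggregate_rbc(m2, small_geom(1), kit_config(), n_fields = 1)
  expect_lt(abs(idx2$mcv - mean(vols)), 1e-9)
  expect_lt(abs(idx2$rdw - 100 * sd(vols) / mean(vols)), 1e-9)
  expect_lt(abs(idx2$rdw - 100 * 12 / 88), 3 * 100 * 12 / 88 / sqrt(2 * 3999))
  # fewer than 2 valid measurements invalidates the indices
  idx3 <- aggregate_rbc(m[0, ], small_geom(1), kit_config(), n_fields = 1)
  expect_true(is.na(idx3$rbc_conc))
})

test_that("red-cell concentration is recovered within counting error", {
  p <- population_params(wbc_conc = 0, plt_conc = 0, debris_conc = 0)
  geom <- chamber_geometry(field_width = 250, field_height = 250,
                           n_fields = 8)
  sim <- simulate_sample(p, geom = geom, seed = 31, n_fields = 8)
  out <- NULL
  for (i in 1:8) {
    fld <- render_field(sim$fields[[i]], opt,
                        seed = cbcsim:::child_seed(31, 100 + i))
    out <- rbind(out, rbc_pipeline(fld, opt))
  }
  idx <- aggregate_rbc(out, geom, kit_config(), n_fields = 8)
  n_true <- sum(sim$sample$cells$kind == "rbc")
  vol <- imaged_blood_volume(geom, kit_config(), 8)
  true_conc <- n_true / (vol * 1e6)
  se <- sqrt(n_true) / (vol * 1e6)
  expect_lt(abs(idx$rbc_conc - true_conc), max(3 * se, 0.03 * true_conc))
})
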