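test_that("a single cell settles into the single field with no overlaps", {
  one <- truth_row()
  one$x <- NULL; one$y <- NULL; one$forced <- NULL
  s <- structure(list(cells = one, params = population_params(),
                      sampled_volume = 1e-5, seed = 1),
                 class = "ground_truth_sample")
  geom <- chamber_geometry(field_width = 100, field_height = 100,
                           n_fields = 1)
  fl <- settle_fields(s, geom, kit_config(), seed = 2)
  expect_length(fl, 1)
  expect_equal(nrow(fl[[1]]$cells), 1)
  expect_equal(nrow(fl[[1]]$overlap_pairs), 0)
  expect_true(fl[[1]]$cells$x >= 0 && fl[[1]]$cells$x <= 100)
})

test_that("settling conserves the sample and is deterministic", {
  s <- sample_cell_population(population_params(),
                              imaged_blood_volume(small_geom(), kit_config(),
                                                  4), seed = 3)
  fl <- settle_fields(s, small_geom(), kit_config(), seed = 4)
  expect_equal(sum(vapply(fl, function(f) nrow(f$cells), numeric(1))),
               nrow(s$cells))
  fl2 <- settle_fields(s, small_geom(), kit_config(), seed = 4)
  expect_identical(lapply(fl, `[[`, "cells"), lapply(fl2, `[[`, "cells"))
})

test_that("the settled monolayer stays mostly overlap-free at 8e6/ul", {
  # simulator contract at the top of the red-cell range, checked against an
  # independent pairwise-distance oracle on the generated positions
  geom <- chamber_geometry(field_width = 300, field_height = 300,
                           n_fields = 10)
  p <- population_params(rbc_conc = 8, wbc_conc = 0, plt_conc = 0,
                         debris_conc = 0)
  s <- sample_cell_population(p, imaged_blood_volume(geom, kit_config(), 10),
                              seed = 5)
  fl <- settle_fields(s, geom, kit_config(), seed = 6)
  in_overlap <- 0; total <- 0
  for (f in fl) {
    n <- nrow(f$cells)
    total <- total + n
    if (n < 2) next
    d <- as.matrix(dist(cbind(f$cells$x, f$cells$y)))
    rr <- outer(f$cells$radius, f$cells$radius, "+")
    hit <- (d < rr) & upper.tri(d)
    in_overlap <- in_overlap + length(unique(c(which(hit, arr.ind = TRUE))))
    # oracle agrees with the reported overlap graph
    expect_equal(sum(hit), nrow(f$overlap_pairs))
  }
  expect_lt(in_overlap / total, 0.10)
})

test_that("doubling the dilution factor halves the expected per-field count", {
  geom <- chamber_geometry(field_width = 200, field_height = 200,
                           n_fields = 50)
  count_at <- function(dil, seed) {
    kit <- kit_config(dilution_factor = dil)
    s <- sample_cell_population(population_params(wbc_conc = 0, plt_conc = 0,
                                                  debris_conc = 0),
                                imaged_blood_volume(geom, kit, 50),
                                seed = seed)
    fl <- settle_fields(s, geom, kit, seed = seed + 1)
    vapply(fl, function(f) nrow(f$cells), numeric(1))
  }
  c1 <- count_at(300, 7)
  c2 <- count_at(600, 8)
  m1 <- mean(c1); m2 <- mean(c2)
  se <- sqrt(m1 / length(c1) + 4 * m2 / length(c2))
  expect_lt(abs(m1 - 2 * m2), 3 * se)
})

test_that("overlap fraction is non-increasing in dilution factor", {
  geom <- chamber_geometry(field_width = 200, field_height = 200,
                           n_fields = 8)
  frac_at <- function(dil, seed) {
    kit <- kit_config(dilution_factor = dil)
    p <- population_params(rbc_conc = 8, wbc_conc = 0, plt_conc = 0,
                           debris_conc = 0)
    s <- sample_cell_population(p, imaged_blood_volume(geom, kit, 8),
                                seed = seed)
    fl <- settle_fields(s, geom, kit, seed = seed + 100)
    tot <- sum(vapply(fl, function(f) nrow(f$cells), numeric(1)))
    ov <- sum(vapply(fl, function(f)
      length(unique(c(f$overlap_pairs))), numeric(1)))
    ov / max(tot, 1)
  }
  fr <- vapply(1:5, function(s)
    c(frac_at(150, s), frac_at(300, s), frac_at(600, s)), numeric(3))
  m <- rowMeans(fr)
  expect_true(m[1] >= m[2] - 1e-9 && m[2] >= m[3] - 1e-9)
})
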