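# Independent oracle: brute-force Passing-Bablok by explicit enumeration of
# all pairwise slopes and direct order statistics.
pb_brute <- function(x, y) {
  S <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) S <- c(S, (y[j] - y[i]) / (x[j] - x[i]))
  S <- sort(S[S != -1])
  K <- sum(S < -1)
  N <- length(S)
  b <- if (N %% 2 == 1) S[(N + 1) / 2 + K]
       else mean(S[N / 2 + K + 0:1])
  list(slope = b, intercept = median(y - b * x))
}

test_that("Passing-Bablok recovers exact affine relations", {
  x <- seq(1, 20)
  r1 <- passing_bablok(paired_measurements(x, x))
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0)
  expect_equal(r1$r, 1)
  r2 <- passing_bablok(paired_measurements(x, 2 * x + 1))
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)
  expect_true(r2$slope_ci[1] <= 2 && 2 <= r2$slope_ci[2])
})

test_that("Passing-Bablok matches the enumerated pairwise-slope oracle", {
  # the worked five-point example
  x <- 1:5; y <- c(2.1, 4.0, 6.2, 7.9, 10.1)
  r <- passing_bablok(paired_measurements(x, y))
  expect_equal(r$slope, 1.975)
  expect_equal(r$intercept, 0.125)
  o <- pb_brute(x, y)
  expect_equal(r$slope, o$slope)
  expect_equal(r$intercept, o$intercept)
  # random instances, n <= 30
  for (s in 1:40) {
    set.seed(s)
    n <- sample(5:30, 1)
    x <- round(runif(n, 1, 50), 2)
    y <- round(1.5 * x + rnorm(n, 0, 3), 2)
    r <- passing_bablok(paired_measurements(x, y))
    o <- pb_brute(x, y)
    expect_equal(r$slope, o$slope)
    expect_equal(r$intercept, o$intercept)
    expect_true(r$slope_ci[1] <= r$slope && r$slope <= r$slope_ci[2])
  }
})

test_that("Passing-Bablok is scale-equivariant and swap-symmetric", {
  # positive-slope data with every pairwise slope positive (no slope crosses
  # the -1 shift boundary) and n = 23, so the 253 ordered slopes have a
  # unique median: under these conditions both properties are exact
  set.seed(7)
  x <- sort(runif(23, 5, 50))
  y <- 1.3 * x + rnorm(23, 0, 0.1)
  r <- passing_bablok(paired_measurements(x, y))
  rs <- passing_bablok(paired_measurements(3 * x, y))
  expect_equal(rs$slope, r$slope / 3, tolerance = 1e-12)
  rw <- passing_bablok(paired_measurements(y, x))
  expect_equal(rw$slope, 1 / r$slope, tolerance = 1e-12)
})

test_that("Passing-Bablok rejects degenerate input and honors exclusions", {
  expect_error(passing_bablok(paired_measurements(1:2, 1:2)), ">= 3")
  expect_error(passing_bablok(paired_measurements(rep(2, 5), 1:5)),
               "identical")
  pm <- paired_measurements(c(1:9, 100), c(1:9, 5),
                            excluded = c(rep(FALSE, 9), TRUE),
                            reason = c(rep("", 9), "invalidated"))
  r <- passing_bablok(pm)
  expect_equal(r$n, 9)
  expect_equal(r$slope, 1)
})

test_that("median bias handles absolute and relative modes", {
  x <- c(2, 4, 6, 8)
  expect_equal(median_bias(paired_measurements(x, x)), 0)
  expect_equal(median_bias(paired_measurements(x, x + 1)), 1)
  expect_equal(median_bias(paired_measurements(x, 1.05 * x), "relative"), 5)
  err <- tryCatch(median_bias(paired_measurements(c(0, 1, 2), 1:3,
                                                  sample_id = c("a", "b", "c")),
                              "relative"),
                  error = conditionMessage)
  expect_match(err, "a")   # the offending pair is named
})

test_that("pooled SD matches hand arithmetic and reduces to the ordinary SD", {
  expect_equal(pooled_sd(rep(3, 10), rep(1:2, each = 5))$pooled_sd, 0)
  # two samples of n = 3 with variances 4 and 16 pool to sqrt(10)
  a <- c(-2, 0, 2); a <- a / sd(a) * 2 + 10          # variance exactly 4
  b <- c(-2, 0, 2); b <- b / sd(b) * 4 + 20          # variance exactly 16
  ps <- pooled_sd(c(a, b), rep(1:2, each = 3))
  expect_equal(ps$pooled_sd, sqrt(10))
  set.seed(3)
  v <- rnorm(25)
  expect_equal(pooled_sd(v)$pooled_sd, sd(v))
  expect_error(pooled_sd(c(1, 2, 3), c(1, 1, 2)), ">= 2 replicates")
})

test_that("pooled SD estimates the true SD across a repeatability design", {
  # 26 samples x 20 replicates at true SD 0.40 (shaped like a whole-blood
  # white-count repeatability row): estimate within the chi-square band
  set.seed(9)
  vals <- unlist(lapply(1:26, function(i) rnorm(20, 9.26 + i / 10, 0.40)))
  ps <- pooled_sd(vals, rep(1:26, each = 20))
  expect_lt(abs(ps$pooled_sd - 0.40) / 0.40, 0.15)
})

test_that("nested reproducibility components recover simulated variances", {
  design <- expand.grid(site = 1:3, device = 1:2, day = 1:5, run = 1:2,
                        rep = 1:4)
  simulate_design <- function(seed, s_run = 0.5, s_day = 0.25, s_rep = 1) {
    set.seed(seed)
    day_key <- interaction(design$site, design$device, design$day)
    run_key <- interaction(day_key, design$run)
    e_day <- rnorm(nlevels(day_key), 0, s_day)[as.integer(day_key)]
    e_run <- rnorm(nlevels(run_key), 0, s_run)[as.integer(run_key)]
    data.frame(site = design$site, device = design$device, day = design$day,
               run = design$run,
               value = 10 + e_day + e_run + rnorm(nrow(design), 0, s_rep))
  }
  # zero variation in, zero components out
  z <- simulate_design(1); z$value <- 5
  rz <- reproducibility_components(z)
  expect_true(all(rz$components$variance == 0))
  expect_equal(rz$total_sd, 0)
  est <- t(vapply(1:50, function(s) {
    r <- reproducibility_components(simulate_design(s))
    v <- setNames(r$components$variance_raw, r$components$stratum)
    expect_true(all(r$components$variance >= 0))
    c(v[["replicate"]], v[["run"]], v[["day"]], r$total_sd^2)
  }, numeric(4)))
  # the method-of-moments solution is unbiased: component SDs within 10% of
  # the simulated sigmas (reported components are additionally truncated at
  # zero, which biases the smallest one upward -- hence the raw column)
  expect_lt(abs(sqrt(mean(est[, 1])) - 1), 0.1)
  expect_lt(abs(sqrt(mean(est[, 2])) - 0.5), 0.05)
  expect_lt(abs(sqrt(mean(est[, 3])) - 0.25), 0.025)
  # total variance equals the sum of simulated components within error
  expect_lt(abs(mean(est[, 4]) - (1 + 0.25 + 0.0625)), 0.15)
  # unbalanced designs are an explicit error
  bad <- simulate_design(2)[-1, ]
  expect_error(reproducibility_components(bad), "unbalanced")
})

test_that("Clopper-Pearson intervals reproduce the printed study bounds", {
  expect_equal(round(100 * clopper_pearson(93, 100), 1),
               c(lower = 86.1, upper = 97.1))
  expect_equal(round(100 * clopper_pearson(87, 108), 1),
               c(lower = 71.8, upper = 87.5))
  expect_equal(round(100 * clopper_pearson(180, 208), 1),
               c(lower = 81.1, upper = 90.9))
  expect_equal(unname(clopper_pearson(0, 20)[1]), 0)
  expect_equal(unname(clopper_pearson(20, 20)[2]), 1)
  expect_error(clopper_pearson(5, 4), "invalid")
})

test_that("Clopper-Pearson contains the estimate and covers at 95%", {
  for (s in c(0, 3, 54, 93, 100)) {
    ci <- clopper_pearson(s, 100)
    expect_true(ci[1] <= s / 100 && s / 100 <= ci[2])
  }
  set.seed(13)
  x <- rbinom(1e4, 108, 0.8)
  lo <- qbeta(0.025, x, 108 - x + 1); lo[x == 0] <- 0
  hi <- qbeta(0.975, x + 1, 108 - x); hi[x == 108] <- 1
  expect_gte(mean(lo <= 0.8 & 0.8 <= hi), 0.95)
})

test_that("agreement statistics reproduce the flagging-study table", {
  tab <- binomial_agreement(tp = 93, fn = 7, tn = 87, fp = 21)
  expect_equal(round(100 * tab$estimate, 1), c(93.0, 80.6, 86.5))
  expect_equal(round(100 * tab$lower, 1), c(86.1, 71.8, 81.1))
  expect_equal(round(100 * tab$upper, 1), c(97.1, 87.5, 90.9))
  perfect <- binomial_agreement(50, 0, 60, 0)
  expect_true(all(perfect$estimate == 1))
  sym <- binomial_agreement(25, 25, 25, 25)
  expect_true(all(sym$estimate == 0.5))
  expect_error(binomial_agreement(0, 0, 10, 10), "margins")
})

test_that("two-examiner differential comparison is an exact conditional test", {
  d1 <- c(neut = 120, lymph = 60, mono = 20)
  r1 <- rumke_compare(d1, d1, n_cells = 200)
  expect_true(r1$agree)
  d2 <- c(neut = 120, lymph = 60, mono = 20)
  d3 <- c(neut = 80, lymph = 100, mono = 20)
  r2 <- rumke_compare(d2, d3, n_cells = 200)
  expect_false(r2$agree)
  # the spec'd discordant and concordant count pairs
  a <- c(x = 20, rest = 180); b <- c(x = 60, rest = 140)
  expect_false(rumke_compare(a, b)$classes$agree[1])
  a2 <- c(x = 20, rest = 180); b2 <- c(x = 24, rest = 176)
  expect_true(rumke_compare(a2, b2)$classes$agree[1])
  expect_error(rumke_compare(c(x = 10, rest = 100), c(x = 10, rest = 190)),
               "sum to")
  # p-values agree with the independent Fisher-exact oracle
  for (x1 in c(5, 20, 40)) for (x2 in c(5, 25, 60)) {
    p_pkg <- cbcsim:::cond_binom_p(x1, x2, 200)
    m <- matrix(c(x1, 200 - x1, x2, 200 - x2), 2)
    p_fisher <- stats::fisher.test(m)$p.value
    expect_equal(p_pkg, p_fisher, tolerance = 1e-6)
  }
})

test_that("arbitration accepts any agreeing pair or discards the sample", {
  d <- c(neut = 120, lymph = 60, mono = 20)
  shift <- c(neut = 70, lymph = 110, mono = 20)
  r1 <- rumke_arbitrate(list(d, shift, d + c(-4, 4, 0)))
  expect_equal(r1$verdict, "agree")
  expect_equal(r1$pair, c(1, 3))
  r2 <- rumke_arbitrate(list(d, shift))
  expect_equal(r2$verdict, "discard")
})

test_that("matrix comparison averages replicates before regression", {
  set.seed(21)
  ids <- sprintf("s%02d", 1:20)
  base <- runif(20, 2, 10)
  rows <- function(matrix_name, mult) do.call(rbind, lapply(1:2, function(r)
    data.frame(specimen_id = ids, analyte = "MONO#", matrix = matrix_name,
               replicate = r, value = base * mult + rnorm(20, 0, 0.1))))
  d <- rbind(rows("venous", 1), rows("capillary", 1.25))
  res <- matrix_comparison(d, x_matrix = "venous", y_matrix = "capillary")
  expect_equal(res$n, 20)
  expect_true(res$slope_lo <= 1.25 && 1.25 <= res$slope_hi)
  # identical matrices: slope 1, intercept 0, zero bias
  d2 <- rbind(rows("venous", 1), rows("capillary", 1))
  d2$value <- rep(base, 4)
  res2 <- matrix_comparison(d2, "venous", "capillary")
  expect_equal(res2$slope, 1)
  expect_equal(res2$intercept, 0)
  expect_equal(res2$bias, 0)
  # unpaired specimens are excluded with a log entry
  d3 <- rbind(rows("venous", 1),
              rows("capillary", 1)[-c(1, 21), ])  # drop both reps of s01
  res3 <- matrix_comparison(d3, "venous", "capillary")
  expect_true(length(attr(res3, "exclusions")) > 0)
})
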