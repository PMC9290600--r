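geom <- chamber_geometry()
kit <- kit_config()

mk_rbc <- function(conc = 5, mcv = 90, rdw = 13, mch = 30, n = 5000)
  structure(list(rbc_conc = conc, mcv = mcv, rdw = rdw, mch = mch,
                 n_cells_measured = n, n_cells_counted = n),
            class = "rbc_indices")

mk_counts <- function(neut = 600, lymph = 300, mono = 70, eos = 20,
                      baso = 10, blast = 0, ig = 0, atyp = 0, nrbc = 0)
  c(neutrophil = neut, lymphocyte = lymph, monocyte = mono, eosinophil = eos,
    basophil = baso, blast = blast, immature_granulocyte = ig,
    atypical_lymphocyte = atyp, nrbc = nrbc)

test_that("derived indices obey the identity relations", {
  rep1 <- compile_cbc(rbc = mk_rbc(conc = 5, mcv = 90), wbc_counts = mk_counts(),
                      plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  # HCT = RBC * MCV / 10 = 45; MCH = 10*HGB/RBC = 30; MCHC = 100*HGB/HCT
  expect_equal(unname(rep1$parameters["HCT"]), 45)
  expect_equal(unname(rep1$parameters["MCH"]), 30)
  expect_equal(unname(rep1$parameters["MCHC"]), 33.3)
})

test_that("identities and differential closure hold on random valid reports", {
  for (s in 1:25) {
    set.seed(s)
    cnt <- mk_counts(neut = rpois(1, 500) + 50, lymph = rpois(1, 250) + 50,
                     mono = rpois(1, 60) + 12, eos = rpois(1, 25) + 12,
                     baso = rpois(1, 12) + 10, nrbc = rpois(1, 5))
    rep1 <- compile_cbc(rbc = mk_rbc(conc = runif(1, 2, 8),
                                     mcv = runif(1, 70, 110)),
                        wbc_counts = cnt, plt_count = rpois(1, 4000) + 100,
                        hgb = runif(1, 6, 20), geom = geom, kit = kit)
    raw <- rep1$raw
    pct <- raw[paste0(c("NEUT", "LYMPH", "MONO", "EOS", "BASO"), "%")]
    expect_lt(abs(sum(pct) - 100), 0.1)
    for (cl in c("NEUT", "LYMPH", "MONO", "EOS", "BASO"))
      expect_lt(abs(raw[paste0(cl, "#")] -
                      raw["WBC"] * raw[paste0(cl, "%")] / 100), 1e-9)
    expect_lt(abs(raw["HCT"] - raw["RBC"] * raw["MCV"] / 10), 1e-9)
    expect_lt(abs(raw["MCH"] - 10 * raw["HGB"] / raw["RBC"]), 1e-9)
    expect_lt(abs(raw["MCHC"] - 100 * raw["HGB"] / raw["HCT"]), 1e-9)
    # NRBC never enters the white count
    vol <- imaged_blood_volume(geom, kit)
    expect_equal(unname(raw["WBC"]),
                 (sum(cnt) - cnt[["nrbc"]]) / (vol * 1e3))
  }
})

test_that("morphological and distributional flags follow the thresholds", {
  # no abnormal cells, all classes in range: no flags
  r0 <- compile_cbc(rbc = mk_rbc(), wbc_counts = mk_counts(),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  expect_length(r0$flags, 0)
  # 5% blasts among 1000 classified cells with defaults (>=10 cells, >=1%)
  r1 <- compile_cbc(rbc = mk_rbc(),
                    wbc_counts = mk_counts(neut = 570, blast = 50),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  expect_true("blast" %in% r1$flags)
  # a class outside its reference range raises the distributional flag
  r2 <- compile_cbc(rbc = mk_rbc(),
                    wbc_counts = mk_counts(neut = 950, lymph = 30, mono = 10,
                                           eos = 7, baso = 3),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  expect_true("distributional_abnormality" %in% r2$flags)
  # flag monotonicity: raising an abnormal count never removes its flag
  # (starting from a count satisfying both the >=10-cell and >=1% rules)
  for (n_blast in c(11, 30, 80, 200)) {
    rr <- compile_cbc(rbc = mk_rbc(),
                      wbc_counts = mk_counts(blast = n_blast),
                      plt_count = 5000, hgb = 15, geom = geom, kit = kit)
    expect_true("blast" %in% rr$flags)
  }
  # below either threshold: no flag
  r3 <- compile_cbc(rbc = mk_rbc(), wbc_counts = mk_counts(blast = 5),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  expect_false("blast" %in% r3$flags)
})

test_that("failsafe verdicts follow the event-count rules", {
  # too few fields: overall invalid with the stated reason
  r1 <- compile_cbc(rbc = mk_rbc(), wbc_counts = mk_counts(),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit,
                    n_fields = 30)
  expect_false(r1$validity$valid)
  expect_match(r1$validity$reasons, "insufficient fields")
  # monocyte events below the subclass minimum invalidate MONO%/# only
  r2 <- compile_cbc(rbc = mk_rbc(),
                    wbc_counts = mk_counts(mono = 3),
                    plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  inv <- r2$validity$invalid_measurands
  expect_true(all(c("MONO%", "MONO#") %in% names(inv)))
  expect_false("NEUT%" %in% names(inv))
  expect_true(r2$validity$valid)   # per-measurand, not overall
  # zero platelets: PLT invalidated by the low-count rule, still reported
  r3 <- compile_cbc(rbc = mk_rbc(), wbc_counts = mk_counts(), plt_count = 0,
                    hgb = 15, geom = geom, kit = kit)
  expect_equal(unname(r3$parameters["PLT"]), 0)
  expect_true("PLT" %in% names(r3$validity$invalid_measurands))
  # a missing pipeline invalidates its measurands, the rest are reported
  r4 <- compile_cbc(rbc = NULL, wbc_counts = mk_counts(), plt_count = 5000,
                    hgb = 15, geom = geom, kit = kit)
  expect_true("RBC" %in% names(r4$validity$invalid_measurands))
  expect_false(is.na(r4$parameters["WBC"]))
})

test_that("report renders to JSON and a printable block", {
  r <- compile_cbc(rbc = mk_rbc(), wbc_counts = mk_counts(),
                   plt_count = 5000, hgb = 15, geom = geom, kit = kit)
  js <- jsonlite::fromJSON(cbc_report_json(r))
  expect_length(js$parameters, 19)
  expect_true(all(c("WBC", "MCHC", "BASO#") %in% names(js$parameters)))
  out <- capture.output(print(r))
  expect_true(any(grepl("WBC", out)))
  expect_true(any(grepl("VALID", out)))
})
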