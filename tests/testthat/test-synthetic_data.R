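test_that("sample_site hits requested bands, deterministically", {
  w <- toy_pwm()
  expect_identical(sample_site(w, c(1, 1), seed = 5), w$consensus)
  expect_identical(sample_site(w, c(0.4, 0.6), seed = 5),
                   sample_site(w, c(0.4, 0.6), seed = 5))
  k <- sample_site(w, c(0.4, 0.6), seed = 5)
  expect_equal(relative_score(w, k), 0.5)  # only achievable value in band

  # the toy motif's spectrum is {0, 0.5, 1}: [0.90, 0.95] is infeasible
  expect_error(sample_site(w, c(0.90, 0.95), seed = 1), "attains")
  expect_error(sample_site(w, c(1.2, 1.3)), "band")

  set.seed(31)
  pwms <- lapply(core_motif_panel(), pfm_to_pwm)
  for (p in pwms) {
    for (band in list(c(0.92, 1), c(0.75, 0.85), c(0, 0.3))) {
      k <- sample_site(p, band)
      r <- relative_score(p, k)
      expect_gte(r, band[1] - 1e-9)
      expect_lte(r, band[2] + 1e-9)
    }
  }
})

test_that("build_promoter_fixture round-trips planted truth", {
  # one active SMAD2/3 site -> exactly one surviving hit at truth offset
  fx <- build_promoter_fixture(
    plant_spec("gA", "SMAD2/3", evidence_score = 700),
    length = 2000, seed = 11)
  hits <- scan_promoter(fx$pwms, fx$promoters[["gA"]], 0.89)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$local_offset, fx$truth$local_offset)
  cfg <- chromatin_config()
  surv <- surviving_hits(encode_evidence_filter(
    active_chromatin_filter(hits, fx$histone_track, cfg),
    fx$cluster_track, cfg))
  expect_equal(nrow(surv), 1)

  # one silent-by-evidence site (score 499): scanned but not surviving
  fx2 <- build_promoter_fixture(
    plant_spec("gB", "ATF4", evidence_score = 499),
    length = 2000, seed = 12)
  hits2 <- scan_promoter(fx2$pwms, fx2$promoters[["gB"]], 0.89)
  expect_equal(nrow(hits2), 1)
  surv2 <- surviving_hits(encode_evidence_filter(
    active_chromatin_filter(hits2, fx2$histone_track, cfg),
    fx2$cluster_track, cfg))
  expect_equal(nrow(surv2), 0)

  # repressed-chromatin site: scanned, chromatin_active fail
  fx3 <- build_promoter_fixture(
    plant_spec("gC", "SOX10", chromatin_status = "silent"),
    length = 2000, seed = 13)
  hits3 <- scan_promoter(fx3$pwms, fx3$promoters[["gC"]], 0.89)
  expect_equal(nrow(hits3), 1)
  expect_identical(active_chromatin_filter(hits3, fx3$histone_track,
                                           cfg)$chromatin_active, "fail")
})

test_that("fixtures are byte-identical across re-runs of one seed", {
  specs <- rbind(plant_spec("g1", "SMAD2/3", n_sites = 2),
                 plant_spec("g1", "PPARG"),
                 plant_spec("g2", "EGR1", chromatin_status = "silent"),
                 plant_spec("g2", "NRF1", band = c(0.75, 0.85)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(build_promoter_fixture(specs, length = 3000, seed = 99), d1)
  write_fixture(build_promoter_fixture(specs, length = 3000, seed = 99), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # and a different seed changes the sequences
  d3 <- withr::local_tempdir()
  write_fixture(build_promoter_fixture(specs, length = 3000, seed = 100), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("minus-strand fixture genes round-trip through extract+scan", {
  specs <- rbind(plant_spec("p1", "SMAD2/3"), plant_spec("m1", "SMAD2/3"))
  fx <- build_promoter_fixture(specs, length = 2500, seed = 17)
  expect_setequal(fx$anchors$strand, c("+", "-"))
  for (g in c("p1", "m1")) {
    anchor <- fx$anchors[fx$anchors$gene_id == g, ]
    prom <- extract_promoter(fx$genome, anchor, window = 2500)
    expect_identical(prom$sequence, fx$promoters[[g]]$sequence)
    hits <- scan_promoter(fx$pwms, prom, 0.89)
    expect_equal(hits$local_offset,
                 fx$truth$local_offset[fx$truth$gene_id == g])
  }
})

test_that("construct fixture: 1302-bp WT, 1296-bp mutant, site excised", {
  cf <- construct_fixture(seed = 4)
  expect_equal(nchar(cf$wt), 1302)
  expect_equal(nchar(cf$mutant), 1296)
  expect_equal(diff(cf$site), 6)
  expect_identical(delete_motif(cf$wt, cf$site), cf$mutant)
  expect_error(delete_motif("ACGT", c(2, 9)), "outside")
})

test_that("make_ct_table inverts through relative_expression", {
  sched <- list(PEX11B = c(1, 2, 4, 2, 1), PEX11A = c(1, 1, 1, 1, 1))
  tab <- make_ct_table(sched, noise_sd = 0, seed = 2)
  prof <- relative_expression(tab)
  expect_equal(prof$relative_amount[prof$gene == "PEX11B"], sched$PEX11B)
  expect_equal(prof$relative_amount[prof$gene == "PEX11A"], sched$PEX11A)
  # calibrator is exactly 1
  expect_equal(prof$relative_amount[prof$time_h == 6], c(1, 1))
})

test_that("make_luciferase_plate inverts through luciferase_fold", {
  plate <- make_luciferase_plate(c(WT = 3, mut = 1, SMAD = 5),
                                 noise_cv = 0, seed = 3)
  folds <- luciferase_fold(plate)
  got <- stats::setNames(folds$fold, folds$construct)
  expect_equal(got[["WT"]], 3)
  expect_equal(got[["mut"]], 1)
  expect_equal(got[["SMAD"]], 5)
  expect_equal(got[["promoterless"]], 1)
  # promoterless firefly signal is ~1000-fold below the promoter constructs
  expect_lt(folds$value_untreated[folds$construct == "promoterless"],
            0.01 * folds$value_untreated[folds$construct == "WT"])
})

test_that("make_morphology_table realises the programmed tubular fraction", {
  tab <- make_morphology_table(n_cells = 200, p_tubular = 0.4, seed = 6)
  expect_true(abs(percent_tubular(tab) - 40) < 10)
  tab0 <- make_morphology_table(n_cells = 50, p_tubular = 0, seed = 6)
  expect_equal(percent_tubular(tab0), 0)
})
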