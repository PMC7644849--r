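htrack <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), label = r[[4]], score = 0,
               stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), label = character(),
                                    score = numeric())
  df
}

ctrack <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), label = r[[4]],
               score = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
  df
}

test_that("active_chromatin_filter applies presence/absence rules", {
  hit <- fake_hit(gstart = 100L, gend = 106L)
  cfg <- chromatin_config()

  # activating mark 800 bp away is inside the +/-1000 window -> pass
  t1 <- htrack(list("chr_g1", 900, 1200, "H3K4me3"))
  expect_identical(active_chromatin_filter(hit, t1, cfg)$chromatin_active,
                   "pass")
  # adding an overlapping repressive mark -> fail
  t2 <- rbind(t1, htrack(list("chr_g1", 50, 200, "H3K27me3")))
  expect_identical(active_chromatin_filter(hit, t2, cfg)$chromatin_active,
                   "fail")
  # no marks within the window -> fail under any-of
  t3 <- htrack(list("chr_g1", 5000, 5100, "H3K27ac"))
  expect_identical(active_chromatin_filter(hit, t3, cfg)$chromatin_active,
                   "fail")
  # all-of rule needs all three activating marks
  t4 <- htrack(list("chr_g1", 0, 300, "H3K4me3"),
               list("chr_g1", 0, 300, "H3K27ac"))
  all_cfg <- chromatin_config(activating_rule = "all")
  expect_identical(active_chromatin_filter(hit, t4, all_cfg)$chromatin_active,
                   "fail")
  t5 <- rbind(t4, htrack(list("chr_g1", 0, 300, "H3K36me3")))
  expect_identical(active_chromatin_filter(hit, t5, all_cfg)$chromatin_active,
                   "pass")
  # marks on another chromosome never count
  t6 <- htrack(list("chr_other", 0, 300, "H3K4me3"))
  expect_identical(active_chromatin_filter(hit, t6, cfg)$chromatin_active,
                   "fail")

  expect_error(active_chromatin_filter(hit, htrack(
    list("chr_g1", 0, 300, "H3K9me3")), cfg), "H3K9me3")
})

test_that("encode_evidence_filter honours the 500/1000 boundary", {
  hit <- fake_hit(tf = "SMAD2/3", gstart = 100L, gend = 106L)
  cfg <- chromatin_config()
  at <- function(score, label = "SMAD2/3")
    ctrack(list("chr_g1", 90, 110, label, score))

  expect_identical(encode_evidence_filter(hit, at(500), cfg)$evidence_pass,
                   "pass")
  expect_identical(encode_evidence_filter(hit, at(499), cfg)$evidence_pass,
                   "fail")
  # no overlapping cluster: default exclude, optional keep
  far <- ctrack(list("chr_g1", 5000, 5100, "SMAD2/3", 900))
  expect_identical(encode_evidence_filter(hit, far, cfg)$evidence_pass,
                   "fail")
  keep_cfg <- chromatin_config(missing_cluster_policy = "keep")
  expect_identical(encode_evidence_filter(hit, far, keep_cfg)$evidence_pass,
                   "pass")
  # TF-name matching: wrong label ignored unless matching disabled
  expect_identical(encode_evidence_filter(hit, at(900, "ATF4"),
                                          cfg)$evidence_pass, "fail")
  any_cfg <- chromatin_config(tf_name_matching = "ignore")
  expect_identical(encode_evidence_filter(hit, at(900, "ATF4"),
                                          any_cfg)$evidence_pass, "pass")
  # case-insensitive exact match
  expect_identical(encode_evidence_filter(hit, at(700, "smad2/3"),
                                          cfg)$evidence_pass, "pass")
  # max over several clusters decides
  multi <- rbind(at(100), at(600))
  expect_identical(encode_evidence_filter(hit, multi, cfg)$evidence_pass,
                   "pass")
  expect_error(encode_evidence_filter(hit, at(1500), cfg), "\\[0, 1000\\]")
})

test_that("filters commute and surviving_hits takes pass-and-pass", {
  set.seed(21)
  hits <- do.call(rbind, lapply(1:20, function(i)
    fake_hit(gstart = 500L * i, gend = 500L * i + 6L)))
  ht <- htrack(list("chr_g1", 400, 5200, "H3K4me3"),
               list("chr_g1", 6900, 7600, "H3K27me3"))
  ct <- ctrack(list("chr_g1", 1000, 1006, "SMAD2/3", 750),
               list("chr_g1", 2500, 2506, "SMAD2/3", 499),
               list("chr_g1", 4000, 4006, "SMAD2/3", 500))
  cfg <- chromatin_config()
  a <- surviving_hits(encode_evidence_filter(
    active_chromatin_filter(hits, ht, cfg), ct, cfg))
  b <- surviving_hits(active_chromatin_filter(
    encode_evidence_filter(hits, ct, cfg), ht, cfg))
  expect_identical(a, b)
  expect_true(all(a$chromatin_active == "pass" & a$evidence_pass == "pass"))

  # monotone in window when no repressive marks exist
  ht2 <- htrack(list("chr_g1", 400, 5200, "H3K4me3"))
  small <- active_chromatin_filter(hits, ht2, chromatin_config(window = 100))
  large <- active_chromatin_filter(hits, ht2, chromatin_config(window = 2000))
  expect_true(all(which(small$chromatin_active == "pass") %in%
                  which(large$chromatin_active == "pass")))

  # surviving_hits identity / subset / empty
  all_pass <- hits
  all_pass$chromatin_active <- "pass"; all_pass$evidence_pass <- "pass"
  expect_identical(surviving_hits(all_pass), all_pass)
  mixed <- all_pass; mixed$evidence_pass[1:5] <- "fail"
  expect_equal(nrow(surviving_hits(mixed)), 15)
  expect_equal(nrow(surviving_hits(all_pass[0, ])), 0)
})
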