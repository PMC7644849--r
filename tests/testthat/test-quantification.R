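ct_row <- function(gene, t, ct, reps = 2) {
  data.frame(gene = gene, time_h = t, replicate = seq_len(reps), ct = ct)
}

test_that("relative_expression implements delta-delta-Ct exactly", {
  times <- c(6, 12, 24, 48, 72)
  flat <- rbind(do.call(rbind, lapply(times, function(t)
                  ct_row("PEX11B", t, 25))),
                do.call(rbind, lapply(times, function(t)
                  ct_row("18S", t, 15))))
  prof <- relative_expression(flat)
  expect_equal(prof$relative_amount, rep(1, 5))
  expect_equal(attr(prof, "calibrator_time"), 6)

  # one-cycle drop at 24 h doubles the relative amount
  drop <- flat
  drop$ct[drop$gene == "PEX11B" & drop$time_h == 24] <- 24
  prof <- relative_expression(drop)
  expect_equal(prof$relative_amount[prof$time_h == 24], 2.0)
  expect_equal(prof$relative_amount[prof$time_h == 6], 1.0)

  # hand arithmetic: gene 24/ref 14 vs calibrator 25/15 -> ddCt 0 -> 1
  two <- rbind(ct_row("G", 6, 25), ct_row("18S", 6, 15),
               ct_row("G", 24, 24), ct_row("18S", 24, 14),
               ct_row("G", 48, 24), ct_row("18S", 48, 15))
  prof <- relative_expression(two)
  expect_equal(prof$relative_amount, c(1, 1, 2))

  # shift invariance: adding a constant to every Ct changes nothing
  shifted <- flat; shifted$ct <- shifted$ct + 3.7
  expect_equal(relative_expression(shifted)$relative_amount,
               relative_expression(flat)$relative_amount)

  # replicate means are taken before dCt
  reps <- rbind(data.frame(gene = "G", time_h = c(6, 6), replicate = 1:2,
                           ct = c(24, 26)),
                ct_row("18S", 6, 15),
                data.frame(gene = "G", time_h = c(24, 24), replicate = 1:2,
                           ct = c(23, 25)),
                ct_row("18S", 24, 15))
  expect_equal(relative_expression(reps)$relative_amount, c(1, 2))

  expect_error(relative_expression(flat[flat$gene != "18S", ]),
               "reference gene")
  expect_error(relative_expression(flat, calibrator_time = 96),
               "calibrator")
  bad <- flat; bad$ct[1] <- 50
  expect_error(relative_expression(bad), "\\(0, 45\\]")
  missing_ref <- flat[!(flat$gene == "18S" & flat$time_h == 48), ]
  expect_error(relative_expression(missing_ref), "48")
})

test_that("correlate_profiles matches a scalar Pearson oracle", {
  expr <- data.frame(time_h = c(6, 12, 24, 48, 72),
                     relative_amount = c(1, 2, 4, 2.5, 1.2))
  morph <- data.frame(time_h = c(6, 12, 24, 48, 72),
                      percent_tubular = c(10, 20, 40, 25, 12))
  prop <- correlate_profiles(
    expr, transform(morph, percent_tubular = 10 * expr$relative_amount))
  expect_equal(prop$r, 1.0)
  expect_identical(prop$classification, "proliferation-correlated")

  neg <- correlate_profiles(
    expr, transform(morph, percent_tubular = 100 - 10 * expr$relative_amount))
  expect_equal(neg$r, -1.0)
  expect_identical(neg$classification, "uncorrelated")

  # scalar oracle: cov / (sd * sd)
  got <- correlate_profiles(expr, morph)
  x <- expr$relative_amount; y <- morph$percent_tubular
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle)

  const <- transform(expr, relative_amount = 1)
  expect_identical(correlate_profiles(const, morph)$classification,
                   "undefined")
  expect_error(correlate_profiles(expr[1:2, ], morph), "3 matched")
})

test_that("classify_cell applies the 2 um / 0.3 um boundaries strictly", {
  expect_identical(classify_cell(c(0.5, 2.5))$category, "tubular")
  expect_identical(classify_cell(c(0.5, 1.9, 2.0))$category, "spherical")
  sub <- classify_cell(c(0.2))
  expect_identical(sub$category, "spherical")
  expect_equal(sub$n_peroxisomes, 0)
  expect_equal(classify_cell(c(0.2, 0.5, 3))$n_peroxisomes, 2)
  expect_error(classify_cell(c(1, -2)), "positive")
})

test_that("percent_tubular is exact and permutation-invariant", {
  cells <- c(lapply(1:3, function(i) c(0.5, 2.5)),
             lapply(1:7, function(i) c(0.5, 1.5)))
  expect_equal(percent_tubular(cells), 30.0)
  expect_equal(percent_tubular(lapply(1:4, function(i) 1)), 0.0)
  expect_equal(percent_tubular(lapply(1:4, function(i) 3)), 100.0)
  set.seed(2)
  expect_equal(percent_tubular(sample(cells)), 30.0)
  df <- data.frame(cell_id = rep(c("a", "b"), each = 2),
                   length_um = c(0.5, 2.4, 0.8, 1.1))
  expect_equal(percent_tubular(df), 50.0)
})

test_that("luciferase_fold normalises firefly to Renilla then to baseline", {
  plate <- data.frame(
    construct = rep("WT", 2), treatment = c("untreated", "TGFb"),
    replicate = 1L,
    fluc1 = c(300, 600), fluc2 = c(310, 620), fluc3 = c(290, 580),
    rluc = 100)
  got <- luciferase_fold(plate)
  expect_equal(got$fold, 2.0)
  expect_equal(got$value_untreated, 3.0)

  same <- plate; same[2, c("fluc1", "fluc2", "fluc3")] <- c(300, 310, 290)
  expect_equal(luciferase_fold(same)$fold, 1.0)

  # three replicates with distinct ratios: oracle mean-of-means quotient
  set.seed(8)
  tri <- do.call(rbind, lapply(1:3, function(r) {
    u <- stats::runif(3, 100, 400); tr <- stats::runif(3, 300, 900)
    data.frame(construct = "WT", treatment = c("untreated", "TGFb"),
               replicate = r,
               fluc1 = c(u[1], tr[1]), fluc2 = c(u[2], tr[2]),
               fluc3 = c(u[3], tr[3]), rluc = c(90 + r, 110 - r))
  }))
  oracle <- function(d) mean(rowMeans(d[, c("fluc1", "fluc2", "fluc3")]) /
                             d$rluc)
  want <- oracle(tri[tri$treatment == "TGFb", ]) /
    oracle(tri[tri$treatment == "untreated", ])
  expect_equal(luciferase_fold(tri)$fold, want)

  # scale invariance: rescaling all luminescence of a replicate
  scaled <- tri
  pick <- scaled$replicate == 2
  scaled[pick, c("fluc1", "fluc2", "fluc3", "rluc")] <-
    scaled[pick, c("fluc1", "fluc2", "fluc3", "rluc")] * 7
  expect_equal(luciferase_fold(scaled)$fold, luciferase_fold(tri)$fold)

  bad <- plate; bad$rluc[1] <- 0
  expect_error(luciferase_fold(bad), "rluc")
  expect_error(luciferase_fold(plate[plate$treatment == "TGFb", ]),
               "untreated")
})
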