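# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Peaked synthetic PFM: `strength` counts (out of 100) on the consensus
# base per column, remainder split equally among the other bases.
peaked_pfm <- function(matrix_id, tf_name, consensus, strengths = NULL) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  L <- length(bases)
  if (is.null(strengths)) strengths <- rep(c(92, 84, 95, 88), length.out = L)
  strengths <- rep(strengths, length.out = L)
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(L)) {
    counts[, i] <- (100 - strengths[i]) / 3
    counts[bases[i], i] <- strengths[i]
  }
  pfm(matrix_id, tf_name, counts)
}

#' Synthetic core motif panel
#'
#' Eight strongly peaked position frequency matrices labelled with the
#' transcription factors of interest (SMAD2/3 under the accession the
#' field associates with it, plus ATF4, SOX10, PPARG, PPARA and three
#' "private" factors).  The counts are synthetic: consensus sequences
#' and column strengths are chosen so that the motifs are mutually
#' dissimilar (no motif's consensus scores above the bona-fide
#' threshold under another motif on either strand), which keeps planted
#' fixtures free of cross-motif collisions.
#'
#' @return Named list of [pfm] objects keyed by TF name.
#' @export
core_motif_panel <- function() {
  panel <- list(
    peaked_pfm("MA0513.1", "SMAD2/3", "GTCTAG",
               c(95, 88, 92, 95, 86, 92)),
    peaked_pfm("MA0833.1", "ATF4", "TGATGCAA"),
    peaked_pfm("MA0442.1", "SOX10", "AACAATG"),
    peaked_pfm("MA0066.1", "PPARG", "AGGTCAAGGTCA"),
    peaked_pfm("MA1148.1", "PPARA", "TGAACTTTGAACT"),
    peaked_pfm("MA0506.1", "NRF1", "GCGCCTGCGC"),
    peaked_pfm("MA0162.1", "EGR1", "GCGTGGGCGT"),
    peaked_pfm("MA0114.1", "HNF4A", "CATTACGTGATC"))
  stats::setNames(panel, vapply(panel, `[[`, "", "tf_name"))
}

#' Sample a k-mer at a controlled relative score
#'
#' Finds a k-mer whose relative score under `pwm` lies within `band`
#' by randomised depth-first search over the motif's columns with
#' exact branch-and-bound pruning (suffix score bounds).  The search
#' is complete: if it exhausts without a hit the band is provably
#' unattainable and an error is raised.  Deterministic for a given
#' seed / RNG state.
#'
#' @param pwm A `pwm` object.
#' @param band Numeric `c(lo, hi)` within `[0, 1]`, `lo <= hi`.
#' @param seed Optional integer; when supplied the caller's RNG state
#'   is left untouched.
#' @return A character k-mer with `relative_score` in `band`.
#' @export
sample_site <- function(pwm, band, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, sample_site(pwm, band)))
  if (length(band) != 2L || band[1] > band[2] ||
      band[1] < 0 || band[2] > 1)
    stop("band must be c(lo, hi) with 0 <= lo <= hi <= 1")
  L <- ncol(pwm$logodds)
  rng <- pwm$s_max - pwm$s_min
  if (rng <= 0) {
    if (band[1] <= 1 && band[2] >= 1) return(pwm$consensus)
    stop("uniform motif: every k-mer scores 1.0, band infeasible")
  }
  eps <- 1e-9 * max(1, abs(rng))
  lo_abs <- pwm$s_min + band[1] * rng - eps
  hi_abs <- pwm$s_min + band[2] * rng + eps
  colmin <- apply(pwm$logodds, 2, min)
  colmax <- apply(pwm$logodds, 2, max)
  # suffix achievable bounds for columns j..L (index L+1 == 0)
  sufmin <- rev(cumsum(c(0, rev(colmin))))
  sufmax <- rev(cumsum(c(0, rev(colmax))))
  recurse <- function(j, acc) {
    if (j > L) return(character(0))
    for (b in sample.int(4L)) {
      v <- acc + pwm$logodds[b, j]
      if (v + sufmax[j + 1L] < lo_abs || v + sufmin[j + 1L] > hi_abs)
        next
      if (j == L) return(DNA_BASES[b])
      rest <- recurse(j + 1L, v)
      if (length(rest)) return(c(DNA_BASES[b], rest))
    }
    character(0)
  }
  res <- recurse(1L, 0)
  if (!length(res))
    stop(sprintf(
      "no k-mer of motif %s attains relative score in [%g, %g]",
      pwm$matrix_id, band[1], band[2]))
  paste(res, collapse = "")
}

#' Specify sites to plant in a synthetic promoter
#'
#' @param gene_id Gene the sites belong to.
#' @param tf_name TF name; must exist in the motif panel in use.
#' @param n_sites Number of sites.
#' @param band Relative-score band `c(lo, hi)` for the planted k-mers.
#' @param chromatin_status `"active"` (activating mark overlaps the
#'   site) or `"silent"` (an H3K27me3 interval overlaps it as well).
#' @param evidence_score ChIP-seq cluster score 0-1000 attached to the
#'   site's cluster interval; `NA` means no cluster interval at all.
#' @return One-row data.frame; rbind rows to build a full plan.
#' @export
plant_spec <- function(gene_id, tf_name, n_sites = 1L,
                       band = c(0.92, 1), chromatin_status = "active",
                       evidence_score = 800) {
  stopifnot(band[1] <= band[2], chromatin_status %in% c("active", "silent"))
  data.frame(gene_id = gene_id, tf_name = tf_name,
             n_sites = as.integer(n_sites), lo = band[1], hi = band[2],
             chromatin_status = chromatin_status,
             evidence_score = as.numeric(evidence_score),
             stringsAsFactors = FALSE)
}

.rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# local [o, o+m) (0-based) in a promoter of `plen` -> genomic interval
.local_to_genomic <- function(o, m, strand, pstart, pend) {
  if (strand == "+") c(pstart + o, pstart + o + m)
  else c(pend - o - m, pend - o)
}

#' Build a synthetic promoter fixture with known ground truth
#'
#' Generates, for each gene mentioned in `specs`, a dedicated
#' chromosome carrying a `length`-bp promoter immediately upstream of
#' a start codon (genes alternate between the two strands), plants the
#' requested motif instances at recorded offsets and strands, and
#' emits matched histone-mark and TF-cluster tracks encoding each
#' site's chromatin status and evidence score.  Background sequence is
#' drawn i.i.d. from the requested GC composition; windows that happen
#' to score above `threshold` for any panel motif without being
#' planted are re-drawn locally until the scan of every promoter
#' recovers exactly the planted sites.
#'
#' Planted sites are kept >= `min_separation` apart; because histone
#' marks act within `mark_window` of a site, genes mixing `"active"`
#' and `"silent"` sites require `min_separation` large enough that
#' marks cannot leak across sites (an error is raised otherwise).
#'
#' @param specs Data frame of [plant_spec()] rows.
#' @param length Promoter length in bp (default 10000, the upstream
#'   window the scanner uses).
#' @param gc Background GC fraction (default 0.5).
#' @param seed Integer seed; the whole fixture is a deterministic
#'   function of it.
#' @param panel Motif panel (named list of [pfm]); default
#'   [core_motif_panel()].
#' @param threshold Bona-fide relative-score threshold used for the
#'   spurious-hit sweep (default 0.89).
#' @param mark_window Half-width of the chromatin filter's "near"
#'   window the fixture must respect (default 1000).
#' @param min_separation Minimum distance between planted site starts
#'   (default `2 * mark_window + 100` when statuses are mixed within a
#'   gene, else 60).
#' @return List with `genome` (named character vector), `anchors`,
#'   `histone_track`, `cluster_track`, `truth` (one row per planted
#'   site: gene_id, matrix_id, tf_name, local_offset, site_strand,
#'   kmer, relative_score, chromatin_status, evidence_score), `pwms`,
#'   and `promoters` (list of `promoter_region`).
#' @export
build_promoter_fixture <- function(specs, length = 10000L, gc = 0.5,
                                   seed = 1L, panel = core_motif_panel(),
                                   threshold = 0.89, mark_window = 1000L,
                                   min_separation = NULL) {
  with_seed(seed, .build_promoter_fixture(specs, as.integer(length), gc, panel,
                                          threshold, mark_window,
                                          min_separation))
}

.build_promoter_fixture <- function(specs, plen, gc, panel, threshold,
                                    mark_window, min_separation) {
  stopifnot(all(specs$tf_name %in% names(panel)))
  pwms <- lapply(panel, pfm_to_pwm)
  genes <- unique(specs$gene_id)
  genome <- character(0)
  anchors <- NULL
  histone <- NULL
  cluster <- NULL
  truth <- NULL
  promoters <- list()
  act_cycle <- ACTIVATING_MARKS

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gspecs <- specs[specs$gene_id == g, ]
    mixed <- length(unique(gspecs$chromatin_status)) > 1L
    sep <- min_separation
    if (is.null(sep)) sep <- if (mixed) 2L * mark_window + 100L else 60L
    site_tf <- rep(gspecs$tf_name, gspecs$n_sites)
    site_lo <- rep(gspecs$lo, gspecs$n_sites)
    site_hi <- rep(gspecs$hi, gspecs$n_sites)
    site_status <- rep(gspecs$chromatin_status, gspecs$n_sites)
    site_ev <- rep(gspecs$evidence_score, gspecs$n_sites)
    nsite <- length(site_tf)
    lens <- vapply(site_tf, function(tf) ncol(pwms[[tf]]$logodds), 0L)
    if (nsite && (nsite - 1L) * sep + sum(lens) > plen - 2L * max(lens))
      stop(sprintf("gene '%s': too many sites for promoter length", g))
    strand <- if (gi %% 2L == 1L) "+" else "-"

    done <- FALSE
    for (attempt in 1:25) {
      seq <- .rand_seq(plen, gc)
      # non-overlapping offsets with minimum separation
      offsets <- integer(0)
      ok <- TRUE
      for (i in seq_len(nsite)) {
        placed <- FALSE
        for (try in 1:400) {
          o <- sample.int(plen - lens[i] + 1L, 1L) - 1L
          if (!any(abs(o - offsets) < sep + max(lens))) {
            offsets <- c(offsets, o); placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      site_strand <- sample(c("+", "-"), nsite, replace = TRUE)
      kmers <- character(nsite)
      for (i in seq_len(nsite)) {
        kmers[i] <- sample_site(pwms[[site_tf[i]]], c(site_lo[i], site_hi[i]))
        ins <- if (site_strand[i] == "+") kmers[i]
               else reverse_complement(kmers[i])
        substr(seq, offsets[i] + 1L, offsets[i] + lens[i]) <- ins
      }
      planted_cov <- rep(FALSE, plen)
      for (i in seq_len(nsite))
        planted_cov[seq.int(offsets[i] + 1L, offsets[i] + lens[i])] <- TRUE

      prom <- list(gene_id = g, chrom = paste0("chr_", g), strand = strand,
                   start = 0L, end = plen, sequence = seq,
                   length = plen, truncated = FALSE)
      class(prom) <- "promoter_region"
      clean <- FALSE
      for (iter in 1:60) {
        hits <- scan_promoter(pwms, prom, threshold)
        is_planted <- rep(FALSE, nrow(hits))
        if (nrow(hits)) {
          key_hit <- paste(hits$matrix_id, hits$local_offset)
          key_truth <- paste(vapply(site_tf,
                                    function(tf) pwms[[tf]]$matrix_id, ""),
                             offsets)
          is_planted <- key_hit %in% key_truth
        }
        spurious <- hits[!is_planted, , drop = FALSE]
        if (!nrow(spurious)) { clean <- TRUE; break }
        redrawn <- FALSE
        for (r in seq_len(nrow(spurious))) {
          span <- seq.int(spurious$local_offset[r] + 1L,
                          spurious$local_offset[r] + nchar(spurious$kmer[r]))
          bg <- span[!planted_cov[span]]
          if (!length(bg)) next
          repl <- strsplit(.rand_seq(length(bg), gc), "")[[1]]
          s <- strsplit(prom$sequence, "")[[1]]
          s[bg] <- repl
          prom$sequence <- paste(s, collapse = "")
          redrawn <- TRUE
        }
        if (!redrawn) break  # hit fully inside planted bases: restart gene
      }
      if (!clean) next
      seq <- prom$sequence

      # assemble chromosome so the promoter occupies the stated window
      if (strand == "+") {
        chromseq <- paste0(seq, "ATG")
        scp <- plen
        pstart <- 0L; pend <- plen
      } else {
        chromseq <- paste0("T", reverse_complement(seq))
        scp <- 0L
        pstart <- 1L; pend <- plen + 1L
      }
      chrom <- paste0("chr_", g)
      genome[chrom] <- chromseq
      anchors <- rbind(anchors,
                       data.frame(gene_id = g, chrom = chrom,
                                  strand = strand, start_codon_pos = scp,
                                  stringsAsFactors = FALSE))
      prom$start <- pstart; prom$end <- pend
      promoters[[g]] <- prom

      for (i in seq_len(nsite)) {
        gint <- .local_to_genomic(offsets[i], lens[i], strand, pstart, pend)
        mark <- act_cycle[1L + (i - 1L) %% 3L]
        histone <- rbind(histone,
                         data.frame(chrom = chrom,
                                    start = max(0L, gint[1] - 50L),
                                    end = gint[2] + 50L, label = mark,
                                    score = 0, stringsAsFactors = FALSE))
        if (site_status[i] == "silent")
          histone <- rbind(histone,
                           data.frame(chrom = chrom,
                                      start = max(0L, gint[1] - 50L),
                                      end = gint[2] + 50L,
                                      label = REPRESSIVE_MARK, score = 0,
                                      stringsAsFactors = FALSE))
        if (!is.na(site_ev[i]))
          cluster <- rbind(cluster,
                           data.frame(chrom = chrom, start = gint[1],
                                      end = gint[2], label = site_tf[i],
                                      score = site_ev[i],
                                      stringsAsFactors = FALSE))
        truth <- rbind(truth,
                       data.frame(gene_id = g,
                                  matrix_id = pwms[[site_tf[i]]]$matrix_id,
                                  tf_name = site_tf[i],
                                  local_offset = offsets[i],
                                  site_strand = site_strand[i],
                                  kmer = kmers[i],
                                  relative_score =
                                    relative_score(pwms[[site_tf[i]]],
                                                   kmers[i]),
                                  chromatin_status = site_status[i],
                                  evidence_score = site_ev[i],
                                  stringsAsFactors = FALSE))
      }
      done <- TRUE
      break
    }
    if (!done)
      stop(sprintf("gene '%s': could not build a collision-free promoter", g))
  }
  if (is.null(histone))
    histone <- data.frame(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          score = numeric(), stringsAsFactors = FALSE)
  if (is.null(cluster))
    cluster <- data.frame(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          score = numeric(), stringsAsFactors = FALSE)
  list(genome = genome, anchors = anchors,
       histone_track = validate_track(histone, "histone"),
       cluster_track = validate_track(cluster, "tf_cluster"),
       truth = truth, pwms = pwms, panel = panel, promoters = promoters)
}

#' Three-promoter fixture reproducing the shared-TF Venn partition
#'
#' Builds promoters for the three PEX11 isoform genes whose surviving
#' TF sets realise the published sharing structure: beta and gamma
#' share SMAD2/3, ATF4, SOX10 and PPARG (4 TFs); alpha and gamma share
#' only PPARA (1 TF); alpha and beta share none; and each gene carries
#' at least one private TF.  All sites are planted in active chromatin
#' with cluster evidence >= 500, so the full scan + filter pipeline
#' recovers exactly these sets.
#'
#' @param seed Integer seed (default 42).
#' @return A fixture list as returned by [build_promoter_fixture()].
#' @export
figure6_fixture <- function(seed = 42L) {
  specs <- rbind(
    plant_spec("PEX11B", "SMAD2/3"), plant_spec("PEX11B", "ATF4"),
    plant_spec("PEX11B", "SOX10"), plant_spec("PEX11B", "PPARG"),
    plant_spec("PEX11B", "NRF1"),
    plant_spec("PEX11G", "SMAD2/3"), plant_spec("PEX11G", "ATF4"),
    plant_spec("PEX11G", "SOX10"), plant_spec("PEX11G", "PPARG"),
    plant_spec("PEX11G", "PPARA"), plant_spec("PEX11G", "EGR1"),
    plant_spec("PEX11A", "PPARA"), plant_spec("PEX11A", "HNF4A"))
  specs$evidence_score <- 500 + (seq_len(nrow(specs)) * 37) %% 500
  build_promoter_fixture(specs, seed = seed)
}

#' Wild-type / mutant promoter-construct fixture
#'
#' A 1,302-bp candidate promoter sequence containing exactly one
#' above-threshold 6-bp SMAD2/3 core site; deleting that site with
#' [delete_motif()] yields the 1,296-bp mutant, which carries no
#' SMAD2/3 hit at the bona-fide threshold.
#'
#' @param seed Integer seed.
#' @param threshold Relative-score threshold used to verify uniqueness
#'   (default 0.89).
#' @return List with `wt` (1302-bp sequence), `site` (`c(start, end)`,
#'   0-based half-open local interval of the SMAD2/3 core),
#'   `mutant` (1296-bp sequence) and `pwm` (the SMAD2/3 model).
#' @export
construct_fixture <- function(seed = 1L, threshold = 0.89) {
  with_seed(seed, {
    smad <- pfm_to_pwm(core_motif_panel()[["SMAD2/3"]])
    L <- ncol(smad$logodds)
    wt_len <- 1302L
    for (attempt in 1:100) {
      seq <- .rand_seq(wt_len)
      off <- sample.int(wt_len - L + 1L, 1L) - 1L
      substr(seq, off + 1L, off + L) <- smad$consensus
      prom <- structure(list(gene_id = "PEX11B_construct", chrom = "construct",
                             strand = "+", start = 0L, end = wt_len,
                             sequence = seq, length = wt_len,
                             truncated = FALSE),
                        class = "promoter_region")
      hits <- scan_promoter(smad, prom, threshold)
      if (!(nrow(hits) == 1L && hits$local_offset == off)) next
      mut <- delete_motif(seq, c(off, off + L))
      pm <- prom; pm$sequence <- mut; pm$length <- nchar(mut)
      pm$end <- pm$length
      if (nrow(scan_promoter(smad, pm, threshold)) == 0L)
        return(list(wt = seq, site = c(off, off + L), mutant = mut,
                    pwm = smad))
    }
    stop("could not realise a unique-site construct; try another seed")
  })
}

#' Delete a motif site from a sequence
#'
#' @param sequence Character sequence.
#' @param site `c(start, end)` 0-based half-open interval to excise.
#' @return The sequence with the site removed.
#' @export
delete_motif <- function(sequence, site) {
  n <- nchar(sequence)
  if (site[1] < 0 || site[2] > n || site[1] >= site[2])
    stop("site interval outside sequence")
  paste0(substr(sequence, 1L, site[1]),
         substr(sequence, site[2] + 1L, n))
}

#' Simulate a qPCR Ct table with programmed fold inductions
#'
#' Target Ct at time t is `base_ct - log2(fold(t)) + N(0, noise_sd)`;
#' the invariant control gene is flat apart from the same noise.  With
#' `noise_sd = 0`, [relative_expression()] recovers the programmed
#' folds exactly (calibrator = the first time point).
#'
#' @param fold_schedule Named list: gene -> numeric vector of fold
#'   changes (relative to the first time point) over `times`.
#' @param times Time points in hours (default `c(6, 12, 24, 48, 72)`).
#' @param base_ct Named numeric of per-gene baseline Ct (default 25
#'   for targets); the control gene uses `control_ct`.
#' @param control_gene Invariant control name (default `"18S"`).
#' @param control_ct Control baseline Ct (default 10).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0).
#' @param n_replicates Replicates per gene x time (default 2,
#'   mirroring duplicate qPCR reactions).
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `time_h`, `replicate`, `ct`.
#' @export
make_ct_table <- function(fold_schedule, times = c(6, 12, 24, 48, 72),
                          base_ct = NULL, control_gene = "18S",
                          control_ct = 10, noise_sd = 0,
                          n_replicates = 2L, seed = 1L) {
  stopifnot(all(lengths(fold_schedule) == length(times)))
  with_seed(seed, {
    rows <- list()
    for (g in names(fold_schedule)) {
      b <- if (!is.null(base_ct) && g %in% names(base_ct)) base_ct[[g]] else 25
      for (ti in seq_along(times)) {
        ct0 <- b - log2(fold_schedule[[g]][ti])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, time_h = times[ti], replicate = seq_len(n_replicates),
          ct = ct0 + stats::rnorm(n_replicates, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    for (ti in seq_along(times)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = control_gene, time_h = times[ti],
        replicate = seq_len(n_replicates),
        ct = control_ct + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a dual-luciferase plate with programmed treatment folds
#'
#' Untreated firefly/Renilla ratios sit near `base_ratio`; treated
#' ratios near `base_ratio * fold`.  The promoterless construct (if
#' present in `construct_folds`, or added with `add_promoterless`)
#' emits a near-zero firefly signal.  Each reaction carries three
#' firefly reads.
#'
#' @param construct_folds Named numeric: construct -> programmed
#'   TGFb-response fold.
#' @param base_ratio Untreated firefly/Renilla ratio (default 2).
#' @param noise_cv Multiplicative coefficient of variation applied to
#'   each read (default 0).
#' @param n_replicates Replicate reactions per arm (default 3).
#' @param rluc Renilla luminescence per reaction (default 1e5).
#' @param treated,untreated Treatment labels.
#' @param add_promoterless Include a `promoterless` control construct
#'   (default TRUE).
#' @param seed Integer seed.
#' @return Data frame with columns `construct`, `treatment`,
#'   `replicate`, `fluc1..3`, `rluc`.
#' @export
make_luciferase_plate <- function(construct_folds, base_ratio = 2,
                                  noise_cv = 0, n_replicates = 3L,
                                  rluc = 1e5, treated = "TGFb",
                                  untreated = "untreated",
                                  add_promoterless = TRUE, seed = 1L) {
  with_seed(seed, {
    if (add_promoterless && !"promoterless" %in% names(construct_folds))
      construct_folds <- c(construct_folds, promoterless = 1)
    rows <- list()
    for (con in names(construct_folds)) {
      ratio0 <- if (con == "promoterless") base_ratio * 1e-3 else base_ratio
      for (trt in c(untreated, treated)) {
        f <- if (trt == treated) construct_folds[[con]] else 1
        for (rep in seq_len(n_replicates)) {
          mu <- ratio0 * f * rluc
          reads <- mu * (1 + stats::rnorm(3L, 0, noise_cv))
          rows[[length(rows) + 1L]] <- data.frame(
            construct = con, treatment = trt, replicate = rep,
            fluc1 = reads[1], fluc2 = reads[2], fluc3 = reads[3],
            rluc = rluc, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a per-cell peroxisome particle-length table
#'
#' Tubular cells carry at least one particle longer than 2 um;
#' spherical cells only particles in the 0.3-2 um range; a little
#' sub-0.3-um debris is sprinkled over all cells.
#'
#' @param n_cells Number of cells.
#' @param p_tubular Probability that a cell is tubular.
#' @param particles_per_cell Mean peroxisome count per cell.
#' @param condition Condition label attached to each row.
#' @param seed Integer seed.
#' @return Data frame with columns `cell_id`, `condition`,
#'   `length_um`.
#' @export
make_morphology_table <- function(n_cells = 100L, p_tubular = 0.3,
                                  particles_per_cell = 30,
                                  condition = "control", seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_cells), function(i) {
      n <- max(1L, stats::rpois(1L, particles_per_cell))
      len <- stats::runif(n, 0.3, 1.9)
      tub <- stats::runif(1) < p_tubular
      if (tub) len[1] <- stats::runif(1, 2.2, 6)
      debris <- stats::runif(stats::rpois(1L, 2), 0.05, 0.29)
      data.frame(cell_id = sprintf("cell_%03d", i), condition = condition,
                 length_um = c(len, debris), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a promoter fixture to a directory
#'
#' Emits `genome.fa`, `anchors.tsv`, `motifs.jaspar`, `histone.bed`,
#' `clusters.bed` and `truth.tsv` in the formats the pipeline reads.
#'
#' @param fixture A fixture from [build_promoter_fixture()] or
#'   [figure6_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             anchors = file.path(dir, "anchors.tsv"),
             motifs = file.path(dir, "motifs.jaspar"),
             histone = file.path(dir, "histone.bed"),
             clusters = file.path(dir, "clusters.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_genome(fixture$genome, paths["genome"])
  write_anchors(fixture$anchors, paths["anchors"])
  write_jaspar(fixture$panel, paths["motifs"])
  write_track(fixture$histone_track, paths["histone"])
  write_track(fixture$cluster_track, paths["clusters"])
  utils::write.table(fixture$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
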