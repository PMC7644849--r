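# Independent oracles: deliberately naive implementations used to
# cross-check the package's vectorised paths.

toy_pfm <- function() {
  pfm("MA0001.1", "TOY", rbind(A = c(8, 0), C = c(0, 8),
                               G = c(0, 0), T = c(0, 0)))
}

toy_pwm <- function() pfm_to_pwm(toy_pfm())

BASES <- c("A", "C", "G", "T")

# scalar per-character log-odds sum (no matrix indexing tricks)
oracle_score <- function(pwm, kmer) {
  chars <- strsplit(kmer, "")[[1]]
  s <- 0
  for (j in seq_along(chars))
    s <- s + unname(pwm$logodds[chars[j], j])
  s
}

oracle_relative <- function(pwm, kmer) {
  (oracle_score(pwm, kmer) - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

# every k-mer of length L
all_kmers <- function(L) {
  do.call(paste0, expand.grid(rep(list(BASES), L),
                              stringsAsFactors = FALSE)[, L:1, drop = FALSE])
}

# exhaustive dual-strand scan: substring every window, score both
# orientations with the scalar oracle
oracle_scan <- function(pwms, promoter, threshold) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  seq <- promoter$sequence
  n <- nchar(seq)
  rows <- list()
  for (p in pwms) {
    L <- ncol(p$logodds)
    if (n < L) next
    for (o in 0:(n - L)) {
      win <- substr(seq, o + 1, o + L)
      for (strand in c("+", "-")) {
        kmer <- if (strand == "+") win else oracle_revcomp(win)
        rel <- oracle_relative(p, kmer)
        if (rel > threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = promoter$gene_id, matrix_id = p$matrix_id,
            local_offset = o, hit_strand = strand, kmer = kmer,
            relative_score = rel, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), matrix_id = character(),
                      local_offset = integer(), hit_strand = character(),
                      kmer = character(), relative_score = numeric()))
  df <- do.call(rbind, rows)
  df[order(df$gene_id, df$local_offset, df$matrix_id, df$hit_strand), ]
}

random_promoter <- function(n, gene_id = "g1") {
  structure(list(gene_id = gene_id, chrom = paste0("chr_", gene_id),
                 strand = "+", start = 0L, end = n,
                 sequence = paste(sample(BASES, n, replace = TRUE),
                                  collapse = ""),
                 length = n, truncated = FALSE),
            class = "promoter_region")
}

random_pwm <- function(L, id = "MA9999.1", tf = "RND") {
  counts <- matrix(stats::rpois(4 * L, 5) + 1, 4, L,
                   dimnames = list(BASES, NULL))
  pfm_to_pwm(pfm(id, tf, counts))
}

# minimal synthetic hit row for filter tests
fake_hit <- function(gene_id = "g1", chrom = "chr_g1", tf = "SMAD2/3",
                     gstart = 100L, gend = 106L, rel = 0.95) {
  data.frame(gene_id = gene_id, chrom = chrom, matrix_id = "MA0513.1",
             tf_name = tf, local_offset = gstart, gstart = gstart,
             gend = gend, hit_strand = "+", kmer = "GTCTAG",
             score = 1, relative_score = rel, efficiency = rel,
             chromatin_active = "untested", evidence_pass = "untested",
             stringsAsFactors = FALSE)
}
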