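#' Read a genome from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a
#' named uppercase character vector keyed by the first whitespace-
#' delimited token of each FASTA header.
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read gene anchors (start-codon coordinates)
#'
#' Two layouts are accepted, both tab-delimited and 0-based:
#' a 4-column TSV with header `gene_id, chrom, strand, start_codon_pos`,
#' or BED6 (`chrom, start, end, name, score, strand`) where `start` is
#' the start-codon base and `name` the gene id.
#'
#' @param path File path.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start_codon_pos`.
#' @export
read_anchors <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    df <- df[, c("gene_id", "chrom", "strand", "start_codon_pos")]
  } else {
    bed <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("anchor BED needs 6 columns")
    df <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                     strand = bed[[6]], start_codon_pos = bed[[2]],
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(df$strand %in% c("+", "-")))
  df
}

#' Write gene anchors as a 4-column TSV
#' @param anchors Data frame as returned by [read_anchors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  utils::write.table(anchors[, c("gene_id", "chrom", "strand",
                                 "start_codon_pos")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the upstream promoter region of a gene
#'
#' Returns the `window` bases immediately 5' of the start codon on the
#' gene's strand (the start-codon base itself is excluded).  For a
#' plus-strand gene with the start codon at 0-based position `p` the
#' genomic interval is `[p - window, p)`; for a minus-strand gene it is
#' `[p + 1, p + 1 + window)` and the returned sequence is
#' reverse-complemented so that it reads 5' to 3' on the gene's strand.
#' Windows extending past a chromosome edge are truncated and flagged.
#'
#' @param genome Named character vector (see [read_genome()]).
#' @param anchor One-row data.frame or list with `gene_id`, `chrom`,
#'   `strand`, `start_codon_pos`.
#' @param window Width in bp (default 10000).
#' @return An object of class `promoter_region`: list with `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open on the
#'   reference strand), `sequence`, `length`, `truncated`.
#' @export
extract_promoter <- function(genome, anchor, window = 10000L) {
  chrom <- as.character(anchor$chrom)
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' not in genome", chrom))
  clen <- nchar(genome[[chrom]])
  p <- as.integer(anchor$start_codon_pos)
  if (p < 0L || p >= clen)
    stop(sprintf("start codon position %d outside chromosome '%s' [0, %d)",
                 p, chrom, clen))
  strand <- as.character(anchor$strand)
  if (strand == "+") {
    start <- max(0L, p - as.integer(window))
    end <- p
    truncated <- (p - window) < 0L
  } else if (strand == "-") {
    start <- p + 1L
    end <- min(clen, p + 1L + as.integer(window))
    truncated <- (p + 1L + window) > clen
  } else stop("strand must be '+' or '-'")
  if (end <= start)
    stop(sprintf("gene '%s': empty promoter window", anchor$gene_id))
  seq <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") seq <- reverse_complement(seq)
  structure(list(gene_id = as.character(anchor$gene_id), chrom = chrom,
                 strand = strand, start = start, end = end,
                 sequence = seq, length = end - start,
                 truncated = truncated),
            class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(sprintf("<promoter_region> %s %s:%d-%d (%s) %d bp%s\n", x$gene_id,
              x$chrom, x$start, x$end, x$strand, x$length,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

empty_hits <- function() {
  data.frame(gene_id = character(), chrom = character(),
             matrix_id = character(),
             tf_name = character(), local_offset = integer(),
             gstart = integer(), gend = integer(),
             hit_strand = character(), kmer = character(),
             score = numeric(), relative_score = numeric(),
             efficiency = numeric(), chromatin_active = character(),
             evidence_pass = character(), stringsAsFactors = FALSE)
}

# Per-offset log-odds scores of `logodds` along integer-encoded
# sequence idx (values 1..4).  Returns numeric vector of length
# n - L + 1 (empty if the sequence is shorter than the motif).
.slide_scores <- function(logodds, idx) {
  L <- ncol(logodds)
  n <- length(idx)
  if (n < L) return(numeric(0))
  nwin <- n - L + 1L
  s <- numeric(nwin)
  for (j in seq_len(L))
    s <- s + logodds[idx[seq.int(j, length.out = nwin)] + 4L * (j - 1L)]
  s
}

.revcomp_logodds <- function(logodds) {
  # scoring the reverse complement of each window == scoring the window
  # itself with a base-complemented, column-reversed matrix
  m <- logodds[4:1, rev(seq_len(ncol(logodds))), drop = FALSE]
  rownames(m) <- DNA_BASES
  m
}

#' Scan a promoter with a panel of PWMs
#'
#' Slides every motif base-pair by base-pair across the promoter
#' sequence on both strands and reports every window whose relative
#' score strictly exceeds `threshold`.  A minus-strand hit means the
#' motif matches the reverse complement of the promoter window; its
#' `local_offset` is still the 0-based offset of the window's leftmost
#' base in the promoter sequence, and `kmer` is the motif-strand
#' (reverse-complemented) sequence actually scored.
#'
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param promoter A `promoter_region` (or any list with `gene_id`,
#'   `sequence`, plus genomic anchoring fields for coordinate mapping).
#' @param threshold Relative-score cutoff in `[0, 1]`; strictly-greater
#'   comparison (default 0.89).
#' @return A hits data.frame (one row per hit) with columns `gene_id`,
#'   `matrix_id`, `tf_name`, `local_offset`, `gstart`, `gend`,
#'   `hit_strand`, `kmer`, `score`, `relative_score`, `efficiency`,
#'   `chromatin_active`, `evidence_pass`; the two filter flags start as
#'   `"untested"`.  Rows are sorted by (gene_id, local_offset,
#'   matrix_id, hit_strand).
#' @export
scan_promoter <- function(pwms, promoter, threshold = 0.89) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  seq <- toupper(promoter$sequence)
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  if (anyNA(idx))
    stop(sprintf("promoter '%s' contains non-ACGT bases", promoter$gene_id))
  rows <- list()
  for (p in pwms) {
    L <- ncol(p$logodds)
    rng <- p$s_max - p$s_min
    for (strand in c("+", "-")) {
      m <- if (strand == "+") p$logodds else .revcomp_logodds(p$logodds)
      s <- .slide_scores(m, idx)
      if (!length(s)) next
      rel <- if (rng > 0) (s - p$s_min) / rng else rep(1, length(s))
      keep <- which(rel > threshold)
      if (!length(keep)) next
      kmers <- substring(seq, keep, keep + L - 1L)
      if (strand == "-") kmers <- reverse_complement(kmers)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = promoter$gene_id,
        chrom = if (is.null(promoter$chrom)) promoter$gene_id
                else promoter$chrom,
        matrix_id = p$matrix_id,
        tf_name = p$tf_name, local_offset = keep - 1L,
        gstart = NA_integer_, gend = NA_integer_, hit_strand = strand,
        kmer = kmers, score = s[keep], relative_score = rel[keep],
        efficiency = rel[keep] / relative_score(p, p$consensus),
        chromatin_active = "untested", evidence_pass = "untested",
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$motif_len <- L
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- map_to_genomic(hits, promoter)
  hits$motif_len <- NULL
  hits <- hits[order(hits$gene_id, hits$local_offset, hits$matrix_id,
                     hits$hit_strand), ]
  rownames(hits) <- NULL
  hits
}

#' Map promoter-local hit offsets to genomic coordinates
#'
#' Fills `gstart`/`gend` (0-based half-open, reference strand) from
#' `local_offset` given the promoter's genomic anchoring.  For a
#' minus-strand promoter the local axis runs antiparallel to the
#' reference, so offset `o` with motif length `m` maps to
#' `[end - o - m, end - o)`.  The inverse ([map_to_local()]) recovers
#' the offset exactly.
#'
#' @param hits Hits data.frame; motif length is taken from
#'   `nchar(kmer)` unless a `motif_len` column is present.
#' @param promoter The `promoter_region` the hits came from.
#' @return `hits` with `gstart`/`gend` populated.
#' @export
map_to_genomic <- function(hits, promoter) {
  if (!nrow(hits)) return(hits)
  m <- if ("motif_len" %in% names(hits)) hits$motif_len else nchar(hits$kmer)
  o <- hits$local_offset
  if (any(o < 0L | o + m > promoter$length))
    stop("local_offset outside promoter")
  if (promoter$strand == "+") {
    hits$gstart <- promoter$start + o
    hits$gend <- promoter$start + o + m
  } else {
    hits$gstart <- promoter$end - o - m
    hits$gend <- promoter$end - o
  }
  hits
}

#' Recover promoter-local offsets from genomic coordinates
#' @param hits Hits data.frame with `gstart`/`gend` set.
#' @param promoter The `promoter_region`.
#' @return `hits` with `local_offset` recomputed.
#' @export
map_to_local <- function(hits, promoter) {
  if (!nrow(hits)) return(hits)
  if (promoter$strand == "+") {
    hits$local_offset <- hits$gstart - promoter$start
  } else {
    hits$local_offset <- promoter$end - hits$gend
  }
  hits
}

#' Write hits as TSV
#' @param hits Hits data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read hits written by [write_hits()]
#' @param path TSV path.
#' @return Hits data.frame.
#' @export
read_hits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df
}

#' Write hits as BED6
#'
#' The BED score column is `round(1000 * relative_score)`; the name
#' column is `matrix_id|tf_name`.  The BED strand is the hit strand
#' relative to the reference: for minus-strand promoters the hit
#' strand is flipped.
#'
#' @param hits Hits data.frame with genomic coordinates.
#' @param promoters Named list of `promoter_region`s keyed by gene_id
#'   (used to orient the strand); if `NULL`, `hit_strand` is written
#'   as-is.
#' @param chrom_of Named character vector mapping gene_id to
#'   chromosome; defaults to taking `chrom` from `promoters`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, promoters = NULL, chrom_of = NULL) {
  if (is.null(chrom_of) && !is.null(promoters))
    chrom_of <- vapply(promoters, `[[`, "", "chrom")
  strand <- hits$hit_strand
  if (!is.null(promoters)) {
    pstr <- vapply(promoters, `[[`, "", "strand")[hits$gene_id]
    flip <- !is.na(pstr) & pstr == "-"
    strand[flip] <- ifelse(hits$hit_strand[flip] == "+", "-", "+")
  }
  chrom <- if (!is.null(chrom_of)) chrom_of[hits$gene_id] else hits$gene_id
  bed <- data.frame(chrom = chrom, start = hits$gstart, end = hits$gend,
                    name = paste(hits$matrix_id, hits$tf_name, sep = "|"),
                    score = round(1000 * hits$relative_score),
                    strand = strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
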