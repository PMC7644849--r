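DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix
#'
#' A PFM holds raw per-position base counts for a transcription-factor
#' binding motif, as distributed by the JASPAR database.  Rows are the
#' four DNA bases in the fixed order A, C, G, T; columns are motif
#' positions.
#'
#' @param matrix_id Motif accession, e.g. `"MA0513.1"`.
#' @param tf_name Transcription-factor name, e.g. `"SMAD2/3"`.
#' @param counts Numeric 4 x L matrix of non-negative counts.  Row
#'   names, if present, must be a permutation of `A,C,G,T`; rows are
#'   reordered to the canonical order.
#' @return An object of class `pfm` with elements `matrix_id`,
#'   `tf_name` and `counts`.
#' @examples
#' pfm("MA0001.1", "TOY", rbind(A = c(8, 0), C = c(0, 8),
#'                              G = c(0, 0), T = c(0, 0)))
#' @export
pfm <- function(matrix_id, tf_name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("PFM must have exactly 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("PFM row names must be A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- DNA_BASES
  }
  if (ncol(counts) < 1L) stop("motif length must be >= 1")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0))
    stop("every PFM column needs at least one positive count")
  structure(list(matrix_id = as.character(matrix_id),
                 tf_name = as.character(tf_name),
                 counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s %s (L=%d)\n", x$matrix_id, x$tf_name,
              ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @export
length.pfm <- function(x) ncol(x$counts)

#' Read motifs from a JASPAR PFM text stream
#'
#' Accepts both JASPAR dialects: the bracketed 2016+ layout
#' (`A  [ 1 2 3 ]`) and the plain whitespace 4-row layout.  Each record
#' is a `>ID NAME` header followed by four count rows; row labels, when
#' present, may appear in any order and are normalised to A, C, G, T.
#'
#' @param con Path to a file, or a character vector of lines (anything
#'   containing a newline or starting with `>` is treated as literal
#'   text).
#' @return A list of [pfm] objects (possibly empty).
#' @seealso [write_jaspar()] for the bit-exact inverse in the plain
#'   dialect.
#' @export
read_jaspar <- function(con) {
  if (length(con) == 1L && !grepl("[>\n]", con)) {
    lines <- readLines(con)
  } else if (length(con) == 1L && grepl("\n", con)) {
    lines <- strsplit(con, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- con
  }
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())

  heads <- grep("^>", lines)
  if (length(heads) == 0L || heads[1] != 1L)
    stop(sprintf("line %d: expected JASPAR header '>ID NAME'",
                 if (length(lineno)) lineno[1] else 1L))
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    h <- heads[k]
    body <- lines[seq.int(h + 1L, length.out = bounds[k + 1L] - h - 1L)]
    if (length(body) != 4L)
      stop(sprintf("line %d: record has %d count rows, expected 4",
                   lineno[h], length(body)))
    hd <- sub("^>\\s*", "", lines[h])
    toks <- strsplit(trimws(hd), "\\s+")[[1]]
    if (length(toks) < 1L || !nzchar(toks[1]))
      stop(sprintf("line %d: malformed header", lineno[h]))
    mid <- toks[1]
    tf <- if (length(toks) >= 2L) paste(toks[-1], collapse = " ") else toks[1]

    labels <- character(4)
    rows <- vector("list", 4)
    for (r in 1:4) {
      ln <- body[r]
      m <- regmatches(ln, regexec("^\\s*([ACGTacgt])[: \t]", ln,
                                  perl = TRUE))[[1]]
      if (length(m)) {
        labels[r] <- toupper(m[2])
        ln <- sub("^\\s*[ACGTacgt][: \t]", "", ln, perl = TRUE)
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(vals) == 0L || anyNA(vals))
        stop(sprintf("line %d: non-numeric count row", lineno[h] + r))
      if (any(vals < 0))
        stop(sprintf("line %d: negative count", lineno[h] + r))
      rows[[r]] <- vals
    }
    L <- unique(lengths(rows))
    if (length(L) != 1L)
      stop(sprintf("line %d: ragged count rows (lengths %s)",
                   lineno[h] + 1L, paste(lengths(rows), collapse = ",")))
    counts <- do.call(rbind, rows)
    if (all(nzchar(labels))) {
      if (!setequal(labels, DNA_BASES))
        stop(sprintf("line %d: row labels must be A,C,G,T", lineno[h] + 1L))
      rownames(counts) <- labels
      counts <- counts[DNA_BASES, , drop = FALSE]
    } else {
      rownames(counts) <- DNA_BASES
    }
    out[[k]] <- pfm(mid, tf, counts)
  }
  out
}

#' Write motifs in plain JASPAR 4-row dialect
#'
#' Inverse of [read_jaspar()]: counts are written as integers when
#' integral so that a read/write round trip reproduces the input
#' exactly.
#'
#' @param pfms A list of [pfm] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  # integral counts print as integers; fractional ones keep full
  # precision so read/write round trips are bit-exact
  fmt1 <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           sprintf("%.17g", x))
  }
  lines <- unlist(lapply(pfms, function(p) {
    c(sprintf(">%s %s", p$matrix_id, p$tf_name),
      vapply(DNA_BASES, function(b)
        paste(fmt1(p$counts[b, ]), collapse = "\t"), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' Counts are turned into probabilities with a background-weighted
#' pseudocount and expressed as log2 odds against the background:
#' `logodds[b, i] = log2(((counts[b, i] + pc * bg[b]) / (N_i + pc)) / bg[b])`
#' where `N_i` is the column count sum.  The minimum and maximum
#' achievable site scores (`s_min`, `s_max`; the column-wise sums of
#' per-column minima/maxima) define the relative "potential match"
#' scale, and the consensus takes each column's arg-max base with ties
#' broken alphabetically.
#'
#' @param x A [pfm].
#' @param background Base probabilities (A, C, G, T) summing to 1.
#'   Default uniform.
#' @param pseudocount Positive smoothing mass. Default 1.
#' @return An object of class `pwm` with elements `matrix_id`,
#'   `tf_name`, `logodds`, `background`, `pseudocount`, `s_min`,
#'   `s_max`, `consensus`.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(inherits(x, "pfm"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 positive probabilities summing to 1")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("pseudocount must be a positive scalar")
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  N <- colSums(x$counts)
  prob <- sweep(x$counts + pseudocount * background, 2, N + pseudocount, "/")
  logodds <- log2(sweep(prob, 1, background, "/"))
  new_pwm(x$matrix_id, x$tf_name, logodds, background, pseudocount)
}

# Low-level constructor: derives s_min/s_max/consensus from a log-odds
# matrix.  Used by pfm_to_pwm() and by tests that need exact score
# values unreachable through count arithmetic.
new_pwm <- function(matrix_id, tf_name, logodds,
                    background = rep(0.25, 4), pseudocount = NA_real_) {
  logodds <- as.matrix(logodds)
  rownames(logodds) <- DNA_BASES
  cons_idx <- apply(logodds, 2, which.max)   # which.max = first max: A<C<G<T
  structure(list(matrix_id = as.character(matrix_id),
                 tf_name = as.character(tf_name),
                 logodds = logodds,
                 background = stats::setNames(as.numeric(background),
                                              DNA_BASES),
                 pseudocount = pseudocount,
                 s_min = sum(apply(logodds, 2, min)),
                 s_max = sum(apply(logodds, 2, max)),
                 consensus = paste(DNA_BASES[cons_idx], collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s %s (L=%d) consensus=%s score range [%.3f, %.3f]\n",
              x$matrix_id, x$tf_name, ncol(x$logodds), x$consensus,
              x$s_min, x$s_max))
  invisible(x)
}

#' @export
length.pwm <- function(x) ncol(x$logodds)

.kmer_index <- function(kmer) {
  idx <- match(strsplit(toupper(kmer), "")[[1]], DNA_BASES)
  idx
}

#' Score a k-mer against a PWM
#'
#' Sums the per-position log2-odds contributions of the k-mer's bases.
#' The result always lies in `[s_min, s_max]`.
#'
#' @param pwm A `pwm` object.
#' @param kmer Character scalar over A/C/G/T of the motif's length.
#' @param ambiguous How to treat non-ACGT bases: `"reject"` (default,
#'   error) or `"background"` (contribute the background-expected
#'   log-odds of that column).
#' @return Numeric log2-odds score.
#' @export
score_site <- function(pwm, kmer, ambiguous = c("reject", "background")) {
  ambiguous <- match.arg(ambiguous)
  L <- ncol(pwm$logodds)
  if (nchar(kmer) != L)
    stop(sprintf("k-mer length %d != motif length %d", nchar(kmer), L))
  idx <- .kmer_index(kmer)
  if (anyNA(idx)) {
    if (ambiguous == "reject")
      stop("k-mer contains a non-ACGT base")
    contrib <- colSums(pwm$logodds * pwm$background)  # E[logodds] per column
    ok <- !is.na(idx)
    s <- sum(pwm$logodds[cbind(idx[ok], which(ok))]) + sum(contrib[!ok])
    return(s)
  }
  sum(pwm$logodds[cbind(idx, seq_len(L))])
}

#' Relative ("potential match") score of a k-mer
#'
#' The site score rescaled to `[0, 1]` by the motif's minimum and
#' maximum achievable scores: `(s - s_min) / (s_max - s_min)`.  A
#' fully uniform motif (`s_max == s_min`) scores 1 by convention.
#'
#' @inheritParams score_site
#' @return Numeric in `[0, 1]`.
#' @export
relative_score <- function(pwm, kmer, ambiguous = c("reject", "background")) {
  rng <- pwm$s_max - pwm$s_min
  if (rng <= 0) return(1.0)
  (score_site(pwm, kmer, ambiguous) - pwm$s_min) / rng
}

#' Consensus-relative binding efficiency of a k-mer
#'
#' The k-mer's relative score divided by the consensus sequence's
#' relative score.  Because the consensus attains `s_max` whenever
#' column maxima are unique, this usually equals the relative score
#' itself; the quotient form keeps the statistic well defined for
#' motifs with tied columns.
#'
#' @inheritParams score_site
#' @return Numeric; 1 for the consensus, 0 for the worst k-mer.
#' @export
binding_efficiency <- function(pwm, kmer,
                               ambiguous = c("reject", "background")) {
  relative_score(pwm, kmer, ambiguous) / relative_score(pwm, pwm$consensus)
}
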