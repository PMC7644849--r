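#' Relative expression by the comparative threshold-cycle method
#'
#' Classic delta-delta-Ct with amplification efficiency fixed at 2.
#' Per gene and time point, replicate Ct values are averaged, the
#' reference gene's mean Ct at the same time point is subtracted
#' (dCt), the calibrator time point's dCt is subtracted (ddCt), and
#' the relative amount is `2^-ddCt`.  The calibrator value is exactly
#' 1 for every gene.
#'
#' @param ct_table Data frame with columns `gene`, `time_h`,
#'   `replicate`, `ct` (cycles, in (0, 45]).
#' @param reference_gene Invariant control gene (default `"18S"`); must
#'   be measured at every time point used by any gene.
#' @param calibrator_time Time point whose value is normalised to 1;
#'   default the earliest time in the table.
#' @return Data frame of class `expression_profiles` with columns
#'   `gene`, `time_h`, `dct`, `ddct`, `relative_amount`, ordered by
#'   gene then time; attribute `calibrator_time` records the choice.
#' @export
relative_expression <- function(ct_table, reference_gene = "18S",
                                calibrator_time = NULL) {
  req <- c("gene", "time_h", "replicate", "ct")
  if (!all(req %in% names(ct_table)))
    stop("ct_table needs columns gene, time_h, replicate, ct")
  if (any(ct_table$ct <= 0 | ct_table$ct > 45))
    stop("Ct values must lie in (0, 45]")
  if (!reference_gene %in% ct_table$gene)
    stop(sprintf("reference gene '%s' absent from table", reference_gene))
  means <- stats::aggregate(ct ~ gene + time_h, data = ct_table, FUN = mean)
  ref <- means[means$gene == reference_gene, ]
  tgt <- means[means$gene != reference_gene, ]
  times <- sort(unique(tgt$time_h))
  missing_ref <- setdiff(times, ref$time_h)
  if (length(missing_ref))
    stop(sprintf("reference gene '%s' not measured at time(s): %s",
                 reference_gene, paste(missing_ref, collapse = ", ")))
  if (is.null(calibrator_time)) calibrator_time <- min(times)
  if (!calibrator_time %in% times)
    stop(sprintf("calibrator time %s absent from table", calibrator_time))
  ref_ct <- stats::setNames(ref$ct, ref$time_h)
  tgt$dct <- tgt$ct - ref_ct[as.character(tgt$time_h)]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(g) {
    if (!calibrator_time %in% g$time_h)
      stop(sprintf("gene '%s' not measured at calibrator time %s",
                   g$gene[1], calibrator_time))
    g <- g[order(g$time_h), ]
    g$ddct <- g$dct - g$dct[g$time_h == calibrator_time]
    g$relative_amount <- 2^(-g$ddct)
    g[, c("gene", "time_h", "dct", "ddct", "relative_amount")]
  }))
  rownames(out) <- NULL
  attr(out, "calibrator_time") <- calibrator_time
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("expression_profiles", "data.frame")
  out
}

#' Correlate an expression profile with a morphology time course
#'
#' Pearson correlation between a gene's relative mRNA amounts and the
#' percentage of cells with tubular peroxisomes across matched time
#' points, with a qualitative classification of whether the gene's
#' expression tracks the peroxisome proliferation cycle.
#'
#' @param expr Data frame with `time_h` and `relative_amount` (one
#'   gene), e.g. one gene's rows of [relative_expression()] output.
#' @param morph Data frame with `time_h` and `percent_tubular`.
#' @param threshold Classification cutoff on r (default 0.7).
#' @return List with `r`, `n` (matched time points) and
#'   `classification` (`"proliferation-correlated"`,
#'   `"uncorrelated"`, or `"undefined"` when a profile is constant).
#' @export
correlate_profiles <- function(expr, morph, threshold = 0.7) {
  m <- merge(expr[, c("time_h", "relative_amount")],
             morph[, c("time_h", "percent_tubular")], by = "time_h")
  if (nrow(m) < 3L) stop("need >= 3 matched time points")
  if (stats::sd(m$relative_amount) == 0 || stats::sd(m$percent_tubular) == 0)
    return(list(r = NA_real_, n = nrow(m), classification = "undefined"))
  r <- stats::cor(m$relative_amount, m$percent_tubular, method = "pearson")
  list(r = r, n = nrow(m),
       classification = if (r >= threshold) "proliferation-correlated"
                        else "uncorrelated")
}

#' Categorise a cell by its peroxisome particle lengths
#'
#' Particles shorter than 0.3 um are discarded as sub-resolution
#' debris; the cell is `"tubular"` iff any remaining particle is
#' strictly longer than 2 um, else `"spherical"` (rod-shaped
#' peroxisomes of 0.3-2 um count as spherical).
#'
#' @param lengths Numeric vector of particle lengths in micrometres
#'   (all > 0).
#' @param min_length Discard threshold in um (default 0.3).
#' @param tubular_cutoff Strict lower bound for tubular in um
#'   (default 2).
#' @return List with `category` and `n_peroxisomes` (particles >=
#'   `min_length`).
#' @export
classify_cell <- function(lengths, min_length = 0.3, tubular_cutoff = 2) {
  if (any(lengths <= 0)) stop("particle lengths must be positive")
  keep <- lengths[lengths >= min_length]
  list(category = if (any(keep > tubular_cutoff)) "tubular" else "spherical",
       n_peroxisomes = length(keep))
}

#' Percentage of cells with tubular peroxisomes
#'
#' @param records List of per-cell particle-length vectors, or a data
#'   frame with columns `cell_id` and `length_um`.
#' @param ... Passed to [classify_cell()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_tubular <- function(records, ...) {
  if (is.data.frame(records))
    records <- split(records$length_um, records$cell_id)
  if (!length(records)) stop("no cells")
  cats <- vapply(records, function(l) classify_cell(l, ...)$category, "")
  100 * mean(cats == "tubular")
}

#' Dual-luciferase fold change in response to treatment
#'
#' Per reaction, the mean of the (triplicate) firefly reads is divided
#' by the Renilla read; per (construct, treatment) these ratios are
#' averaged over replicates; the fold change of a construct is the
#' treated value divided by the untreated value.
#'
#' @param records Data frame with columns `construct`, `treatment`,
#'   `replicate`, `fluc1`, `fluc2`, `fluc3`, `rluc` (or a single
#'   `fluc` column).
#' @param treated Treatment label for the numerator (default
#'   `"TGFb"`).
#' @param untreated Baseline label (default `"untreated"`).
#' @return Data frame with columns `construct`, `value_untreated`,
#'   `value_treated`, `fold`.
#' @export
luciferase_fold <- function(records, treated = "TGFb",
                            untreated = "untreated") {
  fl_cols <- intersect(c("fluc1", "fluc2", "fluc3", "fluc"),
                       names(records))
  if (!length(fl_cols)) stop("no firefly luminescence columns found")
  if (any(records$rluc <= 0)) stop("rluc must be positive")
  records$ratio <- rowMeans(records[, fl_cols, drop = FALSE]) / records$rluc
  agg <- stats::aggregate(ratio ~ construct + treatment, data = records,
                          FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$construct), function(g) {
    u <- g$ratio[g$treatment == untreated]
    tr <- g$ratio[g$treatment == treated]
    if (!length(u))
      stop(sprintf("construct '%s' has no %s arm", g$construct[1],
                   untreated))
    if (!length(tr))
      stop(sprintf("construct '%s' has no %s arm", g$construct[1], treated))
    data.frame(construct = g$construct[1], value_untreated = u,
               value_treated = tr, fold = tr / u,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
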