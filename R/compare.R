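#' Reduce surviving hits to a per-gene transcription-factor set
#'
#' A TF is in the set iff it has at least one surviving hit in the
#' gene's promoter.  For reporting, the best hit per TF is retained:
#' highest relative score, ties broken by smallest local offset.
#'
#' @param hits Surviving hits for a single gene (see
#'   [surviving_hits()]).
#' @param gene_id Gene identifier; defaults to the one in `hits`
#'   (required when `hits` is empty).
#' @return A list of class `tf_binding_set` with `gene_id`, `tfs`
#'   (sorted character vector) and `best_hits` (one row per TF).
#' @export
tf_set <- function(hits, gene_id = NULL) {
  if (is.null(gene_id)) {
    if (!nrow(hits)) stop("gene_id required for empty hit sets")
    gene_id <- unique(hits$gene_id)
    if (length(gene_id) != 1L) stop("hits span multiple genes")
  }
  if (!nrow(hits)) {
    return(structure(list(gene_id = gene_id, tfs = character(0),
                          best_hits = hits),
                     class = "tf_binding_set"))
  }
  ord <- order(hits$tf_name, -hits$relative_score, hits$local_offset)
  h <- hits[ord, ]
  best <- h[!duplicated(h$tf_name), ]
  rownames(best) <- NULL
  structure(list(gene_id = gene_id, tfs = sort(unique(hits$tf_name)),
                 best_hits = best),
            class = "tf_binding_set")
}

#' @export
print.tf_binding_set <- function(x, ...) {
  cat(sprintf("<tf_binding_set> %s: {%s}\n", x$gene_id,
              paste(x$tfs, collapse = ", ")))
  invisible(x)
}

#' Partition TFs among 2-3 promoters (Venn regions)
#'
#' Computes, for every non-empty subset of the input genes, the TFs
#' present in exactly those genes' binding sets.  Regions are keyed by
#' the sorted gene ids joined with `"&"`; members are listed
#' alphabetically.  By construction the regions are pairwise disjoint
#' and their union is the union of the input sets (both are asserted).
#'
#' @param sets List of 2 or 3 [tf_set()] objects (or named character
#'   vectors of TF names, names = gene ids).
#' @return A list of class `venn_partition` with `gene_ids`, `regions`
#'   (named list of character vectors) and `counts`.
#' @export
venn_partition <- function(sets) {
  tfsets <- lapply(sets, function(s) {
    if (inherits(s, "tf_binding_set")) s$tfs else as.character(s)
  })
  names(tfsets) <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "tf_binding_set")) s$gene_id
    else names(sets)[i] %||% stop("plain TF vectors need list names")
  }, "")
  genes <- names(tfsets)
  if (length(genes) < 2L || length(genes) > 3L)
    stop("venn_partition needs 2 or 3 sets")
  if (anyDuplicated(genes)) stop("duplicate gene_ids")
  universe <- sort(unique(unlist(tfsets)))
  membership <- vapply(tfsets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  regions <- list()
  n <- length(genes)
  for (size in seq_len(n)) {
    for (combo in utils::combn(seq_len(n), size, simplify = FALSE)) {
      inside <- rep(TRUE, length(universe))
      for (g in seq_len(n)) {
        want <- g %in% combo
        inside <- inside & (membership[, g] == want)
      }
      key <- paste(sort(genes[combo]), collapse = "&")
      regions[[key]] <- universe[inside]
    }
  }
  # invariants: disjoint, cover the union
  stopifnot(sum(lengths(regions)) == length(universe),
            !anyDuplicated(unlist(regions)))
  structure(list(gene_ids = genes, regions = regions,
                 counts = lengths(regions)),
            class = "venn_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (k in names(x$regions))
    cat(sprintf("  %-24s %2d  {%s}\n", k, length(x$regions[[k]]),
                paste(x$regions[[k]], collapse = ", ")))
  invisible(x)
}

#' Extract one Venn region
#'
#' @param partition A [venn_partition()].
#' @param genes Character vector of gene ids identifying the region
#'   (the TFs exclusive to exactly those genes).
#' @return Character vector of TF names.
#' @export
venn_region <- function(partition, genes) {
  key <- paste(sort(genes), collapse = "&")
  if (!key %in% names(partition$regions)) stop("no such region: ", key)
  partition$regions[[key]]
}

#' Genes whose binding set contains a TF
#'
#' @param sets List of [tf_set()] objects.
#' @param tf TF name (exact, case-insensitive).
#' @return Sorted character vector of gene ids.
#' @export
genes_with_tf <- function(sets, tf) {
  hit <- vapply(sets, function(s) any(toupper(s$tfs) == toupper(tf)),
                logical(1))
  sort(vapply(sets[hit], `[[`, "", "gene_id"))
}

#' Write a Venn partition as JSON and/or TSV
#' @param partition A [venn_partition()].
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, a list of the paths written.
#' @export
write_venn <- function(partition, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(gene_ids = partition$gene_ids,
           regions = lapply(partition$regions, as.list),
           counts = as.list(partition$counts)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(region = names(partition$regions),
                     n = unname(lengths(partition$regions)),
                     tfs = vapply(partition$regions, paste, "",
                                  collapse = ","),
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
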