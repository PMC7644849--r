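#' Assemble a pipeline run configuration
#'
#' @param genome,anchors,motifs,histone,clusters Input file paths
#'   (FASTA, anchor TSV/BED6, JASPAR motifs, histone BED, TF-cluster
#'   BED).
#' @param out_dir Output directory for the report bundle.
#' @param window Promoter window in bp (default 10000).
#' @param threshold Bona-fide relative-score threshold (default 0.89).
#' @param chromatin A [chromatin_config()].
#' @param calibrator_time Calibrator for [relative_expression()]
#'   (`NULL` = earliest time point).
#' @param correlation_threshold Cutoff for [correlate_profiles()].
#' @param seed Seed recorded in the report header.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome = NULL, anchors = NULL, motifs = NULL,
                       histone = NULL, clusters = NULL, out_dir = NULL,
                       window = 10000L, threshold = 0.89,
                       chromatin = chromatin_config(),
                       calibrator_time = NULL,
                       correlation_threshold = 0.7, seed = 1L) {
  structure(list(genome = genome, anchors = anchors, motifs = motifs,
                 histone = histone, clusters = clusters,
                 out_dir = out_dir, window = as.integer(window),
                 threshold = threshold, chromatin = chromatin,
                 calibrator_time = calibrator_time,
                 correlation_threshold = correlation_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the promoter mapping pipeline
#'
#' Orchestrates extract -> scan -> chromatin filter -> evidence filter
#' -> per-gene TF sets -> Venn partition, writing a report bundle to
#' `config$out_dir`: `hits.tsv` (all hits with flags),
#' `surviving_hits.tsv`, `tf_sets.json`, `venn.json`, `venn.tsv`,
#' `run_log.txt` (per-stage counts and the full configuration) and
#' `manifest.json`.  Any stage error is re-raised with the stage name
#' and partial outputs are removed.
#'
#' @param config A [run_config()] with all input paths set.
#' @return Invisibly, a list with `hits`, `surviving`, `tf_sets`,
#'   `venn` (NULL unless 2-3 genes), `counts`, and `paths`.
#' @export
run_promoter_pipeline <- function(config) {
  out <- config$out_dir
  stopifnot(!is.null(out))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_error_cleanup <- function() unlink(written)

  res <- tryCatch({
    genome <- .stage("load_genome", read_genome(config$genome))
    anchors <- .stage("load_anchors", read_anchors(config$anchors))
    pfms <- .stage("load_motifs", read_jaspar(config$motifs))
    if (!length(pfms)) stop("[stage load_motifs] no motifs loaded",
                            call. = FALSE)
    pwms <- lapply(pfms, pfm_to_pwm)
    histone <- .stage("load_histone",
                      read_track(config$histone, "histone"))
    clusters <- .stage("load_clusters",
                       read_track(config$clusters, "tf_cluster"))

    promoters <- .stage("extract_promoters", lapply(
      seq_len(nrow(anchors)),
      function(i) extract_promoter(genome, anchors[i, ], config$window)))
    names(promoters) <- anchors$gene_id

    hits <- .stage("scan", do.call(rbind, lapply(
      promoters, scan_promoter, pwms = pwms,
      threshold = config$threshold)))
    if (is.null(hits)) hits <- empty_hits()
    rownames(hits) <- NULL

    hits <- .stage("chromatin_filter",
                   active_chromatin_filter(hits, histone,
                                           config$chromatin))
    hits <- .stage("evidence_filter",
                   encode_evidence_filter(hits, clusters,
                                          config$chromatin))
    surv <- surviving_hits(hits)

    sets <- .stage("tf_sets", lapply(anchors$gene_id, function(g)
      tf_set(surv[surv$gene_id == g, , drop = FALSE], gene_id = g)))
    names(sets) <- anchors$gene_id
    venn <- if (nrow(anchors) %in% 2:3)
      .stage("venn", venn_partition(sets)) else NULL

    counts <- c(promoters = length(promoters), all_hits = nrow(hits),
                chromatin_pass = sum(hits$chromatin_active == "pass"),
                evidence_pass = sum(hits$evidence_pass == "pass"),
                surviving = nrow(surv))

    paths <- c(hits = file.path(out, "hits.tsv"),
               surviving = file.path(out, "surviving_hits.tsv"),
               tf_sets = file.path(out, "tf_sets.json"),
               log = file.path(out, "run_log.txt"),
               manifest = file.path(out, "manifest.json"))
    if (!is.null(venn))
      paths <- c(paths, venn_json = file.path(out, "venn.json"),
                 venn_tsv = file.path(out, "venn.tsv"))
    written <<- unname(paths)

    write_hits(hits, paths["hits"])
    write_hits(surv, paths["surviving"])
    jsonlite::write_json(lapply(sets, function(s) as.list(s$tfs)),
                         paths["tf_sets"], auto_unbox = TRUE,
                         pretty = TRUE)
    if (!is.null(venn))
      write_venn(venn, paths["venn_json"], paths["venn_tsv"])

    cfg_lines <- c(
      sprintf("window=%d threshold=%g seed=%d", config$window,
              config$threshold, config$seed),
      sprintf("chromatin: window=%d rule=%s min_evidence=%g missing=%s tf_match=%s",
              config$chromatin$window, config$chromatin$activating_rule,
              config$chromatin$min_evidence_score,
              config$chromatin$missing_cluster_policy,
              config$chromatin$tf_name_matching))
    writeLines(c("# promscan promoter pipeline", cfg_lines,
                 sprintf("%s\t%d", names(counts), counts)),
               paths["log"])
    jsonlite::write_json(list(outputs = as.list(paths),
                              counts = as.list(counts)),
                         paths["manifest"], auto_unbox = TRUE,
                         pretty = TRUE)
    list(hits = hits, surviving = surv, tf_sets = sets, venn = venn,
         counts = counts, paths = paths)
  }, error = function(e) { on_error_cleanup(); stop(e) })
  invisible(res)
}

#' Run the quantification utilities as one report
#'
#' @param config A [run_config()] (only `out_dir`, `calibrator_time`
#'   and `correlation_threshold` are used).
#' @param ct_table Optional qPCR Ct data.frame (see
#'   [relative_expression()]).
#' @param luciferase Optional luminescence data.frame (see
#'   [luciferase_fold()]).
#' @param morphology Optional particle table(s): a data.frame with
#'   `condition`, `cell_id`, `length_um`, or a named list of per-cell
#'   length lists.
#' @param reference_gene Invariant qPCR control (default `"18S"`).
#' @return Invisibly, a list with `profiles`, `correlations`, `folds`,
#'   `morphology` (whichever inputs were given) and `paths`.
#' @export
run_quantification <- function(config, ct_table = NULL, luciferase = NULL,
                               morphology = NULL,
                               reference_gene = "18S") {
  out <- config$out_dir
  stopifnot(!is.null(out))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(paths = character(0))

  if (!is.null(ct_table)) {
    prof <- .stage("relative_expression",
                   relative_expression(ct_table, reference_gene,
                                       config$calibrator_time))
    p <- file.path(out, "expression_profiles.tsv")
    hdr <- sprintf("# reference=%s calibrator_time=%s", reference_gene,
                   attr(prof, "calibrator_time"))
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(prof, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    res$profiles <- prof
    res$paths <- c(res$paths, expression = p)
  }
  morph_course <- NULL
  if (!is.null(morphology) && is.data.frame(morphology) &&
      all(c("time_h", "percent_tubular") %in% names(morphology))) {
    # already a per-time % tubular course: pass through for correlation
    morph_course <- morphology
    p <- file.path(out, "morphology.tsv")
    utils::write.table(morphology, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$morphology <- morphology
    res$paths <- c(res$paths, morphology = p)
    morphology <- NULL
  }
  if (!is.null(morphology)) {
    morph <- .stage("morphology", {
      if (is.data.frame(morphology)) {
        do.call(rbind, lapply(split(morphology, morphology$condition),
                              function(d) data.frame(
                                condition = d$condition[1],
                                percent_tubular = percent_tubular(d),
                                n_cells = length(unique(d$cell_id)),
                                stringsAsFactors = FALSE)))
      } else {
        data.frame(condition = names(morphology),
                   percent_tubular = vapply(morphology, percent_tubular, 0),
                   n_cells = vapply(morphology, length, 0L),
                   stringsAsFactors = FALSE)
      }
    })
    rownames(morph) <- NULL
    p <- file.path(out, "morphology.tsv")
    utils::write.table(morph, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$morphology <- morph
    res$paths <- c(res$paths, morphology = p)
  }
  if (!is.null(res$profiles) && !is.null(morph_course)) {
    corr <- .stage("correlation", {
      genes <- unique(res$profiles$gene)
      lapply(stats::setNames(genes, genes), function(g)
        correlate_profiles(res$profiles[res$profiles$gene == g, ],
                           morph_course,
                           threshold = config$correlation_threshold))
    })
    p <- file.path(out, "correlations.json")
    jsonlite::write_json(corr, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    res$correlations <- corr
    res$paths <- c(res$paths, correlations = p)
  }
  if (!is.null(luciferase)) {
    folds <- .stage("luciferase_fold", luciferase_fold(luciferase))
    p <- file.path(out, "luciferase_folds.tsv")
    utils::write.table(folds, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$folds <- folds
    res$paths <- c(res$paths, luciferase = p)
  }
  invisible(res)
}

.cli_opts <- function(args) {
  opts <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else { opts[[key]] <- args[i + 1L]; i <- i + 2L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommand dispatcher intended for
#' `Rscript -e 'promscan::promscan_cli()' <subcommand> ...`.
#' Subcommands: `simulate` (write the three-promoter fixture),
#' `pipeline` (scan + filter + compare from files), `qpcr`,
#' `luciferase`, `morphology`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly on success; errors propagate.
#' @export
promscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: promscan <simulate|pipeline|qpcr|luciferase|morphology> [--opt value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  pa <- .cli_opts(args[-1])
  o <- pa$opts
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(cmd,
    simulate = {
      fx <- figure6_fixture(seed = as.integer(num(o$seed, 42)))
      paths <- write_fixture(fx, o$out %||% "fixture")
      message(sprintf("wrote %d fixture files to %s", length(paths),
                      o$out %||% "fixture"))
    },
    pipeline = {
      cfg <- run_config(genome = o$genome, anchors = o$anchors,
                        motifs = o$motifs, histone = o$histone,
                        clusters = o$clusters,
                        out_dir = o$out %||% "promscan_out",
                        window = num(o$window, 10000),
                        threshold = num(o$threshold, 0.89),
                        chromatin = chromatin_config(
                          window = num(o[["chromatin-window"]], 1000),
                          min_evidence_score = num(o[["min-evidence"]], 500)),
                        seed = as.integer(num(o$seed, 1)))
      res <- run_promoter_pipeline(cfg)
      message(paste(sprintf("%s=%d", names(res$counts), res$counts),
                    collapse = " "))
    },
    qpcr = {
      ct <- utils::read.table(o$ct, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      cfg <- run_config(out_dir = o$out %||% "promscan_out",
                        calibrator_time = if (is.null(o$calibrator)) NULL
                                          else as.numeric(o$calibrator))
      run_quantification(cfg, ct_table = ct,
                         reference_gene = o$reference %||% "18S")
    },
    luciferase = {
      luc <- utils::read.table(o$plate, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      cfg <- run_config(out_dir = o$out %||% "promscan_out")
      run_quantification(cfg, luciferase = luc)
    },
    morphology = {
      m <- utils::read.table(o$table, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      cfg <- run_config(out_dir = o$out %||% "promscan_out")
      run_quantification(cfg, morphology = m)
    },
    stop(sprintf("unknown subcommand '%s'", cmd)))
  invisible(0L)
}
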