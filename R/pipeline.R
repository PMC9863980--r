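# End-to-end pipeline: per-sample analysis, wild-type/mutant comparison,
# ACMG interpretation, report assembly and isoform diagrams.

#' Pipeline parameter set
#'
#' @param read_threshold breakpoint-consensus support threshold (fraction
#'   of aligned reads, default 0.03).
#' @param report_threshold reporting threshold in percent (default 5).
#' @param snap_window snap window in nt (default 10; auto-capped near close
#'   site pairs, see [assign_reads()]).
#' @param collapse_window breakpoint collapse radius in nt.
#' @param intron_min minimum intron-sized gap in nt.
#' @param max_read_gap maximum read-side gap across an intron, nt.
#' @param k aligner anchor length.
#' @param min_reads depth-QC threshold (default 5000).
#' @return a named list of parameters.
#' @export
pipeline_params <- function(read_threshold = 0.03, report_threshold = 5,
                            snap_window = 10L, collapse_window = 21L,
                            intron_min = 30L, max_read_gap = 10L,
                            k = 11L, min_reads = 5000L) {
  list(read_threshold = read_threshold,
       report_threshold = report_threshold,
       snap_window = snap_window, collapse_window = collapse_window,
       intron_min = intron_min, max_read_gap = max_read_gap,
       k = k, min_reads = min_reads)
}

#' Analyse one minigene sample
#'
#' Runs alignment (internal chain aligner for reads, SAM ingestion for
#' pre-aligned input), breakpoint consensus with optional curation, read
#' snapping, quantification, report filtering, event annotation and depth
#' QC.
#'
#' @param construct a `minigene_construct`.
#' @param reads a `read_simulation`, named character vector,
#'   `DNAStringSet`, FASTQ path, SAM path, or a list of `read_alignment`.
#' @param params a [pipeline_params()] list.
#' @param curation optional breakpoint edit list (see
#'   [curate_breakpoints()]).
#' @param label sample label carried through the outputs.
#' @return a `sample_analysis` list: `label`, `table` (annotated
#'   `isoform_table`), `sites`, `qc` (alignment + depth + assignment
#'   accounting).
#' @export
analyze_sample <- function(construct, reads, params = pipeline_params(),
                           curation = NULL, label = "sample") {
  if (is.character(reads) && length(reads) == 1L &&
      tolower(tools::file_ext(reads)) %in% c("sam", "bam")) {
    ing <- ingest_sam(reads, construct, intron_min = params$intron_min)
    alignments <- ing$alignments
    align_qc <- data.frame(n_reads = length(alignments) + ing$skipped,
                           aligned = length(alignments),
                           dropped = ing$skipped,
                           aligned_fraction = length(alignments) /
                             max(1L, length(alignments) + ing$skipped))
  } else if (is.list(reads) && length(reads) &&
             inherits(reads[[1L]], "read_alignment")) {
    alignments <- reads
    align_qc <- data.frame(n_reads = length(alignments),
                           aligned = length(alignments), dropped = 0L,
                           aligned_fraction = 1)
  } else {
    al <- align_reads(reads, construct, k = params$k,
                      intron_min = params$intron_min,
                      max_read_gap = params$max_read_gap)
    alignments <- al$alignments
    align_qc <- al$qc
  }
  sites <- detect_breakpoints(alignments,
                              read_threshold = params$read_threshold,
                              collapse_window = params$collapse_window)
  if (!is.null(curation)) sites <- curate_breakpoints(sites, curation)
  assignment <- assign_reads(alignments, sites,
                             snap_window = params$snap_window)
  table <- quantify(assignment)
  table <- filter_report(table, params$report_threshold)
  table <- annotate_isoforms(table, construct)
  depth <- qc_depth(table, params$min_reads)
  structure(list(label = label, table = table, sites = sites,
                 qc = list(alignment = align_qc, depth = depth,
                           unassigned = assignment$unassigned)),
            class = "sample_analysis")
}

#' @export
print.sample_analysis <- function(x, ...) {
  cat("sample '", x$label, "': ", attr(x$table, "total_assigned"),
      " assigned reads, ", sum(x$table$reported), " reported isoforms",
      if (!x$qc$depth$pass) " [depth QC: FAIL]", "\n", sep = "")
  invisible(x)
}

#' Run the full minigene assay pipeline
#'
#' Drives simulation (when samples declare mixtures), alignment,
#' quantification and event annotation for every sample, then, for each
#' declared wild-type/mutant pair, assay comparison, protein consequences
#' of the mutant's aberrant reported isoforms, functional evidence
#' (PS3/BS3) and the combined ACMG class.  Deterministic given the seed.
#'
#' @param config list with elements:
#'   * `construct`: a `minigene_construct`;
#'   * `samples`: named list; each sample is a list with either `reads`
#'     (any input accepted by [analyze_sample()]) or `mixture` (isoform
#'     specs for [simulate_reads()]) plus optional `n_reads`, `model`,
#'     `curation`;
#'   * `pairs`: optional list of lists with `wt`, `mut` (sample labels),
#'     `variant` (HGVS label) and `annotations` (ACMG tags carried as
#'     opaque annotations, e.g. population/predictor criteria);
#'   * `params`: optional [pipeline_params()];
#'   * `seed`: integer seed (default 1).
#' @return a `minigene_report`: list with `samples`, `comparisons`,
#'   `params`, `seed`.
#' @export
run_pipeline <- function(config) {
  params <- config$params %||% pipeline_params()
  seed <- config$seed %||% 1L
  construct <- config$construct
  samples <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    lab <- s$label %||% names(config$samples)[i]
    cons <- if (!is.null(s$variant)) apply_variant(construct, s$variant)
            else construct
    reads <- s$reads
    if (is.null(reads) && !is.null(s$mixture)) {
      sim <- simulate_reads(cons, s$mixture,
                            n_reads = s$n_reads %||% 5000L,
                            model = s$model %||% error_model(),
                            seed = seed + i)
      reads <- sim
    }
    samples[[lab]] <- analyze_sample(cons, reads, params = params,
                                     curation = s$curation, label = lab)
  }
  comparisons <- list()
  for (pair in config$pairs %||% list()) {
    cmp <- compare_assays(samples[[pair$wt]]$table,
                          samples[[pair$mut]]$table)
    ev <- splice_functional_evidence(cmp)
    tags <- pair$annotations %||% character(0)
    if (ev$verdict %in% c("PS3", "BS3")) tags <- c(tags, ev$verdict)
    acmg <- combine_acmg(tags)
    mut_tab <- samples[[pair$mut]]$table
    aberrant_rows <- which(mut_tab$aberrant)
    consequences <- lapply(aberrant_rows, function(r) {
      ch <- parse_chain(mut_tab$chain[r])
      cons <- translate_consequence(construct, ch)
      nmd <- predict_nmd(cons, ch, construct)
      list(token = mut_tab$token[r], abundance = mut_tab$abundance[r],
           consequence = cons, nmd = nmd)
    })
    comparisons[[pair$variant %||% paste(pair$wt, pair$mut, sep = "_vs_")]] <-
      list(pair = pair, comparison = cmp, evidence = ev,
           criteria = tags, acmg = acmg, consequences = consequences)
  }
  structure(list(samples = samples, comparisons = comparisons,
                 params = params, seed = seed),
            class = "minigene_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.minigene_report <- function(x, ...) {
  cat("minigene assay report: ", length(x$samples), " samples, ",
      length(x$comparisons), " comparisons (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat("  ", nm, ": ", cc$evidence$verdict, ", ACMG class ",
        cc$acmg$class, " (", cc$acmg$label, ")\n", sep = "")
  }
  invisible(x)
}

#' Write pipeline outputs as TSV/JSON files
#'
#' One isoform TSV and one consensus-site TSV per sample, plus a JSON
#' clinical report per comparison.  Every reported number is re-derivable
#' from these tables.
#'
#' @param report a `minigene_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$samples)) {
    s <- report$samples[[nm]]
    tab <- as.data.frame(s$table)
    tab$events <- vapply(tab$events, paste, "", collapse = "+")
    tab$aberrant_events <- vapply(tab$aberrant_events, paste, "",
                                  collapse = "+")
    tab$abundance <- round(tab$abundance, 1L)
    utils::write.table(tab, file.path(outdir, paste0(nm, "_isoforms.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(s$sites, file.path(outdir, paste0(nm, "_sites.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(report$comparisons)) {
    cc <- report$comparisons[[nm]]
    out <- list(variant = nm,
                verdict = cc$evidence$verdict,
                criteria = cc$criteria,
                acmg_class = cc$acmg$class,
                acmg_label = cc$acmg$label,
                aberrant_fraction_mut =
                  round(cc$comparison$aberrant_fraction_mut, 1),
                aberrant_fraction_wt =
                  round(cc$comparison$aberrant_fraction_wt, 1),
                canonical_reduction =
                  round(cc$comparison$canonical_reduction, 1),
                consequences = lapply(cc$consequences, function(q)
                  list(token = q$token,
                       abundance = round(q$abundance, 1),
                       kind = q$consequence$kind,
                       hgvs_p = q$consequence$hgvs_p,
                       nmd = q$nmd$nmd)))
    jsonlite::write_json(out,
                         file.path(outdir, paste0(gsub("[^A-Za-z0-9._-]",
                                                       "_", nm),
                                                  "_clinical.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(outdir)
}

#' Isoform diagram
#'
#' One row per reported isoform: boxes for the chain's segments on the
#' construct axis, labelled with relative abundance and spliced size;
#' rows containing aberrant events are flagged in red.  Returns a ggplot
#' object (deterministic layout); an empty reported set yields a labelled
#' placeholder.
#'
#' @param table an annotated `isoform_table`.
#' @param construct the matching `minigene_construct`.
#' @return a ggplot object.
#' @export
render_isoform_diagram <- function(table, construct) {
  rep_rows <- table[table$reported, , drop = FALSE]
  if (nrow(rep_rows) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no isoforms above threshold") +
             ggplot2::theme_void())
  }
  segs <- do.call(rbind, lapply(seq_len(nrow(rep_rows)), function(i) {
    m <- parse_chain(rep_rows$chain[i])
    data.frame(row = i, start = m[, "start"], end = m[, "end"],
               aberrant = rep_rows$aberrant[i])
  }))
  labels <- sprintf("%s  %.1f%%  (%d bp)", rep_rows$token,
                    rep_rows$abundance, rep_rows$size)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = start, xend = end,
                   y = -row, yend = -row),
      linewidth = 1, colour = "grey70") +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = start, xmax = end,
                   ymin = -row - 0.3, ymax = -row + 0.3,
                   fill = aberrant)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::scale_y_continuous(breaks = -seq_len(nrow(rep_rows)),
                                labels = labels) +
    ggplot2::labs(x = paste0("construct position (", construct$name, ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}
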