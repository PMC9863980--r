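# Consensus exon coordinates from breakpoint frequencies, read snapping,
# isoform definition and relative quantification.

#' Detect consensus breakpoints from aligned reads
#'
#' Every distinct segment start/end position is tallied over all aligned
#' reads; positions supported by at least `read_threshold` of reads become
#' candidate consensus sites.  Because junction placement wobbles by a few
#' nucleotides on noisy long reads, candidates on the same side within
#' `collapse_window` of a stronger candidate are collapsed onto it, so each
#' true junction is represented by its modal position.
#'
#' @param alignments list of `read_alignment` (or the result of
#'   [align_reads()] / [ingest_sam()]).
#' @param read_threshold minimum supporting read fraction (default 0.03,
#'   computed over all aligned reads).
#' @param collapse_window collapse radius (nt) around a stronger candidate
#'   (default 21, just over twice the snap window, so secondary wobble peaks never
#'   survive as spurious sites).
#' @return `data.frame` with `position`, `side` (`"start"`/`"end"`) and
#'   `support` (fraction), ordered by position.
#' @export
detect_breakpoints <- function(alignments, read_threshold = 0.03,
                               collapse_window = 21L) {
  alignments <- as_alignment_list(alignments)
  if (length(alignments) == 0L) stop("no aligned reads")
  seg <- alignment_segments(alignments)
  n_reads <- length(unique(seg$read_id))
  out <- list()
  for (side in c("start", "end")) {
    tab <- table(seg[[side]])
    support <- as.numeric(tab) / n_reads
    pos <- as.integer(names(tab))
    keep <- support >= read_threshold
    pos <- pos[keep]; support <- support[keep]
    # greedy modal collapse: strongest first, ties to smaller coordinate;
    # the reported support sums the whole wobble cluster around the modal
    all_pos <- as.integer(names(tab))
    all_support <- as.numeric(tab) / n_reads
    o <- order(-support, pos)
    accepted <- integer(0)
    acc_support <- numeric(0)
    for (i in o) {
      if (length(accepted) == 0L ||
          min(abs(accepted - pos[i])) > collapse_window) {
        accepted <- c(accepted, pos[i])
        acc_support <- c(acc_support,
                         sum(all_support[abs(all_pos - pos[i]) <=
                                           collapse_window]))
      }
    }
    if (length(accepted)) {
      out[[side]] <- data.frame(position = accepted, side = side,
                                support = acc_support,
                                stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$position, sites$side), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

as_alignment_list <- function(alignments) {
  if (is.list(alignments) && !is.null(alignments$alignments)) {
    return(alignments$alignments)
  }
  alignments
}

#' Curate consensus breakpoints
#'
#' Deterministic application of a user-supplied edit list, the programmatic
#' stand-in for manual curation of detected exon coordinates: known
#' low-abundance or predicted sites can be added, spurious ones removed or
#' moved.
#'
#' @param sites `data.frame` from [detect_breakpoints()].
#' @param edits list with optional elements `add` (`data.frame`:
#'   `position`, `side`), `remove` (same shape) and `move` (`data.frame`:
#'   `from`, `to`, `side`).
#' @return the curated site table.
#' @export
curate_breakpoints <- function(sites, edits = list()) {
  if (!is.null(edits$remove)) {
    for (i in seq_len(nrow(edits$remove))) {
      drop <- sites$position == edits$remove$position[i] &
        sites$side == edits$remove$side[i]
      sites <- sites[!drop, , drop = FALSE]
    }
  }
  if (!is.null(edits$move)) {
    for (i in seq_len(nrow(edits$move))) {
      hit <- sites$position == edits$move$from[i] &
        sites$side == edits$move$side[i]
      sites$position[hit] <- edits$move$to[i]
    }
  }
  if (!is.null(edits$add)) {
    for (i in seq_len(nrow(edits$add))) {
      if (!any(sites$position == edits$add$position[i] &
                 sites$side == edits$add$side[i])) {
        sites <- rbind(sites,
                       data.frame(position = as.integer(edits$add$position[i]),
                                  side = edits$add$side[i],
                                  support = NA_real_,
                                  stringsAsFactors = FALSE))
      }
    }
  }
  sites <- sites[order(sites$position, sites$side), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

snap_to_sites <- function(values, site_pos, window) {
  if (length(site_pos) == 0L) return(rep(NA_integer_, length(values)))
  site_pos <- sort(site_pos)
  i <- findInterval(values, site_pos)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(site_pos))
  d_lo <- abs(values - site_pos[lo])
  d_hi <- abs(values - site_pos[hi])
  # ties break toward the smaller coordinate
  pick <- ifelse(d_lo <= d_hi, site_pos[lo], site_pos[hi])
  dist <- pmin(d_lo, d_hi)
  pick[i == 0L] <- site_pos[1L]
  dist[i == 0L] <- abs(values - site_pos[1L])[i == 0L]
  out <- as.integer(pick)
  out[dist > window] <- NA_integer_
  out
}

#' Snap read segment edges to consensus sites
#'
#' Each segment edge snaps to the nearest consensus site of its side within
#' `snap_window` (ties toward the smaller coordinate).  Reads with any
#' unsnappable edge, or whose snapped chain degenerates, are unassigned
#' with a reason.  The snap window is automatically capped at
#' `floor((d_min - 1) / 2)` where `d_min` is the smallest distance between
#' two same-side consensus sites, so close site pairs are never merged.
#'
#' @param alignments list of `read_alignment` (or [align_reads()] result).
#' @param sites consensus site table ([detect_breakpoints()] /
#'   [curate_breakpoints()]).
#' @param snap_window maximum snap distance in nt (default 10, sized for
#'   the junction wobble of noisy long reads).
#' @return list with `assigned` (`data.frame`: `read_id`, `chain`) and
#'   `unassigned` (`data.frame`: `read_id`, `reason`).
#' @export
assign_reads <- function(alignments, sites, snap_window = 10L) {
  alignments <- as_alignment_list(alignments)
  if (nrow(sites) == 0L) {
    return(list(assigned = data.frame(read_id = character(0),
                                      chain = character(0)),
                unassigned = data.frame(
                  read_id = vapply(alignments, `[[`, "", "read_id"),
                  reason = "no consensus sites",
                  stringsAsFactors = FALSE)))
  }
  for (side in c("start", "end")) {
    p <- sort(sites$position[sites$side == side])
    if (length(p) > 1L) {
      d_min <- min(diff(p))
      snap_window <- min(snap_window, (d_min - 1L) %/% 2L)
    }
  }
  seg <- alignment_segments(alignments)
  seg$snap_start <- snap_to_sites(seg$start,
                                  sites$position[sites$side == "start"],
                                  snap_window)
  seg$snap_end <- snap_to_sites(seg$end,
                                sites$position[sites$side == "end"],
                                snap_window)
  by_read <- split(seg, seg$read_id)
  ids <- names(by_read)
  chains <- character(length(by_read))
  reason <- character(length(by_read))
  for (i in seq_along(by_read)) {
    s <- by_read[[i]]
    if (anyNA(s$snap_start) || anyNA(s$snap_end)) {
      reason[i] <- "unsnappable edge"
    } else {
      m <- cbind(start = s$snap_start, end = s$snap_end)
      m <- m[order(m[, "start"]), , drop = FALSE]
      if (any(m[, "start"] > m[, "end"]) ||
          (nrow(m) > 1L && any(m[-1L, "start"] <= m[-nrow(m), "end"]))) {
        reason[i] <- "degenerate snapped chain"
      } else {
        chains[i] <- format_chain(m)
      }
    }
  }
  ok <- reason == ""
  list(assigned = data.frame(read_id = ids[ok], chain = chains[ok],
                             stringsAsFactors = FALSE),
       unassigned = data.frame(read_id = ids[!ok], reason = reason[!ok],
                               stringsAsFactors = FALSE))
}

#' Quantify isoforms from snapped chains
#'
#' Isoforms are equivalence classes of identical snapped chains; relative
#' abundance is `100 * class count / total assigned reads` (unassigned
#' reads are excluded from the denominator).  The table is sorted by
#' abundance, descending.
#'
#' @param assignment result of [assign_reads()] (or a `data.frame` with a
#'   `chain` column).
#' @return an `isoform_table`: `data.frame` with `chain`, `size` (spliced
#'   length, bp), `n_reads`, `abundance` (percent) and `reported`
#'   (all `TRUE` until [filter_report()] is applied); attributes
#'   `total_assigned` and `unassigned`.
#' @export
quantify <- function(assignment) {
  assigned <- if (is.data.frame(assignment)) assignment
              else assignment$assigned
  if (nrow(assigned) == 0L) stop("no assigned reads to quantify")
  tab <- sort(table(assigned$chain), decreasing = TRUE)
  total <- sum(tab)
  chains <- names(tab)
  size <- vapply(chains, function(ch) {
    m <- parse_chain(ch)
    sum(m[, "end"] - m[, "start"] + 1L)
  }, 0L)
  out <- data.frame(chain = chains,
                    size = unname(size),
                    n_reads = as.integer(tab),
                    abundance = 100 * as.integer(tab) / total,
                    reported = TRUE,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_assigned") <- total
  attr(out, "unassigned") <- if (is.data.frame(assignment)) NULL
                             else assignment$unassigned
  class(out) <- c("isoform_table", "data.frame")
  out
}

#' @export
print.isoform_table <- function(x, digits = 1L, ...) {
  y <- as.data.frame(x)
  y$abundance <- round(y$abundance, digits)
  cat("isoform table: ", attr(x, "total_assigned"), " assigned reads, ",
      nrow(x), " isoforms (", sum(x$reported), " reported)\n", sep = "")
  print(y, ...)
  invisible(x)
}

#' Partition an isoform table into reported and minor rows
#'
#' Rows at or below `report_threshold` percent are moved to the
#' minor-isoform annex (`reported = FALSE`): only isoforms with values
#' strictly above the threshold are reported.  Annexed rows stay in the
#' table because event-level aggregation sums events across reported and
#' sub-threshold isoforms.
#'
#' @param table an `isoform_table`.
#' @param report_threshold percent threshold in `[0, 100]` (default 5).
#' @return the table with its `reported` column updated.
#' @export
filter_report <- function(table, report_threshold = 5) {
  stopifnot(report_threshold >= 0, report_threshold <= 100)
  table$reported <- table$abundance > report_threshold
  attr(table, "report_threshold") <- report_threshold
  table
}

#' Sequencing-depth QC
#'
#' Fails when fewer than `min_reads` reads were assigned (the per-sample
#' sequencing stop rule); report-only, never blocks analysis.
#'
#' @param table an `isoform_table`.
#' @param min_reads minimum assigned reads (default 5000).
#' @return list with `pass`, `total_assigned`, `min_reads`.
#' @export
qc_depth <- function(table, min_reads = 5000L) {
  total <- attr(table, "total_assigned")
  list(pass = total >= min_reads, total_assigned = total,
       min_reads = as.integer(min_reads))
}
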