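# Splicing-event classification, nomenclature and event-level aggregation.
#
# Event tokens follow the field's shorthand: "∆5" (full exon skip),
# "∆'6" (registered partial exon; unregistered partials print the retained
# length, e.g. "∆'6(20)"), "5a" (alternative exon), "PSE13" (pseudoexon of
# 13 nt), "Ins331" (exon elongated 331 nt into the adjacent intron) and
# "IR(6)" (full retention of intron 6).  Combined tokens for one isoform
# are ordered 5'->3' and joined with "+"; the canonical chain is "CT".

event_classes <- c("CANONICAL", "EXON_SKIP", "PARTIAL_EXON", "ALT_EXON",
                   "PSEUDOEXON", "ELONGATION", "INTRON_RETENTION")

new_event <- function(class, anchor, size, token, position) {
  list(class = class, anchor = anchor, size = size, token = token,
       position = position)
}

partial_token <- function(construct, label, retained) {
  reg <- construct$partial_registry
  if (!is.null(reg) &&
      any(reg$label == label & reg$retained == retained)) {
    paste0("∆'", label)
  } else {
    paste0("∆'", label, "(", retained, ")")
  }
}

#' Classify an isoform chain against the construct annotation
#'
#' Performs a segment-by-segment diff of the chain against the canonical
#' exon chain: a missing constitutive exon is an `EXON_SKIP`; a segment
#' sharing one exon boundary with the other edge inside the exon is a
#' `PARTIAL_EXON` (size = retained nt); a segment matching an annotated
#' alternative exon is an `ALT_EXON`; a segment lying fully inside an
#' intron is a `PSEUDOEXON`; an exon segment extended into an adjacent
#' intron is an `ELONGATION` (size = extension); two exons fused across
#' their whole intron are an `INTRON_RETENTION`.  A chain identical to the
#' canonical chain yields the single `CANONICAL` event.  Whether an event
#' is aberrant is decided against the construct's natural-event registry:
#' aberrant means absent from the wild-type repertoire.
#'
#' @param chain two-column (start, end) matrix or chain string.
#' @param construct a `minigene_construct`.
#' @return `data.frame` with columns `class`, `anchor`, `size`, `token`,
#'   `aberrant`, ordered 5' to 3'.
#' @export
classify_isoform <- function(chain, construct) {
  chain <- as_chain_matrix(chain)
  ex <- construct$exons
  events <- list()
  covered <- rep(FALSE, nrow(ex))
  flagged <- character(0)
  for (i in seq_len(nrow(chain))) {
    s <- chain[i, 1L]; e <- chain[i, 2L]
    ov <- which(ex$start <= e & ex$end >= s)
    if (length(ov) == 0L) {
      up <- which(ex$end < s)
      anchor <- if (length(up)) paste0("intron_", ex$label[max(up)])
                else "upstream"
      size <- e - s + 1L
      events[[length(events) + 1L]] <-
        new_event("PSEUDOEXON", anchor, size, paste0("PSE", size), s)
      next
    }
    if (length(ov) == 1L) {
      j <- ov
      covered[j] <- TRUE
      exact_s <- s == ex$start[j]
      exact_e <- e == ex$end[j]
      if (ex$class[j] == "vector" && !(exact_s && exact_e)) {
        flagged <- c(flagged, paste0("segment ", s, "-", e,
                                     " irregular over vector exon ",
                                     ex$label[j]))
        next
      }
      if (exact_s && exact_e) {
        if (ex$class[j] == "alternative") {
          events[[length(events) + 1L]] <-
            new_event("ALT_EXON", ex$label[j], e - s + 1L, ex$label[j], s)
        }
        next
      }
      ext5 <- max(0L, ex$start[j] - s)
      ext3 <- max(0L, e - ex$end[j])
      if (ext5 > 0L || ext3 > 0L) {
        size <- ext5 + ext3
        events[[length(events) + 1L]] <-
          new_event("ELONGATION", ex$label[j], size,
                    paste0("Ins", size), s)
        if ((ext5 > 0L && e < ex$end[j]) || (ext3 > 0L && s > ex$start[j])) {
          flagged <- c(flagged, paste0("segment ", s, "-", e,
                                       " combines elongation and partial ",
                                       "loss of exon ", ex$label[j]))
        }
        next
      }
      retained <- e - s + 1L
      events[[length(events) + 1L]] <-
        new_event("PARTIAL_EXON", ex$label[j], retained,
                  partial_token(construct, ex$label[j], retained), s)
      next
    }
    # segment spans several exons: intron retention if it covers the full
    # span from the first exon's start to the last exon's end
    covered[ov] <- TRUE
    first <- ov[1L]; last <- ov[length(ov)]
    if (s == ex$start[first] && e == ex$end[last]) {
      inner <- ex$label[ov[-length(ov)]]
      size <- (e - s + 1L) - sum(ex$end[ov] - ex$start[ov] + 1L)
      events[[length(events) + 1L]] <-
        new_event("INTRON_RETENTION",
                  paste0("intron_", paste(inner, collapse = ",")),
                  size, paste0("IR(", paste(inner, collapse = ","), ")"), s)
    } else {
      flagged <- c(flagged, paste0("segment ", s, "-", e,
                                   " irregular over exons ",
                                   paste(ex$label[ov], collapse = ",")))
    }
  }
  # skipped constitutive exons
  for (j in which(!covered & ex$class == "constitutive")) {
    events[[length(events) + 1L]] <-
      new_event("EXON_SKIP", ex$label[j], ex$end[j] - ex$start[j] + 1L,
                paste0("∆", ex$label[j]), ex$start[j])
  }
  if (length(events) == 0L) {
    out <- data.frame(class = "CANONICAL", anchor = NA_character_,
                      size = NA_integer_, token = "CT",
                      aberrant = FALSE, stringsAsFactors = FALSE)
  } else {
    events <- events[order(vapply(events, `[[`, 0L, "position"))]
    out <- data.frame(
      class = vapply(events, `[[`, "", "class"),
      anchor = vapply(events, `[[`, "", "anchor"),
      size = vapply(events, function(ev) as.integer(ev$size), 0L),
      token = vapply(events, `[[`, "", "token"),
      stringsAsFactors = FALSE)
    out$aberrant <- !(out$class %in% c("CANONICAL", "ALT_EXON")) &
      !(out$token %in% construct$natural_events)
  }
  attr(out, "flagged") <- flagged
  out
}

#' Parse an event token back to (class, size)
#'
#' Tokens are deterministic given class, anchor and size, and round-trip:
#' parsing a token reproduces the class and size exactly.  Partial-exon
#' tokens in registry shorthand need the construct to recover the retained
#' length.
#'
#' @param token an event token such as `"PSE194"`, `"Ins331"`, `"∆5"`.
#' @param construct optional `minigene_construct` (needed for registered
#'   partial and skip sizes).
#' @return list with `class` and `size` (`NA` when not applicable).
#' @export
parse_event_token <- function(token, construct = NULL) {
  exon_size <- function(lab) {
    if (is.null(construct)) return(NA_integer_)
    ex <- construct$exons
    j <- which(ex$label == lab)
    if (length(j) != 1L) return(NA_integer_)
    ex$end[j] - ex$start[j] + 1L
  }
  if (token == "CT") return(list(class = "CANONICAL", size = NA_integer_))
  if (grepl("^PSE\\d+$", token)) {
    return(list(class = "PSEUDOEXON",
                size = as.integer(sub("^PSE", "", token))))
  }
  if (grepl("^Ins\\d+$", token)) {
    return(list(class = "ELONGATION",
                size = as.integer(sub("^Ins", "", token))))
  }
  if (grepl("^IR\\(.+\\)$", token)) {
    return(list(class = "INTRON_RETENTION", size = NA_integer_))
  }
  if (grepl("^∆'.+\\(\\d+\\)$", token)) {
    return(list(class = "PARTIAL_EXON",
                size = as.integer(sub("^.*\\((\\d+)\\)$", "\\1", token))))
  }
  if (grepl("^∆'", token)) {
    lab <- sub("^∆'", "", token)
    size <- NA_integer_
    if (!is.null(construct) && !is.null(construct$partial_registry)) {
      reg <- construct$partial_registry
      hit <- reg$retained[reg$label == lab]
      if (length(hit) == 1L) size <- as.integer(hit)
    }
    return(list(class = "PARTIAL_EXON", size = size))
  }
  if (grepl("^∆", token)) {
    return(list(class = "EXON_SKIP",
                size = exon_size(sub("^∆", "", token))))
  }
  if (!is.null(construct) &&
      token %in% construct$exons$label[construct$exons$class ==
                                         "alternative"]) {
    return(list(class = "ALT_EXON", size = exon_size(token)))
  }
  stop("unknown event token: ", token)
}

#' Annotate an isoform table with splicing events
#'
#' Classifies every chain in the table (reported and annexed rows alike)
#' and adds the event list, the combined 5'->3' isoform token and the
#' aberrant flag.
#'
#' @param table an `isoform_table`.
#' @param construct the `minigene_construct` the reads were aligned to.
#' @return the annotated table (extra columns `events` (list), `token`,
#'   `aberrant`).
#' @export
annotate_isoforms <- function(table, construct) {
  cls <- lapply(table$chain, classify_isoform, construct = construct)
  table$events <- lapply(cls, function(x) x$token[x$class != "CANONICAL"])
  table$aberrant_events <- lapply(cls, function(x) x$token[x$aberrant])
  table$token <- vapply(cls, function(x) {
    toks <- x$token[x$class != "CANONICAL"]
    if (length(toks) == 0L) "CT" else paste(toks, collapse = "+")
  }, "")
  table$aberrant <- vapply(cls, function(x) any(x$aberrant), TRUE)
  attr(table, "construct") <- construct$name
  table
}

#' Number of distinct aberrant event classes in an assay
#'
#' Counts the distinct aberrant event tokens across all isoforms of the
#' table, reported and annexed.
#'
#' @param table an annotated `isoform_table`.
#' @return integer count.
#' @export
count_aberrant_event_classes <- function(table) {
  stopifnot(!is.null(table$aberrant_events))
  length(unique(unlist(table$aberrant_events)))
}

#' Aggregate event-level abundance across isoforms
#'
#' Sums the relative abundance of every isoform (reported and annexed)
#' containing the event, rounded to 0.1 percent — the event-level totals
#' quoted for complex assays are of this form.
#'
#' @param table an annotated `isoform_table`.
#' @param token event token.
#' @return percent, rounded to 0.1.
#' @export
aggregate_event_abundance <- function(table, token) {
  stopifnot(!is.null(table$events))
  has <- vapply(table$events, function(ev) token %in% ev, TRUE)
  if (!any(has)) parse_event_token(token)  # errors on unknown tokens
  round(sum(table$abundance[has]), 1L)
}

#' Compare a wild-type and a mutant assay
#'
#' Computes per-token abundance deltas, the mutant and wild-type aberrant
#' fractions (summed abundance of isoforms containing at least one
#' aberrant event), the canonical reduction (canonical-transcript
#' abundance, wild-type minus mutant) and the total-variation distance
#' between the reported isoform repertoires (percentage points).
#'
#' @param wt,mut annotated `isoform_table`s from the same construct
#'   annotation.
#' @return an `assay_comparison` object.
#' @export
compare_assays <- function(wt, mut) {
  stopifnot(!is.null(wt$token), !is.null(mut$token))
  cw <- attr(wt, "construct"); cm <- attr(mut, "construct")
  if (!is.null(cw) && !is.null(cm) &&
      sub("_c\\..*$", "", cw) != sub("_c\\..*$", "", cm)) {
    stop("assays come from different construct annotations: ", cw,
         " vs ", cm)
  }
  tok_pct <- function(tab) {
    v <- tapply(tab$abundance, tab$token, sum)
    stats::setNames(as.numeric(v), names(v))
  }
  pw <- tok_pct(wt); pm <- tok_pct(mut)
  tokens <- union(names(pw), names(pm))
  deltas <- data.frame(
    token = tokens,
    wt_pct = unname(ifelse(tokens %in% names(pw), pw[tokens], 0)),
    mut_pct = unname(ifelse(tokens %in% names(pm), pm[tokens], 0)),
    stringsAsFactors = FALSE)
  deltas$delta <- deltas$mut_pct - deltas$wt_pct
  rep_pct <- function(tab) {
    t2 <- tab[tab$reported, , drop = FALSE]
    tok_pct(t2)
  }
  rw <- rep_pct(wt); rm_ <- rep_pct(mut)
  rt <- union(names(rw), names(rm_))
  tv <- 0.5 * sum(abs(ifelse(rt %in% names(rw), rw[rt], 0) -
                        ifelse(rt %in% names(rm_), rm_[rt], 0)))
  structure(
    list(deltas = deltas[order(-abs(deltas$delta)), , drop = FALSE],
         aberrant_fraction_wt = sum(wt$abundance[wt$aberrant]),
         aberrant_fraction_mut = sum(mut$abundance[mut$aberrant]),
         canonical_reduction =
           sum(wt$abundance[wt$token == "CT"]) -
           sum(mut$abundance[mut$token == "CT"]),
         tv_reported = tv,
         wt = wt, mut = mut),
    class = "assay_comparison")
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat("assay comparison: aberrant fraction WT ",
      round(x$aberrant_fraction_wt, 1), "% vs mutant ",
      round(x$aberrant_fraction_mut, 1), "%; canonical reduction ",
      round(x$canonical_reduction, 1), " points; reported-repertoire TV ",
      round(x$tv_reported, 1), " points\n", sep = "")
  print(utils::head(x$deltas, 10L))
  invisible(x)
}
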