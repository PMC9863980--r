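# Read processing: demultiplexing, SAM ingestion and an internal
# anchor-chaining spliced aligner against the construct reference.
#
# A ReadAlignment is a list(read_id, strand, segments, gaps,
# unaligned_fraction): `segments` is an ordered (ref_start, ref_end)
# matrix of matched blocks, `gaps` classifies each inter-segment reference
# gap as "intron" or "deletion", and `unaligned_fraction` is the fraction
# of read bases outside all matched blocks.

new_read_alignment <- function(read_id, strand, segments, gaps,
                               unaligned_fraction) {
  structure(list(read_id = read_id, strand = strand,
                 segments = segments, gaps = gaps,
                 unaligned_fraction = unaligned_fraction),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat("read_alignment ", x$read_id, " (", x$strand, "): ",
      format_chain(x$segments), "\n", sep = "")
  invisible(x)
}

reads_as_character <- function(reads) {
  if (inherits(reads, "read_simulation")) return(reads$reads)
  if (inherits(reads, "DNAStringSet")) {
    x <- as.character(reads)
    if (is.null(names(x))) names(x) <- sprintf("read%06d", seq_along(x))
    return(x)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  stopifnot(is.character(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d",
                                                     seq_along(reads))
  reads
}

#' Demultiplex reads by terminal barcode matching
#'
#' Each barcode (and its reverse complement) is fuzzy-matched inside the
#' two terminal windows of every read using edit distance (generalised
#' Levenshtein, best infix match).  A read is assigned iff exactly one
#' barcode achieves a distance `<= max_edits`; ties and misses go to the
#' unassigned bin.
#'
#' @param reads a `read_simulation`, named character vector, `DNAStringSet`
#'   or FASTQ path.
#' @param barcodes named character vector of unique, equal-length barcodes.
#' @param max_edits maximum edit distance (must be < barcode length / 2).
#' @param search_window terminal window length (nt) searched at each end.
#' @return list with `assignment` (named character vector, `NA` for
#'   unassigned), `bins` (list of read-name vectors per barcode) and
#'   `unassigned`.
#' @export
demultiplex <- function(reads, barcodes, max_edits = 3L,
                        search_window = 60L) {
  reads <- reads_as_character(reads)
  if (length(barcodes) == 0L) stop("empty barcode set")
  if (anyDuplicated(barcodes)) stop("duplicate barcode sequence")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L) stop("barcodes must have equal length")
  if (max_edits >= blen / 2) stop("max_edits must be < barcode length / 2")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(barcodes)))
  probes <- c(barcodes, rc)  # 2 * n_bc probes
  pre <- substr(reads, 1L, pmin(nchar(reads), search_window))
  suf <- substr(reads, pmax(1L, nchar(reads) - search_window + 1L),
                nchar(reads))
  d_pre <- utils::adist(probes, pre, partial = TRUE)
  d_suf <- utils::adist(probes, suf, partial = TRUE)
  n_bc <- length(barcodes)
  # per-barcode best distance over probe orientation and read end
  best <- pmin(d_pre[seq_len(n_bc), , drop = FALSE],
               d_pre[n_bc + seq_len(n_bc), , drop = FALSE],
               d_suf[seq_len(n_bc), , drop = FALSE],
               d_suf[n_bc + seq_len(n_bc), , drop = FALSE])
  hits <- best <= max_edits
  n_hits <- colSums(hits)
  which_bc <- apply(best, 2L, which.min)
  assignment <- ifelse(n_hits == 1L, names(barcodes)[which_bc],
                       NA_character_)
  names(assignment) <- names(reads)
  bins <- split(names(assignment)[!is.na(assignment)],
                assignment[!is.na(assignment)])
  list(assignment = assignment, bins = bins,
       unassigned = names(assignment)[is.na(assignment)])
}

#' Ingest spliced alignments from a SAM file
#'
#' CIGAR `N` operations become intron gaps; `D` operations of at least
#' `intron_min` are promoted to intron gaps, shorter ones are absorbed as
#' deletions within a matched block.  Soft/hard clips count into the
#' unaligned fraction.  Unmapped records are skipped (and counted); a
#' reference-name mismatch aborts.
#'
#' @param sam path to a SAM (or BAM) file.
#' @param construct the `minigene_construct` the reads were aligned to.
#' @param intron_min minimum reference gap (nt) regarded as an intron.
#' @return list with `alignments` (list of `read_alignment`) and `skipped`
#'   (count of unmapped records).
#' @export
ingest_sam <- function(sam, construct, intron_min = 30L) {
  bam <- sam
  if (tolower(tools::file_ext(sam)) == "sam") {
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "strand")))[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  skipped <- sum(!mapped)
  rn <- as.character(rec$rname[mapped])
  if (length(rn) && !all(rn == construct$name)) {
    stop("SAM reference name does not match construct '",
         construct$name, "'")
  }
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar[mapped])
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar[mapped])
  alignments <- vector("list", sum(mapped))
  qn <- rec$qname[mapped]
  st <- as.character(rec$strand[mapped])
  po <- rec$pos[mapped]
  for (i in seq_along(alignments)) {
    alignments[[i]] <- cigar_to_alignment(qn[i], st[i], po[i],
                                          ops[[i]], lens[[i]], intron_min)
  }
  list(alignments = alignments, skipped = skipped)
}

cigar_to_alignment <- function(qname, strand, pos, ops, lens, intron_min) {
  ref_pos <- pos
  seg_start <- pos
  starts <- integer(0)
  ends <- integer(0)
  gaps <- character(0)
  clipped <- 0L
  read_len <- 0L
  close_segment <- function(gap_kind) {
    if (ref_pos > seg_start) {
      starts <<- c(starts, seg_start)
      ends <<- c(ends, ref_pos - 1L)
      if (length(starts) > 1L) gaps <<- c(gaps, gap_kind)
    }
  }
  pending_gap <- "intron"
  for (j in seq_along(ops)) {
    op <- ops[j]
    len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- ref_pos + len
      read_len <- read_len + len
    } else if (op == "D") {
      if (len >= intron_min) {
        close_segment(pending_gap)
        pending_gap <- "intron"
        ref_pos <- ref_pos + len
        seg_start <- ref_pos
      } else {
        ref_pos <- ref_pos + len  # small deletion absorbed in block
      }
    } else if (op == "N") {
      close_segment(pending_gap)
      pending_gap <- "intron"
      ref_pos <- ref_pos + len
      seg_start <- ref_pos
    } else if (op == "I") {
      read_len <- read_len + len
    } else if (op %in% c("S", "H")) {
      clipped <- clipped + len
      if (op == "S") read_len <- read_len + len
    }
  }
  close_segment(pending_gap)
  segments <- cbind(start = starts, end = ends)
  new_read_alignment(qname, strand, segments, gaps,
                     unaligned_fraction = clipped / max(read_len, 1L))
}

# ---- internal anchor-chaining spliced aligner ------------------------------

#' K-mer index of a construct reference
#' @keywords internal
kmer_index <- function(sequence, k) {
  L <- nchar(sequence)
  kmers <- substring(sequence, 1:(L - k + 1L), k:L)
  list(keys = kmers, pos_by_key = split(seq_len(L - k + 1L), kmers), k = k,
       chars = strsplit(sequence, "", fixed = TRUE)[[1L]])
}

# merge co-diagonal runs of consecutive k-mer hits into maximal anchors
collect_anchors <- function(read, idx) {
  k <- idx$k
  n <- nchar(read)
  if (n < k) return(NULL)
  rk <- substring(read, 1:(n - k + 1L), k:n)
  hit <- idx$pos_by_key[rk]
  nh <- lengths(hit)
  if (sum(nh) == 0L) return(NULL)
  qi <- rep.int(seq_along(rk), nh)
  ri <- unlist(hit, use.names = FALSE)
  diag <- ri - qi
  o <- order(diag, qi)
  qi <- qi[o]; ri <- ri[o]; diag <- diag[o]
  new_run <- c(TRUE, diff(diag) != 0L | diff(qi) != 1L)
  run <- cumsum(new_run)
  qs <- qi[new_run]
  rs <- ri[new_run]
  i_last <- c(which(new_run)[-1L] - 1L, length(qi))
  qe <- qi[i_last] + k - 1L
  re <- ri[i_last] + k - 1L
  cbind(qs = qs, qe = qe, rs = rs, re = re, len = qe - qs + 1L)
}

# collinear chaining over anchors, maximising anchored bases
chain_anchors <- function(a, max_chain_read_gap = 200L) {
  n <- nrow(a)
  o <- order(a[, "qs"], a[, "rs"])
  a <- a[o, , drop = FALSE]
  score <- a[, "len"]
  prev <- integer(n)
  for (i in seq_len(n)[-1L]) {
    j <- seq_len(i - 1L)
    ok <- a[j, "qs"] < a[i, "qs"] & a[j, "rs"] < a[i, "rs"] &
      a[j, "re"] < a[i, "re"] &
      (a[i, "qs"] - a[j, "qe"]) <= max_chain_read_gap
    if (any(ok)) {
      overlap <- pmax(0L, a[j, "qe"] - a[i, "qs"] + 1L,
                      a[j, "re"] - a[i, "rs"] + 1L)
      cand <- score[j] + a[i, "len"] - overlap
      cand[!ok] <- -Inf
      b <- which.max(cand)
      if (cand[b] > score[i]) {
        score[i] <- cand[b]
        prev[i] <- b
      }
    }
  }
  end <- which.max(score)
  path <- end
  while (prev[end] > 0L) {
    end <- prev[end]
    path <- c(end, path)
  }
  list(anchors = a[path, , drop = FALSE], score = score[which.max(score)])
}

# Score-based refinement of a chained anchor set: anchors are collapsed
# into blocks, small unanchored read chunks spanning intron gaps are placed
# by (near-)exact search (the small-pseudoexon case, where no anchor can
# land), each junction gap is split between its flanking blocks by
# maximising a +1/-2 match/mismatch score, and terminal read bases are
# attached at their best-scoring extension.
refine_chain <- function(readc, refc, anchors, intron_min, max_read_gap,
                         min_exon_chunk = 8L) {
  qs <- anchors[, "qs"]; qe <- anchors[, "qe"]
  rs <- anchors[, "rs"]; re <- anchors[, "re"]
  blocks <- list()
  cb <- c(qs[1L], qe[1L], rs[1L], re[1L])
  for (i in seq_along(qs)[-1L]) {
    ref_gap <- rs[i] - cb[4L] - 1L
    read_gap <- qs[i] - cb[2L] - 1L
    # a junction needs the reference to advance at least an intron more
    # than the read; co-diagonal error deserts merge into one block
    if (ref_gap < intron_min || (ref_gap - read_gap) < intron_min) {
      cb[2L] <- max(cb[2L], qe[i])
      cb[4L] <- max(cb[4L], re[i])
    } else {
      blocks[[length(blocks) + 1L]] <- cb
      cb <- c(qs[i], qe[i], rs[i], re[i])
    }
  }
  blocks[[length(blocks) + 1L]] <- cb
  b <- do.call(rbind, blocks)
  colnames(b) <- c("qs", "qe", "rs", "re")
  n <- nrow(b)
  L <- length(refc)
  rl <- length(readc)

  # banded extension from (q0, r0) in direction dir: lane d tracks the net
  # ref-minus-read advance (indel tolerance).  Returns, for 0..len read
  # bases consumed, the best score and the ref advance at that best.
  band_ext <- function(q0, r0, len, dir, band = 3L) {
    best_sc <- numeric(len + 1L)
    best_d <- integer(len + 1L)
    if (len <= 0L) return(list(score = best_sc[1L], dref = best_d[1L]))
    band <- min(8L, band + len %/% 40L)
    lanes <- seq.int(-band, band)
    nl <- length(lanes)
    s <- rep(-Inf, nl); s[band + 1L] <- 0
    for (i in seq_len(len)) {
      q <- readc[q0 + dir * i]
      rpos <- r0 + dir * (i + lanes)
      okr <- rpos >= 1L & rpos <= L
      subsc <- rep(-Inf, nl)
      subsc[okr] <- ifelse(refc[rpos[okr]] == q, 1, -1)
      tmp <- pmax(s + subsc, c(s[-1L] - 2, -Inf))
      s <- pmax(tmp, c(-Inf, tmp[-nl] - 2))
      bidx <- which.max(s)
      best_sc[i + 1L] <- s[bidx]
      best_d[i + 1L] <- lanes[bidx]
    }
    list(score = best_sc, dref = best_d)
  }

  inserted <- list()
  extra_aligned <- 0L
  i <- 1L
  while (i < n) {
    # blocks overlapping on the read (chance matches across a junction)
    # are trimmed back on the left block, deterministically
    o <- b[i, "qe"] - b[i + 1L, "qs"] + 1L
    if (o > 0L) {
      o <- min(o, b[i, "qe"] - b[i, "qs"])
      b[i, "qe"] <- b[i, "qe"] - o
      b[i, "re"] <- b[i, "re"] - o
    }
    g <- b[i + 1L, "qs"] - b[i, "qe"] - 1L
    if (g > 0L) {
      # extend each block into the junction gap up to its best score; when
      # both want the same read bases, split the gap at the best total
      Ls <- band_ext(b[i, "qe"], b[i, "re"], g, +1L)
      Rs <- band_ext(b[i + 1L, "qs"], b[i + 1L, "rs"], g, -1L)
      # splice-motif awareness: candidate donor ends followed by GT and
      # acceptor starts preceded by AG earn a bonus, pinning the split at
      # the biological junction when the sequence evidence is ambiguous
      reL <- b[i, "re"] + seq.int(0L, g) + Ls$dref
      donor <- 2 * (refc[pmin(L, reL + 1L)] == "G" &
                      refc[pmin(L, reL + 2L)] == "T")
      rsR <- b[i + 1L, "rs"] - seq.int(0L, g) - Rs$dref
      acc <- 2 * (refc[pmax(1L, rsR - 1L)] == "G" &
                    refc[pmax(1L, rsR - 2L)] == "A")
      iL <- which.max(Ls$score + donor) - 1L
      jR <- which.max(Rs$score + acc) - 1L
      placed <- FALSE
      leftover <- g - iL - jR
      if (leftover >= min_exon_chunk && leftover > max_read_gap) {
        # a sizeable read chunk that neither side wants, across an
        # intron-sized gap: try to place it as a middle segment (a small
        # pseudoexon, shorter than the anchors) by (near-)exact search
        ms <- b[i, "re"] + iL + Ls$dref[iL + 1L]
        me <- b[i + 1L, "rs"] - jR - Rs$dref[jR + 1L]
        if (me - ms - 1L >= intron_min) {
          chunk <- paste(readc[(b[i, "qe"] + iL + 1L):
                                 (b[i + 1L, "qs"] - jR - 1L)],
                         collapse = "")
          gap_seq <- Biostrings::DNAString(
            paste(refc[(ms + 1L):(me - 1L)], collapse = ""))
          hit <- Biostrings::matchPattern(chunk, gap_seq)
          if (length(hit) == 0L) {
            hit <- Biostrings::matchPattern(chunk, gap_seq,
                                            max.mismatch = 1L)
          }
          if (length(hit) == 0L && nchar(chunk) >= 12L) {
            hit <- Biostrings::matchPattern(chunk, gap_seq,
                                            max.mismatch = 2L,
                                            with.indels = TRUE)
          }
          if (length(hit) >= 1L) {
            inserted[[length(inserted) + 1L]] <-
              list(rs = ms + Biostrings::start(hit)[1L],
                   re = ms + Biostrings::end(hit)[1L],
                   qlen = nchar(chunk))
            extra_aligned <- extra_aligned + nchar(chunk)
            placed <- TRUE
          }
        }
      }
      if (!placed) {
        # plain junction: every read base in the gap belongs to one side;
        # split the gap at the best total (motif-aware) score
        tot <- (Ls$score + donor) + rev(Rs$score + acc)
        bi <- which.max(tot) - 1L
        iL <- bi; jR <- g - bi
      }
      b[i, "qe"] <- b[i, "qe"] + iL
      b[i, "re"] <- b[i, "re"] + iL + Ls$dref[iL + 1L]
      b[i + 1L, "qs"] <- b[i + 1L, "qs"] - jR
      b[i + 1L, "rs"] <- b[i + 1L, "rs"] - jR - Rs$dref[jR + 1L]
    }
    i <- i + 1L
  }
  # terminal extension: attach leading/trailing read bases at the longest
  # best-scoring extension (reads span the whole amplicon)
  term_ext <- function(e, len) {
    # prefer long extensions: amplicon reads run to the construct ends, so
    # noisy-but-real tails should still attach (bonus < match reward keeps
    # genuinely foreign tails, e.g. leftover adapters, unaligned)
    sc <- e$score + 0.3 * seq.int(0L, len)
    sc[!is.finite(e$score)] <- -Inf
    max(which(sc == max(sc))) - 1L
  }
  len0 <- b[1L, "qs"] - 1L
  e0 <- band_ext(b[1L, "qs"], b[1L, "rs"], len0, -1L)
  ext <- term_ext(e0, len0)
  b[1L, "qs"] <- b[1L, "qs"] - ext
  b[1L, "rs"] <- max(1L, b[1L, "rs"] - ext - e0$dref[ext + 1L])
  len1 <- rl - b[n, "qe"]
  e1 <- band_ext(b[n, "qe"], b[n, "re"], len1, +1L)
  ext <- term_ext(e1, len1)
  b[n, "qe"] <- b[n, "qe"] + ext
  b[n, "re"] <- min(L, b[n, "re"] + ext + e1$dref[ext + 1L])

  aligned_read <- sum(b[, "qe"] - b[, "qs"] + 1L) + extra_aligned
  segs <- lapply(seq_len(n), function(i) c(b[i, "rs"], b[i, "re"]))
  for (ins in inserted) {
    segs[[length(segs) + 1L]] <- c(ins$rs, ins$re)
  }
  segm <- do.call(rbind, segs)
  segm <- segm[order(segm[, 1L]), , drop = FALSE]
  # merge blocks that ended up adjacent/overlapping on the reference
  merged <- list(segm[1L, ])
  for (i in seq_len(nrow(segm))[-1L]) {
    last <- merged[[length(merged)]]
    gap <- segm[i, 1L] - last[2L] - 1L
    if (gap < intron_min) {
      last[2L] <- max(last[2L], segm[i, 2L])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- segm[i, ]
    }
  }
  segm <- do.call(rbind, merged)
  colnames(segm) <- c("start", "end")
  gaps <- if (nrow(segm) > 1L) rep("intron", nrow(segm) - 1L) else character(0)
  list(segments = segm, gaps = gaps,
       unaligned_fraction = 1 - aligned_read / rl)
}

#' Splice-align one read to a construct by anchor chaining
#'
#' Exact k-mer anchors between read and reference are merged along
#' diagonals and chained collinearly to maximise anchored bases; both
#' orientations are tried and the better kept.  Between consecutive chained
#' blocks, a reference gap of at least `intron_min` with a read gap of at
#' most `max_read_gap` is an intron; smaller reference gaps are absorbed as
#' indels/mismatches.  Segment boundaries are refined by greedy exact
#' extension toward each junction, and unanchored read chunks spanning an
#' intron gap (small pseudoexons shorter than the anchor length) are placed
#' by (near-)exact search inside the gap.
#'
#' @param read a DNA string.
#' @param construct a `minigene_construct`.
#' @param k anchor length (default 11, short enough for anchors to land
#'   inside small pseudoexon segments).
#' @param intron_min minimum intron-sized reference gap (default 30 nt:
#'   safely above small pseudoexons, below any construct intron).
#' @param max_read_gap maximum read-side gap (nt) across an intron.
#' @param read_id identifier recorded in the alignment.
#' @param index optional precomputed [kmer_index()] of the construct.
#' @return a `read_alignment`, or `NULL` when no chain covers at least half
#'   of the read (alignment failure).
#' @export
chain_align <- function(read, construct, k = 11L, intron_min = 30L,
                        max_read_gap = 10L, read_id = "read",
                        index = NULL) {
  if (nchar(read) < k) return(NULL)
  if (is.null(index)) index <- kmer_index(construct$sequence, k)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  best <- NULL
  for (orient in c("+", "-")) {
    rd <- if (orient == "+") read else rc
    a <- collect_anchors(rd, index)
    if (is.null(a)) next
    ch <- chain_anchors(a)
    if (is.null(best) || ch$score > best$score) {
      best <- ch
      best$orient <- orient
      best$read <- rd
    }
  }
  if (is.null(best)) return(NULL)
  res <- refine_chain(strsplit(best$read, "", fixed = TRUE)[[1L]],
                      index$chars, best$anchors,
                      intron_min, max_read_gap)
  if (res$unaligned_fraction > 0.5) return(NULL)
  new_read_alignment(read_id, best$orient, res$segments, res$gaps,
                     res$unaligned_fraction)
}

#' Splice-align a read set and collect QC
#'
#' Vectorised driver around [chain_align()]: builds the k-mer index once,
#' aligns every read, and reports dropped reads (never silently).
#'
#' @param reads a `read_simulation`, named character vector, `DNAStringSet`
#'   or FASTQ path.
#' @inheritParams chain_align
#' @return list with `alignments` (list of `read_alignment`), `dropped`
#'   (read names that failed alignment) and `qc` (`data.frame` of counts).
#' @export
align_reads <- function(reads, construct, k = 11L, intron_min = 30L,
                        max_read_gap = 10L) {
  reads <- reads_as_character(reads)
  index <- kmer_index(construct$sequence, k)
  alignments <- vector("list", length(reads))
  ok <- logical(length(reads))
  for (i in seq_along(reads)) {
    al <- chain_align(reads[[i]], construct, k = k, intron_min = intron_min,
                      max_read_gap = max_read_gap,
                      read_id = names(reads)[i], index = index)
    if (!is.null(al)) {
      alignments[[i]] <- al
      ok[i] <- TRUE
    }
  }
  list(alignments = alignments[ok],
       dropped = names(reads)[!ok],
       qc = data.frame(n_reads = length(reads), aligned = sum(ok),
                       dropped = sum(!ok),
                       aligned_fraction = sum(ok) / length(reads)))
}

#' Alignment segments as one table
#'
#' @param alignments list of `read_alignment`.
#' @return `data.frame` with `read_id`, `segment`, `start`, `end`.
#' @export
alignment_segments <- function(alignments) {
  n_seg <- vapply(alignments, function(a) nrow(a$segments), 0L)
  data.frame(
    read_id = rep.int(vapply(alignments, `[[`, "", "read_id"), n_seg),
    segment = unlist(lapply(n_seg, seq_len), use.names = FALSE),
    start = unlist(lapply(alignments, function(a) a$segments[, "start"]),
                   use.names = FALSE),
    end = unlist(lapply(alignments, function(a) a$segments[, "end"]),
                 use.names = FALSE),
    stringsAsFactors = FALSE)
}
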