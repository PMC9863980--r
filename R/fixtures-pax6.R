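# Synthetic PAX6-like minigene constructs and study mixtures.
#
# The real assay sequences are not redistributed here; these builders
# generate synthetic surrogate sequences with the authentic coordinate
# geometry of the two multi-exonic PAX6 minigenes (exons 5-7 in an
# exon-trapping pSPL3-style vector; exons 10-13 in a rhodopsin-exon trap):
# exon 6 spans c.142-c.357 with the alternative donor at c.156, intron 6
# carries the cryptic acceptor/donor sites at offsets +138/+235/+319 and
# +331 (as AG / GT dinucleotides) and the reference alleles of the two
# intron-6 variants; intron 11 carries the reference alleles of the two
# intron-11 variants.  Coding exon sequence is generated from sense codons
# so the canonical open reading frame is stop-free, which makes frameshift
# and PTC arithmetic behave as on the real transcript.  Everything is
# deterministic (fixed internal seeds).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codon_dna <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_nt / 3, replace = TRUE), collapse = "")
}

with_fixed_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

force_bases <- function(seq, pos, bases) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- bases[i]
  seq
}

#' Synthetic PAX6-like minigene construct, exons 5 to 7
#'
#' Deterministic surrogate for the exon 5-7 exon-trapping minigene: vector
#' trap exons flank a cloned insert of 248 bp of intron 4, exon 5
#' (c.20-141), intron 5 with the 42-nt alternative exon 5a, exon 6
#' (c.142-357, alternative internal donor after c.156), the complete 720-bp
#' intron 6 and exon 7 (c.358-507) with 231 bp of intron 7.  Intron 6
#' contains cryptic acceptor sites whose first exonized bases sit at
#' offsets +138, +235 and +319 and a cryptic donor whose last exonized base
#' sits at +331, plus the reference alleles of c.357+136G>A and
#' c.357+334G>A.
#'
#' @return a `minigene_construct`.
#' @export
pax6_construct_5_7 <- function() {
  with_fixed_seed(5757L, {
    cds <- paste0(random_dna(2L), sense_codon_dna(507L - 22L + 1L))  # c.20..507
    cds_at <- function(c1, c2) substr(cds, c1 - 19L, c2 - 19L)
    v1   <- random_dna(180L)
    vinA <- random_dna(120L)
    fl4  <- random_dna(248L)
    e5   <- cds_at(20L, 141L)
    i5a  <- random_dna(200L)
    e5a  <- random_dna(42L)
    i5b  <- random_dna(180L)
    e6   <- cds_at(142L, 357L)
    i6   <- random_dna(720L)
    e7   <- cds_at(358L, 507L)
    fl7  <- random_dna(231L)
    vinB <- random_dna(120L)
    v2   <- random_dna(160L)
    seq <- paste0(v1, vinA, fl4, e5, i5a, e5a, i5b, e6, i6, e7, fl7, vinB, v2)
    # Canonical splice motifs at every donor/acceptor used by any isoform:
    # GT after the last exonized base (itself forced to C) and AG before the
    # first exonized base (itself forced to A).  Besides being the
    # biological motif, this leaves zero microhomology across any spliced
    # junction, so junction placement is unambiguous.  Forced coding bases
    # are chosen so no in-frame stop can arise.
    donors <- c(180L, 670L, 912L, 1107L, 1308L, 1639L, 2178L)
    acceptors <- c(549L, 871L, 1093L, 1543L, 1627L, 2029L, 2530L)
    seq <- force_bases(seq, donors, rep("C", length(donors)))
    seq <- force_bases(seq, donors + 1L, rep("G", length(donors)))
    seq <- force_bases(seq, donors + 2L, rep("T", length(donors)))
    seq <- force_bases(seq, acceptors - 2L, rep("A", length(acceptors)))
    seq <- force_bases(seq, acceptors - 1L, rep("G", length(acceptors)))
    seq <- force_bases(seq, acceptors, rep("A", length(acceptors)))
    # intron-6 variant reference alleles and the +138 cryptic acceptor: the
    # WT carries GG at +136/+137, so c.357+136G>A creates the AG; +334 is
    # the +3 position of the shared cryptic donor at +331
    seq <- force_bases(seq, 1308L + c(136L, 137L, 138L, 334L),
                       c("G", "G", "A", "G"))
    exons <- data.frame(
      label   = c("V1", "5", "5a", "6", "7", "V2"),
      start   = c(1L, 549L, 871L, 1093L, 2029L, 2530L),
      end     = c(180L, 670L, 912L, 1308L, 2178L, 2689L),
      c_start = c(NA, 20, NA, 142, 358, NA),
      c_end   = c(NA, 141, NA, 357, 507, NA),
      class   = c("vector", "constitutive", "alternative", "constitutive",
                  "constitutive", "vector"),
      stringsAsFactors = FALSE)
    minigene_construct(
      name = "PAX6_5-7",
      sequence = seq, exons = exons,
      cds_anchor = list(construct_pos = 549L, c_pos = 20, phase = 1L),
      insert_region = c(301L, 2409L),
      natural_events = c("5a", "∆'6", "∆5", "∆6"),
      partial_registry = data.frame(label = "6", side = "5prime",
                                    retained = 15L,
                                    stringsAsFactors = FALSE))
  })
}

#' Synthetic PAX6-like minigene construct, exons 10 to 13
#'
#' Deterministic surrogate for the exon 10-13 rhodopsin-trap minigene:
#' exon 10 (c.830-965), exon 11 (c.966-1032), the complete 600-bp intron 11
#' carrying the reference alleles of c.1032+170A>T and c.1033-275A>C (and
#' AG dinucleotides at the predicted cryptic acceptors c.1032+168 /
#' c.1033-262), exon 12 (c.1033-1183) and exon 13 (c.1184-1290, natural
#' stop at c.1267-1269) with 79 bp of 3'UTR-side flank.
#'
#' @return a `minigene_construct`.
#' @export
pax6_construct_10_13 <- function() {
  with_fixed_seed(101313L, {
    cds <- paste0(random_dna(2L),                     # c.830..831
                  sense_codon_dna(1266L - 832L + 1L), # c.832..1266
                  "TAA",                              # c.1267..1269
                  random_dna(1290L - 1270L + 1L))     # c.1270..1290 (UTR side)
    cds_at <- function(c1, c2) substr(cds, c1 - 829L, c2 - 829L)
    vr3  <- random_dna(150L)
    vinA <- random_dna(100L)
    fl9  <- random_dna(37L)
    e10  <- cds_at(830L, 965L)
    i10  <- random_dna(300L)
    e11  <- cds_at(966L, 1032L)
    i11  <- random_dna(600L)
    e12  <- cds_at(1033L, 1183L)
    i12  <- random_dna(250L)
    e13  <- cds_at(1184L, 1290L)
    fl3  <- random_dna(79L)
    vinB <- random_dna(100L)
    vr5  <- random_dna(140L)
    seq <- paste0(vr3, vinA, fl9, e10, i10, e11, i11, e12, i12, e13,
                  fl3, vinB, vr5)
    # canonical GT/AG splice motifs with zero junction microhomology, as in
    # the 5-7 construct (forced coding bases verified stop-safe)
    donors <- c(150L, 423L, 763L, 790L, 1541L, 1898L)
    acceptors <- c(288L, 724L, 1391L, 1442L, 1792L, 2078L)
    seq <- force_bases(seq, donors, rep("C", length(donors)))
    seq <- force_bases(seq, donors + 1L, rep("G", length(donors)))
    seq <- force_bases(seq, donors + 2L, rep("T", length(donors)))
    seq <- force_bases(seq, acceptors - 2L, rep("A", length(acceptors)))
    seq <- force_bases(seq, acceptors - 1L, rep("G", length(acceptors)))
    seq <- force_bases(seq, acceptors, rep("A", length(acceptors)))
    seq <- force_bases(seq, 1439L, "C")  # keep codon 361 (c.1081..) sense
    # intron-11 variant reference alleles and predicted cryptic acceptors
    # (annotation-only): AG at +166/+167 before c.1032+168, variant ref A
    # at +170; variant ref A at c.1033-275; AG before c.1033-262
    seq <- force_bases(seq, 790L + c(166L, 167L, 170L),
                       c("A", "G", "A"))
    seq <- force_bases(seq, c(1116L, 1127L, 1128L), c("A", "A", "G"))
    exons <- data.frame(
      label   = c("RHO3", "10", "11", "12", "13", "RHO5"),
      start   = c(1L, 288L, 724L, 1391L, 1792L, 2078L),
      end     = c(150L, 423L, 790L, 1541L, 1898L, 2217L),
      c_start = c(NA, 830, 966, 1033, 1184, NA),
      c_end   = c(NA, 965, 1032, 1183, 1290, NA),
      class   = c("vector", rep("constitutive", 4L), "vector"),
      stringsAsFactors = FALSE)
    minigene_construct(
      name = "PAX6_10-13",
      sequence = seq, exons = exons,
      cds_anchor = list(construct_pos = 288L, c_pos = 830, phase = 1L),
      insert_region = c(251L, 1977L),
      natural_events = c("∆11", "∆12", "∆'11", "∆'12"),
      partial_registry = data.frame(label = c("11", "12"),
                                    side = c("5prime", "3prime"),
                                    retained = c(40L, 100L),
                                    stringsAsFactors = FALSE))
  })
}

# intron-6 pseudoexons share the cryptic donor at +331; the acceptor offset
# fixes the size (offsets are first/last exonized bases, inclusive)
.pse_acceptor_offset <- c("PSE194" = 138L, "PSE97" = 235L, "PSE13" = 319L)

#' Build an isoform chain from splicing-event tokens
#'
#' Starting from the canonical chain of the construct, applies event tokens
#' in the field's nomenclature: `"5a"` (alternative exon inclusion),
#' `"∆<label>"` (full exon skip), `"∆'<label>"` (registered
#' partial exon), `"Ins<nt>"` (exon 6 elongated `<nt>` nucleotides into
#' intron 6) and `"PSE<nt>"` (intron-6 pseudoexon between the cryptic
#' acceptor for that size and the shared cryptic donor at +331).  Tokens for
#' one isoform can be supplied joined with `"+"`.
#'
#' @param construct one of the two PAX6-like constructs.
#' @param tokens character vector of event tokens (or one `"+"`-joined
#'   string); the canonical transcript is `character(0)` or `"CT"`.
#' @return two-column integer matrix of (start, end) construct segments.
#' @export
pax6_isoform_chain <- function(construct, tokens) {
  if (length(tokens) == 1L) tokens <- strsplit(tokens, "+", fixed = TRUE)[[1L]]
  tokens <- setdiff(tokens, "CT")
  ex <- construct$exons
  seg <- lapply(seq_len(nrow(ex)), function(i)
    c(start = ex$start[i], end = ex$end[i]))
  names(seg) <- ex$label
  keep <- ex$class != "alternative"
  names(keep) <- ex$label
  e6_end_shift <- 0L
  pse <- NULL
  for (tok in tokens) {
    if (tok == "5a") {
      keep[["5a"]] <- TRUE
    } else if (grepl("^∆'", tok)) {
      lab <- sub("^∆'", "", tok)
      reg <- construct$partial_registry
      r <- reg[reg$label == lab, , drop = FALSE]
      if (nrow(r) != 1L) stop("no registered partial exon for ", tok)
      if (r$side == "5prime") {
        seg[[lab]]["end"] <- seg[[lab]]["start"] + r$retained - 1L
      } else {
        seg[[lab]]["start"] <- seg[[lab]]["end"] - r$retained + 1L
      }
    } else if (grepl("^∆", tok)) {
      keep[[sub("^∆", "", tok)]] <- FALSE
    } else if (grepl("^Ins", tok)) {
      e6_end_shift <- as.integer(sub("^Ins", "", tok))
    } else if (tok %in% names(.pse_acceptor_offset)) {
      e6 <- ex[ex$label == "6", ]
      pse <- rbind(pse, c(start = e6$end + .pse_acceptor_offset[[tok]],
                          end = e6$end + 331L))
    } else {
      stop("unknown event token: ", tok)
    }
  }
  if (e6_end_shift > 0L) seg[["6"]]["end"] <- seg[["6"]]["end"] + e6_end_shift
  chain <- do.call(rbind, seg[keep[names(seg)]])
  if (!is.null(pse)) chain <- rbind(chain, pse)
  chain <- chain[order(chain[, "start"]), , drop = FALSE]
  rownames(chain) <- NULL
  storage.mode(chain) <- "integer"
  chain
}

#' Declared isoform mixtures of the minigene assays
#'
#' The study conditions for the synthetic assays: per-sample isoform
#' mixtures given as event-token labels with relative abundances in percent
#' (summing to 100).  The abundances of isoforms reported in the source
#' assays are used verbatim; sub-threshold isoforms that were only
#' summarised in aggregate are completed with plausible minor natural
#' isoforms so each mixture closes to 100% (see the methods vignette).
#'
#' @param sample one of `"wt_5_7"`, `"c.357+136G>A"`, `"c.357+334G>A"`,
#'   `"wt_10_13"`, `"c.1032+170A>T"`, `"c.1033-275A>C"`.
#' @return `data.frame` with columns `label` and `abundance` (percent).
#' @export
pax6_mixture <- function(sample) {
  D <- "∆"
  Dp <- "∆'"
  mix <- switch(
    sample,
    "wt_5_7" = data.frame(
      label = c("CT", paste0(Dp, "6"), "5a", paste0(D, "5"),
                paste0("5a+", Dp, "6"), paste0(D, "6"),
                paste0("5a+", D, "5"), paste0(D, "5+", Dp, "6")),
      abundance = c(45.0, 20.0, 14.8, 5.2, 4.9, 3.0, 3.6, 3.5)),
    "c.357+136G>A" = data.frame(
      label = c("Ins331", paste0(Dp, "6+PSE194"), paste0(Dp, "6"), "CT",
                "5a+Ins331", paste0(Dp, "6+PSE13"), "PSE194",
                paste0("5a+", Dp, "6+PSE194"), paste0(D, "5+Ins331"),
                "5a", paste0("5a+", Dp, "6"), paste0(D, "5"),
                paste0(D, "6"), paste0(D, "5+", Dp, "6")),
      abundance = c(26.2, 15.3, 12.1, 9.6, 4.9, 4.6, 3.6, 2.9, 1.1,
                    4.8, 4.0, 4.0, 3.5, 3.4)),
    "c.357+334G>A" = data.frame(
      label = c(paste0(Dp, "6+PSE13"), paste0(Dp, "6"), "Ins331",
                paste0(D, "6"), paste0("5a+", Dp, "6+PSE13"), "CT",
                "PSE13", paste0(Dp, "6+PSE97"), "PSE97",
                paste0(D, "5+PSE13"), paste0(D, "5"),
                paste0(D, "5+", Dp, "6"), paste0(D, "5+Ins331"),
                paste0(D, "5+", D, "6")),
      abundance = c(32.5, 11.5, 10.9, 5.9, 5.0, 4.9, 4.3, 3.8, 1.6,
                    2.6, 4.9, 4.1, 4.0, 4.0)),
    "wt_10_13" = data.frame(
      label = c("CT", paste0(D, "11"), paste0(D, "12"),
                paste0(D, "11+", D, "12"), paste0(Dp, "12"),
                paste0(Dp, "11")),
      abundance = c(80.7, 4.8, 4.6, 4.5, 2.8, 2.6)),
    "c.1032+170A>T" = data.frame(
      label = c("CT", paste0(D, "11"), paste0(D, "12"),
                paste0(D, "11+", D, "12"), paste0(Dp, "12"),
                paste0(Dp, "11")),
      abundance = c(78.5, 6.1, 4.9, 4.4, 3.3, 2.8)),
    "c.1033-275A>C" = data.frame(
      label = c("CT", paste0(D, "11"), paste0(D, "12"),
                paste0(D, "11+", D, "12"), paste0(Dp, "12"),
                paste0(Dp, "11")),
      abundance = c(79.3, 5.6, 4.7, 4.2, 3.4, 2.8)),
    stop("unknown sample: ", sample))
  stopifnot(abs(sum(mix$abundance) - 100) < 1e-9)
  mix
}

#' Isoform mixture resolved to construct chains
#'
#' Couples [pax6_mixture()] with [pax6_isoform_chain()] into the
#' `IsoformSpec` form consumed by [simulate_reads()].
#'
#' @inheritParams pax6_mixture
#' @param construct the matching construct; inferred from the sample name
#'   when omitted.
#' @return `data.frame` with columns `label`, `abundance` (fraction in
#'   0..1) and a list-column `chain`.
#' @export
pax6_isoform_specs <- function(sample, construct = NULL) {
  if (is.null(construct)) {
    construct <- if (grepl("357|5_7", sample)) pax6_construct_5_7()
                 else pax6_construct_10_13()
  }
  mix <- pax6_mixture(sample)
  mix$chain <- lapply(mix$label, pax6_isoform_chain, construct = construct)
  mix$abundance <- mix$abundance / 100
  mix
}

#' Deterministic native-barcode set
#'
#' A reproducible stand-in for a 24-nt native barcoding expansion set;
#' barcodes are generated once from a fixed seed and screened to keep all
#' pairwise edit distances at 8 or more.
#'
#' @param n number of barcodes (up to 24).
#' @return named character vector (`BC01`, `BC02`, ...).
#' @export
nanopore_barcodes <- function(n = 12L) {
  stopifnot(n >= 1L, n <= 24L)
  with_fixed_seed(2424L, {
    bcs <- character(0L)
    while (length(bcs) < 24L) {
      cand <- random_dna(24L)
      if (length(bcs) == 0L ||
          min(utils::adist(cand, bcs)) >= 8L) {
        bcs <- c(bcs, cand)
      }
    }
    stats::setNames(bcs[seq_len(n)], sprintf("BC%02d", seq_len(n)))
  })
}
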