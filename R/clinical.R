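# Protein consequences of isoform chains, NMD heuristic and ACMG
# functional-evidence logic.

transcript_anchor <- function(construct, chain) {
  chain <- as_chain_matrix(chain)
  pos <- construct$cds_anchor$construct_pos
  widths <- chain[, 2L] - chain[, 1L] + 1L
  seg <- which(chain[, 1L] <= pos & chain[, 2L] >= pos)
  if (length(seg) != 1L) return(NULL)
  before <- if (seg > 1L) sum(widths[seq_len(seg - 1L)]) else 0L
  before + (pos - chain[seg, 1L] + 1L)
}

translate_from <- function(seq, t_start) {
  n_cod <- (nchar(seq) - t_start + 1L) %/% 3L
  if (n_cod < 1L) return("")
  sub <- substr(seq, t_start, t_start + 3L * n_cod - 1L)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE))
}

aa3 <- function(aa) {
  if (aa == "*") return("Ter")
  code <- Biostrings::AMINO_ACID_CODE
  unname(code[aa])
}

#' Protein consequence of an isoform chain
#'
#' Splices the chain's sequence, locates the reading frame from the
#' construct's CDS anchor, translates from the first complete codon of the
#' coding ladder, and diffs against the translation of the canonical
#' chain.  A frameshift is called when the net spliced-length change is
#' not a multiple of three; the first changed residue, the new residue and
#' the frameshift termination length (the `N` of `fs*N`, counting the
#' first changed residue as 1) are reported in HGVS p. shorthand.
#'
#' @param construct a `minigene_construct`.
#' @param chain isoform chain (matrix or chain string).
#' @return a `protein_consequence`: list with `kind` (`"no-change"`,
#'   `"in-frame"`, `"frameshift"`, `"stop-gain"` or `"not evaluable"`),
#'   `first_affected_residue`, `ref_aa`, `new_aa`,
#'   `fs_termination_length`, `hgvs_p` and `ptc_position` (transcript
#'   coordinate of the first base of the premature stop, or `NA`).
#' @export
translate_consequence <- function(construct, chain) {
  chain <- as_chain_matrix(chain)
  anchor <- construct$cds_anchor
  t0 <- transcript_anchor(construct, chain)
  if (is.null(t0)) {
    return(structure(list(kind = "not evaluable",
                          first_affected_residue = NA_integer_,
                          ref_aa = NA_character_, new_aa = NA_character_,
                          fs_termination_length = NA_integer_,
                          hgvs_p = NA_character_,
                          ptc_position = NA_integer_),
                     class = "protein_consequence"))
  }
  shift <- (3L - anchor$phase) %% 3L
  first_residue <- (anchor$c_pos + shift - 1L) %/% 3L + 1L
  canon <- canonical_chain(construct)
  t0c <- transcript_anchor(construct, canon)
  var_seq <- isoform_sequence(construct, chain)
  can_seq <- isoform_sequence(construct, canon)
  p_var <- translate_from(var_seq, t0 + shift)
  p_can <- translate_from(can_seq, t0c + shift)
  stop_var <- as.integer(regexpr("*", p_var, fixed = TRUE))
  stop_can <- as.integer(regexpr("*", p_can, fixed = TRUE))
  trim <- function(p, s) if (s > 0L) substr(p, 1L, s) else p
  p_var_t <- trim(p_var, stop_var)
  p_can_t <- trim(p_can, stop_can)
  net <- nchar(var_seq) - nchar(can_seq)
  if (identical(p_var_t, p_can_t)) {
    kind <- "no-change"
    return(structure(list(kind = kind,
                          first_affected_residue = NA_integer_,
                          ref_aa = NA_character_, new_aa = NA_character_,
                          fs_termination_length = NA_integer_,
                          hgvs_p = "p.(=)",
                          ptc_position = NA_integer_),
                     class = "protein_consequence"))
  }
  # first differing residue of the (untrimmed) translations
  v <- strsplit(p_var, "")[[1L]]
  cc <- strsplit(p_can, "")[[1L]]
  nmin <- min(length(v), length(cc))
  diff_at <- which(v[seq_len(nmin)] != cc[seq_len(nmin)])
  i <- if (length(diff_at)) diff_at[1L] else nmin + 1L
  ref_aa <- if (i <= length(cc)) cc[i] else NA_character_
  new_aa <- if (i <= length(v)) v[i] else NA_character_
  residue <- first_residue + i - 1L
  frameshift <- net %% 3L != 0L
  if (frameshift) {
    js <- if (stop_var >= i) stop_var else NA_integer_
    fs_len <- if (!is.na(js)) as.integer(js - i + 1L) else NA_integer_
    hgvs <- paste0("p.", aa3(ref_aa), residue, aa3(new_aa), "fs*",
                   if (is.na(fs_len)) "?" else fs_len)
    ptc <- if (!is.na(js)) t0 + shift + 3L * (js - 1L) else NA_integer_
    kind <- "frameshift"
  } else if (!is.na(new_aa) && new_aa == "*") {
    fs_len <- NA_integer_
    hgvs <- paste0("p.", aa3(ref_aa), residue, "*")
    ptc <- t0 + shift + 3L * (i - 1L)
    kind <- "stop-gain"
    js <- i
  } else {
    fs_len <- NA_integer_
    hgvs <- "p.?"
    ptc <- NA_integer_
    kind <- "in-frame"
  }
  structure(list(kind = kind, first_affected_residue = as.integer(residue),
                 ref_aa = ref_aa, new_aa = new_aa,
                 fs_termination_length = fs_len, hgvs_p = hgvs,
                 ptc_position = as.integer(ptc)),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("protein consequence: ", x$kind,
      if (!is.na(x$hgvs_p)) paste0(" (", x$hgvs_p, ")"), "\n", sep = "")
  invisible(x)
}

#' Nonsense-mediated decay heuristic (50-nt rule)
#'
#' NMD is predicted iff the premature termination codon lies at least
#' `rule_nt` nucleotides upstream of the last exon-exon junction of the
#' chain.  Single-segment chains cannot trigger the rule.
#'
#' @param consequence a `protein_consequence` with a `ptc_position`.
#' @param chain the isoform chain the consequence was computed on.
#' @param construct the `minigene_construct`.
#' @param rule_nt distance threshold in nucleotides (default 50).
#' @return list with `nmd` (logical) and `trace` (rule explanation).
#' @export
predict_nmd <- function(consequence, chain, construct, rule_nt = 50L) {
  chain <- as_chain_matrix(chain)
  if (is.na(consequence$ptc_position)) {
    return(list(nmd = FALSE, trace = "no premature termination codon"))
  }
  if (nrow(chain) < 2L) {
    return(list(nmd = FALSE, trace = "no junction"))
  }
  widths <- chain[, 2L] - chain[, 1L] + 1L
  last_junction <- sum(widths[-nrow(chain)])
  dist <- last_junction - consequence$ptc_position
  list(nmd = dist >= rule_nt,
       trace = paste0("PTC at transcript position ",
                      consequence$ptc_position, ", last junction at ",
                      last_junction, ": distance ", dist,
                      if (dist >= rule_nt) " >= " else " < ", rule_nt,
                      " nt"))
}

#' ACMG functional evidence from a minigene assay comparison
#'
#' PS3 (functional studies show a damaging splicing effect) is assigned
#' when the mutant aberrant fraction reaches `ps3_min_aberrant` percent
#' while the wild-type assay is clean; BS3 (no splicing defect) when the
#' mutant aberrant fraction stays at or below `bs3_max_aberrant` percent
#' and the reported isoform repertoire matches the wild type (total
#' variation distance at most `repertoire_tv_max` points).  Anything else
#' is inconclusive.  PS3 and BS3 are never co-assigned.
#'
#' @param cmp an `assay_comparison`.
#' @param ps3_min_aberrant minimum mutant aberrant fraction (%) for PS3.
#' @param bs3_max_aberrant maximum mutant aberrant fraction (%) for BS3.
#' @param wt_max_aberrant maximum wild-type aberrant fraction (%) for PS3.
#' @param repertoire_tv_max maximum reported-repertoire total-variation
#'   distance (points) for BS3.
#' @return list with `verdict` (`"PS3"`, `"BS3"` or `"inconclusive"`) and
#'   the metrics used.
#' @export
splice_functional_evidence <- function(cmp, ps3_min_aberrant = 20,
                                       bs3_max_aberrant = 5,
                                       wt_max_aberrant = 5,
                                       repertoire_tv_max = 10) {
  mut_ab <- cmp$aberrant_fraction_mut
  wt_ab <- cmp$aberrant_fraction_wt
  verdict <- if (mut_ab >= ps3_min_aberrant && wt_ab <= wt_max_aberrant) {
    "PS3"
  } else if (mut_ab <= bs3_max_aberrant &&
             cmp$tv_reported <= repertoire_tv_max) {
    "BS3"
  } else {
    "inconclusive"
  }
  list(verdict = verdict,
       aberrant_fraction_mut = mut_ab,
       aberrant_fraction_wt = wt_ab,
       tv_reported = cmp$tv_reported,
       thresholds = list(ps3_min_aberrant = ps3_min_aberrant,
                         bs3_max_aberrant = bs3_max_aberrant,
                         wt_max_aberrant = wt_max_aberrant,
                         repertoire_tv_max = repertoire_tv_max))
}

#' Default ACMG combining-rule table
#'
#' The standard combining rules expressed as data: each row is a
#' sufficient combination of minimum evidence counts per strength
#' (`PVS`, `PS`, `PM`, `PP`, `BA`, `BS`, `BP`) for a class.  Pass a
#' modified table to [combine_acmg()] to emulate platform-specific
#' weighting.
#'
#' @return `data.frame` of rule rows.
#' @export
acmg_rules <- function() {
  rule <- function(class, PVS = 0, PS = 0, PM = 0, PP = 0,
                   BA = 0, BS = 0, BP = 0) {
    data.frame(class = class, PVS = PVS, PS = PS, PM = PM, PP = PP,
               BA = BA, BS = BS, BP = BP)
  }
  rbind(
    rule(5, PVS = 1, PS = 1), rule(5, PVS = 1, PM = 2),
    rule(5, PVS = 1, PM = 1, PP = 1), rule(5, PVS = 1, PP = 2),
    rule(5, PS = 2),
    rule(5, PS = 1, PM = 3), rule(5, PS = 1, PM = 2, PP = 2),
    rule(5, PS = 1, PM = 1, PP = 4),
    rule(4, PVS = 1, PM = 1),
    rule(4, PS = 1, PM = 1), rule(4, PS = 1, PP = 2),
    rule(4, PM = 3), rule(4, PM = 2, PP = 2), rule(4, PM = 1, PP = 4),
    rule(1, BA = 1), rule(1, BS = 2),
    rule(2, BS = 1, BP = 1), rule(2, BP = 2))
}

#' Combine ACMG criteria into a five-class interpretation
#'
#' Counts the supplied evidence tags by strength, matches them against the
#' rule table, and returns class 1 (benign) to 5 (pathogenic); unmatched
#' or conflicting evidence yields class 3 (VUS).
#'
#' @param criteria character vector of ACMG tags (e.g.
#'   `c("PM2", "PP3", "PS3")`).
#' @param rules rule table as from [acmg_rules()].
#' @return list with `class` (1-5), `label` and the strength `counts`.
#' @export
combine_acmg <- function(criteria, rules = acmg_rules()) {
  criteria <- unique(criteria)
  ok <- grepl("^(PVS|PS|PM|PP|BA|BS|BP)[0-9]+$", criteria)
  if (any(!ok)) stop("unknown ACMG tag(s): ",
                     paste(criteria[!ok], collapse = ", "))
  strength <- sub("[0-9]+$", "", criteria)
  counts <- vapply(c("PVS", "PS", "PM", "PP", "BA", "BS", "BP"),
                   function(s) sum(strength == s), 0L)
  matches <- vapply(seq_len(nrow(rules)), function(i) {
    all(counts >= unlist(rules[i, names(counts)]))
  }, TRUE)
  classes <- rules$class[matches]
  path <- classes[classes >= 4]
  ben <- classes[classes <= 2]
  cls <- if (length(path) && length(ben)) {
    3L  # conflicting evidence
  } else if (length(path)) {
    max(path)
  } else if (length(ben)) {
    min(ben)
  } else {
    3L
  }
  labels <- c("benign", "likely benign", "uncertain significance",
              "likely pathogenic", "pathogenic")
  list(class = as.integer(cls), label = labels[cls], counts = counts)
}
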