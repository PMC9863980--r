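# Shared fixtures: a small two-exon toy construct whose second coding exon
# ends at construct position 250 with coding coordinate 357 (so intronic
# offsets like c.357+331 are exercised directly), a SAM writer that turns
# simulation truth into correct spliced alignments, and a brute-force
# codon-walk consequence oracle.

toy_construct <- function() {
  set.seed(4242)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sense_dna <- function(n_nt) paste(sample(sense, n_nt / 3, replace = TRUE),
                                    collapse = "")
  # c.258..357 on exon A (construct 151..250), c.358..457 on exon B
  # (construct 951..1050); 700-bp intron; short vector flanks
  cds <- sense_dna(201)  # 67 stop-free codons covering c.257..457
  exonA <- substr(cds, 2, 101)
  exonB <- substr(cds, 102, 201)
  seq <- paste0(rand(40),            # V1 vector exon 1..40
                rand(110),           # vector intron / flank 41..150
                exonA,               # 151..250
                rand(700),           # intron 251..950
                exonB,               # 951..1050
                rand(20),            # flank 1051..1070
                rand(40))            # V2 vector exon 1071..1110
  exons <- data.frame(
    label = c("V1", "A", "B", "V2"),
    start = c(1L, 151L, 951L, 1071L),
    end = c(40L, 250L, 1050L, 1110L),
    c_start = c(NA, 258, 358, NA),
    c_end = c(NA, 357, 457, NA),
    class = c("vector", "constitutive", "constitutive", "vector"),
    stringsAsFactors = FALSE)
  minigene_construct("toy", seq, exons,
                     cds_anchor = list(c_pos = 258, phase = 2L),
                     insert_region = c(41L, 1070L))
}

# SAM records built directly from the simulation truth: the output of a
# correct external spliced aligner, by construction
write_truth_sam <- function(sim, construct, path) {
  L <- nchar(construct$sequence)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", construct$name, "\tLN:", L))
  for (i in seq_along(sim$reads)) {
    ch <- parse_chain(sim$truth$chain[i])
    widths <- ch[, "end"] - ch[, "start"] + 1L
    cig <- character(0)
    for (j in seq_len(nrow(ch))) {
      cig <- c(cig, paste0(widths[j], "M"))
      if (j < nrow(ch)) cig <- c(cig, paste0(ch[j + 1L, "start"] -
                                               ch[j, "end"] - 1L, "N"))
    }
    flag <- if (sim$truth$strand[i] == "-") 16L else 0L
    lines <- c(lines, paste(sim$truth$read_id[i], flag, construct$name,
                            ch[1L, "start"], 60L,
                            paste(cig, collapse = ""), "*", 0L, 0L,
                            "*", "*", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# brute-force codon walk: translate both chains with plain substring loops
# and derive kind / first affected residue / frameshift termination length
oracle_consequence <- function(construct, chain) {
  chain <- minisplice:::as_chain_matrix(chain)
  splice <- function(ch) paste(substring(construct$sequence,
                                         ch[, 1L], ch[, 2L]), collapse = "")
  a <- construct$cds_anchor
  tpos <- function(ch, pos) {
    w <- ch[, 2L] - ch[, 1L] + 1L
    for (i in seq_len(nrow(ch))) {
      if (pos >= ch[i, 1L] && pos <= ch[i, 2L]) {
        return((if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L) +
                 pos - ch[i, 1L] + 1L)
      }
    }
    NA_integer_
  }
  t0 <- tpos(chain, a$construct_pos)
  if (is.na(t0)) return(list(kind = "not evaluable"))
  shift <- (3L - a$phase) %% 3L
  gc <- Biostrings::GENETIC_CODE
  walk <- function(seq, from) {
    aa <- character(0)
    i <- from
    while (i + 2L <= nchar(seq)) {
      aa <- c(aa, gc[[substr(seq, i, i + 2L)]])
      i <- i + 3L
    }
    aa
  }
  canon <- canonical_chain(construct)
  pv <- walk(splice(chain), t0 + shift)
  pc <- walk(splice(canon), tpos(canon, a$construct_pos) + shift)
  cut <- function(p) {
    s <- which(p == "*")
    if (length(s)) p[seq_len(s[1L])] else p
  }
  pvt <- cut(pv); pct <- cut(pc)
  first_residue <- (a$c_pos + shift - 1L) %/% 3L + 1L
  if (length(pvt) == length(pct) && all(pvt == pct)) {
    return(list(kind = "no-change"))
  }
  nmin <- min(length(pv), length(pc))
  d <- which(pv[seq_len(nmin)] != pc[seq_len(nmin)])
  i <- if (length(d)) d[1L] else nmin + 1L
  net <- nchar(splice(chain)) - nchar(splice(canon))
  if (net %% 3L != 0L) {
    s <- which(pv == "*")
    s <- s[s >= i]
    list(kind = "frameshift",
         first_affected_residue = as.integer(first_residue + i - 1L),
         ref_aa = pc[i], new_aa = pv[i],
         fs_termination_length = if (length(s)) as.integer(s[1L] - i + 1L)
                                 else NA_integer_)
  } else if (i <= length(pv) && pv[i] == "*") {
    list(kind = "stop-gain",
         first_affected_residue = as.integer(first_residue + i - 1L),
         ref_aa = pc[i])
  } else {
    list(kind = "in-frame",
         first_affected_residue = as.integer(first_residue + i - 1L))
  }
}

# random two-exon toy construct plus a random splicing deviation, for the
# translation oracle equivalence suite
random_consequence_case <- function(seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  gcod <- Biostrings::GENETIC_CODE
  sense <- names(gcod)[gcod != "*"]
  n1 <- sample(10:30, 1L) * 3L
  n2 <- sample(10:30, 1L) * 3L
  e1 <- paste(sample(sense, n1 / 3L, replace = TRUE), collapse = "")
  e2 <- paste0(paste(sample(sense, n2 / 3L - 1L, replace = TRUE),
                     collapse = ""), "TAA")
  intron_len <- 150L
  seq <- paste0(e1, rand(intron_len), e2, rand(30L))
  exons <- data.frame(label = c("E1", "E2"),
                      start = c(1L, n1 + intron_len + 1L),
                      end = c(n1, n1 + intron_len + n2),
                      c_start = c(1, n1 + 1),
                      c_end = c(n1, n1 + n2),
                      class = "constitutive",
                      stringsAsFactors = FALSE)
  construct <- minigene_construct("case", seq, exons,
                                  cds_anchor = list(c_pos = 1, phase = 0L),
                                  insert_region = c(1L, n1 + intron_len + n2))
  canon <- canonical_chain(construct)
  kind <- sample(c("pse", "elong", "partial", "canonical"), 1L)
  chain <- canon
  if (kind == "pse") {
    len <- sample(1:60, 1L)
    s <- n1 + sample(10:(intron_len - 70L), 1L)
    chain <- rbind(canon[1L, ], c(s, s + len - 1L), canon[2L, ])
  } else if (kind == "elong") {
    chain[1L, 2L] <- chain[1L, 2L] + sample(1:40, 1L)
  } else if (kind == "partial") {
    chain[2L, 1L] <- chain[2L, 1L] + sample(1:(n2 - 6L), 1L)
  }
  list(construct = construct, chain = chain)
}
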