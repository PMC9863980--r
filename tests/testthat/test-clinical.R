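# Protein consequences, NMD heuristic and ACMG logic.

test_that("splicing deviations translate as expected on the assay constructs", {
  c57 <- pax6_construct_5_7()
  # all three intron-6 pseudoexon sizes and the 331-nt elongation are not
  # multiples of three, so each must frameshift
  for (tok in c("PSE13", "PSE97", "PSE194", "Ins331")) {
    q <- translate_consequence(c57, pax6_isoform_chain(c57, tok))
    expect_identical(q$kind, "frameshift")
    expect_match(q$hgvs_p, "^p\\..*fs\\*\\d+$")
  }
  # pseudoexons splice in right after c.357, codon 119's last base
  q13 <- translate_consequence(c57, pax6_isoform_chain(c57, "PSE13"))
  expect_identical(q13$first_affected_residue, 120L)
  # natural events: exon 5a (42 nt) and the partial exon 6 (201 nt
  # removed) are in frame; full exon-6 skipping (216 nt) likewise
  for (tok in c("5a", "∆'6", "∆6")) {
    q <- translate_consequence(c57, pax6_isoform_chain(c57, tok))
    expect_identical(q$kind, "in-frame")
  }
  expect_identical(
    translate_consequence(c57, pax6_isoform_chain(c57, "CT"))$kind,
    "no-change")
  # a chain missing the anchor exon is not evaluable
  expect_identical(
    translate_consequence(c57, pax6_isoform_chain(c57, "∆5"))$kind,
    "not evaluable")
})

test_that("a 1-nt exonizing insertion frameshifts a toy CDS", {
  # toy CDS "ATG AAA TTT TAA" split across two exons with a 1-nt
  # pseudoexon inserted after codon 2
  seq <- paste0("ATGAAA", strrep("C", 40L), "G", strrep("C", 39L),
                "TTTTAA", strrep("A", 10L))
  exons <- data.frame(label = c("E1", "E2"),
                      start = c(1L, 87L), end = c(6L, 92L),
                      c_start = c(1, 7), c_end = c(6, 12),
                      class = "constitutive", stringsAsFactors = FALSE)
  toy <- minigene_construct("mini", seq, exons,
                            cds_anchor = list(c_pos = 1, phase = 0L),
                            insert_region = c(1L, 92L))
  chain <- rbind(c(1L, 6L), c(47L, 47L), c(87L, 92L))
  q <- translate_consequence(toy, chain)
  o <- oracle_consequence(toy, chain)
  expect_identical(q$kind, "frameshift")
  expect_identical(q$first_affected_residue, o$first_affected_residue)
  expect_identical(q$first_affected_residue, 3L)
  expect_identical(q$fs_termination_length, o$fs_termination_length)
})

test_that("the translation engine agrees with a brute-force codon walk", {
  for (seed in 1:200) {
    cs <- random_consequence_case(seed)
    q <- translate_consequence(cs$construct, cs$chain)
    o <- oracle_consequence(cs$construct, cs$chain)
    expect_identical(q$kind, o$kind)
    if (q$kind %in% c("frameshift", "stop-gain")) {
      expect_identical(q$first_affected_residue, o$first_affected_residue)
      expect_identical(q$ref_aa, o$ref_aa)
    }
    if (q$kind == "frameshift") {
      expect_identical(q$fs_termination_length, o$fs_termination_length)
      expect_identical(q$new_aa, o$new_aa)
    }
    # frameshift iff the net spliced-length change is not a multiple of 3
    net <- nchar(isoform_sequence(cs$construct, cs$chain)) -
      nchar(isoform_sequence(cs$construct,
                             canonical_chain(cs$construct)))
    if (net %% 3L != 0L) expect_identical(q$kind, "frameshift")
  }
})

test_that("the 50-nt rule drives NMD prediction", {
  c57 <- pax6_construct_5_7()
  ch <- pax6_isoform_chain(c57, "PSE194")
  q <- translate_consequence(c57, ch)
  widths <- ch[, "end"] - ch[, "start"] + 1L
  last_junction <- sum(widths[-length(widths)])
  dist <- last_junction - q$ptc_position
  nmd <- predict_nmd(q, ch, c57)
  expect_identical(nmd$nmd, dist >= 50L)
  expect_true(nmd$nmd)
  # PTC downstream of (or too close to) the last junction: no NMD
  expect_false(predict_nmd(q, ch, c57, rule_nt = dist + 1L)$nmd)
  # single-segment chain: rule cannot fire
  single <- matrix(c(1L, 2689L), nrow = 1L,
                   dimnames = list(NULL, c("start", "end")))
  fake <- q
  fake$ptc_position <- 100L
  expect_identical(predict_nmd(fake, single, c57)$trace, "no junction")
  # no PTC, no NMD
  ct <- translate_consequence(c57, pax6_isoform_chain(c57, "CT"))
  expect_false(predict_nmd(ct, pax6_isoform_chain(c57, "CT"), c57)$nmd)
})

test_that("functional evidence thresholds separate PS3, BS3, inconclusive", {
  mk <- function(mut_ab, wt_ab = 0, tv = 0) {
    structure(list(aberrant_fraction_mut = mut_ab,
                   aberrant_fraction_wt = wt_ab,
                   tv_reported = tv),
              class = "assay_comparison")
  }
  expect_identical(splice_functional_evidence(mk(58.6))$verdict, "PS3")
  expect_identical(splice_functional_evidence(mk(0, tv = 4))$verdict, "BS3")
  expect_identical(splice_functional_evidence(mk(10))$verdict,
                   "inconclusive")
  # clean mutant but shifted repertoire: not BS3
  expect_identical(splice_functional_evidence(mk(0, tv = 30))$verdict,
                   "inconclusive")
  # dirty wild-type blocks PS3
  expect_identical(splice_functional_evidence(mk(60, wt_ab = 40))$verdict,
                   "inconclusive")
  # monotone: increasing the mutant aberrant fraction never moves the
  # verdict from PS3 toward BS3
  rank <- c(BS3 = 1L, inconclusive = 2L, PS3 = 3L)
  prev <- 0L
  for (ab in c(0, 2, 5, 10, 20, 40, 80)) {
    v <- rank[[splice_functional_evidence(mk(ab))$verdict]]
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("ACMG combining reproduces the printed criteria sets", {
  expect_identical(combine_acmg(c("PM2", "PP3", "PP4", "PS3"))$class, 4L)
  expect_identical(combine_acmg(c("PM2", "PP3", "BS3"))$class, 3L)
  expect_identical(combine_acmg(c("BS1", "BP6", "BP7", "BS3"))$class, 1L)
  # standard rules elsewhere in the table
  expect_identical(combine_acmg(c("PVS1", "PS1"))$class, 5L)
  expect_identical(combine_acmg(c("PS1", "PS3"))$class, 5L)
  expect_identical(combine_acmg(c("BS1", "BP4"))$class, 2L)
  expect_identical(combine_acmg(c("PM2"))$class, 3L)
  # conflicting evidence lands on VUS
  expect_identical(combine_acmg(c("PS1", "PS2", "BS1", "BS2"))$class, 3L)
  expect_error(combine_acmg(c("PM2", "FOO")), "unknown ACMG tag")
  # the rule table is data: a custom table can emulate other platforms
  custom <- acmg_rules()
  custom <- custom[!(custom$class == 5 & custom$PS == 2), ]
  expect_identical(
    combine_acmg(c("PM2", "PP3", "PP4", "PS2", "PS3"), custom)$class, 4L)
})
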