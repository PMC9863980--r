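# Demultiplexing, SAM ingestion and the internal anchor-chaining aligner.

test_that("demultiplexing assigns noiseless barcoded reads perfectly", {
  c13 <- pax6_construct_10_13()
  mix <- pax6_isoform_specs("wt_10_13", c13)
  sim <- simulate_reads(c13, mix, n_reads = 120L,
                        model = noiseless_model(), seed = 31)
  bcs <- nanopore_barcodes(12L)
  bsim <- attach_barcodes(sim, bcs)
  dm <- demultiplex(bsim, bcs)
  expect_identical(unname(dm$assignment), bsim$truth$barcode)
  expect_length(dm$unassigned, 0L)
  expect_error(demultiplex(bsim, character(0)), "empty")
})

test_that("edit-distance thresholds bound barcode recovery", {
  bcs <- nanopore_barcodes(12L)
  body <- strrep("ACGTTGCA", 40L)
  mutate_at <- function(x, k) {
    ch <- strsplit(x, "")[[1L]]
    idx <- seq(1L, by = 2L, length.out = k)
    ch[idx] <- chartr("ACGT", "CATG", ch[idx])  # every base changed
    paste(ch, collapse = "")
  }
  # 2 substitutions, max_edits 3: recovered
  r2 <- paste0(mutate_at(bcs[["BC05"]], 2L), body)
  expect_identical(unname(demultiplex(c(r = r2), bcs,
                                      max_edits = 3L)$assignment), "BC05")
  # 4 substitutions, max_edits 3: unassigned
  r4 <- paste0(mutate_at(bcs[["BC05"]], 4L), body)
  expect_true(is.na(demultiplex(c(r = r4), bcs, max_edits = 3L)$assignment))
})

test_that("a noisy 12-plex pool demultiplexes at >= 95% accuracy", {
  c13 <- pax6_construct_10_13()
  mix <- pax6_isoform_specs("wt_10_13", c13)
  sim <- simulate_reads(c13, mix, n_reads = 600L, model = error_model(),
                        seed = 3)
  bcs <- nanopore_barcodes(12L)
  bsim <- attach_barcodes(sim, bcs)
  dm <- demultiplex(bsim, bcs)
  acc <- mean(dm$assignment == bsim$truth$barcode, na.rm = FALSE)
  acc <- sum(dm$assignment == bsim$truth$barcode, na.rm = TRUE) / 600
  expect_gte(acc, 0.95)
  # no read is assigned to a wrong barcode
  ok <- !is.na(dm$assignment)
  expect_identical(unname(dm$assignment[ok]), bsim$truth$barcode[ok])
})

test_that("SAM CIGAR semantics map to segments and intron gaps", {
  toy <- toy_construct()
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "toy.sam")
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:toy\tLN:", nchar(toy$sequence)),
               "r1\t0\ttoy\t1\t60\t100M200N150M\t*\t0\t0\t*\t*",
               "r2\t0\ttoy\t1\t60\t100M5D150M\t*\t0\t0\t*\t*",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"),
             sam)
  ing <- ingest_sam(sam, toy)
  expect_identical(ing$skipped, 1L)
  a1 <- ing$alignments[[1L]]
  expect_identical(unname(a1$segments[, "start"]), c(1L, 301L))
  expect_identical(unname(a1$segments[, "end"]), c(100L, 450L))
  expect_identical(a1$gaps, "intron")
  # a 5-bp deletion below intron_min is absorbed into one block
  a2 <- ing$alignments[[2L]]
  expect_identical(nrow(a2$segments), 1L)
  expect_identical(unname(a2$segments[1L, ]), c(1L, 255L))
  # a deletion of intron size is promoted to an intron gap
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:toy\tLN:", nchar(toy$sequence)),
               "r1\t0\ttoy\t1\t60\t100M80D150M\t*\t0\t0\t*\t*"),
             sam)
  a3 <- ingest_sam(sam, toy)$alignments[[1L]]
  expect_identical(nrow(a3$segments), 2L)
  expect_identical(a3$gaps, "intron")
  # reference mismatch aborts
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:other\tLN:5000",
               "r1\t0\tother\t1\t60\t100M\t*\t0\t0\t*\t*"), sam)
  expect_error(ingest_sam(sam, toy), "reference name")
})

test_that("the chain aligner recovers noiseless chains exactly", {
  c57 <- pax6_construct_5_7()
  # two-exon style case and the 13-nt pseudoexon hard case
  ct <- pax6_isoform_chain(c57, "CT")
  read <- isoform_sequence(c57, ct)
  al <- chain_align(read, c57)
  expect_identical(unname(al$segments[, "start"]), unname(ct[, "start"]))
  expect_identical(unname(al$segments[, "end"]), unname(ct[, "end"]))
  expect_true(all(al$gaps == "intron"))
  pse <- pax6_isoform_chain(c57, "∆'6+PSE13")
  alp <- chain_align(isoform_sequence(c57, pse), c57)
  expect_identical(nrow(alp$segments), nrow(pse))
  w <- alp$segments[, "end"] - alp$segments[, "start"] + 1L
  expect_true(13L %in% w)  # the placed pseudoexon segment
  expect_identical(unname(alp$segments), unname(pse))
  # junction classification is invariant to read orientation
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  al_rc <- chain_align(rc, c57)
  expect_identical(al_rc$segments, al$segments)
  expect_identical(al_rc$strand, "-")
})

test_that("chain aligner and SAM ingestion agree on noiseless reads", {
  c57 <- pax6_construct_5_7()
  mix <- pax6_isoform_specs("c.357+136G>A", c57)
  sim <- simulate_reads(c57, mix, n_reads = 120L,
                        model = noiseless_model(), seed = 13)
  internal <- align_reads(sim, c57)
  expect_identical(internal$qc$aligned, 120L)
  dir <- withr::local_tempdir()
  sam <- write_truth_sam(sim, c57, file.path(dir, "truth.sam"))
  external <- ingest_sam(sam, c57)
  seg_i <- alignment_segments(internal$alignments)
  seg_e <- alignment_segments(external$alignments)
  seg_e <- seg_e[order(seg_e$read_id, seg_e$segment), ]
  seg_i <- seg_i[order(seg_i$read_id, seg_i$segment), ]
  rownames(seg_i) <- rownames(seg_e) <- NULL
  expect_identical(seg_i, seg_e)
})

test_that("noisy reads align with junctions inside the snap window", {
  c13 <- pax6_construct_10_13()
  mix <- pax6_isoform_specs("wt_10_13", c13)
  sim <- simulate_reads(c13, mix, n_reads = 800L, model = error_model(),
                        seed = 8)
  al <- align_reads(sim, c13)
  expect_gte(al$qc$aligned_fraction, 0.95)
  segs <- alignment_segments(al$alignments)
  truth <- setNames(sim$truth$chain, sim$truth$read_id)
  ok <- 0L
  ids <- unique(segs$read_id)
  for (rid in ids) {
    s <- segs[segs$read_id == rid, ]
    tm <- parse_chain(truth[[rid]])
    if (nrow(s) == nrow(tm) &&
        max(abs(s$start - tm[, "start"]),
            abs(s$end - tm[, "end"])) <= 10L) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / length(sim$reads), 0.95)
})

test_that("unalignable reads are dropped and accounted, never silently", {
  c13 <- pax6_construct_10_13()
  junk <- vapply(1:5, function(i) {
    set.seed(1000L + i)
    paste(sample(c("A", "C", "G", "T"), 500L, replace = TRUE),
          collapse = "")
  }, "")
  names(junk) <- paste0("junk", 1:5)
  good <- isoform_sequence(c13, pax6_isoform_chain(c13, "CT"))
  al <- align_reads(c(junk, good = good), c13)
  expect_identical(sort(al$dropped), sort(names(junk)))
  expect_identical(al$qc$aligned, 1L)
  expect_identical(al$qc$dropped, 5L)
})
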