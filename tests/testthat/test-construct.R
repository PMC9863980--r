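test_that("c./construct conversion round-trips exhaustively on a toy construct", {
  toy <- toy_construct()
  # independent per-position ladder built by a plain walk over the construct
  ce <- toy$exons[!is.na(toy$exons$c_start), ]
  for (pos in seq(toy$insert_region[1L], toy$insert_region[2L])) {
    cpos <- construct_to_c(toy, pos)
    expect_false(cpos$region == "vector")
    expect_identical(c_to_construct(toy, cpos), pos)
  }
  # vector flank positions have no c. equivalent
  expect_identical(construct_to_c(toy, 10L)$region, "vector")
})

test_that("intronic offsets resolve against an independent walk oracle", {
  toy <- toy_construct()
  expect_identical(c_to_construct(toy, "c.357+1"), 251L)
  # brute-force oracle: walk base by base from the exon end
  walk <- 250L
  for (i in seq_len(331L)) walk <- walk + 1L
  expect_identical(c_to_construct(toy, "c.357+331"), walk)
  expect_identical(walk, 581L)
  # nearer-boundary labelling: distal intron positions use negative offsets
  expect_identical(construct_to_c(toy, 251L)$label, "c.357+1")
  expect_identical(construct_to_c(toy, 950L)$label, "c.358-1")
  expect_identical(construct_to_c(toy, 1000L)$label, "c.407")
  expect_error(c_to_construct(toy, "c.357+0"), "parse|offset")
  expect_error(c_to_construct(toy, "c.357+900"), "exceeds intron length")
  expect_error(c_to_construct(toy, "c.999+10"), "boundary not in construct")
})

test_that("BED and GFF3 encodings load to the identical internal model", {
  toy <- toy_construct()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">toy", toy$sequence), fa)
  ex <- toy$exons
  bed <- file.path(dir, "toy.bed")
  writeLines(sprintf("toy\t%d\t%d\t%s", ex$start - 1L, ex$end, ex$label), bed)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3",
               sprintf("toy\ttest\texon\t%d\t%d\t.\t+\t.\tName=%s",
                       ex$start, ex$end, ex$label)), gff)
  meta <- ex[, c("label", "c_start", "c_end", "class")]
  anchor <- list(c_pos = 258, phase = 2L)
  from_bed <- load_construct(fa, bed, anchor, exon_meta = meta,
                             insert_region = c(41L, 1070L))
  from_gff <- load_construct(fa, gff, anchor, exon_meta = meta,
                             insert_region = c(41L, 1070L))
  expect_identical(from_bed$exons, from_gff$exons)
  expect_identical(from_bed$sequence, from_gff$sequence)
  expect_identical(from_bed$cds_anchor, from_gff$cds_anchor)
  # BED convention check: 0-based half-open "0 100" is internal 1..100
  bed1 <- file.path(dir, "one.bed")
  writeLines("toy\t0\t100\tE", bed1)
  one <- load_construct(fa, bed1, list(construct_pos = 1L, c_pos = 1,
                                       phase = 0L),
                        exon_meta = data.frame(label = "E", c_start = 1,
                                               c_end = 100,
                                               class = "constitutive"))
  expect_identical(one$exons$start, 1L)
  expect_identical(one$exons$end, 100L)
})

test_that("construct manifests bind sequence, annotation and anchor", {
  toy <- toy_construct()
  dir <- withr::local_tempdir()
  writeLines(c(">toy", toy$sequence), file.path(dir, "toy.fa"))
  ex <- toy$exons
  writeLines(sprintf("toy\t%d\t%d\t%s", ex$start - 1L, ex$end, ex$label),
             file.path(dir, "toy.bed"))
  yaml::write_yaml(list(
    fasta = "toy.fa", annotation = "toy.bed",
    cds_anchor = list(c_pos = 258, phase = 2L),
    exon_meta = lapply(seq_len(nrow(ex)), function(i)
      list(label = ex$label[i], c_start = ex$c_start[i],
           c_end = ex$c_end[i], class = ex$class[i])),
    variants = list("c.357+136G>A")),
    file.path(dir, "manifest.yaml"))
  m <- load_construct_manifest(file.path(dir, "manifest.yaml"))
  expect_s3_class(m$construct, "minigene_construct")
  expect_identical(m$variants, "c.357+136G>A")
  expect_identical(c_to_construct(m$construct, "c.357+1"), 251L)
})

test_that("invalid annotations and anchors are rejected", {
  toy <- toy_construct()
  ex <- toy$exons
  bad <- ex
  bad$start[3L] <- 200L  # overlaps exon A
  expect_error(minigene_construct("x", toy$sequence, bad,
                                  list(c_pos = 258, phase = 2L)),
               "overlap")
  expect_error(minigene_construct("x", toy$sequence, ex,
                                  list(c_pos = 258, phase = 5L)),
               "phase")
  oob <- ex
  oob$end[4L] <- 99999L
  expect_error(minigene_construct("x", toy$sequence, oob,
                                  list(c_pos = 258, phase = 2L)),
               "bounds")
})

test_that("pseudoexon lengths follow the inclusive acceptor-donor convention", {
  expect_identical(pseudoexon_length("c.357+138", "c.357+331"), 194L)
  expect_identical(pseudoexon_length("c.357+319", "c.357+331"), 13L)
  expect_identical(pseudoexon_length("c.357+235", "c.357+331"), 97L)
  expect_error(pseudoexon_length("c.357+138", "c.1032+170"),
               "different introns")
  expect_error(pseudoexon_length("c.357+331", "c.357+138"), "upstream")
  expect_error(pseudoexon_length("c.1033-275", "c.357+331"),
               "positive-offset")
})

test_that("amplicon mass conversion matches the 660 fg/fmol/bp formula", {
  expect_equal(amplicon_mass_ng(150, 1000), 99)
  expect_equal(amplicon_mass_ng(2 * 150, 1000), 2 * 99)  # linear in amount
  expect_error(amplicon_mass_ng(0, 1000), "positive")
  expect_error(amplicon_mass_ng(10, -5), "positive")
})

test_that("variant application substitutes exactly one base and reverts", {
  c57 <- pax6_construct_5_7()
  mut <- apply_variant(c57, "c.357+136G>A")
  d <- which(strsplit(mut$sequence, "")[[1L]] !=
               strsplit(c57$sequence, "")[[1L]])
  expect_length(d, 1L)
  expect_identical(d, c_to_construct(c57, "c.357+136"))
  expect_identical(mut$exons, c57$exons)
  back <- apply_variant(mut, "c.357+136A>G")
  expect_identical(back$sequence, c57$sequence)
  expect_error(apply_variant(c57, "c.357+136C>A"),
               "reference allele mismatch")
})

test_that("the synthetic assay constructs carry the documented geometry", {
  c57 <- pax6_construct_5_7()
  e6 <- c57$exons[c57$exons$label == "6", ]
  expect_identical(e6$end - e6$start + 1L, 216L)  # c.142..357
  expect_identical(c57$exons$class[c57$exons$label == "5a"], "alternative")
  # reference alleles of the two intron-6 variants
  p136 <- c_to_construct(c57, "c.357+136")
  expect_identical(substr(c57$sequence, p136, p136), "G")
  p334 <- c_to_construct(c57, "c.357+334")
  expect_identical(substr(c57$sequence, p334, p334), "G")
  # shared cryptic donor: GT after the last exonized base at +331
  p331 <- c_to_construct(c57, "c.357+331")
  expect_identical(substr(c57$sequence, p331 + 1L, p331 + 2L), "GT")
  c13 <- pax6_construct_10_13()
  p170 <- c_to_construct(c13, "c.1032+170")
  expect_identical(substr(c13$sequence, p170, p170), "A")
  p275 <- c_to_construct(c13, "c.1033-275")
  expect_identical(substr(c13$sequence, p275, p275), "A")
  # deterministic builders
  expect_identical(pax6_construct_5_7()$sequence, c57$sequence)
})
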