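# Breakpoint consensus, curation, snapping and quantification.

# hand-built alignments: chains on a 1000-bp virtual reference
fake_alignment <- function(id, chain) {
  m <- minisplice:::as_chain_matrix(chain)
  minisplice:::new_read_alignment(id, "+", m,
                                  rep("intron", nrow(m) - 1L), 0)
}

rep_alignments <- function(spec) {
  # spec: list of list(chain =, n =)
  out <- list()
  k <- 0L
  for (s in spec) {
    for (i in seq_len(s$n)) {
      k <- k + 1L
      out[[k]] <- fake_alignment(sprintf("r%05d", k), s$chain)
    }
  }
  out
}

test_that("breakpoints at or above the read threshold become consensus sites", {
  als <- rep_alignments(list(
    list(chain = "1-100,201-300", n = 960L),
    list(chain = "1-100,251-300", n = 39L),   # 3.9% alternative acceptor
    list(chain = "1-120,201-300", n = 1L)))   # 0.1% private junction
  sites <- detect_breakpoints(als, read_threshold = 0.03)
  expect_setequal(sites$position[sites$side == "start"], c(1L, 201L, 251L))
  expect_setequal(sites$position[sites$side == "end"], c(100L, 300L))
  # the 1-in-1000 private end at 120 is excluded at 3%
  expect_false(120L %in% sites$position)
  # monotonicity: raising the threshold never adds sites
  for (thr in c(0.01, 0.03, 0.05, 0.2, 0.5)) {
    s_lo <- detect_breakpoints(als, read_threshold = thr)
    s_hi <- detect_breakpoints(als, read_threshold = min(1, thr * 2))
    expect_lte(nrow(s_hi), nrow(s_lo))
    expect_true(all(paste(s_hi$position, s_hi$side) %in%
                      paste(s_lo$position, s_lo$side)))
  }
  expect_error(detect_breakpoints(list()), "no aligned reads")
})

test_that("jittered junctions collapse onto their modal position", {
  set.seed(99)
  spec <- lapply(1:1500, function(i) {
    j <- as.integer(round(rnorm(1, 0, 2)))
    list(chain = sprintf("1-%d,201-300", 100L + j), n = 1L)
  })
  als <- rep_alignments(spec)
  sites <- detect_breakpoints(als, read_threshold = 0.03)
  ends <- sites$position[sites$side == "end"]
  expect_identical(sort(ends), c(100L, 300L))
  # cluster-summed support covers the whole wobble cloud
  expect_gt(sites$support[sites$position == 100L & sites$side == "end"], 0.9)
})

test_that("curation edits apply deterministically", {
  als <- rep_alignments(list(list(chain = "1-100,201-300", n = 50L)))
  sites <- detect_breakpoints(als)
  expect_identical(curate_breakpoints(sites, list()), sites)
  added <- curate_breakpoints(sites, list(
    add = data.frame(position = 251L, side = "start")))
  expect_true(any(added$position == 251L & added$side == "start"))
  moved <- curate_breakpoints(sites, list(
    move = data.frame(from = 201L, to = 205L, side = "start")))
  expect_true(any(moved$position == 205L))
  expect_false(any(moved$position == 201L & moved$side == "start"))
  none <- curate_breakpoints(sites, list(remove = sites))
  expect_identical(nrow(none), 0L)
  asn <- assign_reads(als, none)
  expect_identical(nrow(asn$assigned), 0L)
  expect_identical(unique(asn$unassigned$reason), "no consensus sites")
})

test_that("curation rescues reads from a sub-threshold junction", {
  als <- rep_alignments(list(
    list(chain = "1-100,201-300", n = 980L),
    list(chain = "1-100,251-300", n = 20L)))  # 2% < 3% threshold
  sites <- detect_breakpoints(als, read_threshold = 0.03)
  asn <- assign_reads(als, sites)
  expect_identical(nrow(asn$unassigned), 20L)
  cured <- curate_breakpoints(sites, list(
    add = data.frame(position = 251L, side = "start")))
  asn2 <- assign_reads(als, cured)
  expect_identical(nrow(asn2$unassigned), 0L)
  expect_identical(sum(asn2$assigned$chain == "1-100,251-300"), 20L)
})

test_that("edges snap within the window, ties toward smaller coordinates", {
  sites <- data.frame(position = c(1L, 100L, 201L, 300L),
                      side = c("start", "end", "start", "end"),
                      support = 1)
  # edge exactly on a site is unchanged
  asn <- assign_reads(list(fake_alignment("a", "1-100,201-300")), sites,
                      snap_window = 5L)
  expect_identical(asn$assigned$chain, "1-100,201-300")
  # within the window it snaps
  asn <- assign_reads(list(fake_alignment("b", "1-104,198-300")), sites,
                      snap_window = 5L)
  expect_identical(asn$assigned$chain, "1-100,201-300")
  # at window + 1 the read is unassigned
  asn <- assign_reads(list(fake_alignment("c", "1-106,201-300")), sites,
                      snap_window = 5L)
  expect_identical(asn$unassigned$reason, "unsnappable edge")
  # close site pair: the window auto-caps at floor((d_min - 1) / 2), so
  # sites 100/110 (10 apart) cap the window at 4 and can never be merged;
  # an edge midway between them is unassignable, nearer edges snap home
  sites2 <- rbind(sites, data.frame(position = 110L, side = "end",
                                    support = 1))
  asn <- assign_reads(list(fake_alignment("d", "1-104,201-300")), sites2,
                      snap_window = 5L)
  expect_identical(asn$assigned$chain, "1-100,201-300")
  asn <- assign_reads(list(fake_alignment("d2", "1-106,201-300")), sites2,
                      snap_window = 5L)
  expect_identical(asn$assigned$chain, "1-110,201-300")
  asn <- assign_reads(list(fake_alignment("e", "1-105,201-300")), sites2,
                      snap_window = 5L)
  expect_identical(asn$unassigned$reason, "unsnappable edge")
})

test_that("quantification defines isoforms as chain classes", {
  als <- rep_alignments(list(
    list(chain = "1-100,201-300", n = 807L),
    list(chain = "1-100,251-300", n = 96L),
    list(chain = "1-300", n = 97L)))
  sites <- detect_breakpoints(als)
  tab <- quantify(assign_reads(als, sites))
  expect_s3_class(tab, "isoform_table")
  expect_identical(attr(tab, "total_assigned"), 1000L)
  expect_identical(tab$chain[1L], "1-100,201-300")
  expect_equal(tab$abundance[1L], 80.7)
  expect_equal(sum(tab$abundance), 100, tolerance = 1e-9)
  expect_identical(tab$size[tab$chain == "1-300"], 300L)
  # single isoform: one row at 100%
  one <- quantify(data.frame(read_id = "x", chain = "1-100"))
  expect_identical(nrow(one), 1L)
  expect_equal(one$abundance, 100)
  # idempotence: re-quantifying the class expansion reproduces the table
  expanded <- data.frame(
    read_id = sprintf("e%04d", seq_len(sum(tab$n_reads))),
    chain = rep(tab$chain, tab$n_reads))
  tab2 <- quantify(expanded)
  expect_equal(tab2$abundance, tab$abundance)
  expect_identical(tab2$chain, tab$chain)
})

test_that("report filtering keeps annex rows and is monotone", {
  tab <- quantify(data.frame(
    read_id = sprintf("r%04d", 1:1000),
    chain = rep(c("1-100,201-300", "1-100,251-300", "1-300", "1-100"),
                c(807L, 48L, 46L, 99L))))
  f5 <- filter_report(tab, 5)
  expect_identical(sum(f5$reported), 2L)   # 80.7 and 9.9
  expect_identical(nrow(f5), 4L)           # annex retained
  f0 <- filter_report(tab, 0)
  expect_true(all(f0$reported))
  f100 <- filter_report(tab, 100)
  expect_false(any(f100$reported))
  prev <- Inf
  for (thr in c(0, 2, 5, 10, 50, 100)) {
    n <- sum(filter_report(tab, thr)$reported)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("depth QC reports the 5000-read rule without blocking", {
  tab <- quantify(data.frame(read_id = sprintf("r%d", 1:5001),
                             chain = "1-100"))
  expect_true(qc_depth(tab)$pass)
  tab2 <- quantify(data.frame(read_id = sprintf("r%d", 1:4999),
                              chain = "1-100"))
  q <- qc_depth(tab2)
  expect_false(q$pass)
  expect_identical(q$total_assigned, 4999L)
})
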