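# Nanopore-like amplicon read simulation from declared isoform mixtures.
#
# The simulator emulates the observable footprint of nanopore cDNA amplicon
# sequencing that matters downstream: multinomial isoform sampling,
# indel-dominated per-base errors, small Gaussian wobble of splice-junction
# placement, mixed read orientation and constant synthetic quality strings.
# It does not model signal-level artefacts, realistic quality scores or
# chimeras.

#' Per-base error model for simulated reads
#'
#' @param substitution_rate,insertion_rate,deletion_rate independent
#'   per-base probabilities, each in `[0, 0.25]`.  Defaults (2% / 2% / 4%)
#'   are a deliberately simple indel-dominated nanopore surrogate.
#' @param junction_jitter_sd standard deviation (nt) of the rounded
#'   Gaussian perturbation applied to each internal junction edge.
#' @param seed default random seed carried with the model.
#' @return an object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.02, insertion_rate = 0.02,
                        deletion_rate = 0.04, junction_jitter_sd = 2,
                        seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates > 0.25)) {
    stop("error rates must lie in [0, 0.25]")
  }
  if (junction_jitter_sd < 0) stop("junction_jitter_sd must be >= 0")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 junction_jitter_sd = junction_jitter_sd,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Noise-free error model
#' @return an `error_model` with all rates and jitter zero.
#' @export
noiseless_model <- function(seed = 1L) {
  error_model(0, 0, 0, 0, seed = seed)
}

#' Spliced sequence of an isoform chain
#'
#' Concatenates the reference substrings of the ordered (start, end)
#' segments of a chain.
#'
#' @param construct a `minigene_construct`.
#' @param chain two-column matrix of (start, end) construct segments,
#'   ordered and non-overlapping.
#' @return a DNA string (character scalar).
#' @export
isoform_sequence <- function(construct, chain) {
  chain <- as_chain_matrix(chain)
  if (nrow(chain) == 0L) stop("empty chain")
  if (any(chain[, 1L] > chain[, 2L])) stop("segment with start > end")
  if (any(chain[, 1L] < 1L) || any(chain[, 2L] > nchar(construct$sequence))) {
    stop("segment out of construct range")
  }
  if (nrow(chain) > 1L &&
      any(chain[-1L, 1L] <= chain[-nrow(chain), 2L])) {
    stop("chain segments must be ordered and non-overlapping")
  }
  paste(substring(construct$sequence, chain[, 1L], chain[, 2L]),
        collapse = "")
}

as_chain_matrix <- function(chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  m <- as.matrix(chain)
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

#' @rdname format_chain
#' @param x a chain string like `"1-180,549-670"`.
#' @export
parse_chain <- function(x) {
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

#' Chain string representation
#'
#' Chains are serialised as `"start-end,start-end,..."` for table keys and
#' TSV output.
#'
#' @param chain a two-column (start, end) matrix.
#' @return character scalar.
#' @export
format_chain <- function(chain) {
  chain <- as_chain_matrix(chain)
  paste(paste0(chain[, 1L], "-", chain[, 2L]), collapse = ",")
}

mutate_bases <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  cur[is.na(cur)] <- 1L
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

apply_read_errors <- function(seq, model) {
  if (model$substitution_rate == 0 && model$insertion_rate == 0 &&
      model$deletion_rate == 0) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  chars <- mutate_bases(chars, which(stats::runif(n) < model$substitution_rate))
  del <- stats::runif(n) < model$deletion_rate
  ins <- stats::runif(n) < model$insertion_rate
  pieces <- chars
  pieces[del] <- ""
  n_ins <- sum(ins)
  if (n_ins > 0L) {
    pieces[ins] <- paste0(pieces[ins],
                          sample(c("A", "C", "G", "T"), n_ins, replace = TRUE))
  }
  paste(pieces, collapse = "")
}

jitter_chain <- function(chain, sd, seq_len_max) {
  m <- nrow(chain)
  if (sd == 0 || m == 1L) return(chain)
  ends <- chain[, 2L]
  starts <- chain[, 1L]
  ends[-m] <- ends[-m] + as.integer(round(stats::rnorm(m - 1L, 0, sd)))
  starts[-1L] <- starts[-1L] + as.integer(round(stats::rnorm(m - 1L, 0, sd)))
  # defensive clamps: keep each segment non-empty, ordered and in range
  starts <- pmax(starts, 1L)
  ends <- pmin(ends, seq_len_max)
  ends <- pmax(ends, starts)
  for (i in seq_len(m - 1L)) {
    if (starts[i + 1L] <= ends[i]) starts[i + 1L] <- ends[i] + 1L
  }
  cbind(start = starts, end = ends)
}

#' Simulate nanopore-like amplicon reads from an isoform mixture
#'
#' Each read is drawn multinomially from the mixture, its internal junction
#' edges are perturbed by rounded Gaussian jitter, per-base substitution /
#' insertion / deletion errors are applied i.i.d., and half of the reads
#' are emitted reverse-complemented.  The returned truth table records, per
#' read, the generating isoform and the realised (jittered) segment
#' coordinates.
#'
#' @param construct a `minigene_construct`.
#' @param mixture `data.frame` with columns `label`, `abundance` (fractions
#'   summing to 1) and list-column `chain` (see [pax6_isoform_specs()]).
#' @param n_reads number of reads (>= 1); the default mirrors the
#'   5000-read per-sample sequencing stop rule of the assay design.
#' @param model an [error_model()].
#' @param seed random seed (defaults to the model's seed).
#' @return an object of class `read_simulation`: list with `reads` (named
#'   character vector), `truth` (`data.frame`: `read_id`, `isoform`,
#'   `strand`, `chain`, `barcode`) and `model`.
#' @export
simulate_reads <- function(construct, mixture, n_reads = 5000L,
                           model = error_model(), seed = model$seed) {
  stopifnot(n_reads >= 1L)
  if (abs(sum(mixture$abundance) - 1) > 1e-9) {
    stop("mixture abundances must sum to 1")
  }
  set.seed(seed)
  L <- nchar(construct$sequence)
  iso <- sample.int(nrow(mixture), n_reads, replace = TRUE,
                    prob = mixture$abundance)
  reads <- character(n_reads)
  chains <- character(n_reads)
  for (r in seq_len(n_reads)) {
    chain <- as_chain_matrix(mixture$chain[[iso[r]]])
    chain <- jitter_chain(chain, model$junction_jitter_sd, L)
    chains[r] <- format_chain(chain)
    reads[r] <- apply_read_errors(isoform_sequence(construct, chain), model)
  }
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) {
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  names(reads) <- ids
  structure(
    list(reads = reads,
         truth = data.frame(read_id = ids,
                            isoform = mixture$label[iso],
                            strand = ifelse(flip, "-", "+"),
                            chain = chains,
                            barcode = NA_character_,
                            stringsAsFactors = FALSE),
         model = model,
         construct_name = construct$name),
    class = "read_simulation")
}

#' @export
print.read_simulation <- function(x, ...) {
  cat("read simulation: ", length(x$reads), " reads from '",
      x$construct_name, "' (", length(unique(x$truth$isoform)),
      " isoforms)\n", sep = "")
  invisible(x)
}

#' Attach barcodes to simulated reads
#'
#' Prepends the assigned barcode and appends its reverse complement (the
#' double-ended ligation layout of native barcoding), passing both copies
#' through the same per-base error model as the read bodies.  The truth
#' table gains the barcode assignment.
#'
#' @param sim a `read_simulation`.
#' @param barcodes named character vector of unique, equal-length barcodes.
#' @param assignment barcode name per read (recycled); defaults to cycling
#'   through all barcodes.
#' @return the modified `read_simulation`.
#' @export
attach_barcodes <- function(sim, barcodes,
                            assignment = rep_len(names(barcodes),
                                                 length(sim$reads))) {
  if (anyDuplicated(barcodes)) stop("duplicate barcode sequence")
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("barcodes must have equal length")
  }
  assignment <- rep_len(assignment, length(sim$reads))
  set.seed(sim$model$seed + 1L)
  bc <- unname(barcodes[assignment])
  bc_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bc)))
  front <- vapply(bc, apply_read_errors, "", model = sim$model)
  back <- vapply(bc_rc, apply_read_errors, "", model = sim$model)
  sim$reads <- stats::setNames(paste0(front, sim$reads, back),
                               names(sim$reads))
  sim$truth$barcode <- assignment
  sim
}

#' Write simulated reads as FASTQ (constant synthetic quality)
#' @param sim a `read_simulation`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  x <- Biostrings::DNAStringSet(sim$reads)
  qual <- Biostrings::BStringSet(vapply(nchar(sim$reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write the simulation truth table as TSV
#' @param sim a `read_simulation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
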