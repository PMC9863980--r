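# Minigene construct model: exon annotation, coding (c.) coordinates with
# intronic offsets, variant application and small assay-design arithmetic.
#
# Internal convention: all construct coordinates are 1-based inclusive.
# BED input (0-based half-open) is converted once, on ingestion.

#' Create a minigene construct
#'
#' A minigene construct couples a reference DNA sequence (the plasmid region
#' spanned by the RT-PCR amplicon, in transcription orientation) with an
#' ordered exon annotation and a CDS frame anchor.  Vector trap exons are
#' annotated with class `"vector"` and carry no coding coordinates;
#' alternative exons (e.g. an alternatively included cassette) carry class
#' `"alternative"` and are excluded from the canonical chain.
#'
#' @param name construct label.
#' @param sequence a single DNA string (character or [Biostrings::DNAString]).
#' @param exons `data.frame` with columns `label`, `start`, `end` (construct
#'   coordinates, 1-based inclusive), `c_start`, `c_end` (coding coordinates,
#'   `NA` for vector/alternative exons) and `class`
#'   (`"constitutive"`, `"alternative"` or `"vector"`).
#' @param cds_anchor list with `construct_pos` (construct coordinate of one
#'   coding base), `c_pos` (its coding coordinate) and `phase` (0, 1 or 2:
#'   position of that base within its codon).  `construct_pos` may be `NULL`,
#'   in which case it is resolved from `c_pos` through the exon ladder.
#' @param insert_region length-2 integer vector: first and last construct
#'   position of the cloned genomic insert.  Positions outside it are
#'   vector-derived and have no coding-coordinate equivalent.  Defaults to
#'   the span between the vector flank exons (or the whole sequence).
#' @param natural_events character vector of splicing-event tokens that are
#'   part of the wild-type repertoire of this construct (used by
#'   [classify_isoform()]: events absent from this registry are aberrant).
#' @param partial_registry optional `data.frame` (`label`, `side`,
#'   `retained`) of known natural partial-exon events, so their tokens can be
#'   printed in the field's short form (e.g. a partially included exon).
#'
#' @return an object of class `minigene_construct`.
#' @export
minigene_construct <- function(name, sequence, exons, cds_anchor,
                               insert_region = NULL,
                               natural_events = character(),
                               partial_registry = NULL) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  req <- c("label", "start", "end", "c_start", "c_end", "class")
  if (!all(req %in% names(exons))) {
    stop("exons must have columns: ", paste(req, collapse = ", "))
  }
  exons <- exons[order(exons$start), req, drop = FALSE]
  exons$label <- as.character(exons$label)
  for (col in c("start", "end")) exons[[col]] <- as.integer(exons[[col]])
  for (col in c("c_start", "c_end")) exons[[col]] <- as.numeric(exons[[col]])
  if (!all(exons$class %in% c("constitutive", "alternative", "vector"))) {
    stop("exon class must be constitutive, alternative or vector")
  }
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (any(exons$start < 1L) || any(exons$end > nchar(sequence))) {
    stop("exon interval out of sequence bounds")
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons")
  }
  phase <- cds_anchor$phase
  if (is.null(phase) || !phase %in% 0:2) stop("anchor phase not in {0,1,2}")
  ins <- exons[exons$class != "vector", , drop = FALSE]
  if (is.null(cds_anchor$construct_pos)) {
    hit <- which(!is.na(ins$c_start) & ins$c_start <= cds_anchor$c_pos &
                   ins$c_end >= cds_anchor$c_pos)
    if (length(hit) != 1L) stop("cds anchor c_pos not on a coding exon")
    cds_anchor$construct_pos <-
      ins$start[hit] + (cds_anchor$c_pos - ins$c_start[hit])
  }
  cds_anchor$construct_pos <- as.integer(cds_anchor$construct_pos)
  if (is.null(insert_region)) {
    vec <- exons[exons$class == "vector", , drop = FALSE]
    if (nrow(vec) >= 2L) {
      insert_region <- c(min(vec$end[vec$end < min(ins$start)]) + 1L,
                         max(vec$start[vec$start > max(ins$end)]) - 1L)
    } else {
      insert_region <- c(1L, nchar(sequence))
    }
  }
  structure(
    list(name = name, sequence = sequence, exons = exons,
         cds_anchor = cds_anchor,
         insert_region = as.integer(insert_region),
         natural_events = natural_events,
         partial_registry = partial_registry,
         variant = NULL),
    class = "minigene_construct")
}

#' @export
print.minigene_construct <- function(x, ...) {
  cat("minigene construct '", x$name, "': ", nchar(x$sequence), " bp, ",
      nrow(x$exons), " exons (",
      sum(x$exons$class == "vector"), " vector, ",
      sum(x$exons$class == "alternative"), " alternative)\n", sep = "")
  if (!is.null(x$variant)) cat("  variant applied: ", x$variant, "\n", sep = "")
  invisible(x)
}

# exons participating in the c. coordinate ladder
coding_exons <- function(construct) {
  e <- construct$exons
  e[!is.na(e$c_start) & !is.na(e$c_end), , drop = FALSE]
}

#' Load a minigene construct from FASTA plus BED/GFF3 annotation
#'
#' The annotation convention is taken from the file extension: `.bed` files
#' are 0-based half-open, `.gff`/`.gff3` files 1-based inclusive; both are
#' normalised to the internal 1-based inclusive representation on ingestion.
#' Exon metadata (coding coordinates and exon class) can be supplied either
#' as GFF3 attributes (`c_start`, `c_end`, `exon_class`) or through
#' `exon_meta`, keyed by exon label (BED `name` / GFF3 `Name` or `ID`).
#'
#' @param fasta path to a single-record FASTA file with the construct
#'   sequence.
#' @param annotation path to a BED or GFF3 file with one record per exon.
#' @param cds_anchor as in [minigene_construct()].
#' @param exon_meta optional `data.frame` with columns `label`, `c_start`,
#'   `c_end`, `class`; merged onto the annotation by label.
#' @param ... passed on to [minigene_construct()] (`insert_region`,
#'   `natural_events`, ...).
#' @return a `minigene_construct`.
#' @export
load_construct <- function(fasta, annotation, cds_anchor,
                           exon_meta = NULL, ...) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected a single-record FASTA")
  ext <- tolower(tools::file_ext(annotation))
  if (ext == "bed") {
    gr <- rtracklayer::import(annotation, format = "BED")
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(annotation, format = "GFF3")
  } else {
    stop("annotation must be a .bed or .gff3 file")
  }
  df <- as.data.frame(gr)
  label <- if (!is.null(df$Name) && !all(is.na(df$Name))) df$Name
           else if (!is.null(df$name)) df$name
           else if (!is.null(df$ID)) df$ID
           else as.character(seq_len(nrow(df)))
  exons <- data.frame(label = as.character(label),
                      start = df$start, end = df$end,
                      c_start = NA_real_, c_end = NA_real_,
                      class = "constitutive",
                      stringsAsFactors = FALSE)
  for (col in c("c_start", "c_end")) {
    if (!is.null(df[[col]])) exons[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(df$exon_class)) exons$class <- as.character(df$exon_class)
  if (!is.null(exon_meta)) {
    m <- match(exons$label, exon_meta$label)
    for (col in intersect(c("c_start", "c_end", "class"), names(exon_meta))) {
      upd <- !is.na(m)
      exons[[col]][upd] <- exon_meta[[col]][m[upd]]
    }
  }
  minigene_construct(name = names(seqs)[1L],
                     sequence = as.character(seqs[[1L]]),
                     exons = exons, cds_anchor = cds_anchor, ...)
}

#' Parse an HGVS-style c. position or SNV
#'
#' Accepts exonic positions (`c.156`), intronic positions with signed
#' offsets (`c.357+136`, `c.1033-275`) and single-nucleotide substitutions
#' (`c.357+136G>A`).
#'
#' @param x a character scalar.
#' @return a list with `base` (anchoring coding position), `offset` (signed
#'   integer, 0 for exonic positions) and, for substitutions, `ref`/`alt`.
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regexec("^c\\.(\\d+)([+-]\\d+)?(?:([ACGT])>([ACGT]))?$", x)
  g <- regmatches(x, m)[[1L]]
  if (length(g) == 0L) stop("cannot parse HGVS c. expression: ", x)
  offset <- if (nzchar(g[3L])) as.integer(g[3L]) else 0L
  if (nzchar(g[3L]) && offset == 0L) {
    stop("intronic offset of zero is not a valid position: ", x)
  }
  out <- list(base = as.integer(g[2L]), offset = offset)
  if (nzchar(g[4L])) {
    out$ref <- g[4L]
    out$alt <- g[5L]
  }
  out
}

as_c_position <- function(pos) {
  if (is.character(pos)) parse_hgvs_c(pos) else pos
}

#' Convert a c. position (with optional intronic offset) to a construct
#' coordinate
#'
#' Positive offsets count into the intron downstream of the exon ending at
#' the anchoring coding position; negative offsets count upstream of the
#' exon starting at it.  An offset of zero denotes an exonic position.
#'
#' @param construct a `minigene_construct`.
#' @param pos an HGVS c. string or a list as returned by [parse_hgvs_c()].
#' @return integer construct coordinate (1-based).
#' @export
c_to_construct <- function(construct, pos) {
  pos <- as_c_position(pos)
  ce <- coding_exons(construct)
  if (pos$offset == 0L) {
    hit <- which(ce$c_start <= pos$base & ce$c_end >= pos$base)
    if (length(hit) != 1L) stop("coding position c.", pos$base,
                                " not in construct")
    return(as.integer(ce$start[hit] + (pos$base - ce$c_start[hit])))
  }
  if (pos$offset > 0L) {
    hit <- which(ce$c_end == pos$base)
    if (length(hit) != 1L) {
      stop("no exon ends at c.", pos$base, "; boundary not in construct")
    }
    res <- ce$end[hit] + pos$offset
    nxt <- which(ce$start > ce$end[hit])
    bound <- if (length(nxt)) min(ce$start[nxt]) - 1L
             else construct$insert_region[2L]
    if (res > bound) stop("offset +", pos$offset, " exceeds intron length")
  } else {
    hit <- which(ce$c_start == pos$base)
    if (length(hit) != 1L) {
      stop("no exon starts at c.", pos$base, "; boundary not in construct")
    }
    res <- ce$start[hit] + pos$offset
    prv <- which(ce$end < ce$start[hit])
    bound <- if (length(prv)) max(ce$end[prv]) + 1L
             else construct$insert_region[1L]
    if (res < bound) stop("offset ", pos$offset, " exceeds intron length")
  }
  as.integer(res)
}

#' Convert a construct coordinate to a c. position
#'
#' Exonic positions map to plain coding coordinates; intronic positions are
#' expressed relative to the nearer flanking exon boundary (the standard
#' HGVS convention: `+` offsets in the proximal half of the intron, `-`
#' offsets in the distal half).  Positions outside the cloned insert have no
#' coding equivalent and are flagged as vector-derived.
#'
#' @param construct a `minigene_construct`.
#' @param pos integer construct coordinate.
#' @return a list with `base`, `offset` and `region` (`"exon"`, `"intron"`
#'   or `"vector"`), plus `label` for the printable HGVS form.
#' @export
construct_to_c <- function(construct, pos) {
  stopifnot(length(pos) == 1L)
  pos <- as.integer(pos)
  if (pos < construct$insert_region[1L] || pos > construct$insert_region[2L]) {
    return(list(base = NA_integer_, offset = NA_integer_, region = "vector",
                label = NA_character_))
  }
  ce <- coding_exons(construct)
  hit <- which(ce$start <= pos & ce$end >= pos)
  if (length(hit) == 1L) {
    base <- ce$c_start[hit] + (pos - ce$start[hit])
    return(list(base = as.integer(base), offset = 0L, region = "exon",
                label = paste0("c.", base)))
  }
  up <- which(ce$end < pos)
  dn <- which(ce$start > pos)
  d_up <- if (length(up)) pos - max(ce$end[up]) else NA_integer_
  d_dn <- if (length(dn)) min(ce$start[dn]) - pos else NA_integer_
  if (!is.na(d_up) && (is.na(d_dn) || d_up <= d_dn)) {
    i <- up[which.max(ce$end[up])]
    base <- ce$c_end[i]
    offset <- d_up
    lab <- paste0("c.", base, "+", offset)
  } else {
    i <- dn[which.min(ce$start[dn])]
    base <- ce$c_start[i]
    offset <- -d_dn
    lab <- paste0("c.", base, offset)
  }
  list(base = as.integer(base), offset = as.integer(offset),
       region = "intron", label = lab)
}

#' Apply a single-nucleotide variant to a construct
#'
#' The in silico equivalent of site-directed mutagenesis: the variant is
#' resolved through the coordinate ladder, the reference allele is checked
#' against the construct sequence, and a new construct differing at exactly
#' that base is returned.  A reference-allele mismatch signals a wrong
#' construct or a wrong coordinate convention and is an error.
#'
#' @param construct a `minigene_construct`.
#' @param variant HGVS c. SNV string, e.g. `"c.357+136G>A"`.
#' @return a new `minigene_construct` with the substitution applied and the
#'   variant recorded; the annotation is unchanged.
#' @export
apply_variant <- function(construct, variant) {
  v <- parse_hgvs_c(variant)
  if (is.null(v$ref)) stop("variant must be a substitution, e.g. c.357+136G>A")
  p <- c_to_construct(construct, v)
  have <- substr(construct$sequence, p, p)
  if (have != v$ref) {
    stop("reference allele mismatch at ", variant, ": construct has ", have,
         ", variant states ", v$ref)
  }
  out <- construct
  substr(out$sequence, p, p) <- v$alt
  out$variant <- variant
  out$name <- paste0(construct$name, "_", variant)
  out
}

#' Length of a pseudoexon from its cryptic acceptor and donor positions
#'
#' Both sites are given as intronic positions in positive-offset form in the
#' same intron.  The printed site position is the first (acceptor) and last
#' (donor) *included* nucleotide of the pseudoexon, so the inclusive length
#' is `donor_offset - acceptor_offset + 1`.  Note this differs from the
#' common habit of labelling a 3'SS by its intronic AG dinucleotide: here the
#' acceptor coordinate is already the first exonized base.
#'
#' @param acceptor,donor HGVS c. strings or parsed positions with positive
#'   intronic offsets anchored at the same exon boundary.
#' @return integer length in nucleotides.
#' @export
#' @examples
#' pseudoexon_length("c.357+138", "c.357+331")  # 194
#' pseudoexon_length("c.357+319", "c.357+331")  # 13
pseudoexon_length <- function(acceptor, donor) {
  a <- as_c_position(acceptor)
  d <- as_c_position(donor)
  if (a$offset <= 0L || d$offset <= 0L) {
    stop("sites must be in positive-offset form (normalise negative offsets ",
         "against the upstream exon boundary first)")
  }
  if (a$base != d$base) stop("acceptor and donor are in different introns")
  if (a$offset >= d$offset) stop("acceptor must lie upstream of the donor")
  as.integer(d$offset - a$offset + 1L)
}

#' Amplicon amount conversion, femtomoles to nanograms
#'
#' Mass of a double-stranded amplicon of `length_bp` base pairs present at
#' `fmol` femtomoles, using an average 660 fg per fmol per base pair:
#' `ng = fmol * length_bp * 660 / 1e6`.
#'
#' @param fmol amount in femtomoles (> 0).
#' @param length_bp amplicon length in base pairs (> 0).
#' @return mass in nanograms.
#' @export
#' @examples
#' amplicon_mass_ng(150, 1000)  # 99 ng
amplicon_mass_ng <- function(fmol, length_bp) {
  if (any(fmol <= 0)) stop("fmol must be positive")
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  fmol * length_bp * 660 / 1e6
}

#' Canonical exon chain of a construct
#'
#' The ordered (start, end) segments of the canonical transcript: vector
#' trap exons plus constitutive insert exons.  Alternative exons are
#' excluded.
#'
#' @param construct a `minigene_construct`.
#' @return a two-column integer matrix (`start`, `end`).
#' @export
canonical_chain <- function(construct) {
  e <- construct$exons[construct$exons$class != "alternative", , drop = FALSE]
  cbind(start = e$start, end = e$end)
}

#' Load a construct from a YAML manifest
#'
#' A manifest binds the pieces of a construct definition: `fasta` and
#' `annotation` paths (resolved relative to the manifest), a `cds_anchor`
#' mapping (`c_pos`, `phase`, optional `construct_pos`), optional
#' `exon_meta` rows (`label`, `c_start`, `c_end`, `class`), an optional
#' `natural_events` list and an optional `variants` list of HGVS SNV
#' strings (returned alongside the construct, not applied).
#'
#' @param path path to the YAML manifest.
#' @return list with `construct` (a `minigene_construct`) and `variants`
#'   (character vector).
#' @export
load_construct_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  exon_meta <- NULL
  if (!is.null(m$exon_meta)) {
    exon_meta <- do.call(rbind, lapply(m$exon_meta, function(r)
      data.frame(label = as.character(r$label),
                 c_start = r$c_start %||% NA_real_,
                 c_end = r$c_end %||% NA_real_,
                 class = r$class %||% "constitutive",
                 stringsAsFactors = FALSE)))
  }
  construct <- load_construct(
    fasta = resolve(m$fasta), annotation = resolve(m$annotation),
    cds_anchor = m$cds_anchor, exon_meta = exon_meta,
    natural_events = unlist(m$natural_events) %||% character(0))
  list(construct = construct, variants = unlist(m$variants) %||% character(0))
}
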