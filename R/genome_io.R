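#' Genome container
#'
#' A genome is an ordered set of named uppercase nucleotide sequences over
#' the alphabet A, C, G, T, N, together with per-sequence lengths and the
#' cumulative 0-based offset of each sequence in the concatenated text used
#' by the index. Sequences are joined with one separator symbol, so the
#' concatenated length is `sum(lengths) + (n_seq - 1)` plus a terminator;
#' the separator can never match a pattern character, so matches cannot span
#' sequence boundaries.
#'
#' @param sequences named character vector of nucleotide strings.
#' @return An object of class `genome` with elements `sequences`, `lengths`
#'   and `offsets`.
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0) stop("a genome needs at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence name: ",
                              nm[duplicated(nm)][1])
  seqs <- toupper(sequences)
  seqs <- chartr("URYSWKMBDHV", "TNNNNNNNNNN", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("sequence '", nm[bad][1], "' contains invalid characters")
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, head(lens + 1L, -1L)))
  structure(list(sequences = setNames(seqs, nm),
                 lengths = setNames(as.integer(lens), nm),
                 offsets = setNames(as.integer(offsets), nm)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "sequence(s),",
      sum(x$lengths), "bp total\n")
  for (nm in head(names(x$sequences), 10))
    cat(sprintf("  %s  %d bp\n", nm, x$lengths[[nm]]))
  if (length(x$sequences) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Lowercase (soft-masked) residues are uppercased and treated as
#' targetable; any IUPAC ambiguity code other than A/C/G/T is mapped to N.
#' Gzip-compressed files are handled transparently.
#'
#' @param path path to a FASTA file, optionally `.gz`.
#' @return A [genome] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA record name: ",
                              nm[duplicated(nm)][1])
  genome(setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param g a [genome].
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  ss <- Biostrings::DNAStringSet(g$sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Vectorised.
#'
#' @param seq character vector over the alphabet A, C, G, T, N.
#' @return The reverse complement(s).
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) stop("sequence contains characters outside {A,C,G,T,N}")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Read a gene annotation (GTF or GFF3)
#'
#' Only gene, exon and CDS features are retained. Coordinates are converted
#' from the file's 1-based inclusive convention to the internal 0-based
#' half-open convention. Every exon/CDS must carry a gene id that resolves
#' to a gene feature (or at least a gene id attribute).
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"gff3"`; guessed from the extension by default.
#' @return An annotation data frame with columns `seqnames`, `start`, `end`
#'   (0-based half-open), `strand`, `type` and `gene_id`, of class
#'   `c("annotation", "data.frame")`.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  # structural pre-check so malformed lines are reported with their number
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8))
    stop("malformed annotation line ", body[which(nf < 8)[1]], " in ", path)
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  keep <- S4Vectors::mcols(gr)$type %in% c("gene", "exon", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else rep(NA_character_, length(gr))
  if (format == "gff3" && any(is.na(gid))) {
    # GFF3 often carries gene linkage through Parent/ID instead
    alt <- if ("Parent" %in% names(mc)) vapply(mc$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)) else gid
    gid <- ifelse(is.na(gid), alt, gid)
  }
  type <- as.character(mc$type)
  if (any(is.na(gid) & type %in% c("exon", "CDS")))
    stop("exon/CDS feature without a resolvable gene_id in ", path)
  ann <- data.frame(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    gene_id = gid,
    stringsAsFactors = FALSE)
  gene_ids <- unique(ann$gene_id[ann$type == "gene"])
  sub_ids <- unique(ann$gene_id[ann$type != "gene"])
  if (length(gene_ids) && length(setdiff(sub_ids, gene_ids)))
    stop("exon/CDS gene_id not present among gene features: ",
         setdiff(sub_ids, gene_ids)[1])
  class(ann) <- c("annotation", "data.frame")
  ann
}

#' Write an annotation data frame as GTF
#'
#' Inverse of [read_annotation()] for the retained feature types; internal
#' 0-based half-open coordinates are converted back to 1-based inclusive.
#'
#' @param ann annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  attr_str <- sprintf('gene_id "%s";', ann$gene_id)
  lines <- sprintf("%s\tcrisprtrie\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ann$seqnames, ann$type, ann$start + 1L, ann$end,
                   ann$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based half-open and are preserved as-is.
#' Overlapping lines are both retained; no merging is performed.
#'
#' @param path path to a BED3+ file.
#' @return Data frame with columns `seqnames`, `start`, `end`, `strand`
#'   (`"*"` when absent) and `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("BED line with fewer than 3 columns in ", path)
  start <- as.integer(vapply(fields, `[`, character(1), 2))
  end <- as.integer(vapply(fields, `[`, character(1), 3))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates in ", path)
  if (any(start >= end)) stop("BED interval with start >= end in ", path)
  data.frame(
    seqnames = vapply(fields, `[`, character(1), 1),
    start = start, end = end,
    strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else "*", character(1)),
    name = vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", character(1)),
    stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param intervals data frame with `seqnames`, `start`, `end` and
#'   optionally `name`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "*"
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$seqnames,
                     intervals$start, intervals$end, name,
                     ifelse(strand %in% c("+", "-"), strand, ".")), path)
  invisible(path)
}

# concatenated text codes: sequences joined by separators, terminator last
.genome_codes <- function(g) {
  parts <- lapply(unname(g$sequences), .seq_to_codes)
  n <- length(parts)
  if (n > 1) {
    joined <- vector("list", 2L * n - 1L)
    joined[seq(1, 2L * n - 1L, by = 2L)] <- parts
    joined[seq(2, 2L * n - 2L, by = 2L)] <- list(1L)
    parts <- joined
  }
  c(unlist(parts, use.names = FALSE), 0L)
}

# map a 0-based position in the concatenated text to (seqname, local pos)
.text_to_coord <- function(g, tpos) {
  idx <- findInterval(tpos, g$offsets)
  local <- tpos - g$offsets[idx]
  ok <- local < g$lengths[idx]
  list(seqnames = names(g$sequences)[idx], pos = as.integer(local), valid = ok)
}

# extract [start, end) from a sequence, 0-based half-open
.subseq0 <- function(g, seqname, start, end) {
  substr(g$sequences[[seqname]], start + 1L, end)
}
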