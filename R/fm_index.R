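#' Build an FM-index of a genome
#'
#' Constructs the Burrows-Wheeler transform of the concatenated genome text
#' (one separator between sequences, one terminator at the end) by
#' worst-case-linear induced sorting (SA-IS), together with checkpointed
#' rank structures and a sampled suffix array. The index supports exact
#' backward search, occurrence counting and position recovery, and is the
#' substrate over which off-target enumeration simulates a reverse-prefix
#' trie traversal. N residues are replaced by the separator symbol at index
#' time, so no pattern can match through an N run.
#'
#' Only the forward text is indexed; minus-strand search queries the reverse
#' complement of the pattern and maps coordinates back.
#'
#' @param g a [genome].
#' @param sa_sample_rate suffix-array sampling rate; any value produces
#'   identical search results (default 16, a conventional locate/memory
#'   trade-off).
#' @return An object of class `fm_index`.
#' @export
build_index <- function(g, sa_sample_rate = 16L) {
  stopifnot(inherits(g, "genome"))
  codes <- .genome_codes(g)
  ptr <- fm_build_cpp(codes, as.integer(sa_sample_rate))
  structure(list(ptr = ptr,
                 sequences = g$sequences,
                 lengths = g$lengths,
                 offsets = g$offsets,
                 text_length = length(codes),
                 sa_sample_rate = as.integer(sa_sample_rate),
                 text_hash = text_hash_cpp(codes)),
            class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat("fm_index:", length(x$sequences), "sequence(s),",
      "text length", x$text_length,
      "(SA sample rate", paste0(x$sa_sample_rate, ")"), "\n")
  invisible(x)
}

# genome view of the sequences embedded in an index
.index_genome <- function(index) genome(index$sequences)

#' Root suffix-array interval of an index
#'
#' The interval covering every suffix; the root node of the simulated
#' reverse-prefix trie.
#'
#' @param index an `fm_index`.
#' @return Integer vector `c(low, high)`, a half-open interval.
#' @export
sa_root <- function(index) fm_root_cpp(index$ptr)

#' Backward-search extension of a suffix-array interval
#'
#' Prepends one symbol to the pattern represented by `interval`. An empty
#' interval (`low == high`) signals a dead trie branch and is absorbing.
#'
#' @param index an `fm_index`.
#' @param interval integer `c(low, high)`.
#' @param symbol one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return The extended interval `c(low, high)`.
#' @export
sa_extend <- function(index, interval, symbol) {
  code <- .BASE_CODE[[toupper(symbol)]]
  if (is.null(code) || code < 2L) stop("symbol must be one of A, C, G, T")
  fm_extend_cpp(index$ptr, interval[1], interval[2], code)
}

#' Count exact occurrences of a pattern
#'
#' Number of occurrences of `pattern` in the concatenated genome text,
#' forward orientation only. Patterns containing N return 0 (N never
#' matches).
#'
#' @param index an `fm_index`.
#' @param pattern nucleotide string.
#' @return Non-negative occurrence count.
#' @export
fm_count <- function(index, pattern) {
  if (nchar(pattern) == 0) return(index$text_length)
  codes <- .seq_to_codes(toupper(pattern))
  fm_count_cpp(index$ptr, codes)
}

#' Recover genomic positions for a suffix-array interval
#'
#' Positions are exact, recovered by LF-walking to the nearest suffix-array
#' sample, and returned sorted by (sequence, position).
#'
#' @param index an `fm_index`.
#' @param interval integer `c(low, high)`.
#' @return Data frame with `seqnames` and 0-based `pos`.
#' @export
fm_locate <- function(index, interval) {
  tpos <- fm_locate_cpp(index$ptr, interval[1], interval[2])
  if (length(tpos) == 0)
    return(data.frame(seqnames = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  g <- list(sequences = index$sequences, lengths = index$lengths,
            offsets = index$offsets)
  cc <- .text_to_coord(g, tpos)
  stopifnot(all(cc$valid))  # separators never match, so this cannot fire
  out <- data.frame(seqnames = cc$seqnames, pos = cc$pos,
                    stringsAsFactors = FALSE)
  out[order(out$seqnames, out$pos), , drop = FALSE]
}

# single-file binary index format:
#   magic "CTIDX" (5 bytes), format version int32, text hash double,
#   n_seq int32, then per sequence: name length int32, name bytes,
#   length int32; then sequence text lengths-prefixed concatenated string;
#   then payload length int32 + FM payload (see fm_core.cpp)
.INDEX_MAGIC <- charToRaw("CTIDX")
.INDEX_VERSION <- 1L

#' Save / load an FM-index
#'
#' A versioned single-file binary format with a magic header and the genome
#' names, lengths, offsets and sequence text embedded, so a loaded index
#' behaves identically to the original on count/locate for all patterns.
#'
#' @param index an `fm_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns an
#'   `fm_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.INDEX_MAGIC, con)
  writeBin(.INDEX_VERSION, con, size = 4, endian = "little")
  writeBin(as.double(index$text_hash), con, endian = "little")
  nm <- names(index$sequences)
  writeBin(length(nm), con, size = 4, endian = "little")
  for (i in seq_along(nm)) {
    nb <- charToRaw(nm[i])
    writeBin(length(nb), con, size = 4, endian = "little")
    writeBin(nb, con)
    writeBin(index$lengths[[i]], con, size = 4, endian = "little")
  }
  seq_raw <- charToRaw(paste(index$sequences, collapse = ""))
  writeBin(length(seq_raw), con, size = 4, endian = "little")
  writeBin(seq_raw, con)
  payload <- fm_serialize_cpp(index$ptr)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(.INDEX_MAGIC))
  if (!identical(magic, .INDEX_MAGIC)) stop("not a crisprtrie index file: ", path)
  version <- readBin(con, "integer", size = 4, endian = "little")
  if (!identical(version, .INDEX_VERSION))
    stop("unsupported index format version: ", version)
  hash <- readBin(con, "double", endian = "little")
  n_seq <- readBin(con, "integer", size = 4, endian = "little")
  if (length(n_seq) != 1 || is.na(n_seq) || n_seq < 1)
    stop("corrupted index file: ", path)
  nm <- character(n_seq)
  lens <- integer(n_seq)
  for (i in seq_len(n_seq)) {
    nb <- readBin(con, "integer", size = 4, endian = "little")
    nm[i] <- rawToChar(readBin(con, "raw", n = nb))
    lens[i] <- readBin(con, "integer", size = 4, endian = "little")
  }
  sr_len <- readBin(con, "integer", size = 4, endian = "little")
  all_seq <- rawToChar(readBin(con, "raw", n = sr_len))
  if (nchar(all_seq) != sum(lens)) stop("corrupted index file: ", path)
  starts <- cumsum(c(0L, head(lens, -1L)))
  seqs <- setNames(substring(all_seq, starts + 1L, starts + lens), nm)
  pl <- readBin(con, "integer", size = 4, endian = "little")
  payload <- readBin(con, "raw", n = pl)
  if (length(payload) != pl) stop("corrupted index file: ", path)
  ptr <- fm_deserialize_cpp(payload)
  offsets <- cumsum(c(0L, head(lens + 1L, -1L)))
  idx <- structure(list(ptr = ptr,
                        sequences = seqs,
                        lengths = setNames(as.integer(lens), nm),
                        offsets = setNames(as.integer(offsets), nm),
                        text_length = fm_length_cpp(ptr),
                        sa_sample_rate = fm_sample_rate_cpp(ptr),
                        text_hash = hash),
                   class = "fm_index")
  if (!identical(text_hash_cpp(.genome_codes(.index_genome(idx))), hash))
    stop("corrupted index file (checksum mismatch): ", path)
  idx
}

# error unless the index was built from this genome
.check_index_genome <- function(index, g) {
  if (!identical(text_hash_cpp(.genome_codes(g)), index$text_hash))
    stop("index/genome mismatch: the index was built from a different genome")
  invisible(TRUE)
}
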