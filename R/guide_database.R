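#' Database construction parameters
#'
#' @param spacer_length protospacer/spacer length (default 20).
#' @param pam a [pam_spec]; candidates are required to carry the primary
#'   motif, while off-target annotation also covers the alternatives.
#' @param budget a [search_budget] for off-target annotation (default 3
#'   mismatches, no bulges).
#' @param partitions number of deterministic candidate partitions.
#' @return An object of class `database_params`.
#' @export
database_params <- function(spacer_length = 20L, pam = pam_spec(),
                            budget = search_budget(3L), partitions = 1L) {
  stopifnot(spacer_length >= 10, inherits(pam, "pam_spec"),
            inherits(budget, "search_budget"), partitions >= 1)
  structure(list(spacer_length = as.integer(spacer_length), pam = pam,
                 budget = budget, partitions = as.integer(partitions)),
            class = "database_params")
}

#' Enumerate candidate guide sites in a genome
#'
#' Every window on both strands whose PAM region matches the primary motif
#' and whose spacer+PAM window contains no N, in deterministic order
#' (sequence, position, + before -).
#'
#' @param g a [genome].
#' @param pam a [pam_spec] (3'-side).
#' @param length spacer length.
#' @return Data frame with `seqnames`, `start`, `end` (protospacer, 0-based
#'   half-open, + strand coordinates), `strand`, `spacer` (spacer
#'   orientation), `pam` (observed genomic PAM, spacer orientation).
#' @export
enumerate_candidates <- function(g, pam = pam_spec(), length = 20L) {
  stopifnot(inherits(g, "genome"))
  if (pam$side != "3prime")
    stop("candidate enumeration is defined for 3'-side PAMs")
  motif <- pam$primary
  pamlen <- nchar(motif)
  L <- as.integer(length)
  rows <- list()
  for (seqname in names(g$sequences)) {
    seq <- g$sequences[[seqname]]
    len <- g$lengths[[seqname]]
    if (len < L + pamlen) next
    subject <- Biostrings::DNAString(seq)
    for (strand in c("+", "-")) {
      m <- if (strand == "+") motif else reverse_complement(motif)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(m), subject,
                                       fixed = FALSE)
      pam_start <- Biostrings::start(hits) - 1L  # 0-based
      if (strand == "+") {
        start <- pam_start - L
        keep <- start >= 0L
        start <- start[keep]
        end <- start + L
        pam_s <- pam_start[keep]
      } else {
        start <- pam_start + pamlen
        keep <- start + L <= len
        start <- start[keep]
        end <- start + L
        pam_s <- pam_start[keep]
      }
      if (!length(start)) next
      if (strand == "+") {
        full_s <- start
        full_e <- pam_s + pamlen
      } else {
        full_s <- pam_s
        full_e <- end
      }
      window <- substring(seq, full_s + 1L, full_e)
      keep2 <- !grepl("N", window, fixed = TRUE)
      if (!any(keep2)) next
      start <- start[keep2]; end <- end[keep2]; window <- window[keep2]
      if (strand == "-") window <- reverse_complement(window)
      # window is [spacer][pam] in spacer orientation on both strands
      spacer <- substr(window, 1L, L)
      pam_obs <- substr(window, L + 1L, L + pamlen)
      # fixed=FALSE lets N in the text match the motif wildcard; those
      # windows were removed above, but a concrete motif base must also
      # not have paired with text N
      okpam <- vapply(pam_obs, .matches_iupac, logical(1), motif = motif)
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = seqname, start = start, end = end, strand = strand,
        spacer = spacer, pam = pam_obs,
        stringsAsFactors = FALSE)[okpam, , drop = FALSE]
    }
  }
  if (!length(rows))
    return(data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer = character(), pam = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$seqnames, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a genome-wide guide database
#'
#' Each candidate whose spacer has more than one perfect primary-PAM
#' occurrence genome-wide is dropped (only uniquely targeting guides enter
#' the database). Survivors are annotated with all off-targets within the
#' budget — alternative PAMs included, with alternative-PAM perfect sites
#' recorded at distance 0 — plus specificity (when a CFD table is given and
#' the spacer is 20 nt) and cutting efficiency (when a model is given).
#'
#' @param index an `fm_index` built from the same genome as `candidates`.
#' @param candidates data frame from [enumerate_candidates()].
#' @param params a [database_params].
#' @param cfd_table optional `cfd_table` for specificity.
#' @param efficiency_model optional function `f(spacer)` in \[0, 1\].
#' @return Data frame of guide records sorted by locus, with off-target
#'   distance counts (`ot_d0` ... within budget), `specificity`,
#'   `efficiency` and a hex-encoded off-target summary (`offtargets_hex`).
#' @export
build_database <- function(index, candidates, params = database_params(),
                           cfd_table = NULL, efficiency_model = NULL) {
  stopifnot(inherits(index, "fm_index"), inherits(params, "database_params"))
  k <- params$budget$max_mismatches
  n <- nrow(candidates)
  keep <- logical(n)
  counts <- matrix(0L, n, k + 1L)
  spec <- rep(NA_real_, n)
  hex <- character(n)
  for (i in seq_len(n)) {
    q <- guide_query(candidates$spacer[i], params$pam,
                     on_target = list(seqnames = candidates$seqnames[i],
                                      pos = candidates$start[i],
                                      strand = candidates$strand[i]))
    ot <- enumerate_offtargets(index, q, params$budget)
    # >1 perfect primary occurrence: the own locus plus any 0-mm primary hit
    no_bulge <- ot$rna_bulges == 0 & ot$dna_bulges == 0
    if (any(ot$n_mismatches == 0 & no_bulge & ot$pam_class == "primary")) next
    keep[i] <- TRUE
    counts[i, ] <- tabulate(ot$distance[no_bulge] + 1L, k + 1L)
    if (!is.null(cfd_table) && nchar(candidates$spacer[i]) == 20)
      spec[i] <- specificity(q, ot, cfd_table,
                             max_scored_mm = min(k, 3L))$specificity
    hex[i] <- encode_offtargets_hex(ot, index$offsets)
  }
  out <- candidates[keep, , drop = FALSE]
  out$guide_id <- sprintf("%s:%d:%s", out$seqnames, out$start, out$strand)
  for (d in 0:k) out[[paste0("ot_d", d)]] <- counts[keep, d + 1L]
  out$specificity <- spec[keep]
  out$efficiency <- if (!is.null(efficiency_model) && any(keep))
    as.numeric(efficiency_model(out$spacer)) else rep(NA_real_, sum(keep))
  out$offtargets_hex <- hex[keep]
  out <- out[order(out$seqnames, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --------------------------------------------------------------------------
# Hex off-target encoding, format version 1:
#   byte 0: format version (0x01)
#   then per off-target, 9 bytes little-endian:
#     uint64  global_coordinate * 2 + strand_bit   (strand_bit: '-' = 1)
#     uint8   mismatch distance
# global_coordinate = per-genome cumulative offset of the sequence + the
# 0-based protospacer start. Values stay below 2^53 so the arithmetic is
# exact in doubles.
# --------------------------------------------------------------------------

.HEX_VERSION <- 1L

#' Encode / decode off-target summaries as hex
#'
#' Compact, versioned round-trip encoding of (absolute position, strand,
#' distance) triples; see the package source for the exact byte layout.
#'
#' @param ot off-target data frame with `seqnames`, `start`, `strand`,
#'   `distance`.
#' @param offsets named cumulative sequence offsets (as in a `genome` or
#'   `fm_index`).
#' @return `encode_offtargets_hex` returns one hex string;
#'   `decode_offtargets_hex` returns a data frame with `seqnames`, `start`,
#'   `strand`, `distance`.
#' @export
encode_offtargets_hex <- function(ot, offsets) {
  if (nrow(ot) == 0) return("")
  gpos <- unname(offsets[ot$seqnames]) + ot$start
  if (anyNA(gpos)) stop("off-target on a sequence missing from offsets")
  val <- gpos * 2 + (ot$strand == "-")
  bytes <- vapply(seq_along(val), function(i) {
    v <- val[i]
    b <- numeric(8)
    for (j in 1:8) { b[j] <- v %% 256; v <- v %/% 256 }
    paste(sprintf("%02x", c(b, ot$distance[i])), collapse = "")
  }, character(1))
  paste0(sprintf("%02x", .HEX_VERSION), paste(bytes, collapse = ""))
}

#' @rdname encode_offtargets_hex
#' @param hex hex string produced by `encode_offtargets_hex`.
#' @export
decode_offtargets_hex <- function(hex, offsets) {
  empty <- data.frame(seqnames = character(), start = integer(),
                      strand = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(hex) || !nzchar(hex)) return(empty)
  if (nchar(hex) %% 2 != 0 || grepl("[^0-9a-fA-F]", hex))
    stop("malformed hex off-target encoding")
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), 16L)
  if (bytes[1] != .HEX_VERSION)
    stop("unsupported off-target encoding version: ", bytes[1])
  body <- bytes[-1]
  if (length(body) %% 9 != 0) stop("malformed hex off-target encoding")
  n <- length(body) / 9
  if (n == 0) return(empty)
  seq_starts <- unname(offsets)
  seq_names <- names(offsets)
  out <- empty[rep(1, 0), ]
  recs <- lapply(seq_len(n), function(i) {
    chunk <- body[(9 * (i - 1) + 1):(9 * i)]
    v <- sum(chunk[1:8] * 256^(0:7))
    strand <- if (v %% 2 == 1) "-" else "+"
    gpos <- v %/% 2
    idx <- findInterval(gpos, seq_starts)
    data.frame(seqnames = seq_names[idx],
               start = as.integer(gpos - seq_starts[idx]),
               strand = strand, distance = chunk[9],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# --------------------------------------------------------------------------
# SAM emission. One alignment line per guide record covering the full
# protospacer+PAM footprint; POS is 1-based, FLAG 0/16 encodes strand, SEQ
# is the reference-forward sequence of the footprint. Custom tags:
#   cs:f specificity, ds:f efficiency, of:H hex off-target summary,
#   sp:Z spacer (spacer orientation), oc:B:I off-target counts by distance.
# --------------------------------------------------------------------------

#' Write guide records as SAM / read them back
#'
#' @param records guide-record data frame from [build_database()].
#' @param g the [genome] the records refer to (for headers and SEQ).
#' @param path output path.
#' @return `write_sam` returns `path` invisibly; `read_sam` returns the
#'   records data frame (fields round-trip losslessly).
#' @export
write_sam <- function(records, g, path) {
  stopifnot(inherits(g, "genome"))
  unknown <- setdiff(unique(records$seqnames), names(g$sequences))
  if (length(unknown)) stop("unknown sequence name: ", unknown[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(g$sequences))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, g$lengths[[nm]]), con)
  writeLines(sprintf("@PG\tID:crisprtrie\tPN:crisprtrie\tVN:%s",
                     as.character(utils::packageVersion("crisprtrie"))), con)
  if (nrow(records) == 0) return(invisible(path))
  pamlen <- nchar(records$pam[1])
  full_s <- ifelse(records$strand == "+", records$start, records$start - pamlen)
  full_e <- ifelse(records$strand == "+", records$end + pamlen, records$end)
  seqtxt <- vapply(seq_len(nrow(records)), function(i)
    .subseq0(g, records$seqnames[i], full_s[i], full_e[i]), character(1))
  ocols <- grep("^ot_d", names(records), value = TRUE)
  oc <- apply(records[, ocols, drop = FALSE], 1, paste, collapse = ",")
  fmtf <- function(x) sprintf("%.17g", x)  # exact double round-trip
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tsp:Z:%s\tpc:Z:%s\toc:B:I,%s%s%s\tof:H:%s",
    records$guide_id, ifelse(records$strand == "+", 0L, 16L),
    records$seqnames, full_s + 1L, full_e - full_s, seqtxt,
    records$spacer, records$pam, oc,
    ifelse(is.na(records$specificity), "",
           sprintf("\tcs:f:%s", fmtf(records$specificity))),
    ifelse(is.na(records$efficiency), "",
           sprintf("\tds:f:%s", fmtf(records$efficiency))),
    ifelse(nzchar(records$offtargets_hex), records$offtargets_hex, "01"))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  cols <- c("seqnames", "start", "end", "strand", "spacer", "pam")
  if (length(body) == 0) {
    out <- data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer = character(), pam = character(),
                      guide_id = character(), specificity = numeric(),
                      efficiency = numeric(), offtargets_hex = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  get_tag <- function(f, tag) {
    hit <- f[startsWith(f, tag)]
    if (length(hit)) sub(tag, "", hit[1], fixed = TRUE) else NA_character_
  }
  recs <- lapply(fields, function(f) {
    flag <- as.integer(f[2])
    strand <- if (bitwAnd(flag, 16L)) "-" else "+"
    pos0 <- as.integer(f[4]) - 1L
    spacer <- get_tag(f, "sp:Z:")
    pam <- get_tag(f, "pc:Z:")
    pamlen <- nchar(pam)
    flen <- nchar(spacer) + pamlen
    start <- if (strand == "+") pos0 else pos0 + pamlen
    end <- start + nchar(spacer)
    oc <- get_tag(f, "oc:B:")
    counts <- as.integer(strsplit(oc, ",", fixed = TRUE)[[1]][-1])
    cs <- get_tag(f, "cs:f:")
    ds <- get_tag(f, "ds:f:")
    hex <- get_tag(f, "of:H:")
    rec <- data.frame(seqnames = f[3], start = start, end = end,
                      strand = strand, spacer = spacer, pam = pam,
                      guide_id = f[1], stringsAsFactors = FALSE)
    for (d in seq_along(counts)) rec[[paste0("ot_d", d - 1L)]] <- counts[d]
    rec$specificity <- if (is.na(cs)) NA_real_ else as.numeric(cs)
    rec$efficiency <- if (is.na(ds)) NA_real_ else as.numeric(ds)
    rec$offtargets_hex <- if (is.na(hex) || hex == "01") {
      if (is.na(hex)) "" else hex
    } else hex
    rec
  })
  out <- do.call(rbind, recs)
  out$offtargets_hex[out$offtargets_hex == "01"] <- ""
  rownames(out) <- NULL
  out[, c(cols, setdiff(names(out), cols)), drop = FALSE]
}

#' Partitioned database construction
#'
#' Splits the (sorted) candidate list round-robin into `partitions` groups,
#' runs the worker on each, and merges the outputs into one globally sorted
#' record set. The merged result is identical to a single-partition run;
#' partition assignment is deterministic.
#'
#' @param candidates candidate data frame (will be sorted).
#' @param partitions number of partitions (>= 1; may exceed the candidate
#'   count, in which case some partitions are empty).
#' @param worker function taking a candidate subset and returning records.
#' @return Merged, sorted record data frame.
#' @export
partition_run <- function(candidates, partitions, worker) {
  stopifnot(partitions >= 1)
  candidates <- candidates[order(candidates$seqnames, candidates$start,
                                 candidates$strand), , drop = FALSE]
  assignment <- (seq_len(nrow(candidates)) - 1L) %% partitions
  parts <- lapply(0:(partitions - 1L), function(p)
    candidates[assignment == p, , drop = FALSE])
  outs <- lapply(parts, function(part) {
    res <- tryCatch(worker(part), error = function(e)
      stop("partition worker failed: ", conditionMessage(e)))
    res
  })
  outs <- outs[vapply(outs, nrow, integer(1)) > 0]
  if (!length(outs)) return(worker(candidates[0, , drop = FALSE]))
  merged <- do.call(rbind, outs)
  merged <- merged[order(merged$seqnames, merged$start, merged$strand), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}
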