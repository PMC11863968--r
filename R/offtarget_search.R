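#' PAM specification
#'
#' A primary IUPAC motif (e.g. NGG for SpCas9), optional alternative motifs
#' (e.g. NAG, tolerated but less efficiently cut), and the side of the
#' protospacer on which the PAM sits.
#'
#' @param primary IUPAC motif string.
#' @param alternatives character vector of alternative IUPAC motifs, all of
#'   the same length as `primary`.
#' @param side `"3prime"` (Cas9-like) or `"5prime"` (Cas12a-like).
#' @return An object of class `pam_spec`.
#' @export
pam_spec <- function(primary = "NGG", alternatives = "NAG", side = "3prime") {
  side <- match.arg(side, c("3prime", "5prime"))
  motifs <- c(primary, alternatives)
  if (any(!nzchar(motifs))) stop("PAM motifs must be non-empty")
  bad <- !grepl(paste0("^[", paste(names(.IUPAC), collapse = ""), "]+$"),
                toupper(motifs))
  if (any(bad)) stop("invalid IUPAC code in PAM motif: ", motifs[bad][1])
  if (length(unique(nchar(motifs))) != 1)
    stop("all PAM motifs must have the same length")
  structure(list(primary = toupper(primary),
                 alternatives = toupper(alternatives),
                 side = side),
            class = "pam_spec")
}

#' Expand an IUPAC motif to its concrete ACGT motifs
#'
#' N is a wildcard matching any nucleotide; degenerate codes expand to the
#' exact set of matching ACGT strings.
#'
#' @param motif IUPAC motif string.
#' @return Character vector of all concrete expansions.
#' @export
expand_pam <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  sets <- .IUPAC[chars]
  if (any(vapply(sets, is.null, logical(1))))
    stop("invalid IUPAC code in motif: ", motif)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

# allowed-base bitmask per motif position (bit 0=A .. bit 3=T)
.pam_masks <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  vapply(chars, function(ch) {
    bases <- .IUPAC[[ch]]
    if (is.null(bases)) stop("invalid IUPAC code: ", ch)
    sum(bitwShiftL(1L, match(bases, c("A", "C", "G", "T")) - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

# does `seq` (concrete, may contain N) match the IUPAC motif? N never matches.
.matches_iupac <- function(seq, motif) {
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  mc <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (length(sc) != length(mc)) return(FALSE)
  all(mapply(function(s, m) s %in% .IUPAC[[m]], sc, mc))
}

#' Guide query
#'
#' A spacer sequence (5'->3') plus a PAM specification, optionally with a
#' declared on-target locus that enumeration should exclude.
#'
#' @param spacer nucleotide string over A, C, G, T, length >= 10.
#' @param pam a [pam_spec].
#' @param on_target optional list/data.frame row with `seqnames`, `pos`
#'   (0-based protospacer start on the + strand) and `strand`.
#' @return An object of class `guide_query`.
#' @export
guide_query <- function(spacer, pam = pam_spec(), on_target = NULL) {
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over {A,C,G,T}")
  if (nchar(spacer) < 10) stop("spacer length must be >= 10")
  stopifnot(inherits(pam, "pam_spec"))
  structure(list(spacer = spacer, pam = pam, on_target = on_target),
            class = "guide_query")
}

#' Search budget
#'
#' @param max_mismatches maximum spacer mismatches k.
#' @param max_rna_bulges maximum unpaired spacer bases (genomic gaps).
#' @param max_dna_bulges maximum unpaired genomic bases (spacer gaps).
#' @return An object of class `search_budget`.
#' @export
search_budget <- function(max_mismatches = 3L, max_rna_bulges = 0L,
                          max_dna_bulges = 0L) {
  b <- lapply(list(max_mismatches, max_rna_bulges, max_dna_bulges), as.integer)
  if (any(unlist(b) < 0)) stop("budgets must be non-negative")
  structure(list(max_mismatches = b[[1]], max_rna_bulges = b[[2]],
                 max_dna_bulges = b[[3]]),
            class = "search_budget")
}

# plain-list data.frame constructor; avoids data.frame()'s deparse overhead
# on the per-candidate hot path
.quick_df <- function(lst) {
  n <- if (length(lst)) length(lst[[1]]) else 0L
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

.EMPTY_OT <- .quick_df(list(
  seqnames = character(), start = integer(), end = integer(),
  strand = character(), protospacer = character(), pam = character(),
  pam_class = character(), n_mismatches = integer(),
  mismatch_string = character(), rna_bulges = integer(),
  dna_bulges = integer(), distance = integer(), pam_start = integer(),
  rb_pos = integer(), db_gap = integer()))

.empty_offtargets <- function() .EMPTY_OT

# run the trie-traversal search for one motif on one strand and attach
# coordinates; 5' PAMs search the reverse-complement geometry (a 5'-side
# PAM on the + strand is a 3'-side PAM for the - strand pattern).
.search_one <- function(index, spacer, motif, strand, budget, pam_class,
                        side = "3prime") {
  sp_codes <- match(strsplit(spacer, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T")) - 1L
  masks <- if (nchar(motif) > 0) .pam_masks(motif) else integer(0)
  minus <- strand == "-"
  if (side == "5prime") {
    # treat as a 3'-PAM search of the reverse complement geometry
    sp_codes <- rev(3L - sp_codes)
    masks <- rev(bitwAnd(15L, vapply(masks, function(m) {
      r <- 0L
      for (b in 0:3) if (bitwAnd(m, bitwShiftL(1L, b))) r <- bitwOr(r, bitwShiftL(1L, 3L - b))
      r
    }, integer(1))))
    minus <- !minus
  }
  res <- fm_search_cpp(index$ptr, sp_codes, masks, minus,
                       budget$max_mismatches, budget$max_rna_bulges,
                       budget$max_dna_bulges)
  n <- length(res$tpos)
  if (n == 0) return(.empty_offtargets())
  pamlen <- nchar(motif)
  g <- list(sequences = index$sequences, lengths = index$lengths,
            offsets = index$offsets)
  cc <- .text_to_coord(g, res$tpos)
  if (!minus) {
    proto_start <- cc$pos
    proto_end <- cc$pos + res$winlen
    pam_start <- proto_end
  } else {
    pam_start <- cc$pos
    proto_start <- cc$pos + pamlen
    proto_end <- proto_start + res$winlen
  }
  # on the original (side-aware) strand labels
  out_strand <- if (side == "5prime") ifelse(minus, "+", "-") else strand
  proto <- pam <- character(n)
  for (i in seq_len(n)) {
    sq <- cc$seqnames[i]
    p <- .subseq0(g, sq, proto_start[i], proto_end[i])
    pm <- if (pamlen > 0) {
      if (!minus) .subseq0(g, sq, pam_start[i], pam_start[i] + pamlen)
      else .subseq0(g, sq, pam_start[i], pam_start[i] + pamlen)
    } else ""
    if (minus) {
      p <- reverse_complement(p)
      if (pamlen > 0) pm <- reverse_complement(pm)
    }
    proto[i] <- p
    pam[i] <- pm
  }
  # 5'-PAM searches run on the reverse-complemented geometry; flip the
  # reported strings and mismatch positions back to the original spacer frame
  ms <- res$mismatch_string
  if (side == "5prime") {
    L <- nchar(spacer)
    ms <- vapply(strsplit(ms, ";", fixed = TRUE), function(parts) {
      parts <- parts[nzchar(parts)]
      if (length(parts) == 0) return("")
      mat <- regmatches(parts, regexec("^(\\d+):([ACGT])>([ACGT])$", parts))
      flipped <- vapply(mat, function(m) {
        j <- L + 1L - as.integer(m[2])
        sprintf("%d:%s>%s", j, chartr("ACGT", "TGCA", m[3]),
                chartr("ACGT", "TGCA", m[4]))
      }, character(1))
      ord <- order(as.integer(sub(":.*", "", flipped)))
      paste(flipped[ord], collapse = ";")
    }, character(1))
    proto <- reverse_complement(proto)
    pam <- ifelse(nzchar(pam), reverse_complement(pam), pam)
  }
  .quick_df(list(seqnames = cc$seqnames, start = as.integer(proto_start),
                 end = as.integer(proto_end),
                 strand = rep(out_strand, n),
                 protospacer = proto, pam = pam,
                 pam_class = rep(pam_class, n),
                 n_mismatches = res$mm, mismatch_string = ms,
                 rna_bulges = res$rna_bulges, dna_bulges = res$dna_bulges,
                 distance = res$mm, pam_start = as.integer(pam_start),
                 rb_pos = res$rb_pos, db_gap = res$db_gap))
}

# one row per locus: keep the alignment minimising (mismatches + bulges),
# ties broken by fewer bulges, then leftmost gap placement, then primary PAM
.dedup_offtargets <- function(ot) {
  if (nrow(ot) == 0) return(ot)
  key <- paste(ot$seqnames, ot$strand, ot$pam_start, sep = "\r")
  bulges <- ot$rna_bulges + ot$dna_bulges
  ord <- order(key, ot$n_mismatches + bulges, bulges, ot$rb_pos, ot$db_gap,
               ot$pam_class != "primary")
  ot <- ot[ord, , drop = FALSE]
  ot[!duplicated(paste(ot$seqnames, ot$strand, ot$pam_start, sep = "\r")), ,
     drop = FALSE]
}

#' Enumerate all off-target sites of a guide
#'
#' Exhaustively enumerates every genomic site, on both strands, where a
#' window adjacent to a PAM-matching window aligns to the spacer within the
#' mismatch and bulge budgets. Degenerate PAM positions and alternative
#' PAMs carry no mismatch penalty (PAM-wildcard semantics); with
#' `legacy_pam = TRUE` an alternative-PAM site instead consumes one unit of
#' the mismatch budget, reproducing the more restrictive historical
#' behaviour, whose results are always a subset of the default.
#'
#' A genomic locus reachable by several alignments (common with bulges) is
#' reported once with the alignment minimising mismatches + bulges, ties
#' broken by fewer bulges, then leftmost gap placement. Sites whose window
#' or PAM contains N are never reported. If the query declares an
#' on-target, that single site is excluded.
#'
#' @param index an `fm_index`.
#' @param query a [guide_query] (or a plain spacer string, in which case
#'   `pam` supplies the PAM).
#' @param budget a [search_budget].
#' @param pam a [pam_spec], used when `query` is a plain string.
#' @param legacy_pam count an alternative PAM as one mismatch.
#' @return Data frame of off-target sites sorted by (sequence, position,
#'   strand): `seqnames`, `start`, `end` (0-based half-open protospacer on
#'   the + strand), `strand`, `protospacer` and `pam` (spacer orientation),
#'   `pam_class`, `n_mismatches`, `mismatch_string` (1-based spacer
#'   positions from the 5' end, e.g. `"3:A>G;17:C>T"`), `rna_bulges`,
#'   `dna_bulges`, `distance`.
#' @export
enumerate_offtargets <- function(index, query, budget = search_budget(),
                                 pam = pam_spec(), legacy_pam = FALSE) {
  stopifnot(inherits(index, "fm_index"))
  if (is.character(query)) query <- guide_query(query, pam)
  stopifnot(inherits(query, "guide_query"), inherits(budget, "search_budget"))
  ps <- query$pam
  motifs <- c(ps$primary, ps$alternatives)
  classes <- c("primary", rep("alternative", length(ps$alternatives)))
  # when the motifs factor exactly into one positionwise-union IUPAC motif
  # (e.g. NGG + NAG = NRG) a single traversal per strand suffices and the
  # PAM class is recovered from the matched trinucleotide afterwards
  if (length(motifs) > 1) {
    sets <- lapply(seq_len(nchar(motifs[1])), function(p)
      sort(unique(unlist(lapply(motifs, function(m)
        .IUPAC[[substr(m, p, p)]])))))
    concrete <- unique(unlist(lapply(motifs, expand_pam)))
    if (prod(lengths(sets)) == length(concrete)) {
      codes <- .IUPAC_REV[vapply(sets, paste, character(1), collapse = ",")]
      if (!anyNA(codes)) {
        motifs <- paste(codes, collapse = "")
        classes <- "auto"
      }
    }
  }
  pieces <- list()
  for (strand in c("+", "-"))
    for (i in seq_along(motifs))
      pieces[[length(pieces) + 1L]] <-
        .search_one(index, query$spacer, motifs[i], strand, budget,
                    classes[i], ps$side)
  ot <- do.call(rbind, pieces)
  if (nrow(ot) > 0 && identical(classes, "auto"))
    ot$pam_class <- ifelse(vapply(ot$pam, .matches_iupac, logical(1),
                                  motif = ps$primary),
                           "primary", "alternative")
  ot <- .dedup_offtargets(ot)
  if (legacy_pam && nrow(ot) > 0) {
    eff <- ot$n_mismatches + (ot$pam_class == "alternative")
    ot <- ot[eff <= budget$max_mismatches, , drop = FALSE]
  }
  if (!is.null(query$on_target) && nrow(ot) > 0) {
    tgt <- query$on_target
    ot <- ot[!(ot$seqnames == tgt$seqnames & ot$start == tgt$pos &
                 ot$strand == tgt$strand), , drop = FALSE]
  }
  ot <- ot[order(ot$seqnames, ot$start, ot$strand), , drop = FALSE]
  rownames(ot) <- NULL
  ot
}

#' Find perfect-match sites of a spacer
#'
#' Enumeration with zero mismatches and no bulges; used for uniqueness
#' filtering and allele cross-exclusion.
#'
#' @param index an `fm_index`.
#' @param spacer nucleotide string.
#' @param pam a [pam_spec].
#' @param primary_only restrict to the primary PAM motif.
#' @return Off-target data frame as in [enumerate_offtargets()].
#' @export
find_perfect_sites <- function(index, spacer, pam = pam_spec(),
                               primary_only = FALSE) {
  p <- if (primary_only) pam_spec(pam$primary, character(0), pam$side) else pam
  enumerate_offtargets(index, guide_query(spacer, p),
                       search_budget(0L, 0L, 0L))
}

#' Count PAM-free Hamming-neighbourhood occurrences
#'
#' Number of genomic windows, on either strand, within Hamming distance
#' `max_mm` of `seq`, with no PAM requirement. Used to validate
#' non-targeting control guides.
#'
#' @param index an `fm_index`.
#' @param seq nucleotide string over A, C, G, T.
#' @param max_mm maximum Hamming distance.
#' @return Non-negative count.
#' @export
hamming_occurrences <- function(index, seq, max_mm) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}")
  sp_codes <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T")) - 1L
  n <- 0L
  for (minus in c(FALSE, TRUE)) {
    res <- fm_search_cpp(index$ptr, sp_codes, integer(0), minus,
                         as.integer(max_mm), 0L, 0L)
    n <- n + length(res$tpos)
  }
  n
}

#' Cut-site coordinate of a guide or off-target
#'
#' The SpCas9 blunt cut 3 nt upstream of the PAM: between spacer positions
#' 17 and 18 of a 20-mer, reported as the 0-based reference coordinate of
#' the base at spacer position 17 counted from the 5' end, strand-aware.
#' Defined only for 3'-side PAMs.
#'
#' @param site data frame with columns `seqnames`, `start`, `end`,
#'   `strand` (one or more rows).
#' @param pam_side PAM side; only `"3prime"` is defined.
#' @return Data frame with `seqnames` and `cut` (0-based coordinate).
#' @export
cut_site <- function(site, pam_side = "3prime") {
  if (pam_side != "3prime")
    stop("cut-site rule undefined for this enzyme (5'-side PAM)")
  cut <- ifelse(site$strand == "+", site$end - 4L, site$start + 3L)
  data.frame(seqnames = site$seqnames, cut = as.integer(cut),
             stringsAsFactors = FALSE)
}

#' Write an off-target report as TSV
#'
#' @param ot off-target data frame.
#' @param path output path.
#' @param query_id identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_offtargets_tsv <- function(ot, path, query_id = "query") {
  cols <- c("seqnames", "start", "end", "strand", "protospacer", "pam",
            "pam_class", "n_mismatches", "mismatch_string", "rna_bulges",
            "dna_bulges")
  out <- cbind(query_id = query_id, ot[, cols, drop = FALSE],
               cfd = if ("cfd" %in% names(ot)) ot$cfd else NA_real_)
  names(out)[names(out) == "seqnames"] <- "chrom"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
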