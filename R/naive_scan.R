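#' Brute-force off-target scan
#'
#' Enumerates off-target sites by direct examination of every PAM-adjacent
#' window on both strands, with no index. For each candidate alignment shape
#' (optionally one unpaired spacer base and/or one unpaired genomic base)
#' the Hamming mismatches against the spacer are counted position by
#' position. This scanner is the independent verification oracle used to
#' validate the index-based traversal and the truth tables of planted
#' fixtures; it is quadratic and intended for small genomes only.
#'
#' Alignment geometry, duplicate suppression and PAM semantics match
#' [enumerate_offtargets()] exactly: bulges are disallowed at the
#' PAM-adjacent and 5'-terminal spacer positions, a locus is reported once
#' with the alignment minimising mismatches + bulges, and windows containing
#' N never match.
#'
#' @param g a [genome].
#' @param spacer nucleotide string over A, C, G, T.
#' @param pam a [pam_spec] (3'-side), or `NULL` for a PAM-free Hamming scan.
#' @param budget a [search_budget]; at most one bulge of each kind.
#' @param legacy_pam count an alternative PAM as one mismatch.
#' @param on_target optional locus (`seqnames`, `pos`, `strand`) to exclude.
#' @return Off-target data frame with columns `seqnames`, `start`, `end`,
#'   `strand`, `pam_class`, `n_mismatches`, `rna_bulges`, `dna_bulges`,
#'   `distance`, `pam_start`, sorted by (sequence, position, strand).
#' @export
scan_offtargets_naive <- function(g, spacer, pam = pam_spec(),
                                  budget = search_budget(),
                                  legacy_pam = FALSE, on_target = NULL) {
  stopifnot(inherits(g, "genome"))
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over {A,C,G,T}")
  if (budget$max_rna_bulges > 1 || budget$max_dna_bulges > 1)
    stop("the brute-force scanner supports at most one bulge of each kind")
  L <- nchar(spacer)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pamlen <- if (is.null(pam)) 0L else nchar(pam$primary)
  motifs <- if (is.null(pam)) character(0) else c(pam$primary, pam$alternatives)

  r_opts <- c(0L, if (budget$max_rna_bulges >= 1 && L >= 3) 2:(L - 1))
  d_opts <- c(0L, if (budget$max_dna_bulges >= 1 && L >= 2) 1:(L - 1))

  rows <- list()
  for (seqname in names(g$sequences)) {
    len <- g$lengths[[seqname]]
    for (strand in c("+", "-")) {
      work <- if (strand == "+") g$sequences[[seqname]] else
        reverse_complement(g$sequences[[seqname]])
      wc <- strsplit(work, "", fixed = TRUE)[[1]]
      cumN <- c(0L, cumsum(wc == "N"))  # cumN[i+1] = # of N in [0, i)
      # anchors: all PAM positions q (0-based working coords)
      if (pamlen > 0) {
        qmax <- len - pamlen
        if (qmax < 1) next
        q_all <- 0:(qmax)
        match_motif <- function(motif) {
          mc <- strsplit(motif, "", fixed = TRUE)[[1]]
          ok <- rep(TRUE, length(q_all))
          for (p in seq_len(pamlen))
            ok <- ok & wc[q_all + p] %in% .IUPAC[[mc[p]]]
          ok
        }
        prim <- match_motif(motifs[1])
        alt <- rep(FALSE, length(q_all))
        for (m in motifs[-1]) alt <- alt | match_motif(m)
        anchors <- q_all[prim | alt]
        classes <- ifelse(prim[prim | alt], "primary", "alternative")
      } else {
        # PAM-free: the "anchor" is simply the window end, any position
        anchors <- seq_len(len)
        classes <- rep("primary", length(anchors))
      }
      if (length(anchors) == 0) next
      for (r in r_opts) for (d in d_opts) {
        W <- L - (r > 0L) + (d > 0L)
        t0 <- anchors - W
        keep <- t0 >= 0L
        if (!any(keep)) next
        tt <- t0[keep]
        qq <- anchors[keep]
        cls <- classes[keep]
        mm <- integer(length(tt))
        for (j in seq_len(L)) {
          if (j == r) next
          oj <- (j - 1L) - (r > 0L && r < j) + (d > 0L && j > d)
          mm <- mm + (wc[tt + oj + 1L] != sp[j])
        }
        hasN <- (cumN[qq + pamlen + 1L] - cumN[tt + 1L]) > 0L
        ok <- !hasN & mm <= budget$max_mismatches
        if (!any(ok)) next
        tt <- tt[ok]; qq <- qq[ok]; mm <- mm[ok]; cls <- cls[ok]
        if (strand == "+") {
          start <- tt; end <- qq; pstart <- qq
        } else {
          start <- len - qq; end <- len - tt; pstart <- len - qq - pamlen
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = seqname, start = start, end = end, strand = strand,
          pam_class = cls, n_mismatches = mm,
          rna_bulges = as.integer(r > 0L), dna_bulges = as.integer(d > 0L),
          distance = mm, pam_start = as.integer(pstart),
          rb_pos = r, db_gap = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- .empty_offtargets()
    return(out[, setdiff(names(out), c("protospacer", "pam",
                                       "mismatch_string")), drop = FALSE])
  }
  ot <- do.call(rbind, rows)
  ot <- .dedup_offtargets(ot)
  if (legacy_pam && nrow(ot) > 0) {
    eff <- ot$n_mismatches + (ot$pam_class == "alternative")
    ot <- ot[eff <= budget$max_mismatches, , drop = FALSE]
  }
  if (!is.null(on_target) && nrow(ot) > 0)
    ot <- ot[!(ot$seqnames == on_target$seqnames & ot$start == on_target$pos &
                 ot$strand == on_target$strand), , drop = FALSE]
  ot <- ot[order(ot$seqnames, ot$start, ot$strand), , drop = FALSE]
  rownames(ot) <- NULL
  ot
}
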