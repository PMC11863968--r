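#' Read variants from a VCF file
#'
#' Consumes only CHROM, POS, REF, ALT and (when present) the first
#' sample's GT field. Multi-allelic records are an error; split them
#' upstream. Positions are converted to 0-based.
#'
#' @param path path to a VCF (plain text).
#' @return Variant data frame with columns `seqnames`, `pos` (0-based),
#'   `ref`, `alt`, `kind` (`SNP`, `insertion`, `deletion`), `zygosity`
#'   (`hom`, `het` or NA).
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported; split them first")
  zyg <- rep(NA_character_, nrow(fix))
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) >= 1) {
    g <- gt[, 1]
    a <- sub("[/|].*", "", g)
    b <- sub(".*[/|]", "", g)
    zyg <- ifelse(is.na(g), NA_character_, ifelse(a == b, "hom", "het"))
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(alt)
  kind <- ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1, "SNP",
                 ifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
  out <- data.frame(seqnames = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]) - 1L,
                    ref = ref, alt = alt, kind = kind, zygosity = zyg,
                    stringsAsFactors = FALSE)
  out[order(out$seqnames, out$pos), , drop = FALSE]
}

#' Write variants as VCF
#'
#' Minimal VCFv4.2 emission, inverse of [read_vcf_variants()].
#'
#' @param variants variant data frame.
#' @param path output path.
#' @param sample_gt genotype string written for the single sample column
#'   when `zygosity` is present (`het` becomes `0/1`, `hom` `1/1`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_gt = TRUE) {
  has_z <- sample_gt && "zygosity" %in% names(variants) &&
    any(!is.na(variants$zygosity))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=crisprtrie",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (has_z) "\tFORMAT\tsample1" else ""))
  gt <- if (has_z)
    paste0("\tGT\t", ifelse(is.na(variants$zygosity), "./.",
                            ifelse(variants$zygosity == "het", "0/1", "1/1")))
  else ""
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.%s", variants$seqnames,
                  variants$pos + 1L, variants$ref, variants$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply variants to a genome (pseudo-genome construction)
#'
#' Left-to-right application of SNPs, insertions and deletions to each
#' sequence, producing the pseudo-genome of the second allele plus a
#' piecewise-linear coordinate map from reference to pseudo-genome
#' coordinates. Each variant's REF allele is verified against the
#' reference; overlapping variants are an error.
#'
#' @param g the reference [genome].
#' @param variants variant data frame (as from [read_vcf_variants()]).
#' @return List with `genome` (the pseudo-genome) and `map` (class
#'   `coord_map`), usable with [map_coordinate()].
#' @export
apply_variants <- function(g, variants) {
  stopifnot(inherits(g, "genome"))
  variants <- variants[order(variants$seqnames, variants$pos), , drop = FALSE]
  new_seqs <- g$sequences
  segments <- list()
  for (seqname in names(g$sequences)) {
    seq <- g$sequences[[seqname]]
    vs <- variants[variants$seqnames == seqname, , drop = FALSE]
    if (nrow(vs) == 0) {
      segments[[seqname]] <- data.frame(ref_start = 0L, ref_end = nchar(seq),
                                        offset = 0L, deleted = FALSE)
      next
    }
    # REF spans in reference coordinates; insertions anchor on one base
    span <- nchar(vs$ref)
    if (any(vs$pos + span > nchar(seq)))
      stop("variant beyond end of sequence ", seqname)
    if (nrow(vs) > 1 && any(vs$pos[-1] < (vs$pos + span)[-nrow(vs)]))
      stop("overlapping variants on ", seqname)
    obs <- substring(seq, vs$pos + 1L, vs$pos + span)
    bad <- obs != vs$ref
    if (any(bad))
      stop(sprintf("REF mismatch at %s:%d (expected %s, found %s)",
                   seqname, vs$pos[bad][1] + 1L, vs$ref[bad][1], obs[bad][1]))
    pieces <- character(0)
    segs <- list()
    cursor <- 0L     # reference coordinate
    out_len <- 0L    # pseudo-genome length so far
    for (i in seq_len(nrow(vs))) {
      keep <- substring(seq, cursor + 1L, vs$pos[i])
      if (nchar(keep) > 0) {
        segs[[length(segs) + 1L]] <- data.frame(
          ref_start = cursor, ref_end = vs$pos[i],
          offset = out_len - cursor, deleted = FALSE)
      }
      pieces <- c(pieces, keep, vs$alt[i])
      out_len <- out_len + nchar(keep)
      # the variant's own span: anchor base maps through for indels
      if (vs$kind[i] == "SNP") {
        segs[[length(segs) + 1L]] <- data.frame(
          ref_start = vs$pos[i], ref_end = vs$pos[i] + 1L,
          offset = out_len - vs$pos[i], deleted = FALSE)
      } else {
        segs[[length(segs) + 1L]] <- data.frame(
          ref_start = vs$pos[i], ref_end = vs$pos[i] + 1L,
          offset = out_len - vs$pos[i], deleted = FALSE)
        if (span[i] > 1)  # deleted reference bases are unmappable
          segs[[length(segs) + 1L]] <- data.frame(
            ref_start = vs$pos[i] + 1L, ref_end = vs$pos[i] + span[i],
            offset = NA_integer_, deleted = TRUE)
      }
      out_len <- out_len + nchar(vs$alt[i])
      cursor <- vs$pos[i] + span[i]
    }
    tailseq <- substring(seq, cursor + 1L, nchar(seq))
    if (nchar(tailseq) > 0)
      segs[[length(segs) + 1L]] <- data.frame(
        ref_start = cursor, ref_end = nchar(seq),
        offset = out_len - cursor, deleted = FALSE)
    pieces <- c(pieces, tailseq)
    new_seqs[[seqname]] <- paste(pieces, collapse = "")
    segments[[seqname]] <- do.call(rbind, segs)
  }
  map <- structure(segments, class = "coord_map")
  list(genome = genome(new_seqs), map = map)
}

#' Map a reference coordinate to pseudo-genome coordinates
#'
#' @param map a `coord_map` from [apply_variants()].
#' @param seqnames,pos sequence name(s) and 0-based reference position(s).
#' @return Integer vector of pseudo-genome positions; NA where the
#'   reference base was deleted (unmappable).
#' @export
map_coordinate <- function(map, seqnames, pos) {
  stopifnot(inherits(map, "coord_map"))
  seqnames <- rep_len(seqnames, length(pos))
  vapply(seq_along(pos), function(i) {
    segs <- map[[seqnames[i]]]
    if (is.null(segs)) return(NA_integer_)
    hit <- which(segs$ref_start <= pos[i] & pos[i] < segs$ref_end)
    if (length(hit) == 0) return(NA_integer_)
    if (segs$deleted[hit[1]]) return(NA_integer_)
    as.integer(pos[i] + segs$offset[hit[1]])
  }, integer(1))
}

#' Design allele-specific guides for a hybrid diploid genome
#'
#' A guide from genome A's database is A-specific when its spacer has zero
#' perfect-match occurrences in genome B (under the primary and — by
#' default, conservatively — the alternative PAMs, since an NAG-adjacent
#' perfect protospacer in the other allele can still cut), and
#' symmetrically for B. Survivors are annotated with their off-target
#' summaries in both genomes, controlling for all potential off-targets in
#' the hybrid diploid.
#'
#' @param db_a,db_b guide-record data frames from [build_database()] for
#'   genomes A and B.
#' @param index_a,index_b the corresponding `fm_index` objects.
#' @param pam a [pam_spec].
#' @param budget a [search_budget] for cross-genome off-target annotation.
#' @param check_alt_pam also require absence of alternative-PAM perfect
#'   matches in the other genome (default TRUE).
#' @param labels names of the two alleles/genomes.
#' @return List with `a_specific` and `b_specific` record data frames,
#'   each with `target_allele` and per-genome off-target count columns
#'   (`own_d*`, `other_d*`).
#' @export
design_allele_specific <- function(db_a, index_b, db_b, index_a,
                                   pam = pam_spec(),
                                   budget = search_budget(3L),
                                   check_alt_pam = TRUE,
                                   labels = c("A", "B")) {
  one_side <- function(db, own_index, other_index, label) {
    keep <- logical(nrow(db))
    other_counts <- matrix(0L, nrow(db), budget$max_mismatches + 1L)
    for (i in seq_len(nrow(db))) {
      perf <- find_perfect_sites(other_index, db$spacer[i], pam,
                                 primary_only = !check_alt_pam)
      if (nrow(perf) > 0) next
      keep[i] <- TRUE
      ot <- enumerate_offtargets(other_index, guide_query(db$spacer[i], pam),
                                 budget)
      other_counts[i, ] <- vapply(0:budget$max_mismatches, function(d)
        sum(ot$distance == d & ot$rna_bulges == 0 & ot$dna_bulges == 0),
        integer(1))
    }
    out <- db[keep, , drop = FALSE]
    out$target_allele <- label
    ocols <- grep("^ot_d", names(db), value = TRUE)
    for (d in seq_along(ocols))
      out[[sub("^ot_", "own_", ocols[d])]] <- out[[ocols[d]]]
    for (d in 0:budget$max_mismatches)
      out[[paste0("other_d", d)]] <- other_counts[keep, d + 1L]
    rownames(out) <- NULL
    out
  }
  list(a_specific = one_side(db_a, index_a, index_b, labels[1]),
       b_specific = one_side(db_b, index_b, index_a, labels[2]))
}

#' Classify how a guide discriminates between alleles
#'
#' `pam_variant` when any variant overlaps the PAM window, else
#' `protospacer_variant` when any overlaps the protospacer, else
#' `structural` (e.g. a guide lying inside allele-private inserted
#' sequence, with no overlapping small-variant record).
#'
#' @param record one guide record row (`seqnames`, `start`, `end`,
#'   `strand`, `pam`), located on its target genome.
#' @param variants variant data frame in reference coordinates.
#' @param map optional `coord_map`; supply it when the record lives on the
#'   pseudo-genome so variant positions are mapped before overlap testing.
#' @return One of `"pam_variant"`, `"protospacer_variant"`, `"structural"`.
#' @export
classify_discrimination <- function(record, variants, map = NULL) {
  pamlen <- nchar(record$pam)
  if (record$strand == "+") {
    pam_lo <- record$end; pam_hi <- record$end + pamlen
  } else {
    pam_lo <- record$start - pamlen; pam_hi <- record$start
  }
  vs <- variants[variants$seqnames == record$seqnames, , drop = FALSE]
  if (nrow(vs) == 0) return("structural")
  span <- pmax(nchar(vs$ref), 1L)
  lo <- vs$pos
  hi <- vs$pos + span
  if (!is.null(map)) {
    mlo <- map_coordinate(map, vs$seqnames, lo)
    # map the span endpoints; deleted/unmappable ends fall back to the start
    mhi <- map_coordinate(map, vs$seqnames, hi - 1L)
    hi <- ifelse(is.na(mhi), ifelse(is.na(mlo), NA, mlo + 1L), mhi + 1L)
    lo <- mlo
    ok <- !is.na(lo) & !is.na(hi)
    lo <- lo[ok]; hi <- hi[ok]
    # an insertion widens the footprint on the pseudo-genome
    ins <- vs$kind[ok] == "insertion"
    hi[ins] <- hi[ins] + nchar(vs$alt[ok][ins]) - nchar(vs$ref[ok][ins])
  }
  overlaps <- function(a_lo, a_hi) any(lo < a_hi & hi > a_lo)
  if (overlaps(pam_lo, pam_hi)) return("pam_variant")
  if (overlaps(record$start, record$end)) return("protospacer_variant")
  "structural"
}

#' High-confidence filter for allele-specific guides
#'
#' Stages, in the order applied: drop guides annotated with heterozygous
#' variants (when zygosity is available and `exclude_het`); require zero
#' 2-mismatch off-targets in either genome; at most `max_3mm` 3-mismatch
#' off-targets in either genome; cutting efficiency in the top quantile of
#' the surviving set; cut site at least `repeat_distance` bp from any
#' annotated repeat interval.
#'
#' @param records allele-specific records carrying `own_d*`/`other_d*`
#'   counts, `efficiency`, and optionally `het_variant` (logical).
#' @param repeats repeat intervals (e.g. from [read_bed()]); may be empty.
#' @param exclude_het drop records flagged `het_variant`.
#' @param max_2mm maximum 2-mismatch off-targets per genome (default 0).
#' @param max_3mm maximum 3-mismatch off-targets per genome (default 3).
#' @param efficiency_quantile keep efficiency at or above this quantile of
#'   the current survivors (default 0.75, i.e. the top 25 percent).
#' @param repeat_distance minimum cut-site distance to a repeat (bp).
#' @return List with `records` (survivors) and `report` (`filter_report`).
#' @export
high_confidence_filter <- function(records, repeats = NULL,
                                   exclude_het = TRUE, max_2mm = 0L,
                                   max_3mm = 3L, efficiency_quantile = 0.75,
                                   repeat_distance = 200L) {
  stages <- character(0); counts <- integer(0)
  note <- function(name, recs) {
    stages <<- c(stages, name); counts <<- c(counts, nrow(recs)); recs
  }
  r <- note("input", records)
  if (exclude_het && "het_variant" %in% names(r))
    r <- note("exclude_het", r[!(r$het_variant %in% TRUE), , drop = FALSE])
  else r <- note("exclude_het", r)
  d2 <- pmax(r$own_d2, r$other_d2)
  r <- note("no_2mm_offtargets", r[d2 <= max_2mm, , drop = FALSE])
  if (all(c("own_d3", "other_d3") %in% names(r))) {
    d3 <- pmax(r$own_d3, r$other_d3)
    r <- note("max_3mm_offtargets", r[d3 <= max_3mm, , drop = FALSE])
  } else r <- note("max_3mm_offtargets", r)
  if (!is.null(efficiency_quantile)) {
    if (nrow(r) > 0 && anyNA(r$efficiency))
      stop("missing efficiency for guide ", r$guide_id[is.na(r$efficiency)][1])
    thr <- if (nrow(r) > 0) quantile(r$efficiency, efficiency_quantile,
                                     names = FALSE) else 0
    r <- note("top_efficiency", r[r$efficiency >= thr, , drop = FALSE])
  } else r <- note("top_efficiency", r)
  if (!is.null(repeats) && nrow(repeats) > 0 && nrow(r) > 0) {
    cuts <- cut_site(r)
    rep_gr <- GenomicRanges::GRanges(repeats$seqnames,
                                     IRanges::IRanges(repeats$start + 1L,
                                                      repeats$end))
    cut_gr <- GenomicRanges::GRanges(cuts$seqnames,
                                     IRanges::IRanges(cuts$cut + 1L,
                                                      cuts$cut + 1L))
    dd <- GenomicRanges::distanceToNearest(cut_gr, rep_gr)
    dist <- rep(Inf, nrow(r))
    dist[S4Vectors::queryHits(dd)] <- S4Vectors::mcols(dd)$distance
    r <- note("repeat_distance", r[dist >= repeat_distance, , drop = FALSE])
  } else r <- note("repeat_distance", r)
  report <- data.frame(stage = stages, survivors = counts,
                       stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  list(records = r, report = report)
}

#' Annotate guides with genes by exon overlap of the cut site
#'
#' A guide is annotated with a gene when its cut site (3 nt upstream of
#' the PAM) lies within an exon of that gene; when several genes qualify
#' the lexicographically smallest gene id is chosen (a deterministic
#' stand-in for an arbitrary choice).
#'
#' @param records guide records.
#' @param annotation annotation data frame from [read_annotation()].
#' @return `records` with a `gene_id` column (NA when intronic or
#'   intergenic).
#' @export
annotate_genes <- function(records, annotation) {
  genes <- .genes_at_cut(records, annotation, feature = "exon")
  records$gene_id <- vapply(genes, function(g)
    if (length(g)) g[1] else NA_character_, character(1))
  records
}
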