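#' Generate a random genome
#'
#' I.i.d. bases with the requested G+C fraction, deterministic under the
#' seed. Used as the substrate for planted-site fixtures.
#'
#' @param length total length in bases (split across `n_sequences`).
#' @param gc target G+C fraction.
#' @param seed RNG seed.
#' @param n_sequences number of sequences (`chr1`, `chr2`, ...).
#' @return A [genome].
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, n_sequences = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1, n_sequences >= 1)
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    per <- diff(round(seq(0, length, length.out = n_sequences + 1)))
    seqs <- vapply(per, function(n)
      paste(sample(names(probs), n, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    genome(setNames(seqs, paste0("chr", seq_len(n_sequences))))
  })
}

# mutate a spacer to exactly n_mm mismatches at seeded positions (avoiding
# bulge positions), returning the genomic window sequence
.mutate_window <- function(spacer, n_mm, rb_pos = 0L, db_gap = 0L,
                           mm_positions = NULL) {
  L <- nchar(spacer)
  chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
  avail <- setdiff(seq_len(L), rb_pos)
  if (is.null(mm_positions)) {
    if (n_mm > 0) mm_positions <- sort(sample(avail, n_mm))
  } else stopifnot(all(mm_positions %in% avail), length(mm_positions) == n_mm)
  for (j in mm_positions)
    chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
  if (rb_pos > 0) chars <- chars[-rb_pos]
  if (db_gap > 0) {
    ins <- sample(c("A", "C", "G", "T"), 1)
    chars <- append(chars, ins, after = db_gap - (rb_pos > 0 && rb_pos <= db_gap))
  }
  paste(chars, collapse = "")
}

#' Plant off-target sites into a genome
#'
#' Writes mutated copies of `spacer` plus a concrete PAM at the requested
#' placements (strand-aware), then re-scans the mutated genome with the
#' brute-force scanner so the returned truth table is exactly the set of
#' sites discoverable within the budget — including any accidental
#' background matches the random genome already contained or that the
#' edits created.
#'
#' @param g a [genome].
#' @param spacer the query spacer.
#' @param pam a [pam_spec]; each placement may name a concrete PAM,
#'   otherwise one is drawn from the primary expansion.
#' @param placements data frame with columns `seqnames`, `pos` (0-based
#'   start of the full site footprint on the + strand), `strand`, and
#'   optionally `n_mm`, `rb_pos`, `db_gap`, `pam`.
#' @param budget the [search_budget] the truth table must be complete for.
#' @param seed RNG seed for mutation choices.
#' @return List with `genome` (mutated), `truth` (the verified off-target
#'   data frame from [scan_offtargets_naive()]) and `planted` (the
#'   placements with their realised site sequences).
#' @export
plant_sites <- function(g, spacer, pam = pam_spec(), placements,
                        budget = search_budget(3L), seed = 1L) {
  stopifnot(inherits(g, "genome"))
  withr::with_seed(seed, {
    for (col in c("n_mm", "rb_pos", "db_gap"))
      if (is.null(placements[[col]])) placements[[col]] <- 0L
    if (is.null(placements$pam)) placements$pam <- NA_character_
    seqs <- g$sequences
    sites <- character(nrow(placements))
    occupied <- list()
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      window <- .mutate_window(spacer, p$n_mm, p$rb_pos, p$db_gap)
      pam3 <- if (is.na(p$pam)) sample(expand_pam(pam$primary), 1) else p$pam
      site <- paste0(window, pam3)
      if (p$strand == "-") site <- reverse_complement(site)
      lo <- p$pos; hi <- p$pos + nchar(site)
      if (hi > nchar(seqs[[p$seqnames]]))
        stop("placement ", i, " extends beyond sequence ", p$seqnames)
      for (occ in occupied)
        if (occ$seqnames == p$seqnames && lo < occ$hi && hi > occ$lo)
          stop("overlapping placements at ", p$seqnames, ":", lo)
      occupied[[length(occupied) + 1L]] <- list(seqnames = p$seqnames,
                                                lo = lo, hi = hi)
      s <- seqs[[p$seqnames]]
      substr(s, lo + 1L, hi) <- site
      seqs[[p$seqnames]] <- s
      sites[i] <- site
    }
    g2 <- genome(seqs)
    truth <- scan_offtargets_naive(g2, spacer, pam, budget)
    placements$site <- sites
    list(genome = g2, truth = truth, planted = placements)
  })
}

#' Generate a toy gene annotation
#'
#' Non-overlapping genes laid out left to right, each with the requested
#' number of exons; every exon doubles as a CDS interval. Deterministic
#' under the seed and writable as GTF via [write_gtf()].
#'
#' @param g a [genome].
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene.
#' @param seed RNG seed.
#' @return Annotation data frame as from [read_annotation()].
#' @export
toy_annotation <- function(g, n_genes = 5L, exons_per_gene = 2L, seed = 1L) {
  stopifnot(inherits(g, "genome"))
  withr::with_seed(seed, {
    seqname <- names(g$sequences)[1]
    len <- g$lengths[[1]]
    exon_len <- 120L
    gap <- 80L
    gene_len <- exons_per_gene * exon_len + (exons_per_gene - 1L) * gap
    spacing <- (len - n_genes * gene_len) %/% (n_genes + 1L)
    if (spacing < 1) stop("genome too short for ", n_genes, " genes")
    rows <- list()
    pos <- spacing
    for (k in seq_len(n_genes)) {
      gid <- sprintf("gene%02d", k)
      strand <- sample(c("+", "-"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = seqname, start = pos, end = pos + gene_len,
        strand = strand, type = "gene", gene_id = gid,
        stringsAsFactors = FALSE)
      for (e in seq_len(exons_per_gene)) {
        es <- pos + (e - 1L) * (exon_len + gap)
        for (tp in c("exon", "CDS"))
          rows[[length(rows) + 1L]] <- data.frame(
            seqnames = seqname, start = es, end = es + exon_len,
            strand = strand, type = tp, gene_id = gid,
            stringsAsFactors = FALSE)
      }
      pos <- pos + gene_len + spacing
    }
    ann <- do.call(rbind, rows)
    class(ann) <- c("annotation", "data.frame")
    ann
  })
}

#' Simulate a diploid genome (variants + pseudo-genome)
#'
#' Draws SNPs and small indels at the given per-base rates (rejection
#' resampled so variants never overlap), applies them with
#' [apply_variants()], and returns both the variant table (VCF-writable)
#' and the resulting pseudo-genome with its coordinate map.
#'
#' @param g the reference [genome].
#' @param snp_rate per-base SNP probability.
#' @param indel_rate per-base indel probability (split evenly between
#'   insertions and deletions of 1-3 bp).
#' @param het_fraction fraction of variants labelled heterozygous.
#' @param seed RNG seed.
#' @return List with `variants`, `genome` (pseudo-genome) and `map`.
#' @export
simulate_diploid <- function(g, snp_rate = 0.002, indel_rate = 0.0002,
                             het_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(g, "genome"), snp_rate >= 0, snp_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (seqname in names(g$sequences)) {
      seq <- g$sequences[[seqname]]
      len <- nchar(seq)
      n_snp <- rbinom(1, len, snp_rate)
      n_ind <- rbinom(1, len, indel_rate)
      if (n_snp + n_ind == 0) next
      # sample positions with room for the largest REF span, then drop
      # any that would overlap (rejection)
      pos <- sort(sample(0:(len - 5L), n_snp + n_ind))
      kinds <- sample(c(rep("SNP", n_snp),
                        sample(c("insertion", "deletion"), n_ind,
                               replace = TRUE)))
      keep <- rep(TRUE, length(pos))
      if (length(pos) > 1) keep[c(FALSE, diff(pos) < 5L)] <- FALSE
      pos <- pos[keep]; kinds <- kinds[keep]
      for (i in seq_along(pos)) {
        refb <- substr(seq, pos[i] + 1L, pos[i] + 1L)
        if (refb == "N") next
        if (kinds[i] == "SNP") {
          ref <- refb
          alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        } else if (kinds[i] == "insertion") {
          ref <- refb
          alt <- paste0(refb, paste(sample(c("A", "C", "G", "T"),
                                           sample(1:3, 1), replace = TRUE),
                                    collapse = ""))
        } else {
          span <- sample(1:3, 1)
          ref <- substr(seq, pos[i] + 1L, pos[i] + 1L + span)
          if (grepl("N", ref)) next
          alt <- refb
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = seqname, pos = pos[i], ref = ref, alt = alt,
          kind = kinds[i], stringsAsFactors = FALSE)
      }
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(seqnames = character(), pos = integer(), ref = character(),
                 alt = character(), kind = character(),
                 stringsAsFactors = FALSE)
    variants$zygosity <- if (nrow(variants))
      sample(c("het", "hom"), nrow(variants), replace = TRUE,
             prob = c(het_fraction, 1 - het_fraction))
    else character(0)
    applied <- apply_variants(g, variants)
    list(variants = variants, genome = applied$genome, map = applied$map)
  })
}
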