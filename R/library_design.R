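#' Library design configuration
#'
#' Thresholds of the gene-targeting library filter cascade and the control
#' set sizes. Defaults: drop guides with any additional 0- or 1-mismatch
#' genomic occurrence; require the cut site inside a CDS; cutting
#' efficiency >= 0.25; specificity >= 0.20; spacer G+C content within
#' \[0.20, 0.80\] (strictly more extreme content is removed, so boundary
#' guides survive); no monopolymer run longer than 3; six guides per gene
#' ranked by `min(Spec(g), Spec(g'), 1.25 * Eff(g))`; 5000 safe-targeting
#' and 5000 non-targeting controls, the latter with no genomic alignment
#' within Hamming distance 3.
#'
#' @param min_efficiency,min_specificity,gc_min,gc_max,max_monopolymer,guides_per_gene,score_weight,n_safe_controls,n_nontargeting_controls,control_hamming_radius
#'   see description.
#' @return An object of class `library_config`.
#' @export
library_config <- function(min_efficiency = 0.25, min_specificity = 0.20,
                           gc_min = 0.20, gc_max = 0.80,
                           max_monopolymer = 3L, guides_per_gene = 6L,
                           score_weight = 1.25, n_safe_controls = 5000L,
                           n_nontargeting_controls = 5000L,
                           control_hamming_radius = 3L) {
  stopifnot(min_efficiency >= 0, min_efficiency <= 1,
            min_specificity >= 0, min_specificity <= 1,
            gc_min >= 0, gc_max <= 1, gc_min < gc_max,
            guides_per_gene >= 1)
  structure(list(min_efficiency = min_efficiency,
                 min_specificity = min_specificity,
                 gc_min = gc_min, gc_max = gc_max,
                 max_monopolymer = as.integer(max_monopolymer),
                 guides_per_gene = as.integer(guides_per_gene),
                 score_weight = score_weight,
                 n_safe_controls = as.integer(n_safe_controls),
                 n_nontargeting_controls = as.integer(n_nontargeting_controls),
                 control_hamming_radius = as.integer(control_hamming_radius)),
            class = "library_config")
}

# G+C fraction of the spacer only (the synthesised sequence), PAM excluded
.gc_fraction <- function(spacer) {
  vapply(strsplit(toupper(spacer), "", fixed = TRUE),
         function(x) mean(x %in% c("G", "C")), numeric(1))
}

# length of the longest run of identical bases
.max_run <- function(spacer) {
  vapply(strsplit(toupper(spacer), "", fixed = TRUE),
         function(x) max(rle(x)$lengths), integer(1))
}

# gene ids (CDS) containing each record's cut site; list column
.genes_at_cut <- function(records, annotation, feature = "CDS") {
  cds <- annotation[annotation$type == feature, , drop = FALSE]
  cuts <- cut_site(records)
  if (nrow(cds) == 0) return(rep(list(character(0)), nrow(records)))
  cds_gr <- GenomicRanges::GRanges(cds$seqnames,
                                   IRanges::IRanges(cds$start + 1L, cds$end))
  cut_gr <- GenomicRanges::GRanges(cuts$seqnames,
                                   IRanges::IRanges(cuts$cut + 1L, cuts$cut + 1L))
  ov <- GenomicRanges::findOverlaps(cut_gr, cds_gr)
  out <- rep(list(character(0)), nrow(records))
  for (i in unique(S4Vectors::queryHits(ov))) {
    hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    out[[i]] <- sort(unique(cds$gene_id[hits]))
  }
  out
}

#' Apply the library filter cascade
#'
#' Stages, in order: (1) drop guides with any additional genomic occurrence
#' at 0 or 1 mismatches (primary or alternative PAM); (2) keep guides whose
#' cut site lies within a CDS; (3) cutting efficiency at or above the
#' threshold; (4) specificity at or above the threshold; (5) spacer G+C
#' content within bounds; (6) no monopolymer run longer than the cap.
#' Survivor counts per stage are reported.
#'
#' @param records guide records from [build_database()], carrying
#'   `specificity`, `efficiency` and off-target distance counts.
#' @param annotation annotation data frame from [read_annotation()].
#' @param config a [library_config].
#' @return List with `records` (survivors, plus a `genes` list column of
#'   CDS gene assignments) and `report` (data frame `stage`, `survivors`,
#'   class `filter_report`).
#' @export
apply_library_filters <- function(records, annotation,
                                  config = library_config()) {
  stages <- character(0)
  counts <- integer(0)
  note <- function(name, recs) {
    stages <<- c(stages, name)
    counts <<- c(counts, nrow(recs))
    recs
  }
  r <- note("input", records)
  if (nrow(r) > 0) {
    if (!all(c("ot_d0", "ot_d1") %in% names(r)))
      stop("records lack 0/1-mismatch off-target counts")
    r <- note("unique_0_1_mismatch", r[r$ot_d0 + r$ot_d1 == 0, , drop = FALSE])
  } else r <- note("unique_0_1_mismatch", r)
  genes <- .genes_at_cut(r, annotation)
  r$genes <- genes
  r <- note("cut_in_cds", r[lengths(genes) > 0, , drop = FALSE])
  if (nrow(r) > 0 && anyNA(r$efficiency))
    stop("missing efficiency for guide ", r$guide_id[is.na(r$efficiency)][1])
  r <- note("efficiency", r[nrow(r) > 0 & r$efficiency >= config$min_efficiency, ,
                            drop = FALSE])
  if (nrow(r) > 0 && anyNA(r$specificity))
    stop("missing specificity for guide ", r$guide_id[is.na(r$specificity)][1])
  r <- note("specificity", r[nrow(r) > 0 & r$specificity >= config$min_specificity, ,
                             drop = FALSE])
  gc <- .gc_fraction(r$spacer)
  r <- note("gc_content", r[gc >= config$gc_min & gc <= config$gc_max, ,
                            drop = FALSE])
  r <- note("monopolymer", r[.max_run(r$spacer) <= config$max_monopolymer, ,
                             drop = FALSE])
  report <- data.frame(stage = stages, survivors = counts,
                       stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  list(records = r, report = report)
}

#' Select guides per gene
#'
#' Genes with at most `guides_per_gene` filtered guides keep all of them;
#' genes with more are ranked by `library_score()`, where the specificity
#' of the 5'-G synthesis variant g' is computed by a fresh off-target
#' search of the substituted spacer (identical to the original search when
#' the spacer already starts with G). Ties are broken by higher
#' specificity, then lower genomic coordinate. A guide whose cut site lies
#' in the CDS of several genes is eligible for each of them.
#'
#' @param filtered result of [apply_library_filters()] (or its `records`).
#' @param index the `fm_index` of the genome (for the g' search).
#' @param cfd_table a `cfd_table` (for the g' specificity).
#' @param config a [library_config].
#' @param budget search budget for the g' specificity search.
#' @return List with `library` (data frame: one row per selected
#'   guide-gene pair with `score` and `rank`) and `no_coverage` (gene ids
#'   from the records' assignments with zero surviving guides — with
#'   cascade-filtered input this is empty by construction, but callers may
#'   pass a wider gene universe via `attr(filtered, "all_genes")`).
#' @export
select_guides_per_gene <- function(filtered, index, cfd_table,
                                   config = library_config(),
                                   budget = search_budget(3L)) {
  records <- if (is.list(filtered) && !is.data.frame(filtered))
    filtered$records else filtered
  if (is.null(records$genes)) stop("records carry no gene assignments; run apply_library_filters first")
  gp_cache <- new.env(parent = emptyenv())
  spec_gprime <- function(rec) {
    gp <- five_prime_g_variant(rec$spacer)
    key <- paste(gp, rec$guide_id)
    if (!is.null(gp_cache[[key]])) return(gp_cache[[key]])
    q <- guide_query(gp, pam_spec(), on_target = list(
      seqnames = rec$seqnames, pos = rec$start, strand = rec$strand))
    ot <- enumerate_offtargets(index, q, budget)
    s <- specificity(q, ot, cfd_table)$specificity
    gp_cache[[key]] <- s
    s
  }
  all_genes <- sort(unique(unlist(records$genes)))
  out <- list()
  for (gene in all_genes) {
    in_gene <- which(vapply(records$genes, function(g) gene %in% g, logical(1)))
    sub <- records[in_gene, , drop = FALSE]
    sub$spacer_5pG <- vapply(sub$spacer, five_prime_g_variant, character(1),
                             USE.NAMES = FALSE)
    if (nrow(sub) <= config$guides_per_gene) {
      sub$specificity_5pG <- NA_real_
      sub$score <- NA_real_
      sel <- sub
    } else {
      sub$specificity_5pG <- vapply(seq_len(nrow(sub)), function(i)
        spec_gprime(sub[i, ]), numeric(1))
      sub$score <- library_score(sub$specificity, sub$specificity_5pG,
                                 sub$efficiency, config$score_weight)
      ord <- order(-sub$score, -sub$specificity, sub$seqnames, sub$start)
      sel <- sub[ord[seq_len(config$guides_per_gene)], , drop = FALSE]
    }
    sel$gene_id <- gene
    sel$rank <- seq_len(nrow(sel))
    sel$genes <- NULL
    out[[gene]] <- sel
  }
  lib <- if (length(out)) do.call(rbind, out) else records[0, , drop = FALSE]
  rownames(lib) <- NULL
  universe <- attr(filtered, "all_genes")
  no_cov <- if (is.null(universe)) character(0) else setdiff(universe, all_genes)
  list(library = lib, no_coverage = no_cov)
}

#' Generate non-targeting control guides
#'
#' Uniformly random spacers with no genomic alignment within the Hamming
#' radius on either strand (PAM-free), reproducible under the seed.
#'
#' @param index an `fm_index`.
#' @param n number of controls.
#' @param radius Hamming exclusion radius.
#' @param length spacer length.
#' @param seed RNG seed.
#' @param max_attempts attempt cap before erroring.
#' @return Character vector of `n` distinct spacers.
#' @export
make_nontargeting_controls <- function(index, n, radius = 3L, length = 20L,
                                       seed = 1L, max_attempts = 200L * n) {
  withr::with_seed(seed, {
    found <- character(0)
    attempts <- 0L
    while (length(found) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      sp <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
      if (sp %in% found) next
      if (hamming_occurrences(index, sp, radius) == 0L)
        found <- c(found, sp)
    }
    if (length(found) < n)
      stop(sprintf("could not find %d non-targeting controls in %d attempts",
                   n, attempts))
    found
  })
}

#' Select safe-targeting control guides
#'
#' Guides whose cut site falls within a safe-harbor region, passing the
#' cascade stages that apply to controls (uniqueness, efficiency,
#' specificity, G+C, monopolymer — the CDS stage does not apply), ranked
#' by specificity with ties broken by coordinate.
#'
#' @param records scored guide records.
#' @param safe_regions interval data frame (e.g. from [read_bed()]).
#' @param n number of controls to keep.
#' @param config a [library_config].
#' @return The top `n` records (all of them, with a warning, if fewer
#'   qualify).
#' @export
select_safe_targeting <- function(records, safe_regions, n,
                                  config = library_config()) {
  r <- records
  if (nrow(r) > 0)
    r <- r[r$ot_d0 + r$ot_d1 == 0, , drop = FALSE]
  if (nrow(r) > 0 && !anyNA(r$efficiency))
    r <- r[r$efficiency >= config$min_efficiency, , drop = FALSE]
  if (nrow(r) > 0)
    r <- r[!is.na(r$specificity) & r$specificity >= config$min_specificity, ,
           drop = FALSE]
  if (nrow(r) > 0) {
    gc <- .gc_fraction(r$spacer)
    r <- r[gc >= config$gc_min & gc <= config$gc_max, , drop = FALSE]
    r <- r[.max_run(r$spacer) <= config$max_monopolymer, , drop = FALSE]
  }
  if (nrow(r) == 0 || nrow(safe_regions) == 0) {
    if (n > 0 && nrow(r) < n) warning("fewer safe-targeting guides than requested")
    return(r[0, , drop = FALSE])
  }
  cuts <- cut_site(r)
  safe_gr <- GenomicRanges::GRanges(safe_regions$seqnames,
                                    IRanges::IRanges(safe_regions$start + 1L,
                                                     safe_regions$end))
  cut_gr <- GenomicRanges::GRanges(cuts$seqnames,
                                   IRanges::IRanges(cuts$cut + 1L, cuts$cut + 1L))
  inside <- S4Vectors::queryHits(GenomicRanges::findOverlaps(cut_gr, safe_gr))
  r <- r[sort(unique(inside)), , drop = FALSE]
  if (nrow(r) < n) warning("fewer safe-targeting guides than requested: ",
                           nrow(r), " < ", n)
  ord <- order(-r$specificity, r$seqnames, r$start)
  out <- r[ord[seq_len(min(n, nrow(r)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by their worst guides
#'
#' For screen design: genes sorted ascending by the mean specificity of
#' their two lowest-specificity guides, or (for libraries where
#' specificity is undefined) descending by the mean off-target count of
#' their two most promiscuous guides.
#'
#' @param library library data frame with `gene_id` plus `specificity` or
#'   off-target count columns (`ot_d*`).
#' @param mode `"specificity"` or `"offtarget_count"`.
#' @return Data frame `gene_id`, `key`, ranked; genes with fewer than two
#'   guides are excluded and listed in the `excluded` attribute.
#' @export
rank_problem_genes <- function(library, mode = c("specificity",
                                                 "offtarget_count")) {
  mode <- match.arg(mode)
  split_idx <- split(seq_len(nrow(library)), library$gene_id)
  excluded <- names(split_idx)[lengths(split_idx) < 2]
  split_idx <- split_idx[lengths(split_idx) >= 2]
  if (mode == "specificity") {
    key <- vapply(split_idx, function(i)
      mean(sort(library$specificity[i])[1:2]), numeric(1))
    ord <- order(key)
  } else {
    ocols <- grep("^ot_d", names(library), value = TRUE)
    tot <- rowSums(library[, ocols, drop = FALSE])
    key <- vapply(split_idx, function(i)
      mean(sort(tot[i], decreasing = TRUE)[1:2]), numeric(1))
    ord <- order(-key)
  }
  out <- data.frame(gene_id = names(split_idx)[ord], key = unname(key[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}
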