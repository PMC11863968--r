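load_cascade_fixture <- function() {
  g <- read_fasta(fixture_path("library_fixture.fa"))
  ann <- read_annotation(fixture_path("library_fixture.gtf"))
  guides <- read.delim(fixture_path("library_fixture.guides.tsv"),
                       stringsAsFactors = FALSE)
  eff <- efficiency_from_file(fixture_path("library_fixture.efficiency.tsv"))
  idx <- build_index(g)
  db <- build_database(idx, guides, database_params(), load_cfd_table(), eff)
  list(g = g, ann = ann, idx = idx, db = db)
}

test_that("the engineered cascade fixture loses exactly one guide per stage", {
  fx <- load_cascade_fixture()
  expect_equal(nrow(fx$db), 12L)
  res <- apply_library_filters(fx$db, fx$ann, library_config())
  expect_equal(res$report$survivors, c(12L, 11L, 10L, 9L, 8L, 7L, 6L))
  expect_equal(res$report$stage,
               c("input", "unique_0_1_mismatch", "cut_in_cds", "efficiency",
                 "specificity", "gc_content", "monopolymer"))
  # counts never increase along the cascade
  expect_true(all(diff(res$report$survivors) <= 0))
  # every survivor re-checks against all thresholds independently
  surv <- res$records
  expect_true(all(surv$ot_d0 + surv$ot_d1 == 0))
  expect_true(all(surv$efficiency >= 0.25))
  expect_true(all(surv$specificity >= 0.20))
  gc <- vapply(strsplit(surv$spacer, ""), function(x)
    mean(x %in% c("G", "C")), numeric(1))
  expect_true(all(gc >= 0.20 & gc <= 0.80))
  runs <- vapply(strsplit(surv$spacer, ""), function(x)
    max(rle(x)$lengths), integer(1))
  expect_true(all(runs <= 3))
})

test_that("single-rule examples: monopolymer and G+C removal", {
  fx <- load_cascade_fixture()
  db <- fx$db
  db$spacer[1] <- "AAAAGCGCGCGCGCGCGCGC"  # run of four A
  db$spacer[2] <- "GCGCGGCGCAGCGGCGCTGC"  # 17/20 G+C = 85%
  res <- apply_library_filters(db, fx$ann, library_config())
  rep <- res$report
  expect_false(db$spacer[1] %in% res$records$spacer)
  expect_false(db$spacer[2] %in% res$records$spacer)
  expect_equal(rep$survivors[rep$stage == "gc_content"] -
                 rep$survivors[rep$stage == "monopolymer"], 1L)
})

test_that("per-gene selection takes the top guides by score, ties broken deterministically", {
  set.seed(71)
  g <- random_genome(30000, seed = 71)
  ann <- toy_annotation(g, n_genes = 3L, exons_per_gene = 3L, seed = 71)
  idx <- build_index(g)
  cand <- enumerate_candidates(g, pam_spec(), 20L)
  cfd <- load_cfd_table()
  db <- build_database(idx, cand, database_params(), cfd,
                       toy_efficiency_model())
  res <- apply_library_filters(db, ann, library_config(min_efficiency = 0,
                                                       min_specificity = 0,
                                                       gc_min = 0, gc_max = 1,
                                                       max_monopolymer = 20L))
  counts <- table(unlist(res$records$genes))
  expect_gt(max(counts), 6L)  # deterministic under the fixed seed
  config <- library_config(guides_per_gene = 6L)
  sel <- select_guides_per_gene(res, idx, cfd, config)
  lib <- sel$library
  expect_true(all(table(lib$gene_id) <= 6L))
  # brute-force check of the top-6 for the fullest gene
  gene <- names(counts)[which.max(counts)]
  in_gene <- res$records[vapply(res$records$genes, function(x)
    gene %in% x, logical(1)), ]
  gp_spec <- vapply(seq_len(nrow(in_gene)), function(i) {
    gp <- five_prime_g_variant(in_gene$spacer[i])
    q <- guide_query(gp, pam_spec(), on_target = list(
      seqnames = in_gene$seqnames[i], pos = in_gene$start[i],
      strand = in_gene$strand[i]))
    specificity(q, enumerate_offtargets(idx, q, search_budget(3L)),
                cfd)$specificity
  }, numeric(1))
  score <- library_score(in_gene$specificity, gp_spec, in_gene$efficiency)
  ord <- order(-score, -in_gene$specificity, in_gene$seqnames, in_gene$start)
  expect_setequal(lib$guide_id[lib$gene_id == gene],
                  in_gene$guide_id[ord[1:6]])
  # genes at or below the cap keep everything
  small_genes <- names(counts)[counts <= 6]
  for (sg in small_genes)
    expect_equal(sum(lib$gene_id == sg), unname(counts[sg]))
})

test_that("non-targeting controls have no genomic neighbourhood and are reproducible", {
  set.seed(72)
  g <- random_genome(10000, seed = 72)
  idx <- build_index(g)
  ctrl <- make_nontargeting_controls(idx, n = 8L, radius = 3L, seed = 99L)
  expect_length(ctrl, 8L)
  expect_equal(anyDuplicated(ctrl), 0L)
  for (sp in ctrl) {
    nv <- scan_offtargets_naive(g, sp, pam = NULL, budget = search_budget(3L))
    expect_equal(nrow(nv), 0L)
  }
  expect_identical(make_nontargeting_controls(idx, 8L, 3L, seed = 99L), ctrl)
  # an impossible radius exhausts the attempt cap
  expect_error(make_nontargeting_controls(idx, 1L, radius = 20L, seed = 1L,
                                          max_attempts = 25L),
               "attempts")
})

test_that("safe-targeting selection keeps the most specific in-region guides", {
  recs <- data.frame(
    seqnames = "chr1", start = c(100L, 300L, 500L, 900L),
    end = c(120L, 320L, 520L, 920L), strand = "+",
    spacer = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
               "ACGGACGGACGGTACGTTCA", "TTGACCATGGTCAATGGACC"),
    pam = "AGG", guide_id = paste0("g", 1:4), ot_d0 = 0L, ot_d1 = 0L,
    ot_d2 = 0L, ot_d3 = 0L, specificity = c(0.9, 0.5, 0.7, 0.95),
    efficiency = 0.8, offtargets_hex = "", stringsAsFactors = FALSE)
  # cut sites: 116, 316, 516, 916; safe region [116, 520) catches g1..g3,
  # with the boundary cut site at exactly the region start included
  safe <- data.frame(seqnames = "chr1", start = 116L, end = 520L)
  sel <- select_safe_targeting(recs, safe, n = 2L)
  expect_equal(sel$guide_id, c("g1", "g3"))  # 0.9 then 0.7; g4 out of region
  expect_equal(nrow(select_safe_targeting(recs,
                                          data.frame(seqnames = "chr1",
                                                     start = 5000L,
                                                     end = 6000L),
                                          n = 0L)), 0L)
  expect_warning(select_safe_targeting(recs, safe, n = 10L), "fewer")
})

test_that("problem-gene ranking keys on the two worst guides per gene", {
  lib <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC"),
    specificity = c(0.9, 0.2, 0.1, 0.4, 0.2, 0.5),
    ot_d0 = 0L, ot_d1 = 0L,
    ot_d2 = c(2L, 40L, 50L, 1L, 2L, 0L),
    ot_d3 = c(3L, 50L, 50L, 2L, 3L, 1L), stringsAsFactors = FALSE)
  r <- rank_problem_genes(lib, "specificity")
  expect_equal(r$gene_id, c("gA", "gB"))
  expect_equal(r$key, c((0.1 + 0.2) / 2, (0.2 + 0.4) / 2))
  expect_equal(attr(r, "excluded"), "gC")
  r2 <- rank_problem_genes(lib, "offtarget_count")
  expect_equal(r2$gene_id[1], "gA")
  expect_equal(r2$key[1], (100 + 90) / 2)  # guide totals are 5, 90, 100
})
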