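test_that("variant application edits sequences and builds a correct coordinate map", {
  g <- genome(c(c1 = "AAAAAAAAAA"))
  snp <- data.frame(seqnames = "c1", pos = 5L, ref = "A", alt = "G",
                    kind = "SNP", stringsAsFactors = FALSE)
  res <- apply_variants(g, snp)
  expect_equal(unname(res$genome$sequences["c1"]), "AAAAAGAAAA")
  # a 2 bp insertion shifts all downstream coordinates by +2
  ins <- data.frame(seqnames = "c1", pos = 3L, ref = "A", alt = "ACG",
                    kind = "insertion", stringsAsFactors = FALSE)
  res2 <- apply_variants(g, ins)
  expect_equal(unname(res2$genome$sequences["c1"]), "AAAACGAAAAAA")
  expect_equal(map_coordinate(res2$map, "c1", c(0L, 3L, 4L, 9L)),
               c(0L, 3L, 6L, 11L))
  # deleted bases are unmappable; flanks map through
  del <- data.frame(seqnames = "c1", pos = 2L, ref = "AAA", alt = "A",
                    kind = "deletion", stringsAsFactors = FALSE)
  res3 <- apply_variants(g, del)
  expect_equal(unname(res3$genome$sequences["c1"]), "AAAAAAAA")
  expect_true(all(is.na(map_coordinate(res3$map, "c1", c(3L, 4L)))))
  expect_equal(map_coordinate(res3$map, "c1", c(2L, 5L)), c(2L, 3L))
})

test_that("variant application validates REF alleles and overlaps", {
  g <- genome(c(c1 = "ACGTACGTAC"))
  bad <- data.frame(seqnames = "c1", pos = 0L, ref = "G", alt = "T",
                    kind = "SNP", stringsAsFactors = FALSE)
  expect_error(apply_variants(g, bad), "REF mismatch")
  overlap <- data.frame(seqnames = "c1", pos = c(2L, 3L),
                        ref = c("GTA", "T"), alt = c("G", "A"),
                        kind = c("deletion", "SNP"), stringsAsFactors = FALSE)
  expect_error(apply_variants(g, overlap), "overlapping")
})

test_that("every non-variant base survives the coordinate map unchanged", {
  set.seed(81)
  g <- random_genome(5000, seed = 81)
  dip <- simulate_diploid(g, snp_rate = 0.01, indel_rate = 0.002, seed = 81)
  expect_gt(nrow(dip$variants), 10L)
  ref <- strsplit(g$sequences[[1]], "")[[1]]
  alt <- strsplit(dip$genome$sequences[[1]], "")[[1]]
  # positions covered by any variant REF span
  varpos <- unlist(mapply(function(p, r) p:(p + nchar(r) - 1L),
                          dip$variants$pos, dip$variants$ref))
  clean <- setdiff(0:(g$lengths[[1]] - 1L), varpos)
  mapped <- map_coordinate(dip$map, rep("chr1", length(clean)), clean)
  expect_false(anyNA(mapped))
  expect_equal(alt[mapped + 1L], ref[clean + 1L])
})

test_that("diploid simulation round-trips through VCF and rates of zero are the identity", {
  set.seed(82)
  g <- random_genome(3000, seed = 82)
  same <- simulate_diploid(g, 0, 0, seed = 82)
  expect_identical(same$genome$sequences, g$sequences)
  dip <- simulate_diploid(g, 0.01, 0.002, seed = 82)
  tf <- tempfile(fileext = ".vcf")
  write_vcf(dip$variants, tf)
  back <- read_vcf_variants(tf)
  cols <- c("seqnames", "pos", "ref", "alt", "kind", "zygosity")
  expect_equal(back[, cols], dip$variants[, cols], ignore_attr = TRUE)
  # pseudo-genome equals a fresh application of the variants
  expect_identical(apply_variants(g, dip$variants)$genome$sequences,
                   dip$genome$sequences)
})

test_that("allele-specific guides have no perfect site in the other genome", {
  set.seed(83)
  g <- random_genome(20000, seed = 83)
  dip <- simulate_diploid(g, snp_rate = 0.004, indel_rate = 5e-4, seed = 83)
  idx_a <- build_index(g)
  idx_b <- build_index(dip$genome)
  pam <- pam_spec()
  params <- database_params(budget = search_budget(3L))
  db_a <- build_database(idx_a, enumerate_candidates(g, pam, 20L), params)
  db_b <- build_database(idx_b, enumerate_candidates(dip$genome, pam, 20L),
                         params)
  res <- design_allele_specific(db_a, idx_b, db_b, idx_a, pam,
                                search_budget(3L))
  expect_gt(nrow(res$a_specific), 0L)
  expect_gt(nrow(res$b_specific), 0L)
  # soundness re-verified by the brute-force scanner on a sample
  take <- head(seq_len(nrow(res$a_specific)), 5)
  for (i in take) {
    nv <- scan_offtargets_naive(dip$genome, res$a_specific$spacer[i], pam,
                                search_budget(0L))
    expect_equal(nrow(nv), 0L)
  }
  # guides in variant-free regions appear in neither list
  vf <- db_a$spacer[!db_a$spacer %in% c(res$a_specific$spacer)]
  common <- intersect(db_a$spacer, db_b$spacer)
  expect_false(any(common %in% res$a_specific$spacer))
  expect_false(any(common %in% res$b_specific$spacer))
  # swapping the genome labels swaps the outputs exactly
  swapped <- design_allele_specific(db_b, idx_a, db_a, idx_b, pam,
                                    search_budget(3L), labels = c("B", "A"))
  expect_equal(swapped$a_specific$guide_id, res$b_specific$guide_id)
  expect_equal(swapped$b_specific$guide_id, res$a_specific$guide_id)
})

test_that("discrimination classes follow the variant location", {
  g <- genome(c(c1 = paste0(strrep("A", 50), "TACGTTGCAACGTGACTGGC", "AGG",
                            strrep("A", 50))))
  rec <- data.frame(seqnames = "c1", start = 50L, end = 70L, strand = "+",
                    pam = "AGG", stringsAsFactors = FALSE)
  pam_var <- data.frame(seqnames = "c1", pos = 71L, ref = "G", alt = "T",
                        kind = "SNP", stringsAsFactors = FALSE)
  proto_var <- data.frame(seqnames = "c1", pos = 59L, ref = "A", alt = "G",
                          kind = "SNP", stringsAsFactors = FALSE)
  far_var <- data.frame(seqnames = "c1", pos = 5L, ref = "A", alt = "G",
                        kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(classify_discrimination(rec, pam_var), "pam_variant")
  expect_equal(classify_discrimination(rec, proto_var), "protospacer_variant")
  expect_equal(classify_discrimination(rec, far_var), "structural")
  expect_equal(classify_discrimination(rec, far_var[0, ]), "structural")
  # PAM takes precedence when variants hit both windows
  both <- rbind(pam_var, proto_var)
  expect_equal(classify_discrimination(rec, both), "pam_variant")
})

test_that("the high-confidence cascade removes exactly the planted violators", {
  base <- data.frame(
    seqnames = "chr1", start = seq(100L, by = 200L, length.out = 8L),
    strand = "+", stringsAsFactors = FALSE)
  base$end <- base$start + 20L
  base$guide_id <- paste0("g", 1:8)
  base$spacer <- replicate(8, rand_seq(20))
  base$pam <- "AGG"
  base$het_variant <- c(TRUE, rep(FALSE, 7))             # g1 heterozygous
  base$own_d2 <- c(0L, 1L, rep(0L, 6))                   # g2 has a 2-mm hit
  base$other_d2 <- 0L
  base$own_d3 <- c(0L, 0L, 4L, rep(0L, 5))               # g3 exceeds 3x 3-mm
  base$other_d3 <- 0L
  base$efficiency <- c(0.9, 0.9, 0.9, 0.05, rep(0.9, 4)) # g4 bottom quartile
  repeats <- data.frame(seqnames = "chr1", start = 950L, end = 1000L)
  # g5 cut site is at 1016; 950..1000 lies within 200 bp of it -> removed,
  # and so are g4's neighbours? distances: cut sites 116,316,...,1516
  res <- high_confidence_filter(base, repeats, efficiency_quantile = 0.75,
                                repeat_distance = 200L)
  rep_tab <- res$report
  expect_equal(rep_tab$stage,
               c("input", "exclude_het", "no_2mm_offtargets",
                 "max_3mm_offtargets", "top_efficiency", "repeat_distance"))
  expect_true(all(diff(rep_tab$survivors) <= 0))
  expect_false("g1" %in% res$records$guide_id)
  expect_false("g2" %in% res$records$guide_id)
  expect_false("g3" %in% res$records$guide_id)
  expect_false("g4" %in% res$records$guide_id)
  # every survivor is > 200 bp from the repeat
  cuts <- cut_site(res$records)$cut
  expect_true(all(pmin(abs(cuts - 950L), abs(cuts - 1000L)) >= 200L |
                    (cuts >= 950L & cuts < 1000L) == FALSE))
  expect_true(all(abs(cuts - 975L) > 200L))
})

test_that("gene annotation uses exon overlap of the cut site with a deterministic tie rule", {
  recs <- data.frame(seqnames = "c1",
                     start = c(100L, 500L, 300L), end = c(120L, 520L, 320L),
                     strand = "+", stringsAsFactors = FALSE)
  ann <- data.frame(
    seqnames = "c1",
    start = c(100L, 100L, 110L, 110L, 1000L, 1000L),
    end = c(400L, 400L, 350L, 350L, 1200L, 1200L),
    strand = "+",
    type = c("gene", "exon", "gene", "exon", "gene", "exon"),
    gene_id = c("zebra", "zebra", "alpha", "alpha", "omega", "omega"),
    stringsAsFactors = FALSE)
  class(ann) <- c("annotation", "data.frame")
  out <- annotate_genes(recs, ann)
  expect_equal(out$gene_id[1], "alpha")   # both overlap; smallest id wins
  expect_true(is.na(out$gene_id[2]))      # intergenic cut site
  expect_equal(out$gene_id[3], "alpha")
})
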