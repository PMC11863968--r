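test_that("IUPAC PAM motifs expand to their exact concrete sets", {
  expect_setequal(expand_pam("NGG"), c("AGG", "CGG", "GGG", "TGG"))
  expect_length(expand_pam("NRG"), 8L)
  expect_setequal(expand_pam("NRG"),
                  union(expand_pam("NGG"), expand_pam("NAG")))
  expect_equal(expand_pam("GG"), "GG")
  expect_error(expand_pam("NXG"), "IUPAC")
})

test_that("planted sites are recovered exactly, budgets are monotone", {
  set.seed(31)
  g0 <- random_genome(50000, seed = 31)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = c(2000L, 30000L),
                            strand = c("+", "+"), n_mm = c(0L, 2L),
                            pam = c("AGG", "AGG")),
    budget = search_budget(3L), seed = 31)
  idx <- build_index(planted$genome)
  ot3 <- enumerate_offtargets(idx, spacer, search_budget(3L))
  expect_setequal(ot_key(ot3), ot_key(planted$truth))
  expect_equal(sort(ot3$distance), sort(planted$truth$distance))
  # distances of the two planted sites
  expect_true(all(c(0L, 2L) %in% ot3$distance))
  # tighter budget returns a subset on the same fixture
  ot1 <- enumerate_offtargets(idx, spacer, search_budget(1L))
  expect_true(all(ot_key(ot1) %in% ot_key(ot3)))
  expect_true(all(ot1$distance <= 1))
  ot0 <- enumerate_offtargets(idx, spacer, search_budget(0L))
  expect_true(all(ot_key(ot0) %in% ot_key(ot1)))
})

test_that("minus-strand sites report + strand coordinates and strand '-'", {
  set.seed(32)
  g0 <- random_genome(8000, seed = 32)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = 4000L, strand = "-",
                            n_mm = 0L, pam = "TGG"),
    budget = search_budget(2L), seed = 32)
  idx <- build_index(planted$genome)
  ot <- enumerate_offtargets(idx, spacer, search_budget(2L))
  hit <- ot[ot$distance == 0, ]
  expect_equal(hit$strand, "-")
  # footprint planted at 4000: PAM occupies [4000,4003), protospacer next
  expect_equal(hit$start, 4003L)
  expect_equal(hit$end, 4023L)
  expect_equal(hit$protospacer, spacer)
  expect_equal(hit$pam, "TGG")
})

test_that("off-target enumeration equals the brute-force scan on random genomes", {
  set.seed(33)
  for (trial in 1:4) {
    g <- random_genome(sample(5000:15000, 1), gc = runif(1, 0.35, 0.65),
                       seed = 330 + trial)
    idx <- build_index(g)
    for (j in 1:3) {
      spacer <- rand_seq(20)
      k <- sample(0:3, 1)
      ot <- enumerate_offtargets(idx, spacer, search_budget(k))
      nv <- scan_offtargets_naive(g, spacer, budget = search_budget(k))
      expect_setequal(ot_key(ot), ot_key(nv))
    }
  }
})

test_that("sites with both an RNA and a DNA bulge are found", {
  set.seed(34)
  g0 <- random_genome(6000, seed = 34)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1",
                            pos = c(1000L, 2500L, 4000L),
                            strand = c("+", "+", "-"),
                            n_mm = c(0L, 1L, 0L),
                            rb_pos = c(0L, 5L, 9L),
                            db_gap = c(0L, 11L, 14L)),
    budget = search_budget(2L, 1L, 1L), seed = 34)
  idx <- build_index(planted$genome)
  ot <- enumerate_offtargets(idx, spacer, search_budget(2L, 1L, 1L))
  expect_setequal(locus_key(ot), locus_key(planted$truth))
  both <- ot[ot$rna_bulges == 1 & ot$dna_bulges == 1, ]
  expect_gte(nrow(both), 2L)  # the two sites carrying both bulge kinds
})

test_that("bulge enumeration equals the banded brute-force oracle", {
  set.seed(35)
  for (trial in 1:3) {
    g <- random_genome(4000, seed = 350 + trial)
    spacer <- rand_seq(20)
    b <- search_budget(2L, 1L, 1L)
    ot <- enumerate_offtargets(idx <- build_index(g), spacer, b)
    nv <- scan_offtargets_naive(g, spacer, budget = b)
    expect_setequal(locus_key(ot), locus_key(nv))
    # the chosen best alignment agrees too
    m_ot <- ot[order(locus_key(ot)), c("n_mismatches", "rna_bulges", "dna_bulges")]
    m_nv <- nv[order(locus_key(nv)), c("n_mismatches", "rna_bulges", "dna_bulges")]
    expect_equal(m_ot, m_nv, ignore_attr = TRUE)
  }
})

test_that("each locus is reported once even when several alignments reach it", {
  set.seed(36)
  g0 <- random_genome(5000, seed = 36)
  # a site with one mismatch is also reachable as rna+dna bulge pairs;
  # dedup must keep the plain mismatch alignment
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = 2000L, strand = "+",
                            n_mm = 1L),
    budget = search_budget(2L, 1L, 1L), seed = 36)
  idx <- build_index(planted$genome)
  ot <- enumerate_offtargets(idx, spacer, search_budget(2L, 1L, 1L))
  keys <- locus_key(ot)
  expect_equal(anyDuplicated(keys), 0L)
  # the planted PAM sits at 2020; that locus keeps the pure-mismatch alignment
  hit <- ot[ot$pam_start == 2020 & ot$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_mismatches, 1L)
  expect_equal(hit$rna_bulges + hit$dna_bulges, 0L)
})

test_that("legacy PAM semantics yield a subset, strict on NAG at full budget", {
  set.seed(37)
  g0 <- random_genome(20000, seed = 37)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1",
                            pos = c(1000L, 6000L, 12000L),
                            strand = "+",
                            n_mm = c(0L, 2L, 2L),
                            pam = c("AGG", "TAG", "CGG")),
    budget = search_budget(2L), seed = 37)
  idx <- build_index(planted$genome)
  wild <- enumerate_offtargets(idx, spacer, search_budget(2L))
  legacy <- enumerate_offtargets(idx, spacer, search_budget(2L),
                                 legacy_pam = TRUE)
  expect_true(all(ot_key(legacy) %in% ot_key(wild)))
  # the 2-mismatch NAG site is found only under wildcard semantics
  nag2 <- wild$pam_class == "alternative" & wild$n_mismatches == 2
  expect_true(any(nag2))
  expect_false(any(legacy$pam_class == "alternative" &
                     legacy$n_mismatches == 2))
  expect_gt(nrow(wild), nrow(legacy))
})

test_that("strand symmetry: mirrored genome and spacer give mirrored results", {
  set.seed(38)
  g <- random_genome(6000, seed = 38)
  spacer <- rand_seq(20)
  rc_g <- genome(setNames(reverse_complement(g$sequences), names(g$sequences)))
  b <- search_budget(2L)
  ot_f <- enumerate_offtargets(build_index(g), spacer, b)
  ot_r <- enumerate_offtargets(build_index(rc_g), reverse_complement(spacer), b)
  len <- g$lengths[[1]]
  mirrored <- data.frame(seqnames = ot_r$seqnames,
                         start = len - ot_r$end, end = len - ot_r$start,
                         strand = ifelse(ot_r$strand == "+", "-", "+"),
                         n_mismatches = ot_r$n_mismatches,
                         rna_bulges = ot_r$rna_bulges,
                         dna_bulges = ot_r$dna_bulges)
  expect_setequal(ot_key(ot_f), ot_key(mirrored))
})

test_that("perfect-site search respects PAM requirement and multiplicity", {
  set.seed(39)
  g0 <- random_genome(9000, seed = 39)
  spacer <- rand_seq(20)
  # two NGG copies (duplicated gene) and one PAM-less copy
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = c(500L, 4000L),
                            strand = "+", n_mm = 0L, pam = c("AGG", "GGG")),
    budget = search_budget(0L), seed = 39)
  g2 <- planted$genome
  s <- g2$sequences[["chr1"]]
  substr(s, 7001, 7023) <- paste0(spacer, "TTT")  # no PAM
  g2 <- genome(c(chr1 = s))
  idx <- build_index(g2)
  sites <- find_perfect_sites(idx, spacer, pam_spec(), primary_only = TRUE)
  expect_equal(nrow(sites), 2L)
  expect_false(any(sites$start == 7000L))
})

test_that("PAM-free Hamming occurrence counts match a naive scan", {
  set.seed(40)
  g <- random_genome(3000, seed = 40)
  idx <- build_index(g)
  own <- substr(g$sequences[[1]], 1001, 1020)
  expect_gte(hamming_occurrences(idx, own, 0L), 1L)
  # distance 20 matches every window on both strands
  n_windows <- 2L * (g$lengths[[1]] - 20L + 1L)
  expect_equal(hamming_occurrences(idx, rand_seq(20), 20L), n_windows)
  for (i in 1:5) {
    sp <- rand_seq(20)
    mm <- sample(0:2, 1)
    nv <- scan_offtargets_naive(g, sp, pam = NULL,
                                budget = search_budget(mm))
    expect_equal(hamming_occurrences(idx, sp, mm), nrow(nv))
  }
})

test_that("cut sites sit 3 nt upstream of the PAM on either strand", {
  plus <- data.frame(seqnames = "c", start = 100L, end = 120L, strand = "+")
  minus <- data.frame(seqnames = "c", start = 100L, end = 120L, strand = "-")
  expect_equal(cut_site(plus)$cut, 116L)
  expect_equal(cut_site(minus)$cut, 103L)
  expect_error(cut_site(plus, pam_side = "5prime"), "undefined")
})

test_that("a declared on-target is excluded from enumeration", {
  set.seed(41)
  g0 <- random_genome(8000, seed = 41)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = c(1000L, 5000L),
                            strand = "+", n_mm = c(0L, 1L),
                            pam = c("AGG", "CGG")),
    budget = search_budget(2L), seed = 41)
  idx <- build_index(planted$genome)
  q <- guide_query(spacer, pam_spec(),
                   on_target = list(seqnames = "chr1", pos = 1000L,
                                    strand = "+"))
  ot <- enumerate_offtargets(idx, q, search_budget(2L))
  expect_false(any(ot$start == 1000L & ot$strand == "+"))
  expect_true(any(ot$start == 5000L))
})
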