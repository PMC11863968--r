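test_that("candidate enumeration finds exactly the PAM-adjacent windows", {
  g <- genome(c(s = "AAACGGTTT"))
  cand <- enumerate_candidates(g, pam_spec(), length = 3L)
  plus <- cand[cand$strand == "+", ]
  expect_equal(plus$spacer, "AAA")
  expect_equal(plus$pam, "CGG")
  expect_equal(plus$start, 0L)
  # all-A genome has no GG anywhere
  expect_equal(nrow(enumerate_candidates(genome(c(s = strrep("A", 100))),
                                         pam_spec(), 20L)), 0L)
  # a CC on the + strand is a GG for the - strand
  g2 <- genome(c(s = paste0(strrep("A", 10), "CCT", strrep("A", 30))))
  cand2 <- enumerate_candidates(g2, pam_spec(), length = 5L)
  minus <- cand2[cand2$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  expect_true(all(substr(minus$pam, 2, 3) == "GG"))
  # windows containing N are never emitted
  g3 <- genome(c(s = paste0(strrep("A", 10), "NACGTACGT", "TGG",
                            strrep("A", 10))))
  cand3 <- enumerate_candidates(g3, pam_spec(), length = 9L)
  expect_false(any(grepl("N", cand3$spacer)))
})

test_that("guides with duplicated perfect sites never enter the database", {
  set.seed(61)
  g0 <- random_genome(12000, seed = 61)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = c(1000L, 7000L),
                            strand = "+", n_mm = 0L, pam = "AGG"),
    budget = search_budget(0L), seed = 61)
  idx <- build_index(planted$genome)
  cand <- enumerate_candidates(planted$genome, pam_spec(), 20L)
  dup <- cand[cand$spacer == spacer, ]
  expect_equal(nrow(dup), 2L)
  db <- build_database(idx, dup, database_params())
  expect_equal(nrow(db), 0L)
})

test_that("database records carry off-target distance counts and scores", {
  set.seed(62)
  g0 <- random_genome(15000, seed = 62)
  spacer <- rand_seq(20)
  planted <- plant_sites(
    g0, spacer, pam_spec(),
    placements = data.frame(seqnames = "chr1", pos = c(2000L, 9000L),
                            strand = "+", n_mm = c(0L, 2L),
                            pam = c("AGG", "CAG")),
    budget = search_budget(3L), seed = 62)
  idx <- build_index(planted$genome)
  cand <- data.frame(seqnames = "chr1", start = 2000L, end = 2020L,
                     strand = "+", spacer = spacer, pam = "AGG",
                     stringsAsFactors = FALSE)
  db <- build_database(idx, cand, database_params(),
                       cfd_table = load_cfd_table(),
                       efficiency_model = toy_efficiency_model())
  expect_equal(nrow(db), 1L)
  expect_equal(db$ot_d2, 1L)  # the planted 2-mismatch NAG site
  expect_equal(db$ot_d0, 0L)
  expect_true(db$specificity > 0 && db$specificity < 1)
  expect_true(db$efficiency >= 0 && db$efficiency <= 1)
  # empty candidate set -> empty database with full schema
  empty <- build_database(idx, cand[0, ], database_params())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("guide_id", "ot_d0", "offtargets_hex") %in% names(empty)))
})

test_that("hex off-target encoding round-trips and matches the documented layout", {
  offsets <- c(chr1 = 0L, chr2 = 5000L)
  expect_equal(encode_offtargets_hex(data.frame()[0, ], offsets), "")
  # hand-computed single record: version byte 01, then
  # value = (5000 + 10) * 2 + 1 = 10021 = 0x2725 little-endian, distance 2
  one <- data.frame(seqnames = "chr2", start = 10L, strand = "-",
                    distance = 2L, stringsAsFactors = FALSE)
  expect_equal(encode_offtargets_hex(one, offsets),
               "01252700000000000002")
  dec <- decode_offtargets_hex("01252700000000000002", offsets)
  expect_equal(dec$seqnames, "chr2")
  expect_equal(dec$start, 10L)
  expect_equal(dec$strand, "-")
  expect_equal(dec$distance, 2L)
  # random round-trips
  set.seed(63)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    ot <- data.frame(
      seqnames = sample(names(offsets), n, replace = TRUE),
      start = sample(0:4999, n), strand = sample(c("+", "-"), n, TRUE),
      distance = sample(0:4, n, TRUE), stringsAsFactors = FALSE)
    dec <- decode_offtargets_hex(encode_offtargets_hex(ot, offsets), offsets)
    expect_equal(dec, ot, ignore_attr = TRUE)
  }
  expect_error(decode_offtargets_hex("012527", offsets), "malformed")
  expect_error(decode_offtargets_hex("0xz", offsets), "malformed")
  expect_error(decode_offtargets_hex("ff", offsets), "version")
})

test_that("SAM emission is valid, 1-based, strand-flagged, and lossless", {
  set.seed(64)
  g <- random_genome(20000, seed = 64)
  idx <- build_index(g)
  cand <- enumerate_candidates(g, pam_spec(), 20L)
  cand <- cand[sample(nrow(cand), 40), ]
  db <- build_database(idx, cand, database_params(),
                       cfd_table = load_cfd_table(),
                       efficiency_model = toy_efficiency_model())
  tf <- tempfile(fileext = ".sam")
  write_sam(db, g, tf)
  lines <- readLines(tf)
  expect_true(any(startsWith(lines, "@HD")))
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:20000$", lines)))
  body <- lines[!startsWith(lines, "@")]
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_setequal(unique(flags), c(0L, 16L))
  # a + record at 0-based start s has POS s+1
  first <- strsplit(body[1], "\t")[[1]]
  rec1 <- db[1, ]
  expected_pos <- if (rec1$strand == "+") rec1$start + 1L else
    rec1$start - 3L + 1L
  expect_equal(as.integer(first[4]), expected_pos)
  rt <- read_sam(tf)
  cols <- c("seqnames", "start", "end", "strand", "spacer", "pam",
            "guide_id", "ot_d0", "ot_d1", "ot_d2", "ot_d3",
            "specificity", "efficiency", "offtargets_hex")
  expect_equal(rt[, cols], db[, cols], ignore_attr = TRUE)
  expect_error(write_sam(transform(db, seqnames = "chrZ"), g, tempfile()),
               "unknown sequence")
})

test_that("partitioned runs merge to the single-partition result", {
  set.seed(65)
  g <- random_genome(15000, seed = 65)
  idx <- build_index(g)
  cand <- enumerate_candidates(g, pam_spec(), 20L)
  cand <- cand[sample(nrow(cand), 60), ]
  cfd <- load_cfd_table()
  worker <- function(part) build_database(idx, part, database_params(), cfd)
  one <- partition_run(cand, 1L, worker)
  seven <- partition_run(cand, 7L, worker)
  expect_equal(seven, one, ignore_attr = TRUE)
  # more partitions than candidates still works (empty partitions allowed)
  many <- partition_run(cand[1:3, ], 10L, worker)
  expect_equal(many, worker(cand[1:3, ]), ignore_attr = TRUE)
  # a failing partition aborts the merge
  expect_error(partition_run(cand, 2L, function(p) stop("boom")),
               "partition worker failed")
})
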