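# Generates the engineered library-cascade fixture under inst/extdata/:
#   library_fixture.fa              6 kb single-chromosome genome
#   library_fixture.gtf             one gene whose CDS covers the planting region
#   library_fixture.guides.tsv      the 12 planted candidate guides
#   library_fixture.efficiency.tsv  per-spacer efficiencies
# The 12 guides are engineered so that each stage of the library filter
# cascade removes exactly one: g01 has a 1-mismatch second occurrence,
# g02 cuts outside the CDS, g03 has efficiency 0.10, g04 has five planted
# 2-mismatch off-targets (specificity < 0.20 under the packaged synthetic
# CFD table), g05 has 85% G+C, g06 contains a 4-base monopolymer, and
# g07..g12 are clean. Verified against the package cascade before writing.

devtools::load_all(".", quiet = TRUE)
set.seed(20240901)

bases <- c("A", "C", "G", "T")
rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
gc_frac <- function(s) mean(strsplit(s, "")[[1]] %in% c("G", "C"))
max_run <- function(s) max(rle(strsplit(s, "")[[1]])$lengths)

ok_spacer <- function(s, others, min_ham = 8) {
  if (gc_frac(s) < 0.35 || gc_frac(s) > 0.65) return(FALSE)
  if (max_run(s) > 3) return(FALSE)
  a <- strsplit(s, "")[[1]]
  for (o in c(others, vapply(others, reverse_complement, character(1)))) {
    if (!nzchar(o)) next
    if (sum(a != strsplit(o, "")[[1]]) < min_ham) return(FALSE)
  }
  TRUE
}

draw_spacer <- function(others) {
  repeat { s <- rnd(20); if (ok_spacer(s, others)) return(s) }
}

spacers <- character(0)
for (i in 1:10) spacers <- c(spacers, draw_spacer(spacers))  # g01-g04, g07-g12
# g05: exactly 17/20 G+C (85%), runs <= 3
repeat {
  g5 <- paste(sample(c(rep("G", 9), rep("C", 8), "A", "T", "A")), collapse = "")
  if (max_run(g5) <= 3) break
}
# g06: contains AAAA, GC in bounds
repeat {
  g6 <- paste0(rnd(6), "AAAA", rnd(10))
  if (gc_frac(g6) >= 0.35 && gc_frac(g6) <= 0.65 && max_run(g6) == 4) break
}

ids <- sprintf("g%02d", 1:12)
spc <- c(spacers[1:4], g5, g6, spacers[5:10])
names(spc) <- ids

# background genome, then overwrite planting windows
glen <- 6000L
bg <- rnd(glen)

plant <- function(seq, pos0, site) {  # pos0 0-based
  substr(seq, pos0 + 1L, pos0 + nchar(site)) <- site
  seq
}

# CDS region [1000, 4000); guides inside it except g02
cds_lo <- 1000L; cds_hi <- 4000L
pos <- setNames(as.integer(seq(1100, by = 240, length.out = 12)), ids)
pos["g02"] <- 4500L  # cut site 4516, outside the CDS

seq <- bg
for (id in ids) seq <- plant(seq, pos[[id]], paste0(spc[[id]], "CGG"))

# g01: a second occurrence at 1 mismatch (position 10 substituted), NGG PAM
mm1 <- spc[["g01"]]
substr(mm1, 10, 10) <- setdiff(bases, substr(mm1, 10, 10))[1]
seq <- plant(seq, 5200L, paste0(mm1, "TGG"))

# g04: five 2-mismatch off-targets (transitions at positions 1 and 2 keep
# the synthetic CFD penalty high so the CFD sum exceeds 4)
tr <- c(A = "G", G = "A", C = "T", T = "C")
mm2 <- spc[["g04"]]
substr(mm2, 1, 1) <- tr[[substr(mm2, 1, 1)]]
substr(mm2, 2, 2) <- tr[[substr(mm2, 2, 2)]]
ot_pos <- as.integer(seq(4600, by = 40, length.out = 5))
for (p in ot_pos) seq <- plant(seq, p, paste0(mm2, "AGG"))

g <- genome(c(chrF = seq))
ann <- data.frame(seqnames = "chrF",
                  start = c(cds_lo, cds_lo, cds_lo),
                  end = c(cds_hi, cds_hi, cds_hi),
                  strand = "+", type = c("gene", "exon", "CDS"),
                  gene_id = "geneA", stringsAsFactors = FALSE)

guides <- data.frame(seqnames = "chrF", start = unname(pos),
                     end = unname(pos) + 20L, strand = "+",
                     spacer = unname(spc), pam = "CGG",
                     stringsAsFactors = FALSE)

eff <- data.frame(spacer = unname(spc),
                  efficiency = ifelse(ids == "g03", 0.10, 0.80))

# ---- verification with the package itself ----
idx <- build_index(g)
cfd <- load_cfd_table("inst/extdata/cfd_table_synthetic.tsv")
db <- build_database(idx, guides, database_params(), cfd,
                     efficiency_from_file(textConnection_path <- {
                       tf <- tempfile(); write.table(eff, tf, sep = "\t",
                                                     quote = FALSE,
                                                     row.names = FALSE); tf
                     }))
stopifnot(nrow(db) == 12)
res <- apply_library_filters(db, structure(ann, class = c("annotation", "data.frame")),
                             library_config())
print(res$report)
stopifnot(identical(res$report$survivors, c(12L, 11L, 10L, 9L, 8L, 7L, 6L)))
surv <- sort(sub(":.*", "", rownames(res$records)))
spec4 <- db$specificity[db$spacer == spc[["g04"]]]
cat("g04 specificity:", spec4, "\n")
stopifnot(spec4 < 0.20)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_fasta(g, "inst/extdata/library_fixture.fa")
write_gtf(ann, "inst/extdata/library_fixture.gtf")
write.table(guides, "inst/extdata/library_fixture.guides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(eff, "inst/extdata/library_fixture.efficiency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("fixture written\n")
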