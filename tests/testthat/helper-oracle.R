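# shared test utilities: random sequences, site keys, and a second
# independent mismatch-only oracle built on Biostrings::matchPattern
# (used to cross-check the package's own brute-force scanner)

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

ot_key <- function(ot) {
  paste(ot$seqnames, ot$start, ot$end, ot$strand, ot$n_mismatches,
        ot$rna_bulges, ot$dna_bulges, sep = "/")
}

locus_key <- function(ot) {
  paste(ot$seqnames, ot$strand, ot$pam_start, sep = "/")
}

# Hamming-window oracle via Biostrings: protospacer windows within max_mm
# on either strand whose adjacent 3-mer matches one of the PAM motifs
biostrings_offtargets <- function(g, spacer, motifs = c("NGG", "NAG"),
                                  max_mm = 3) {
  L <- nchar(spacer)
  pamlen <- nchar(motifs[1])
  rows <- list()
  for (seqname in names(g$sequences)) {
    subj <- Biostrings::DNAString(g$sequences[[seqname]])
    len <- g$lengths[[seqname]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else
        crisprtrie::reverse_complement(spacer)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      starts <- Biostrings::start(m) - 1L
      for (s in starts) {
        if (s < 0 || s + L > len) next
        window <- as.character(Biostrings::subseq(subj, s + 1L, s + L))
        if (grepl("N", window)) next
        if (strand == "+") {
          if (s + L + pamlen > len) next
          pam <- as.character(Biostrings::subseq(subj, s + L + 1L,
                                                 s + L + pamlen))
          proto <- window
        } else {
          if (s - pamlen < 0) next
          pam <- crisprtrie::reverse_complement(
            as.character(Biostrings::subseq(subj, s - pamlen + 1L, s)))
          proto <- crisprtrie::reverse_complement(window)
        }
        if (grepl("N", pam)) next
        matches_any <- any(vapply(motifs, function(mo) {
          all(mapply(function(p, q) {
            p %in% crisprtrie:::.IUPAC[[q]]
          }, strsplit(pam, "")[[1]], strsplit(mo, "")[[1]]))
        }, logical(1)))
        if (!matches_any) next
        mm <- sum(strsplit(proto, "")[[1]] != strsplit(spacer, "")[[1]])
        if (mm > max_mm) next
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = seqname, start = s, end = s + L, strand = strand,
          n_mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(seqnames = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_mismatches = integer(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out[order(out$seqnames, out$start, out$strand), , drop = FALSE]
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "crisprtrie", mustWork = TRUE)
}
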