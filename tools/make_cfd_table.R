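# Generates inst/extdata/cfd_table_synthetic.tsv, the packaged SYNTHETIC
# CFD penalty table. Values come from a smooth deterministic formula, not
# from any published empirical dataset: mismatch tolerance decays from the
# PAM-distal 5' end toward the PAM-proximal seed region, transitions are
# slightly better tolerated than transversions, NGG is unpenalised and
# alternative PAMs are strongly down-weighted. Replace with an empirically
# derived table for production guide design.

bases <- c("A", "C", "G", "T")
grid <- expand.grid(position = 1:20, rna_base = bases, dna_base = bases,
                    stringsAsFactors = FALSE)
grid <- grid[grid$rna_base != grid$dna_base, ]
transition <- with(grid, (rna_base %in% c("A", "G") & dna_base %in% c("A", "G")) |
                         (rna_base %in% c("C", "T") & dna_base %in% c("C", "T")))
pen <- pmin(1, pmax(0.02, 0.95 - 0.042 * grid$position + ifelse(transition, 0.08, 0)))
mm <- data.frame(record_type = "mismatch", position = grid$position,
                 rna_base = grid$rna_base, dna_base = grid$dna_base,
                 pam = "", penalty = round(pen, 3))
mm <- mm[order(mm$position, mm$rna_base, mm$dna_base), ]

pams <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
pam_pen <- ifelse(substr(pams, 2, 3) == "GG", 1,
           ifelse(substr(pams, 2, 3) == "AG", 0.25,
           ifelse(substr(pams, 2, 3) == "GA", 0.07,
           ifelse(substr(pams, 2, 3) == "CG", 0.03, 0))))
pm <- data.frame(record_type = "pam", position = NA, rna_base = "",
                 dna_base = "", pam = sort(pams),
                 penalty = pam_pen[order(pams)])

out <- rbind(mm, pm)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(out, "inst/extdata/cfd_table_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(out), "rows\n")
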