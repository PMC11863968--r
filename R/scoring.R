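#' Load a CFD penalty table
#'
#' The cutting-frequency-determination (CFD) model assigns each spacer
#' mismatch a penalty in \[0,1\] indexed by (spacer position 1..20 from the
#' 5' end, spacer base, genomic base read in spacer orientation), and each
#' concrete PAM trinucleotide a penalty in \[0,1\]. The CFD of an off-target
#' is the product of its per-mismatch penalties times its PAM penalty.
#'
#' The file is tab-delimited with columns `record_type` (`mismatch` or
#' `pam`), `position`, `rna_base`, `dna_base`, `pam`, `penalty`. Validation
#' requires a complete mismatch grid (every position 1..20 and every
#' non-matching base pair), penalty 1 for any matching base pair present,
#' penalty 1 for every NGG expansion, and all penalties in \[0,1\].
#'
#' The packaged default (`cfd_table_synthetic.tsv`) is a synthetic table
#' generated from a smooth position-dependent formula; it reproduces the
#' qualitative structure of empirical CFD models (PAM-proximal "seed"
#' mismatches penalised most, NGG unpenalised, NAG strongly down-weighted)
#' but not any published values, and should be replaced with an empirically
#' derived table for production guide design.
#'
#' @param path path to the table; default is the packaged synthetic table.
#' @return An object of class `cfd_table` with elements `mismatch` (a
#'   named numeric lookup) and `pam` (named numeric, by trinucleotide).
#' @export
load_cfd_table <- function(path = system.file("extdata",
                                              "cfd_table_synthetic.tsv",
                                              package = "crisprtrie")) {
  if (!file.exists(path)) stop("CFD table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_type", "position", "rna_base", "dna_base", "pam", "penalty")
  if (!all(need %in% names(tab)))
    stop("CFD table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$penalty < 0 | tab$penalty > 1))
    stop("CFD penalties must lie in [0, 1]")
  mm <- tab[tab$record_type == "mismatch", ]
  pm <- tab[tab$record_type == "pam", ]
  bases <- c("A", "C", "G", "T")
  mkey <- sprintf("%d:%s>%s", mm$position, mm$rna_base, mm$dna_base)
  if (anyDuplicated(mkey)) stop("duplicate mismatch entries in CFD table")
  lookup <- setNames(mm$penalty, mkey)
  grid <- expand.grid(position = 1:20, rna_base = bases, dna_base = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$rna_base != grid$dna_base, ]
  missing <- setdiff(sprintf("%d:%s>%s", grid$position, grid$rna_base,
                             grid$dna_base), mkey)
  if (length(missing))
    stop("CFD table is missing mismatch entries: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  match_rows <- mm$rna_base == mm$dna_base
  if (any(mm$penalty[match_rows] != 1))
    stop("CFD penalty for a matching base pair must be 1")
  if (anyDuplicated(pm$pam)) stop("duplicate PAM entries in CFD table")
  pam_lookup <- setNames(pm$penalty, pm$pam)
  ngg <- expand_pam("NGG")
  present <- intersect(ngg, names(pam_lookup))
  if (length(setdiff(ngg, names(pam_lookup))) ||
      any(pam_lookup[present] != 1))
    stop("CFD pam_penalty must be 1 for every NGG expansion")
  structure(list(mismatch = lookup, pam = pam_lookup), class = "cfd_table")
}

#' Build an in-memory CFD table with uniform mismatch penalty
#'
#' Convenience constructor for tests and examples: every mismatch carries
#' the same penalty, every NGG expansion penalty 1, and other PAMs the
#' given value.
#'
#' @param mismatch_penalty penalty for every mismatch.
#' @param alt_pam_penalty penalty for non-NGG PAM trinucleotides.
#' @return A `cfd_table`.
#' @export
uniform_cfd_table <- function(mismatch_penalty = 0.5, alt_pam_penalty = 0.5) {
  stopifnot(mismatch_penalty >= 0, mismatch_penalty <= 1,
            alt_pam_penalty >= 0, alt_pam_penalty <= 1)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(position = 1:20, rna_base = bases, dna_base = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$rna_base != grid$dna_base, ]
  lookup <- setNames(rep(mismatch_penalty, nrow(grid)),
                     sprintf("%d:%s>%s", grid$position, grid$rna_base,
                             grid$dna_base))
  all_pams <- expand_pam("NNN")
  pam_lookup <- setNames(ifelse(all_pams %in% expand_pam("NGG"), 1,
                                alt_pam_penalty), all_pams)
  structure(list(mismatch = lookup, pam = pam_lookup), class = "cfd_table")
}

#' CFD score of one off-target
#'
#' Product of per-position mismatch penalties times the PAM penalty for the
#' concretely matched PAM trinucleotide. Defined only for 20-nt spacers and
#' for bulge-free alignments (the underlying empirical model covers
#' neither).
#'
#' @param query a [guide_query] or 20-nt spacer string.
#' @param off one off-target row (as returned by [enumerate_offtargets()]).
#' @param table a `cfd_table`.
#' @return CFD value in \[0, 1\].
#' @export
cfd_score <- function(query, off, table) {
  spacer <- if (inherits(query, "guide_query")) query$spacer else toupper(query)
  if (nchar(spacer) != 20)
    stop("CFD is defined only for length 20nt gRNAs")
  if (off$rna_bulges > 0 || off$dna_bulges > 0)
    stop("CFD is undefined for bulged alignments")
  stopifnot(inherits(table, "cfd_table"))
  val <- 1
  if (nzchar(off$mismatch_string)) {
    for (part in strsplit(off$mismatch_string, ";", fixed = TRUE)[[1]]) {
      p <- table$mismatch[[part]]
      if (is.null(p) || is.na(p)) stop("CFD table has no entry for ", part)
      val <- val * p
    }
  }
  pam3 <- off$pam
  if (nchar(pam3) == 3) {
    q <- table$pam[[pam3]]
    if (is.null(q) || is.na(q)) stop("CFD table has no PAM entry for ", pam3)
    val <- val * q
  }
  val
}

# vectorised CFD over parallel mismatch-string / PAM vectors
.cfd_scores <- function(mismatch_strings, pams, table) {
  n <- length(mismatch_strings)
  if (n == 0) return(numeric(0))
  val <- rep(1, n)
  parts <- strsplit(mismatch_strings, ";", fixed = TRUE)
  lens <- lengths(parts)
  has <- which(lens > 0 & nzchar(mismatch_strings))
  if (length(has)) {
    flat <- unlist(parts[has], use.names = FALSE)
    pen <- table$mismatch[flat]
    if (anyNA(pen)) stop("CFD table has no entry for ",
                         flat[is.na(pen)][1])
    idx <- rep(has, lens[has])
    for (i in seq_along(flat)) val[idx[i]] <- val[idx[i]] * pen[i]
  }
  scored_pam <- nchar(pams) == 3
  if (any(scored_pam)) {
    q <- table$pam[pams[scored_pam]]
    if (anyNA(q)) stop("CFD table has no PAM entry for ",
                       pams[scored_pam][is.na(q)][1])
    val[scored_pam] <- val[scored_pam] * q
  }
  unname(val)
}

#' Aggregate CFD values into a specificity score
#'
#' `1 / (1 + sum(cfd))`: 1 when there are no off-targets, decreasing toward
#' 0 as predicted off-target cutting accumulates.
#'
#' @param cfd numeric vector of per-off-target CFD values.
#' @return Specificity in \[0, 1\].
#' @export
specificity_from_cfd <- function(cfd) {
  stopifnot(all(cfd >= 0), all(cfd <= 1))
  1 / (1 + sum(cfd))
}

#' Specificity score of a guide
#'
#' Computes the CFD of every scorable off-target and aggregates them as
#' `1 / (1 + sum CFD)`. Scoring covers bulge-free off-targets with at most
#' `max_scored_mm` mismatches (default 3); bulged sites carry no CFD
#' definition and are excluded when `drop_bulged = TRUE`, otherwise they
#' are an error. On-target exclusion: when the query declares an on-target
#' it is assumed already excluded by enumeration; otherwise the first
#' 0-mismatch primary-PAM site in coordinate order is treated as the
#' implied on-target and excluded, so every additional perfect site is
#' penalised with its full CFD.
#'
#' @param query a [guide_query] or 20-nt spacer string.
#' @param offtargets off-target data frame from [enumerate_offtargets()].
#' @param table a `cfd_table`.
#' @param max_scored_mm score off-targets with at most this many
#'   mismatches.
#' @param drop_bulged silently exclude bulged sites instead of erroring.
#' @return A list of class `specificity_result`: `specificity`,
#'   `n_offtargets_by_distance` (counts at distances `0:max_scored_mm`),
#'   `cfd_sum`.
#' @export
specificity <- function(query, offtargets, table, max_scored_mm = 3L,
                        drop_bulged = TRUE) {
  spacer <- if (inherits(query, "guide_query")) query$spacer else toupper(query)
  if (nchar(spacer) != 20)
    stop("the specificity score is defined only for length 20nt gRNAs")
  ot <- offtargets
  bulged <- ot$rna_bulges > 0 | ot$dna_bulges > 0
  if (any(bulged)) {
    if (!drop_bulged)
      stop("off-targets with bulges present; CFD is undefined for them")
    ot <- ot[!bulged, , drop = FALSE]
  }
  ot <- ot[ot$n_mismatches <= max_scored_mm, , drop = FALSE]
  declared <- inherits(query, "guide_query") && !is.null(query$on_target)
  if (!declared && nrow(ot) > 0) {
    perfect <- which(ot$n_mismatches == 0 & ot$pam_class == "primary")
    if (length(perfect) > 0) {
      ord <- perfect[order(ot$seqnames[perfect], ot$start[perfect])]
      ot <- ot[-ord[1], , drop = FALSE]
    }
  }
  cfd <- .cfd_scores(ot$mismatch_string, ot$pam, table)
  counts <- vapply(0:max_scored_mm, function(d) sum(ot$n_mismatches == d),
                   integer(1))
  structure(list(specificity = specificity_from_cfd(cfd),
                 n_offtargets_by_distance = setNames(counts,
                                                     as.character(0:max_scored_mm)),
                 cfd_sum = sum(cfd)),
            class = "specificity_result")
}

#' 5'-G spacer variant
#'
#' The spacer with its 5'-terminal nucleotide replaced by G, matching the
#' common synthesis constraint of U6-driven guides.
#'
#' @param spacer nucleotide string.
#' @return The substituted spacer (unchanged if it already starts with G).
#' @export
five_prime_g_variant <- function(spacer) {
  if (!nzchar(spacer)) stop("spacer must be non-empty")
  paste0("G", substr(spacer, 2, nchar(spacer)))
}

#' Library ranking score
#'
#' `min(spec_g, spec_gprime, weight * efficiency)`: the score used to rank
#' guides within a gene, balancing the specificity of the guide and of its
#' 5'-G synthesis variant against cutting efficiency. The default weight
#' 1.25 lets an efficiency of 0.8 or more stop being the limiting term.
#'
#' @param spec_g specificity of the guide.
#' @param spec_gprime specificity of its 5'-G variant.
#' @param efficiency predicted cutting efficiency in \[0, 1\].
#' @param weight efficiency weight.
#' @return The score (vectorised).
#' @export
library_score <- function(spec_g, spec_gprime, efficiency, weight = 1.25) {
  stopifnot(all(spec_g >= 0 & spec_g <= 1), all(spec_gprime >= 0 & spec_gprime <= 1),
            all(efficiency >= 0 & efficiency <= 1))
  pmin(spec_g, spec_gprime, weight * efficiency)
}

#' Cutting-efficiency providers
#'
#' The efficiency model is pluggable: any function mapping a spacer (plus
#' optional genomic context) to a value in \[0, 1\]. `efficiency_from_file`
#' wraps a two-column TSV (`spacer`, `efficiency`); `toy_efficiency_model`
#' is a deterministic synthetic stand-in that hashes the spacer sequence
#' into \[0, 1\], useful for fixtures and pipeline tests but carrying no
#' biological signal.
#'
#' @param path TSV with columns `spacer` and `efficiency`.
#' @return A function `f(spacer)` returning efficiencies (NA when a spacer
#'   is absent from the file).
#' @export
efficiency_from_file <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("spacer", "efficiency") %in% names(tab)))
    stop("efficiency file needs columns 'spacer' and 'efficiency'")
  if (any(tab$efficiency < 0 | tab$efficiency > 1, na.rm = TRUE))
    stop("efficiency values must lie in [0, 1]")
  lookup <- setNames(tab$efficiency, toupper(tab$spacer))
  function(spacer) unname(lookup[toupper(spacer)])
}

#' @rdname efficiency_from_file
#' @export
toy_efficiency_model <- function() {
  function(spacer) {
    vapply(toupper(spacer), function(s) {
      codes <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
      if (anyNA(codes)) return(NA_real_)
      h <- 0
      for (c in codes) h <- (h * 31 + c) %% 100003
      h / 100002
    }, numeric(1), USE.NAMES = FALSE)
  }
}
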