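---
title: "Methods: off-target enumeration, specificity scoring and guide library design"
author: "crisprtrie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-target enumeration, specificity scoring and guide library design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtrie)
```

## The problem

A CRISPR-Cas9 guide RNA (gRNA) is programmed by a ~20-nt spacer that
base-pairs with genomic DNA next to a protospacer-adjacent motif (PAM; NGG
for SpCas9, with NAG tolerated at reduced efficiency). Cas9 also cleaves at
*off-target* sites — genomic windows that match the spacer imperfectly, with
mismatches and occasionally with single-base bulges on either strand of the
RNA:DNA duplex. Designing a usable guide therefore requires enumerating all
such sites genome-wide, summarising their predicted activity in a single
specificity score, and filtering candidate guides accordingly. `crisprtrie`
implements that workflow end to end: a compressed full-text index of the
genome, an exhaustive off-target search over it, CFD-based specificity
aggregation, genome-wide guide databases in SAM format, a gene-targeting
library filter cascade with control guides, and allele-specific design for
hybrid diploid genomes.

## Index and search model

The genome's sequences are concatenated with a separator symbol between
them and a terminator at the end, and indexed by a Burrows–Wheeler
transform (BWT) with checkpointed rank structures and a sampled suffix
array. The suffix array is built by induced sorting (SA-IS), which is
worst-case linear and therefore safe on repetitive input; construction is
deterministic, so two indexes of the same genome serialise byte-identically.
Only the forward text is indexed; minus-strand sites are found by searching
the reverse complement of the query pattern and mapping coordinates back,
which halves the index at the cost of a pure coordinate transform.

N residues are replaced by the separator symbol at index time. Because the
search alphabet is strictly `{A, C, G, T}`, no pattern can match across a
sequence boundary or through an N run; candidate windows containing N are
likewise never emitted as guides. Soft-masked (lowercase) bases are
uppercased and treated as targetable — repeat avoidance is an explicit,
separate interval filter (see the allele-specific cascade), not an implicit
property of the index.

Backward search maps a pattern suffix to a suffix-array interval; extending
the pattern by one symbol on the left is two rank queries. The set of all
reachable intervals forms an implicit reverse-prefix trie, and off-target
enumeration is a depth-first traversal of that trie with pruning: a branch
dies as soon as its interval is empty or its spent mismatch/bulge budget
exceeds the allowance. For a 3'-side PAM the traversal consumes the PAM
first (exactly — degenerate positions admit their IUPAC set, but a PAM
mismatch never spends budget), then the spacer 3'→5'. This makes the
PAM the most selective prefix of every branch and keeps the explored trie
small even at four mismatches.

### PAM semantics

Two semantics are implemented:

* **Wildcard (default).** A site counts if its PAM matches the primary or
  any alternative motif; the PAM contributes no mismatches. With NGG + NAG
  the two motifs factor exactly into the positionwise union NRG, so a
  single traversal per strand suffices and the PAM class (primary vs
  alternative) is recovered from the matched trinucleotide.
* **Legacy (`legacy_pam = TRUE`).** An alternative-PAM site consumes one
  unit of the mismatch budget, reproducing the older, more restrictive
  behaviour. Legacy results are provably a subset of wildcard results, and
  the test suite asserts strict inclusion on fixtures carrying a
  full-budget-mismatch NAG site.

### Bulge geometry

An RNA bulge is an unpaired spacer base (the genomic window is one base
shorter); a DNA bulge is an unpaired genomic base (one longer). Both may
occur in the same site, and budgets for each are independent parameters.
Two geometric conventions had to be fixed because no standard exists:

* Bulges are disallowed at the PAM-adjacent spacer position and in the gap
  between the spacer and the PAM (bulge-aware search tools conventionally
  anchor the PAM; an unanchored gap there is indistinguishable from a
  shifted site).
* Bulges are also disallowed at the 5'-terminal spacer position: a terminal
  gap is degenerate — it describes the same duplex as a shorter spacer —
  and admitting it would double-count loci.

So for a length-L spacer, an RNA bulge may sit at positions 2..L−1 and a
DNA bulge in the gaps between positions 1..L−1. A genomic locus reachable
by several alignments (common with bulges: a substitution is also
reachable as an adjacent RNA+DNA bulge pair) is reported once, keyed by
(sequence, strand, PAM coordinate) so that windows of different lengths at
the same PAM collapse. The kept alignment minimises mismatches + bulges,
with ties broken by fewer bulges, then leftmost gap placement, then primary
PAM class — a total order, so output is deterministic.

### Verification strategy

The package ships its own independent oracle, `scan_offtargets_naive()`: a
direct scan over every PAM-matching anchor on both strands that enumerates
all alignment shapes (each bulge position separately) and counts mismatches
vectorised over anchors. It shares only the *geometry contract* above with
the index-based search — no code — and is itself cross-checked against
`Biostrings::matchPattern` for the mismatch-only case. The acceptance suite
requires exact set equality between the traversal and this oracle over
twenty random genomes of 10–100 kb (fifty random plus twenty planted guides
each, mismatch budgets 0–4, NGG+NAG) and, with bulges enabled (≤2
mismatches, ≤1 RNA, ≤1 DNA bulge), over planted fixtures on ≤10 kb genomes
including sites that carry a DNA and an RNA bulge simultaneously.
`plant_sites()` closes the loop: after writing mutated sites it re-scans
the mutated genome with the oracle, so accidental background matches are
part of the truth table and can never cause spurious test failures.

## Specificity scoring

Each bulge-free off-target `o` of a 20-nt guide `g` receives a
cutting-frequency-determination (CFD) value: the product of per-position
mismatch penalties — indexed by (spacer position 1..20 from the 5' end,
spacer base, genomic base read in spacer orientation) — times a penalty for
the concretely matched PAM trinucleotide. Specificity aggregates them as

$$\mathrm{Specificity}(g) = \frac{1}{1 + \sum_{o} \mathrm{CFD}(o, g)}$$

so a guide with no predicted off-target activity scores exactly 1, and the
score decreases strictly as activity accumulates. Both CFD and specificity
are defined only for 20-nt spacers and bulge-free alignments (the
underlying empirical model covers neither); non-conforming inputs are
reported as missing, never approximated. The default scoring scope is
off-targets with at most three mismatches under primary and alternative
PAMs.

When a guide declares its intended target, that single locus is excluded
from the sum. Without a declaration, the first perfect primary-PAM site in
coordinate order is treated as the implied on-target; every additional
perfect site contributes its full CFD, so a guide with m extra perfect
sites is bounded above by 1/(1+m). (Database construction removes such
multi-mapping guides anyway; the bound matters for ad hoc queries.)

**The packaged CFD table is synthetic.** The file
`inst/extdata/cfd_table_synthetic.tsv` is generated by
`tools/make_cfd_table.R` from a smooth deterministic formula: tolerance
decays linearly from the PAM-distal 5' end (≈0.91) into the PAM-proximal
seed (≈0.11 at position 20), transitions get a small bonus over
transversions, NGG expansions score 1, NAG 0.25, NGA 0.07, NCG 0.03, other
PAMs 0. This reproduces the *qualitative* structure of empirical CFD models
— seed mismatches penalised most, alternative PAMs strongly down-weighted —
but none of their fitted values. Every numeric claim in the tests holds for
any table satisfying the validated invariants (penalties in [0,1], matches
scoring 1, NGG scoring 1); for production design the table should be
replaced, via `load_cfd_table(path)`, with one derived from empirical
mismatch data.

## Genome-wide databases

`enumerate_candidates()` lists every spacer-length window adjacent to a
primary-PAM match on either strand (N-free, deterministic order);
`build_database()` runs one off-target search per candidate with the
candidate's own locus declared as the on-target, drops candidates with any
additional perfect primary-PAM occurrence, and stores per-distance
off-target counts, specificity, efficiency, and the full off-target list in
a compact hex encoding (format version 1: a leading version byte, then 9
bytes per site — `uint64` little-endian `2·global_coordinate + strand_bit`
followed by a distance byte; all arithmetic stays below 2^53 so the R
implementation is exact). Records are emitted as headered, coordinate-sorted
SAM: POS is 1-based over the full protospacer+PAM footprint, FLAG 16 marks
the minus strand, and custom tags carry specificity (`cs:f`), efficiency
(`ds:f`, written with 17 significant digits so doubles round-trip exactly),
the spacer and observed PAM (`sp:Z`, `pc:Z`), distance counts (`oc:B:I`)
and the hex off-target payload (`of:H`). `read_sam()` inverts `write_sam()`
losslessly.

Construction parallelises over candidates only: `partition_run()` splits
the sorted candidate list round-robin, runs a worker per partition, and
merges to a result provably identical to a single-partition run. No
parallelism exists inside a traversal, so output is bitwise deterministic
regardless of the partition count — the 1-vs-7-partition equality on a
100 kb fixture is an acceptance requirement. Alternative-PAM perfect sites
are recorded as distance-0 off-targets with `pam_class = "alternative"`;
they do not disqualify a candidate but do enter its counts and score.

## Library design

The gene-targeting cascade applies, in order: (1) remove guides with any
additional 0- or 1-mismatch occurrence (counted over primary and
alternative PAM windows, consistent with how the database defines
occurrences); (2) keep guides whose cut site — 3 nt upstream of the PAM,
between spacer positions 17 and 18 — lies in a CDS; (3) cutting efficiency
≥ 0.25; (4) specificity ≥ 0.20; (5) spacer G+C content within [0.20, 0.80],
read literally from "greater than 80% or less than 20%", so boundary guides
survive, and computed over the 20-mer spacer only since that is the
synthesised sequence; (6) no run of more than three identical bases. The
per-stage survivor counts form a `filter_report` whose monotonicity is
asserted in tests; a checked-in engineered fixture
(`inst/extdata/library_fixture.*`) is constructed so that each stage
removes exactly one of twelve guides (12→11→10→9→8→7→6).

Within each gene (a guide cutting in the CDS of several genes is eligible
for each, flagged in output), up to six guides are kept. Genes with more
are ranked by

$$\mathrm{Score}(g) = \min\{\mathrm{Specificity}(g),\ \mathrm{Specificity}(g'),\ 1.25 \cdot \mathrm{Efficiency}(g)\}$$

where `g'` is the spacer with its 5' base replaced by G (the common
U6-synthesis constraint) and its specificity always comes from a fresh
search of the substituted sequence — identical to the original when the
spacer already starts with G, so the uniform rule costs nothing. The 1.25
weight makes efficiency stop being the limiting term above 0.8. Ties break
by higher specificity, then lower coordinate. Controls: non-targeting
guides are uniformly random 20-mers accepted only if they have zero genomic
windows within Hamming distance 3 on either strand (PAM-free), reproducible
under a seed; safe-targeting guides are database records whose cut site
falls in user-supplied safe-harbor intervals, passed through the applicable
cascade stages and ranked by specificity.

Efficiency is a pluggable provider — any function from spacer to [0,1].
`efficiency_from_file()` wraps a per-guide TSV (the practical route:
compute scores with an external on-target model and attach them);
`toy_efficiency_model()` is a deterministic hash into [0,1] used by
fixtures and pipeline tests, and carries no biological signal.

## Allele-specific design

For an F1 hybrid, the second allele is represented as a pseudo-genome:
`apply_variants()` applies REF-verified, non-overlapping SNPs and indels
left to right and returns a piecewise-linear coordinate map (deleted bases
are unmappable; `map_coordinate()` resolves everything else). Databases are
built per genome; a guide is allele-specific when its spacer has zero
perfect-match occurrences in the other genome. That check covers primary
*and* alternative PAMs by default (`check_alt_pam`): a SNP that degrades
NGG to NAG leaves a cuttable site on the other allele, so such guides are
conservatively rejected. Near-perfect cross-genome matches (1–3 mismatches)
are not excluded — discrimination is by perfect-match absence; they are
reported in the two-genome off-target summary instead. Survivors are
classified as `pam_variant`, `protospacer_variant` or `structural`
(fallback, e.g. a guide inside allele-private inserted sequence), and gene
annotation takes the exon containing the cut site, choosing the
lexicographically smallest gene id on overlap so output is deterministic.

The high-confidence cascade mirrors a validation-selection protocol: drop
guides with heterozygous variants (when zygosity is present); zero
2-mismatch off-targets in either genome; at most three 3-mismatch
off-targets in either genome; efficiency in the top quartile of the
surviving set; cut site at least 200 bp from any annotated repeat interval.

## Synthetic fixtures, and what passing them shows

All tests run on generated data: i.i.d. random genomes with a configurable
G+C fraction, toy annotations of non-overlapping genes, simulated diploids
(binomially thinned SNPs/indels, rejection-resampled to avoid overlap), and
planted off-target scenarios with exact truth tables. Problem sizes were
chosen so the whole suite runs in minutes on one core: 10–100 kb genomes
for the mismatch oracle, ≤10 kb for the bulge oracle, 100 kb for the
partition-equivalence database, 20–30 kb for library selection and
allele-specific fixtures. These fixtures establish algorithmic correctness
— completeness of the search, exactness of scores and filters, determinism
— on any composition of inputs. They do not emulate the repeat structure,
segmental duplication, chromatin context or mutational spectra of real
genomes, so quantities that depend on genome content (how many guides
survive a cascade, realistic specificity distributions, database sizes) are
not predicted by the tests; on real genomes the same code paths apply but
the numbers are properties of the input.

## Numerical and interface choices

* Internal coordinates are 0-based half-open everywhere; the single
  conversion to 1-based happens at SAM/GTF/VCF emission, preventing
  off-by-one drift.
* The suffix-array sample rate (default 16) trades locate speed for
  memory and provably never changes results; it is recorded in, and
  restored from, the versioned single-file index format, which embeds the
  genome text and an FNV-1a checksum so index/genome mismatches are caught.
* Traversal explores the expected (matching) base first at each depth —
  a pure performance choice that finds the 0-mismatch branch early and
  cannot affect the result set.
* The brute-force scanner supports at most one bulge of each kind per
  site; oracle comparisons therefore cap bulge budgets at one, which is
  also the regime the duplex biology supports.
* Empty inputs are contracts, not errors: empty guide files, empty
  candidate sets and empty partitions all produce empty, well-formed
  outputs.

## Limitations

Bulged sites carry no CFD definition and are enumerated but never scored;
specificity is undefined for spacers other than 20 nt. The packaged CFD
table is synthetic (above). Cut-site logic is defined for 3'-PAM nucleases
only; 5'-PAM (Cas12a-like) search is supported through a geometry flip, but
cut sites and the library cascade assume SpCas9 conventions. The
allele-specific workflow assumes a VCF of simple, non-overlapping variants
against a single reference; graph genomes and phased population VCFs are
out of scope.
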