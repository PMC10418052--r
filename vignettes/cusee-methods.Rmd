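---
title: "Methods: predicting APOBEC3A/G C-to-U editing sites and screening variants"
author: "cusee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting APOBEC3A/G C-to-U editing sites and screening variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusee)
```

## The biological problem

APOBEC3A and APOBEC3G are human cytidine deaminases that convert
cytosine to uracil (C>U) in single-stranded nucleic acids. Their
preferred RNA substrate is a stem-loop (hairpin): a base-paired stem
closing a 3–4 nucleotide loop, with the edited cytosine at the
3′-terminal position of the loop. Because a C>U edit in mRNA can change
the encoded amino acid, transient editing at high-affinity sites can
produce the same variant proteins as heritable C>T (or, on the opposite
strand, G>A) DNA polymorphisms. `cusee` predicts such editing sites
from sequence alone and screens catalogued SNPs for those whose protein
consequence could equally arise from RNA editing.

## The two primary models and their consensus

### Rules-based hairpin score

For a candidate cytosine, every stem-loop in which the C occupies the
loop's 3′ end is enumerated: loop length 3 or 4, a contiguous run of
complementary stem pairs (no bulges), all bases within a search window
of the target. Each hairpin is scored

```
total = 3·(GC pairs) + (AU pairs)
        + 2·[uracil in loop] + 2·[purine after the C]
        - 2·[guanine in loop]
```

and the site's score is the maximum over detected hairpins. A site is
called an editing site when its score is at least 10 ("greater than
nine"). The components reward stem strength (a GC pair is worth three
times an AU pair) and the sequence features enriched at known editing
sites, and penalise loop guanines.

Tunable parameters (`rules_config()`), with defaults:

* `min_stem_pairs = 3`, `max_stem_pairs = 10` — the stem must be long
  enough to plausibly fold yet short enough to search exhaustively. No
  published bounds exist for the ancestral stem-identification step,
  so both are exposed.
* `search_window = 25` nt each side — matches the feature window of
  the forest model, so both models see the same context; truncated
  silently at sequence ends.
* `allow_gu_in_stem = FALSE` — G:U wobble pairs can optionally extend
  a stem, but always score 0 because the formula prices only GC and AU
  pairs.
* `call_threshold = 10`.
* `anchor = "loop3p"` — the published description of the loop anchor
  is internally inconsistent (the methods prose says the C sits at the
  loop's 5′ end; the structural figure and introduction place it at
  the 3′ end). We follow the structural account; `anchor = "loop5p"`
  flips the convention for sensitivity analysis.
* `bonus_mode = "each"` — the "+2 for a uracil in the loop or a purine
  following the cytosine" clause is read as two independent +2
  features (max +4), since the score is described component-wise;
  `"either"` implements the single-bonus reading.

Ties between hairpins with equal totals are broken toward more GC
pairs, then the shorter loop, then the smallest loop start, purely so
that the reported best hairpin is deterministic; the score itself is
unaffected. T and U are treated as identical everywhere, so DNA-spelled
CDS files can be scored without explicit transcription.

### Random-forest classifier

The forest model classifies the 25 nucleotides around a cytosine (15
preceding, 10 following; the constant C itself is not encoded) as a
50-bit vector: per nucleotide, `isPurine` (A/G) and `pairsGC` (G/C),
so A=(1,0), G=(1,1), C=(0,1), U=(0,0). Training follows the published
regime for severely imbalanced data (roughly 468 non-editing cytosines
per editing site in the reference dataset):

1. stratified, seeded 70/30 train/test split;
2. training negatives downsampled to `downsample_ratio = 3` per
   training positive;
3. half of the kept negatives (`hard_negative_fraction = 0.5`) are the
   negatives the rules model scores highest — hard negatives that teach
   the forest to reject plausible-looking hairpins. The published
   account says only that the proportion of high-scoring negatives was
   "increased"; 0.5 is our choice, recorded in the model object.

The forest itself is 500 trees, unrestricted depth (`randomForest`
defaults otherwise), seeded so that the entire train→predict path is
reproducible. A site is called when its editing probability strictly
exceeds 0.5. Sites with insufficient flank are excluded from training
and produce an explicit no-call at prediction — zero-padding would
fabricate sequence. A SMOTE up-sampling switch exists in the
configuration for completeness but is unsupported: the published model
rejected up-sampling in favour of downsampling with hard negatives.

### Consensus and benchmarking

The union model calls a site when either primary model does; the
intersection model when both do. The benchmark protocol evaluates all
four models on a testing set (3:1 non-editing:editing) and a
proportional set that keeps the same positives and tops up seeded,
uniformly drawn negatives to 468:1. Because the positives are
identical, recall is necessarily identical between the two sets — the
package asserts this structurally rather than taking it from data.
ROC curves sweep the distinct score values (forest probability, or the
integer rules score with unscored sites ranked below all scored ones);
AUROC is the trapezoidal area, which with tied scores grouped equals
the Mann–Whitney convention of half credit for ties. Precision with
zero predicted positives is reported as `NA`, not 0.

## The variant screen

The screen consumes a tab-separated variant table in the ClinVar
`variant_summary` dialect and per-gene CDS FASTA files (CCDS
convention: sequence begins at the initiator codon; protein position
*p* spans CDS bases 3p−2..3p). Filters retain single nucleotide
variants on GRCh38 with specific, unequal single-base alleles and a
recorded, non-synonymous protein change; every excluded record is
assigned exactly one named exclusion reason, so records are conserved
across the pipeline. Clinical significance collapses to
pathogenic/benign/unspecified by case-insensitive substring matching,
with "pathogenic" taking precedence — except the phrase "conflicting
interpretations of pathogenicity", which asserts nothing and is mapped
to unspecified via an explicit exception list.

For each retained variant the recorded reference amino acid is
verified against the codon in the CDS; a mismatch discards the whole
gene (the CDS evidently does not correspond to the variant
coordinates). When several CDS records exist for a gene, the longest
one compatible with all of the gene's variants is used. The C>U
decision then enumerates the at most nine single-nucleotide changes of
the codon, keeps those producing the recorded alternate amino acid,
and requires consistency with the genomic alleles read on either
strand: a candidate matches directly for a plus-strand gene, or as its
complement for a minus-strand gene (genomic G>A ↔ coding C>T). The SNP
is a C>U site exactly when the single consistent candidate is a
coding-strand C→T. If more than one candidate survives, the record is
excluded as `ambiguous_codon_change` rather than guessed. The allele
check can be disabled (`allele_check = FALSE`) to reproduce a screen
based on the amino-acid change alone.

Each C>U site is annotated with all four model calls evaluated on the
transcribed CDS, and the screen emits the pathogenicity-bin breakdown
of the exonic, C>U, and predicted sets.

## MeSH rollup

Disease associations roll up a MeSH-style tree (`Heading;TreeNumber`
lines). A heading's level is the number of dot-separated components of
its tree number; headings with several tree numbers belong to every
lineage. Top-level counts are once-per-SNP: however many of a SNP's
conditions map to headings under the same top-level term, that term is
incremented once. Conditions with no MeSH equivalent carry the
sentinel "Not found", which behaves as its own top-level heading.
Third-level terms ("grandchildren" of top-level terms) are treated as
individual diseases; a grandchild is covered when any SNP maps to it
or to any of its descendants, and coverage is reported separately for
SNPs with and without a predicted editing site. The condition→heading
mapping is consumed as a prebuilt table; text matching of conditions
to MeSH is out of scope.

## What the synthetic generators emulate — and what they do not

`gen_hairpin_dataset()` plants designed hairpins (2–4 GC plus 0–2 AU
pairs, loop ending in the target C with a uracil and no guanine, a
loop-proximal C:G pair so a purine follows the C — designed score
always ≥ 10) in random background of configurable GC content (default
0.5), and rejection-samples negatives until the rules model makes no
call. Negatives are rejected against the rules model only: the
forest's decision boundary is data-dependent, so forest tests use
AUROC thresholds rather than exact recovery. The generator reproduces
the *geometry* of real substrates, not the sequence statistics of the
human transcriptome, expression levels, or interferon-dependent
editing rates; a perfect score on these fixtures shows the machinery
is self-consistent, not that real-data benchmark figures transfer.

`gen_variant_fixture()` builds CDSs (ATG start, no internal stop) and
a variant table whose C>U truth is known by construction, presenting
half of the planted C>U rows with minus-strand (G>A) alleles, and
appends one row per exclusion filter (deletion, GRCh37, like-to-like,
synonymous, CDS-mismatch gene). Every planted change is checked at
construction time to be uniquely resolvable, so exact recovery is the
correct expectation. `gen_mesh_fixture()` builds a regular tree whose
expected counts and coverage are computed by direct prefix arithmetic
on tree numbers, independent of the package's tree-walking rollup.

All generators are seeded, restore the caller's RNG state, and are
byte-identical under a fixed seed.

## Numerical and scale choices

Scores are exact integers; the call boundary is exactly between 9 and
10, and the forest call uses a strict inequality at 0.5, so no
floating-point tolerance enters any call. The percentage of
non-synonymous codon changes attributable to C>T/G>A is reported
half-up at one decimal (63/438 = 14.4%); stop codons count as products
(stop→stop synonymous, sense↔stop non-synonymous) — the convention
that reproduces the published figure, with the alternative (excluding
stop-origin changes) yielding 15.2%.

The shipped tests and the acceptance script use fixture sizes chosen
to exercise every property at meaningful scale while keeping a full
run inside a coffee break: ~1,000 random sequences for the
score-vs-enumeration equivalence, 286 planted positives (≈200 in the
training split) with 4:1 negatives for forest recovery, a 10,000-site
label-shuffled set for the permutation null, a 468:1 proportional set
built over 10 positives, 20-variant screen fixtures, and
3-ary/depth-4 MeSH trees.

## Known limitations

* No thermodynamic (minimum-free-energy) folding: stems are contiguous
  Watson–Crick (optionally wobble) runs; bulges, internal loops and
  pseudoknots are invisible.
* The hard-negative proportion and forest hyperparameters are
  defaults, not published values; they are recorded in the model
  object and exposed in the configuration.
* The screen resolves strand from allele complementarity, not from
  annotation; a variant whose amino-acid change is reproducible by
  several codon edits consistent with the alleles is excluded rather
  than resolved.
* Published benchmark figures (AUROC 0.962/0.892, union recall 82.8%,
  ClinVar-derived counts) depend on external datasets that are not
  shipped; the package reproduces the protocols and their structural
  invariants, and users supplying those datasets can regenerate the
  corresponding tables.
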