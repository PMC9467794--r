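---
title: "Methods: codon usage bias statistics in cubtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias statistics in cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

# The problem

Synonymous codons are not used at random. Two forces shape the departure
from uniformity: *mutational pressure*, which pushes the base composition of
all positions (visible most cleanly at synonymous third positions, where
changes are silent), and *natural selection*, which favours codons matching
the tRNA pool of highly expressed genes. cubtools implements the standard
battery used to separate these forces in comparative surveys of a single
gene across species: composition statistics, RSCU, ENC/CAI/FOP/CBI, PR2 and
neutrality analyses, ENC-plot classification, RSCU clustering, and
distance-based NJ trees — plus a synthetic CDS generator so that every stage
has deterministic, download-free test inputs.

# Counting conventions

Sequences are tokenized into consecutive triplets from position 1; the
reading frame is never inferred. The default frame policy is **strict**
(non-multiple-of-3 input is an error): a silent trim would hide annotation
errors, so trimming is opt-in. Triplets containing `N` are skipped and
reported; internal stop codons are counted with a warning rather than
rejected, because pooled RSCU tables legitimately carry a stop (`TER`)
family. Codons are stored in the DNA alphabet and reported in RNA. The
canonical reporting order sorts sense codons by second, first, then third
base with rank U < C < A < G — the column-wise reading of the classical
codon table, which is also the row order of the published survey tables the
package ships — with stops last.

The "s" subscript (GC3s, T3s, ...) always refers to the 59 sense codons of
amino acids with two or more synonyms; Met, Trp and stops are excluded.

# Composition statistics

`composition_profile()` computes whole-gene A/T and G/C over *all* counted
codons, and GC1s/GC2s/GC3s over the synonymous universe, with
GC12 = (GC1s + GC2s)/2. Two open conventions had to be fixed:

* **Per-base third-position fractions** (T3s/C3s/A3s/G3s). The default
  denominator for base B counts only synonymous codons whose family has at
  least one member ending in B (CodonW's behaviour). This is the only
  convention compatible with published survey rows whose four fractions sum
  to more than 1; a `simple` partition (the four sum to 1) is available by
  argument.
* **GC1s/GC2s universe.** The survey literature never defines whether the
  first/second-position GC is taken over all codons or the synonymous ones.
  We default to the synonymous universe for internal consistency with the
  "s" subscript and expose `s_universe = "all"` as the alternative; the
  choice cannot be validated against the shipped tables because the
  underlying accessions are not printed.

# RSCU and its averaging across species

RSCU for codon j of an n-fold family with counts X is `X_j * n / sum(X)`;
an unobserved family is *undefined* (`NA`), never 0. Cross-species tables
average the per-species RSCU arithmetically over the species where the
family is observed, while frequencies are summed. This convention — rather
than recomputing RSCU from pooled counts — is what makes every family in
the pooled table sum exactly to its degeneracy, which is the checkable
identity the shipped reference tables satisfy (the six pooled Leu values
sum to 6 within rounding). Preference flags are RSCU > 1 (preferred) and
RSCU > 2 (strong); rows carry the DAA/SAA/BCAA flavour classes used in
meat-quality work.

# ENC

Wright's effective number of codons uses family homozygosity
F = (n·Σp² − 1)/(n − 1), averaged within degeneracy classes, and
ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, capped at 61. Families with n < 2 or
F ≤ 0 are skipped; a missing threefold average (Ile unobserved) is imputed
as (F̄₂ + F̄₄)/2; any other missing class makes the statistic undefined
(`NA` with a warning). These are Wright's original recipes; the choice is
ours to fix since survey papers typically cite only ENC ranges. Note ENC is
*not* invariant under count scaling (F depends on n by design); RSCU, CAI,
FOP and CBI are.

# CAI, FOP, CBI and the reference-set problem

CAI is the geometric mean of relative-adaptiveness weights w over counted
synonymous codons, with a configurable floor (default 0.01) guarding
log 0. The survey literature frequently leaves the reference set unstated —
and the shipped tables' CAI values are explicitly treated as non-targets
here for that reason. cubtools therefore requires weights to be supplied,
and ships a data-driven builder (`reference_weights()`: w = RSCU/RSCUmax
from a user-chosen reference table). Similarly FOP and CBI need an optimal
codon set; the default is `derive_optimal_codons()` (highest mean RSCU per
family, ties broken by canonical order), with file-based external sets
supported. Indices computed with self-derived sets are comparative, not
absolute.

# PR2, neutrality, ENC plot

PR2 coordinates default to the fourfold-degenerate boxes (Ala, Gly, Pro,
Thr, Val and the fourfold halves of Leu/Ser/Arg), where third-position
changes are strictly synonymous — Sueoka's construction; `all3` is
available and the mode is recorded in the output. The neutrality analysis
is the OLS regression (and Pearson correlation) of GC12 on GC3s; p-values
use the exact t distribution on n − 2 df, and printed "0.000" values in
surveys are read as p < 0.0005, not literal zeros. The ENC plot compares
observed ENC with `expected_enc(s) = 2 + s + 29/(s² + (1−s)²)`; a point is
"on" the curve within 1e-9, otherwise below/above. Heat-map correlations
(`codon_gc3s_correlations()`) use RSCU values, the quantity displayed
alongside such heat maps; per-codon results with fewer than 3 defined pairs
or zero variance are missing entries with a reason, not errors.

# Clustering and trees

RSCU dendrograms use Euclidean distance with complete linkage by default
(the defaults of the common heat-map tooling), average linkage by flag.
Neighbor joining is implemented directly (Saitou–Nei Q-criterion) with two
documented conventions: ties in Q break toward the smallest pair in current
node order, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving the joined pair's distance.
On additive matrices the implementation reconstructs the generating
topology and branch lengths exactly (property-tested against `ape::nj` and
a cophenetic-distance check). p-distances use pairwise deletion of sites
with `N` or gaps; alignment is out of scope — NJ consumes pre-aligned
FASTA or a PHYLIP square matrix. A Robinson–Foulds comparison
(`compare_trees()`) quantifies the survey-style disagreement between RSCU
dendrograms and sequence trees.

# The synthetic generator: what it emulates, and what it does not

`generate_cds()` draws each site's amino acid from `aa_freqs` (default
uniform over the 20), then the codon within the family with probability
proportional to m(c)·exp(s·1[c ∈ optimal]), where the mutational factor
m(c) puts total weight θ on G/C-ending synonyms and 1 − θ on A/T-ending
ones, split uniformly within each class; families with only one class
(none in the standard code's multi-codon families, but the rule also covers
Ile's asymmetric 1 G/C vs 2 A/T split) use the same class-weight rule.
This is the simplest model whose no-selection limit tracks the expected-ENC
curve by construction of Wright's statistic: at θ = 0.5 every family is
uniform, and for other θ the class structure reproduces
s² + (1 − s)² homozygosity in 2-, 4- and 6-fold families. Seeds are
mandatory and the caller's RNG state is restored, so fixtures are
byte-reproducible.

`generate_species_set()` evolves one ancestral CDS along a star or a
supplied topology by per-site substitutions (uniform over the three
alternative bases; no indels, so frames and lengths are preserved). When
the topology carries branch lengths, the per-edge substitution probability
is `min(sub_prob × edge_length, 0.75)` — `sub_prob` acts as a rate per unit
branch length; on a star it is the per-branch probability directly.

Deliberate non-realisms, hence what a green test does *not* establish:
mutational pressure acts only on third-position class membership, so
synthetic GC12 carries no mutational signal and the neutrality regression
on synthetic data is uninformative (the end-to-end "mutation-dominated"
check rests on the ENC-plot rule); there is no codon-substitution model, no
indel process, no amino-acid exchange realism, and divergence ignores
selection. Stated-world defaults used by the tests: 10,000 codons for
parameter-recovery checks (|gc3s − θ| < 0.02, |ENC − expected| < 2),
2,500–4,000 codons in faster property tests, substitution probabilities
0.02–0.06 for species sets, selection strength 2 for the below-curve
signature.

# Numerical choices and degenerate inputs

Undefined values (empty families, zero denominators) propagate as `NA`
with explicit reasons; they are never coerced to 0. Tolerances: RSCU family
sums 1e-9; ENC-plot classification 1e-9; distance-matrix symmetry 1e-12.
Output TSVs print floats at 6 decimals while all comparisons happen on
full-precision objects. Correlation stages require n ≥ 3 and degrade to
"skipped" in the pipeline summary rather than failing the bundle. The run
configuration is a flat `key: value` file read with base R's `read.dcf`
(no YAML parser is required by the package's dependency footprint).

# Known limitations

* CAI/CBI/FOP against the shipped survey tables are not reproducible
  because the original reference/optimal sets are unstated; they are
  treated as non-targets.
* Exact per-base T3s/C3s/A3s/G3s equality with the shipped composition
  tables is not promised — the default denominator convention reproduces
  their >1 row-sum signature, but the upstream tool's exact rule is not
  verifiable from the printed values alone.
* The yak accession check (GC3s 0.637/0.685, ENC 48.04/44.44) needs the two
  GenBank CDS (MZ476247/MZ476248) downloaded by the user; the package
  cannot fetch or redistribute them.
* No multivariate correspondence analysis, no tAI/ENC′, no alignment, no
  bootstrap supports.
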