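---
title: "Methods: integrated miRNA-mRNA network analysis of bud dormancy release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA network analysis of bud dormancy release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mirnet` implements, as a reusable and fully testable pipeline, the
integrated small-RNA / mRNA analysis used to dissect floral bud break in
temperate woody perennials: expression screening of genes and miRNAs across
four dormancy stages (endodormancy I and II, ecodormancy, bud flush; three
biological replicates each), plant-style miRNA target prediction under six
duplex-alignment criteria, degradome (PARE) validation of predicted
cleavage sites with a five-category signal classification, weighted
co-expression network analysis with bud-break-rate trait association and
hub selection, hypergeometric term enrichment, and assembly of a
miRNA-transcription-factor regulatory network. Read alignment,
quantification from raw reads, ncRNA annotation, and novel-miRNA hairpin
discovery are upstream of this package: count and FPKM/TPM matrices,
mature miRNA sequences, transcript sequences, and degradome tag tables are
its inputs.

Because the original sequencing data live in external archives, the package
ships a synthetic-data generator (`sim_config()`, `simulate_bundle()`) that
reproduces the statistical *structure* of such a study. Every analytical
guarantee the test suite makes is a statement about data with planted,
known truth; what passes says the machinery is correct and calibrated, not
that any particular biological dataset will behave as cleanly.

# Target prediction

A mature miRNA (5'→3') is aligned against every transcript window read
3'→5'. Pairs are Watson-Crick, G:U wobble, or mismatch; the alignment score
is `#MM + 0.5·#GU + #gaps`, with G:U wobbles deliberately penalized at half
weight as is conventional for plant cleavage targets. Six conjunctive
criteria screen each duplex:

1. binding-energy ratio to the perfect duplex ≥ 74%,
2. weighted score ≤ 4,
3. at most 2 adjacent-mismatch pairs anywhere in the duplex,
4. no two consecutive mismatches within miRNA positions 2–12,
5. no mismatch at positions 10–11 (the cleavage-defining pair),
6. weighted mismatches within positions 2–12 ≤ 2.5.

Positions are 1-based from the miRNA 5' end. Two readings deserve note.
The adjacent-mismatch rule (3) is counted as the number of adjacent
mismatch *pairs* duplex-wide, with rule (4) separately forbidding any such
pair inside positions 2–12; rules (2) and (6) are treated as independent
conjunctive filters. These are documented package choices between
plausible readings of a compound rule set, not claims about intent.

**Energy model.** No folding engine is attached to the criteria; instead a
deterministic stacking-free per-pair model is used: G/C pair −3, A/U pair
−2, G:U wobble −1, mismatch/gap 0 (arbitrary units). Criterion 1 is a
*ratio* against the perfect duplex of the same miRNA, which makes it
largely insensitive to affine rescaling of the energies; the 74% threshold
is kept as the screening default. This makes criterion 1 exact and
testable at the cost of ignoring stacking context, which a thermodynamic
folding model would capture.

**Gaps.** The printed criteria mention no gaps. `align_duplex()` accepts at
most one bulge (`max_gaps = 1`, the common plant-target practice), placed
to maximize Watson-Crick pairs with leftmost tie-breaking; a gap counts 1
toward the score and as a mismatch for every positional rule. The shipped
pipeline profile scans ungapped (`max_gaps = 0`), which reproduces the
criteria exactly as printed; gapped scanning is one switch away.

Overlapping passing windows of a pair collapse to the lowest-scoring one
(ties to the smallest start). The reported cleavage site is the transcript
coordinate paired with miRNA position 10.

# Degradome validation

Degradome 5'-end tag counts are summed per transcript position
(`build_profile()`). A predicted site is classified by comparing the count
`s` at its cleavage position with the transcript-wide maximum `M` and the
median `med` of *nonzero* positions — degradome profiles are sparse, and a
median over all positions would be zero almost everywhere:

- category 4: `s = 1` (single read),
- category 0: `s = M`, unique maximum,
- category 1: `s = M`, shared maximum,
- category 2: `med < s < M`,
- category 3: `1 < s ≤ med`,
- no call when `s = 0`.

These are the category conventions of the standard degradome pipeline the
field uses; they are isolated in `classify_category()` so an alternative
definition is a one-function substitution. A site is *kept* as a true
target when its category is ≤ 2, its duplex score is ≤ 4, and positions
10–11 are mismatch-free. The keep threshold is configurable because
published target tables sometimes retain category-3/4 sites; the package
defaults to the stricter ≤ 2 rule and leaves relaxation to the caller. A
±1-nt tolerance window around the expected cleavage position is available
but off by default.

# Expression screening

miRNA tag counts are normalized as `TPM = count / library total × 1e6` (no
length term — tags are single-species counts). Differential expression
uses a negative-binomial Wald screen: median-of-ratios library
normalization (column totals when no all-positive reference exists),
pseudocount 0.5, per-entity method-of-moments dispersion floored at 1e-4,
moderated toward the dataset median with 4 prior degrees of freedom, and a
t reference with `nA + nB − 2 + 4` degrees of freedom. The moderation is
the package's small-sample design: at three replicates the raw
method-of-moments dispersion is far too unstable to test against, and a
plain normal reference is anticonservative (measured null false-positive
rate ≈ 0.12 versus ≈ 0.04 with moderation). Thresholds follow the study
profile: genes `|log2FC| > 1.5` with adjusted `P < 0.05` (strict
inequality), miRNAs `log2FC ≥ 1` with FDR `< 0.05` (inclusive), applied
between adjacent stages. The exact DESeq-style machinery of the original
analysis is not re-implemented; the contribution this package carries is
the thresholds and the downstream integration, and the screen's null
calibration and power are themselves under test.

# Co-expression networks

Entities are filtered (expression ≥ 2 in ≥ 70% of samples, SD > 0.25),
then correlated with Pearson's r. The pipeline correlates `log2(x + 1)`
transformed abundances — standard network practice; raw-scale correlation
of log-normal abundances would be dominated by the heaviest-expressed
samples. Adjacency is unsigned, `|r|^β`, with soft powers 9 (genes) and 8
(miRNAs) from the study profile; a signed variant is a flag. The
topological overlap matrix follows the usual shared-neighbor formula and
is verified against an O(n³) triple-loop oracle.

Modules come from average-linkage clustering on `1 − TOM` with a *static*
cut (default height 0.99), branches below the 50-member minimum pooling
into grey. The full dynamic hybrid tree cut is intentionally replaced by
this deterministic variant: it is reproducible, easily tested, and
adequate at desk scale. Two refinements keep the static cut honest:
modules whose eigengenes correlate at ≥ 0.8 are iteratively merged
(highest pair first, eigengenes recomputed), and members whose module
membership (kME) fails a correlation t-test at p < 0.05 are returned to
grey — average-linkage branches under a fixed cut otherwise absorb
unconnected entities. Module labels are assigned from a fixed color
palette in size order, so naming is reproducible but the specific colors
carry no meaning.

Eigengenes are the unit-variance first principal component of the
standardized member profiles, sign-oriented so members correlate
positively on average. Trait association is the Pearson correlation of
eigengene and trait with a t-distribution p-value; hubs are the top 0.1%
of members by kME (always at least one, ties broken by id).

# Enrichment

Term enrichment uses the upper-tail hypergeometric probability
`P = 1 − Σ_{i<m} C(M,i)·C(N−M,n−i)/C(N,n)` with Benjamini-Hochberg FDR
across tested terms and a default significance cut of FDR ≤ 0.05 (the
inclusive reading of the threshold). Terms with no candidate overlap are
excluded from testing rather than diluting the FDR. The background
defaults to the annotation universe and is overridable; no ontology-graph
propagation is applied — annotations are taken as flat sets.

# Network assembly

Validated, differentially expressed miRNAs targeting annotated
transcription factors inside trait-associated modules form directed
targeting edges; each TF brings its `k` most correlated module genes
(default `k = 10`, a package choice — "most connected" is read as highest
`|r|` to the focus gene) as undirected co-expression edges. TF identity
comes from a user-supplied annotation table; the families expected in this
system (MADS, AP2/ERF, HD-ZIP, SBP, GRAS, TCP, MYB, NAC, ARF, GRF) are a
vocabulary, not hard-coded biology. Exports are SIF, node/edge attribute
tables, and GraphML, all Cytoscape-loadable.

# Phenology

Chilling hours count hourly readings in the `(0, 7.2]` °C band — the lower
bound exclusive so frozen hours do not accumulate, the upper inclusive;
both bounds and their openness are configurable since the printed range
notation is ambiguous. Missing hours are skipped and reported, never
interpolated. The endodormancy release date is the earliest observation
with bud break rate ≥ 50%. Relative qPCR expression follows 2^−ΔΔCt; the
calibrator sample is exactly 1 by construction.

# The synthetic-data generator

`simulate_bundle()` draws everything from one seeded stream in a fixed
order, so identical configurations are byte-identical. What it emulates,
and how the defaults were chosen:

- **Design**: 4 stages × 3 replicates; 600 genes of which three planted
  modules of 150 share stage-structured latent factors and 150 are
  unstructured noise. Latent factors are orthogonalized across modules —
  with only four stages, independently drawn stage profiles collide by
  chance — and the trait (bud break rate proxy) is the trait module's
  factor plus 10% noise, keeping its module-trait |r| ≥ 0.9 detectable.
- **Correlation target**: members mix factor and noise so that the
  *realized* log2-scale pairwise correlation matches `within_module_cor`
  (default 0.8); the mixing weight compensates for count-noise attenuation
  explicitly.
- **Counts**: negative-binomial around FPKM-derived means (dispersion
  0.05, log2 FPKM means uniform on 5–9, library sizes 1.5–2.5 million) —
  conventional bulk RNA-seq values; the study reports none. FPKM is
  recomputed from the realized counts with the true transcript lengths so
  the expression filters are exercised end to end.
- **Planted hubs**: the first member of each module is a noiseless,
  high-expression copy of the latent factor, giving the top-kME rule an
  unambiguous ground truth at twelve samples.
- **Planted DE**: 50 genes from the noise pool carry a single-stage
  8-fold bump (log2 effect 3), cycling over the non-initial stages with
  alternating sign so planted effects touch every adjacent comparison
  without forming a correlated block that the network stage would pick up
  as a spurious module; their latent noise is suppressed so the realized
  fold change is the planted effect plus counting noise. Planted-edge
  miRNAs carry the same kind of bump at log2 effect 3.
- **Planted sites**: each descriptor embeds the reverse complement of a
  generated miRNA in a random background transcript (uniform A/C/G/U,
  lengths 300–600 nt) and perturbs stated miRNA positions into mismatches
  (target base set equal to the miRNA base) or G:U wobbles. The default
  set holds 50 compliant sites and 50 single-criterion violators (≥ 8 per
  criterion); violator compositions force only the bases their violation
  needs (e.g. A/U at mismatch positions to keep the energy ratio
  criterion satisfied, or G-bases under wobbles to break it), leaving the
  rest random so planted miRNAs do not cross-react with other sites. The
  truth table's criterion flags are computed by a separate literal
  rule application, so generator and alignment engine audit each other.
- **Degradome**: validated sites receive a 50-tag 5'-end peak at the
  position paired with miRNA position 10; background positions carry
  Poisson(0.2) noise that never lands on a planted position, so peak
  height alone controls the planted category.

What the generator does *not* emulate: sequencing adapters and quality
profiles, ncRNA contamination, multi-mapping, isoform structure,
GC-dependent biases, batch effects, or annotation incompleteness. Chance
background windows that genuinely satisfy all six criteria do occur in
random sequence — the scan reports them, as it should; they carry no
degradome peak and are dropped at validation.

# Numerical and policy choices

- Ties everywhere break deterministically (leftmost gap, lowest score then
  smallest start, lexicographic ids), so reruns are identical.
- `hypergeom_p()` computes the printed finite sum in log space; it agrees
  with the distribution function to 1e-12 and with complete enumeration on
  small universes.
- The DE screen's pseudocount (0.5), dispersion floor (1e-4) and prior
  degrees of freedom (4) are package constants documented at the function;
  exact DEG counts from the original study are not reproducible from
  matrices alone and are not targets.
- Problem sizes in the tests (600-gene networks, 2-kb scan transcripts,
  2000-gene null screens, 1000-replicate enrichment nulls) were chosen as
  the smallest sizes at which the planted structure is comfortably
  identifiable; they run on a laptop in minutes.

# Known limitations

- The energy model ignores stacking and loop entropies; criterion-1
  decisions near the 74% boundary can differ from folding-based tools.
- The static tree cut needs a sensible `cut_height` for very noisy data;
  the dynamic hybrid algorithm it replaces adapts per branch.
- The DE screen is a calibrated screen, not a shrinkage estimator;
  borderline effects at three replicates are conservatively called.
- Degradome validation is prediction-guided only; it does not discover
  cleavage sites without a predicted duplex.
- miRNA co-expression networks on a few hundred miRNAs with the 50-member
  minimum module size frequently return only grey — the parameters are
  exposed rather than silently adapted.
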