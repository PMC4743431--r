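---
title: "Tag-based digital gene expression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based digital gene expression (DGE) counts transcripts by sequencing
one short tag per cDNA molecule instead of the whole molecule. The library
chemistry anchors each tag at an NlaIII restriction site: NlaIII cuts at
CATG, and a type IIS enzyme (MmeI) then cuts 17 bp downstream, so every
genuine tag is a 21-mer of the form CATG + 17 nt taken from a transcript.
Gene expression is estimated by counting how many sequenced tags originate
from each gene.

`tagdge` implements that pipeline end to end:

1. **Cleaning** (`clean_tags`): raw reads are filtered in a fixed order —
   empty reads, adaptor reads (exact prefix match), reads containing `N`
   ("low quality" in the tag-sequencing sense), reads of abnormal length,
   and finally, after collapsing to distinct sequences, tags seen only once
   (singletons). The order is a design choice of this package: the filter
   list is standard but its precedence is usually unstated, and fixing it
   makes every removed read count in exactly one category so the audit
   table is reproducible.
2. **Virtual tag library** (`build_index`): every CATG with at least 17 nt
   downstream on a reference transcript defines a virtual tag; the index is
   the exhaustive map from 21-mer to the genes carrying it. Sites whose
   window contains `N` are skipped. Site ranks count from the 3' end
   (rank 0 = 3'-most) because the MmeI chemistry sequences the 3'-most site
   preferentially.
3. **Mapping** (`map_tags`): a clean tag is assigned the gene set of its
   exact index key, or, failing that, the union of gene sets over its 63
   Hamming-distance-1 neighbours. One gene = unambiguous, several =
   ambiguous, none = unknown. Exact hits suppress the mismatch
   neighbourhood — without that priority a perfectly matching tag could be
   declared ambiguous by a near-neighbour, which would be absurd.
   Ambiguity is decided at the gene level: a tag hitting two sites of the
   same gene is still unambiguous. Mismatches are allowed at any of the 21
   positions, including the CATG anchor, by default; `mismatch_positions`
   can confine them to the 17-nt variable region.
4. **Quantification** (`quantify`): only unambiguous tags contribute; a
   gene's expression is its summed tag copies, normalized to TPM = copies
   per million *clean* tags. The denominator is deliberately the clean
   total, not the mapped total — "per million clean tags" is the
   conventional definition — so library TPMs sum to less than one million
   when some tags fail to map. Tags here are fixed-length, so no
   gene-length correction applies (this TPM is a tag frequency, not the
   RNA-seq transcripts-per-million of length-normalizing estimators).

## The exact test for differential expression

Two libraries are compared per gene on raw unambiguous counts with the
Audic–Claverie exact test. Given `x` copies in a library of `N1` clean tags,
the probability of `y` copies in a library of `N2` is

$$
p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\bigl(1+N_2/N_1\bigr)^{x+y+1}} ,
$$

a proper distribution over `y` (it is a negative binomial with size
$x+1$ and success probability $N_1/(N_1+N_2)$ — the test-suite exploits
this identity as an independent numerical oracle). `ac_probability`
evaluates it in log space; `ac_two_sided_p` doubles the smaller tail,
capped at 1. Sidedness is a choice: doubling the smaller tail is the
default, and a `minlike` alternative (sum of all outcomes at most as
probable as the observed one) is available. Genes with zero counts in both
libraries are excluded before the Benjamini–Hochberg correction so they do
not dilute the FDR. A gene is called differentially expressed at
`fdr <= 0.001` and `|log2Ratio| >= 1` (at least 2-fold), the rigorous
thresholds conventional for single-library DGE comparisons.

Two numerical facts discovered while validating are worth recording.
First, $p(y\mid x, N_1, N_2) = (N_1/N_2)\, p(x \mid y, N_2, N_1)$: the
conditional is symmetric under exchanging the two observations only when
the libraries are the same size. Second, the doubled-tail two-sided
p-value of a *discrete* test is not exactly invariant under swapping the
libraries — the observed point lands in a different tail, which can move p
by up to a factor of 2 at extreme counts (e.g. $x=0,y=20$ at equal sizes
gives $2^{-19}$ one way and $2^{-20}$ the other). Signs, up/down calls and
ranks are exchange-stable; the p-values agree within that discreteness
bound.

The `log2Ratio` is computed on TPM; when a gene is detected in exactly one
library, the zero side is floored at a pseudo-TPM of 0.001 so the ratio
stays finite while genes expressed in both libraries remain exact. The
floor's value only affects genes that would otherwise be at infinity; any
such gene with a significant FDR clears the 2-fold threshold regardless.

## Term enrichment

Enrichment of a DEG set against flat annotations (GO-style CC/MF/BP
classes and pathways) uses the hypergeometric upper tail

$$
P \;=\; 1-\sum_{i=0}^{m-1}\frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},
$$

where `N` is the number of genes with at least one annotation in the
tested ontology (the universe), `n` the annotated DEGs, `M` the genes
annotated to the term, and `m` the annotated DEGs in the term. The package
evaluates the complementary sum $\sum_{i \ge m}$ directly in log space —
mathematically identical, numerically stable when `P` is small. The
corrected value `Q` is Benjamini–Hochberg within each ontology
(Bonferroni behind a flag); `significant` means `Q <= 0.05`. Terms are
independent labels: no ontology-graph propagation is performed, and
pre-propagated annotations are accepted as input. With a discrete test the
null probability of `P <= 0.05` is at most, and usually below, 0.05; the
calibration test accounts for that conservatism.

## qPCR arithmetic

`relative_level` implements $2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = (Ct_\text{target}-Ct_\text{ref})_\text{treated} -
(Ct_\text{target}-Ct_\text{ref})_\text{control}$; replicate Ct values are
averaged before the difference (`qpcr_relative_table`), and variance
propagation and amplification-efficiency correction are out of scope.
`concordance` summarizes agreement with DGE ratios as the sign-agreement
fraction and a Spearman correlation.

## The synthetic study

The generator (`synthetic_config` and friends) exists so the whole
pipeline can be exercised with known truth and no downloads. What it
emulates, per library:

- **Reference**: i.i.d. uniform transcripts, 300–3000 nt by default; a
  CATG site with 17 nt of room is implanted where a transcript happens to
  lack one, so at least `taggable_fraction` (default 0.98) of genes are
  taggable.
- **Expression**: baseline weights log-uniform over three decades
  (`baseline_mean_log10_range = c(0, 3)`), matching the empirical shape of
  tag libraries where ~70% of distinct tags sit below 10 copies. A
  `de_fraction` (default 0.1) of taggable genes get a fold change from
  `de_fold_changes` (default 0.25/0.5/2/4) in every treated library; all
  other genes have fold change exactly 1.
- **Counts**: per-gene rates receive multiplicative gamma noise with shape
  `1/dispersion` (variance $\mu + \phi\mu^2$, the negative-binomial
  parameterization; default $\phi = 0.1$, a mild biological-replicate
  level), and reads are then allocated multinomially so the library total
  equals `library_depth` *exactly* — the gamma–multinomial construction
  reconciles NB-distributed counts with an exact total. `dispersion = 0`
  degenerates to multinomial (Poisson-like) sampling.
- **Reads**: each genuine read is one of its gene's virtual tags — the
  3'-most site with probability `three_prime_weight` (default 0.8,
  reflecting MmeI chemistry; there is no published per-site bias to copy,
  so this is our choice and it is configurable), the remaining sites
  uniformly — with i.i.d. per-base substitution errors at `error_rate`
  (default 0.005). Artifact reads (adaptor-only, N-containing,
  abnormal-length, empty) are injected per read at `artifact_rates`;
  singletons are *not* injected — they arise naturally from sampling and
  sequencing error, as in real libraries. Default depth is $10^5$ raw
  tags, a scaled-down stand-in for the several-million-tag libraries of
  real experiments; the analysis drivers use $2\times10^5$ and the
  operating-characteristic checks $10^5$–$10^6$.
- **Seeds**: one master seed; reference, truth, annotation and each
  library draw from deterministically derived child seeds, so any library
  can be regenerated independently and identical configurations give
  byte-identical outputs.

What it does **not** emulate: PCR amplification bias, GC bias, base-quality
distributions, positional error profiles, or annotation structure
correlated with expression. Passing tests therefore demonstrate the
pipeline's arithmetic and its operating characteristics under its own
sampling assumptions — not robustness to every artifact of a real
sequencer.

## Operating characteristics, and a deliberate limitation

The type-I calibration and spiked-recovery checks run the full pipeline at
`dispersion = 0`, `error_rate = 0` and zero artifact rates: the
Audic–Claverie test models *sampling* variation only, so its nominal
behaviour is measured under that model. Under it, null libraries of 2,000
genes at depth $10^5$ yield essentially no calls at FDR ≤ 0.05 and
fewer than one false call per run at FDR ≤ 0.001, and spiked 4-fold genes
with control counts ≥ 100 at depth $10^6$ are recovered with sensitivity
≥ 0.9 and correct signs.

With biological overdispersion the same test is *anticonservative*: the
analysis drivers, run at the default `dispersion = 0.1`, show a
substantial excess of calls over the spiked truth. That is a faithful
property of the single-library exact-test methodology itself — it has no
replicate-based dispersion estimate, which is precisely why modern designs
prefer replicated negative-binomial models. Reproducing that methodology,
not improving on it, is this package's scope; the simulator's dispersion
knob is what makes the limitation measurable.

## Numerical choices and degenerate inputs

- Tail sums of the exact test are computed by direct log-space summation
  with a log-sum-exp reduction; the upper tail extends until terms fall 40
  nats below the running maximum (further terms cannot move a double).
- `hypergeom_upper_tail` refuses inconsistent arguments
  (`m > min(n, M)`, `M > N`, `n > N`) rather than clamping.
- Empty read sets clean to an empty table with zero statistics (not an
  error); an all-zero library is an error at quantification, where it
  first matters.
- Copy-number bins must partition `[2, Inf)` exactly; overlaps or gaps are
  configuration errors.
- Fold-change bins treat the boundary inclusively on the extreme bins
  (FC = 5 is "≥ 5-fold up" when the boundary is 5).
- BH ties follow the step-up definition with no randomization.
- A requested DE fraction exceeding the number of taggable genes warns and
  assigns DE only to taggable genes.

## Problem sizes

Tests and the acceptance script run the generator at $10^4$–$10^6$ reads
per library and 40–2,000 genes — sizes chosen so the full suite completes
in about a minute while every stochastic check retains comfortable
statistical margin (binomial standard errors are computed alongside each
tolerance in the tests). The exhaustive oracles sweep all
$x, y \le 50$ at three library-size ratios for the exact test and every
valid hypergeometric configuration with $N \le 12$.
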