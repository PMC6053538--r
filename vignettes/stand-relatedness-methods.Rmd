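---
title: "Methods: simulating and analysing a mixed oak stand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a mixed oak stand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`standkin` is built around one study design: a natural mixed stand of two
hybridizing sister tree species (the *Quercus petraea* / *Q. robur*
situation), genotyped at thousands of SNPs obtained by targeted sequence
capture, with a handful of pedigree-known sibling relationships available
as ground truth, and two fitness proxies (reproductive success and stem
circumference) measured on century-old adults. This vignette documents the
models behind each module, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based tests do and do not
demonstrate about real data.

## The synthetic stand

### Species divergence

Per-site allele frequencies for the two species come from the
Balding–Nichols construction: an ancestral frequency $p$ is drawn uniformly
on $[0.05, 0.95]$ and each species' frequency is an independent draw from
$\mathrm{Beta}\big(p\,\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which has
mean $p$ and variance $F\,p(1-p)$. The single knob $F$
(`fst`, default 0.07 in the pipeline configuration, matching the magnitude
of genome-wide differentiation between closely related white oaks) controls
the expected Weir–Cockerham $F_{ST}$ pooled over loci. The per-locus
$F_{ST}$ distribution that results is L-shaped — most loci nearly
undifferentiated, a thin tail of strongly differentiated ones — which is the
qualitative pattern this model is chosen to reproduce. Frequencies are never
clipped: loci may drift to fixation in one species by chance, as in real
data.

### Pedigree and gene dropping

`build_pedigree()` produces unrelated founders per species plus offspring
families in the four relationship categories observable among sibling pairs
in such stands — parent–offspring by selfing (expected additive
relationship 1), parent–offspring (0.5), full sibs (0.5) and half sibs
(0.25). Founders are allocated to families without reuse so no incidental
relatedness contaminates the categories. `drop_genotypes()` draws founder
alleles Hardy–Weinberg from the species frequencies and transmits one
allele per parent per locus (Mendelian gene dropping); `admixed` founders
use the mid-point of the two species' frequencies — a deliberately crude
stand-in, adequate because the study design excludes admixed trees from
species-level analyses.

### Read counts and genotype calling

Depth per individual × site is negative binomial with mean `mean_depth`
(default 97×, a realistic capture depth) and size `depth_dispersion`
(default 5): capture experiments show large run-to-run depth variation, so
overdispersion is a first-class knob. Alternate-allele reads are binomial
with success probability `error_rate`, 0.5, or `1 − error_rate` according
to the true genotype. The caller then applies the two rules the design is
meant to exercise: calls require depth ≥ 10, and a heterozygote requires an
intra-individual allele-read fraction of at least 30% (boundary inclusive:
a fraction of exactly 0.30 calls a heterozygote; this resolves an ambiguity
the thresholds alone leave open, and is pinned by a test). At depth exactly
10 and zero error, the probability that a true heterozygote passes the 30%
rule is the binomial mass $P(3 \le \mathrm{Bin}(10, 0.5) \le 7) = 0.891$ —
the test suite checks the caller against this enumeration.

### Fitness traits

Five environmental covariates follow a one-factor model
($\mathrm{env}_j = \lambda_j Z + \sqrt{1-\lambda_j^2}\,\varepsilon$); the
factor $Z$ is what the analysis recovers as PC1. The study never names the
five variables, so the loadings are generic (0.9–0.5). Reproductive success
is $\mathrm{Poisson}(\exp(\alpha + \beta_1 Z + \gamma I))$ with defaults
$\alpha = \log 9$ (a few surviving offspring per adult over a regeneration
episode), $\beta_1 = 0.2$, and $\gamma = -3.6$ — the magnitude reported for
the species in which reproductive-success inbreeding depression was
detectable. Circumference is linear in $Z$, $I$ and age (ages uniform on
78–102 years, centered at 90), with residual SD `noise` (default 20 cm);
`noise = 0` makes it an exact linear function, which the tests exploit.

## Capture-target design

Target selection mirrors capture design in a TE-rich genome. Genes under
1.5 kb get one 150 bp exonic target; longer genes are cut into thirds and
get two targets in the extreme thirds, one exonic and one spanning an
intron–exon boundary. Where the design rule is silent the package takes a
position and documents it:

* a single-exon long gene has no junction; it receives a second exonic
  target in the opposite extreme third (logged in the `"fallback"`
  attribute);
* if the default arrangement (exon target in the first third, junction in
  the last) is infeasible, the swapped arrangement is tried before the
  fallback;
* GC bounds 30–60% are inclusive at both ends;
* "fewer than 10 alignments" is counted by a self-contained approximate
  matcher: full-length matches at ≥ 90% identity (mismatches only), found
  by k-mer seeding — the query is cut into `max_mismatch + 1` consecutive
  seeds so any qualifying match contains an exact seed (pigeonhole), and
  candidates are verified by Hamming distance. Both strands are counted; a
  unique sequence scores 1 (its own locus). The mismatch budget is computed
  as $L - \lceil 0.9\,L \rceil$ to avoid floating-point edge effects at
  identity boundaries;
* intergenic candidates are placed at the start of each empty 100 kb
  window and shifted downstream in 150 bp steps while they overlap a TE
  *or a gene* (the second condition keeps "intergenic" truthful; the
  window yields nothing if exhausted, and this is logged);
* probes are 120 bp; "one or two non-overlapping probes per target" is
  resolved by arithmetic — a 150 bp target fits only one, targets of
  ≥ 240 bp get one at each end.

All intervals are 0-based half-open internally (BED convention); GFF3 is
converted on read/write.

## Capture QC

"On target" means ≥ 1 bp of overlap by default, since published on-target
percentages rarely state an overlap rule; a full-containment mode is a
flag. Breadth (fraction of target bases covered ≥ 1×) and mean depth come
from a run-length pileup and are tested against a naive per-base oracle.
Replicate concordance treats a within-individual SNP as a heterozygous
call, reports SNPs per replicate, SNPs common to both, and identical
alleles among the common ones; with strictly diallelic simulated data two
common heterozygotes always agree, so the "different alleles" column is
only informative for multi-allelic inputs — the pooled identical-allele
fraction over published replicate counts is computed by
`concordance_from_counts()`. All-site similarity is restricted to sites
covered ≥ 20× in both replicates, the depth floor quoted for
monomorphic-site comparisons, exposed as a flag.

## Filtering cascade

The cascade order is fixed: call → polymorphism screen (≥ 1 heterozygote —
sites segregating only the two homozygote classes do not qualify under the
literal within-individual definition) → drop individuals with > 20%
missingness → drop sites with call rate < 95% or on unanchored scaffolds.
Analysis branches then choose among: the Hardy–Weinberg exact test (sites
retained when the FDR-adjusted p exceeds 0.05), LD pruning (greedy,
left-to-right within a 50-marker window at $r^2 > 0.4$, computed as the
squared genotypic correlation on the −1/0/1 codes — the original workflow
pruned phased data, which the simulator does not produce; the earlier
marker of an offending pair always survives, making the result
deterministic and order-stable), 1,000 bp spacing pruning, and maf tiers
(strictly greater than the tier, per "exceeding"). Each stage removes rows
or columns and never edits calls.

The HWE test enumerates every feasible heterozygote count conditional on
the allele counts and sums probabilities no greater than the observed
configuration's (with a `1 + 1e-9` tie tolerance); it is verified against
an exhaustive pairing enumeration at tiny $n$ and an independent
ratio-recurrence implementation up to $n = 200$, and shown
uniform-conservative under a simulated null.

## Relatedness and inbreeding

The genomic relationship matrix is
$$G = \frac{(M - P)(M - P)'}{2\sum_i p_i (1 - p_i)},$$
with genotypes $M$ coded −1/0/+1 and column $i$ of $P$ equal to
$2(p_i - 0.5)$. One reading note is worth stating prominently: the
centering term is sometimes printed as $2(p_i \pm 0.5)$; only the minus
sign centers $M$ to mean zero under Hardy–Weinberg, so that is what is
implemented, with $p_i$ the frequency of the allele coded +1 (not folded
to minor — folding would break orientation consistency). Missing genotypes
are imputed to the locus mean $2p_i - 1$ before centering (contributing
zero); a pairwise-complete mode exists behind a flag. Genomic inbreeding
is $G_{ii} - 1$.

Frequencies are estimated in-sample by default. In a sample containing
relatives this induces the well-documented slight downward bias of
realized relatedness against pedigree expectation, and pushes the mean
off-diagonal to approximately $-1/(n-1)$ rather than 0; the
parameter-recovery suite (100 simulated stands, 10,000 markers, maf tier
0.01) verifies both the closeness (category means within ±0.05 of 0.25 /
0.5 / 1) and the sign of the bias, and that 82-marker panels scatter far
more than 10,000-marker panels. A known-truth frequency mode is available
for simulation studies.

The pedigree expectation $A$ uses the recursive tabular method and is
checked exhaustively against a recursive-kinship oracle on small
pedigrees.

## Species structure

Per-locus $F_{ST}$ is the Weir–Cockerham (1984) variance-components
estimator computed from genotype counts, with mean, median and pooled
(ratio-of-sums) summaries; a locus with no data in one group is an error,
so callers filter first. Assignment uses a two-cluster maximum-likelihood
admixture model (each allele copy originates from cluster A with
probability $q_i$) — a deliberately lightweight surrogate for the
variational program used in the original workflow, adequate because only
$q$ with coarse 0.9/0.1 thresholds is consumed downstream. Two standard
remedies for EM's slow crawl toward the $q$ boundaries are built in:
initialization from a PC1 split of the dosage matrix, and SQUAREM-type
squared extrapolation with fallback to the plain double EM step whenever
extrapolation would lower the likelihood (the trace therefore stays
monotone, which is asserted in tests). Convergence is declared when the
log-likelihood gain drops below $10^{-8}(1 + |\ell|)$, within 1,000
accelerated cycles. Cluster labels are arbitrary; the pipeline aligns them
to the simulated truth by majority vote before reporting concordance.
Identical cluster frequencies leave $q$ unidentifiable and surface as a
flat likelihood trace, which is flagged.

## Inbreeding–fitness regressions

Reproductive success is regressed on PC1 of the standardized environmental
covariates (sign fixed by a non-negative first loading) and inbreeding via
a Poisson log-link GLM (IRLS as implemented in `stats::glm`); covariates
are centered so the intercept sits at the phenotypic-mean scale, and the
tests assert that centering leaves slopes, standard errors and p-values
unchanged. Circumference uses OLS with age added. Wald z (Poisson) and t
(linear) two-sided p-values and 95% CIs are reported. The recovery suite
shows $\gamma = -3.6$ at $n = 150$ is covered by its 95% CI in ≥ 90% of
replicates and that the null type-I error is near nominal. Individuals
with extreme genomic inbreeding (> 0.5) are discarded before fitting, the
same pragmatic outlier rule used in the motivating analysis; the package
discards before the PCA and fit.

## Pipeline, problem sizes, and what the tests show

`run_pipeline()` chains all stages under one seeded configuration and
writes plain-text artifacts plus a checksummed manifest, so identical
configurations yield byte-identical outputs. Default problem sizes (138
trees, 5,000 markers, 1 Mb toy genome; test fixtures smaller still) were
chosen so the whole suite runs in minutes on a laptop core while keeping
every statistical check comfortably powered; they are package choices, not
statements about the scale of real capture experiments.

Passing tests demonstrate internal correctness (estimators match oracles,
rules match their definitions, recovery works under the generator's
assumptions). They do not demonstrate robustness to what the generator
omits: mapping and alignment artefacts, paralog collapse in a duplicated
genome, reference bias, batch effects between sequencing runs,
multi-allelic and indel variation, linkage (markers are simulated
unlinked, so LD pruning is exercised only by planted correlation), or
genuine admixture pedigrees. Conclusions about real stands should lean on
the published analyses; this package reproduces their machinery, not
their data.
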