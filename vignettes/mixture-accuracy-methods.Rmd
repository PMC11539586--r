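---
title: "Methods: simulating the accuracy of DNA mixture interpretation across groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the accuracy of DNA mixture interpretation across groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamixr)
```

## The question

Forensic DNA mixture interpretation asks whether a person of interest (POI)
contributed to a multi-person DNA sample, summarised by a likelihood ratio

$$\mathrm{LR} = \frac{P(G \mid H_p)}{P(G \mid H_d)},$$

where $G$ is the observed mixture profile, $H_p$ the prosecution hypothesis
that the POI contributed, and $H_d$ the defense hypothesis that an unknown
individual contributed instead. Both hypotheses are evaluated against a
*reference* allele-frequency distribution. Groups of humans differ in their
STR allele-frequency distributions, and in particular in their genetic
diversity (average expected heterozygosity,
$\bar H = \frac{1}{L}\sum_\ell (1 - \sum_i p_{i\ell}^2)$). `dnamixr` asks,
by simulation: how do false positive rates (FPR) and power of the LR > 1
decision rule vary with the contributors' genetic diversity, and with
*mis-specification* of the reference — using one group's frequencies to
judge a mixture simulated from another group's?

## The likelihood model

The engine implements the standard semi-continuous (presence/absence)
model: only which alleles are seen matters, not peak heights. For a
hypothesised contributor set at one locus, let the dropout survival of a
carried allele $a$ be $1 - D(a)$ with
$D(a) = \prod_{\text{carriers of } a} d$, where $d = d_{\text{het}}$ for a
heterozygous carrier and $d = d_{\text{hom}}$ for a homozygote. The locus
likelihood is

$$\prod_{a \text{ carried}} \begin{cases} 1 - D(a) & a \text{ observed}\\
D(a) & a \text{ not observed}\end{cases}
\;\times \prod_{a \text{ observed, uncarried}} c\, p_a
\;\times (1 - c)^{[\text{no uncarried observed allele}]}$$

with drop-in rate $c$. Under $H_d$ the unknown contributor is summed over
all unordered genotypes with Hardy–Weinberg weights ($p_x^2$ or
$2 p_x p_y$); $\theta = 0$ throughout — no co-ancestry correction, matching
the simulation model. The total LR is the product of per-locus ratios.

Parameters and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `d_het` | dropout probability per allele of a heterozygote | 0.01 | the study's dropout setting |
| `d_hom` | dropout probability of a homozygote's allele | 0.0001 | independent parameter; default happens to equal `d_het`² |
| `drop_in` | per-locus drop-in rate $c$ | 0 | with all non-POI contributors known and one unknown under $H_d$, every observed allele is explainable without drop-in |
| `freq_floor` | frequency substituted for alleles absent from the reference | 1e-4 | makes mis-specified references usable; of the order of a singleton allele in a few thousand sampled chromosomes |
| `floor_policy` | `floor` or `error` | `floor` | `error` turns silent extrapolation into a hard failure |

Flooring is applied per evaluation: only alleles observed in the evidence
or carried by the hypothesised contributors enter the spectrum, which is
then renormalised. Because the numerator ($H_p$: POI + known others) and
denominator ($H_d$: known others + one unknown) can involve different
allele universes in POI− scenarios, each hypothesis floors its own
universe; the vectorised study kernel reproduces this replicate by
replicate and is asserted bit-compatible with the scalar path in the test
suite.

## The simulation design

Contributors are drawn under Hardy–Weinberg equilibrium (two independent
alleles per locus), unrelated, all from the simulation group's table. A
mixture is the per-locus set union of its contributors' alleles — no
simulated dropout, drop-in, stutter or degradation, so the dropout
parameters act only inside the LR. For $k$ contributors:

* **POI+**: the POI is contributor 1; power is the proportion of
  replicates with LR > 1.
* **POI−**: contributor 1 is the true unknown, and an independent
  individual from the same group plays the POI; the FPR is the proportion
  with LR > 1.

In both states contributors 2..$k$ are *known* under both hypotheses, so
the hypothesised contributor count always equals $k$: the POI (or the
unknown) occupies the slot of contributor 1. This is the cheapest scenario
for the defense — the only latitude is one unknown genotype — and
therefore a lower bound on FPRs with unknown co-contributors.

Classification is strict: LR exactly 1 (e.g. from a monomorphic,
uninformative locus) is not an inclusion. Infinite LRs (defense likelihood
exactly 0 with a non-zero prosecution likelihood) count as inclusions and
are tallied separately; zero/zero replicates are flagged degenerate and
count as exclusions. Every rate is reported with a Wilson 95% interval.

**Seed policy.** One root seed per study; each
(simulation group, reference group, contributor count, POI state) cell
derives a sub-stream seed by a polynomial hash of its label
(`derive_seed()`). Results are therefore independent of cell evaluation
order, and the diagonal cells of the mis-specified study are bit-identical
to the corresponding correct-reference cells under the same root seed.

## Population-genetic components

*Genetic diversity* is the unweighted mean of $1 - \sum_i p_i^2$ over
loci. *Pairwise $F_{ST}$* is the Weir–Cockerham (1984) estimator
$\hat\theta$, ratio-of-sums of the variance components over all alleles
and shared loci, which accounts for unequal sample sizes. Published
compilations report frequencies rather than genotypes, so observed
heterozygote frequencies are taken at their Hardy–Weinberg values
$2p(1-p)$ per group — stated explicitly because the estimator's $\bar h$
term is otherwise data-driven. Negative estimates (an estimator property
near zero differentiation) are reported as-is.

*Panel pruning* (`prune_by_fst()`) iteratively removes one random member
of the lowest-$F_{ST}$ pair until the minimum strictly exceeds the
threshold (default 0.005), never touching exempt groups; ties break
lexicographically on the group-id pair, and the removal choice is seeded.
Pairwise values are computed once — they do not depend on panel
composition — so pruning is $O(n^2)$ overall.

## The synthetic panel generator

Real inputs are wide CSV allele-frequency tables (alleles × loci, with an
`N` row of donor counts); the generator emulates their structure so every
analysis runs with no external data. Each base table has 13 CODIS loci
with 8–14 alleles per locus and a *geometric-decay* frequency profile
$p_i \propto r^i$, with $r$ solved per locus by bracketed root-finding so
expected heterozygosity hits the requested target to 1e-9. Diversity is a
smooth monotone function of the single decay parameter, which makes exact
target-hitting verifiable — the reason for preferring this profile over
Dirichlet draws. Divergent groups come from a Balding–Nichols
perturbation: per locus, Dirichlet draws centred on the base frequencies
with concentration $(1-f)/f$, so frequencies drift with variance
$f\,p(1-p)$. Two independent perturbations of one base give a pair whose
expected pairwise $\hat\theta$ is approximately $f$ (a single perturbation
against its base gives roughly $f/2$); estimator recovery within 30%
relative error at $f \in \{0.005, 0.02, 0.1\}$ is part of the test suite.

What the generator deliberately does *not* emulate: within-group
variation of per-locus diversity (all loci share the target, because the
study's predictor is the group mean), real CODIS allele label
distributions and microvariants, linkage, and genotype sampling noise in
the published frequencies. Passing tests therefore demonstrate the
*mechanism* — lower diversity and larger simulation–reference divergence
degrade accuracy — not the paper-scale rates of any real group. Allele
labels start at a random per-locus offset, so unrelated synthetic groups
overlap only partially, exercising the frequency floor in mis-specified
runs the way rare unshared alleles do in real tables.

## Quality control

Tables are filtered, never repaired: (1) locus completeness against the 13
original core CODIS loci (extra loci allowed); (2) per-locus frequency
sums within $[0.99, 1.01]$, bounds inclusive — the permissive reading,
affecting only boundary tables. No silent renormalisation is ever applied
to input frequencies (an explicit `normalize` flag exists for synthetic
workflows); sampling and genotype probabilities renormalise internally
within QC tolerance. Cross-referencing a compilation against its source
publications is manual literature work, representable only as a
caller-supplied concordance flag. A missing sample size defaults to 200
with a warning, since $F_{ST}$ needs one and published tables do not
always carry it.

## Numerical choices

* The defense-hypothesis sum is vectorised by adjusting only the one or
  two allele columns each unknown genotype changes; exclusion of a column
  uses division of equal quantities rather than multiplication by a
  precomputed reciprocal, so uninformative loci give LR = 1 to the last
  bit and the strict threshold behaves exactly.
* Root-finding for the geometric decay uses `uniroot` on $(10^{-9}, 1)$
  with tolerance 1e-14; achievability requires the target to be below
  $1 - 1/m_{\min}$ for the smallest allowed allele count.
* Sub-stream seeds come from a 31-ary polynomial hash modulo a prime
  below $2^{31}$, keeping every derived seed a valid R integer.
* Perturbed frequencies are floored at 1e-8 and renormalised to avoid
  numerically zero gamma draws at small concentrations.

## Problem sizes

The full-scale design — 100,000 replicates per cell for the
correct-reference study (1,000,000 LRs per group) and 10,000 per ordered
pair for the mis-specified study — is instantiated and counted by
`enumerate_design()`. The shipped analyses and tests run the same code at
desk scale, chosen to keep each driver in the minutes range on one core
while leaving binomial noise well below the effects measured: 2,000
replicates per cell in the analysis scripts and power target, 5,000 for
the diversity-correlation property at six contributors, 20,000 for the
FPR-versus-contributor-count property, and 100,000 simulated individuals
per group (24 groups spanning diversity 0.62–0.84) for the
heterozygosity validation of the genotype sampler.

## Known limitations

Presence/absence only — no peak heights, stutter or continuous models; no
simulated dropout or drop-in in the profiles; $\theta = 0$ everywhere
(accuracy is expected to be worse under realistic co-ancestry); one
unknown contributor in the study pipeline (the engine's multi-unknown
support is untested surface); and synthetic panels stand in for published
compilations, so absolute rates are illustrative while directions and
orderings are the tested claims.
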