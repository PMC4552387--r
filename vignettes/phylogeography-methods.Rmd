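---
title: "Models and methods behind paicdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paicdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paicdemog)
```

`paicdemog` analyses the historical demography of co-distributed island
populations from a mitochondrial alignment and a sample-metadata table.
This vignette is the package's account of the models it implements, the
conventions it adopts where the literature leaves choices open, and what
its synthetic-data tests do and do not demonstrate about real data.

## Data model and site handling

An alignment is an `n × L` character matrix over the IUPAC DNA alphabet
plus gap (`-`) and missing (`N`, `?`). All statistics operate on a fixed,
deterministic site set produced by **complete deletion**: any site carrying
a gap, a missing symbol or an IUPAC ambiguity code in *any* sequence is
removed before haplotypes are defined and before any distance is computed.
Ambiguity codes are treated as missing rather than as heterozygous states
because the target marker is effectively haploid mtDNA, where double peaks
represent read uncertainty, not genotypes. A `pairwise` policy (sites
dropped per sequence pair) is available for distance-style statistics, but
it makes haplotype identity a non-transitive relation, so it is not the
default. Comparison is case-insensitive.

## Diversity and divergence

Haplotype (gene) diversity uses the unbiased estimator
$Hd = \frac{n}{n-1}\bigl(1-\sum_i p_i^2\bigr)$ with Nei's sampling variance
$V(Hd) = \frac{2}{n(n-1)}\bigl[2(n-2)(\sum p_i^3 - (\sum p_i^2)^2) +
\sum p_i^2 - (\sum p_i^2)^2\bigr]$. Nucleotide diversity is the mean
per-site pairwise difference over the $\binom{n}{2}$ sequence pairs.

Between-population divergence $D_{xy}$ averages the Jukes–Cantor corrected
distance $d = -\tfrac34\ln(1-\tfrac43 p)$ over every between-population
pair; the correction is applied **per pair and then averaged**, matching
the pairwise definition of the statistic (at within-species divergences
the difference from correcting the average is second order). Net
divergence is $D_a = D_{xy} - (\pi_X + \pi_Y)/2$, where the within terms
use the frequency-weighted normalisation over all $n^2$ ordered pairs so
that a population measured against itself gives exactly $D_a = 0$.
Distances at or beyond the Jukes–Cantor singularity ($p \ge 0.75$) raise a
saturation error naming the offending pair. Both raw and percentage forms
are reported because published tables usually print percentages.

The `grant_bowen_category()` rubric dichotomises $Hd$ and $\pi$; the
high/low cut points (0.5 and 0.005 by default) are conventions, not
theory, and are exposed as arguments.

## AMOVA and gene flow

`amova3()` partitions the matrix of pairwise difference counts — entering
the sums of squares directly as squared distances — into among-group,
among-population-within-group and within-population components via the
standard expected-mean-square coefficients, giving
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$ and
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$. Negative variance
components are reported as estimated (they are legitimate method-of-moments
outcomes and published tables print them), but $\Phi$ statistics computed
from them are clamped to $[-1, 1]$.

Permutation significance follows the standard schemes: individuals among
populations ignoring groups for $\Phi_{ST}$; individuals among populations
within their group for $\Phi_{SC}$; whole populations among groups for
$\Phi_{CT}$. P-values use the add-one rule $(g+1)/(P+1)$ so they are never
exactly zero, and the permutation seed is a required, logged parameter.
With very few populations the $\Phi_{CT}$ permutation space is tiny and
the test is conservative by construction — a property of the design, not
of the implementation.

Gene flow uses the haploid island-model conversion
$Nm = (1-F_{st})/(2F_{st})$, appropriate for a maternally inherited
marker. Published tables built with mixed software sometimes print $Nm$
values inconsistent with any single conversion; this package implements
the haploid formula only and documents the mismatch rather than
reverse-engineering table cells.

## Neutrality statistics and their significance

Tajima's $D$ follows the standard constants. Fu's $F_s$ evaluates
$S' = \Pr(K \ge k_{obs})$ under the Ewens sampling formula with
$\theta = \bar k$, using an exact log-space recurrence for the unsigned
Stirling numbers of the first kind — numerically stable far beyond
$n = 60$ (a sample fixed for one haplotype gives $S' = 1$ and an infinite
$F_s$, reported as a degenerate-input warning). $R_2$ is
$\sqrt{\tfrac1n\sum_i (U_i - \bar k/2)^2}\,/\,S$ with $U_i$ the number of
singleton variants (carried by exactly one sequence) on sequence $i$; this
normalisation was cross-checked against exhaustive small-sample oracles in
the property suite before being frozen.

Significance comes from neutral coalescent simulation. The default
conditions each replicate on the observed number of segregating sites
(fixed-S), the customary default of the software ecosystem this package
replaces; a θ-conditioned mode (Watterson's estimate) is available because
the choice is not settled in the literature. $F_s$ and $R_2$ are tested
one-tailed against small values (the expansion signal); $D$ two-tailed.
$F_s$ is flagged significant at $p \le 0.02$ — its non-standard null
distribution makes 0.02 the operative 5% level — while $D$ and $R_2$ use
0.05.

## Mismatch distributions and the sudden-expansion model

Under a stepwise expansion from size $\theta_0$ to $\theta_1$ at $\tau$
mutational units before present, the pairwise coalescence-time mixture
gives the expected mismatch distribution in closed form as
incomplete-gamma terms (see `?expected_mismatch`); the implementation is
verified against its two analytic limits (equilibrium geometric when
$\theta_0=\theta_1$ or $\tau=0$) and against a Monte-Carlo draw from the
mixture density.

Fitting minimises $\sum_j (F^{obs}_j - F^{exp}_j)^2$ on difference classes
$0..(j_{max}+5)$, where $j_{max}$ is the largest observed mismatch — the
small tail padding stabilises the fit without chasing long empty tails.
The optimiser is a fixed coarse grid ($\tau \in [0,20]$,
$\theta_0 \in [0,10]$, $\theta_1 \in [\theta_0, 1000]$) followed by
Nelder–Mead refinement with parameters clamped to the valid region; the
grid is fixed so point estimates are exactly reproducible. $\theta_1$ is
estimated freely rather than pinned at infinity because the model names it
explicitly; in practice it is weakly identified and often runs to the
upper bound, which is expected and harmless for $\tau$. Confidence
intervals for $\tau$ are percentile bootstrap: simulate under the fitted
model, refit (warm-started from the original fit, whose neighbourhood
contains the truth by construction), take the 2.5/97.5 quantiles; the
median of the bootstrap distribution is reported alongside. More than 10%
refit failures flag the interval unreliable.

At realistic sample sizes the least-squares $\hat\tau$ is noisy and
upward-skewed — a property of the estimator, not a defect: with $n = 25$,
$L = 1392$ and truth $(\tau, \theta_0, \theta_1) = (4, 1, 50)$ the test
suite verifies that the median relative error over 100 synthetic datasets
stays below 25% and that percentile bootstrap intervals cover the true
$\tau$ in at least 90% of outer replicates.

## Dating

$\tau$ converts to years as $t = \tau/(2\mu k)$ for per-site rate $\mu$
and $k$ sites, generation time one year (the `"table"` convention, the
default because published expansion-date tables derived from these
statistics are internally consistent under it). A literal reading of the
textual relation $t = \tau/2u$ with $u = 2\mu k$ would halve every value;
it is exposed as the `"text"` convention so users can see both. Default
calibrations are 1, 2.7 and 4 × 10⁻⁹ substitutions/site/year and
$k = 1392$ (a 1041 + 351 bp concatenated mitochondrial marker pair).
Because published tables mix floor and nearest-integer rounding, the
dating table reports both.

## Median-joining networks

Only variable sites enter the computation, with equal weights. The
backbone is the ε-relaxed minimum spanning network: processing Hamming
distance classes in increasing order, an edge joins two nodes unless they
are already connected by edges of weight ≤ w − ε − 1; at ε = 0 this is
exactly the union of all minimum spanning trees. Median joining then
repeatedly forms the site-wise majority (median) vector of node triplets
joined through a shared neighbour, adds the candidates whose connection
cost is within ε of the round's minimum *and* whose addition strictly
shortens the minimum spanning tree of the node set, rebuilds, and prunes
inferred vectors of degree < 3 that carry no samples. Where three states
tie at a site the lexicographically smallest is taken, and nodes are
processed in lexicographic order throughout, so the network is invariant
to input order — the original algorithm leaves these tie-breaks open.
Iteration is capped at 100 rounds with fixpoint detection (a guard against
pathological cycling; synthetic data converge in one or two rounds).

## Tree-hypothesis classification

With tips mapped to regions and regions to island complexes, a rooted tree
is classified H0 when every complex is monophyletic and none is split into
two or more monophyletic region clades; H2 when every complex is
monophyletic and at least one is so split (inside a monophyletic complex,
monophyletic regions are necessarily sisters); H1 when some complex is
non-monophyletic but its region clades are each monophyletic (separate
colonizations); and "other" otherwise, including basal polytomies that
interleave complexes. The boundary between "unrelated clades" and
paraphyly with sister subclades is operationalised as the sister-clade
test — an interpretation, recorded here because the schematic hypotheses
do not pin it down. Outgroup-labelled tips are pruned first. Tree
*inference* is out of scope: trees arrive as Newick.

## The coalescent simulator

Time is measured in per-lineage mutational units: with $\theta = 2Nu$ per
locus, $j$ lineages coalesce at rate $j(j-1)/\theta$ and a pair separated
for time $T$ differs at Poisson($2T$) sites, so the expected pairwise
difference under a constant-size model is exactly $\theta$ and the
stepwise-expansion breakpoint sits at $\tau/2$ — simulator parameters
align one-to-one with the mismatch model's $(\tau, \theta_0, \theta_1)$.
Mutations are placed either Poisson per branch (θ mode) or exactly $S$
multinomially by branch length (fixed-S mode), each on its own site drawn
without replacement from $L$ positions — the infinite-sites assumption of
every downstream statistic, mapped onto a finite alignment (an error is
raised if mutations exceed sites). Ancestral bases are uniform and derived
states a random different base; the statistics are allele-configuration
based, so base identities are cosmetic. The two-deme model isolates demes
for `t_div` units with no migration (expected between-deme difference
$2\,t_{div} + \theta_{anc}$), which is how synthetic fixtures with a known
expected $F_{st}$ and $D_{xy}$ are built.

The simulator is validated against analytic expectations (pairwise
$E[\bar k] = \theta$, Watterson's $E[S]$, the closed-form mismatch
distribution) and is fully deterministic given a seed.

### What the synthetic tests show — and what they cannot

The generator reproduces the neutral, non-recombining, infinite-sites,
panmictic-deme world in which these statistics were derived. Passing tests
therefore demonstrate that the implementation computes its statistics
correctly and that the simulation-based tests hold their nominal size
*under the model*. Real mitochondrial data can violate the model —
selection on the mitochondrion, rate heterogeneity among sites, recurrent
mutation at hotspots, population structure within sampled demes — and no
synthetic calibration here speaks to those violations. Sample sizes in
this kind of study are small; the wide bootstrap intervals and the
documented skew of $\hat\tau$ are honest reflections of that.

## Problem sizes and numerical choices

The shipped test suite calibrates test size with 500 replicate datasets
against a 1000-replicate null table (reusing one table is valid because
all replicates share the same $(n, S)$ conditioning), measures $\tau$
recovery over 100 datasets at $n = 25$, $L = 1392$, and bootstrap coverage
over 50 outer replicates at $B = 200$ — a smoke-scale stand-in for the
3000-replicate production setting, which the package supports unchanged.
Tolerances: distribution identities to $10^{-8}$–$10^{-9}$; oracle
equivalences to $10^{-9}$ or better; stochastic calibrations at the
Monte-Carlo resolution of their replicate counts. Degenerate inputs are
contracts, not crashes: $S = 0$ makes the neutrality statistics undefined
(error), a single haplotype makes $F_s$ infinite (warning), saturated
distances name the offending pair, and a single group is a degenerate
AMOVA design.
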