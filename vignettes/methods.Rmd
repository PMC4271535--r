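---
title: "Estimating the spontaneous mutation rate from a simulated pedigree-sequencing experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the spontaneous mutation rate from a simulated pedigree-sequencing experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmutr)
```

## The problem

Direct estimation of the spontaneous mutation rate compares offspring
genomes with their parents' and counts de novo heterozygotes.  With a
draft genome assembly this is dominated by one artifact: reads from
paralogous loci that are missing from the reference map to the wrong
place and create spurious heterozygote calls that recur across
individuals.  The study design `pedmutr` implements addresses this with
family structure rather than with mapping heuristics: besides the 13
deeply sequenced *focal* offspring in which mutations are called, 17
shallowly sequenced *bait* siblings act as a tripwire — mismapping
contaminates siblings at the same position, a genuine de novo mutation
does not.  The estimator is

$$\hat\mu \;=\; \frac{m}{2\,C\,n_\text{focal}\,\hat c},$$

where $m$ is the number of candidate mutations, $C$ the number of
callable sites, $n_\text{focal}$ the number of focal offspring (the
factor 2 counts base copies per individual), and $\hat c$ the probability
that a mutation at a callable site is actually called.  $C$ and
$\hat c$ come from a synthetic-mutation spike-in calibration; neither is
observable directly.

All computations run on per-site read *base counts* ("piles"), not on
read sequences: every statistic in the analysis — genotype calls, allele
depths, filters, spike-ins — is a function of counts, so the package
neither stores nor aligns reads.

## Genotype calling

The multi-sample caller is a deliberately transparent stand-in for a
GATK-style pipeline.  At each site, the alternate allele is the most
frequent non-reference base across all individuals (ties to the
alphabetically first).  Per individual, with $n$ reads supporting
reference or alternate and $k$ of them alternate, the three genotype
likelihoods are binomial with alternate-read probability $\varepsilon$
(hom-ref), $1/2$ (het) and $1-\varepsilon$ (hom-alt), combined with the
standard variant prior $P(\text{het}) = \theta$,
$P(\text{hom-alt}) = \theta/2$ ($\theta = 0.01$ by default; calls are
insensitive to it at depth).  Ties in the posterior resolve to hom-ref,
zero depth is undefined.  Site quality is
$-10\log_{10} P(\text{no individual carries a non-reference allele})$,
and LowQual (threshold 30) applies only when a non-reference genotype was
actually called, mirroring caller conventions.

Two caller parameters deserve comment:

* **error rate** $\varepsilon$ (default 0.01): the likelihood's per-read
  error probability.  It need not equal the simulation's error rate; the
  genome-wide scan used in the pipeline defaults to matching it.
* **multiallelic exclusion.**  Sites showing two distinct non-reference
  bases, each supported by at least two reads *within a single
  individual*, are excluded outright.  The per-individual requirement is
  deliberate: with ~600 reads per site across 32 individuals, scattered
  single-read errors would otherwise mark essentially every site
  multiallelic at any realistic error rate, while two reads of the same
  base in one individual is the signature of a real second allele (or a
  contaminating paralog) rather than of independent errors.

## The six filter rules

A site is callable iff (1) not LowQual; (2) both parents: depth ≥ 10,
hom-ref call, zero alternate-allele reads; (3) zero alternate reads in
every bait offspring; (4) all focal genotypes defined; (5) at most two
focal het calls (two are flagged as a premeiotic cluster and counted as
two events); (6) zero alternate reads in focal offspring outside the het
set.  "Alternate reads" always means the site's called alternate base —
third-base reads are the multiallelic rule's business.  There is no depth
filter on offspring, and sites lost to parental polymorphism are simply
absent from both numerator and denominator, which leaves the rate
unbiased under the assumption that mutation is not elevated at
polymorphic sites.

A subtlety that matters for validation: classifying *unmutated* sites
with these rules is **not** the same thing as the callable fraction the
estimator needs.  A mutation supplies the reads that define the site's
alternate allele; a lone error read elsewhere in the family defines an
error-base alternate that blocks its own site under rules 2/3/6, yet
would not have blocked a mutation of a different base there.  At an error
rate of 0.005 the literal classification calls ~4% of sites callable
while a mutation would in fact have been detectable at ~34% of them.
`scan_mutations()` reports the literal count;
`callable_probability()` computes the mutation-conditional quantity
exactly, by enumerating the 3 possible mutant bases × 13 carriers per
site with the carrier exempt — the deterministic limit of the spike-in
procedure and the oracle the test suite checks it against.

## Heterozygote depth distributions and the spike-in

Because offspring inherit whole maternal chromosomes (no recombination in
female Lepidoptera), every maternal SNP on one chromosome shows the same
segregation pattern across offspring.  `informative_sites()` keeps sites
where the mother is called het, the father hom, and the bait offspring's
het/hom vector exactly matches one chromosome's pattern projection
(ambiguous double matches are dropped and counted); focal heterozygotes
are then read off the pattern, *not* from their own genotypes.
`tabulate_het_depths()` records, for each such focal heterozygote, the
number of non-reference reads $y$ at its total depth $d$, for
$d = 1,\dots,100$.  These empirical distributions carry exactly the
features that cause false negatives — allele sampling, error, and the
mapping bias against non-reference-bearing reads — so a synthetic
mutation planted with $y$ drawn from them at the carrier's depth is
distributionally indistinguishable from a real one.  Depths without
observations fall back to Binomial$(d, 1/2)$, the idealized reference
model.

`spikein_evaluate()` plants `n_spikes` (default 1,000) such mutations at
uniformly random sites in uniformly random focal offspring, re-calls each
site on a fresh copy of its counts, and classifies it with the carrier
exempt from rules 4–6 (the rule-5 cap drops by one for the remaining
offspring) — a real mutation must not block its own detection.  The
callable fraction of spikes estimates $C/\text{sites}$; the fraction of
callable spikes whose carrier is called het for the planted base
estimates $\hat c$.

## The simulator

`generate()` draws, per site and individual: depth
$\sim \text{Poisson}(\lambda_\text{role})$ (defaults 33× parents, 26.3×
focal, 12.7× bait — Poisson keeps it one parameter per role; real data
are somewhat overdispersed, which the analysis never exploits); each read
copies one of the two true alleles and is misread as a uniformly chosen
other base with probability `error_rate`; inside a paralog region every
read is replaced by the region's fixed alternate base with probability
`paralog_alt_rate` in *every* individual (mismapping is equally likely at
mutated and unmutated sites); and any read carrying a non-reference
allele is dropped with probability `mapping_bias`, shrinking the realized
depth.  Applying the bias to inherited SNP alternates as well as to
planted mutants is deliberate: it is what imprints the bias on the
heterozygote depth distributions, which is the channel through which the
spike-in learns about false negatives.  Maternal SNPs (mother het, father
hom-ref) segregate by whole-chromosome inheritance; paternal transmission
is whole-chromosome too (male recombination exists in the organism but no
implemented statistic is sensitive to it).  Modelling only maternal
polymorphism is likewise a simplification: sites polymorphic in the
father would be removed by rule 2 exactly like mother-polymorphic sites,
shrinking numerator and denominator proportionally.

Defaults where judgement was required: chromosomes are 200 kb stand-ins
for the real ~12.9 Mb (a desk-scale genome of 4.2 Mb), with
`mu_true = 5e-7` scaled up correspondingly so a family carries a
realistic number of detectable mutations (~55 in focal offspring);
`error_rate = 1e-3` as a post-filtering base-error rate, which yields a
spike-in callable fraction near one half, like the real draft-genome
experiment; `maternal_het_density = 0.02` for an outbred F1 mother;
`paralog_fraction = 0.05` of the genome contaminated at
`paralog_alt_rate = 0.1`; `mapping_bias = 0.05`, enough to shift
heterozygote allele fractions visibly below one half.  Parent depth 33×
follows the study's parent coverage.  The seed lives in the
configuration; identical configurations are byte-identical.

What the simulator does *not* emulate: indels and structural variants,
alignment and duplicate-removal artifacts beyond the paralog model,
base-quality variation, batch effects between sequencing runs, and
overdispersed coverage.  Passing tests therefore demonstrate the
*procedure's* correctness — unbiasedness of the calibrated estimator,
zero false positives under paralog contamination, exact interval
behaviour — on data satisfying the model's assumptions, not the fidelity
of any particular real dataset.

## Rates, intervals and derived quantities

`rate_estimate()` computes $m/2S$ with $S$ the callable site-individuals,
and attaches the exact (Garwood) Poisson interval for $m$: bounds solve
$P(X \ge m \mid \lambda) = \alpha/2$ and $P(X \le m \mid \lambda) =
\alpha/2$, implemented through the gamma-quantile identity, with a
bisection inversion of the tail sums retained as an independent
cross-check (they agree to better than $10^{-9}$ relative; the exact
method's coverage at $\lambda = 9$ is 95.7%, conservative as designed).
The false-negative correction divides the point estimate and both bounds
by $\hat c$; no uncertainty in $\hat c$ is propagated, matching the
experiment's own arithmetic, because its binomial error (±1%) is
negligible beside the Poisson width on nine events.  `ne_from_pi()`
equates neutral diversity to $4 N_e \mu$; `divergence_time()` assumes
neutral divergence $d = 2\mu t$.  `spectrum()` classifies base changes
into transitions (A↔G, C↔T) and transversions.

Numerical conventions: coordinates are 1-based inclusive; bases are
coded A, C, G, T; alternate-allele ties break to the first base in that
order; genotype-posterior ties break to hom-ref; all randomness flows
from R's RNG so a single `set.seed()` (or the simulation seed) fixes
every downstream draw.

## Validation scale

The test suite exercises the full pipeline at the study's design scale —
21 chromosomes × 200 kb, 13 focal and 17 bait offspring, `mu_true =
5e-7`, `error_rate = 0.005`, `mapping_bias = 0.05` — over 50 seeds,
checking that the mean corrected estimate recovers the simulated truth
within two Monte-Carlo standard errors (about ±7% at this scale), that
the spike-in callable fraction agrees with the exhaustive enumeration,
and that no candidate is ever emitted where paralog contamination is
visible in a bait individual.  Smaller fixtures (2–3 chromosomes of
20–30 kb) back the per-module properties: caller/engine equivalence,
rule isolation, binomial heterozygote distributions at zero error and
bias, the $(1-\beta)/(2-\beta)$ mean shift under mapping bias, and
monotone degradation of the spike-in call rate as the bias grows.

## Known limitations

* The genotype model is biallelic; true multiallelic variation is
  excluded rather than resolved.
* Premeiotic clusters are flagged but the rate treats events as
  independent; with two carriers per cluster the Poisson interval is
  slightly anti-conservative if clusters are common.
* The spike-in exempts the carrier analytically rather than re-running a
  global alignment, so alignment-level feedback between a mutation and
  *other* sites (read pairs rescued or lost elsewhere) is outside the
  model.
* At extreme mapping bias (β ≳ 0.7 at these depths) heterozygote calls in
  the bait offspring fail, segregation matching starves, and the
  calibration degrades — visible in simulation, and a real caveat for any
  dataset whose non-reference reads map that poorly.
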