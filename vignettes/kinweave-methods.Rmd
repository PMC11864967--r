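---
title: "Methods: pedigree reconstruction, reproductive practices and IBD networks"
author: "kinweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree reconstruction, reproductive practices and IBD networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinweave)
```

## What the package does

Whole-cemetery ancient-DNA studies of early-medieval burial communities
estimate pairwise relatedness degrees (first to sixth) from genotype
likelihoods, summarise identity-by-descent (IBD) segment sharing, and
type uniparental markers (mtDNA and Y haplogroups).  From those summary
tables — not from genotypes — analysts reconstruct multi-generation
pedigrees and read social structure off them: who married in, who
stayed, how often men or women had children with several partners,
whether widows re-married their husband's kin (levirate), and whether
consanguinity was avoided.  `kinweave` implements that analysis layer
as tested, reusable code, together with a forward gene-dropping
simulator that provides exact ground truth to validate every step.
Everything downstream of genotype processing is in scope; sequencing,
imputation, and genotype-based kinship estimation are not.

## The kinship machinery

The analytic core is Wright's coancestry recursion.  The kinship
coefficient $\varphi(i,j)$ is the probability that random alleles, one
from each individual, are identical by descent:
$\varphi(i,i) = (1 + F_i)/2$, and for $i$ with parents $f, m$,
$\varphi(i,j) = (\varphi(f,j) + \varphi(m,j))/2$, missing parents
contributing zero.  The inbreeding coefficient $F_i$ is the kinship of
$i$'s parents and equals the expected autozygous genome fraction,
observable as runs of homozygosity (ROH).  The implementation is the
standard tabular recursion in topological order; the test suite checks
it exactly against an independent oracle that enumerates all ancestral
path pairs on pedigrees of up to fifteen members.

Relatedness degree $d$ corresponds to an expected kinship of
$2^{-(d+1)}$.  Published kinship classifiers do not print their internal
cut-offs, so the package uses the standard powers-of-two scheme: bins
are cut halfway between neighbouring degrees on the log2 scale, at
$2^{-(d+1.5)}$, and a value exactly on a boundary goes to the
closer-relative bin — a deterministic, documented tie rule.  On the
numeric scale used by the consistency score, "unrelated" is coded as
degree 7 and differences are capped at 3, so a far-degree misestimate
cannot dominate the fit.

## The community simulator

`simulate_community()` runs a generation loop over a patrilocal
community: adult sons stay with probability `p_son_stays`, daughters
leave to marry elsewhere with probability `p_daughter_leaves`, staying
men take exogamous brides (or, with probability `p_local_union`, an
unrelated local woman), child counts are Poisson with mean
`fertility_mean`, ages at death are drawn from a seven-category
mortality table, and reproduction requires surviving to adulthood.
With probability `p_polygyny` a man takes an additional partner; when a
married man dies before 36, his widow re-partners with probability
`p_levirate` with a male relative of the deceased at second degree or
closer, or with a stepson (his son by another woman) — the partner then
stays on site, since he fathers children there.  mtDNA passes from
mother to child, Y from father to son, and a child's ancestry vector is
the mean of its parents'.  Burial sampling marks each deceased resident
with probability `sampling_prob`; emigrants are never sampled.

The defaults describe the study conditions the analyses are validated
under: six generations from four founder couples, `p_son_stays = 0.85`,
`p_daughter_leaves = 0.85`, `fertility_mean = 4`, one dominant founder
Y lineage at 80%, and East Asian-dominant ancestry (founders 0.75,
brides 0.70) with a diverse bride mtDNA pool.  These sizes yield
roughly 120–220 sampled burials — the scale of a fully excavated
cemetery — and the rates `p_polygyny = 0.10` and `p_levirate = 0.15`
reproduce the observed scale of multi-reproductive unions (roughly a
quarter of reproductive relations).  With four founder couples a
community occasionally dies out before six generations; this is
reported as an explicit extinction flag, and benchmark drivers then
move to the next seed.  Mean ancestry of the male line converges to the
bride pool geometrically, as
$a_b + (a_0 - a_b)\,2^{-(g-1)}$ at generation $g$; the tests verify
this within Monte-Carlo error, mirroring the observation that
assortative bride choice keeps a community's ancestry stable across
generations.

Gene dropping assigns two uniquely labelled founder haplotypes per
founder and simulates one recombinant gamete per parent–child link.
Crossovers are interference-free (Haldane): Poisson counts with mean
length/100 per chromosome and uniform positions.  At the 4–20 cM
segment scales used here, crossover interference would change segment
statistics only marginally, which is why the simpler process is
adequate.  The default map is a 22-autosome human-like map scaled to a
3,400 cM total.  IBD between two individuals is extracted by
intersecting founder-segment mosaics over all four haplotype pairings;
a duplicated genome therefore totals twice the map length — the
signature segment-based detectors report for identical twins, and the
package's convention throughout.  Under it, the expected IBD total for
a pair with kinship $\varphi$ is $2\varphi \cdot 2L$; tests confirm
parent–offspring pairs cover the map, sibling IBD2 is 25%, and
second-cousin (degree-5) totals average $L/16$.  ROH are the
self-intersections of an individual's two haplotypes, reported above
4 cM, with expected total $F \cdot L$.

The observation layer perturbs true degrees with an adjacent-degree
confusion matrix (default: a single swap rate, split evenly between
neighbours), drops unsampled individuals from every table, and keeps
the unperturbed truth for validation.  Only adjacent-degree errors are
modelled because that is the dominant error mode of likelihood-based
degree classifiers; gross misclassification across two or more degrees
is rare enough to ignore at the rates studied here.

What the simulator does not emulate: genotype-level noise (coverage,
contamination, imputation error) — degrees arrive as labels with a
stylised error model; calendar-time demography (generations are
relative layers, not radiocarbon dates); migration between several
simulated sites; and identical twins.  Passing tests therefore show
that the inference machinery is correct under the stated error model,
not that any particular excavated dataset satisfies that model.

## Pedigree reconstruction

Assembly follows the stepwise procedure used in whole-cemetery kinship
studies, made explicit and scored:

1. **First-degree scaffold.**  Siblings are connected first: sibling
   -typed first-degree edges are closed transitively, with missing
   within-sibship edges flagged.  An individual linked parent–offspring
   to a sibship of two or more (a noise-tolerant majority of typed
   edges, with every member observed at degree ≤ 2) is its parent;
   the slot follows sex.  Remaining parent–offspring edges are oriented
   by hard rules only — an individual who died below the minimum
   reproductive age (15 years, configurable) cannot be a parent; a
   female parent must match the child's mtDNA; occupied slots and
   cycles are forbidden — plus a structural rule for couple–child
   triangles: when one individual has parent–offspring links to two
   people who are themselves observed as more distant than second
   degree, both must be its parents.  Everything still ambiguous is
   deferred to the scoring stage, where age ordering (elder as parent
   when death-age intervals are disjoint) survives as the tie-break.
   Death ages do not order generations — a mother can die younger than
   her son — so age is deliberately a tie-break, not a hard rule.

2. **Latent parents.**  Sibships lacking identified parents gain latent
   ones (flagged unsampled; a latent mother inherits the children's
   shared mtDNA), children of one "sibship" with conflicting mtDNA are
   split into maternal subsets sharing a latent father, and children
   with exactly one identified parent gain the missing co-parent, so
   reproductive unions remain countable.

3. **Second-degree hypotheses.**  Each unexplained second-degree pair
   is expanded into half-sibling (paternal/maternal), avuncular and
   grandparent–grandchild hypotheses in all orientations, pruned by the
   sibling-equality principle (full siblings of one member must be
   observed at a compatible degree to the other), age feasibility (a
   grandparent needs two generation gaps of 15 years), haplogroup
   consistency (Y match on male–male paternal chains, mtDNA match on
   maternal chains), and — where both avuncular and grandparent survive
   and an IBD record exists — a segment-count discriminant.  Because a
   true first-degree record can reach this stage through one step of
   classification noise, both feasible parent–offspring orientations
   also stay in the hypothesis space; the score arbitrates.

4. **Scored greedy assembly.**  Candidates are inserted in descending
   order of improvement to the consistency score
   $S = \sum_{\text{pairs}} -\min(3, |d_{\text{expected}} - d_{\text{observed}}|)$,
   with backtracking: a placement that violates an invariant (two
   parents, parental sexes, mtDNA/Y transmission, acyclicity, minimum
   reproductive age) is reverted and marked infeasible.  Ties break
   toward fewer new latent individuals, then the age preference, then
   lexicographic order, making assembly deterministic for a fixed
   input.  Competing placements within one score unit of the winner are
   kept in an alternatives ledger, preserving the practice of listing
   plausible alternative pedigrees rather than silently committing.
   Greedy insertion with backtracking is used instead of exhaustive
   search because enumerating placements is intractable beyond roughly
   twenty uncertain pairs; the ledger records what the greedy path did
   not take.

The avuncular/grandparent discriminant rests on segment counts, not
totals: both classes share a quarter of the genome in expectation, but
the avuncular path has three meioses against the grandparent's two, so
avuncular sharing is split into more, shorter segments.  The packaged
calibration table (`inst/extdata/segment_count_calibration.tsv`,
regenerated by `calibrate_segment_counts()`) puts the means near 47
versus 37 segments at an 8 cM floor on the default map; the midpoint is
the classification threshold.  This reproduces the published practice
of using IBD segment structure to separate the two classes, at about
85% accuracy on simulated pairs.

Pairs with duplicate-level IBD (total above a configurable threshold,
or an explicit `identical` degree) are merged into a twin unit treated
as a single placement node and flagged in the output.

## Reproductive-practice statistics

A *reproductive relation* is a distinct parent pair with at least one
child, latent parents included — the only reading that makes the
published union counts and multi-union counts mutually consistent.  A
union is *multi-reproductive* when either parent appears in two or more
unions; the single-to-multiple ratio is reported rounded
(`round((n - m)/m):1`) with the raw fraction alongside.  Children with
a single known parent are listed as half-unions and excluded from the
ratio.  Levirate is flagged for mothers with two or more partners when
any two partners are male relatives at second degree or closer, or
stand in a stepson relation; cross-generation arrangements qualify
through the degree rule.

Descent lines are maximal parent-to-child chains among reproducing
members.  Within each maximal chain, runs of consistent same-sex
transmission spanning at least three generations are recorded as
patrilineages or matrilineages — the three-generation floor follows the
observation that shorter stretches of consistent transmission are not
evidence of a lineage system.  A chain of three or more generations
with no such run is a bilineage, but only when it contains a genuine
descent switch: a single leading mother link is merely the co-parent
view of a paternal line (every patriline starts at somebody's mother)
and is not counted.  Lines contained in longer recorded lines are not
double counted.

Mother exogamy counts sampled mothers of sampled children without a
sampled parent or grandparent on site; deeper ancestor horizons change
nothing when parents are already absent.  Because excavated counts may
or may not include mothers known only as latent nodes, both variants
are reported.  The juvenile sex ratio uses age-at-death interval
midpoints within 7–17 years, excludes but counts unknown-sex
individuals, and marks the no-females case explicitly.  The
consanguinity check runs two routes — pedigree $F$ and, when supplied,
total ROH against a configurable fraction of the map (default $1/32$,
half the first-cousin expectation) — and issues a site verdict only
when no individual is flagged.

## IBD networks

The dyad universe is the complete graph over sampled individuals with
usable covariates; non-ties are explicit zeros, and dyads with missing
covariates are excluded with a logged count.  Two tie rules are
emitted and fitted in parallel, because published effect sizes do not
always state which network they refer to: the long-segment relatedness
rule (more than two segments over 20 cM) and the segment-length rule
(any segment over 16 cM).

With only dyad-independent covariate terms, the exponential-family
network model factorises into independent Bernoulli ties whose log-odds
are linear in the covariates.  `fit_dyadic_ergm()` maximises that
likelihood directly by iteratively reweighted least squares and reports
coefficients, Wald Z-tests (two-sided, uncorrected, with a Bonferroni
column for transparency), fold-changes $e^{\beta}$, log-likelihood and
AIC ($2k - 2\ell$).  Reference categories are female–female pairs and
zero prestige-object carriers; the default prestige set is
`{belt_set, coat_clasp}`, the male- and female-linked status objects.
Separation is flagged and reported as a boundary estimate; aliased
columns are dropped with a notice.  `select_model()` fits all additive
candidate term sets and keeps the minimum-AIC fit, ties toward fewer
terms.  No dependence terms (triangles, stars) are offered: the effects
of interest are all covariate effects, and dyadic independence makes
the likelihood exact — no MCMC approximation is involved.

Site-level sharing is a weighted network whose edge weight is the mean
total IBD over all cross-site pairs, zero-sharing pairs included.
Continuous covariates (geographic distance, ancestry dissimilarity) are
tested by QAP: Pearson correlation over off-diagonal entries against a
null built by jointly permuting the covariate's node labels, two-sided
with the add-one correction.  A generalised exponential-family model
for weighted edges was considered and rejected: its edge-weight
transformation is under-documented for exact replication, while the
claims at stake are sign-and-significance claims that the permutation
test addresses directly with exact level control.  This design decision
is deliberate and recorded here.

## Numerical choices and problem sizes

All randomness flows from one base seed through named substreams
(a deterministic hash of the stage name), so stages are reproducible
in isolation; no stage consumes global RNG state, and callers' RNG
state is restored.  Pair tables are canonicalised at a single point
(lexicographic `id_a < id_b`); duplicate pairs are integrity errors.
The IRLS stops at a $10^{-10}$ step norm; likelihood terms are clipped
at $10^{-300}$ before logs.  QAP p-values use the add-one correction
and a $10^{-12}$ tolerance on the comparison.

The validation suite runs at sizes chosen to make Monte-Carlo error
small relative to the tolerances while keeping a laptop-scale runtime:
500 gene-dropping replicates for ROH and sibling-IBD expectations,
1,000 for degree-5 sharing, 400 pairs for the avuncular/grandparent
benchmark, 20 simulated communities for the noisy-recovery benchmark,
5,000 dyads for planted-effect recovery, and 200 null draws for QAP
calibration.

## Known limitations

Exact zero-noise recovery is proven on simulated communities of up to
six generations and ~150 sampled individuals; larger or deeper
pedigrees may contain symmetric configurations the observations cannot
distinguish, which the isomorphism check treats as equivalent.  The
greedy assembler is not globally optimal under noise; its alternatives
ledger is the honest record of close calls.  Degree-classification
noise is modelled as adjacent swaps only.  Site-level analyses assume
sites are exchangeable under the QAP null, which is appropriate for
label permutations but does not model spatial autocorrelation within
sites.  The published site-level headline proportions (patrilineage
percentages, specific fold-changes) depend on the excavated genomes
and are not reproducible from summaries; the package validates the
machinery that produces such numbers against simulator truth instead.
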