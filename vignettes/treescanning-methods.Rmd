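---
title: "Haplotype-network association scanning: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-network association scanning: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtTreeScan)
```

## The problem

Mitochondrial DNA is maternally inherited without recombination, so every
subject carries one haplotype and the haplotypes of a cohort are related by a
single genealogy. A case-control association question ("does some part of
this genealogy carry disease risk or protection?") is then naturally asked
*per branch*: each branch of the haplotype network splits the haplotypes — and
hence the subjects — into two clades, giving a haploid bi-allelic marker. The
scan tests every such branch marker against case status with covariates and
corrects across the (strongly correlated) branch family by permutation. This
package implements that whole chain for mtDNA cohorts with matrilineal
pedigree structure: per-subject variant tables in reference coordinates,
majority-rule heteroplasmy resolution, haplotype collapse, matrilineal
imputation of haplotypes to unsequenced relatives, statistical-parsimony
network construction, branch-partition enumeration under loop resolutions,
Firth-penalized logistic regression, step-down minP permutation correction,
conditional second-round scans, and a familial-risk covariate from pedigree
kinship.

## Data model and coordinates

Variants are kept in 1-based reference coordinates using m-dot notation
(`m.263A>G`); insertions are anchored after a position
(`m.3915_3916insACC`) and deletions are closed intervals (`m.3915_3917del`).
Each indel counts as one mutational step. A haplotype is a set of variant
tokens; the step distance between haplotypes is the size of the symmetric
difference of their sets. The reference is pluggable: tests run on short toy
references, while full-scale work uses the 16,569-bp mtDNA coordinate
system. The bundled `syntheticRCRS()` is a *synthetic* stand-in occupying
those coordinates — deterministic filler patched so that a handful of
well-documented sites carry their true alleles and codon contexts — because
the package ships no copyrighted or downloaded sequence data. Gene
annotation uses the standard mtDNA gene coordinate table (13 coding genes,
2 rRNAs) and the vertebrate mitochondrial genetic code; codon 1 starts at
the annotated gene start. Under that convention `m.4727A>G` is ND2 codon 86
and `m.9380G>A` is COX3 codon 58, both synonymous; `m.3915G>A` falls in ND1
codon 203 — published variant labels for ND1 sometimes use a different codon
numbering convention, and we document ours rather than matching any one
label.

Heteroplasmic sites are resolved to the majority allele; exact ties resolve
to the reference allele (deterministic and conservative). A configuration
option can exclude position windows (e.g. the poly-C tracts at 303–315 and
16183–16194) from haplotype definition; the default excludes nothing.

## Network construction

The network connects haplotypes in nondecreasing step distance, keeping
*every* connection of minimal length between components — the union of all
minimum spanning trees under the step metric. Equally parsimonious
alternatives therefore survive as loops (reticulations), as in statistical
parsimony networks; the full TCS probability calculus is deliberately not
reproduced, because the network's only analytical role here is to define
branch partitions. A pair at distance $d>1$ is joined through $d-1$ inferred
intermediate haplotypes. Chain construction starts from the endpoint with
the larger carrier count and sheds the *rarest* variants first, then gains
the *commonest* first (carrier-weighted frequency; position and token as
tie-breaks). Because allele frequency is a proxy for allele age, these
intermediates approximate ancestral sequences, and intermediates generated
by different chains coincide exactly where the data are tree-like — networks
built from infinite-sites data stay close to the true genealogy instead of
sprouting spurious reticulation. Inferred nodes are deduplicated by variant
set; observed haplotypes are never duplicated.

`maxSteps` caps connection length (default unlimited); haplotypes further
apart remain in separate components.

## Branch partitions and loop ambiguity

For a tree-like component every edge induces one partition of the observed
haplotypes. Edges joined through *inferred* degree-two nodes induce the same
partition and are reported as one multi-segment branch carrying all their
variants. Where the network retains loops, partitions are enumerated per
spanning-tree resolution and deduplicated by their sides; each partition
reports how many resolutions of its biconnected component support it.
Resolutions are enumerated over chain-contracted cycles (cutting a chain of
inferred nodes anywhere yields the same observed partition), which keeps the
enumeration exact and fast for the loop structures the generator produces.
For pathologically fused cycle systems whose resolution count exceeds
20,000, the package falls back to the single deterministic resolution given
by Kruskal's algorithm in construction order; partitions from such
components are still produced, but alternative resolutions of those cycles
are not enumerated. Defining variants of a deduplicated branch are taken
from its first supporting resolution.

## The branch test

Each eligible branch is tested by the likelihood-ratio statistic for the
branch allele in a logistic regression of case status on allele plus
covariates. A branch is eligible when both genotypic classes contain at
least `minClassSize` (default 5) subjects with non-missing phenotype — the
filter removes tests with no power and shrinks the family. The default
statistic is the Firth-penalized LRT (Jeffreys-prior penalty), because a
fully protective clade — the very signal of interest — produces complete
separation, where the unpenalized estimate diverges; the penalized statistic
stays finite. A plain LRT flavor exists for oracle comparisons (with no
covariates it equals the closed-form 2x2 G-statistic). The engine is an
undamped Newton iteration with warm starts and a step-halving fallback,
implemented in C++; permutation fits warm-start from the converged covariate
coefficients with the allele coefficient at zero.

Default covariate encoding: age in years at blood draw, sex as a male
indicator, APOE as two allele-dosage terms (e4 count, e2 count), plus
optionally the familial-risk score with its missing-indicator. Subjects with
missing phenotype or covariates are excluded listwise from testing but kept
in network construction and reporting.

## Permutation inference and multiplicity

The permutation unit is the subject-to-haplotype assignment: each of the `B`
permutations shuffles which subject carries which haplotype, leaving the
joint phenotype-covariate distribution untouched, and recomputes every
branch statistic — preserving the correlation structure of the family. This
choice (rather than permuting phenotypes) keeps phenotype-covariate
dependence intact under the null of no haplotype effect. Nominal p-values
use the add-one convention $(b+1)/(B+1)$; with $B = 10{,}000$ the smallest
reportable value is $10^{-4}$.

Family-wise correction is step-down minP: the observed data joins the null
set as one extra row so that all p-values share the granularity $1/(B+1)$;
branches are ordered by nominal p (ties by statistic, then id), each ordered
branch is compared with the permutation distribution of the minimum p over
the not-yet-rejected branches, and monotonicity is enforced. Corrected
p-values therefore always dominate nominal ones. In exhaustive mode (all
$n!$ assignment permutations, feasible for $n \le 9$) the identity
assignment is part of the enumeration and all p-values are exact counts.

A structural property worth knowing: the smallest achievable corrected
p-value is approximately $m^\*/(B+1)$, where $m^\*$ is the number of
effectively independent branches, because in each permutation *some* branch
attains its own null maximum. With a family of 100+ branches, corrected
p-values below 0.05 require permutation budgets well above 1,000 — the
published analyses of this design run 10,000 permutations for exactly this
reason. See "Known limitations" below.

Conditional rounds add the allele of the most significant branch as a fixed
covariate and rescan; branches collinear with a conditioning allele are
reported degenerate and skipped; rounds repeat until no new branch is
significant. Nested branches carrying the same clade signal lose
significance once their parent is conditioned on, which is how the scan
distinguishes one association from several.

## Pedigrees, familial risk and imputation

Kinship is computed by the standard tabular recurrence (founders unrelated
and non-inbred; missing parents contribute zero), and the coefficient of
relationship is twice the kinship. The familial-risk score of a subject is
the r-weighted sum of affected relatives divided by the r-weighted sum of
at-risk-cohort relatives, excluding the subject; affected relatives count
only if they are also at-risk members. "Relatives" means all pedigree
members with $r > 0$ (a minimum-r cutoff is configurable). Subjects with no
at-risk relatives get score 0 plus a missing-indicator covariate instead of
being dropped.

Matrilines follow mother links to the maternal founder. Because an unbroken
maternal line shares one mtDNA haplotype (barring recent mutation, which the
imputation assumes absent), every ungenotyped member of a matriline with
exactly one observed haplotype receives that haplotype, flagged imputed.
Matrilines with discordant genotyped members are handled per policy
(`leave_missing` default, `majority`, or `abort`) and always reported.

## The synthetic cohort generator

No cohort data are distributed with this package, so all testing runs on a
generator that emulates the *statistical structure* the analysis assumes:

* **Haplotypes** come from a neutral coalescent (`ape::rcoal`) with Poisson
  infinite-sites mutations at rate $\theta/2$ per unit branch length, so
  the expected segregating-site count follows Watterson's formula. Human
  mtDNA genealogies are strongly star-like (recent expansion); a plain
  neutral coalescent cannot show ~250 distinct haplotypes with only ~900
  segregating sites at these sample sizes, so a `tipExtra` parameter adds
  extra terminal branch length, mimicking expansion-driven private
  variation. Defaults ($H = 250$, $\theta = 75$, `tipExtra` = 0.045) give
  roughly 240–260 observed haplotypes and 800–950 sites at cohort scale.
* **Cohort structure**: 1007 subjects in 274 matrilines (sizes
  truncated-geometric), one haplotype per matriline (every haplotype seeds
  at least one matriline; extras reuse haplotypes frequency-weighted), one
  random genotyped representative per matriline, the rest imputable.
  Pedigrees are three-generation: maternal founder, sibship mothers,
  cohort subjects — so full sibs ($r = 1/2$) and matrilineal cousins
  ($r = 1/8$) exist.
* **Covariates and phenotype**: age truncated-normal (mean 75.64, sd 7.50,
  minimum 65), male fraction 442/1007, APOE allele frequencies 0.15 (e4)
  and 0.06 (e2), a logistic phenotype model with fixed documented effects
  (0.08 per year, -0.2 male, 1.2 per e4, -0.5 per e2) and an intercept
  calibrated by root finding so the expected case rate among phenotyped
  subjects is 101/733. Sex and phenotype-missingness margins are fixed at
  their expected counts (274 missing of 1007) with random assignment, so
  cohort margins are reproduced exactly.
* **Planted effect**: `effectClade = "auto"` picks a genealogy clade with
  about `targetCarriers` phenotyped carriers whose stem branch carries at
  least one mutation *and* whose haplotypes stay connected in the minimum
  network (clades can genuinely fragment when private variation outweighs
  the stem path; such clades are not recoverable by any branch test and
  are excluded from planting). `beta` is the carrier log-odds shift;
  `beta = -Inf` forces every phenotyped carrier to be a control.
* **Heteroplasmy**: each variant row independently gains a secondary allele
  with probability `hetRate`; the major (alternate) fraction is drawn in
  (0.5, 1), so majority-rule resolution recovers the original haplotypes
  exactly.

Regeneration from the same parameters and seed is byte-identical, including
all emitted files. What the generator does *not* emulate: real haplogroup
structure and allele spectra, sequencing error, pedigree founder overlap
between matrilines, phenotype misclassification, and covariate-haplotype
confounding. Passing tests demonstrate the machinery, calibration and
power behaviour under this idealized structure, not performance on any real
cohort.

## Problem sizes used by the test-suite experiments

Unit tests run on toy cohorts (150 subjects, 30 haplotypes, 2,000-bp
reference). The calibration experiment uses 60 null cohorts of 400
subjects at 500 permutations; the planted-effect experiment uses 12
cohorts at full scale (1007 subjects, ~733 phenotyped, ~38 phenotyped
carriers, 1000 permutations); the study-scale smoke test pushes one
full-size cohort through the complete pipeline at 1000 permutations.
These replicate counts keep the default suite to a desk-scale runtime;
given the structural behaviour described under "Known limitations", the
calibration and detection conclusions are not replicate-limited.

## Numerical choices

* Logistic fits: Newton with warm starts, convergence at step
  $\|\delta\|_\infty < 10^{-6}$, iteration cap 25, step-halving fallback;
  probabilities clamped to $[10^{-10}, 1-10^{-10}]$; the Jeffreys log-det
  of the final iterate is used in the penalized likelihood.
* Permutation tie handling compares statistics with tolerance $10^{-7}$.
* Heteroplasmy ties (fraction exactly 0.5) resolve to the reference.
* Degenerate fits (non-convergent or constant allele) are excluded from the
  step-down family and reported with missing p-values.
* All tie-breaks in network construction and branch ordering are
  deterministic (count, then position, then lexicographic id); no RNG is
  consumed outside the generator and the permutation draw.

## Known limitations

* The minP granularity floor described above means that at $B = 1000$ and a
  branch family of ~100 eligible tests, no branch can reach a corrected
  p-value below roughly 0.06–0.12 even when its nominal p-value is at the
  floor. Family-wise detection at 0.05 in such designs requires the full
  10,000-permutation budget. Equivalently, over null cohorts the scan at
  moderate B is conservative: it essentially never rejects, which is valid
  control but makes small-B rejection-rate calibration experiments
  degenerate.
* Under subject-level assignment permutation, the nominal p-value of a
  fully protective clade with $k$ phenotyped carriers is bounded below by
  roughly the null probability that a random subset of $k$ phenotyped
  subjects contains no case (about $\prod(1-p_i)$, e.g. ~2-4 in 1000 for
  k = 38 at a 13.8% case rate). High covariate-driven risk heterogeneity
  among the actual carriers is what pushes real-data nominal p-values
  further down; the generator draws carriers' covariates at random, so its
  planted clades sit near that bound.
* Loop-resolution enumeration is exact only up to the documented cap;
  beyond it one deterministic resolution is used.
* Sequence-to-variant recovery for indels in repetitive contexts is
  alignment-based and returns the aligner's leftmost placement.
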