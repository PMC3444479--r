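# mtTreeScan

Evolution-based association scanning of full mitochondrial genomes in
case-control cohorts.

Mitochondrial DNA is maternally inherited without recombination: every
subject carries one haplotype, and all haplotypes in a cohort are related by
a single genealogy. Instead of testing markers one SNV at a time,
`mtTreeScan` builds a statistical-parsimony **haplotype network** (one
mutational step per edge, unsampled intermediates inferred, equally
parsimonious alternatives retained as loops) and tests **every branch**: a
branch splits the haplotypes into two clades, giving a haploid bi-allelic
genotype per subject. Each eligible branch (both classes holding at least 5
phenotyped subjects) is tested by the likelihood-ratio statistic for the
branch allele in a logistic regression

&nbsp;&nbsp;&nbsp;&nbsp;logit P(case) = β₀ + β_allele·g + β'·(age, sex, APOE ε4/ε2 dosage, familial risk)

using **Firth's penalized likelihood** so that a fully protective clade
(zero cases — complete separation) still yields a finite statistic.
Inference is by permutation of the subject→haplotype assignment, with
family-wise correction by the **step-down minP** (Westfall–Young) method,
which respects the strong correlation among nested branches. Conditional
second-round scans (the top branch allele entered as a covariate) decide
whether multiple significant branches represent one or several effects.

The package also provides the surrounding machinery such a study needs:
m-dot variant parsing against a pluggable reference, majority-rule
heteroplasmy resolution, gene/codon/synonymous annotation, pedigree kinship
(tabular method) and an r-weighted **familial-risk covariate**, matrilineal
haplotype **imputation** to unsequenced relatives, and a fully **synthetic
cohort generator** (coalescent haplotypes with expansion-style private
variation, matrilineal three-generation pedigrees, calibrated logistic
phenotypes, planted protective clades, heteroplasmy, missingness) so that
every stage is testable end to end without any cohort data.

## Worked example

```r
library(mtTreeScan)

# a synthetic cohort: 150 subjects in 40 matrilines, a fully protective
# clade of ~25 phenotyped carriers planted at a 35% baseline case rate
co <- simulateCohort(toyParams(seed = 21, beta = -Inf,
                               effectClade = "auto", targetCarriers = 25,
                               baselineCaseRate = 0.35))

prep <- prepareScan(co@variantTable, co@pedigree,
  co@subjects[, c("subject_id", "status", "age", "sex",
                  "apoe_e4", "apoe_e2", "genotyped")],
  co@reference,
  genotypedIds = co@subjects$subject_id[co@subjects$genotyped])
prep$network
#> HaplotypeNetwork: 55 nodes ( 18 observed, 37 inferred ), 55 edges,
#>   1 component(s), 1 loop(s)

res <- permutationScan(prep$network, prep$subjects,
                       scanConfig(B = 400, seed = 21))
res
#> TreeScanResult (round 1): 20 branches, 8 tested, 6 significant at alpha = 0.05
#>   b014  nominal 2.49e-03  corrected 0.02  (m.1758G>C)
#>   b015  nominal 7.48e-03  corrected 0.0324  (m.1249A>C,m.1653T>A)
#>   b017  nominal 4.99e-03  corrected 0.0324  (m.1472T>G)
#>   ...
```

The planted fully protective clade is the branch family's top signal: the
scan flags it together with its correlated neighbours, and the conditional
round then shows they represent a single association.

The show method lists each significant branch with its nominal and
corrected permutation p-values and the variants that define the branch
(a multi-segment branch lists one variant per segment). Per-clade
demographics in the cohort-table style (`N, mean age (sd), M/F,
cases/controls/missing`) come from `reportClade()`; `conditionalScan()`
reruns the scan conditioning on the top branch to separate nested signals.
`runPipeline()` drives the whole chain (simulate or load → collapse →
impute → network → scan ± familial-risk covariate → conditional rounds →
reports) from a YAML config and writes scan tables, GraphML, familial-risk
scores, clade demographics, a manifest and a log, all byte-deterministic
for a fixed seed. A thin command-line wrapper lives at
`inst/scripts/mtscan.R` (subcommands `run`, `simulate`, `famrisk`).

Numbers above are from the exact code shown (seeds included), so rerunning
reproduces them.

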