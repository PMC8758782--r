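# ocaphase

Pedigree-based phasing and classification of the *TYR* S192Y/R402Q
haplotype in oculocutaneous albinism (OCA).

## The problem

Two common *TYR* missense variants — p.(Ser192Tyr) (S192Y, c.575C>A,
chr11:g.89178528C>A) and p.(Arg402Gln) (R402Q, c.1205G>A,
chr11:g.89284793G>A; GRCh38) — are individually benign at population
frequencies of 36% and 27%, yet when they sit **in cis** on one
chromosome they form a hypomorphic OCA1B allele. Establishing that
requires resolving *phase*: whether an individual who carries both
variants has them on the same haplotype (cis) or on opposite haplotypes
(trans). In families segregating a clearly pathogenic *TYR* allele in
trans — such as Amish families carrying the founder variant
p.(Met252Arg) (M252R, c.755T>G) — phase can be read off Mendelian
transmission. `ocaphase` implements that inference chain as a tested,
reusable pipeline for clinical geneticists and rare-disease
statisticians:

1. **core model** — PED/FAM pedigree and VCF/TSV genotype I/O over a
   2–4 variant panel, with single-locus Mendelian validation;
2. **phasing** — exact cis/trans resolution across a pedigree from
   unphased genotypes by constraint satisfaction (arc-consistency
   pruning plus backtracking), under the no-recombination assumption
   justified by the ~106 kb panel span, plus a brute-force oracle for
   validation;
3. **classification** — haplotype compatibility screening
   (`haplotypePossible`), haplotype → allele-type assignment, and a
   deterministic diplotype → phenotype penetrance model
   (null/null → complete OCA; null / cis-haplotype → partial OCA1B;
   cis/cis homozygote → mild but fully penetrant hypomorphic phenotype;
   otherwise unaffected carrier);
4. **cohort statistics** — combined proportions across OCA cohorts with
   missing heritability and 2×2 Pearson chi-squared enrichment tests
   (Yates correction on by default);
5. **simulation** — gene-dropping over configurable founder haplotype
   frequency models (European and Amish defaults) with retained truth
   phase, so every stage is testable without patient data.

Formally, for individual $i$ with ordered diplotype
$(h^P_i, h^M_i) \in \{0,1\}^k \times \{0,1\}^k$, the engine enumerates
all diplotypes consistent with the observed dosage vector
$g_i \in \{0,1,2,\mathrm{NA}\}^k$ and retains those assignments where
$h^P_i \in \{h^P_{f(i)}, h^M_{f(i)}\}$ and
$h^M_i \in \{h^P_{m(i)}, h^M_{m(i)}\}$ for father $f(i)$ and mother
$m(i)$ — i.e. faithful transmission without recombination. A variant
pair is called CIS for $i$ iff every surviving global configuration
places both alternate alleles on one haplotype of $i$.

## Worked example

The packaged four-family fixture encodes the published constraints on
the Amish pedigrees (13 affected compound heterozygotes for M252R and
the S192Y/R402Q cis-haplotype, one affected M252R homozygote, seven
named unaffected carriers):

```r
library(ocaphase)
fx <- makeFixtureFamilies()
calls <- phaseVariantPair(fx$pedigree, fx$genotypes, fx$panel)
head(calls[calls$call == "CIS", ], 4)
#>     iid        pair call nCisStates nTransStates
#> 2 IX:10 R402Q,S192Y  CIS          1            0
#> 3 IX:12 R402Q,S192Y  CIS          1            0
#> 4 IX:14 R402Q,S192Y  CIS          1            0
#> 5 IX:15 R402Q,S192Y  CIS          1            0
```

Every affected compound heterozygote resolves CIS with a single
surviving state. Classification reproduces the genotype–phenotype
table exactly:

```r
res <- classifyPedigree(fx$pedigree, fx$genotypes, fx$panel)
res$concordance
#>                     observed
#> predicted            AFFECTED_COMPLETE AFFECTED_PARTIAL UNAFFECTED
#>   COMPLETE_OCA                       1                0          0
#>   PARTIAL_OCA1B                      0               13          0
#>   UNAFFECTED_CARRIER                 0                0         21
#>   UNAFFECTED                         0                0          2
```

Cohort-level screening and enrichment over the packaged count tables:

```r
runPipeline("reproduce-tables")
#> missing-heritability combined: 144/284 (50.7%)
#> molecularly diagnosed combined: 2/101 (2.0%)
#> informative-cohort cis-in-trans: 64/64 (100.0%)
#> diagnostic uplift: 64/251 (25.5%)
#> enrichment chi-squared: p < 2.2e-16 (Yates), p < 2.2e-16 (uncorrected)
```

So the haplotype is compatible in half of all missing-heritability OCA
individuals but only 2% of molecularly diagnosed ones, and in every
phase-informative case it sat in cis and in trans to the pathogenic
variant — a diagnostic uplift of 25.5% of missing-heritability cases.

A shell entry point wrapping the same functions ships at
`inst/scripts/ocaphase.R`
(`Rscript ocaphase.R {phase|classify|enrich|simulate|reproduce-tables}`).

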