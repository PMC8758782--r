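---
title: "Methods: pedigree phasing and classification of the TYR S192Y/R402Q haplotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree phasing and classification of the TYR S192Y/R402Q haplotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocaphase)
```

# The scientific model

Oculocutaneous albinism type 1 (OCA1) is recessive loss of tyrosinase
(*TYR*) function. Two common *TYR* missense variants, S192Y and R402Q,
are individually benign, but the recombinant haplotype carrying both
**in cis** is a hypomorphic allele: paired in trans with a pathogenic
null *TYR* allele it produces partial albinism (OCA1B), and in
homozygous form a mild but fully penetrant phenotype dominated by
foveal hypoplasia. The evidential crux is *phase*: an individual
heterozygous for both variants may carry them on one chromosome (cis)
or on opposite chromosomes (trans), and unphased sequencing cannot
distinguish these. In extended families that also segregate a rare
pathogenic allele — the package's motivating case is the Amish founder
variant M252R, whose haplotype itself carries R402Q — phase follows
deterministically from Mendelian transmission.

`ocaphase` operates on a `VariantPanel` of 2–4 biallelic loci on one
chromosome (default: S192Y, M252R, R402Q spanning ~106 kb of *TYR*), a
`Pedigree`, and a `GenotypeMatrix` of unphased alternate-allele
dosages. Any phase separators in input GT fields are discarded on
read: inferring phase is the engine's job, and pre-phased input must
not leak into its evaluation.

# The phasing engine

A haplotype is a length-$k$ binary vector (stored as a bit code); an
ordered diplotype state is a (paternal, maternal) pair. The engine
solves a constraint-satisfaction problem:

* **Dosage constraints.** Each individual's state must reproduce its
  observed dosages; missing loci are unconstrained. A genotype with $h$
  heterozygous and $m$ missing loci admits $2^h 4^m$ ordered states.
* **Transmission constraints.** Each non-founder's paternal haplotype
  must be one of the father's two haplotypes, and likewise maternally —
  faithful transmission with **no recombination** across the panel.
  With a per-meiosis recombination fraction of roughly 0.1% over
  106 kb, an apparent recombinant within a family is far more likely a
  sample swap or genotyping error, so it surfaces loudly as
  `INCONSISTENT` rather than being silently explained.

The solver prunes per-individual state sets to arc consistency over all
parent–child links, then uses backtracking search (most-constrained
variable first, ties and all iteration broken by sorted individual ids,
so output is reproducible bit for bit) to keep exactly the states that
occur in at least one globally consistent configuration of the whole
pedigree. Disconnected family components are solved independently; if
any component admits no configuration the whole solution is flagged
inconsistent and every state set is emptied, reporting the nuclear
family where the contradiction surfaced.

`exhaustivePhaseOracle()` implements the same contract by brute-force
enumeration (refusing pedigrees over 10 members). It shares no search
machinery with the solver and exists purely to validate it; the test
suite checks exact equivalence on hundreds of random gene-dropped
pedigrees, with and without missing genotypes.

## Phase calls

For a variant pair, a surviving state is *cis-bearing* if one of its
haplotypes carries both alternate alleles. An individual with both
dosages $\ge 1$ is called `CIS` if every surviving state is
cis-bearing, `TRANS` if none is, `UNINFORMATIVE` if both kinds survive,
`INCONSISTENT` if none survive. Individuals with dosage 0 at either
locus get `NOT_DOUBLE_HET`. Two consequences worth noting:

* Genotypes with a homozygous-alternate locus (dosages (1,2), (2,1),
  (2,2)) are *phase-forced*: every dosage-consistent state contains a
  double-alternate haplotype, so they resolve `CIS` without any family
  information. This generalises the textbook rule that a
  double-homozygote is trivially cis, and it matters in practice: a
  compound heterozygote for M252R and the cis-haplotype has R402Q
  dosage 2 because both disease alleles carry R402Q.
* The per-call counts reported are counts of surviving per-individual
  states per phase class, not counts of global configurations. Global
  configuration counts grow combinatorially in uninformative pedigrees
  while deciding nothing; the call mapping is identical either way.

## Mendelian validation

Single-locus violations (a child dosage producible by no choice of one
transmitted allele per recorded parent; missing dosages compatible with
everything) are detected by `validateMendelian()` before phasing. De
novo mutation is deliberately not modelled — the transmission argument
assumes faithful inheritance — so a flagged individual's entire
genotype row is masked out of phasing, the conservative reading of
"exclude the individual". Validation itself is report-only.

# The penetrance model

`assignAlleleType()` maps each haplotype to an allele type: any
`PATHOGENIC_NULL` variant makes the allele `NULL_PATHOGENIC` (common
variants riding along do not rescue it); both hypomorphic components
together make `HYPOMORPHIC_CIS`; otherwise `SINGLE_VARIANT` or
`REFERENCE`. `classifyDiplotype()` is a deterministic, symmetric map
from unordered allele-type pairs to phenotype predictions. Penetrance
is modelled as *deterministic given the diplotype*: the central claim
being encoded is that the cis-haplotype phenotypes are fully penetrant,
and apparent non-penetrance in the literature is attributed to
phenotyping depth (mild iris transillumination and foveal hypoplasia
are easily missed without OCT), not to a stochastic penetrance
parameter. The simulator can still inject label noise to model
misphenotyping. Two open design points were settled as follows:

* `HYPOMORPHIC_CIS` paired with `SINGLE_VARIANT` is unobserved in the
  source families; it defaults to `UNAFFECTED_CARRIER` with confidence
  `EXTRAPOLATED` (single variants are individually benign in the
  pedigree data).
* `MILD_HYPOMORPHIC` is kept distinct from `UNAFFECTED` because such
  individuals can self-report as unaffected; whether that mismatch
  counts against concordance is a switch
  (`mildMatchesUnaffected`, default strict) with no default claim
  intended.

`classifyPedigree()` assigns a prediction only when *all* surviving
phase states imply the same allele-type pair; otherwise
`INDETERMINATE`. Predictions computed from engine-resolved states
therefore agree with truth-diplotype predictions wherever the engine
resolves — a property the suite tests on simulations.

# Cohort statistics

Cohort evidence arrives as count tables (per-cohort totals,
haplotype-compatible counts, phase-informative counts, cis-in-trans
counts), because per-individual genotypes for the published cohorts are
not available. `aggregateCohorts()` sums numerators and denominators
and reports percentages rounded **half-up** to one decimal, matching
the published table formatting (base `round()` is half-even and would
give 2.0 vs 1.9 discrepancies). `pearsonChi2()` wraps
`stats::chisq.test` with the Yates continuity correction on by default
— the conventional default of the cited test for 2×2 tables — with the
uncorrected statistic one flag away; tests validate both against the
closed-form formula. The printed significance floor `p < 2.2e-16` is a
display convention; the actual double-precision p-value is reported
alongside the display string. Because the control-cohort denominator
behind one published percentage is not printed, the enrichment bound is
checked on the fully printed missing-heritability vs diagnosed table
(144/284 vs 2/101), where both corrections give $p \approx 10^{-17}$.

# The simulator and the packaged fixture

`simulatePedigrees()` gene-drops: founder haplotype pairs are drawn
i.i.d. from a `HapFreqModel`, and each child receives one uniformly
chosen haplotype per parent, no recombination. Default frequency
models encode the study populations:

| parameter | default | rationale |
|---|---|---|
| S192Y marginal | 0.36 | European allele frequency (gnomAD v2.1.1) |
| R402Q marginal | 0.27 | European allele frequency (gnomAD v2.1.1) |
| cis-haplotype | 0.015 | midpoint of the 1.1–1.9% European estimate; both endpoints reachable via `cisFreq` |
| M252R (Amish model) | 0.0023 | Amish control-cohort allele frequency; the founder haplotype carries R402Q in cis |

Residual mass goes to single-variant and reference haplotypes so the
marginals hold exactly; an infeasible combination errors rather than
renormalising silently. Family structure defaults — 3 generations,
Poisson sibship with mean 2 (first-generation sibships truncated at one
child so every family contains a transmission), each non-terminal child
marrying a newly drawn founder — are artifact choices representing
modest European-style families; endogamy is approximated only through
founder-frequency enrichment (the Amish model), not loop pedigrees.
All randomness flows from the single config seed; a fixed seed gives
byte-identical output.

What the simulator does *not* emulate: genotyping error, de novo
mutation, recombination within the panel, ascertainment bias, or
pedigree loops. Passing phase-recovery tests therefore demonstrate
correctness of the inference under the stated transmission model, not
robustness to data artefacts — which is the appropriate claim, since
the motivating genotypes were Sanger-confirmed.

`makeFixtureFamilies()` hand-builds the packaged four-family fixture to
satisfy every textual constraint on the source pedigrees: 14 affected
(9 in family 4 across generations IX/X, 4 in families 2–3, 1 in family
1), 13 affected compound heterozygotes resolving CIS, one affected
M252R homozygote, and the seven named unaffected carriers (five with
R402Q-only in trans to M252R, two with S192Y-only). The published
pedigree figure is not machine-readable, so sibship sizes and marriage
links beyond those constraints are synthetic; parental genotypes were
chosen so the engine can resolve phase for every affected individual.

# Validation scale and numerical choices

The shipped test suite validates at these problem sizes, chosen to
exercise each guarantee meaningfully: solver–oracle equivalence on 100+
random pedigrees of ≤ 10 members (including 15–20% missing genotypes);
zero CIS/TRANS-vs-truth contradictions across 1,000 simulated
pedigrees; founder-frequency recovery within 3 binomial standard errors
at 10,000 haplotype draws; exhaustive symmetry over all 16 ordered
allele-type pairs. Degenerate inputs are defined behaviour: singleton
individuals phase from their own genotype (forced or uninformative),
all-missing genotypes classify `INDETERMINATE`, empty margins in the
2×2 test and infeasible frequency models are named errors, and panels
beyond 4 loci are refused rather than degraded.

# Known limitations

* Hard constraints only: no error-tolerant or likelihood-based phasing
  (Lander–Green/Elston–Stewart), no population/LD phasing, no
  read-backed phasing. At panel scale (2–4 loci, Sanger-grade
  genotypes) hard constraints are exact and auditable.
* Severity is not graded among null alleles; OCA1A/OCA1B nuance beyond
  the modelled diplotype classes is out of scope.
* The enrichment module ships no confidence intervals or heterogeneity
  models; it reproduces combined proportions and 2×2 tests only.
* The exhaustive oracle is exponential by design and refuses pedigrees
  over 10 members; it is a validation tool, not an analysis path.
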