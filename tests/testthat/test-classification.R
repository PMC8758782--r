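test_that("haplotype-possible rule: both variants present, missing is
           conservative, and the rule is monotone in each dosage", {
  expect_true(haplotypePossible(2L, 1L))
  expect_true(haplotypePossible(1L, 1L))
  expect_false(haplotypePossible(1L, 0L))
  expect_false(haplotypePossible(0L, 0L))
  expect_false(haplotypePossible(NA, 2L))
  ## monotone non-decreasing in each argument
  for (a in 0:2) for (b in 0:2) {
    if (a < 2) expect_gte(haplotypePossible(a + 1L, b),
                          haplotypePossible(a, b))
    if (b < 2) expect_gte(haplotypePossible(a, b + 1L),
                          haplotypePossible(a, b))
  }
})

test_that("allele types follow the panel pathogenicity classes", {
  panel <- tyrPanel()  # bits: 1 = S192Y, 2 = M252R, 4 = R402Q
  ## the Amish M252R haplotype carries R402Q in cis yet stays a null allele
  expect_identical(assignAlleleType(c(0L, 1L, 1L), panel),
                   "NULL_PATHOGENIC")
  expect_identical(assignAlleleType(c(1L, 1L, 1L), panel),
                   "NULL_PATHOGENIC")
  expect_identical(assignAlleleType(c(1L, 0L, 1L), panel),
                   "HYPOMORPHIC_CIS")
  expect_identical(assignAlleleType(c(1L, 0L, 0L), panel),
                   "SINGLE_VARIANT")
  expect_identical(assignAlleleType(c(0L, 0L, 1L), panel),
                   "SINGLE_VARIANT")
  expect_identical(assignAlleleType(c(0L, 0L, 0L), panel), "REFERENCE")
  ## integer haplotype codes decode identically
  expect_identical(assignAlleleType(6L, panel), "NULL_PATHOGENIC")
  expect_identical(assignAlleleType(5L, panel), "HYPOMORPHIC_CIS")
})

test_that("diplotype classification is symmetric and maps the observed
           genotype-phenotype pairs", {
  types <- c("NULL_PATHOGENIC", "HYPOMORPHIC_CIS", "SINGLE_VARIANT",
             "REFERENCE")
  for (a in types) for (b in types) {
    ab <- classifyDiplotype(a, b)
    ba <- classifyDiplotype(b, a)
    expect_identical(ab$predicted, ba$predicted)
    expect_identical(ab$confidence, ba$confidence)
    ## deterministic penetrance: always a definite class, never a
    ## probability
    expect_true(ab$predicted %in% c("COMPLETE_OCA", "PARTIAL_OCA1B",
                                    "MILD_HYPOMORPHIC",
                                    "UNAFFECTED_CARRIER", "UNAFFECTED"))
  }
  expect_identical(
    classifyDiplotype("NULL_PATHOGENIC", "HYPOMORPHIC_CIS")$predicted,
    "PARTIAL_OCA1B")
  expect_identical(
    classifyDiplotype("NULL_PATHOGENIC", "NULL_PATHOGENIC")$predicted,
    "COMPLETE_OCA")
  expect_identical(
    classifyDiplotype("NULL_PATHOGENIC", "SINGLE_VARIANT")$predicted,
    "UNAFFECTED_CARRIER")
  mild <- classifyDiplotype("HYPOMORPHIC_CIS", "HYPOMORPHIC_CIS")
  expect_identical(mild$predicted, "MILD_HYPOMORPHIC")
  ## the pairing never observed in the families is flagged extrapolated
  expect_identical(
    classifyDiplotype("HYPOMORPHIC_CIS", "SINGLE_VARIANT")$confidence,
    "EXTRAPOLATED")
})

test_that("pedigree classification: fixture counts and concordance", {
  fx <- makeFixtureFamilies()
  res <- classifyPedigree(fx$pedigree, fx$genotypes, fx$panel)
  pred <- res$predictions
  aff <- pred[pred$iid %in% fx$affected, ]
  expect_identical(sum(aff$predicted == "PARTIAL_OCA1B"), 13L)
  expect_identical(sum(aff$predicted == "COMPLETE_OCA"), 1L)
  carriers <- pred[pred$iid %in% fx$namedCarriers, ]
  expect_true(all(carriers$predicted == "UNAFFECTED_CARRIER"))
  ## every prediction on the fixture is concordant with the recorded
  ## phenotype
  expect_true(all(pred$concordant == "Y"))
  expect_identical(
    unname(res$concordance["PARTIAL_OCA1B", "AFFECTED_PARTIAL"]), 13L)
})

test_that("all-missing genotypes give INDETERMINATE throughout", {
  fx <- makeFixtureFamilies()
  d <- dosages(fx$genotypes)
  d[] <- NA_integer_
  g <- GenotypeMatrix(d, fx$pedigree, fx$panel)
  res <- classifyPedigree(fx$pedigree, g, fx$panel)
  expect_true(all(res$predictions$predicted == "INDETERMINATE"))
  expect_true(all(res$predictions$concordant == "NA"))
})

test_that("mild homozygotes can optionally count as concordant with an
           unaffected label", {
  panel <- tyrPanel()
  solo <- Pedigree(data.frame(fid = "S", iid = "a", father = NA,
                              mother = NA, sex = "UNKNOWN",
                              phenotype = "UNAFFECTED"))
  ## homozygous for the in-cis haplotype: dosages (2, 0, 2)
  g <- genoFromList(list(a = c(2L, 0L, 2L)), panel, solo)
  strict <- classifyPedigree(solo, g, panel)
  expect_identical(strict$predictions$predicted, "MILD_HYPOMORPHIC")
  expect_identical(strict$predictions$concordant, "N")
  lax <- classifyPedigree(solo, g, panel, mildMatchesUnaffected = TRUE)
  expect_identical(lax$predictions$concordant, "Y")
})

test_that("predictions from engine-resolved phase agree with truth
           diplotypes wherever the engine resolves", {
  for (seed in c(401, 402, 403)) {
    sim <- randomSim(seed, nFamilies = 3L, generations = 3L,
                     sibshipMean = 2)
    panel <- sim$panel
    typeOf <- function(h) assignAlleleType(h, panel)
    truthPred <- vapply(seq_len(nrow(sim$truth)), function(i)
      classifyDiplotype(typeOf(sim$truth$hapPat[i]),
                        typeOf(sim$truth$hapMat[i]))$predicted,
      character(1L))
    names(truthPred) <- sim$truth$iid
    res <- classifyPedigree(sim$pedigree, sim$genotypes, panel)
    resolved <- res$predictions[res$predictions$predicted !=
                                  "INDETERMINATE", ]
    expect_identical(resolved$predicted,
                     unname(truthPred[resolved$iid]))
  }
})
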