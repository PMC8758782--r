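test_that("diplotype state enumeration has the expected cardinalities", {
  ## 2-locus genotypes: 2^h ordered states, x4 per missing locus
  expect_identical(nrow(enumerateDiplotypeStates(c(2L, 2L), 2L)), 1L)
  expect_identical(nrow(enumerateDiplotypeStates(c(1L, 1L), 2L)), 4L)
  expect_identical(nrow(enumerateDiplotypeStates(c(1L, NA), 2L)), 8L)
  expect_identical(nrow(enumerateDiplotypeStates(c(NA, NA), 2L)), 16L)
  ## homozygote forces phase: the single (2,2) state is alt-alt/alt-alt
  st <- enumerateDiplotypeStates(c(2L, 2L), 2L)
  expect_identical(unname(st[1L, ]), c(3L, 3L))
})

test_that("trio transmissions resolve cis, trans and uninformative phase", {
  panel <- twoLocusPanel()
  ped <- trioPed()
  pair <- c("S192Y", "R402Q")
  callOf <- function(calls, iid) calls$call[calls$iid == iid]

  ## mother (1,1) x father (0,0), child (1,1): child's maternal haplotype
  ## carries both alts, so mother and child are CIS
  g <- genoFromList(list(dad = c(0L, 0L), mum = c(1L, 1L),
                         kid = c(1L, 1L)), panel, ped)
  calls <- phaseVariantPair(ped, g, panel, pair)
  expect_identical(callOf(calls, "mum"), "CIS")
  expect_identical(callOf(calls, "kid"), "CIS")

  ## child (1,0): the transmitted maternal haplotype carries only the
  ## first alt, so the mother's alts sit on opposite haplotypes
  g <- genoFromList(list(dad = c(0L, 0L), mum = c(1L, 1L),
                         kid = c(1L, 0L)), panel, ped)
  calls <- phaseVariantPair(ped, g, panel, pair)
  expect_identical(callOf(calls, "mum"), "TRANS")

  ## all three double-het: both cis-cis and trans-trans configurations
  ## survive, so everyone is uninformative
  g <- genoFromList(list(dad = c(1L, 1L), mum = c(1L, 1L),
                         kid = c(1L, 1L)), panel, ped)
  calls <- phaseVariantPair(ped, g, panel, pair)
  expect_true(all(calls$call == "UNINFORMATIVE"))

  ## each matches the exhaustive oracle
  for (kid in list(c(1L, 1L), c(1L, 0L))) {
    g <- genoFromList(list(dad = c(0L, 0L), mum = c(1L, 1L), kid = kid),
                      panel, ped)
    expect_same_solution(solvePedigreePhase(ped, g, panel),
                         exhaustivePhaseOracle(ped, g, panel))
  }
})

test_that("singletons: homozygous-alt is forced CIS, double-het is not", {
  panel <- twoLocusPanel()
  solo <- Pedigree(data.frame(fid = "S", iid = "a", father = NA,
                              mother = NA, sex = "UNKNOWN",
                              phenotype = "UNKNOWN"))
  g <- genoFromList(list(a = c(2L, 2L)), panel, solo)
  expect_identical(phaseVariantPair(solo, g, panel)$call, "CIS")
  ## het at one locus, hom-alt at the other is also phase-forced
  g <- genoFromList(list(a = c(1L, 2L)), panel, solo)
  expect_identical(phaseVariantPair(solo, g, panel)$call, "CIS")
  g <- genoFromList(list(a = c(1L, 1L)), panel, solo)
  expect_identical(phaseVariantPair(solo, g, panel)$call, "UNINFORMATIVE")
  g <- genoFromList(list(a = c(1L, 0L)), panel, solo)
  expect_identical(phaseVariantPair(solo, g, panel)$call, "NOT_DOUBLE_HET")
})

test_that("phase calls are invariant to locus order in the pair", {
  fx <- makeFixtureFamilies()
  sol <- solvePedigreePhase(fx$pedigree, fx$genotypes, fx$panel)
  a <- phaseVariantPair(fx$pedigree, fx$genotypes, fx$panel,
                        c("S192Y", "R402Q"), solution = sol)
  b <- phaseVariantPair(fx$pedigree, fx$genotypes, fx$panel,
                        c("R402Q", "S192Y"), solution = sol)
  expect_identical(a$call, b$call)
  expect_identical(a$nCisStates, b$nCisStates)
})

test_that("adding genotyped relatives only sharpens phase calls", {
  panel <- twoLocusPanel()
  ## the child alone is uninformative ...
  solo <- Pedigree(data.frame(fid = "S", iid = "kid", father = NA,
                              mother = NA, sex = "UNKNOWN",
                              phenotype = "UNKNOWN"))
  g1 <- genoFromList(list(kid = c(1L, 1L)), panel, solo)
  expect_identical(phaseVariantPair(solo, g1, panel)$call, "UNINFORMATIVE")
  ## ... and resolves to CIS, never the opposite, once parents are typed
  ped <- trioPed()
  g2 <- genoFromList(list(dad = c(0L, 0L), mum = c(1L, 1L),
                          kid = c(1L, 1L)), panel, ped)
  calls <- phaseVariantPair(ped, g2, panel)
  expect_identical(calls$call[calls$iid == "kid"], "CIS")
})

test_that("a phase-contradictory pedigree is flagged INCONSISTENT", {
  panel <- twoLocusPanel()
  ## one father, two spouses: child1 proves the father cis, child2
  ## proves him trans; every genotype is single-locus Mendelian-clean
  ped <- Pedigree(data.frame(
    fid = "C",
    iid = c("dad", "mum1", "mum2", "kid1", "kid2"),
    father = c(NA, NA, NA, "dad", "dad"),
    mother = c(NA, NA, NA, "mum1", "mum2"),
    sex = c("MALE", "FEMALE", "FEMALE", "UNKNOWN", "UNKNOWN"),
    phenotype = "UNKNOWN"))
  g <- genoFromList(list(dad = c(1L, 1L), mum1 = c(0L, 0L),
                         mum2 = c(0L, 0L), kid1 = c(1L, 1L),
                         kid2 = c(1L, 0L)), panel, ped)
  expect_identical(nrow(validateMendelian(ped, g, panel)), 0L)
  sol <- solvePedigreePhase(ped, g, panel)
  expect_false(sol$consistent)
  expect_true(all(vapply(sol$domains, nrow, integer(1L)) == 0L))
  calls <- phaseVariantPair(ped, g, panel, solution = sol)
  expect_true(all(calls$call == "INCONSISTENT"))
  ## the oracle agrees there is no consistent configuration
  ora <- exhaustivePhaseOracle(ped, g, panel)
  expect_false(ora$consistent)
  expect_identical(ora$nConfigs, 0L)
})

test_that("a trans haplotype gene-dropped across generations is called
           TRANS by both solver and oracle", {
  panel <- twoLocusPanel()
  ## grandmother carries the alts in trans; each descendant inherits the
  ## S192Y-only haplotype while R402Q enters again via a spouse
  ped <- Pedigree(data.frame(
    fid = "G",
    iid = c("gma", "gpa", "dad", "mum", "kid"),
    father = c(NA, NA, "gpa", NA, "dad"),
    mother = c(NA, NA, "gma", NA, "mum"),
    sex = c("FEMALE", "MALE", "MALE", "FEMALE", "UNKNOWN"),
    phenotype = "UNKNOWN"))
  g <- genoFromList(list(gma = c(1L, 1L), gpa = c(0L, 0L),
                         dad = c(1L, 0L), mum = c(0L, 1L),
                         kid = c(1L, 1L)), panel, ped)
  sol <- solvePedigreePhase(ped, g, panel)
  calls <- phaseVariantPair(ped, g, panel, solution = sol)
  expect_identical(calls$call[calls$iid == "kid"], "TRANS")
  expect_identical(calls$call[calls$iid == "gma"], "TRANS")
  expect_same_solution(sol, exhaustivePhaseOracle(ped, g, panel))
})

test_that("solver matches the exhaustive oracle on random pedigrees with
           missing genotypes", {
  set.seed(11)
  done <- 0L
  for (i in 1:40) {
    sim <- randomSim(seed = 300 + i, maskFrac = 0.2)
    if (length(sim$pedigree) > 10L) next
    sol <- solvePedigreePhase(sim$pedigree, sim$genotypes, sim$panel)
    ora <- exhaustivePhaseOracle(sim$pedigree, sim$genotypes, sim$panel)
    expect_same_solution(sol, ora)
    done <- done + 1L
  }
  expect_gte(done, 20L)
})

test_that("Mendelian-violating individuals are excluded from phasing", {
  panel <- twoLocusPanel()
  ped <- trioPed()
  ## impossible child: alt from both parents required but absent in dad
  g <- genoFromList(list(dad = c(0L, 0L), mum = c(2L, 0L),
                         kid = c(2L, 2L)), panel, ped)
  sol <- solvePedigreePhase(ped, g, panel)
  expect_true("kid" %in% sol$excluded)
  expect_true(sol$consistent)  # remaining members still phase cleanly
  calls <- phaseVariantPair(ped, g, panel, solution = sol)
  expect_false("kid" %in% calls$iid)
})
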