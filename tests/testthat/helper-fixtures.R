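## Shared in-code fixtures for the test suite.

## two-locus panel holding just the hypomorphic pair
twoLocusPanel <- function() {
  VariantPanel(id = c("S192Y", "R402Q"), chrom = "chr11",
               pos = c(89178528L, 89284793L), ref = c("C", "G"),
               alt = c("A", "A"),
               pathoClass = rep("HYPOMORPHIC_COMPONENT", 2L))
}

## father/mother/child trio pedigree
trioPed <- function(fid = "T1") {
  Pedigree(data.frame(
    fid = fid, iid = c("dad", "mum", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
    sex = c("MALE", "FEMALE", "UNKNOWN"),
    phenotype = "UNKNOWN"))
}

## genotype matrix from a named list of dosage vectors
genoFromList <- function(dosList, panel, pedigree = NULL) {
  d <- do.call(rbind, dosList)
  rownames(d) <- names(dosList)
  colnames(d) <- variantIds(panel)
  GenotypeMatrix(d, pedigree = pedigree, panel = panel)
}

## unordered key set of a phase-solution domain, for solver comparisons
domainKeys <- function(dom) {
  sort(paste(pmin(dom[, 1L], dom[, 2L]), pmax(dom[, 1L], dom[, 2L])))
}

## ordered key set (distinguishes (a,b) from (b,a))
domainKeysOrdered <- function(dom) sort(paste(dom[, 1L], dom[, 2L]))

expect_same_solution <- function(sol, ora) {
  expect_identical(sol$consistent, ora$consistent)
  for (iid in names(sol$domains))
    expect_identical(domainKeysOrdered(sol$domains[[iid]]),
                     domainKeysOrdered(ora$domains[[iid]]),
                     label = paste("domain of", iid))
}

## random small pedigree + genotypes via gene dropping, optionally with
## genotypes masked at random
randomSim <- function(seed, nFamilies = 1L, generations = 2L,
                      sibshipMean = 3, m252r = 0.2, maskFrac = 0) {
  cfg <- simConfig(
    nFamilies = nFamilies, generations = generations,
    sibshipMean = sibshipMean,
    freqModel = defaultFrequencyModel("AMISH", freqM252R = m252r),
    seed = seed)
  sim <- simulatePedigrees(cfg)
  if (maskFrac > 0) {
    d <- dosages(sim$genotypes)
    idx <- sample(length(d), ceiling(length(d) * maskFrac))
    d[idx] <- NA_integer_
    sim$genotypes <- GenotypeMatrix(d, sim$pedigree, sim$panel)
  }
  sim
}
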