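## Gene-dropping pedigree simulator. Founder haplotypes are drawn from a
## population frequency model; each child receives one uniformly chosen
## haplotype from each parent with no recombination across the panel
## span. Truth phase is retained so engine calls can be scored exactly.

#' Construct a founder haplotype frequency model
#'
#' @param panel A \linkS4class{VariantPanel}.
#' @param freq Named numeric vector of haplotype frequencies; names are
#'   \code{"+"}-joined variant ids (\code{"REF"} for the reference
#'   haplotype), e.g. \code{c(REF = 0.385, S192Y = 0.345,
#'   "S192Y+R402Q" = 0.015, R402Q = 0.255)}.
#' @return A \linkS4class{HapFreqModel}.
#' @export
HapFreqModel <- function(panel, freq) {
  ids <- variantIds(panel)
  codes <- vapply(names(freq), function(nm) {
    if (nm == "REF") return(0L)
    parts <- strsplit(nm, "+", fixed = TRUE)[[1L]]
    bad <- setdiff(parts, ids)
    if (length(bad))
      stop("unknown variant in haplotype name '", nm, "': ",
           paste(bad, collapse = ", "))
    sum(bitwShiftL(1L, match(parts, ids) - 1L))
  }, integer(1L))
  new("HapFreqModel", panel = panel, hapCodes = unname(codes),
      freq = unname(freq))
}

#' @rdname HapFreqModel-class
#' @export
setMethod("hapFrequencies", "HapFreqModel", function(x) {
  ids <- variantIds(x@panel)
  nm <- vapply(x@hapCodes, function(h) {
    on <- ids[hapAlleles(h, x@panel)[1L, ] == 1L]
    if (!length(on)) "REF" else paste(on, collapse = "+")
  }, character(1L))
  stats::setNames(x@freq, nm)
})

#' @rdname HapFreqModel-class
#' @export
setMethod("marginalAlleleFreqs", "HapFreqModel", function(x) {
  al <- hapAlleles(x@hapCodes, x@panel)
  stats::setNames(drop(crossprod(al, x@freq)), variantIds(x@panel))
})

#' @rdname HapFreqModel-class
#' @export
setMethod("show", "HapFreqModel", function(object) {
  cat("HapFreqModel over", length(object@panel), "loci\n")
  print(round(hapFrequencies(object), 4L))
  cat("marginal allele frequencies:\n")
  print(round(marginalAlleleFreqs(object), 4L))
})

#' Default founder haplotype frequency models
#'
#' \code{EUROPEAN}: marginal allele frequencies 0.36 (S192Y) and 0.27
#' (R402Q) as reported for European populations (gnomAD v2.1.1), with
#' the S192Y/R402Q in-cis haplotype at 0.015 -- the midpoint of the
#' 1.1--1.9\% range estimated for European populations -- and no M252R.
#' \code{AMISH}: additionally an M252R-bearing haplotype, itself
#' carrying R402Q in cis, at the Amish control-cohort allele frequency
#' 0.0023. Residual mass goes to the single-variant and reference
#' haplotypes so the marginals hold exactly; an infeasible combination
#' (e.g. a cis frequency above a marginal) is an error, never a silent
#' renormalisation.
#'
#' @param population \code{"EUROPEAN"} or \code{"AMISH"}.
#' @param freqS192Y,freqR402Q Marginal allele frequencies.
#' @param cisFreq In-cis S192Y/R402Q haplotype frequency.
#' @param freqM252R M252R allele frequency (AMISH only).
#' @param panel The variant panel (default \code{\link{tyrPanel}}).
#' @return A \linkS4class{HapFreqModel}.
#' @examples
#' marginalAlleleFreqs(defaultFrequencyModel("AMISH"))
#' @export
defaultFrequencyModel <- function(population = c("EUROPEAN", "AMISH"),
                                  freqS192Y = 0.36, freqR402Q = 0.27,
                                  cisFreq = 0.015, freqM252R = 0.0023,
                                  panel = tyrPanel()) {
  population <- match.arg(population)
  m252r <- if (population == "AMISH") freqM252R else 0
  fS <- freqS192Y - cisFreq
  fR <- freqR402Q - cisFreq - m252r
  fRef <- 1 - fS - fR - cisFreq - m252r
  checks <- c("S192Y-only haplotype (freqS192Y - cisFreq)" = fS,
              "R402Q-only haplotype (freqR402Q - cisFreq - freqM252R)" = fR,
              "reference haplotype (residual)" = fRef)
  if (any(checks < 0))
    stop("infeasible frequency model; negative mass for: ",
         paste(names(checks)[checks < 0], collapse = "; "))
  freq <- c(REF = fRef, S192Y = fS, R402Q = fR, `S192Y+R402Q` = cisFreq)
  if (m252r > 0) freq <- c(freq, `M252R+R402Q` = m252r)
  HapFreqModel(panel, freq)
}

#' Simulation configuration
#'
#' @param nFamilies Number of independent families.
#' @param generations Number of generations (founder couple = 1).
#' @param sibshipMean Mean of the Poisson sibship-size distribution
#'   (first-generation sibships are truncated at one child so every
#'   family contains at least one transmission).
#' @param freqModel A \linkS4class{HapFreqModel} for founder haplotypes.
#' @param labelNoise Probability that a truth phenotype label is
#'   replaced by a different label or \code{UNKNOWN}.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(nFamilies = 1L, generations = 3L, sibshipMean = 2,
                      freqModel = defaultFrequencyModel("EUROPEAN"),
                      labelNoise = 0, seed = 1L) {
  stopifnot(nFamilies >= 1L, generations >= 2L, sibshipMean >= 0,
            labelNoise >= 0, labelNoise <= 1)
  structure(list(nFamilies = as.integer(nFamilies),
                 generations = as.integer(generations),
                 sibshipMean = sibshipMean, freqModel = freqModel,
                 labelNoise = labelNoise, seed = as.integer(seed)),
            class = "SimConfig")
}

.predictionToPhenotype <- c(
  COMPLETE_OCA = "AFFECTED_COMPLETE", PARTIAL_OCA1B = "AFFECTED_PARTIAL",
  MILD_HYPOMORPHIC = "AFFECTED_MILD", UNAFFECTED_CARRIER = "UNAFFECTED",
  UNAFFECTED = "UNAFFECTED")

#' Simulate pedigrees by gene dropping
#'
#' Builds each family from a founder couple: every child in a
#' non-terminal generation marries a newly drawn founder spouse and the
#' couple has a Poisson-distributed number of children. Founder
#' haplotype pairs are drawn from the frequency model; each child
#' receives one uniformly chosen haplotype from each parent, with no
#' recombination. Truth phase is retained, the released genotype matrix
#' carries dosages only, and phenotype labels come from the
#' deterministic penetrance model applied to the truth diplotypes
#' (optionally perturbed by label noise).
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list: \code{pedigree} (\linkS4class{Pedigree}, with the
#'   noisy labels as observed phenotypes), \code{genotypes}
#'   (\linkS4class{GenotypeMatrix}, phase masked), \code{truth}
#'   (data.frame \code{iid}, \code{hapPat}, \code{hapMat} codes,
#'   \code{founder}), \code{labels} (data.frame \code{iid},
#'   \code{truthPhenotype}, \code{phenotype}), \code{panel},
#'   \code{config}.
#' @export
simulatePedigrees <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  model <- config$freqModel
  panel <- model@panel
  haps <- model@hapCodes
  pfreq <- model@freq
  drawFounderHaps <- function(n)
    matrix(sample(haps, 2L * n, replace = TRUE, prob = pfreq), ncol = 2L)
  rows <- list(); hp <- list()
  for (fam in seq_len(config$nFamilies)) {
    fid <- paste0("F", fam)
    nextId <- 1L
    newIid <- function() {
      id <- sprintf("%s_I%03d", fid, nextId)
      nextId <<- nextId + 1L
      id
    }
    addFounder <- function(sex) {
      iid <- newIid()
      rows[[length(rows) + 1L]] <<- data.frame(
        fid = fid, iid = iid, father = NA_character_,
        mother = NA_character_, sex = sex, phenotype = "UNKNOWN")
      hp[[iid]] <<- drawFounderHaps(1L)[1L, ]
      iid
    }
    addChild <- function(fatherIid, motherIid, sex) {
      iid <- newIid()
      rows[[length(rows) + 1L]] <<- data.frame(
        fid = fid, iid = iid, father = fatherIid, mother = motherIid,
        sex = sex, phenotype = "UNKNOWN")
      hp[[iid]] <<- c(hp[[fatherIid]][sample.int(2L, 1L)],
                      hp[[motherIid]][sample.int(2L, 1L)])
      iid
    }
    couples <- list(c(addFounder("MALE"), addFounder("FEMALE")))
    for (g in seq_len(config$generations - 1L)) {
      nextCouples <- list()
      for (cp in couples) {
        nKids <- stats::rpois(1L, config$sibshipMean)
        if (g == 1L) nKids <- max(1L, nKids)
        for (kid in seq_len(nKids)) {
          sex <- if (kid %% 2L == 1L) "MALE" else "FEMALE"
          child <- addChild(cp[1L], cp[2L], sex)
          if (g < config$generations - 1L) {
            spouse <- addFounder(if (sex == "MALE") "FEMALE" else "MALE")
            nextCouples[[length(nextCouples) + 1L]] <-
              if (sex == "MALE") c(child, spouse) else c(spouse, child)
          }
        }
      }
      couples <- nextCouples
      if (!length(couples)) break
    }
  }
  ped <- do.call(rbind, rows)
  iids <- ped$iid
  hapPat <- vapply(iids, function(i) hp[[i]][1L], integer(1L))
  hapMat <- vapply(iids, function(i) hp[[i]][2L], integer(1L))
  truth <- data.frame(iid = iids, hapPat = hapPat, hapMat = hapMat,
                      founder = is.na(ped$father) & is.na(ped$mother))
  ## truth labels from the deterministic penetrance model
  typeOfHap <- vapply(0:(2L^length(panel) - 1L),
                      function(h) assignAlleleType(h, panel), character(1L))
  truthPheno <- vapply(seq_along(iids), function(i) {
    cls <- classifyDiplotype(typeOfHap[hapPat[i] + 1L],
                             typeOfHap[hapMat[i] + 1L])
    unname(.predictionToPhenotype[cls$predicted])
  }, character(1L))
  pheno <- truthPheno
  if (config$labelNoise > 0) {
    flip <- stats::runif(length(pheno)) < config$labelNoise
    pheno[flip] <- vapply(pheno[flip], function(p)
      sample(setdiff(.phenotypeLevels, p), 1L), character(1L))
  }
  ped$phenotype <- pheno
  pedigree <- Pedigree(ped)
  dos <- hapAlleles(hapPat, panel) + hapAlleles(hapMat, panel)
  rownames(dos) <- iids
  genotypes <- GenotypeMatrix(dos, pedigree = pedigree, panel = panel)
  list(pedigree = pedigree, genotypes = genotypes, truth = truth,
       labels = data.frame(iid = iids, truthPhenotype = truthPheno,
                           phenotype = pheno),
       panel = panel, config = config)
}

#' True cis/trans phase of a variant pair from simulator truth
#'
#' @param truth The \code{truth} data.frame from
#'   \code{\link{simulatePedigrees}}.
#' @param panel The simulation panel.
#' @param pair Two variant ids.
#' @return Character vector (\code{CIS}/\code{TRANS}/
#'   \code{NOT_DOUBLE_HET}) named by iid: \code{CIS} when some truth
#'   haplotype carries both alternate alleles, \code{TRANS} when both
#'   are present but on opposite haplotypes.
#' @export
truthPhase <- function(truth, panel, pair = c("S192Y", "R402Q")) {
  ids <- variantIds(panel)
  a <- match(pair[1L], ids); b <- match(pair[2L], ids)
  al <- function(h, j) as.integer(bitwAnd(h, bitwShiftL(1L, j - 1L)) > 0)
  dA <- al(truth$hapPat, a) + al(truth$hapMat, a)
  dB <- al(truth$hapPat, b) + al(truth$hapMat, b)
  cis <- .hapHasBoth(truth$hapPat, a, b) | .hapHasBoth(truth$hapMat, a, b)
  out <- ifelse(dA >= 1L & dB >= 1L, ifelse(cis, "CIS", "TRANS"),
                "NOT_DOUBLE_HET")
  stats::setNames(out, truth$iid)
}
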