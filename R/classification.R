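## Genotype-compatibility rule and deterministic diplotype -> phenotype
## model for the TYR S192Y/R402Q in-cis haplotype.

#' Is the S192Y/R402Q haplotype possible for a genotype?
#'
#' The cohort-screening rule: an individual could carry the in-cis
#' haplotype iff they are homozygous or heterozygous for both variants,
#' i.e. both dosages are at least 1. Missing dosages are conservative:
#' \code{FALSE}.
#'
#' @param dosageS192Y,dosageR402Q Integer dosages (0/1/2/\code{NA});
#'   vectorised.
#' @return Logical vector.
#' @examples
#' haplotypePossible(2, 1)  # TRUE
#' haplotypePossible(1, 0)  # FALSE
#' @export
haplotypePossible <- function(dosageS192Y, dosageR402Q) {
  !is.na(dosageS192Y) & !is.na(dosageR402Q) &
    dosageS192Y >= 1L & dosageR402Q >= 1L
}

#' Classify a haplotype into an allele type
#'
#' A haplotype carrying any \code{PATHOGENIC_NULL} panel variant is a
#' \code{NULL_PATHOGENIC} allele regardless of accompanying common
#' variants (the Amish M252R haplotype itself carries R402Q in cis). A
#' haplotype carrying every \code{HYPOMORPHIC_COMPONENT} variant (here
#' S192Y and R402Q) is the \code{HYPOMORPHIC_CIS} allele. Otherwise the
#' haplotype is \code{SINGLE_VARIANT} if it carries any alternate allele
#' and \code{REFERENCE} if none.
#'
#' @param hap Haplotype as a 0/1 vector in panel order, or an integer
#'   bit code (see \code{\link{hapAlleles}}).
#' @param panel A \linkS4class{VariantPanel}.
#' @return One of \code{"NULL_PATHOGENIC"}, \code{"HYPOMORPHIC_CIS"},
#'   \code{"SINGLE_VARIANT"}, \code{"REFERENCE"}.
#' @export
assignAlleleType <- function(hap, panel) {
  if (length(hap) == 1L && length(panel) > 1L)
    hap <- drop(hapAlleles(as.integer(hap), panel))
  stopifnot(length(hap) == length(panel))
  pc <- unname(pathoClasses(panel))
  if (any(hap == 1L & pc == "PATHOGENIC_NULL")) return("NULL_PATHOGENIC")
  comp <- pc == "HYPOMORPHIC_COMPONENT"
  if (sum(comp) >= 2L && all(hap[comp] == 1L)) return("HYPOMORPHIC_CIS")
  if (any(hap == 1L)) return("SINGLE_VARIANT")
  "REFERENCE"
}

## diplotype -> (prediction, confidence); deterministic penetrance
.diploRules <- local({
  r <- list(
    c("NULL_PATHOGENIC", "NULL_PATHOGENIC", "COMPLETE_OCA", "OBSERVED_IN_PAPER"),
    c("NULL_PATHOGENIC", "HYPOMORPHIC_CIS", "PARTIAL_OCA1B", "OBSERVED_IN_PAPER"),
    c("HYPOMORPHIC_CIS", "HYPOMORPHIC_CIS", "MILD_HYPOMORPHIC", "OBSERVED_IN_PAPER"),
    c("NULL_PATHOGENIC", "SINGLE_VARIANT", "UNAFFECTED_CARRIER", "OBSERVED_IN_PAPER"),
    c("NULL_PATHOGENIC", "REFERENCE", "UNAFFECTED_CARRIER", "OBSERVED_IN_PAPER"),
    c("HYPOMORPHIC_CIS", "SINGLE_VARIANT", "UNAFFECTED_CARRIER", "EXTRAPOLATED"),
    c("HYPOMORPHIC_CIS", "REFERENCE", "UNAFFECTED_CARRIER", "EXTRAPOLATED"),
    c("SINGLE_VARIANT", "SINGLE_VARIANT", "UNAFFECTED", "OBSERVED_IN_PAPER"),
    c("SINGLE_VARIANT", "REFERENCE", "UNAFFECTED", "OBSERVED_IN_PAPER"),
    c("REFERENCE", "REFERENCE", "UNAFFECTED", "OBSERVED_IN_PAPER"))
  keys <- vapply(r, function(x) paste(sort(x[1:2]), collapse = "|"),
                 character(1L))
  stats::setNames(lapply(r, function(x) list(predicted = x[3L],
                                             confidence = x[4L])), keys)
})

#' Predict phenotype from a pair of allele types
#'
#' Deterministic penetrance model: the phenotype follows from the
#' unordered allele-type pair. Two null alleles give complete OCA; a
#' null allele in trans with the hypomorphic in-cis haplotype gives
#' partial OCA1B; two in-cis haplotypes give a mild but fully penetrant
#' hypomorphic phenotype; a null or in-cis allele against a single
#' benign variant or reference allele leaves a clinically unaffected
#' carrier; single-variant and reference pairs are unaffected.
#' Symmetric in its two arguments.
#'
#' @param a1,a2 Allele types (see \code{\link{assignAlleleType}}).
#' @return A list with elements \code{predicted} and \code{confidence}
#'   (\code{OBSERVED_IN_PAPER} or \code{EXTRAPOLATED}).
#' @examples
#' classifyDiplotype("NULL_PATHOGENIC", "HYPOMORPHIC_CIS")$predicted
#' @export
classifyDiplotype <- function(a1, a2) {
  a1 <- .checkChoice(a1, .alleleTypes, "a1")
  a2 <- .checkChoice(a2, .alleleTypes, "a2")
  key <- paste(sort(c(a1, a2)), collapse = "|")
  rule <- .diploRules[[key]]
  if (is.null(rule))
    list(predicted = "INDETERMINATE", confidence = "EXTRAPOLATED")
  else rule
}

#' Classify every pedigree member from resolved phase
#'
#' Runs (or reuses) the phasing engine and maps each individual's
#' surviving diplotype states to allele-type pairs. When all surviving
#' states agree on one unordered allele-type pair the deterministic
#' penetrance model assigns the phenotype prediction; individuals whose
#' phase is unresolved between allele-type pairs, or with no usable
#' genotype, are \code{INDETERMINATE}. A concordance (confusion) table
#' against the observed phenotype labels is attached.
#'
#' Observed labels are compared via the natural mapping
#' (\code{COMPLETE_OCA} ~ \code{AFFECTED_COMPLETE}, \code{PARTIAL_OCA1B}
#' ~ \code{AFFECTED_PARTIAL}, \code{MILD_HYPOMORPHIC} ~
#' \code{AFFECTED_MILD}, carriers/unaffected ~ \code{UNAFFECTED}).
#' Because mild hypomorphic individuals may self-report as unaffected,
#' \code{mildMatchesUnaffected = TRUE} additionally counts
#' \code{MILD_HYPOMORPHIC} vs \code{UNAFFECTED} as concordant; the
#' default keeps them as separate mismatches.
#'
#' @inheritParams solvePedigreePhase
#' @param solution Optional precomputed \code{PhaseSolution}.
#' @param mildMatchesUnaffected Logical; see Details.
#' @return A list with \code{predictions} (data.frame: \code{iid},
#'   \code{predicted}, \code{confidence}, \code{observed},
#'   \code{concordant} Y/N/NA) and \code{concordance} (predicted x
#'   observed contingency table).
#' @export
classifyPedigree <- function(pedigree, genotypes, panel, solution = NULL,
                             mildMatchesUnaffected = FALSE) {
  if (is.null(solution))
    solution <- solvePedigreePhase(pedigree, genotypes, panel)
  m <- members(pedigree)
  obs <- stats::setNames(m$phenotype, m$iid)
  typeOfHap <- vapply(0:(2L^length(panel) - 1L),
                      function(h) assignAlleleType(h, panel), character(1L))
  rows <- lapply(sort(m$iid), function(iid) {
    dom <- solution$domains[[iid]]
    if (is.null(dom) || nrow(dom) == 0L)
      return(data.frame(iid = iid, predicted = "INDETERMINATE",
                        confidence = NA_character_,
                        observed = obs[[iid]]))
    pairs <- unique(vapply(seq_len(nrow(dom)), function(s)
      paste(sort(c(typeOfHap[dom[s, 1L] + 1L],
                   typeOfHap[dom[s, 2L] + 1L])), collapse = "|"),
      character(1L)))
    if (length(pairs) != 1L)
      return(data.frame(iid = iid, predicted = "INDETERMINATE",
                        confidence = NA_character_,
                        observed = obs[[iid]]))
    at <- strsplit(pairs, "|", fixed = TRUE)[[1L]]
    cls <- classifyDiplotype(at[1L], at[2L])
    data.frame(iid = iid, predicted = cls$predicted,
               confidence = cls$confidence, observed = obs[[iid]])
  })
  pred <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  expect <- c(COMPLETE_OCA = "AFFECTED_COMPLETE",
              PARTIAL_OCA1B = "AFFECTED_PARTIAL",
              MILD_HYPOMORPHIC = "AFFECTED_MILD",
              UNAFFECTED_CARRIER = "UNAFFECTED",
              UNAFFECTED = "UNAFFECTED",
              INDETERMINATE = NA_character_)
  exp <- unname(expect[pred$predicted])
  conc <- ifelse(is.na(exp) | pred$observed == "UNKNOWN", "NA",
                 ifelse(pred$observed == exp, "Y", "N"))
  if (mildMatchesUnaffected)
    conc[pred$predicted == "MILD_HYPOMORPHIC" &
           pred$observed == "UNAFFECTED"] <- "Y"
  pred$concordant <- conc
  list(predictions = pred,
       concordance = table(
         predicted = factor(pred$predicted, levels = .predictionLevels),
         observed = factor(pred$observed, levels = .phenotypeLevels)))
}
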