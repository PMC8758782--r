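#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' Panel of biallelic variants phased jointly within a pedigree
#'
#' A \code{VariantPanel} holds 2--4 biallelic variants on one chromosome,
#' ordered by position, together with their pathogenicity class. The
#' default TYR panel (see \code{\link{tyrPanel}}) carries the three
#' variants whose joint segregation defines the hypomorphic
#' S192Y/R402Q in-cis allele: S192Y (c.575C>A), M252R (c.755T>G) and
#' R402Q (c.1205G>A), spanning ~106 kb of TYR on chromosome 11
#' (GRCh38, 1-based coordinates).
#'
#' Pathogenicity classes: \code{PATHOGENIC_NULL} marks an allele-null
#' variant (here M252R); \code{HYPOMORPHIC_COMPONENT} marks a variant that
#' is individually benign but pathogenic when both components sit in cis
#' (S192Y, R402Q); \code{REFERENCE_SCALE} marks variants carried only for
#' phasing leverage.
#'
#' @slot ranges A \link[GenomicRanges]{GRanges} with one range per variant
#'   and metadata columns \code{id}, \code{ref}, \code{alt}, \code{hgvsC},
#'   \code{pathoClass}.
#' @seealso \code{\link{tyrPanel}}, \code{\link{readPanel}}
#' @exportClass VariantPanel
setClass("VariantPanel", representation(ranges = "GRanges"))

setValidity("VariantPanel", function(object) {
  gr <- object@ranges
  msg <- character()
  n <- length(gr)
  if (n < 2L || n > 4L)
    msg <- c(msg, "panel must hold between 2 and 4 variants")
  md <- S4Vectors::mcols(gr)
  need <- c("id", "ref", "alt", "hgvsC", "pathoClass")
  if (!all(need %in% colnames(md)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(md)), collapse = ", ")))
  if (anyDuplicated(md$id))
    msg <- c(msg, "variant ids must be unique within a panel")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L)
    msg <- c(msg, "all panel variants must share one chromosome")
  if (is.unsorted(GenomicRanges::start(gr)))
    msg <- c(msg, "panel variants must be ordered by position")
  if (any(md$ref == md$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if (!all(md$pathoClass %in% .pathoClasses))
    msg <- c(msg, paste("pathoClass must be one of:",
                        paste(.pathoClasses, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Family structure with per-individual phenotype labels
#'
#' A \code{Pedigree} stores one or more families as a table of
#' individuals with parent links, sex and an observed phenotype label.
#' Individual identifiers (\code{iid}) are unique across the whole
#' object; founders are the members with neither parent recorded.
#'
#' Phenotype labels use a four-level albinism scale plus unknown:
#' \code{AFFECTED_COMPLETE} (classical OCA), \code{AFFECTED_PARTIAL}
#' (partial albinism, OCA1B), \code{AFFECTED_MILD} (mild hypomorphic
#' features such as isolated foveal hypoplasia), \code{UNAFFECTED},
#' \code{UNKNOWN}.
#'
#' @slot members A \link[S4Vectors]{DataFrame} with columns \code{fid},
#'   \code{iid}, \code{father}, \code{mother} (\code{NA} when unknown),
#'   \code{sex} and \code{phenotype}; row names are the \code{iid}s.
#' @seealso \code{\link{readPedigree}}, \code{\link{founders}}
#' @exportClass Pedigree
setClass("Pedigree", representation(members = "DataFrame"))

.pedigreeCycles <- function(iid, father, mother) {
  ## Kahn-style peeling: repeatedly remove individuals whose parents are
  ## all removed; leftovers participate in a cycle.
  parent <- cbind(match(father, iid), match(mother, iid))
  alive <- rep(TRUE, length(iid))
  repeat {
    removable <- alive & vapply(seq_along(iid), function(i) {
      p <- parent[i, ]
      p <- p[!is.na(p)]
      length(p) == 0L || !any(alive[p])
    }, logical(1L))
    if (!any(removable & alive)) break
    alive[removable] <- FALSE
    if (!any(alive)) break
  }
  iid[alive]
}

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("fid", "iid", "father", "mother", "sex", "phenotype")
  if (!all(need %in% colnames(m)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  msg <- character()
  if (anyDuplicated(m$iid))
    msg <- c(msg, "individual ids must be unique")
  if (any(!is.na(m$father) & m$father == m$iid) ||
      any(!is.na(m$mother) & m$mother == m$iid))
    msg <- c(msg, "an individual cannot be its own parent")
  both <- !is.na(m$father) & !is.na(m$mother)
  if (any(both & m$father == m$mother))
    msg <- c(msg, "father and mother must be distinct individuals")
  bad <- setdiff(c(m$father, m$mother), c(m$iid, NA))
  if (length(bad))
    msg <- c(msg, paste("unresolved parent ids:", paste(bad, collapse = ", ")))
  if (!all(m$sex %in% .sexLevels))
    msg <- c(msg, "sex must be MALE, FEMALE or UNKNOWN")
  if (!all(m$phenotype %in% .phenotypeLevels))
    msg <- c(msg, paste("phenotype must be one of:",
                        paste(.phenotypeLevels, collapse = ", ")))
  sexOf <- stats::setNames(m$sex, m$iid)
  fa <- stats::na.omit(unique(m$father)); fa <- fa[fa %in% m$iid]
  mo <- stats::na.omit(unique(m$mother)); mo <- mo[mo %in% m$iid]
  if (any(sexOf[fa] == "FEMALE"))
    msg <- c(msg, paste("recorded father has female sex:",
                        paste(fa[sexOf[fa] == "FEMALE"], collapse = ", ")))
  if (any(sexOf[mo] == "MALE"))
    msg <- c(msg, paste("recorded mother has male sex:",
                        paste(mo[sexOf[mo] == "MALE"], collapse = ", ")))
  if (!length(msg)) {
    cyc <- .pedigreeCycles(m$iid, m$father, m$mother)
    if (length(cyc))
      msg <- c(msg, paste("cyclic parentage involving:",
                          paste(sort(cyc), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Unphased allele-dosage matrix over a variant panel
#'
#' Rows are individuals (\code{iid}), columns are panel variant ids;
#' entries are alternate-allele dosages 0, 1, 2 or \code{NA} (missing).
#' Input phase separators are always discarded on construction: the
#' phasing engine infers phase from transmission, so pre-phased input
#' must not leak in.
#'
#' @slot dosage Integer matrix with dimnames \code{list(iid, variant id)}.
#' @seealso \code{\link{readGenotypes}}, \code{\link{solvePedigreePhase}}
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", representation(dosage = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage matrix needs iid row names and variant column names")
  if (!all(d %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(d)))
    msg <- c(msg, "duplicated individual ids")
  if (anyDuplicated(colnames(d)))
    msg <- c(msg, "duplicated variant ids")
  if (length(msg)) msg else TRUE
})

#' Founder haplotype frequency model for gene-dropping simulation
#'
#' Assigns a probability to every haplotype over the panel loci. The
#' packaged defaults (see \code{\link{defaultFrequencyModel}}) encode the
#' European marginal allele frequencies of S192Y (36\%) and R402Q (27\%),
#' a S192Y/R402Q in-cis haplotype frequency of 1.5\% (midpoint of the
#' 1.1--1.9\% range estimated for European populations), and, for the
#' Amish model, an M252R-bearing haplotype (carrying R402Q in cis) at
#' allele frequency 0.0023.
#'
#' @slot panel The \linkS4class{VariantPanel} the haplotypes refer to.
#' @slot hapCodes Integer haplotype codes (bit j set = alt at panel locus j).
#' @slot freq Numeric probabilities, parallel to \code{hapCodes}, summing
#'   to one.
#' @seealso \code{\link{defaultFrequencyModel}},
#'   \code{\link{simulatePedigrees}}
#' @exportClass HapFreqModel
setClass("HapFreqModel",
         representation(panel = "VariantPanel", hapCodes = "integer",
                        freq = "numeric"))

setValidity("HapFreqModel", function(object) {
  msg <- character()
  k <- length(object@panel@ranges)
  if (length(object@hapCodes) != length(object@freq))
    msg <- c(msg, "hapCodes and freq lengths differ")
  if (any(object@freq < 0))
    msg <- c(msg, "haplotype frequencies must be non-negative")
  if (abs(sum(object@freq) - 1) > 1e-8)
    msg <- c(msg, "haplotype frequencies must sum to 1")
  if (any(object@hapCodes < 0L) || any(object@hapCodes >= 2L^k))
    msg <- c(msg, "haplotype codes out of range for panel size")
  if (anyDuplicated(object@hapCodes))
    msg <- c(msg, "duplicated haplotype codes")
  if (length(msg)) msg else TRUE
})
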