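## Single-locus Mendelian validation.
##
## A child dosage is a violation iff no choice of one transmitted allele
## from each parent's dosage can produce it; a missing parent or child
## dosage is compatible with anything. De novo mutation is deliberately
## not modelled: the transmission argument the phasing engine encodes
## assumes faithful inheritance, so violations are reported and the
## individual is excluded from phasing rather than explained away.

## alleles a parent with dosage d can transmit (NA -> either)
.transmissible <- function(d) {
  if (is.na(d)) c(0L, 1L)
  else if (d == 0L) 0L
  else if (d == 1L) c(0L, 1L)
  else 1L
}

.mendelCompatible <- function(dFather, dMother, dChild) {
  if (is.na(dChild)) return(TRUE)
  sums <- outer(.transmissible(dFather), .transmissible(dMother), "+")
  dChild %in% sums
}

#' Detect single-locus Mendelian violations
#'
#' Checks every parent--child transmission at each panel locus. A child
#' genotype is flagged iff no assignment of one allele from each
#' recorded parent's genotype can produce it (missing genotypes are
#' compatible with anything). Report-only: nothing is modified.
#'
#' @param pedigree A \linkS4class{Pedigree}.
#' @param genotypes A \linkS4class{GenotypeMatrix}.
#' @param panel A \linkS4class{VariantPanel}; checked loci default to the
#'   whole panel.
#' @param variants Optional subset of variant ids to check.
#' @return A data.frame with columns \code{iid} and \code{variant},
#'   one row per violating (child, locus) pair; zero rows when clean.
#' @seealso \code{\link{solvePedigreePhase}}, which excludes flagged
#'   individuals before phasing.
#' @export
validateMendelian <- function(pedigree, genotypes, panel,
                              variants = variantIds(panel)) {
  d <- dosages(genotypes)
  par <- .parentsOf(pedigree)
  m <- members(pedigree)
  out <- list()
  for (iid in m$iid) {
    fa <- par$father[[iid]]
    mo <- par$mother[[iid]]
    if (is.na(fa) && is.na(mo)) next
    for (v in variants) {
      dc <- d[iid, v]
      df <- if (!is.na(fa)) d[fa, v] else NA_integer_
      dm <- if (!is.na(mo)) d[mo, v] else NA_integer_
      if (!.mendelCompatible(df, dm, dc))
        out[[length(out) + 1L]] <- data.frame(iid = iid, variant = v)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(iid = character(), variant = character())
}
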