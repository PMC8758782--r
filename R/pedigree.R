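#' Construct a pedigree from a data frame
#'
#' @param df A data.frame with columns \code{fid}, \code{iid},
#'   \code{father}, \code{mother} (use \code{NA} for unknown parents),
#'   \code{sex} (\code{MALE}/\code{FEMALE}/\code{UNKNOWN}) and
#'   \code{phenotype} (see \linkS4class{Pedigree}).
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("fid", "iid", "father", "mother", "sex", "phenotype"))
    if (!col %in% names(df)) stop("missing pedigree column: ", col)
  m <- S4Vectors::DataFrame(
    fid = as.character(df$fid), iid = as.character(df$iid),
    father = as.character(df$father), mother = as.character(df$mother),
    sex = as.character(df$sex), phenotype = as.character(df$phenotype))
  rownames(m) <- m$iid
  new("Pedigree", members = m)
}

.defaultPhenoMap <- c("1" = "UNAFFECTED", "2" = "AFFECTED_PARTIAL",
                      "0" = "UNKNOWN", "-9" = "UNKNOWN")

#' Read a PLINK-style PED/FAM pedigree file
#'
#' Parses the six leading whitespace-delimited columns
#' (FID IID PAT MAT SEX PHENO; \code{"0"} marks a missing parent) and
#' builds a validated \linkS4class{Pedigree}. The binary PED phenotype
#' column cannot carry the four-level albinism phenotype scale, so a
#' sidecar TSV mapping \code{iid} to a phenotype label overrides column 6
#' when provided.
#'
#' @param path Path to the PED/FAM file.
#' @param phenotypeMap Named character vector mapping PED phenotype codes
#'   to phenotype labels; default \code{1} unaffected, \code{2} affected
#'   (partial), \code{0}/\code{-9} unknown.
#' @param phenotypeFile Optional sidecar TSV with header columns
#'   \code{iid} and \code{phenotype}; overrides column 6 for listed iids.
#' @return A \linkS4class{Pedigree}.
#' @seealso \code{\link{writePedigree}}
#' @export
readPedigree <- function(path, phenotypeMap = .defaultPhenoMap,
                         phenotypeFile = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 6L)
    stop("PED file must have at least 6 whitespace-delimited columns")
  tab <- tab[, 1:6]
  names(tab) <- c("fid", "iid", "father", "mother", "sex", "pheno")
  pheno <- unname(phenotypeMap[tab$pheno])
  pheno[is.na(pheno)] <- "UNKNOWN"
  if (!is.null(phenotypeFile)) {
    side <- utils::read.delim(phenotypeFile, colClasses = "character")
    if (!all(c("iid", "phenotype") %in% names(side)))
      stop("phenotype sidecar needs columns iid and phenotype")
    hit <- match(tab$iid, side$iid)
    pheno[!is.na(hit)] <- side$phenotype[hit[!is.na(hit)]]
  }
  sex <- unname(c("1" = "MALE", "2" = "FEMALE")[tab$sex])
  sex[is.na(sex)] <- "UNKNOWN"
  Pedigree(data.frame(
    fid = tab$fid, iid = tab$iid,
    father = ifelse(tab$father == "0", NA_character_, tab$father),
    mother = ifelse(tab$mother == "0", NA_character_, tab$mother),
    sex = sex, phenotype = pheno))
}

#' Write a pedigree as a PED file
#'
#' Inverse of \code{\link{readPedigree}} up to phenotype-code
#' normalisation: affected levels collapse to PED code 2, unaffected to
#' 1, unknown to 0. Use a phenotype sidecar to preserve the four-level
#' scale.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param path Output file path.
#' @param phenotypeFile Optional path; when given, the full phenotype
#'   labels are written there as a two-column TSV sidecar.
#' @return Invisibly, \code{path}.
#' @export
writePedigree <- function(ped, path, phenotypeFile = NULL) {
  m <- members(ped)
  code <- ifelse(m$phenotype %in% c("AFFECTED_COMPLETE", "AFFECTED_PARTIAL",
                                    "AFFECTED_MILD"), "2",
                 ifelse(m$phenotype == "UNAFFECTED", "1", "0"))
  out <- data.frame(
    fid = m$fid, iid = m$iid,
    father = ifelse(is.na(m$father), "0", m$father),
    mother = ifelse(is.na(m$mother), "0", m$mother),
    sex = c(MALE = "1", FEMALE = "2", UNKNOWN = "0")[m$sex],
    pheno = code)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(phenotypeFile))
    utils::write.table(
      data.frame(iid = m$iid, phenotype = m$phenotype), phenotypeFile,
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname Pedigree-class
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @rdname Pedigree-class
#' @export
setMethod("founders", "Pedigree", function(x) {
  m <- x@members
  m$iid[is.na(m$father) & is.na(m$mother)]
})

#' @rdname Pedigree-class
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@members))

#' @rdname Pedigree-class
#' @export
setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree with", nrow(m), "individuals in",
      length(unique(m$fid)), "families;",
      length(founders(object)), "founders\n")
  tab <- table(factor(m$phenotype, levels = .phenotypeLevels))
  cat("phenotypes:",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), "\n")
})

## parent lookup (internal): named character vectors, NA when absent
.parentsOf <- function(ped) {
  m <- members(ped)
  list(father = stats::setNames(m$father, m$iid),
       mother = stats::setNames(m$mother, m$iid))
}
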