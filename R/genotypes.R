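#' Construct a genotype matrix
#'
#' @param dosage Matrix (or coercible) of alternate-allele dosages with
#'   iid row names and variant-id column names; values 0, 1, 2 or
#'   \code{NA}.
#' @param pedigree Optional \linkS4class{Pedigree}; when given, every row
#'   must be a pedigree member and pedigree members absent from
#'   \code{dosage} are added as all-missing rows.
#' @param panel Optional \linkS4class{VariantPanel}; when given, columns
#'   are checked and reordered against the panel, with absent panel
#'   variants added as all-missing columns.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, pedigree = NULL, panel = NULL) {
  d <- as.matrix(dosage)
  mode(d) <- "integer"
  if (!is.null(panel)) {
    ids <- variantIds(panel)
    extra <- setdiff(colnames(d), ids)
    if (length(extra))
      stop("genotype columns not in panel: ", paste(extra, collapse = ", "))
    miss <- setdiff(ids, colnames(d))
    if (length(miss)) {
      add <- matrix(NA_integer_, nrow(d), length(miss),
                    dimnames = list(rownames(d), miss))
      d <- cbind(d, add)
    }
    d <- d[, ids, drop = FALSE]
  }
  if (!is.null(pedigree)) {
    iids <- members(pedigree)$iid
    extra <- setdiff(rownames(d), iids)
    if (length(extra))
      stop("genotyped individuals not in pedigree: ",
           paste(extra, collapse = ", "))
    miss <- setdiff(iids, rownames(d))
    if (length(miss)) {
      add <- matrix(NA_integer_, length(miss), ncol(d),
                    dimnames = list(miss, colnames(d)))
      d <- rbind(d, add)
    }
    d <- d[iids, , drop = FALSE]
  }
  new("GenotypeMatrix", dosage = d)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat("GenotypeMatrix:", nrow(d), "individuals x", ncol(d), "variants;",
      sum(is.na(d)), "missing entries\n")
})

## GT string -> dosage, ignoring the phase separator ("0/1" == "1|0").
.gtToDosage <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    if (any(a == "." | a == "")) return(NA_integer_)
    sum(a == "1")
  }, integer(1L))
}

#' Read unphased genotypes for a panel
#'
#' Reads per-individual genotypes at the panel loci from a VCF
#' (matched by chrom, pos, ref, alt; GT field decoded with any phase
#' separator deliberately ignored) or from a TSV dosage matrix with
#' header \code{iid} followed by variant ids and cells 0/1/2/NA.
#' Pedigree members absent from the file get missing genotypes at all
#' loci; a panel variant absent from a VCF yields a warning and a
#' missing column; a multi-allelic record at a panel position is an
#' error.
#'
#' @param path Path to a \code{.vcf}/\code{.vcf.gz} file or a TSV matrix.
#' @param panel A \linkS4class{VariantPanel}.
#' @param pedigree A \linkS4class{Pedigree}.
#' @return A \linkS4class{GenotypeMatrix} with one row per pedigree
#'   member, in pedigree order.
#' @export
readGenotypes <- function(path, panel, pedigree) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path))
    .readGenotypesVcf(path, panel, pedigree)
  else
    .readGenotypesTsv(path, panel, pedigree)
}

.readGenotypesVcf <- function(path, panel, pedigree) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- variantIds(panel)
  md <- S4Vectors::mcols(panel@ranges)
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  keep <- intersect(members(pedigree)$iid, samples)
  d <- matrix(NA_integer_, length(keep), length(ids),
              dimnames = list(keep, ids))
  pchrom <- as.character(GenomicRanges::seqnames(panel@ranges))
  ppos <- GenomicRanges::start(panel@ranges)
  vchrom <- as.character(GenomicRanges::seqnames(rr))
  vpos <- GenomicRanges::start(rr)
  for (j in seq_along(ids)) {
    atPos <- which(vchrom == pchrom[j] & vpos == ppos[j])
    if (!length(atPos)) {
      warning("panel variant ", ids[j], " absent from VCF; set to missing")
      next
    }
    nalt <- lengths(rr$ALT[atPos])
    if (any(nalt > 1L))
      stop("multi-allelic VCF record at panel variant ", ids[j],
           " is not supported")
    hit <- atPos[as.character(rr$REF[atPos]) == md$ref[j] &
                   vapply(rr$ALT[atPos],
                          function(a) as.character(a)[1L] == md$alt[j],
                          logical(1L))]
    if (!length(hit)) {
      warning("panel variant ", ids[j],
              " has no matching ref/alt in VCF; set to missing")
      next
    }
    if (length(hit) > 1L)
      stop("duplicate VCF records for panel variant ", ids[j])
    d[, j] <- .gtToDosage(gt[hit, keep])
  }
  GenotypeMatrix(d, pedigree = pedigree, panel = panel)
}

.readGenotypesTsv <- function(path, panel, pedigree) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (names(tab)[1L] != "iid")
    stop("genotype TSV must start with an 'iid' header column")
  keep <- intersect(members(pedigree)$iid, tab$iid)
  cols <- intersect(variantIds(panel), names(tab))
  miss <- setdiff(variantIds(panel), names(tab))
  if (length(miss))
    warning("panel variants absent from TSV: ", paste(miss, collapse = ", "))
  d <- matrix(NA_integer_, length(keep), length(cols),
              dimnames = list(keep, cols))
  rows <- match(keep, tab$iid)
  for (j in seq_along(cols)) {
    v <- tab[[cols[j]]][rows]
    v[v %in% c("NA", ".", "")] <- NA
    d[, j] <- as.integer(v)
  }
  GenotypeMatrix(d, pedigree = pedigree, panel = panel)
}

#' Write a genotype matrix as a TSV dosage table
#'
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypes <- function(geno, path) {
  d <- dosages(geno)
  out <- data.frame(iid = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
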