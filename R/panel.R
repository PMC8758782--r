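#' Construct a variant panel
#'
#' @param id Character vector of short variant labels (e.g. \code{"S192Y"}).
#' @param chrom Chromosome name shared by all variants.
#' @param pos 1-based genomic coordinates (GRCh38 convention).
#' @param ref,alt Reference and alternate allele strings.
#' @param hgvsC Transcript-level HGVS names.
#' @param pathoClass One of \code{"PATHOGENIC_NULL"},
#'   \code{"HYPOMORPHIC_COMPONENT"}, \code{"REFERENCE_SCALE"} per variant.
#' @return A \linkS4class{VariantPanel}, ordered by position.
#' @examples
#' tyrPanel()
#' @export
VariantPanel <- function(id, chrom, pos, ref, alt, hgvsC = NA_character_,
                         pathoClass) {
  stopifnot(length(id) == length(pos))
  o <- order(pos)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(chrom, length(pos))[o],
    ranges = IRanges::IRanges(start = pos[o], width = nchar(ref)[o]))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = id[o], ref = ref[o], alt = alt[o],
    hgvsC = rep_len(hgvsC, length(id))[o], pathoClass = pathoClass[o])
  new("VariantPanel", ranges = gr)
}

#' The three-variant TYR panel
#'
#' Default panel of the three TYR missense variants whose joint
#' segregation identifies the hypomorphic S192Y/R402Q in-cis allele:
#' p.(Ser192Tyr) and p.(Arg402Gln) as hypomorphic components, and the
#' Amish founder variant p.(Met252Arg) as a pathogenic null allele.
#' Coordinates are GRCh38, 1-based.
#'
#' @return A \linkS4class{VariantPanel} of the three TYR variants.
#' @examples
#' panelSpan(tyrPanel())  # ~106 kb
#' @export
tyrPanel <- function() {
  VariantPanel(
    id = c("S192Y", "M252R", "R402Q"),
    chrom = "chr11",
    pos = c(89178528L, 89178708L, 89284793L),
    ref = c("C", "T", "G"),
    alt = c("A", "G", "A"),
    hgvsC = c("NM_000372.4:c.575C>A", "NM_000372.4:c.755T>G",
              "NM_000372.4:c.1205G>A"),
    pathoClass = c("HYPOMORPHIC_COMPONENT", "PATHOGENIC_NULL",
                   "HYPOMORPHIC_COMPONENT"))
}

#' Read a variant panel from JSON
#'
#' Expects a JSON array of objects with fields \code{id}, \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{patho_class} and optionally
#' \code{hgvs_c}.
#'
#' @param path Path to the panel JSON file.
#' @return A \linkS4class{VariantPanel}.
#' @export
readPanel <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(x$hgvs_c)) x$hgvs_c <- NA_character_
  VariantPanel(id = x$id, chrom = unique(x$chrom), pos = as.integer(x$pos),
               ref = x$ref, alt = x$alt, hgvsC = x$hgvs_c,
               pathoClass = x$patho_class)
}

#' @rdname VariantPanel-class
#' @export
setMethod("variantIds", "VariantPanel",
          function(x) S4Vectors::mcols(x@ranges)$id)

#' @rdname VariantPanel-class
#' @export
setMethod("pathoClasses", "VariantPanel", function(x)
  stats::setNames(S4Vectors::mcols(x@ranges)$pathoClass,
                  S4Vectors::mcols(x@ranges)$id))

#' @rdname VariantPanel-class
#' @export
setMethod("panelSpan", "VariantPanel", function(x)
  diff(range(GenomicRanges::start(x@ranges))))

#' @rdname VariantPanel-class
#' @export
setMethod("length", "VariantPanel", function(x) length(x@ranges))

#' @rdname VariantPanel-class
#' @export
setMethod("show", "VariantPanel", function(object) {
  md <- S4Vectors::mcols(object@ranges)
  cat("VariantPanel with", length(object), "variants on",
      as.character(unique(GenomicRanges::seqnames(object@ranges))),
      sprintf("(span %d bp)\n", panelSpan(object)))
  df <- data.frame(id = md$id, pos = GenomicRanges::start(object@ranges),
                   ref = md$ref, alt = md$alt, class = md$pathoClass)
  print(df, row.names = FALSE)
})

## GRanges view of the panel (internal; used for VCF matching)
panelRanges <- function(panel) panel@ranges
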