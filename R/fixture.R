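## Hand-built fixture reproducing the textual constraints on the four
## Amish families: 14 affected in total (9 in family 4, 4 in families
## 2-3, 1 in family 1); 13 affected are compound heterozygotes for the
## M252R haplotype (which carries R402Q in cis) and the S192Y/R402Q
## in-cis haplotype; the family-1 individual is M252R homozygous; the
## named relatives VIII:9, IX:2, IX:21, X:6, X:8 carry M252R with
## R402Q-only in trans and IX:1, IX:4 carry M252R with S192Y-only in
## trans, all unaffected. Parental genotypes are chosen so the phasing
## engine resolves CIS for every affected compound heterozygote. The
## published pedigree figure is not machine-readable, so the structure
## beyond these constraints is synthetic.

#' Packaged four-family fixture pedigree
#'
#' Builds the pedigree, truth haplotypes, unphased genotype matrix and
#' phenotype labels of the four-family fixture (see the package
#' vignette for the constraints it encodes). Haplotype codes follow
#' \code{\link{hapAlleles}} over \code{\link{tyrPanel}}: 6 = M252R
#' haplotype (M252R + R402Q in cis), 5 = S192Y/R402Q in-cis haplotype,
#' 4 = R402Q only, 1 = S192Y only, 0 = reference.
#'
#' @param dir Optional directory; when given, writes
#'   \code{families.ped}, \code{families_genotypes.tsv} and
#'   \code{families_phenotypes.tsv} there.
#' @return A list: \code{pedigree}, \code{genotypes}, \code{truth}
#'   (data.frame \code{iid}, \code{hapPat}, \code{hapMat}),
#'   \code{panel}, \code{affected} (iids), \code{namedCarriers} (the
#'   seven named unaffected relatives).
#' @export
makeFixtureFamilies <- function(dir = NULL) {
  panel <- tyrPanel()
  ## fid, iid, father, mother, sex, hapPat, hapMat, phenotype
  spec <- rbind(
    ## family 4 founders, generation VIII
    c("4", "VIII:1", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("4", "VIII:2", NA, NA, "FEMALE", 5, 0, "UNAFFECTED"),
    c("4", "VIII:3", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("4", "VIII:4", NA, NA, "FEMALE", 4, 0, "UNAFFECTED"),
    c("4", "VIII:5", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("4", "VIII:6", NA, NA, "FEMALE", 5, 4, "UNAFFECTED"),
    c("4", "VIII:7", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("4", "VIII:8", NA, NA, "FEMALE", 5, 1, "UNAFFECTED"),
    c("4", "VIII:9", NA, NA, "MALE",   6, 4, "UNAFFECTED"),
    ## family 4, generation IX
    c("4", "IX:9",  "VIII:1", "VIII:2", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:10", "VIII:1", "VIII:2", "FEMALE", 6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:12", "VIII:1", "VIII:2", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:2",  "VIII:3", "VIII:4", "FEMALE", 6, 4, "UNAFFECTED"),
    c("4", "IX:14", "VIII:5", "VIII:6", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:15", "VIII:5", "VIII:6", "FEMALE", 6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:16", "VIII:5", "VIII:6", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:21", "VIII:5", "VIII:6", "FEMALE", 6, 4, "UNAFFECTED"),
    c("4", "IX:20", "VIII:7", "VIII:8", "FEMALE", 6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:22", "VIII:7", "VIII:8", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "IX:1",  "VIII:7", "VIII:8", "MALE",   6, 1, "UNAFFECTED"),
    c("4", "IX:4",  "VIII:7", "VIII:8", "FEMALE", 6, 1, "UNAFFECTED"),
    c("4", "IX:23", NA, NA, "FEMALE", 5, 0, "UNAFFECTED"),
    c("4", "IX:24", NA, NA, "FEMALE", 4, 0, "UNAFFECTED"),
    ## family 4, generation X
    c("4", "X:15", "IX:22", "IX:23", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("4", "X:6",  "IX:9",  "IX:24", "FEMALE", 6, 4, "UNAFFECTED"),
    c("4", "X:8",  "IX:9",  "IX:24", "MALE",   6, 4, "UNAFFECTED"),
    ## family 1: M252R homozygote with classical OCA
    c("1", "IX:25", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("1", "IX:26", NA, NA, "FEMALE", 6, 0, "UNAFFECTED"),
    c("1", "X:1", "IX:25", "IX:26", "FEMALE", 6, 6, "AFFECTED_COMPLETE"),
    ## family 2
    c("2", "IX:27", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("2", "IX:28", NA, NA, "FEMALE", 5, 0, "UNAFFECTED"),
    c("2", "X:2", "IX:27", "IX:28", "MALE", 6, 5, "AFFECTED_PARTIAL"),
    ## family 3
    c("3", "IX:29", NA, NA, "MALE",   6, 0, "UNAFFECTED"),
    c("3", "IX:30", NA, NA, "FEMALE", 5, 0, "UNAFFECTED"),
    c("3", "X:3", "IX:29", "IX:30", "MALE",   6, 5, "AFFECTED_PARTIAL"),
    c("3", "X:4", "IX:29", "IX:30", "FEMALE", 6, 5, "AFFECTED_PARTIAL"),
    c("3", "X:5", "IX:29", "IX:30", "FEMALE", 6, 5, "AFFECTED_PARTIAL"))
  df <- data.frame(fid = spec[, 1L], iid = spec[, 2L],
                   father = spec[, 3L], mother = spec[, 4L],
                   sex = spec[, 5L],
                   hapPat = as.integer(spec[, 6L]),
                   hapMat = as.integer(spec[, 7L]),
                   phenotype = spec[, 8L])
  pedigree <- Pedigree(df[, c("fid", "iid", "father", "mother", "sex",
                              "phenotype")])
  dos <- hapAlleles(df$hapPat, panel) + hapAlleles(df$hapMat, panel)
  rownames(dos) <- df$iid
  genotypes <- GenotypeMatrix(dos, pedigree = pedigree, panel = panel)
  out <- list(
    pedigree = pedigree, genotypes = genotypes,
    truth = df[, c("iid", "hapPat", "hapMat")],
    panel = panel,
    affected = df$iid[df$phenotype != "UNAFFECTED"],
    namedCarriers = c("VIII:9", "IX:2", "IX:21", "X:6", "X:8",
                      "IX:1", "IX:4"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writePedigree(pedigree, file.path(dir, "families.ped"),
                  phenotypeFile = file.path(dir,
                                            "families_phenotypes.tsv"))
    writeGenotypes(genotypes, file.path(dir, "families_genotypes.tsv"))
  }
  out
}
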