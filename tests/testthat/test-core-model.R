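test_that("a trio PED file parses into a pedigree with two founders", {
  f <- withr::local_tempfile(lines = c(
    "T1 dad 0 0 1 1",
    "T1 mum 0 0 2 1",
    "T1 kid dad mum 2 2"))
  ped <- readPedigree(f)
  expect_s4_class(ped, "Pedigree")
  expect_identical(sort(founders(ped)), c("dad", "mum"))
  expect_identical(length(ped), 3L)
  expect_identical(members(ped)["kid", "phenotype"], "AFFECTED_PARTIAL")
})

test_that("structural pedigree errors are rejected by name", {
  selfpar <- withr::local_tempfile(lines = c(
    "T1 dad 0 0 1 1",
    "T1 kid kid 0 1 2"))
  expect_error(readPedigree(selfpar), "own parent")

  unresolved <- withr::local_tempfile(lines = "T1 kid ghost 0 1 2")
  expect_error(readPedigree(unresolved), "ghost")

  ## grandparent loop: a is parent of b, b is parent of a
  cyc <- withr::local_tempfile(lines = c(
    "T1 a b 0 1 0",
    "T1 b a 0 1 0"))
  expect_error(readPedigree(cyc), "[Cc]ycl")

  sexconf <- withr::local_tempfile(lines = c(
    "T1 dad 0 0 2 1",
    "T1 mum 0 0 2 1",
    "T1 kid dad mum 1 1"))
  expect_error(readPedigree(sexconf), "father.*female")
})

test_that("pedigree IO round-trips structural content", {
  fx <- makeFixtureFamilies()
  ped <- withr::local_tempfile(fileext = ".ped")
  side <- withr::local_tempfile(fileext = ".tsv")
  writePedigree(fx$pedigree, ped, phenotypeFile = side)
  back <- readPedigree(ped, phenotypeFile = side)
  expect_identical(as.data.frame(members(back)),
                   as.data.frame(members(fx$pedigree)))
  ## without the sidecar, phenotype normalises to the binary PED coding
  coarse <- readPedigree(ped)
  expect_true(all(coarse@members$phenotype %in%
                    c("AFFECTED_PARTIAL", "UNAFFECTED", "UNKNOWN")))
})

test_that("packaged family-4 fixture has 9 affected in generations IX/X", {
  ped <- readPedigree(
    system.file("extdata", "families.ped", package = "ocaphase"),
    phenotypeFile = system.file("extdata", "families_phenotypes.tsv",
                                package = "ocaphase"))
  m <- as.data.frame(members(ped))
  fam4aff <- m[m$fid == "4" & grepl("^AFFECTED", m$phenotype), ]
  expect_identical(nrow(fam4aff), 9L)
  expect_true(all(grepl("^(IX|X):", fam4aff$iid)))
})

test_that("VCF genotypes decode to dosages ignoring phase separators", {
  panel <- tyrPanel()
  ped <- trioPed()
  vcf <- withr::local_tempfile(fileext = ".vcf", lines = c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr11>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdad\tmum\tkid",
    "chr11\t89178528\t.\tC\tA\t.\tPASS\t.\tGT\t0/1\t1|0\t1/1",
    "chr11\t89178708\t.\tT\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t./.",
    "chr11\t89284793\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t0|1\t0/1"))
  g <- readGenotypes(vcf, panel, ped)
  d <- dosages(g)
  expect_identical(d["dad", ], c(S192Y = 1L, M252R = 0L, R402Q = 2L))
  ## "1|0" decodes identically to "0/1": input phase must not leak in
  expect_identical(d["mum", ], c(S192Y = 1L, M252R = 0L, R402Q = 1L))
  expect_identical(d["kid", "M252R"], NA_integer_)
})

test_that("VCF edge cases: absent panel variant warns, multi-allelic errors", {
  panel <- tyrPanel()
  ped <- trioPed()
  vcf <- withr::local_tempfile(fileext = ".vcf", lines = c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr11>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdad\tmum\tkid",
    "chr11\t89178528\t.\tC\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1"))
  w <- capture_warnings(g <- readGenotypes(vcf, panel, ped))
  expect_true(any(grepl("M252R", w)))  # R402Q is absent too
  expect_true(all(is.na(dosages(g)[, "M252R"])))

  multi <- withr::local_tempfile(fileext = ".vcf", lines = c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr11>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdad\tmum\tkid",
    "chr11\t89178528\t.\tC\tA,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/2"))
  expect_error(suppressWarnings(readGenotypes(multi, panel, ped)),
               "multi-allelic")
})

test_that("TSV genotypes decode with NA cells and missing individuals", {
  panel <- tyrPanel()
  ped <- trioPed()
  tsv <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "iid\tS192Y\tM252R\tR402Q",
    "dad\t1\tNA\t2",
    "mum\t0\t0\t1"))
  g <- readGenotypes(tsv, panel, ped)
  d <- dosages(g)
  expect_identical(d["dad", ], c(S192Y = 1L, M252R = NA_integer_,
                                 R402Q = 2L))
  expect_true(all(is.na(d["kid", ])))  # absent member -> all missing
})

test_that("Mendelian validation agrees with exhaustive transmission
           enumeration over all parental dosage combinations", {
  panel <- twoLocusPanel()
  ped <- trioPed()
  ## independent oracle: enumerate the 2x2 transmitted-allele choices
  alleleSet <- function(d)
    if (is.na(d)) 0:1 else switch(d + 1L, 0L, 0:1, 1L)
  oracleOK <- function(df, dm, dc) {
    if (is.na(dc)) return(TRUE)
    any(outer(alleleSet(df), alleleSet(dm), "+") == dc)
  }
  dosVals <- c(0L, 1L, 2L, NA_integer_)
  for (df in dosVals) for (dm in dosVals) for (dc in c(0L, 1L, 2L)) {
    g <- genoFromList(
      list(dad = c(df, 0L), mum = c(dm, 0L), kid = c(dc, 0L)),
      panel, ped)
    viol <- validateMendelian(ped, g, panel)
    expect_identical(
      "S192Y" %in% viol$variant, !oracleOK(df, dm, dc),
      label = sprintf("father=%s mother=%s child=%s", df, dm, dc))
  }
  ## spot cases: de novo not modelled; one-missing-parent still constrains
  g <- genoFromList(list(dad = c(0L, 0L), mum = c(0L, 0L),
                         kid = c(1L, 0L)), panel, ped)
  expect_identical(nrow(validateMendelian(ped, g, panel)), 1L)
  g <- genoFromList(list(dad = c(NA_integer_, 0L), mum = c(0L, 0L),
                         kid = c(2L, 0L)), panel, ped)
  expect_identical(validateMendelian(ped, g, panel)$iid, "kid")
})
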