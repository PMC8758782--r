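## Cohort-level counting and enrichment statistics for the S192Y/R402Q
## haplotype across albinism cohorts.

.cohortGroups <- c("MISSING_HERITABILITY", "MOLECULARLY_DIAGNOSED", "CONTROL")

#' Read a cohort count table
#'
#' TSV with columns \code{cohort_id}, \code{group} (one of
#' \code{MISSING_HERITABILITY}, \code{MOLECULARLY_DIAGNOSED},
#' \code{CONTROL}), \code{n_total}, \code{n_hap_possible} and optionally
#' \code{phenotype_desc}, \code{n_informative}, \code{n_cis_in_trans}
#' (\code{NA} allowed). Count invariants (\code{0 <= n_cis_in_trans <=
#' n_informative <= n_hap_possible <= n_total}) are enforced.
#'
#' Packaged transcriptions of the published per-cohort counts ship as
#' \code{system.file("extdata", "table2.tsv", package = "ocaphase")} and
#' \code{"table3.tsv"}.
#'
#' @param path Path to the TSV.
#' @return A data.frame of cohort rows.
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cohort_id", "group", "n_total", "n_hap_possible")
  if (!all(need %in% names(tab)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  for (col in c("n_informative", "n_cis_in_trans"))
    if (!col %in% names(tab)) tab[[col]] <- NA_integer_
  for (col in c("n_total", "n_hap_possible", "n_informative",
                "n_cis_in_trans"))
    tab[[col]] <- as.integer(tab[[col]])
  if (!all(tab$group %in% .cohortGroups))
    stop("group must be one of: ", paste(.cohortGroups, collapse = ", "))
  bad <- with(tab, n_hap_possible < 0 | n_hap_possible > n_total |
                (!is.na(n_informative) & n_informative > n_hap_possible) |
                (!is.na(n_cis_in_trans) & is.na(n_informative)) |
                (!is.na(n_cis_in_trans) & n_cis_in_trans > n_informative))
  if (any(bad))
    stop("count invariants violated for cohorts: ",
         paste(tab$cohort_id[bad], collapse = ", "))
  tab
}

#' Combine per-cohort counts into one proportion
#'
#' Sums a numerator and denominator column over the (optionally
#' group-filtered) cohort rows and reports the combined percentage,
#' rounded half-up to one decimal to match the published table
#' formatting. Rows with a missing numerator are excluded from both
#' sums, with a warning.
#'
#' @param rows Cohort rows (see \code{\link{readCohortTable}}).
#' @param group Optional group filter.
#' @param numerator Column used as numerator (default
#'   \code{"n_hap_possible"}; use \code{"n_cis_in_trans"} for
#'   informative-cohort mode).
#' @param denominator Column used as denominator (default
#'   \code{"n_total"}; use \code{"n_informative"} for
#'   informative-cohort mode).
#' @return A list with \code{k} (summed numerator), \code{n} (summed
#'   denominator) and \code{pct}.
#' @examples
#' rows <- data.frame(cohort_id = c("a", "b"),
#'                    group = "MISSING_HERITABILITY",
#'                    n_total = c(51L, 20L), n_hap_possible = c(49L, 1L))
#' aggregateCohorts(rows)  # 50/71
#' @export
aggregateCohorts <- function(rows, group = NULL,
                             numerator = "n_hap_possible",
                             denominator = "n_total") {
  if (!is.null(group)) rows <- rows[rows$group %in% group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no cohort rows left after group filter")
  drop <- is.na(rows[[numerator]])
  if (any(drop)) {
    warning("excluding cohorts with missing ", numerator, ": ",
            paste(rows$cohort_id[drop], collapse = ", "))
    rows <- rows[!drop, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("all rows have missing ", numerator)
  k <- sum(rows[[numerator]])
  n <- sum(rows[[denominator]])
  list(k = k, n = n, pct = roundHalfUp(100 * k / n, 1L))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Wraps \code{\link[stats]{chisq.test}} for the 2x2 enrichment
#' comparison. The Yates continuity correction defaults on, mirroring
#' the conventional default of the R test the analysis relies on; set
#' \code{yates = FALSE} for the uncorrected Pearson statistic. Because
#' double precision bottoms out, the human-readable display string
#' reports \code{"p < 2.2e-16"} below that floor while \code{p} carries
#' the actual value.
#'
#' @param a,b,c,d Cell counts, row-wise (\code{a,b} first row), or a
#'   2x2 matrix as \code{a} with the rest missing.
#' @param yates Apply the continuity correction (default \code{TRUE}).
#' @return A list: \code{table}, \code{chi2}, \code{df} (1), \code{p},
#'   \code{correction}, \code{proportions} (per-row k/n and percent) and
#'   \code{display}.
#' @examples
#' pearsonChi2(144, 140, 2, 99)$display
#' @export
pearsonChi2 <- function(a, b = NULL, c = NULL, d = NULL, yates = TRUE) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  storage.mode(tab) <- "double"
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("degenerate 2x2 table: row margin ", which(rs == 0)[1L], " is zero")
  if (any(cs == 0))
    stop("degenerate 2x2 table: column margin ", which(cs == 0)[1L],
         " is zero")
  ht <- stats::chisq.test(tab, correct = yates)
  p <- ht$p.value
  list(table = tab, chi2 = unname(ht$statistic), df = 1L, p = p,
       correction = yates,
       proportions = data.frame(
         k = tab[, 1L], n = rs,
         pct = roundHalfUp(100 * tab[, 1L] / rs, 1L)),
       display = if (p < 2.2e-16) "p < 2.2e-16" else
         paste0("p = ", format(p, digits = 3L)))
}

#' Cohort enrichment report
#'
#' Aggregates the packaged-style cohort tables into the headline
#' quantities of the analysis: the combined proportion of
#' missing-heritability individuals in whom the S192Y/R402Q haplotype is
#' possible, the same proportion for molecularly diagnosed cohorts, the
#' chi-squared enrichment test between the two (with and without
#' continuity correction), the combined informative-cohort proportion in
#' which the haplotype was in cis and in trans to the pathogenic
#' variant, and the combined diagnostic-uplift proportion over all
#' missing-heritability individuals with phase data.
#'
#' @param cohorts Haplotype-screening rows (Table 2 layout): per-cohort
#'   \code{n_total} and \code{n_hap_possible} with at least the
#'   \code{MISSING_HERITABILITY} and \code{MOLECULARLY_DIAGNOSED} groups.
#' @param informative Optional phase-informative rows (Table 3 layout)
#'   with \code{n_informative} and \code{n_cis_in_trans}.
#' @return A list with elements \code{missingHeritability},
#'   \code{diagnosed} (each \code{k}/\code{n}/\code{pct}),
#'   \code{enrichment} (list \code{yates}, \code{uncorrected}),
#'   \code{perCohort}, and when \code{informative} is given
#'   \code{informativeCis} and \code{uplift}.
#' @export
enrichmentReport <- function(cohorts, informative = NULL) {
  if (length(unique(cohorts$group)) < 2L)
    stop("enrichment report needs at least two cohort groups")
  mh <- aggregateCohorts(cohorts, "MISSING_HERITABILITY")
  dx <- aggregateCohorts(cohorts, "MOLECULARLY_DIAGNOSED")
  enrich <- list(
    yates = pearsonChi2(mh$k, mh$n - mh$k, dx$k, dx$n - dx$k, yates = TRUE),
    uncorrected = pearsonChi2(mh$k, mh$n - mh$k, dx$k, dx$n - dx$k,
                              yates = FALSE))
  perCohort <- data.frame(
    cohort_id = cohorts$cohort_id, group = cohorts$group,
    k = cohorts$n_hap_possible, n = cohorts$n_total,
    pct = roundHalfUp(100 * cohorts$n_hap_possible / cohorts$n_total, 1L))
  out <- list(missingHeritability = mh, diagnosed = dx,
              enrichment = enrich, perCohort = perCohort)
  if (!is.null(informative)) {
    out$informativeCis <- aggregateCohorts(
      informative, numerator = "n_cis_in_trans",
      denominator = "n_informative")
    out$uplift <- aggregateCohorts(
      informative, numerator = "n_cis_in_trans", denominator = "n_total")
    out$perCohortUplift <- data.frame(
      cohort_id = informative$cohort_id,
      k = informative$n_cis_in_trans, n = informative$n_total,
      pct = roundHalfUp(100 * informative$n_cis_in_trans /
                          informative$n_total, 1L))
  }
  out
}

#' Reproduce the packaged cohort tables end to end
#'
#' Loads the packaged per-cohort count tables (transcribed published
#' counts) and runs \code{\link{enrichmentReport}} on them.
#'
#' @return The \code{\link{enrichmentReport}} list.
#' @examples
#' rep <- reproduceCohortTables()
#' rep$missingHeritability$pct  # 50.7
#' rep$uplift$pct               # 25.5
#' @export
reproduceCohortTables <- function() {
  t2 <- readCohortTable(system.file("extdata", "table2.tsv",
                                    package = "ocaphase"))
  t3 <- readCohortTable(system.file("extdata", "table3.tsv",
                                    package = "ocaphase"))
  enrichmentReport(t2, informative = t3)
}
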