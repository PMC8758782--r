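## Pedigree phase resolution by Mendelian constraint satisfaction.
##
## Haplotypes over the k panel loci are integer bit codes (bit j set =
## alternate allele at panel locus j, loci in panel order). An ordered
## diplotype state is a (paternal, maternal) code pair. Within a
## pedigree the panel span is treated as recombination-free, so each
## non-founder's paternal haplotype must equal one of the father's two
## haplotypes, and likewise on the maternal side. Phase is whatever
## survives that constraint system.

.hapCache <- new.env(parent = emptyenv())

## all ordered (pat, mat) code pairs for k loci, plus per-locus dosage
.stateTable <- function(k) {
  key <- as.character(k)
  if (!is.null(.hapCache[[key]])) return(.hapCache[[key]])
  haps <- 0:(2L^k - 1L)
  grid <- expand.grid(mat = haps, pat = haps)[, c("pat", "mat")]
  states <- as.matrix(grid)
  dos <- sapply(seq_len(k), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    as.integer(bitwAnd(states[, 1L], bit) > 0) +
      as.integer(bitwAnd(states[, 2L], bit) > 0)
  })
  dos <- matrix(as.integer(dos), nrow = nrow(states))
  res <- list(states = states, dosage = dos)
  .hapCache[[key]] <- res
  res
}

#' Decode a haplotype bit code to per-locus alleles
#'
#' @param code Integer haplotype code(s).
#' @param panel A \linkS4class{VariantPanel} (or an integer locus count).
#' @return A 0/1 matrix, one row per code, columns named by variant id.
#' @export
hapAlleles <- function(code, panel) {
  k <- if (is(panel, "VariantPanel")) length(panel) else as.integer(panel)
  out <- sapply(seq_len(k), function(j)
    as.integer(bitwAnd(code, bitwShiftL(1L, j - 1L)) > 0))
  out <- matrix(as.integer(out), nrow = length(code))
  if (is(panel, "VariantPanel")) colnames(out) <- variantIds(panel)
  out
}

#' Enumerate the diplotype states consistent with one genotype
#'
#' All ordered (paternal, maternal) haplotype pairs whose per-locus
#' allele sums match the observed dosages; loci with missing dosage are
#' unconstrained. For h heterozygous and m missing loci this yields
#' \eqn{2^h \cdot 4^m} ordered states.
#'
#' @param dosage Integer vector of dosages (0/1/2/\code{NA}), one per
#'   panel locus, in panel order.
#' @param panel A \linkS4class{VariantPanel} (or an integer locus count).
#' @return Integer matrix with columns \code{pat} and \code{mat} of
#'   haplotype codes (see \code{\link{hapAlleles}}).
#' @export
enumerateDiplotypeStates <- function(dosage, panel) {
  k <- if (is(panel, "VariantPanel")) length(panel) else as.integer(panel)
  stopifnot(length(dosage) == k)
  tab <- .stateTable(k)
  keep <- rep(TRUE, nrow(tab$states))
  for (j in seq_len(k))
    if (!is.na(dosage[j])) keep <- keep & tab$dosage[, j] == dosage[j]
  tab$states[keep, , drop = FALSE]
}

## ---- constraint propagation ------------------------------------------

## edges: data.frame(parent, child, side) with side 1 = paternal copy
.pedigreeEdges <- function(ped) {
  m <- members(ped)
  e <- rbind(
    data.frame(parent = m$father, child = m$iid, side = 1L),
    data.frame(parent = m$mother, child = m$iid, side = 2L))
  e <- e[!is.na(e$parent), , drop = FALSE]
  e[order(e$child, e$side), , drop = FALSE]
}

## connected components over parent-child links; returns list of iid sets
.pedigreeComponents <- function(iids, edges) {
  parent <- seq_along(iids)
  findi <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- stats::setNames(seq_along(iids), iids)
  for (r in seq_len(nrow(edges))) {
    a <- findi(idx[[edges$parent[r]]]); b <- findi(idx[[edges$child[r]]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(iids), findi, integer(1L))
  split(iids, roots)
}

## arc-consistency fixpoint over one component; NULL if a domain empties
.prune <- function(domains, edges) {
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      p <- edges$parent[r]; ch <- edges$child[r]; side <- edges$side[r]
      pd <- domains[[p]]; cd <- domains[[ch]]
      if (is.null(pd) || is.null(cd)) next
      ph <- unique(c(pd[, 1L], pd[, 2L]))
      keepC <- cd[, side] %in% ph
      if (!all(keepC)) {
        cd <- cd[keepC, , drop = FALSE]
        domains[[ch]] <- cd
        changed <- TRUE
        if (nrow(cd) == 0L) return(NULL)
      }
      chh <- unique(cd[, side])
      keepP <- pd[, 1L] %in% chh | pd[, 2L] %in% chh
      if (!all(keepP)) {
        pd <- pd[keepP, , drop = FALSE]
        domains[[p]] <- pd
        changed <- TRUE
        if (nrow(pd) == 0L) return(NULL)
      }
    }
    if (!changed) return(domains)
  }
}

## backtracking search for one globally consistent configuration;
## returns domains all reduced to single states, or NULL
.btSolve <- function(domains, edges) {
  sizes <- vapply(domains, nrow, integer(1L))
  if (any(sizes == 0L)) return(NULL)
  open <- names(domains)[sizes > 1L]
  if (!length(open)) return(domains)
  var <- open[which.min(sizes[open])]
  dom <- domains[[var]]
  for (s in seq_len(nrow(dom))) {
    d2 <- domains
    d2[[var]] <- dom[s, , drop = FALSE]
    d2 <- .prune(d2, edges)
    if (!is.null(d2)) {
      res <- .btSolve(d2, edges)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

## ---- solver ----------------------------------------------------------

#' Resolve diplotype states across a pedigree
#'
#' Constraint-satisfaction phasing: each individual's candidate ordered
#' diplotype states are those matching its observed dosages
#' (\code{\link{enumerateDiplotypeStates}}); each non-founder's paternal
#' haplotype is constrained to one of the father's two haplotypes and
#' the maternal one likewise, with no recombination across the panel
#' span. Arc-consistency pruning runs first, then backtracking search
#' establishes, for every individual, exactly the states it takes in at
#' least one globally consistent configuration of the whole pedigree.
#'
#' Individuals flagged by \code{\link{validateMendelian}} are excluded
#' (their genotypes masked) before phasing. If no globally consistent
#' configuration exists, every individual's state set is empty and the
#' solution is flagged inconsistent, reporting the nuclear family where
#' the contradiction surfaced when determinable.
#'
#' @param pedigree A \linkS4class{Pedigree}.
#' @param genotypes A \linkS4class{GenotypeMatrix}.
#' @param panel A \linkS4class{VariantPanel} with at most 4 loci.
#' @param excludeMendelian Mask individuals with single-locus Mendelian
#'   violations before phasing (default \code{TRUE}).
#' @return A \code{PhaseSolution} list: \code{domains} (per-iid integer
#'   matrices of surviving ordered states, columns \code{pat},
#'   \code{mat}), \code{consistent}, \code{conflict} (character note or
#'   \code{NA}), \code{excluded} (masked iids), \code{panel}.
#' @seealso \code{\link{phaseVariantPair}},
#'   \code{\link{exhaustivePhaseOracle}}
#' @export
solvePedigreePhase <- function(pedigree, genotypes, panel,
                               excludeMendelian = TRUE) {
  k <- length(panel)
  if (k > 4L)
    stop("phasing supports at most 4 panel loci (", k, " given)")
  geno <- GenotypeMatrix(dosages(genotypes), pedigree = pedigree,
                         panel = panel)
  d <- dosages(geno)
  excluded <- character()
  if (excludeMendelian) {
    viol <- validateMendelian(pedigree, geno, panel)
    excluded <- sort(unique(viol$iid))
    d[excluded, ] <- NA_integer_
  }
  iids <- sort(members(pedigree)$iid)
  domains <- lapply(iids, function(i)
    enumerateDiplotypeStates(d[i, ], panel))
  names(domains) <- iids
  edges <- .pedigreeEdges(pedigree)
  comps <- .pedigreeComponents(iids, edges)
  consistent <- TRUE
  conflict <- NA_character_
  for (comp in comps) {
    comp <- sort(comp)
    ce <- edges[edges$child %in% comp, , drop = FALSE]
    sub <- domains[comp]
    if (nrow(ce) == 0L) { domains[comp] <- sub; next }  # singleton
    pruned <- .prune(sub, ce)
    if (is.null(pruned)) {
      consistent <- FALSE
      conflict <- .conflictNote(sub, ce)
      next
    }
    sub <- .supportFilter(pruned, ce)
    if (is.null(sub)) {
      consistent <- FALSE
      conflict <- .conflictNote(pruned, ce)
      next
    }
    domains[comp] <- sub[comp]
  }
  if (!consistent)   # no global configuration exists for the pedigree
    domains <- lapply(domains, function(x) x[0L, , drop = FALSE])
  structure(list(domains = domains, consistent = consistent,
                 conflict = conflict, excluded = excluded,
                 panel = panel),
            class = "PhaseSolution")
}

## keep only states that occur in >= 1 globally consistent configuration
.supportFilter <- function(domains, edges) {
  supported <- lapply(domains, function(x) logical(nrow(x)))
  for (iid in names(domains)) {
    dom <- domains[[iid]]
    for (s in seq_len(nrow(dom))) {
      if (supported[[iid]][s]) next
      d2 <- domains
      d2[[iid]] <- dom[s, , drop = FALSE]
      d2 <- .prune(d2, edges)
      sol <- if (is.null(d2)) NULL else .btSolve(d2, edges)
      if (!is.null(sol)) {
        ## every state in the found configuration is supported
        for (j in names(sol)) {
          st <- sol[[j]]
          hit <- which(domains[[j]][, 1L] == st[1L] &
                         domains[[j]][, 2L] == st[2L])
          supported[[j]][hit] <- TRUE
        }
      }
    }
    ## unsupported states of a finished individual can never reappear
    domains[[iid]] <- dom[supported[[iid]], , drop = FALSE]
    supported[[iid]] <- supported[[iid]][supported[[iid]]]
    if (nrow(domains[[iid]]) == 0L) return(NULL)
  }
  domains
}

.conflictNote <- function(domains, edges) {
  empty <- names(domains)[vapply(domains, nrow, integer(1L)) == 0L]
  if (!length(empty))
    return("no globally consistent configuration")
  child <- empty[1L]
  par <- unique(edges$parent[edges$child == child])
  paste0("no consistent configuration; contradiction surfaced in the ",
         "nuclear family of ", child,
         if (length(par)) paste0(" (parents ",
                                 paste(par, collapse = ", "), ")") else "")
}

#' @export
print.PhaseSolution <- function(x, ...) {
  n <- length(x$domains)
  sizes <- vapply(x$domains, nrow, integer(1L))
  cat("PhaseSolution over", n, "individuals;",
      if (x$consistent) "consistent" else paste("INCONSISTENT:", x$conflict),
      "\n")
  if (length(x$excluded))
    cat("excluded (Mendelian violation):",
        paste(x$excluded, collapse = ", "), "\n")
  cat("surviving states per individual: min", min(sizes),
      "median", stats::median(sizes), "max", max(sizes), "\n")
  invisible(x)
}

## ---- pairwise phase calls --------------------------------------------

## does haplotype code carry the alt allele at both loci a and b (1-based)?
.hapHasBoth <- function(code, a, b) {
  bitwAnd(code, bitwShiftL(1L, a - 1L)) > 0 &
    bitwAnd(code, bitwShiftL(1L, b - 1L)) > 0
}

#' Call the cis/trans phase of a variant pair per individual
#'
#' For every pedigree member with non-missing dosages at both loci, the
#' surviving diplotype states from \code{\link{solvePedigreePhase}} are
#' classified: a state is cis-bearing if one of its haplotypes carries
#' the alternate allele at both loci. The call is \code{CIS} when every
#' surviving state is cis-bearing, \code{TRANS} when none is,
#' \code{UNINFORMATIVE} when both kinds survive and \code{INCONSISTENT}
#' when none survive. Members with dosage 0 at either locus get
#' \code{NOT_DOUBLE_HET}: no cis haplotype is possible for them.
#' Genotypes with a homozygous-alternate locus (e.g. dosages 1 and 2)
#' are phase-forced and therefore resolve without family information.
#'
#' @param pedigree A \linkS4class{Pedigree}.
#' @param genotypes A \linkS4class{GenotypeMatrix}.
#' @param panel A \linkS4class{VariantPanel}.
#' @param pair Character vector of two panel variant ids; default the
#'   S192Y/R402Q pair.
#' @param solution Optional precomputed \code{PhaseSolution}.
#' @return A data.frame with columns \code{iid}, \code{pair},
#'   \code{call}, \code{nCisStates}, \code{nTransStates} (counts of
#'   surviving ordered states supporting each phase).
#' @export
phaseVariantPair <- function(pedigree, genotypes, panel,
                             pair = c("S192Y", "R402Q"),
                             solution = NULL) {
  ids <- variantIds(panel)
  if (!all(pair %in% ids))
    stop("pair variants not in panel: ",
         paste(setdiff(pair, ids), collapse = ", "))
  a <- match(pair[1L], ids); b <- match(pair[2L], ids)
  if (is.null(solution))
    solution <- solvePedigreePhase(pedigree, genotypes, panel)
  geno <- GenotypeMatrix(dosages(genotypes), pedigree = pedigree,
                         panel = panel)
  d <- dosages(geno)
  d[solution$excluded, ] <- NA_integer_
  pairLab <- paste(sort(pair), collapse = ",")
  rows <- list()
  for (iid in sort(members(pedigree)$iid)) {
    dA <- d[iid, a]; dB <- d[iid, b]
    if (is.na(dA) || is.na(dB)) next
    dom <- solution$domains[[iid]]
    cisState <- .hapHasBoth(dom[, 1L], a, b) | .hapHasBoth(dom[, 2L], a, b)
    nCis <- sum(cisState); nTrans <- nrow(dom) - nCis
    call <- if (nrow(dom) == 0L) "INCONSISTENT"
    else if (min(dA, dB) == 0L) "NOT_DOUBLE_HET"
    else if (nTrans == 0L) "CIS"
    else if (nCis == 0L) "TRANS"
    else "UNINFORMATIVE"
    if (call == "NOT_DOUBLE_HET") { nCis <- 0L; nTrans <- 0L }
    rows[[length(rows) + 1L]] <- data.frame(
      iid = iid, pair = pairLab, call = call,
      nCisStates = nCis, nTransStates = nTrans)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(iid = character(), pair = character(),
                      call = character(), nCisStates = integer(),
                      nTransStates = integer())
  out
}
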