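## Brute-force phasing oracle: enumerates every joint assignment of
## dosage-consistent ordered diplotype states and keeps those in which
## each child's paternal haplotype is one of the father's two and
## likewise maternally. Independent of the constraint-propagation
## solver; used to validate it on small pedigrees.

## parents-before-children ordering (pedigree is acyclic by validity)
.topoOrder <- function(ped) {
  m <- members(ped)
  placed <- character()
  todo <- sort(m$iid)
  fa <- stats::setNames(m$father, m$iid)
  mo <- stats::setNames(m$mother, m$iid)
  while (length(todo)) {
    ready <- todo[vapply(todo, function(i) {
      p <- c(fa[[i]], mo[[i]])
      p <- p[!is.na(p)]
      all(p %in% placed)
    }, logical(1L))]
    if (!length(ready)) stop("pedigree parent graph is cyclic")
    placed <- c(placed, ready)
    todo <- setdiff(todo, ready)
  }
  placed
}

#' Exhaustive phasing oracle for small pedigrees
#'
#' Same contract as \code{\link{solvePedigreePhase}} but computed by
#' direct enumeration of all joint state assignments (growing a table of
#' partial configurations individual by individual, parents first, and
#' filtering on the transmission constraint). Refuses pedigrees of more
#' than \code{maxMembers} individuals or enumerations beyond
#' \code{maxConfigs} partial configurations.
#'
#' @inheritParams solvePedigreePhase
#' @param maxMembers Size refusal threshold (default 10).
#' @param maxConfigs Cap on the running number of partial configurations.
#' @return A \code{PhaseSolution} (see \code{\link{solvePedigreePhase}}),
#'   with the additional element \code{nConfigs}, the number of globally
#'   consistent configurations.
#' @export
exhaustivePhaseOracle <- function(pedigree, genotypes, panel,
                                  excludeMendelian = TRUE,
                                  maxMembers = 10L, maxConfigs = 2e6) {
  if (length(pedigree) > maxMembers)
    stop("exhaustive oracle refuses pedigrees of more than ",
         maxMembers, " members")
  geno <- GenotypeMatrix(dosages(genotypes), pedigree = pedigree,
                         panel = panel)
  d <- dosages(geno)
  excluded <- character()
  if (excludeMendelian) {
    viol <- validateMendelian(pedigree, geno, panel)
    excluded <- sort(unique(viol$iid))
    d[excluded, ] <- NA_integer_
  }
  ord <- .topoOrder(pedigree)
  m <- members(pedigree)
  fa <- stats::setNames(m$father, m$iid)
  mo <- stats::setNames(m$mother, m$iid)
  stateSets <- lapply(ord, function(i)
    enumerateDiplotypeStates(d[i, ], panel))
  names(stateSets) <- ord
  ## configs: matrix of state-row indices, one column per placed individual
  configs <- matrix(seq_len(nrow(stateSets[[1L]])), ncol = 1L)
  colnames(configs) <- ord[1L]
  for (i in ord[-1L]) {
    si <- stateSets[[i]]
    nNew <- nrow(configs) * nrow(si)
    if (nNew > maxConfigs)
      stop("exhaustive oracle enumeration exceeds maxConfigs")
    idxOld <- rep(seq_len(nrow(configs)), each = nrow(si))
    idxNew <- rep(seq_len(nrow(si)), times = nrow(configs))
    keep <- rep(TRUE, nNew)
    if (!is.na(fa[[i]]) && fa[[i]] %in% colnames(configs)) {
      fstates <- stateSets[[fa[[i]]]][configs[idxOld, fa[[i]]], ,
                                      drop = FALSE]
      keep <- keep & (si[idxNew, 1L] == fstates[, 1L] |
                        si[idxNew, 1L] == fstates[, 2L])
    }
    if (!is.na(mo[[i]]) && mo[[i]] %in% colnames(configs)) {
      mstates <- stateSets[[mo[[i]]]][configs[idxOld, mo[[i]]], ,
                                      drop = FALSE]
      keep <- keep & (si[idxNew, 2L] == mstates[, 1L] |
                        si[idxNew, 2L] == mstates[, 2L])
    }
    configs <- cbind(configs[idxOld[keep], , drop = FALSE],
                     idxNew[keep])
    colnames(configs)[ncol(configs)] <- i
    if (nrow(configs) == 0L) break
  }
  consistent <- nrow(configs) > 0L
  domains <- lapply(ord, function(i) {
    if (!consistent) return(stateSets[[i]][0L, , drop = FALSE])
    rows <- sort(unique(configs[, i]))
    stateSets[[i]][rows, , drop = FALSE]
  })
  names(domains) <- ord
  domains <- domains[sort(ord)]
  structure(list(domains = domains, consistent = consistent,
                 conflict = if (consistent) NA_character_ else
                   "no globally consistent configuration",
                 excluded = excluded, panel = panel,
                 nConfigs = nrow(configs)),
            class = "PhaseSolution")
}
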