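## Internal helpers shared across modules.

# round() in R is round-half-even; cohort tables use half-up at 1 dp.
roundHalfUp <- function(x, digits = 1L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

.sexLevels <- c("MALE", "FEMALE", "UNKNOWN")

.phenotypeLevels <- c("AFFECTED_COMPLETE", "AFFECTED_PARTIAL", "AFFECTED_MILD",
                      "UNAFFECTED", "UNKNOWN")

.pathoClasses <- c("PATHOGENIC_NULL", "HYPOMORPHIC_COMPONENT",
                   "REFERENCE_SCALE")

.alleleTypes <- c("NULL_PATHOGENIC", "HYPOMORPHIC_CIS", "SINGLE_VARIANT",
                  "REFERENCE")

.predictionLevels <- c("COMPLETE_OCA", "PARTIAL_OCA1B", "MILD_HYPOMORPHIC",
                       "UNAFFECTED_CARRIER", "UNAFFECTED", "INDETERMINATE")

.phaseCalls <- c("CIS", "TRANS", "UNINFORMATIVE", "NOT_DOUBLE_HET",
                 "INCONSISTENT")

.checkChoice <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices)
    stop(what, " must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  x
}
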