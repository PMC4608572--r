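#' Screening counts from a PCR + serology survey
#'
#' Validated container for the tallies of a two-tissue PCR screen
#' combined with a serological (antibody) screen of the same animals:
#' PCR positives in each tissue (e.g. chest-cavity fluid and kidney),
#' animals positive in both tissues, seropositive animals, and the
#' overlap between seropositives and PCR positives. Validation enforces
#' the obvious set relations; a violated field is named in the error.
#'
#' @param pcr_pos_tissue1,pcr_pos_tissue2 PCR-positive animals per
#'   tissue.
#' @param pcr_pos_both_tissues animals positive in both tissues.
#' @param sero_pos seropositive animals.
#' @param sero_pos_and_pcr_pos animals both seropositive and
#'   PCR-positive.
#' @param total_animals animals screened.
#' @return object of class `pvgc_screening_counts`.
#' @export
screening_counts <- function(pcr_pos_tissue1, pcr_pos_tissue2,
                             pcr_pos_both_tissues, sero_pos,
                             sero_pos_and_pcr_pos, total_animals) {
  x <- list(pcr_pos_tissue1 = pcr_pos_tissue1,
            pcr_pos_tissue2 = pcr_pos_tissue2,
            pcr_pos_both_tissues = pcr_pos_both_tissues,
            sero_pos = sero_pos,
            sero_pos_and_pcr_pos = sero_pos_and_pcr_pos,
            total_animals = total_animals)
  for (f in names(x)) {
    if (length(x[[f]]) != 1 || !is.finite(x[[f]]) || x[[f]] < 0 ||
        x[[f]] != round(x[[f]])) {
      stop("field `", f, "` must be a single non-negative integer")
    }
  }
  if (x$pcr_pos_both_tissues > min(x$pcr_pos_tissue1, x$pcr_pos_tissue2)) {
    stop("field `pcr_pos_both_tissues` exceeds a single-tissue count")
  }
  if (x$sero_pos_and_pcr_pos > x$sero_pos) {
    stop("field `sero_pos_and_pcr_pos` exceeds `sero_pos`")
  }
  over <- names(x)[unlist(x) > x$total_animals]
  if (length(over)) {
    stop("field `", over[1], "` exceeds `total_animals`")
  }
  structure(x, class = "pvgc_screening_counts")
}

#' Animals with any sign of infection
#'
#' Inclusion-exclusion union of the PCR and serology screens: PCR
#' positives counted once across tissues, plus seropositives not
#' already counted among the PCR positives. An animal that is both
#' seropositive and PCR-positive contributes once.
#'
#' @param counts a [screening_counts()].
#' @return integer count of animals with molecular or serological
#'   evidence of previous or acute infection.
#' @examples
#' # bank vole survey: 23 + 41 - 2 PCR positives, 17 - 6 extra
#' # seropositives -> 73 of 172 animals
#' infection_sign_union(screening_counts(23, 41, 2, 17, 6, 172))
#' @export
infection_sign_union <- function(counts) {
  stopifnot(inherits(counts, "pvgc_screening_counts"))
  u <- (counts$pcr_pos_tissue1 + counts$pcr_pos_tissue2 -
          counts$pcr_pos_both_tissues) +
    (counts$sero_pos - counts$sero_pos_and_pcr_pos)
  if (u > counts$total_animals) {
    stop("union exceeds `total_animals`; check the overlap fields")
  }
  as.integer(u)
}

#' Prevalence as a percentage, one decimal
#'
#' 100 * positive / total, rounded half-away-from-zero to one decimal
#' place (so 42.4418... prints as 42.4 and 17.647... as 17.6). The
#' half-away-from-zero rule is fixed for determinism across platforms;
#' base R's `round()` rounds half to even.
#'
#' @param positive,total non-negative counts, `positive <= total`,
#'   `total > 0`.
#' @return percentage with one decimal.
#' @export
prevalence_percent <- function(positive, total) {
  stopifnot(length(positive) == 1, length(total) == 1)
  if (total <= 0) stop("total must be positive")
  if (positive < 0 || positive > total) {
    stop("require 0 <= positive <= total")
  }
  pct <- 100 * positive / total
  floor(pct * 10 + 0.5) / 10
}
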