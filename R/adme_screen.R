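#' Default six-criterion screening thresholds
#'
#' The Lipinski-style screen used to select orally active, drug-like
#' compounds: MW <= 500 Da, AlogP <= 5, Hdon <= 5, Hacc <= 10,
#' OB >= 30 percent, DL >= 0.18. All comparisons are inclusive.
#'
#' @param mw_max maximum molecular weight, Dalton
#' @param alogp_max maximum octanol/water partition estimate
#' @param hdon_max maximum hydrogen-bond donor count
#' @param hacc_max maximum hydrogen-bond acceptor count
#' @param ob_min minimum oral bioavailability, percent
#' @param dl_min minimum drug-likeness, in \[0, 1\]
#' @return a `screening_criteria` list
#' @export
screening_criteria <- function(mw_max = 500, alogp_max = 5, hdon_max = 5,
                               hacc_max = 10, ob_min = 30, dl_min = 0.18) {
  crit <- list(mw_max = mw_max, alogp_max = alogp_max, hdon_max = hdon_max,
               hacc_max = hacc_max, ob_min = ob_min, dl_min = dl_min)
  stopifnot(all(vapply(crit, is.finite, logical(1))),
            ob_min >= 0, dl_min >= 0, dl_min <= 1)
  structure(crit, class = "screening_criteria")
}

#' Tanimoto similarity of two descriptor vectors
#'
#' `T(A, B) = A.B / (|A|^2 + |B|^2 - A.B)`, the continuous Tanimoto
#' coefficient used to score a molecule's descriptor profile against known
#' drugs. Symmetric; equals 1 exactly when `a == b` (nonzero); can be
#' negative for anticorrelated vectors.
#'
#' @param a,b equal-length finite numeric vectors, not both zero
#' @return scalar in (-Inf, 1\]
#' @examples
#' tanimoto_dl(c(1, 2, 2), c(1, 2, 2))  # 1
#' tanimoto_dl(c(1, 0), c(0, 1))        # 0
#' @export
tanimoto_dl <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("descriptor vectors have different lengths")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) stop("zero denominator: both descriptor vectors are zero")
  ab / denom
}

#' Drug-likeness of a query against a reference descriptor panel
#'
#' Aggregates [tanimoto_dl()] of the query against every reference vector.
#' The field's DL scores average over a drug reference library, so `"mean"`
#' is the default; `"max"` (nearest-drug similarity) is offered as well.
#'
#' @param query numeric descriptor vector
#' @param reference non-empty list of descriptor vectors
#' @param aggregate `"mean"` (default) or `"max"`
#' @return scalar drug-likeness
#' @export
dl_against_reference <- function(query, reference,
                                 aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (length(reference) == 0) stop("reference panel is empty")
  sims <- vapply(reference, function(r) tanimoto_dl(query, r), numeric(1))
  if (aggregate == "mean") mean(sims) else max(sims)
}

#' Does one compound record pass the screen?
#'
#' @param record one-row data.frame (or list) with fields `mw`, `alogp`,
#'   `hdon`, `hacc`, `ob`, `dl`
#' @param criteria a [screening_criteria()]
#' @return logical
#' @export
passes_criteria <- function(record, criteria = screening_criteria()) {
  record$mw <= criteria$mw_max &
    record$alogp <= criteria$alogp_max &
    record$hdon <= criteria$hdon_max &
    record$hacc <= criteria$hacc_max &
    record$ob >= criteria$ob_min &
    record$dl >= criteria$dl_min
}

#' Screen a compound table on the six criteria
#'
#' Applies [passes_criteria()] row-wise, preserving input order among the
#' kept entries. Counts are reported at two levels: herb-compound entries
#' (the same molecule contributed by several herbs counts once per herb)
#' and unique molecule ids.
#'
#' @param compounds data.frame as from [read_compound_table()]
#' @param criteria a [screening_criteria()]
#' @return list with `kept` (filtered data.frame), `per_herb` (named integer
#'   vector over all eight [HERB_CODES], zeros included), `n_kept` and
#'   `n_unique` (distinct `mol_id` among kept).
#' @examples
#' res <- screen_compounds(dchd_compounds())
#' res$n_kept      # 77
#' res$n_unique    # 72
#' @export
screen_compounds <- function(compounds, criteria = screening_criteria()) {
  keep <- if (nrow(compounds) == 0) logical(0)
          else as.logical(passes_criteria(compounds, criteria))
  kept <- compounds[keep, , drop = FALSE]
  per_herb <- vapply(HERB_CODES, function(h) sum(kept$herb == h), integer(1))
  list(kept = kept,
       per_herb = per_herb,
       n_kept = nrow(kept),
       n_unique = length(unique(kept$mol_id)))
}
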