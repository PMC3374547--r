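#' Diversity of a patient's values on one quasi-identifier
#'
#' Distinct values over total values across the patient's claims, in
#' (0, 1]. A chronic patient whose diagnosis repeats across 12 claims has
#' diagnosis diversity 1/12; a patient whose every claim differs has
#' diversity 1.
#'
#' @param values non-empty vector of one patient's claim values for one QI.
#' @return Fraction in (0, 1].
#' @export
qi_diversity <- function(values) {
  if (length(values) == 0) stop("values must be non-empty")
  length(unique(values)) / length(values)
}

#' Adversary power for one patient and quasi-identifier
#'
#' The number of claim values for this QI an adversary is assumed to know.
#' Power grows with the patient's claim count and shrinks with the
#' diversity of the values (repetition makes values easier to learn), and
#' is capped by `p_m` and by the claim count itself:
#' `clamp(ceiling(n/u), 1, min(p_m, n))`. A patient with no claims has
#' power 0 (no transactional background knowledge exists).
#'
#' @param n claim count.
#' @param u distinct-value count, `1 <= u <= n`.
#' @param p_m power cap (default 5).
#' @return Integer power.
#' @export
adversary_power <- function(n, u, p_m = 5L) {
  if (n == 0) return(0L)
  if (u < 1 || u > n) stop("u must satisfy 1 <= u <= n")
  as.integer(min(max(ceiling(n / u), 1), min(p_m, n)))
}

#' Per-patient, per-QI adversary profile
#'
#' Computes claim counts, distinct-value counts, diversity and power for
#' every patient and every level-2 quasi-identifier, on the dataset's
#' current (possibly generalized) values — the adversary's background
#' knowledge is expressed in the released vocabulary, and coarsening lowers
#' diversity, so power can only grow under generalization.
#'
#' @param ds a `claims_dataset` (original or generalized).
#' @param qis level-2 QI columns; default [level2_qis()].
#' @param p_m power cap (default 5).
#' @return An object of class `adversary_profile`: data.frame with
#'   `member_id`, `qi`, `n`, `u`, `diversity`, `power`; patients without
#'   claims get power 0 rows.
#' @export
adversary_profile <- function(ds, qis = level2_qis(), p_m = 5L) {
  validate_dataset(ds)
  members <- ds$patients$member_id
  mfac <- factor(ds$claims$member_id, levels = members)
  rows <- list()
  for (qi in qis) {
    v <- as.character(ds$claims[[qi]])
    n <- as.integer(table(mfac))
    u <- as.integer(tapply(v, mfac, function(x) length(unique(x))))
    u[is.na(u)] <- 0L
    power <- mapply(function(ni, ui) {
      if (ni == 0) 0L else adversary_power(ni, ui, p_m)
    }, n, u)
    rows[[qi]] <- data.frame(
      member_id = members, qi = qi, n = n, u = u,
      diversity = ifelse(n > 0, u / n, NA_real_),
      power = as.integer(power),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("adversary_profile", "data.frame"),
            p_m = as.integer(p_m))
}
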