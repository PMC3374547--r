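#' Configuration of a simulated re-identification attack
#'
#' @param alpha membership probability: the chance the adversary's target is
#'   in the released sample at all.
#' @param iterations Monte-Carlo iterations (reference analyses use 10000).
#' @param p_m adversary power cap.
#' @param variant `"baseline"` (inexact knowledge, inexact order),
#'   `"same_claim"` (the adversary additionally knows all quasi-identifiers
#'   of one claim), or `"ordered"` (the adversary knows the temporal order
#'   of one value pair per QI with power above 1).
#' @param seed integer seed.
#' @return An object of class `attack_config`.
#' @export
attack_config <- function(alpha, iterations = 10000L, p_m = 5L,
                          variant = c("baseline", "same_claim", "ordered"),
                          seed = 1L) {
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(
    list(alpha = alpha, iterations = as.integer(iterations),
         p_m = as.integer(p_m), variant = variant, seed = as.integer(seed)),
    class = "attack_config"
  )
}

# ---- independent matcher ----------------------------------------------------
# Deliberately separate from the lattice-search matcher (different author
# role in the methodology): operates on per-patient claim frames with
# sort-based multiset containment, and returns the full matching member set.

.attack_prep <- function(ds, qis) {
  members <- ds$patients$member_id
  l1cols <- lapply(level1_qis(), function(col) as.character(ds$patients[[col]]))
  demo <- Reduce(function(a, b) paste(a, b, sep = "|"), l1cols)
  mfac <- factor(ds$claims$member_id, levels = members)
  per_qi <- lapply(qis, function(qi) {
    unname(split(as.character(ds$claims[[qi]]), mfac))
  })
  names(per_qi) <- qis
  order_key <- unname(split(dsfc_rank(ds$claims$dsfc), mfac))
  claim_sig <- if (length(qis) > 0) {
    sig <- Reduce(function(a, b) paste(a, b, sep = "|"),
                  lapply(qis, function(qi) as.character(ds$claims[[qi]])))
    unname(split(sig, mfac))
  } else {
    NULL
  }
  list(members = members, demo = demo, per_qi = per_qi,
       order_key = order_key, claim_sig = claim_sig, qis = qis)
}

# containment test by sorted-vector sweep (no tables)
.contains_all <- function(known, observed) {
  if (length(known) == 0) return(TRUE)
  if (length(known) > length(observed)) return(FALSE)
  known <- sort(known)
  observed <- sort(observed)
  j <- 1L
  for (val in known) {
    while (j <= length(observed) && observed[j] < val) j <- j + 1L
    if (j > length(observed) || observed[j] != val) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

.independent_match_set <- function(bk, prep) {
  bk_demo <- gsub("\x1f", "|", bk$level1, fixed = TRUE)
  hits <- character(0)
  for (p in seq_along(prep$members)) {
    if (prep$demo[p] != bk_demo) next
    ok <- TRUE
    for (qi in prep$qis) {
      if (!.contains_all(bk$level2[[qi]], prep$per_qi[[qi]][[p]])) {
        ok <- FALSE
        break
      }
    }
    if (ok && !is.null(bk$same_claim_tuple)) {
      sig <- gsub("\x1f", "|", bk$same_claim_tuple, fixed = TRUE)
      ok <- any(prep$claim_sig[[p]] == sig)
    }
    if (ok && !is.null(bk$ordered_pairs)) {
      for (qi in names(bk$ordered_pairs)) {
        pr <- bk$ordered_pairs[[qi]]
        vals <- prep$per_qi[[qi]][[p]]
        keys <- prep$order_key[[p]]
        if (pr[["first"]] == pr[["second"]]) {
          ok <- sum(vals == pr[["first"]]) >= 2
        } else {
          k1 <- keys[vals == pr[["first"]]]
          k2 <- keys[vals == pr[["second"]]]
          ok <- length(k1) > 0 && length(k2) > 0 && min(k1) <= max(k2)
        }
        if (!ok) break
      }
    }
    if (ok) hits <- c(hits, prep$members[p])
  }
  hits
}

# ---- the simulated attack ---------------------------------------------------

.check_d1_d2 <- function(d1, d2) {
  if (!setequal(d1$patients$member_id, d2$patients$member_id)) {
    stop("d2 is not derived from d1: patient sets differ beyond truncation")
  }
}

#' Simulate the nosey-neighbor re-identification attack
#'
#' Replays, many times, what an adversary with partial background knowledge
#' would do. Per iteration: (1) draw membership — with probability
#' `1 - alpha` the target is not in the sample and the iteration fails;
#' (2) choose a target patient uniformly from the untruncated dataset `d1`;
#' (3) draw the adversary's background knowledge from `d1` (per-QI power
#' from the adversary profile, variant payloads per `cfg$variant`);
#' (4) match it against the released dataset `d2`, yielding a matching
#' equivalence class; (5) pick one matching record uniformly; (6) succeed
#' iff the pick is the target. Failed membership draws stay in the
#' denominator.
#'
#' `d1` and `d2` must be generalized at the same node and hold the same
#' patients; they differ only by claim truncation.
#'
#' @param d1 untruncated (generalized) `claims_dataset`.
#' @param d2 released truncated (generalized) `claims_dataset`.
#' @param cfg an [attack_config()].
#' @param qis level-2 QI columns.
#' @return An object of class `attack_result`: `successes`, `iterations`,
#'   `rate`, `se` (binomial), `variant`, `p_m`.
#' @export
simulate_attack1 <- function(d1, d2, cfg, qis = level2_qis()) {
  validate_dataset(d1)
  validate_dataset(d2)
  stopifnot(inherits(cfg, "attack_config"))
  .check_d1_d2(d1, d2)
  profile <- adversary_profile(d1, qis, cfg$p_m)
  d1cache <- .match_cache(d1, qis)
  powermat <- .power_matrix(profile, qis)
  prep <- .attack_prep(d2, qis)
  n <- d1cache$n

  set.seed(cfg$seed)
  member_draws <- rbinom(cfg$iterations, 1L, cfg$alpha)
  targets <- sample.int(n, cfg$iterations, replace = TRUE)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, cfg$iterations)

  successes <- 0L
  for (it in seq_len(cfg$iterations)) {
    if (member_draws[it] == 0L) next
    idx <- targets[it]
    set.seed(iter_seeds[it])
    bk <- .draw_bk(
      d1cache, idx, powermat,
      same_claim = cfg$variant == "same_claim",
      ordered = cfg$variant == "ordered"
    )
    matches <- .independent_match_set(bk, prep)
    if (length(matches) == 0) next
    pick <- matches[sample.int(length(matches), 1L)]
    if (pick == d1cache$members[idx]) successes <- successes + 1L
  }
  rate <- successes / cfg$iterations
  structure(
    list(
      successes = successes, iterations = cfg$iterations, rate = rate,
      se = sqrt(rate * (1 - rate) / cfg$iterations),
      variant = cfg$variant, p_m = cfg$p_m
    ),
    class = "attack_result"
  )
}

#' @export
print.attack_result <- function(x, ...) {
  cat("<attack_result> ", x$variant, ", p_m=", x$p_m, ": ",
      x$successes, "/", x$iterations, " = ",
      format(100 * x$rate, digits = 4), "% (se ",
      format(100 * x$se, digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Sensitivity grid of simulated attack rates
#'
#' Runs [simulate_attack1()] over the cross of assumption variants and
#' adversary power caps. All cells in one variant row share the same master
#' seed, so rates within a row are paired: power-cap comparisons see the
#' same membership draws, targets and (prefix-coupled) knowledge draws.
#'
#' @param d1,d2 as in [simulate_attack1()].
#' @param alpha membership probability.
#' @param p_m_values power caps (columns), default `c(5, 10, 15)`.
#' @param variants assumption rows, default all three.
#' @param iterations per cell.
#' @param seed master seed; row `r` uses `seed + r - 1`.
#' @param qis level-2 QI columns.
#' @return data.frame with `variant`, `p_m`, `successes`, `iterations`,
#'   `rate`, `se`.
#' @export
attack_grid <- function(d1, d2, alpha, p_m_values = c(5L, 10L, 15L),
                        variants = c("baseline", "same_claim", "ordered"),
                        iterations = 10000L, seed = 1L,
                        qis = level2_qis()) {
  out <- list()
  for (r in seq_along(variants)) {
    for (pm in p_m_values) {
      cfg <- attack_config(alpha, iterations, pm, variants[r],
                           seed = seed + r - 1L)
      res <- simulate_attack1(d1, d2, cfg, qis)
      out[[length(out) + 1L]] <- data.frame(
        variant = variants[r], p_m = pm, successes = res$successes,
        iterations = res$iterations, rate = res$rate, se = res$se,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
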