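#' Risk parameters for a release
#'
#' Bundles the re-identification risk calculus: the per-record probability
#' threshold `theta`, the implied population class-size floor
#' `F_min = 1/theta`, the sampling fraction `alpha`, the residual
#' high-risk budget `maxsup = u/theta` derived by equating risk exposure
#' with the Safe Harbor population-uniqueness rate `u`, and the adversary
#' power cap `p_m`.
#'
#' @param theta per-record re-identification probability threshold
#'   (default `.05`).
#' @param alpha sampling fraction in (0, 1].
#' @param u reference population-uniqueness rate (default `0.0004`, the
#'   rate observed for Safe Harbor-compliant data).
#' @param F_min population class-size floor; defaults to `1/theta`.
#' @param maxsup allowed proportion of above-threshold records; defaults to
#'   `u/theta`.
#' @param p_m adversary power cap (default 5).
#' @return An object of class `risk_params`.
#' @export
risk_params <- function(theta = 0.05, alpha = 1, u = 0.0004,
                        F_min = NULL, maxsup = NULL, p_m = 5L) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (u < 0 || u > 1) stop("u must be in [0, 1]")
  if (is.null(F_min)) F_min <- 1 / theta
  if (is.null(maxsup)) maxsup <- maxsup_from_exposure(theta, u)
  structure(
    list(theta = theta, alpha = alpha, u = u, F_min = F_min,
         maxsup = maxsup, p_m = as.integer(p_m),
         k = compute_k(F_min, alpha)),
    class = "risk_params"
  )
}

#' @export
print.risk_params <- function(x, ...) {
  cat("<risk_params> theta=", x$theta, " alpha=", x$alpha,
      " F_min=", x$F_min, " k=", x$k, " maxsup=", x$maxsup,
      " p_m=", x$p_m, "\n", sep = "")
  invisible(x)
}

#' Partition records into equivalence classes
#'
#' Records sharing identical values on all the listed quasi-identifier
#' columns form one class; class sizes drive every identity-disclosure
#' metric.
#'
#' @param records non-empty data.frame.
#' @param qi_columns character vector of column names to partition on.
#' @return An object of class `equivalence_table`: `keys` (data.frame of
#'   distinct tuples), `f` (sample class sizes), `index` (class id per
#'   input record), optionally `F_hat` after
#'   [add_population_estimates()].
#' @export
equivalence_classes <- function(records, qi_columns) {
  if (nrow(records) == 0) stop("records must be non-empty")
  missing_cols <- setdiff(qi_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- do.call(paste, c(lapply(qi_columns, function(col) {
    as.character(records[[col]])
  }), sep = "\x1f"))
  if (length(qi_columns) == 0) key <- rep("", nrow(records))
  fac <- factor(key, levels = unique(key))
  idx <- as.integer(fac)
  f <- as.integer(table(fac))
  keys <- records[!duplicated(idx), qi_columns, drop = FALSE]
  rownames(keys) <- NULL
  structure(
    list(keys = keys, f = f, index = idx, F_hat = NULL,
         key_strings = levels(fac)),
    class = "equivalence_table"
  )
}

#' @export
print.equivalence_table <- function(x, ...) {
  cat("<equivalence_table> ", length(x$f), " classes over ",
      sum(x$f), " records; sizes ", min(x$f), "..", max(x$f), "\n", sep = "")
  invisible(x)
}

#' Estimate a population equivalence-class size from a sample size
#'
#' Converts a sample class size `f_j` into an estimate of the class size in
#' the source population sampled at fraction `alpha`.
#' `large_sample` inverts the expectation `f_j = alpha * F_j` directly.
#' `truncated_poisson` accounts for classes observed only because they were
#' sampled at all: it solves `f_j = lambda / (1 - exp(-lambda))`
#' (mean-matching the zero-truncated Poisson) and returns `lambda / alpha`,
#' floored at `f_j` (a population class is never smaller than its sample);
#' `f_j = 1` forces `lambda = 0` and is returned as `f_j` itself.
#'
#' @param f_j sample class size (>= 1).
#' @param alpha sampling fraction in (0, 1].
#' @param method `"large_sample"` or `"truncated_poisson"`.
#' @return Estimated population class size.
#' @export
estimate_population_class_size <- function(f_j, alpha,
                                           method = c("large_sample",
                                                      "truncated_poisson")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (f_j < 1) stop("f_j must be >= 1")
  if (method == "large_sample") {
    return(f_j / alpha)
  }
  if (f_j <= 1) {
    return(f_j)
  }
  # f(lambda) = lambda/(1-exp(-lambda)) is increasing, ranges (1, Inf);
  # root is bracketed by (0, f_j] since f(lambda) <= 1 + lambda.
  g <- function(lam) lam / (1 - exp(-lam)) - f_j
  lam <- uniroot(g, lower = 1e-12, upper = f_j, tol = 1e-10)$root
  # a population class is never smaller than its observed sample class
  max(lam / alpha, f_j)
}

#' Attach population class-size estimates to an equivalence table
#'
#' @param tab an [equivalence_classes()] result.
#' @param alpha sampling fraction.
#' @param method estimator passed to [estimate_population_class_size()].
#' @param F_known optional vector of known population sizes (census or
#'   registry), overriding estimation.
#' @return The table with `F_hat` filled in.
#' @export
add_population_estimates <- function(tab, alpha,
                                     method = "large_sample",
                                     F_known = NULL) {
  stopifnot(inherits(tab, "equivalence_table"))
  if (!is.null(F_known)) {
    if (length(F_known) != length(tab$f)) {
      stop("F_known must have one entry per class")
    }
    if (any(F_known < tab$f)) {
      stop("population class sizes cannot be below sample sizes")
    }
    tab$F_hat <- as.numeric(F_known)
  } else {
    tab$F_hat <- vapply(tab$f, estimate_population_class_size,
                        numeric(1), alpha = alpha, method = method)
  }
  tab
}

#' Per-record re-identification probability
#'
#' The reciprocal of the record's population equivalence-class size.
#'
#' @param F_j population class size(s), >= 1.
#' @return Probability vector `1/F_j`.
#' @export
record_risk <- function(F_j) {
  if (any(F_j < 1)) stop("F_j must be >= 1")
  1 / F_j
}

#' Maximum (prosecutor) risk of a release
#'
#' The risk of the most exposed record: `1 / min(F_j)`.
#'
#' @param tab an [equivalence_classes()] table with `F_hat` set, or a
#'   numeric vector of population class sizes.
#' @return The maximum per-record probability.
#' @export
max_risk <- function(tab) {
  F_j <- if (inherits(tab, "equivalence_table")) {
    if (is.null(tab$F_hat)) stop("population sizes not set; see add_population_estimates()")
    tab$F_hat
  } else {
    tab
  }
  max(record_risk(F_j))
}

#' Minimum sample class size implied by the population floor
#'
#' Under the large-sample relation `f_j = alpha * F_j`, enforcing a
#' population class-size floor `F_min` on a sample drawn at fraction `alpha`
#' requires sample classes of at least `k = ceiling(alpha * F_min)` records.
#' The ceiling is conservative: it never admits a class whose implied
#' population size is below `F_min`.
#'
#' @param F_min population class-size floor (>= 1).
#' @param alpha sampling fraction in (0, 1].
#' @return Integer `k`.
#' @export
#' @examples
#' compute_k(20, 0.2) # 4
compute_k <- function(F_min, alpha) {
  if (F_min < 1) stop("F_min must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  as.integer(ceiling(alpha * F_min))
}

#' Residual high-risk budget from risk-exposure equality
#'
#' Risk exposure is loss times probability. Assuming every above-threshold
#' record is re-identified with probability 1, a release keeps its exposure
#' at or below that of a reference standard with population-uniqueness rate
#' `u` exactly when the proportion of above-threshold records is at most
#' `u / theta`.
#'
#' @param theta per-record probability threshold in (0, 1].
#' @param u reference uniqueness rate in [0, 1].
#' @return The maximum tolerable proportion (`MaxSup`).
#' @export
#' @examples
#' maxsup_from_exposure(0.05, 0.0004) # 0.008
maxsup_from_exposure <- function(theta, u) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  if (u < 0 || u > 1) stop("u must be in [0, 1]")
  u / theta
}

#' Worst-case expected re-identified fraction
#'
#' Conservative bound: a `maxsup` fraction of records re-identified with
#' probability 1, everyone else sitting exactly at the threshold `theta`.
#'
#' @param maxsup high-risk proportion in [0, 1].
#' @param theta probability threshold in [0, 1].
#' @return `maxsup + (1 - maxsup) * theta`.
#' @export
#' @examples
#' worst_case_reident_fraction(0.008, 0.05) # 0.0576, i.e. at most 5.8%
worst_case_reident_fraction <- function(maxsup, theta) {
  if (maxsup < 0 || maxsup > 1 || theta < 0 || theta > 1) {
    stop("maxsup and theta must be in [0, 1]")
  }
  maxsup * 1 + (1 - maxsup) * theta
}

#' Acceptability of a release under the risk budget
#'
#' A release is acceptable when the proportion of records whose estimated
#' per-record probability `1/F_hat_j` exceeds `theta` is at most `maxsup`.
#'
#' @param F_hat per-record population class-size estimates (one entry per
#'   record, not per class), or an [equivalence_classes()] table with
#'   `F_hat` set (expanded to records internally).
#' @param params a [risk_params()] object.
#' @return An object of class `risk_report`: `per_record_risk`, `max_risk`,
#'   `prop_high_risk`, `acceptable`.
#' @export
acceptability <- function(F_hat, params) {
  stopifnot(inherits(params, "risk_params"))
  if (inherits(F_hat, "equivalence_table")) {
    if (is.null(F_hat$F_hat)) stop("population sizes not set")
    F_hat <- F_hat$F_hat[F_hat$index]
  }
  risk <- record_risk(F_hat)
  prop <- mean(risk > params$theta)
  structure(
    list(
      per_record_risk = risk,
      max_risk = max(risk),
      prop_high_risk = prop,
      acceptable = prop <= params$maxsup,
      params = params
    ),
    class = "risk_report"
  )
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> max risk ", format(x$max_risk, digits = 4),
      "; ", format(100 * x$prop_high_risk, digits = 4),
      "% of records above theta=", x$params$theta,
      " (budget ", format(100 * x$params$maxsup, digits = 4), "%): ",
      if (x$acceptable) "ACCEPTABLE" else "NOT acceptable", "\n", sep = "")
  invisible(x)
}

#' Marketer risk: expected number of correct matches
#'
#' When every sample record is matched to a uniformly chosen population
#' record in its equivalence class, the expected number of correct matches
#' is `sum_j f_j / F_j`. Divide by the sample size for the expected
#' proportion. This is the metric for list-matching attacks (voter
#' registries, state inpatient databases).
#'
#' @param f named numeric vector of sample class sizes, keyed by tuple.
#' @param F named numeric vector of population class sizes covering every
#'   name in `f`.
#' @return List with `expected_matches` and `proportion`.
#' @export
marketer_risk <- function(f, F) {
  if (is.null(names(f)) || is.null(names(F))) {
    stop("f and F must be named by class tuple")
  }
  missing_keys <- setdiff(names(f), names(F))
  if (length(missing_keys) > 0) {
    stop("sample class(es) absent from population: ",
         paste(head(missing_keys, 5), collapse = ", "))
  }
  Fm <- F[names(f)]
  if (any(Fm < f)) stop("population class sizes cannot be below sample sizes")
  em <- sum(f / Fm)
  list(expected_matches = em, proportion = em / sum(f))
}
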