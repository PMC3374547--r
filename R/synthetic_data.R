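#' Configuration for the synthetic claims generator
#'
#' The generator emulates the structural features of longitudinal claims
#' that drive re-identification risk: heavy-tailed per-patient claim counts
#' (negative binomial), chronic patients whose diagnosis repeats across
#' claims (low diversity, high adversary power), skewed categorical
#' vocabularies (Zipf), within-patient-year increasing day offsets, and —
#' for oracle tests — an optional exact blueprint of level-1
#' equivalence-class sizes.
#'
#' @param n_patients number of patients in the population.
#' @param seed integer seed; generation is deterministic given the config.
#' @param claims_mean,claims_dispersion negative-binomial mean and dispersion
#'   of per-patient claim counts (minimum 1 claim; defaults give a median
#'   near 11 with a long right tail).
#' @param chronic_fraction fraction of patients whose diagnosis repeats
#'   across all their claims.
#' @param zipf_s Zipf exponent for categorical value frequencies.
#' @param vocab optional named list of custom vocabularies per level-2
#'   categorical QI (`specialty`, `place_of_service`, `cpt_code`,
#'   `diagnosis`); defaults come from the packaged demonstration grouping
#'   tables so generated data is always covered by the default hierarchies.
#' @param blueprint optional data.frame with columns `age`, `sex`,
#'   `dih_y2`, `dih_y3`, `size`: exact level-1 tuples and class sizes
#'   (sizes must sum to `n_patients`).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 200L, seed = 1L,
                         claims_mean = 13, claims_dispersion = 1.2,
                         chronic_fraction = 0.3, zipf_s = 1.2,
                         vocab = NULL, blueprint = NULL) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (chronic_fraction < 0 || chronic_fraction > 1) {
    stop("chronic_fraction must be in [0, 1]")
  }
  if (!is.null(blueprint)) {
    need <- c("age", "sex", "dih_y2", "dih_y3", "size")
    if (!all(need %in% names(blueprint))) {
      stop("blueprint needs columns ", paste(need, collapse = ", "))
    }
    if (sum(blueprint$size) != n_patients) {
      stop("blueprint sizes must sum to n_patients")
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         claims_mean = claims_mean, claims_dispersion = claims_dispersion,
         chronic_fraction = chronic_fraction, zipf_s = zipf_s,
         vocab = vocab, blueprint = blueprint),
    class = "synth_config"
  )
}

.default_vocab <- function() {
  read_codes <- function(which) .read_grouping(.default_grouping_path(which))$code
  dx_prefixes <- read_codes("diagnosis")
  list(
    specialty = read_codes("specialty"),
    place_of_service = read_codes("place_of_service"),
    cpt_code = read_codes("cpt_code"),
    diagnosis = as.vector(outer(dx_prefixes, c(".0", ".1"), paste0))
  )
}

.zipf_sample <- function(n, vocab, s) {
  p <- seq_along(vocab)^(-s)
  sample(vocab, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic population of longitudinal claims
#'
#' @param cfg a [synth_config()].
#' @return A `claims_dataset` with `alpha = 1` (it is the population).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  vocab <- cfg$vocab
  if (is.null(vocab)) vocab <- .default_vocab()

  member_id <- sprintf("M%06d", seq_len(n))
  if (!is.null(cfg$blueprint)) {
    bp <- cfg$blueprint
    rep_i <- rep(seq_len(nrow(bp)), bp$size)
    patients <- data.frame(
      member_id = member_id,
      age = as.integer(bp$age[rep_i]),
      sex = as.character(bp$sex[rep_i]),
      dih_y2 = as.integer(bp$dih_y2[rep_i]),
      dih_y3 = as.integer(bp$dih_y3[rep_i]),
      stringsAsFactors = FALSE
    )
  } else {
    patients <- data.frame(
      member_id = member_id,
      age = sample(0:99, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      # many zeros, long right tail: exercises top-coding
      dih_y2 = rnbinom(n, size = 0.25, mu = 1),
      dih_y3 = rnbinom(n, size = 0.25, mu = 1),
      stringsAsFactors = FALSE
    )
  }

  n_claims <- 1L + rnbinom(n, size = cfg$claims_dispersion,
                           mu = max(cfg$claims_mean - 1, 0.01))
  chronic <- runif(n) < cfg$chronic_fraction
  providers <- sprintf("PR%03d", 1:30)
  vendors <- sprintf("V%02d", 1:12)
  pcps <- sprintf("PCP%02d", 1:20)

  claims <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_claims[i]
    year <- sort(sample(c("Y1", "Y2", "Y3"), k, replace = TRUE))
    dsfc <- integer(k)
    for (y in unique(year)) {
      rows <- which(year == y)
      gaps <- if (length(rows) > 1) rpois(length(rows) - 1, 14) + 1L else integer(0)
      dsfc[rows] <- cumsum(c(0L, gaps))
    }
    diagnosis <- if (chronic[i]) {
      rep(.zipf_sample(1, vocab$diagnosis, cfg$zipf_s), k)
    } else {
      .zipf_sample(k, vocab$diagnosis, cfg$zipf_s)
    }
    claims[[i]] <- data.frame(
      member_id = member_id[i],
      provider_id = sample(providers, k, replace = TRUE),
      vendor = sample(vendors, k, replace = TRUE),
      pcp = rep(sample(pcps, 1), k),
      year = year,
      specialty = .zipf_sample(k, vocab$specialty, cfg$zipf_s),
      place_of_service = .zipf_sample(k, vocab$place_of_service, cfg$zipf_s),
      cpt_code = .zipf_sample(k, vocab$cpt_code, cfg$zipf_s),
      los = rnbinom(k, size = 0.5, mu = 2),
      dsfc = dsfc,
      pay_delay = as.integer(round(stats::rgamma(k, shape = 2, scale = 20))),
      diagnosis = diagnosis,
      stringsAsFactors = FALSE
    )
  }
  claims_dataset(patients, do.call(rbind, claims), alpha = 1)
}

#' Draw the released sample from a population
#'
#' Simple random sampling of `round(alpha * N)` patients without
#' replacement, keeping all their claims; `alpha` is recorded on the
#' returned dataset (it feeds every population-size estimate downstream).
#' Fixed-size (not Bernoulli) sampling keeps fixture sizes reproducible.
#'
#' @param pop a population `claims_dataset`.
#' @param alpha sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return The sampled `claims_dataset`.
#' @export
sample_dataset <- function(pop, alpha, seed = 1L) {
  validate_dataset(pop)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  set.seed(seed)
  n <- nrow(pop$patients)
  keep <- sort(sample.int(n, round(alpha * n)))
  members <- pop$patients$member_id[keep]
  claims_dataset(
    pop$patients[keep, , drop = FALSE],
    pop$claims[pop$claims$member_id %in% members, , drop = FALSE],
    alpha = alpha
  )
}

.mk_fixture_claims <- function(member_id, specialty = "Internal",
                               place = "Office", cpt = "99213",
                               los = 0L, dsfc = 0L, diagnosis = "250.0") {
  k <- length(member_id)
  data.frame(
    member_id = member_id,
    provider_id = "PR001", vendor = "V01", pcp = "PCP01", year = "Y1",
    specialty = specialty, place_of_service = place, cpt_code = cpt,
    los = los, dsfc = dsfc, pay_delay = 10L, diagnosis = diagnosis,
    stringsAsFactors = FALSE
  )
}

#' Hand-constructed micro-fixtures with known answers
#'
#' Registry of tiny datasets whose risk quantities are known in closed
#' form, shared across the test suite:
#' * `"uniform_classes_c4"`: 16 patients in 4 level-1 classes of 4, all
#'   claims identical — the matching equivalence class is always the full
#'   level-1 class, so the simulated attack succeeds with probability
#'   `alpha / 4`.
#' * `"all_unique"`: 8 patients, all level-1 unique — maximum risk 1.
#' * `"boundary_maxsup"`: 125 patients, exactly one level-1 unique record
#'   and four classes of 31 — at `alpha = 1`, `theta = .05` the high-risk
#'   proportion is 1/125 = 0.008, sitting exactly on the budget boundary
#'   (acceptable).
#'
#' @param name fixture name.
#' @return List with `dataset` (a `claims_dataset`) and `expected` (named
#'   list of analytic values).
#' @export
make_oracle_fixture <- function(name) {
  if (name == "uniform_classes_c4") {
    ages <- rep(c(20L, 30L, 40L, 50L), each = 4)
    sex <- rep("F", 16)
    ids <- sprintf("U%02d", 1:16)
    patients <- data.frame(
      member_id = ids, age = ages, sex = sex,
      dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE
    )
    ds <- claims_dataset(patients, .mk_fixture_claims(ids), alpha = 1)
    return(list(
      dataset = ds,
      expected = list(class_size = 4L, n_classes = 4L,
                      attack_rate = function(alpha) alpha / 4)
    ))
  }
  if (name == "all_unique") {
    ids <- sprintf("A%02d", 1:8)
    patients <- data.frame(
      member_id = ids, age = seq(10L, 80L, by = 10L), sex = "M",
      dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE
    )
    ds <- claims_dataset(patients, .mk_fixture_claims(ids), alpha = 1)
    return(list(dataset = ds, expected = list(max_risk = 1)))
  }
  if (name == "boundary_maxsup") {
    sizes <- c(1L, 31L, 31L, 31L, 31L)
    ages <- rep(c(15L, 25L, 35L, 45L, 55L), sizes)
    ids <- sprintf("B%03d", seq_len(sum(sizes)))
    patients <- data.frame(
      member_id = ids, age = ages, sex = "F",
      dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE
    )
    ds <- claims_dataset(patients, .mk_fixture_claims(ids), alpha = 1)
    return(list(
      dataset = ds,
      expected = list(prop_high_risk = 1 / 125, acceptable = TRUE)
    ))
  }
  stop("unknown fixture: ", name)
}
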