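# Small in-code fixtures shared across the suite.

.mk_empty_claims <- function() tiny_claims()[0, ]

.read_demo_codes <- function(which) {
  path <- system.file("extdata", paste0(which, "_groups.csv"),
                      package = "longdeid")
  read.csv(path, colClasses = "character")$code
}

tiny_patients <- function() {
  data.frame(
    member_id = c("P1", "P2"),
    age = c(34L, 67L),
    sex = c("F", "M"),
    dih_y2 = c(0L, 3L),
    dih_y3 = c(1L, 0L),
    stringsAsFactors = FALSE
  )
}

tiny_claims <- function() {
  data.frame(
    member_id = c("P1", "P1", "P2"),
    provider_id = c("PR001", "PR002", NA),
    vendor = c("V01", "V01", "V02"),
    pcp = c("PCP01", "PCP01", "PCP02"),
    year = c("Y1", "Y2", "Y1"),
    specialty = c("Internal", "Cardiology", "Internal"),
    place_of_service = c("Office", "Office", "InpatientHospital"),
    cpt_code = c("99213", "93000", "99285"),
    los = c(0L, 0L, 4L),
    dsfc = c(0L, 0L, 0L),
    pay_delay = c(12L, 40L, 7L),
    diagnosis = c("401.0", "414.1", "401.0"),
    stringsAsFactors = FALSE
  )
}

tiny_dataset <- function(alpha = 1) {
  claims_dataset(tiny_patients(), tiny_claims(), alpha = alpha)
}

# n patients sharing `n_classes` level-1 tuples; each patient gets
# `claims_per_patient` claims over a small vocabulary, deterministic under
# seed. Level-2 values vary so matching is non-trivial.
varied_fixture <- function(n = 50, n_classes = 10, claims_per_patient = 4,
                           seed = 11) {
  set.seed(seed)
  ids <- sprintf("V%03d", seq_len(n))
  cls <- rep_len(seq_len(n_classes), n)
  patients <- data.frame(
    member_id = ids,
    age = 20L + 5L * cls,
    sex = ifelse(cls %% 2 == 0, "F", "M"),
    dih_y2 = cls %% 3,
    dih_y3 = 0L,
    stringsAsFactors = FALSE
  )
  ks <- rep_len(claims_per_patient, n)
  claims <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- ks[i]
    data.frame(
      member_id = ids[i],
      provider_id = sprintf("PR%02d", sample(1:5, k, replace = TRUE)),
      vendor = "V01", pcp = "PCP01",
      year = sample(c("Y1", "Y2", "Y3"), k, replace = TRUE),
      specialty = sample(c("Internal", "Cardiology", "Surgery"), k,
                         replace = TRUE),
      place_of_service = sample(c("Office", "InpatientHospital"), k,
                                replace = TRUE),
      cpt_code = sample(c("99213", "93000", "80053"), k, replace = TRUE),
      los = sample(0:3, k, replace = TRUE),
      dsfc = sort(sample(0:60, k)),
      pay_delay = sample(5:50, k, replace = TRUE),
      diagnosis = sample(c("250.0", "401.0", "414.1", "428.0"), k,
                         replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  claims_dataset(patients, claims, alpha = 1)
}

# every patient's level-2 values are constant within patient (u = 1 per QI),
# so background-knowledge draws are value-deterministic and match counts are
# exact; level-1 classes follow `sizes`.
deterministic_fixture <- function(sizes, claims_per_patient = 3,
                                  per_patient_diagnosis = FALSE) {
  n <- sum(sizes)
  ids <- sprintf("D%03d", seq_len(n))
  cls <- rep(seq_along(sizes), sizes)
  patients <- data.frame(
    member_id = ids,
    age = 20L + 10L * cls,
    sex = "F",
    dih_y2 = 0L,
    dih_y3 = 0L,
    stringsAsFactors = FALSE
  )
  claims <- do.call(rbind, lapply(seq_len(n), function(i) {
    dx <- if (per_patient_diagnosis) sprintf("250.%d", i %% 10) else "250.0"
    data.frame(
      member_id = ids[i],
      provider_id = "PR01", vendor = "V01", pcp = "PCP01", year = "Y1",
      specialty = "Internal", place_of_service = "Office",
      cpt_code = "99213", los = 0L,
      dsfc = seq(0L, by = 7L, length.out = claims_per_patient),
      pay_delay = 10L, diagnosis = dx,
      stringsAsFactors = FALSE
    )
  }))
  claims_dataset(patients, claims, alpha = 1)
}
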