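test_that("top-coding uses the nearest-rank percentile and is idempotent", {
  tc <- top_code(1:100, 0.99)
  expect_equal(tc$cap, 99)
  expect_equal(max(tc$values), 99)
  expect_equal(sum(tc$values == 99), 2) # 99 itself plus the capped 100
  # degenerate distribution: unchanged
  same <- top_code(rep(7, 20), 0.99)
  expect_equal(same$values, rep(7, 20))
  expect_equal(same$cap, 7)
  # idempotence across percentiles and shapes
  for (p in c(0.5, 0.9, 0.99)) {
    v <- rnbinom(200, size = 0.5, mu = 8)
    once <- top_code(v, p)$values
    expect_equal(top_code(once, p)$values, once)
  }
  expect_error(top_code(numeric(0), 0.99), "non-empty")
})

test_that("claim scores are negative log frequencies summed over level-2 QIs", {
  # 4 claims identical on everything except one singleton diagnosis
  patients <- data.frame(
    member_id = c("A", "B"), age = c(30L, 40L), sex = "F",
    dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE
  )
  claims <- do.call(rbind, replicate(4, tiny_claims()[1, ], simplify = FALSE))
  claims$member_id <- c("A", "A", "B", "B")
  claims$diagnosis <- c("401.0", "401.0", "401.0", "250.0")
  ds <- claims_dataset(patients, claims)
  s <- score_claims(ds)
  # shared components cancel in the difference: exactly the diagnosis term
  expect_equal(s[4] - s[1], -log2(1 / 4) - (-log2(3 / 4)))
  expect_equal(s[1], s[2])
  # all values shared by all claims -> score 0
  claims$diagnosis <- "401.0"
  expect_equal(score_claims(claims_dataset(patients, claims)), rep(0, 4))
})

test_that("truncation caps per-patient counts at the percentile cut-off", {
  # every patient at the same count: nothing removed
  ds <- deterministic_fixture(c(2, 2), claims_per_patient = 3)
  tr <- truncate_claims(ds, 0.95)
  expect_equal(nrow(tr$dataset$claims), nrow(ds$claims))
  expect_equal(tr$plan$cutoff, 3)

  # one 10-claim patient among 19 8-claim patients: the 95th-percentile
  # cut-off is 8 and the over-limit patient loses its two rarest claims
  pats <- sprintf("Q%02d", 1:20)
  ids <- c(rep(pats[1], 10), rep(pats[-1], each = 8))
  claims <- do.call(rbind, lapply(seq_along(ids), function(i) {
    row <- tiny_claims()[1, ]
    row$member_id <- ids[i]
    row$dsfc <- i
    row$diagnosis <- if (i <= 2) sprintf("rare.%d", i) else "401.0"
    row
  }))
  patients <- data.frame(
    member_id = pats, age = 30L, sex = "F",
    dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE
  )
  ds2 <- claims_dataset(patients, claims)
  tr2 <- truncate_claims(ds2, 0.95)
  expect_equal(tr2$plan$cutoff, 8)
  scores <- score_claims(ds2)
  q1 <- which(ds2$claims$member_id == "Q01")
  expected_removed <- q1[order(-scores[q1], -ds2$claims$dsfc[q1], -q1)][1:2]
  expect_equal(tr2$plan$removed, sort(expected_removed))
  counts <- table(tr2$dataset$claims$member_id)
  expect_equal(max(as.integer(counts)), 8L)
  # patients at or below the cut-off untouched
  expect_equal(sum(tr2$dataset$claims$member_id == "Q02"), 8)
})

test_that("high-risk patients are removed whole, by exact or prefix match", {
  ds <- varied_fixture(n = 10, claims_per_patient = 3)
  expect_equal(
    remove_high_risk_patients(ds, high_risk_code_list())$patients,
    ds$patients
  )
  # plant listed codes on 3 patients: one ICD-9 family prefix, one exact
  # ICD-9, one CPT
  carriers <- ds$patients$member_id[c(2, 5, 9)]
  i1 <- which(ds$claims$member_id == carriers[1])[1]
  i2 <- which(ds$claims$member_id == carriers[2])[1]
  i3 <- which(ds$claims$member_id == carriers[3])[1]
  ds$claims$diagnosis[i1] <- "042.1"
  ds$claims$diagnosis[i2] <- "635"
  ds$claims$cpt_code[i3] <- "59840"
  codes <- high_risk_code_list(icd9_codes = c("042", "635"),
                               cpt_codes = "59840")
  out <- remove_high_risk_patients(ds, codes)
  expect_equal(nrow(out$patients), 7)
  expect_false(any(carriers %in% out$patients$member_id))
  expect_false(any(carriers %in% out$claims$member_id))
  expect_silent(validate_dataset(out))
})

test_that("rare provider patterns are suppressed via the population estimate", {
  # 8 distinct providers share one pattern; at alpha = 0.5 the estimated 16
  # providers fall below the threshold of 20 -> suppressed
  ids <- sprintf("S%02d", 1:8)
  patients <- data.frame(
    member_id = ids, age = 30L, sex = "F", dih_y2 = 0L, dih_y3 = 0L,
    stringsAsFactors = FALSE
  )
  claims <- do.call(rbind, lapply(1:8, function(i) {
    row <- tiny_claims()[1, ]
    row$member_id <- ids[i]
    row$provider_id <- sprintf("PR%02d", i)
    row
  }))
  ds <- claims_dataset(patients, claims, alpha = 0.5)
  out <- suppress_provider_ids(ds, min_count = 20)
  expect_true(all(is.na(out$claims$provider_id)))
  # alpha = 1 with >= 20 distinct providers on the pattern: kept
  ids20 <- sprintf("T%02d", 1:20)
  patients20 <- data.frame(
    member_id = ids20, age = 30L, sex = "F", dih_y2 = 0L, dih_y3 = 0L,
    stringsAsFactors = FALSE
  )
  claims20 <- do.call(rbind, lapply(1:20, function(i) {
    row <- tiny_claims()[1, ]
    row$member_id <- ids20[i]
    row$provider_id <- sprintf("PR%02d", i)
    row
  }))
  ds20 <- claims_dataset(patients20, claims20, alpha = 1)
  out20 <- suppress_provider_ids(ds20, min_count = 20)
  expect_false(any(is.na(out20$claims$provider_id)))
})

test_that("suppression is monotone in alpha under the default estimator", {
  # f/alpha shrinks toward the sample count as alpha rises to a census, so
  # growing alpha can only add suppressions, never remove them
  ds <- varied_fixture(n = 40, claims_per_patient = 5)
  suppressed_at <- function(alpha) {
    ds$alpha <- alpha
    out <- suppress_provider_ids(ds, min_count = 20)
    which(is.na(out$claims$provider_id))
  }
  s1 <- suppressed_at(1)
  s05 <- suppressed_at(0.5)
  s02 <- suppressed_at(0.2)
  expect_true(all(s02 %in% s05))
  expect_true(all(s05 %in% s1))
  expect_gt(length(s1), 0) # patterns rare enough to trip the threshold
})

test_that("patient removal and truncation commute with pseudonymization", {
  ds <- varied_fixture(n = 20, claims_per_patient = 6)
  codes <- high_risk_code_list(icd9_codes = "428")
  a <- pseudonymize(remove_high_risk_patients(ds, codes), secret = "k")
  b <- remove_high_risk_patients(pseudonymize(ds, secret = "k"), codes)
  expect_equal(a$patients, b$patients)
  expect_equal(a$claims, b$claims)
  ds_uneven <- varied_fixture(n = 20, claims_per_patient = c(3, 6, 9))
  ta <- pseudonymize(truncate_claims(ds_uneven)$dataset, secret = "k")
  tb <- truncate_claims(pseudonymize(ds_uneven, secret = "k"))$dataset
  expect_equal(ta$claims, tb$claims)
})
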