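test_that("attack matcher and search matcher agree on random draws", {
  ds <- varied_fixture(n = 30, n_classes = 6, claims_per_patient = 4,
                       seed = 13)
  prof <- adversary_profile(ds, p_m = 3)
  cache <- longdeid:::.match_cache(ds, level2_qis())
  prep <- longdeid:::.attack_prep(ds, level2_qis())
  powermat <- longdeid:::.power_matrix(prof, level2_qis())
  for (r in 1:1000) {
    set.seed(2000 + r)
    idx <- sample.int(cache$n, 1)
    bk <- longdeid:::.draw_bk(cache, idx, powermat,
                              same_claim = r %% 3 == 0,
                              ordered = r %% 3 == 1)
    lola_set <- cache$members[
      vapply(seq_len(cache$n), function(q) {
        cache$level1_key[q] == bk$level1 &&
          longdeid:::.matches_patient(cache, bk, q)
      }, logical(1))
    ]
    indep_set <- longdeid:::.independent_match_set(bk, prep)
    expect_setequal(lola_set, indep_set)
  }
})

test_that("both matchers agree with the brute-force oracle", {
  ds <- varied_fixture(n = 12, n_classes = 3, claims_per_patient = 3,
                       seed = 31)
  prof <- adversary_profile(ds, p_m = 4)
  prep <- longdeid:::.attack_prep(ds, level2_qis())
  for (r in 1:60) {
    set.seed(500 + r)
    target <- sample(ds$patients$member_id, 1)
    bk <- sample_background_knowledge(ds, target, prof,
                                      same_claim = r %% 2 == 0,
                                      ordered = r %% 2 == 1)
    oracle <- sort(oracle_match_set(bk, ds))
    expect_equal(sort(longdeid:::.independent_match_set(bk, prep)), oracle)
    expect_equal(match_count(bk, ds), length(oracle))
  }
})

test_that("the simulated attack hits its analytic limits", {
  # alpha = 1, all level-1 unique, no truncation: always re-identified
  fx <- make_oracle_fixture("all_unique")
  res <- simulate_attack1(fx$dataset, fx$dataset,
                          attack_config(alpha = 1, iterations = 300,
                                        seed = 5))
  expect_equal(res$rate, 1)
  # two indistinguishable patients: a coin flip
  ids <- c("T1", "T2")
  pat <- data.frame(member_id = ids, age = 40L, sex = "F",
                    dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE)
  twin <- claims_dataset(pat, longdeid:::.mk_fixture_claims(ids))
  res2 <- simulate_attack1(twin, twin,
                           attack_config(alpha = 1, iterations = 10000,
                                         seed = 6))
  expect_lt(abs(res2$rate - 0.5), 3 * sqrt(0.25 / 10000))
  # membership ceiling: rate <= alpha + 3 SE
  ds <- varied_fixture(n = 20, seed = 17)
  res3 <- simulate_attack1(ds, ds,
                           attack_config(alpha = 0.3, iterations = 4000,
                                         seed = 7))
  expect_lte(res3$rate, 0.3 + 3 * res3$se + 1e-12)
  # patient sets must agree up to truncation
  ds_drop <- ds
  ds_drop$patients <- ds$patients[-1, ]
  ds_drop$claims <- ds$claims[ds$claims$member_id %in%
                                ds_drop$patients$member_id, ]
  expect_error(
    simulate_attack1(ds, claims_dataset(ds_drop$patients, ds_drop$claims),
                     attack_config(alpha = 1, iterations = 10)),
    "truncation"
  )
})

test_that("uniform classes give the analytic success rate alpha / c", {
  fx <- make_oracle_fixture("uniform_classes_c4")
  alpha <- 0.6
  res <- simulate_attack1(fx$dataset, fx$dataset,
                          attack_config(alpha = alpha, iterations = 10000,
                                        seed = 11))
  expected <- fx$expected$attack_rate(alpha)
  se <- sqrt(expected * (1 - expected) / res$iterations)
  expect_lt(abs(res$rate - expected), 3 * se)
})

test_that("sensitivity variants move the rate in the expected direction", {
  # distinctive single claims: knowing a full claim tuple identifies the
  # patient outright
  ids <- sprintf("W%02d", 1:12)
  pat <- data.frame(member_id = ids, age = 50L, sex = "M",
                    dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE)
  claims <- longdeid:::.mk_fixture_claims(ids)
  claims$cpt_code <- sprintf("CPT%02d", 1:12)
  # two claims per patient so level-2 multisets overlap across patients
  claims2 <- claims
  claims2$cpt_code <- "99213"
  claims2$dsfc <- 7L
  dsx <- claims_dataset(pat, rbind(claims, claims2))
  base <- simulate_attack1(dsx, dsx,
                           attack_config(1, 4000, 5, "baseline", seed = 3))
  same <- simulate_attack1(dsx, dsx,
                           attack_config(1, 4000, 5, "same_claim", seed = 3))
  expect_gte(same$rate, base$rate - 3 * base$se)
  # one claim per patient: the ordered variant has no pairs and is vacuous
  ds1 <- claims_dataset(pat, claims)
  b1 <- simulate_attack1(ds1, ds1,
                         attack_config(1, 1500, 5, "baseline", seed = 9))
  o1 <- simulate_attack1(ds1, ds1,
                         attack_config(1, 1500, 5, "ordered", seed = 9))
  expect_equal(o1$rate, b1$rate)
})

test_that("the sensitivity grid is reproducible and monotone in power", {
  # patients distinguished only by how often one diagnosis repeats: a
  # higher power cap buys strictly more discriminating knowledge
  n <- 12
  ids <- sprintf("G%02d", seq_len(n))
  pat <- data.frame(member_id = ids, age = 60L, sex = "F",
                    dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE)
  claims <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- 5 + i # 6 .. 17 identical claims
    data.frame(
      member_id = ids[i], provider_id = "PR01", vendor = "V01",
      pcp = "PCP01", year = "Y1", specialty = "Internal",
      place_of_service = "Office", cpt_code = "99213", los = 0L,
      dsfc = seq(0L, by = 3L, length.out = k), pay_delay = 10L,
      diagnosis = "250.0", stringsAsFactors = FALSE
    )
  }))
  ds <- claims_dataset(pat, claims)
  grid <- attack_grid(ds, ds, alpha = 1, p_m_values = c(5L, 10L, 15L),
                      variants = c("baseline", "same_claim"),
                      iterations = 2000, seed = 21)
  grid_again <- attack_grid(ds, ds, alpha = 1,
                            p_m_values = c(5L, 10L, 15L),
                            variants = c("baseline", "same_claim"),
                            iterations = 2000, seed = 21)
  expect_identical(grid, grid_again)
  for (v in unique(grid$variant)) {
    rates <- grid$rate[grid$variant == v]
    ses <- grid$se[grid$variant == v]
    expect_true(all(diff(rates) >= -3 * ses[-1]))
  }
})
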