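test_that("background knowledge is a without-replacement value sample", {
  ds <- varied_fixture(n = 10, claims_per_patient = c(1, 6))
  prof <- adversary_profile(ds, p_m = 5)
  # single-claim patient: every level-2 multiset is that claim's value
  single <- ds$patients$member_id[1]
  row <- ds$claims[ds$claims$member_id == single, ]
  set.seed(1)
  bk <- sample_background_knowledge(ds, single, prof)
  for (qi in level2_qis()) {
    expect_equal(bk$level2[[qi]], as.character(row[[qi]]))
  }
  # power >= claim count: the full column multiset is known
  prof_all <- adversary_profile(ds, p_m = 100)
  prof_all$power <- prof_all$n # exhaustive-knowledge profile
  many <- ds$patients$member_id[2]
  rows <- ds$claims[ds$claims$member_id == many, ]
  set.seed(2)
  bk2 <- sample_background_knowledge(ds, many, prof_all)
  for (qi in level2_qis()) {
    expect_equal(sort(bk2$level2[[qi]]), sort(as.character(rows[[qi]])))
  }
  # determinism under a fixed seed
  set.seed(33)
  a <- sample_background_knowledge(ds, many, prof)
  set.seed(33)
  b <- sample_background_knowledge(ds, many, prof)
  expect_identical(a, b)
  # knowledge is always a sub-multiset of the patient's true values
  for (r in 1:20) {
    set.seed(100 + r)
    bk3 <- sample_background_knowledge(ds, many, prof)
    for (qi in level2_qis()) {
      expect_true(oracle_submultiset(bk3$level2[[qi]],
                                     as.character(rows[[qi]])))
    }
  }
})

test_that("match counting agrees with brute-force enumeration", {
  ds <- varied_fixture(n = 5, n_classes = 2, claims_per_patient = 3,
                       seed = 21)
  prof <- adversary_profile(ds, p_m = 3)
  for (r in 1:50) {
    set.seed(r)
    target <- sample(ds$patients$member_id, 1)
    bk <- sample_background_knowledge(ds, target, prof)
    expect_equal(match_count(bk, ds),
                 length(oracle_match_set(bk, ds)))
    # the target always matches its own knowledge (no truncation here)
    expect_gte(match_count(bk, ds), 1)
  }
  # empty level-2 knowledge counts the whole level-1 class
  bk0 <- structure(
    list(
      level1 = paste(ds$patients[1, level1_qis()], collapse = "\x1f"),
      level2 = setNames(vector("list", 6), level2_qis()),
      same_claim_tuple = NULL, ordered_pairs = NULL
    ),
    class = "background_knowledge"
  )
  bk0$level2 <- lapply(bk0$level2, function(x) character(0))
  l1 <- do.call(paste, c(ds$patients[level1_qis()], sep = "\x1f"))
  expect_equal(match_count(bk0, ds), sum(l1 == bk0$level1))
})

test_that("node evaluation hits the degenerate limits exactly", {
  params <- risk_params(theta = 0.25, alpha = 1, u = 0.05) # k = 4
  hs <- build_default_hierarchies()[c("age", "dih")]
  # everyone identical on every QI: nobody is below k = 4 matches
  same <- deterministic_fixture(c(12))
  ev <- evaluate_node(same, c(age = 0L, dih = 0L), hs, params,
                      iterations = 5, patients_per_iteration = 30, seed = 3)
  expect_equal(ev$prop_high_risk, 0)
  expect_true(ev$acceptable)
  # everyone unique on level 1: every match count is 1 < k
  uniq <- deterministic_fixture(rep(1, 10))
  uniq$patients$age <- 10L + seq_len(10)
  ev2 <- evaluate_node(uniq, c(age = 0L, dih = 0L), hs, params,
                       iterations = 5, patients_per_iteration = 30, seed = 3)
  expect_equal(ev2$prop_high_risk, 1)
  expect_false(ev2$acceptable)
})

test_that("the bootstrap mean tracks the exact expectation", {
  # u = 1 on every level-2 QI makes each patient's match count
  # deterministic, so the exact high-risk proportion is computable by
  # enumeration
  ds <- deterministic_fixture(c(6, 5, 3, 2, 1, 1), claims_per_patient = 4,
                              per_patient_diagnosis = TRUE)
  params <- risk_params(theta = 0.25, alpha = 1, u = 0.05) # k = 4
  hs <- build_default_hierarchies()[c("age", "dih")]
  node <- c(age = 0L, dih = 0L)
  prof <- adversary_profile(ds, p_m = params$p_m)
  exact_flags <- vapply(ds$patients$member_id, function(m) {
    set.seed(1) # draw is value-deterministic; seed irrelevant
    bk <- sample_background_knowledge(ds, m, prof)
    match_count(bk, ds) < params$k
  }, logical(1))
  exact <- mean(exact_flags)
  ev <- evaluate_node(ds, node, hs, params, iterations = 60,
                      patients_per_iteration = 40, seed = 17)
  expect_lt(abs(ev$prop_high_risk - exact), 3 * ev$se + 1e-9)
})

test_that("entropy information loss counts bits of lost precision", {
  ds <- varied_fixture(n = 20)
  hs <- build_default_hierarchies()[c("age", "dih")]
  bottom <- c(age = 0L, dih = 0L)
  expect_equal(info_loss_entropy(ds, apply_node(ds, bottom, hs)), 0)
  # {a,a,b,b} merged into one group: 4 records at 1 bit each
  orig <- data.frame(member_id = sprintf("E%d", 1:4),
                     age = c(10L, 10L, 11L, 11L), sex = "F",
                     dih_y2 = 0L, dih_y3 = 0L, stringsAsFactors = FALSE)
  gen <- orig
  gen$age <- "10-11"
  ds_o <- claims_dataset(orig, .mk_empty_claims())
  ds_g <- claims_dataset(gen, .mk_empty_claims())
  expect_equal(info_loss_entropy(ds_o, ds_g, qi_columns = "age"), 4)
  # a constant column loses nothing however it is relabelled
  orig$age <- 50L
  gen$age <- "50-54"
  expect_equal(
    info_loss_entropy(claims_dataset(orig, .mk_empty_claims()),
                      claims_dataset(gen, .mk_empty_claims()),
                      qi_columns = "age"),
    0
  )
})

test_that("the lattice search matches exhaustive evaluation", {
  # deterministic fixture: level-1 classes of mixed sizes; ages distinct at
  # level 0, pooled as the age ladder coarsens
  sizes <- c(3, 3, 2, 1, 1)
  ds <- deterministic_fixture(sizes)
  ds$patients$age <- c(60L, 60L, 60L, 61L, 61L, 61L, 63L, 63L, 67L, 78L)
  hs <- build_default_hierarchies()[c("age", "dih")]
  lat <- build_lattice(hs)
  expect_equal(nrow(lat$nodes), 12)
  params <- risk_params(theta = 1 / 3, alpha = 1, u = 1 / 30) # k=3, maxsup=.1
  bargs <- list(iterations = 40, patients_per_iteration = 60, seed = 5)
  exhaustive <- lapply(seq_len(nrow(lat$nodes)), function(i) {
    do.call(evaluate_node,
            c(list(ds, lat$nodes[i, ], hs, params), bargs))
  })
  acc <- vapply(exhaustive, function(e) e$acceptable, logical(1))
  res <- do.call(lola_search, c(list(ds, lat, hs, params), bargs))
  expect_false(res$cannot_release)
  expect_setequal(rownames(res$candidates),
                  rownames(lat$nodes)[acc])
  # brute-force optimum: min info loss, ties to lower height then lex order
  loss <- vapply(which(acc), function(i) {
    info_loss_entropy(ds, apply_node(ds, lat$nodes[i, ], hs),
                      qi_columns = c("age", "dih_y2", "dih_y3"))
  }, numeric(1))
  hts <- rowSums(lat$nodes)[acc]
  best <- which(acc)[order(loss, hts)][1]
  expect_equal(unname(res$optimal), unname(lat$nodes[best, ]))
  expect_equal(min(res$info_loss), min(loss))
})

test_that("search degenerates correctly at the lattice ends", {
  hs <- build_default_hierarchies()["age"]
  params <- risk_params(theta = 0.5, alpha = 1, u = 0.05) # k = 2
  bargs <- list(iterations = 10, patients_per_iteration = 40, seed = 2)
  # acceptable at the bottom: the original data come back untouched
  ds_ok <- deterministic_fixture(c(5, 5))
  lat1 <- build_lattice(hs)
  res <- do.call(lola_search, c(list(ds_ok, lat1, hs, params), bargs))
  expect_equal(unname(res$optimal), 0L)
  expect_equal(min(res$info_loss), 0)
  # a chain where only the top level pools enough patients
  ds_chain <- deterministic_fixture(rep(1, 10))
  ds_chain$patients$age <- c(0L, 11L, 25L, 33L, 47L, 55L, 62L, 78L, 85L, 96L)
  # distinct at the 5- and 10-year coarsenings (bar the 80+ pair); only the
  # 20-year level pools everyone into classes of two
  res2 <- do.call(lola_search, c(list(ds_chain, lat1, hs, params), bargs))
  expect_equal(unname(res2$optimal), 3L)
  # nothing acceptable anywhere: explicit cannot-release result
  ds_bad <- deterministic_fixture(rep(1, 6))
  ds_bad$patients$sex <- c("F", "M", "F", "M", "F", "M")
  ds_bad$patients$age <- c(10L, 10L, 30L, 30L, 50L, 50L)
  res3 <- do.call(lola_search, c(list(ds_bad, lat1, hs, params), bargs))
  expect_true(res3$cannot_release)
  expect_null(res3$optimal)
})

test_that("search is invariant to node enumeration order", {
  ds <- deterministic_fixture(c(3, 3, 2, 1, 1))
  ds$patients$age <- c(60L, 60L, 60L, 61L, 61L, 61L, 63L, 63L, 67L, 78L)
  hs <- build_default_hierarchies()[c("age", "dih")]
  lat <- build_lattice(hs)
  params <- risk_params(theta = 1 / 3, alpha = 1, u = 1 / 30)
  bargs <- list(iterations = 20, patients_per_iteration = 40, seed = 5)
  shuffled <- lat
  set.seed(4)
  shuffled$nodes <- shuffled$nodes[sample(nrow(shuffled$nodes)), ,
                                   drop = FALSE]
  a <- do.call(lola_search, c(list(ds, lat, hs, params), bargs))
  b <- do.call(lola_search, c(list(ds, shuffled, hs, params), bargs))
  expect_equal(a$optimal, b$optimal)
  expect_setequal(rownames(a$candidates), rownames(b$candidates))
})

test_that("with no level-2 QIs and a census the search is plain k-anonymity", {
  ds <- deterministic_fixture(c(6, 5, 4, 2, 1), claims_per_patient = 2)
  ds$patients$age <- c(rep(40L, 6), rep(42L, 5), rep(44L, 4), 46L, 46L, 48L)
  hs <- build_default_hierarchies()["age"]
  lat <- build_lattice(hs)
  params <- risk_params(theta = 0.25, alpha = 1, u = 0) # k = 4, maxsup = 0
  res <- lola_search(ds, lat, hs, params, qis = character(0),
                     iterations = 5, patients_per_iteration = 80, seed = 9)
  expect_false(res$cannot_release)
  released <- apply_node(ds, res$optimal, hs)
  expect_true(oracle_k_anonymous(released, params$k))
  # and no strictly lower node is k-anonymous
  for (i in seq_len(nrow(lat$nodes))) {
    node <- lat$nodes[i, ]
    if (all(node <= res$optimal) && any(node < res$optimal)) {
      expect_false(oracle_k_anonymous(apply_node(ds, node, hs), params$k))
    }
  }
})
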