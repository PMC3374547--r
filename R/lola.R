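# Precomputed per-patient matching structures for one (generalized) dataset.
# Built once per node evaluation; all matching and background-knowledge
# drawing runs off this cache.
.match_cache <- function(ds, qis = level2_qis()) {
  members <- ds$patients$member_id
  n <- length(members)
  l1 <- do.call(paste, c(lapply(level1_qis(), function(col) {
    as.character(ds$patients[[col]])
  }), sep = "\x1f"))
  mfac <- factor(ds$claims$member_id, levels = members)
  vals <- lapply(qis, function(qi) {
    v <- split(as.character(ds$claims[[qi]]), mfac)
    v[match(members, names(v))]
  })
  names(vals) <- qis
  ranks <- split(dsfc_rank(ds$claims$dsfc), mfac)
  ranks <- ranks[match(members, names(ranks))]
  tuples <- if (length(qis) > 0) {
    tp <- do.call(paste, c(lapply(qis, function(qi) {
      as.character(ds$claims[[qi]])
    }), sep = "\x1f"))
    sp <- split(tp, mfac)
    sp[match(members, names(sp))]
  } else {
    NULL
  }
  list(
    members = members, n = n, qis = qis,
    level1_key = l1,
    by_key = split(seq_len(n), l1),
    vals = vals, ranks = ranks, tuples = tuples
  )
}

.power_matrix <- function(profile, qis) {
  members <- unique(profile$member_id)
  mat <- matrix(0L, nrow = length(members), ncol = length(qis),
                dimnames = list(members, qis))
  for (qi in qis) {
    sub <- profile[profile$qi == qi, ]
    mat[match(sub$member_id, members), qi] <- sub$power
  }
  mat
}

# Draw one background-knowledge instance for patient index `idx`.
.draw_bk <- function(cache, idx, powermat, same_claim = FALSE,
                     ordered = FALSE) {
  level2 <- list()
  ordered_pairs <- NULL
  for (qi in cache$qis) {
    v <- cache$vals[[qi]][[idx]]
    ni <- length(v)
    if (ni == 0) {
      level2[[qi]] <- character(0)
      next
    }
    take <- min(powermat[idx, qi], ni)
    picked <- sample.int(ni, take)
    level2[[qi]] <- v[picked]
    if (ordered && take > 1) {
      pair_idx <- picked[sample.int(take, 2)]
      r <- cache$ranks[[idx]][pair_idx]
      ord <- order(r)
      ordered_pairs[[qi]] <- c(first = v[pair_idx[ord[1]]],
                               second = v[pair_idx[ord[2]]])
    }
  }
  sc <- NULL
  if (same_claim && !is.null(cache$tuples)) {
    tuples <- cache$tuples[[idx]]
    if (length(tuples) > 0) sc <- tuples[sample.int(length(tuples), 1)]
  }
  structure(
    list(
      level1 = cache$level1_key[idx],
      level2 = level2,
      same_claim_tuple = sc,
      ordered_pairs = ordered_pairs
    ),
    class = "background_knowledge"
  )
}

#' Draw one adversary background-knowledge instance
#'
#' Copies the patient's level-1 (demographic) values exactly and, for each
#' level-2 quasi-identifier, draws `min(p_ih, n_i)` claim values by simple
#' random sampling without replacement — the adversary knows some of the
#' patient's claim values, but not which values sat in the same claim nor
#' their order. The sensitivity variants attach extra payloads: one full
#' claim tuple (`same_claim`), or one precedence-ordered value pair per QI
#' with power above 1 (`ordered`).
#'
#' @param ds the (generalized) `claims_dataset` the knowledge is drawn from.
#' @param member_id the target patient.
#' @param profile an [adversary_profile()] computed on `ds`.
#' @param qis level-2 QI columns.
#' @param same_claim,ordered sensitivity-variant payload switches.
#' @return An object of class `background_knowledge` with elements `level1`
#'   (key string), `level2` (named list of value multisets),
#'   `same_claim_tuple`, `ordered_pairs`.
#' @export
sample_background_knowledge <- function(ds, member_id, profile,
                                        qis = level2_qis(),
                                        same_claim = FALSE,
                                        ordered = FALSE) {
  cache <- .match_cache(ds, qis)
  idx <- match(member_id, cache$members)
  if (is.na(idx)) stop("unknown member_id: ", member_id)
  powermat <- .power_matrix(profile, qis)
  if (!identical(rownames(powermat), cache$members)) {
    powermat <- powermat[match(cache$members, rownames(powermat)), ,
                         drop = FALSE]
  }
  .draw_bk(cache, idx, powermat, same_claim, ordered)
}

# multiset containment: every value of `sub` appears in `full` at least as
# often
.submultiset <- function(sub, full) {
  ns <- length(sub)
  if (ns == 0L) return(TRUE)
  if (ns > length(full)) return(FALSE)
  if (ns == 1L) return(any(full == sub))
  u <- unique(sub)
  cs <- tabulate(match(sub, u), length(u))
  cf <- tabulate(match(full, u), length(u))
  all(cs <= cf)
}

.matches_patient <- function(cache, bk, q) {
  for (qi in cache$qis) {
    if (!.submultiset(bk$level2[[qi]], cache$vals[[qi]][[q]])) return(FALSE)
  }
  if (!is.null(bk$same_claim_tuple)) {
    if (!(bk$same_claim_tuple %in% cache$tuples[[q]])) return(FALSE)
  }
  if (!is.null(bk$ordered_pairs)) {
    r <- cache$ranks[[q]]
    for (qi in names(bk$ordered_pairs)) {
      v <- cache$vals[[qi]][[q]]
      pr <- bk$ordered_pairs[[qi]]
      if (pr["first"] == pr["second"]) {
        if (sum(v == pr["first"]) < 2) return(FALSE)
      } else {
        r1 <- r[v == pr["first"]]
        r2 <- r[v == pr["second"]]
        if (length(r1) == 0 || length(r2) == 0 ||
            min(r1) > max(r2)) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

.match_count_cached <- function(cache, bk) {
  cand <- cache$by_key[[bk$level1]]
  if (is.null(cand)) return(0L)
  m <- 0L
  for (q in cand) {
    if (.matches_patient(cache, bk, q)) m <- m + 1L
  }
  m
}

#' Count the records matching a background-knowledge instance
#'
#' A patient matches when their level-1 tuple equals the adversary's and,
#' for every level-2 QI, the adversary's value multiset is a sub-multiset of
#' the patient's claim values. Variant payloads tighten the match: the
#' `same_claim` tuple must appear as one single claim; each ordered pair
#' must be realizable with `dsfc(first) <= dsfc(second)` (ties count as
#' consistent with either order). A count of 0 is possible — truncation may
#' have removed the claims the adversary knows about.
#'
#' @param bk a [sample_background_knowledge()] result.
#' @param ds the released (generalized) `claims_dataset`, in the same
#'   vocabulary as `bk`.
#' @param qis level-2 QI columns.
#' @return Integer match count.
#' @export
match_count <- function(bk, ds, qis = level2_qis()) {
  .match_count_cached(.match_cache(ds, qis), bk)
}

#' Evaluate one lattice node by hierarchical bootstrap
#'
#' Generalizes the dataset to the node, computes the adversary profile on
#' the generalized values, then repeats `iterations` times: sample
#' `patients_per_iteration` patients with replacement; for each, draw a
#' background-knowledge instance and count its matches `m` in the
#' generalized data; flag the draw high-risk when `m < k` (the sample-side
#' test equivalent to an estimated population class below the floor). The
#' node's high-risk proportion is the mean of the per-iteration fractions.
#'
#' @param ds a `claims_dataset` with original values.
#' @param node named integer vector of hierarchy levels.
#' @param hierarchies named list of [qi_hierarchy()] objects.
#' @param params a [risk_params()] (supplies `k`, `maxsup`, `p_m`).
#' @param qis level-2 QI columns used for background knowledge (may be
#'   empty, reducing the test to level-1 k-anonymity).
#' @param iterations bootstrap iterations (reference analyses use 1000).
#' @param patients_per_iteration patients resampled per iteration
#'   (reference analyses use 10000).
#' @param seed integer seed; evaluations that should share random draws
#'   (all nodes within one search) pass the same seed.
#' @return An object of class `node_evaluation`: `node`, `prop_high_risk`,
#'   `se` (Monte-Carlo standard error over iterations), `iterations`,
#'   `patients_per_iteration`, `seed`, `acceptable`.
#' @export
evaluate_node <- function(ds, node, hierarchies, params,
                          qis = level2_qis(),
                          iterations = 1000L,
                          patients_per_iteration = 10000L,
                          seed = 1L) {
  validate_dataset(ds)
  stopifnot(inherits(params, "risk_params"))
  if (nrow(ds$patients) == 0) stop("empty dataset")
  if (iterations < 1 || patients_per_iteration < 1) {
    stop("bootstrap parameters must be positive")
  }
  gds <- apply_node(ds, node, hierarchies)
  cache <- .match_cache(gds, qis)
  powermat <- if (length(qis) > 0) {
    .power_matrix(adversary_profile(gds, qis, params$p_m), qis)
  } else {
    matrix(0L, nrow = cache$n, ncol = 0)
  }
  k <- params$k
  set.seed(seed)
  props <- numeric(iterations)
  for (b in seq_len(iterations)) {
    picks <- sample.int(cache$n, patients_per_iteration, replace = TRUE)
    high <- 0L
    for (idx in picks) {
      bk <- .draw_bk(cache, idx, powermat)
      if (.match_count_cached(cache, bk) < k) high <- high + 1L
    }
    props[b] <- high / patients_per_iteration
  }
  prop <- mean(props)
  se <- if (iterations > 1) stats::sd(props) / sqrt(iterations) else NA_real_
  structure(
    list(node = node, prop_high_risk = prop, se = se,
         iterations = iterations,
         patients_per_iteration = patients_per_iteration,
         seed = seed, acceptable = prop <= params$maxsup),
    class = "node_evaluation"
  )
}

#' @export
print.node_evaluation <- function(x, ...) {
  cat("<node_evaluation> [", .node_key(x$node), "] prop_high_risk=",
      format(x$prop_high_risk, digits = 4),
      if (!is.na(x$se)) paste0(" (se ", format(x$se, digits = 3), ")"),
      " -> ", if (x$acceptable) "acceptable" else "not acceptable",
      "\n", sep = "")
  invisible(x)
}

#' Non-uniform entropy information loss
#'
#' For every record and quasi-identifier column, the loss is
#' `-log2(count of the record's original value within its generalized group
#' / group size)` — the number of bits needed to recover the original value
#' given the released label, summed over records and columns. Zero when
#' nothing was generalized.
#'
#' @param original a `claims_dataset` with level-0 values.
#' @param generalized the same dataset after [apply_node()] (row-aligned).
#' @param qi_columns columns to score; default all level-1 and level-2 QIs.
#' @return Total loss in bits.
#' @export
info_loss_entropy <- function(original, generalized,
                              qi_columns = c(level1_qis(), level2_qis())) {
  total <- 0
  for (col in qi_columns) {
    tab <- if (col %in% names(original$patients)) "patients" else "claims"
    o <- as.character(original[[tab]][[col]])
    g <- as.character(generalized[[tab]][[col]])
    if (length(o) != length(g)) stop("datasets are not row-aligned")
    if (length(o) == 0) next
    key <- paste(g, o, sep = "\x1f")
    n_og <- table(key)[key]
    n_g <- table(g)[g]
    total <- total + sum(-log2(as.numeric(n_og) / as.numeric(n_g)))
  }
  total
}

# strict/unstrict lattice order helpers over the node matrix
.ancestors_of <- function(nodes, i) {
  which(rowSums(nodes >= rep(nodes[i, ], each = nrow(nodes))) == ncol(nodes) &
          seq_len(nrow(nodes)) != i)
}

.descendants_of <- function(nodes, i) {
  which(rowSums(nodes <= rep(nodes[i, ], each = nrow(nodes))) == ncol(nodes) &
          seq_len(nrow(nodes)) != i)
}

#' Search the generalization lattice for the optimal release node
#'
#' Finds the set of nodes whose bootstrap-estimated high-risk proportion is
#' within the `maxsup` budget, exploiting the monotonicity of acceptability
#' over the lattice order (generalizing further never increases risk):
#' when an evaluation clears the budget boundary decisively, all
#' generalizations of an acceptable node are tagged acceptable and all
#' specializations of an unacceptable node unacceptable without evaluation.
#' Because the acceptability estimate is stochastic, predictive tagging is
#' applied only when the estimate clears the boundary by at least
#' `se_guard` Monte-Carlo standard errors; boundary-hugging nodes are
#' evaluated directly. All evaluations share one seed (common random
#' numbers), so compared nodes see identical adversary draws.
#'
#' Among the acceptable candidates the optimum minimizes non-uniform
#' entropy information loss; ties break toward the lower total level sum,
#' then lexicographically. Information loss is monotone non-decreasing up
#' the lattice, so only minimal candidates are scored.
#'
#' @param ds a `claims_dataset` with original values.
#' @param lattice a [build_lattice()] result.
#' @param hierarchies the hierarchies the lattice was built from.
#' @param params a [risk_params()].
#' @param qis level-2 QI columns for background knowledge.
#' @param iterations,patients_per_iteration bootstrap size per node.
#' @param seed common seed for every node evaluation.
#' @param se_guard predictive-tagging guard in standard errors (default 2).
#' @return An object of class `search_result`: `optimal` (named levels, or
#'   `NULL` with `cannot_release = TRUE` when even the top node fails),
#'   `candidates` (matrix of acceptable nodes), `info_loss` (bits, for the
#'   scored candidates), `evaluations` (list of [evaluate_node()] results).
#' @export
lola_search <- function(ds, lattice, hierarchies, params,
                        qis = level2_qis(),
                        iterations = 200L,
                        patients_per_iteration = 2000L,
                        seed = 1L, se_guard = 2) {
  stopifnot(inherits(lattice, "gen_lattice"))
  nodes <- lattice$nodes
  # canonical height-then-lexicographic order: the search result does not
  # depend on how the caller enumerated the nodes
  ord <- do.call(order, c(list(rowSums(nodes)),
                          lapply(seq_len(ncol(nodes)),
                                 function(j) nodes[, j])))
  nodes <- nodes[ord, , drop = FALSE]
  n_nodes <- nrow(nodes)
  tag <- rep(NA, n_nodes)
  evaluations <- list()

  eval_i <- function(i) {
    node <- nodes[i, ]
    ev <- evaluate_node(
      ds, node, hierarchies, params, qis = qis,
      iterations = iterations,
      patients_per_iteration = patients_per_iteration, seed = seed
    )
    evaluations[[.node_key(node)]] <<- ev
    ev
  }

  heights <- rowSums(nodes)
  while (anyNA(tag)) {
    open <- which(is.na(tag))
    med <- stats::median(heights[open])
    i <- open[which.min(abs(heights[open] - med))]
    ev <- eval_i(i)
    tag[i] <- ev$acceptable
    clear <- is.na(ev$se) || ev$se == 0 ||
      abs(ev$prop_high_risk - params$maxsup) >= se_guard * ev$se
    if (clear) {
      if (ev$acceptable) {
        anc <- .ancestors_of(nodes, i)
        tag[anc[is.na(tag[anc])]] <- TRUE
      } else {
        dec <- .descendants_of(nodes, i)
        tag[dec[is.na(tag[dec])]] <- FALSE
      }
    }
  }

  cand_idx <- which(tag)
  if (length(cand_idx) == 0) {
    return(structure(
      list(optimal = NULL, cannot_release = TRUE,
           candidates = nodes[integer(0), , drop = FALSE],
           info_loss = numeric(0), evaluations = evaluations),
      class = "search_result"
    ))
  }
  # minimal candidates: no other candidate strictly below them
  minimal <- cand_idx[vapply(cand_idx, function(i) {
    below <- .descendants_of(nodes, i)
    !any(tag[below] %in% TRUE)
  }, logical(1))]
  loss <- vapply(minimal, function(i) {
    info_loss_entropy(ds, apply_node(ds, nodes[i, ], hierarchies),
                      qi_columns = .qi_columns_of(hierarchies))
  }, numeric(1))
  names(loss) <- rownames(nodes)[minimal]
  ord <- order(loss, heights[minimal])
  # final lexicographic tie-break comes free: nodes are stored in
  # height-then-lexicographic order
  best <- minimal[ord[1]]
  structure(
    list(
      optimal = nodes[best, ],
      cannot_release = FALSE,
      candidates = nodes[cand_idx, , drop = FALSE],
      info_loss = loss,
      evaluations = evaluations
    ),
    class = "search_result"
  )
}

.qi_columns_of <- function(hierarchies) {
  unlist(lapply(hierarchies, function(h) h$columns), use.names = FALSE)
}

#' @export
print.search_result <- function(x, ...) {
  if (x$cannot_release) {
    cat("<search_result> no acceptable node: cannot release\n")
  } else {
    cat("<search_result> optimal node [", .node_key(x$optimal),
        "], info loss ", format(min(x$info_loss), digits = 6), " bits; ",
        nrow(x$candidates), " acceptable node(s), ",
        length(x$evaluations), " evaluated\n", sep = "")
  }
  invisible(x)
}
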