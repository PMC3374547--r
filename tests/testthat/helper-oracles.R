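# Independent brute-force oracles, deliberately written with different
# mechanics than the package implementations.

# multiset containment by element-wise deletion
oracle_submultiset <- function(sub, full) {
  pool <- as.character(full)
  for (v in as.character(sub)) {
    hit <- match(v, pool)
    if (is.na(hit)) return(FALSE)
    pool <- pool[-hit]
  }
  TRUE
}

# set of member_ids matching a background-knowledge instance, by direct
# nested-loop enumeration over the data frames
oracle_match_set <- function(bk, ds, qis = level2_qis()) {
  l1 <- do.call(paste, c(lapply(level1_qis(), function(col) {
    as.character(ds$patients[[col]])
  }), sep = "\x1f"))
  hits <- character(0)
  for (p in seq_len(nrow(ds$patients))) {
    if (l1[p] != bk$level1) next
    mid <- ds$patients$member_id[p]
    rows <- ds$claims[ds$claims$member_id == mid, , drop = FALSE]
    ok <- TRUE
    for (qi in qis) {
      if (!oracle_submultiset(bk$level2[[qi]], rows[[qi]])) {
        ok <- FALSE
        break
      }
    }
    if (ok && !is.null(bk$same_claim_tuple)) {
      sig <- do.call(paste, c(lapply(qis, function(qi) {
        as.character(rows[[qi]])
      }), sep = "\x1f"))
      ok <- bk$same_claim_tuple %in% sig
    }
    if (ok && !is.null(bk$ordered_pairs)) {
      rk <- dsfc_rank(rows$dsfc)
      for (qi in names(bk$ordered_pairs)) {
        pr <- bk$ordered_pairs[[qi]]
        found <- FALSE
        for (a in seq_len(nrow(rows))) {
          for (b in seq_len(nrow(rows))) {
            if (a != b &&
                as.character(rows[[qi]][a]) == pr[["first"]] &&
                as.character(rows[[qi]][b]) == pr[["second"]] &&
                rk[a] <= rk[b]) {
              found <- TRUE
            }
          }
        }
        if (!found) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) hits <- c(hits, mid)
  }
  hits
}

# nested-loop equivalence partition
oracle_class_sizes <- function(records, qi_columns) {
  n <- nrow(records)
  assigned <- rep(NA_integer_, n)
  next_id <- 0L
  same <- function(i, j) {
    all(vapply(qi_columns, function(col) {
      identical(as.character(records[[col]][i]),
                as.character(records[[col]][j]))
    }, logical(1)))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (same(i, j)) {
        assigned[i] <- assigned[j]
        break
      }
    }
    if (is.na(assigned[i])) {
      next_id <- next_id + 1L
      assigned[i] <- next_id
    }
  }
  as.integer(table(assigned))
}

# brute-force k-anonymity check on the level-1 view of a dataset
oracle_k_anonymous <- function(ds, k) {
  sizes <- oracle_class_sizes(ds$patients, level1_qis())
  all(sizes >= k)
}
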