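#' Generalization hierarchy for one quasi-identifier
#'
#' An ordered ladder of coarsenings. Level 0 is the original value domain;
#' every subsequent level is a strict partition coarsening of the one below
#' (the refinement property the lattice search relies on). A hierarchy may
#' drive more than one dataset column (the two `DaysInHospital` years share
#' one ladder and are generalized in lock-step).
#'
#' @param qi_name identifier for the quasi-identifier.
#' @param mappers list of vectorized functions `values -> labels`, one per
#'   generalization level (level 1 upward). May be empty (`Sex` never
#'   changes).
#' @param columns dataset column(s) the hierarchy applies to; defaults to
#'   `qi_name`.
#' @return An object of class `qi_hierarchy` with `n_levels = 1 +
#'   length(mappers)` levels (level 0 = identity).
#' @export
qi_hierarchy <- function(qi_name, mappers = list(), columns = qi_name) {
  stopifnot(is.character(qi_name), length(qi_name) == 1)
  structure(
    list(qi = qi_name, mappers = mappers, columns = columns,
         n_levels = length(mappers) + 1L),
    class = "qi_hierarchy"
  )
}

#' @export
print.qi_hierarchy <- function(x, ...) {
  cat("<qi_hierarchy> ", x$qi, ": ", x$n_levels, " level(s)\n", sep = "")
  invisible(x)
}

#' Generalize values to a hierarchy level
#'
#' @param h a [qi_hierarchy()].
#' @param values vector of original (level-0) values.
#' @param level integer level; 0 returns `values` unchanged.
#' @return Labels at the requested level.
#' @export
generalize_value <- function(h, values, level) {
  stopifnot(inherits(h, "qi_hierarchy"))
  if (level < 0 || level >= h$n_levels) {
    stop("level ", level, " outside hierarchy '", h$qi, "' (0..",
         h$n_levels - 1L, ")")
  }
  if (level == 0) return(values)
  h$mappers[[level]](values)
}

# ---- interval ladders -------------------------------------------------------

.age_mapper <- function(width) {
  force(width)
  function(v) {
    v <- as.numeric(v)
    if (anyNA(v)) stop("age hierarchy: non-numeric or missing value")
    lo <- width * floor(v / width)
    ifelse(v >= 80, "80+", sprintf("%d-%d", lo, lo + width - 1))
  }
}

.dih_mapper <- function(level) {
  force(level)
  function(v) {
    v <- as.numeric(v)
    if (anyNA(v)) stop("days-in-hospital hierarchy: missing value")
    if (level == 1) {
      ifelse(v > 14, ">2 weeks", as.character(v))
    } else {
      ifelse(v > 14, ">2 weeks",
             ifelse(v > 7, "1-2 weeks", as.character(v)))
    }
  }
}

.los_week_bin <- function(v) {
  ifelse(v <= 14, "(1-2] weeks",
         ifelse(v <= 28, "(2-4] weeks",
                ifelse(v <= 56, "(4-8] weeks",
                       ifelse(v <= 84, "(8-12] weeks",
                              ifelse(v <= 182, "(12-26] weeks",
                                     "26+ weeks")))))
}

.los_mapper <- function(level) {
  force(level)
  function(v) {
    v <- as.numeric(v)
    if (anyNA(v)) stop("length-of-stay hierarchy: missing value")
    if (level == 1) {
      w <- ceiling(v / 7)
      ifelse(v <= 6, as.character(v),
             ifelse(w > 26, "26+ weeks", sprintf("week %d", w)))
    } else if (level == 2) {
      ifelse(v <= 6, as.character(v), .los_week_bin(v))
    } else if (level == 3) {
      ifelse(v <= 6, "<1 week", .los_week_bin(v))
    } else {
      ifelse(v <= 28, "<4 weeks", .los_week_bin(v))
    }
  }
}

# dsfc stored 0-based (first claim of the patient-year = day 0); displayed
# 1-based, so blocks are days [1-7], [8-14], ... and "months" = 28-day blocks.
.dsfc_mapper <- function(block_days, prefix) {
  force(block_days); force(prefix)
  function(v) {
    v <- as.numeric(v)
    if (anyNA(v)) stop("days-since-first-claim hierarchy: missing value")
    sprintf("%s%02d", prefix, ceiling((v + 1) / block_days))
  }
}

#' Block index of a generalized DSFC label
#'
#' Parses the trailing integer of labels produced by the DSFC ladder
#' (`wk03`, `2wk02`, `4wk01`); numeric day values are returned as-is. Gives
#' every DSFC representation a total order, which the ordered-pair attack
#' variant needs.
#'
#' @param x DSFC values (numeric days or generalized labels).
#' @return Numeric ranks comparable within one generalization level.
#' @export
dsfc_rank <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  lab <- is.na(num)
  num[lab] <- as.numeric(sub("^.*?([0-9]+)$", "\\1", x[lab]))
  num
}

# ---- grouping-table ladders -------------------------------------------------

#' Build a categorical mapper from a grouping table
#'
#' `table` has columns `code` and `group`. Lookup is exact first, then
#' longest-prefix (ICD-9 family semantics: pattern `042` matches `042.1`),
#' then the optional `.default` row; otherwise a domain error names the
#' offending value.
#'
#' @param table data.frame with columns `code`, `group`.
#' @param qi_name used in error messages.
#' @return A vectorized mapper function.
#' @keywords internal
grouping_mapper <- function(table, qi_name) {
  codes <- as.character(table$code)
  groups <- as.character(table$group)
  default <- if (".default" %in% codes) groups[match(".default", codes)]
  real <- codes != ".default"
  codes <- codes[real]
  groups <- groups[real]
  # longest prefixes first so the most specific pattern wins
  ord <- order(-nchar(codes))
  codes <- codes[ord]
  groups <- groups[ord]
  function(v) {
    v <- as.character(v)
    out <- groups[match(v, codes)]
    todo <- which(is.na(out))
    for (i in todo) {
      hit <- which(startsWith(v[i], codes))
      if (length(hit) > 0) {
        out[i] <- groups[hit[1]]
      } else if (!is.null(default)) {
        out[i] <- default
      } else {
        stop("value '", v[i], "' not covered by the ", qi_name,
             " grouping table")
      }
    }
    out
  }
}

.read_grouping <- function(path) {
  tab <- read.csv(path, colClasses = "character")
  names(tab) <- .norm_header(names(tab))
  if (!all(c("code", "group") %in% names(tab))) {
    if (all(c("originalcode", "grouplabel") %in% names(tab))) {
      tab <- data.frame(code = tab$originalcode, group = tab$grouplabel,
                        stringsAsFactors = FALSE)
    } else {
      stop("grouping table needs columns code, group: ", path)
    }
  }
  tab
}

.default_grouping_path <- function(which) {
  system.file("extdata", paste0(which, "_groups.csv"), package = "longdeid",
              mustWork = TRUE)
}

#' Build the default generalization hierarchies
#'
#' The ladders used for longitudinal claims releases:
#' * `age`: years -> 5-year interval (80+) -> 10-year (80+) -> 20-year (80+);
#' * `dih` (both `DaysInHospital` years, generalized in lock-step):
#'   days -> days-to-2-weeks / >2 weeks -> days-to-1-week / 1-2 weeks /
#'   >2 weeks;
#' * `los`: days -> days-up-to-6 + week index -> days-up-to-6 + week bins ->
#'   <1 week + week bins -> <4 weeks + coarser bins;
#' * `dsfc`: days -> weeks -> 2-week blocks -> 28-day blocks;
#' * `sex`: never generalized;
#' * `specialty`, `place_of_service`, `cpt_code`, `diagnosis`: exactly one
#'   predetermined grouping level each, driven by two-column grouping tables
#'   (`code`, `group`). The tables shipped with the package are small
#'   synthetic demonstration tables; real releases supply their own via
#'   `grouping_paths`.
#'
#' @param grouping_paths optional named list/vector with paths for elements
#'   `specialty`, `place_of_service`, `cpt_code`, `diagnosis`; unnamed
#'   entries fall back to the packaged demonstration tables.
#' @return Named list of [qi_hierarchy()] objects.
#' @export
build_default_hierarchies <- function(grouping_paths = list()) {
  path_for <- function(key) {
    if (!is.null(grouping_paths[[key]])) grouping_paths[[key]]
    else .default_grouping_path(key)
  }
  grp <- function(key) {
    grouping_mapper(.read_grouping(path_for(key)), key)
  }
  list(
    age = qi_hierarchy("age", list(.age_mapper(5), .age_mapper(10),
                                   .age_mapper(20))),
    sex = qi_hierarchy("sex"),
    dih = qi_hierarchy("dih", list(.dih_mapper(1), .dih_mapper(2)),
                       columns = c("dih_y2", "dih_y3")),
    los = qi_hierarchy("los", list(.los_mapper(1), .los_mapper(2),
                                   .los_mapper(3), .los_mapper(4))),
    dsfc = qi_hierarchy("dsfc", list(.dsfc_mapper(7, "wk"),
                                     .dsfc_mapper(14, "2wk"),
                                     .dsfc_mapper(28, "4wk"))),
    specialty = qi_hierarchy("specialty", list(grp("specialty"))),
    place_of_service = qi_hierarchy("place_of_service",
                                    list(grp("place_of_service"))),
    cpt_code = qi_hierarchy("cpt_code", list(grp("cpt_code"))),
    diagnosis = qi_hierarchy("diagnosis", list(grp("diagnosis")))
  )
}

# ---- lattice ----------------------------------------------------------------

#' Build the lattice of generalization states
#'
#' The cross product of the hierarchy levels: one node per tuple of per-QI
#' levels, partially ordered componentwise. The bottom node (all zeros) is
#' the original data; moving up coarsens.
#'
#' @param hierarchies named list of [qi_hierarchy()] objects.
#' @return An object of class `gen_lattice` with `heights` (named integer
#'   vector) and `nodes` (integer matrix, one row per node, columns named by
#'   QI).
#' @export
build_lattice <- function(hierarchies) {
  if (length(hierarchies) == 0) stop("need at least one hierarchy")
  heights <- vapply(hierarchies, function(h) h$n_levels, integer(1))
  grid <- do.call(
    expand.grid,
    c(lapply(heights, function(k) 0:(k - 1L)),
      list(KEEP.OUT.ATTRS = FALSE))
  )
  nodes <- as.matrix(grid)
  storage.mode(nodes) <- "integer"
  # order by total height then lexicographically: a stable traversal order
  ord <- do.call(order, c(list(rowSums(nodes)), lapply(seq_len(ncol(nodes)),
                                                       function(j) nodes[, j])))
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- apply(nodes, 1, paste, collapse = ",")
  structure(list(heights = heights, nodes = nodes), class = "gen_lattice")
}

#' @export
print.gen_lattice <- function(x, ...) {
  cat("<gen_lattice> ", nrow(x$nodes), " nodes over ",
      length(x$heights), " QI(s): ",
      paste(names(x$heights), x$heights, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.node_key <- function(node) paste(node, collapse = ",")

#' Apply a lattice node to a dataset
#'
#' Replaces every quasi-identifier column by its labels at the node's level
#' for that QI; all other columns are untouched. The bottom node is the
#' identity.
#'
#' @param ds a `claims_dataset` holding original (level-0) values.
#' @param node named integer vector of levels (names matching
#'   `hierarchies`), or a row of `lattice$nodes`.
#' @param hierarchies named list of [qi_hierarchy()] objects.
#' @return The generalized `claims_dataset`.
#' @export
apply_node <- function(ds, node, hierarchies) {
  validate_dataset(ds)
  if (is.null(names(node))) names(node) <- names(hierarchies)
  for (qi in names(node)) {
    lev <- node[[qi]]
    if (lev == 0) next
    h <- hierarchies[[qi]]
    if (is.null(h)) stop("no hierarchy for QI '", qi, "'")
    for (col in h$columns) {
      tab <- if (col %in% names(ds$patients)) "patients" else "claims"
      ds[[tab]][[col]] <- generalize_value(h, ds[[tab]][[col]], lev)
    }
  }
  ds
}

# ---- comorbidity ------------------------------------------------------------

#' Categorized Charlson comorbidity score per patient-year
#'
#' Sums configurable per-condition weights over the distinct diagnosis codes
#' (prefix-matched) in each patient-year and bins the total as `0`, `1-2`,
#' `3-4`, or `5+`. The packaged weight table is a synthetic demonstration
#' table.
#'
#' @param ds a `claims_dataset`.
#' @param weights_path CSV with columns `code` (ICD-9 prefix) and `weight`;
#'   defaults to the packaged demonstration table.
#' @return data.frame with `member_id`, `year`, `score`, `category`.
#' @export
charlson_comorbidity <- function(ds, weights_path = NULL) {
  validate_dataset(ds)
  if (is.null(weights_path)) {
    weights_path <- system.file("extdata", "charlson_weights.csv",
                                package = "longdeid", mustWork = TRUE)
  }
  wt <- read.csv(weights_path, colClasses = c("character", "numeric"))
  names(wt) <- .norm_header(names(wt))
  key <- paste(ds$claims$member_id, ds$claims$year, sep = "\x1f")
  score_one <- function(dx) {
    dx <- unique(as.character(dx))
    s <- 0
    for (i in seq_len(nrow(wt))) {
      if (any(startsWith(dx, wt$code[i]))) s <- s + wt$weight[i]
    }
    s
  }
  scores <- tapply(ds$claims$diagnosis, key, score_one)
  parts <- strsplit(names(scores), "\x1f", fixed = TRUE)
  out <- data.frame(
    member_id = vapply(parts, `[`, "", 1),
    year = vapply(parts, `[`, "", 2),
    score = as.numeric(scores),
    stringsAsFactors = FALSE
  )
  out$category <- cut(out$score, c(-Inf, 0, 2, 4, Inf),
                      labels = c("0", "1-2", "3-4", "5+"))
  out$category <- as.character(out$category)
  rownames(out) <- NULL
  out
}
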