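# Probability-based small/large-effect mutation classifier.
#
# Four "flags" are attached to every mutation: the wild-type residue type,
# the mutant residue type, and the interface-location class of the site in
# the WT and MT structures.  From a mutation dataset each flag value gets an
# empirical probability of causing a large effect (|ddG| >= 1 kcal/mol); the
# consensus probability of a mutation is the mean of its four flag
# probabilities, and P >= 0.5 routes it to the large-effect weight set.

FLAG_DIMS <- c("wt_residue", "mt_residue", "wt_location", "mt_location")

new_probability_tables <- function(wt_residue, mt_residue, wt_location,
                                   mt_location, tol = 1e-9) {
  tabs <- list(wt_residue = wt_residue, mt_residue = mt_residue,
               wt_location = wt_location, mt_location = mt_location)
  for (nm in FLAG_DIMS) {
    t <- tabs[[nm]]
    stopifnot(all(c("key", "n", "p_small", "p_large") %in% names(t)))
    if (any(t$p_small < 0 | t$p_small > 1 | t$p_large < 0 | t$p_large > 1))
      stop("probabilities must lie in [0, 1] (table ", nm, ")", call. = FALSE)
    if (any(abs(t$p_small + t$p_large - 1) > tol))
      stop("p_small + p_large must equal 1 (table ", nm, ")", call. = FALSE)
    if (any(t$n < 0)) stop("case counts must be >= 0", call. = FALSE)
  }
  structure(tabs, class = "probability_tables")
}

#' Bundled effect-probability tables
#'
#' The shipped per-residue and per-location probabilities of a mutation
#' causing a large change in binding free energy, derived from the altered
#' (reweighted) curated mutation dataset.  Printed to two decimals, so rows
#' satisfy `p_small + p_large = 1` only within rounding.
#'
#' @return a `probability_tables` object.
#' @export
bundled_probability_tables <- function() {
  res <- read.delim(system.file("extdata", "residue_effect_probabilities.tsv",
                                package = "saambe"), stringsAsFactors = FALSE)
  loc <- read.delim(system.file("extdata", "location_effect_probabilities.tsv",
                                package = "saambe"), stringsAsFactors = FALSE)
  mk <- function(df, keycol, pre) {
    data.frame(key = df[[keycol]], n = df[[paste0(pre, "_n")]],
               p_small = df[[paste0(pre, "_p_small")]],
               p_large = df[[paste0(pre, "_p_large")]],
               stringsAsFactors = FALSE)
  }
  new_probability_tables(mk(res, "aa", "wt"), mk(res, "aa", "mt"),
                         mk(loc, "location", "wt"), mk(loc, "location", "mt"),
                         tol = 0.011)
}

p_large_of <- function(tables, dim, key) {
  t <- tables[[dim]]
  i <- match(key, t$key)
  if (is.na(i)) NA_real_ else t$p_large[i]
}

#' Mutation annotation for the classifier
#'
#' @param wt_aa,mt_aa one-letter residue types.
#' @param loc_wt,loc_mt location classes (COR/SUP/RIM/INT/SUR) of the site
#'   in the WT and MT structure.
#' @return a `mutation_annotation`.
#' @export
mutation_annotation <- function(wt_aa, mt_aa, loc_wt, loc_mt) {
  stopifnot(wt_aa %in% AA1, mt_aa %in% AA1,
            loc_wt %in% c("COR", "SUP", "RIM", "INT", "SUR"),
            loc_mt %in% c("COR", "SUP", "RIM", "INT", "SUR"))
  structure(list(wt_aa = wt_aa, mt_aa = mt_aa, loc_wt = loc_wt,
                 loc_mt = loc_mt), class = "mutation_annotation")
}

check_records <- function(records) {
  need <- c("wt_aa", "mt_aa", "loc_wt", "loc_mt", "ddg_exp")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("empty dataset", call. = FALSE)
  invisible(records)
}

build_dim <- function(keys, abs_ddg) {
  large <- abs_ddg >= 1
  ks <- sort(unique(keys))
  data.frame(key = ks,
             n = as.integer(tapply(large, keys, length)[ks]),
             p_small = as.numeric(tapply(!large, keys, mean)[ks]),
             p_large = as.numeric(tapply(large, keys, mean)[ks]),
             stringsAsFactors = FALSE)
}

#' Build effect-probability tables from an annotated mutation dataset
#'
#' For each value of each of the four flags, the probability of a large
#' effect is the fraction of records with `|ddG_exp| >= 1` kcal/mol
#' (the boundary value counts as large).  Flag values with no records are
#' simply absent from the tables (never defaulted to 0.5).
#'
#' @param records data.frame with columns `wt_aa`, `mt_aa`, `loc_wt`,
#'   `loc_mt`, `ddg_exp`.
#' @return a `probability_tables` object.
#' @export
build_probability_tables <- function(records) {
  check_records(records)
  abs_ddg <- abs(records$ddg_exp)
  new_probability_tables(build_dim(records$wt_aa, abs_ddg),
                         build_dim(records$mt_aa, abs_ddg),
                         build_dim(records$loc_wt, abs_ddg),
                         build_dim(records$loc_mt, abs_ddg))
}

#' Alter an experimental |ddG| with respect to one flag
#'
#' Reweights the magnitude of a record by how strongly the other three
#' flags support its observed class:
#' `(2/3) * sum_{j != i} p_j * |ddG|` when `|ddG| < 1`, and
#' `(2/3) * sum_{j != i} (1 - p_j) * |ddG|` otherwise.  When all
#' probabilities are 0.5 the value is unchanged.
#'
#' @param abs_ddg absolute experimental ddG (kcal/mol, >= 0).
#' @param i flag index in 1..4 whose table is being rebuilt.
#' @param p numeric length-4 vector of large-effect probabilities for the
#'   record's four flags.
#' @return altered |ddG|.
#' @export
#' @examples
#' alter_ddg(10, 1, c(0.2, 0.86, 0.68, 0.56))  # 6
alter_ddg <- function(abs_ddg, i, p) {
  stopifnot(length(p) == 4L, all(p >= 0 & p <= 1), abs_ddg >= 0,
            i %in% 1:4)
  others <- p[-i]
  if (abs_ddg < 1) {
    (2 / 3) * sum(others) * abs_ddg
  } else {
    (2 / 3) * sum(1 - others) * abs_ddg
  }
}

record_probs <- function(records, tables) {
  cbind(vapply(records$wt_aa, p_large_of, 0, tables = tables, dim = "wt_residue"),
        vapply(records$mt_aa, p_large_of, 0, tables = tables, dim = "mt_residue"),
        vapply(records$loc_wt, p_large_of, 0, tables = tables, dim = "wt_location"),
        vapply(records$loc_mt, p_large_of, 0, tables = tables, dim = "mt_location"))
}

#' Recompute probability tables from the altered dataset
#'
#' Every record's |ddG| is altered with [alter_ddg()] with respect to each
#' flag dimension in turn, and that dimension's table is rebuilt from its
#' own altered values (a single pass; no fixed-point iteration).  Records
#' whose flags have no row in the initial tables are excluded with a
#' warning.
#'
#' @param records annotated dataset (see [build_probability_tables()]).
#' @param initial initial `probability_tables`.
#' @return altered `probability_tables`.
#' @export
reweight_tables <- function(records, initial) {
  check_records(records)
  pr <- record_probs(records, initial)
  ok <- !apply(pr, 1, anyNA)
  if (!all(ok)) {
    warning(sum(!ok), " record(s) with undefined flag rows excluded")
    records <- records[ok, , drop = FALSE]
    pr <- pr[ok, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records remain", call. = FALSE)
  }
  abs_ddg <- abs(records$ddg_exp)
  keys <- list(records$wt_aa, records$mt_aa, records$loc_wt, records$loc_mt)
  dims <- vector("list", 4L)
  for (i in 1:4) {
    altered <- vapply(seq_len(nrow(records)),
                      function(k) alter_ddg(abs_ddg[k], i, pr[k, ]), 0)
    dims[[i]] <- build_dim(keys[[i]], altered)
  }
  new_probability_tables(dims[[1]], dims[[2]], dims[[3]], dims[[4]])
}

#' Consensus probability and small/large-effect assignment
#'
#' The consensus probability of a mutation causing a large change in
#' binding free energy is the mean of its four flag probabilities; the
#' mutation is classed `"large"` when `P >= 0.5` (boundary inclusive),
#' otherwise `"small"`.
#'
#' @param annotation a [mutation_annotation()].
#' @param tables a `probability_tables` object (default: bundled).
#' @return list with `p` (consensus probability), `subset` (`"small"` or
#'   `"large"`) and `flags` (the four probabilities used).
#' @export
consensus_probability <- function(annotation, tables = bundled_probability_tables()) {
  keys <- c(annotation$wt_aa, annotation$mt_aa,
            annotation$loc_wt, annotation$loc_mt)
  p4 <- c(p_large_of(tables, "wt_residue", keys[1]),
          p_large_of(tables, "mt_residue", keys[2]),
          p_large_of(tables, "wt_location", keys[3]),
          p_large_of(tables, "mt_location", keys[4]))
  if (anyNA(p4)) {
    bad <- FLAG_DIMS[is.na(p4)]
    stop("no probability row for flag(s): ",
         paste(paste0(bad, "=", keys[is.na(p4)]), collapse = ", "),
         call. = FALSE)
  }
  p <- mean(p4)
  list(p = p, subset = if (p >= 0.5) "large" else "small",
       flags = setNames(p4, FLAG_DIMS))
}
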