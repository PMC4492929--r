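# SKEMPI-style mutation dataset loading and curation.

#' Read a mutation dataset
#'
#' CSV (or TSV) with header columns `pdb`, `chain_a`, `chain_b`,
#' `mutation` (SKEMPI-style, e.g. `"QA123P"`), `ddg` (kcal/mol); an
#' optional `disordered` logical column flags mutations in structurally
#' disordered segments.
#'
#' @param path file path.
#' @param sep field separator (guessed from the extension by default).
#' @return data.frame of `mutation_record`s: `pdb`, `chain_a`, `chain_b`,
#'   `chain`, `site`, `insert`, `wt_aa`, `mt_aa`, `ddg_exp`, `disordered`,
#'   `source`.
#' @export
read_mutation_data <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("pdb", "chain_a", "chain_b", "mutation", "ddg")
  if (!all(need %in% names(df)))
    stop("mutation file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  muts <- lapply(df$mutation, parse_mutation)
  out <- data.frame(pdb = df$pdb,
                    chain_a = df$chain_a, chain_b = df$chain_b,
                    chain = vapply(muts, `[[`, "", "chain"),
                    site = vapply(muts, `[[`, 0L, "site"),
                    insert = vapply(muts, `[[`, "", "insert"),
                    wt_aa = vapply(muts, `[[`, "", "wt_aa"),
                    mt_aa = vapply(muts, `[[`, "", "mt_aa"),
                    ddg_exp = as.numeric(df$ddg),
                    stringsAsFactors = FALSE)
  out$disordered <- if ("disordered" %in% names(df)) as.logical(df$disordered) else FALSE
  out$source <- if ("source" %in% names(df)) df$source else basename(path)
  if (any(!is.finite(out$ddg_exp)))
    stop("non-finite ddg value(s) in rows: ",
         paste(which(!is.finite(out$ddg_exp)), collapse = ", "), call. = FALSE)
  out
}

#' Curate a mutation dataset
#'
#' Applies the curation rules for repeated measurements of the same
#' mutation in the same complex: exact duplicates collapse to one record;
#' groups whose experimental spread (max - min) is below 1.5 kcal/mol are
#' fused to their mean; groups with spread of 1.5 kcal/mol or more are
#' deleted (the boundary is assigned to deletion, conservatively).
#' Records flagged as lying in disordered segments are removed.  Every
#' action is recorded in an audit log, and the operation is idempotent.
#'
#' @param records data.frame as returned by [read_mutation_data()].
#' @param spread_threshold fusion/deletion threshold (kcal/mol, default 1.5).
#' @return list with `records` (curated data.frame) and `audit`
#'   (data.frame of actions: `group`, `action`, `n`, `detail`).
#' @export
curate_records <- function(records, spread_threshold = 1.5) {
  audit <- data.frame(group = character(), action = character(),
                      n = integer(), detail = character(),
                      stringsAsFactors = FALSE)
  log_it <- function(group, action, n, detail = "") {
    audit[nrow(audit) + 1L, ] <<- list(group, action, as.integer(n), detail)
  }
  if (!is.null(records$disordered) && any(records$disordered)) {
    drop <- which(records$disordered)
    for (i in drop)
      log_it(group_key(records[i, ]), "removed_disordered", 1L, "")
    records <- records[-drop, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    return(list(records = records, audit = audit))
  key <- apply(records[, c("pdb", "chain", "site", "insert", "wt_aa", "mt_aa")],
               1, paste, collapse = ":")
  keep <- list()
  for (k in unique(key)) {
    g <- records[key == k, , drop = FALSE]
    n0 <- nrow(g)
    g <- g[!duplicated(g$ddg_exp), , drop = FALSE]
    if (nrow(g) < n0)
      log_it(k, "dedup_exact", n0 - nrow(g), "")
    if (nrow(g) == 1L) {
      keep[[k]] <- g
      next
    }
    spread <- max(g$ddg_exp) - min(g$ddg_exp)
    if (spread < spread_threshold) {
      fused <- g[1, , drop = FALSE]
      fused$ddg_exp <- mean(g$ddg_exp)
      keep[[k]] <- fused
      log_it(k, "fused", nrow(g), sprintf("spread %.3f -> mean %.3f",
                                          spread, fused$ddg_exp))
    } else {
      log_it(k, "deleted", nrow(g), sprintf("spread %.3f >= %.2f",
                                            spread, spread_threshold))
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  list(records = out, audit = audit)
}

group_key <- function(row) {
  paste(row$pdb, row$chain, row$site, row$insert, row$wt_aa, row$mt_aa,
        sep = ":")
}
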