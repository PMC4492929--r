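# The linear scoring formula: evaluation with a weight set, weight fitting
# by multiple linear regression, cross-validation, +/-2SD outlier trimming,
# and the dielectric-constant scan harness.

#' Construct a weight set
#'
#' Intercept plus one weight per feature; features absent from a fitted or
#' published set are explicit zeros.
#'
#' @param w0 intercept (kcal/mol).
#' @param weights named numeric vector over (a subset of) `TERM_NAMES`.
#' @param subset `"small"`, `"large"` or `"all"`.
#' @param pvalues,slope,y_intercept optional fit metadata.  The slope and
#'   y-intercept of the experimental-vs-predicted line are stored verbatim
#'   but never applied to predictions.
#' @return a `weight_set`.
#' @export
weight_set <- function(w0, weights, subset = c("all", "small", "large"),
                       pvalues = NULL, slope = NULL, y_intercept = NULL) {
  subset <- match.arg(subset)
  stopifnot(is.numeric(w0), length(w0) == 1L, is.numeric(weights))
  unknown <- setdiff(names(weights), TERM_NAMES)
  if (length(unknown) > 0L)
    stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  full <- setNames(rep(0, length(TERM_NAMES)), TERM_NAMES)
  full[names(weights)] <- weights
  structure(list(subset = subset, w0 = unname(w0), weights = full,
                 pvalues = pvalues, slope = slope, y_intercept = y_intercept),
            class = "weight_set")
}

#' Bundled published weight sets
#'
#' Loads one of the three shipped weight sets fitted on the full training
#' database and on its small-/large-effect halves.
#'
#' @param which `"tdb"`, `"tdb_small"` or `"tdb_large"`, or a path to a
#'   weight-set JSON file with fields `subset`, `w0`, `weights`.
#' @return a `weight_set`.
#' @export
saambe_weights <- function(which = c("tdb", "tdb_small", "tdb_large")) {
  if (length(which) == 1L && file.exists(which) &&
      !which %in% c("tdb", "tdb_small", "tdb_large")) {
    path <- which
  } else {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("weights_", which, ".json"),
                        package = "saambe")
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_set(j$w0, unlist(j$weights), subset = j$subset,
             pvalues = j$pvalues, slope = j$slope, y_intercept = j$y_intercept)
}

#' Predict ddG from a feature vector
#'
#' `ddG = w0 + sum_k w_k x_k` (kcal/mol).  Every term carrying a nonzero
#' weight must be present and non-missing.
#'
#' @param terms named numeric feature vector (see `TERM_NAMES`).
#' @param weights a `weight_set`.
#' @return predicted ddG (kcal/mol).
#' @export
predict_ddg <- function(terms, weights) {
  stopifnot(inherits(weights, "weight_set"))
  active <- names(weights$weights)[weights$weights != 0]
  missing <- active[!(active %in% names(terms)) | is.na(terms[active])]
  if (length(missing) > 0L)
    stop("required term(s) unavailable: ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(weights$w0 + sum(weights$weights[active] * terms[active]))
}

#' Classifier-routed prediction
#'
#' Computes the consensus large-effect probability of the mutation and
#' evaluates the small- or large-effect weight set accordingly (P >= 0.5
#' routes to the large set).
#'
#' @param terms named feature vector.
#' @param annotation a [mutation_annotation()].
#' @param tables effect-probability tables (default: bundled).
#' @param weights_small,weights_large the two weight sets (default: bundled).
#' @return list with `ddg`, `subset`, `p`.
#' @export
predict_auto <- function(terms, annotation,
                         tables = bundled_probability_tables(),
                         weights_small = saambe_weights("tdb_small"),
                         weights_large = saambe_weights("tdb_large")) {
  cons <- consensus_probability(annotation, tables)
  w <- if (cons$subset == "large") weights_large else weights_small
  list(ddg = predict_ddg(terms, w), subset = cons$subset, p = cons$p)
}

#' Fit scoring-function weights by multiple linear regression
#'
#' Ordinary least squares with intercept (QR decomposition via
#' [stats::lm()]); reports the Pearson correlation between fitted and
#' experimental values and per-coefficient two-sided t-test p-values.
#'
#' @param features data.frame of feature columns.
#' @param ddg_exp experimental ddG values (kcal/mol).
#' @param active_terms which feature columns enter the fit (default: all).
#' @return a `fit_result`: list with `weights` (a `weight_set`),
#'   `pearson_r`, `pvalues`, `n_cases`, `residual_sd`, `fitted`.
#' @export
fit_weights <- function(features, ddg_exp, active_terms = colnames(features)) {
  stopifnot(is.data.frame(features), nrow(features) == length(ddg_exp))
  missing <- setdiff(active_terms, colnames(features))
  if (length(missing) > 0L)
    stop("feature column(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- features[, active_terms, drop = FALSE]
  p <- length(active_terms)
  if (nrow(x) < p + 2L)
    stop(sprintf("insufficient data: n = %d cases for %d terms (need >= %d)",
                 nrow(x), p, p + 2L), call. = FALSE)
  dat <- cbind(x, .ddg = ddg_exp)
  fit <- lm(.ddg ~ ., data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  pv <- sm$coefficients[, "Pr(>|t|)"]
  names(pv)[1] <- "w0"
  ws <- weight_set(cf[1], setNames(cf[-1], active_terms),
                   pvalues = as.list(pv))
  structure(list(weights = ws,
                 pearson_r = cor(fitted(fit), ddg_exp),
                 pvalues = pv,
                 std_errors = setNames(sm$coefficients[, "Std. Error"],
                                       c("w0", active_terms)),
                 n_cases = nrow(x),
                 residual_sd = sm$sigma,
                 fitted = unname(fitted(fit))),
            class = "fit_result")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' K-fold cross-validated correlation
#'
#' Randomly partitions the cases into `k` folds of sizes differing by at
#' most one, fits on k-1 folds, evaluates the Pearson correlation on the
#' held-out fold, and averages.  Reproducible given `seed`.
#'
#' @inheritParams fit_weights
#' @param k number of folds (default 5).
#' @param seed RNG seed for the partition.
#' @return list with `mean_r`, `fold_r`, `fold_sizes`.
#' @export
cross_validate <- function(features, ddg_exp, k = 5,
                           active_terms = colnames(features),
                           seed = 20150706) {
  n <- nrow(features)
  p <- length(active_terms)
  if (n < k * (p + 1L))
    stop("insufficient data for cross-validation", call. = FALSE)
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fold_r <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_weights(features[tr, , drop = FALSE], ddg_exp[tr], active_terms)
    pred <- vapply(which(!tr), function(i)
      predict_ddg(unlist(features[i, active_terms, drop = FALSE]), fit$weights), 0)
    cor(pred, ddg_exp[!tr])
  }, 0)
  list(mean_r = mean(fold_r), fold_r = fold_r,
       fold_sizes = as.integer(table(fold)))
}

#' Trim points beyond two residual standard deviations
#'
#' Fits the experimental-vs-predicted line, drops points whose residual
#' magnitude exceeds twice the residual standard deviation (single pass),
#' and recomputes the correlation on the survivors.
#'
#' @param predicted,experimental paired ddG values (>= 10 points).
#' @return list with `keep` (logical mask), `r_trimmed`, `r_all`,
#'   `n_dropped`.
#' @export
trim_2sd <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  if (length(predicted) < 10L)
    stop("need at least 10 points", call. = FALSE)
  if (sd(predicted) == 0)
    stop("degenerate input: all predictions identical", call. = FALSE)
  fit <- lm(experimental ~ predicted)
  res <- stats::residuals(fit)
  scale <- max(sd(experimental), 1e-12)
  keep <- if (sd(res) < 1e-10 * scale) {
    rep(TRUE, length(res))  # numerically perfect line: nothing to trim
  } else {
    abs(res) <= 2 * sd(res)
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 points survive trimming", call. = FALSE)
  list(keep = keep,
       r_trimmed = cor(predicted[keep], experimental[keep]),
       r_all = cor(predicted, experimental),
       n_dropped = sum(!keep))
}

#' Dielectric-constant scan
#'
#' Re-fits the scoring function restricted to the dielectric-dependent
#' terms over a grid of per-class dielectric constants (charged, polar,
#' other) and reports the correlation surface and its argmax.  The default
#' ranges are 5..15 for charged and 3..13 for polar and other residues,
#' step 2 (a 6 x 6 x 6 grid).
#'
#' @param provider function `(eps_charged, eps_polar, eps_other)` returning
#'   a data.frame with the columns named in `terms` for every case.
#' @param ddg_exp experimental ddG values.
#' @param eps_charged,eps_polar,eps_other grid values.
#' @param terms dielectric-dependent terms to refit (default
#'   `dd_ee`, `dd_ve`, `dd_sp`).
#' @return list with `grid` (data.frame `eps_charged`, `eps_polar`,
#'   `eps_other`, `r`), `best` (the argmax grid row) and `refined` (the
#'   continuous argmax read off the interpolated correlation surface).
#' @export
scan_dielectrics <- function(provider, ddg_exp,
                             eps_charged = seq(5, 15, by = 2),
                             eps_polar = seq(3, 13, by = 2),
                             eps_other = seq(3, 13, by = 2),
                             terms = c("dd_ee", "dd_ve", "dd_sp")) {
  if (!is.function(provider))
    stop("a dielectric-dependent energy provider function is required",
         call. = FALSE)
  grid <- expand.grid(eps_charged = eps_charged, eps_polar = eps_polar,
                      eps_other = eps_other, KEEP.OUT.ATTRS = FALSE)
  grid$r <- vapply(seq_len(nrow(grid)), function(i) {
    feats <- provider(grid$eps_charged[i], grid$eps_polar[i], grid$eps_other[i])
    fit_weights(feats, ddg_exp, terms)$pearson_r
  }, 0)
  best <- grid[which.max(grid$r), , drop = FALSE]
  list(grid = grid, best = best, refined = refine_scan_optimum(grid, best))
}

# Read the continuous optimum off the sampled correlation surface, one
# dielectric class at a time: a parabola is fitted through the best node
# and its two neighbors along that class, in the 1/eps coordinate (the
# energies vary as 1/eps, so the surface is far more symmetric there than
# in eps itself; interpolating in eps biases the vertex high).  At a range
# boundary, or when the slice has no interior curvature, the node value is
# kept.
refine_scan_optimum <- function(grid, best) {
  dims <- c("eps_charged", "eps_polar", "eps_other")
  out <- unlist(best[1, dims])
  for (dm in dims) {
    others <- setdiff(dims, dm)
    sel <- grid[grid[[others[1]]] == best[[others[1]]] &
                  grid[[others[2]]] == best[[others[2]]], ]
    sel <- sel[order(sel[[dm]]), ]
    i <- match(best[[dm]], sel[[dm]])
    if (i > 1L && i < nrow(sel)) {
      x <- 1 / sel[[dm]][(i - 1):(i + 1)]
      y <- sel$r[(i - 1):(i + 1)]
      cf <- coef(lm(y ~ x + I(x^2)))
      if (is.finite(cf[3]) && cf[3] < 0) {
        vx <- -cf[2] / (2 * cf[3])
        if (vx > min(x) && vx < max(x)) out[dm] <- 1 / vx
      }
    }
  }
  out
}
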