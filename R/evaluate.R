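# Confusion-matrix benchmarking: four-outcome flag assignment and the six
# ROC summary metrics.

#' Assign the prediction outcome flag for one case
#'
#' Thresholds: a prediction or measurement is "positive" (a real change)
#' when its magnitude is >= 1.5 kcal/mol and "negative" when < 0.5.
#' `tp`: both >= 1.5 with matching signs; `fp`: |calc| >= 1.5 but
#' |exp| < 0.5; `tn`: both < 0.5; `fn`: |calc| < 0.5 but |exp| >= 1.5.
#' The middle band (0.5 <= |ddG| < 1.5 on either axis) and large pairs with
#' opposite signs fall in no cell and are returned as `"unclassified"`.
#' The sign of 0 is treated as positive.
#'
#' @param ddg_calc,ddg_exp predicted and experimental ddG (kcal/mol),
#'   vectorized.
#' @return character vector: `"tp"`, `"tn"`, `"fp"`, `"fn"` or
#'   `"unclassified"`.
#' @export
assign_flag <- function(ddg_calc, ddg_exp) {
  stopifnot(length(ddg_calc) == length(ddg_exp),
            all(is.finite(ddg_calc)), all(is.finite(ddg_exp)))
  out <- rep("unclassified", length(ddg_calc))
  ac <- abs(ddg_calc); ae <- abs(ddg_exp)
  same_sign <- (ddg_calc >= 0) == (ddg_exp >= 0)
  out[ac >= 1.5 & ae >= 1.5 & same_sign] <- "tp"
  out[ac >= 1.5 & ae < 0.5] <- "fp"
  out[ac < 0.5 & ae < 0.5] <- "tn"
  out[ac < 0.5 & ae >= 1.5] <- "fn"
  out
}

#' Confusion counts from predictions
#'
#' @param ddg_calc,ddg_exp paired ddG values, or `flags` a precomputed flag
#'   vector.
#' @param flags optional character vector from [assign_flag()].
#' @return a `confusion_counts` list: `tp`, `tn`, `fp`, `fn`,
#'   `n_unclassified`.
#' @export
confusion_counts <- function(ddg_calc = NULL, ddg_exp = NULL, flags = NULL) {
  if (is.null(flags)) flags <- assign_flag(ddg_calc, ddg_exp)
  structure(list(tp = sum(flags == "tp"), tn = sum(flags == "tn"),
                 fp = sum(flags == "fp"), fn = sum(flags == "fn"),
                 n_unclassified = sum(flags == "unclassified")),
            class = "confusion_counts")
}

#' ROC summary metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision, negative predictive
#' value, and the Matthews correlation coefficient with the conventional
#' numerator `tp * tn - fp * fn`.  A metric whose denominator is zero is
#' reported as `NA` (undefined).
#'
#' @param counts list with non-negative integers `tp`, `tn`, `fp`, `fn`.
#' @return list of the six metrics.
#' @export
#' @examples
#' roc_metrics(list(tp = 320, tn = 239, fp = 5, fn = 47))
roc_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(accuracy = div(tn + tp, tn + tp + fn + fp),
       sensitivity = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       precision = div(tp, tp + fp),
       npv = div(tn, tn + fn),
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_)
}
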