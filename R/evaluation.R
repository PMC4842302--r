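## Confusion-matrix evaluation of labeled ligand-target pair predictions.
##
## The multi-target prediction task is scored as binary classification on
## a labeled pair list; metrics are always computed from integer counts,
## never from pre-rounded rates, and undefined ratios are reported as NA
## rather than silently zero.

#' Confusion counts container
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  assert_that(all(v >= 0) && all(v == round(v)),
              "confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts of a prediction set against labels
#'
#' @param predicted data.frame of predicted-positive pairs with
#'   `molecule_id` and `target_id`.
#' @param labels data.frame with `molecule_id`, `target_id` and a `label`
#'   column coded `"active"` / `"inactive"`. Every predicted pair must be
#'   labeled; labeled pairs that were not predicted count as tn/fn.
#' @return a `confusion_counts` object.
#' @export
confusion <- function(predicted, labels) {
  key <- function(df) paste(df$molecule_id, df$target_id, sep = "\r")
  lk <- key(labels)
  assert_that(!anyDuplicated(lk), "duplicate pairs in the label table")
  pk <- unique(key(predicted))
  unlabeled <- setdiff(pk, lk)
  if (length(unlabeled))
    stop(sprintf("%d predicted pair(s) are not in the label table",
                 length(unlabeled)))
  pos <- lk[labels$label == "active"]
  neg <- lk[labels$label == "inactive"]
  assert_that(length(pos) + length(neg) == length(lk),
              "labels must be coded 'active' or 'inactive'")
  tp <- sum(pk %in% pos)
  fp <- sum(pk %in% neg)
  confusion_counts(tp = tp, fp = fp,
                   tn = length(neg) - fp, fn = length(pos) - tp)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion tp=%d fp=%d tn=%d fn=%d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' F-beta measure from precision and sensitivity
#'
#' The weighted harmonic mean `(1 + beta^2) * P * S / (beta^2 * P + S)`;
#' beta below 1 weights precision more heavily (0.5 twice, 0.25 four
#' times).
#'
#' @param precision,sensitivity rates in \[0, 1\].
#' @param beta weight(s).
#' @return F-beta value(s); NA where the denominator vanishes.
#' @export
f_beta <- function(precision, sensitivity, beta) {
  denom <- beta^2 * precision + sensitivity
  ifelse(denom > 0, (1 + beta^2) * precision * sensitivity / denom, NA_real_)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and the F-beta
#' measures for the requested betas, all from integer counts. Ratios with
#' a zero denominator are NA ("undefined"), never silently 0.
#'
#' @param counts a `confusion_counts` object.
#' @param betas numeric vector of F-measure weights (default 0.5 and 0.25,
#'   the precision-weighted conventions for incompletely labeled test
#'   sets).
#' @return a `metric_set`: list with `accuracy`, `precision`,
#'   `sensitivity`, `specificity` and named vector `f_beta`.
#' @export
classification_metrics <- function(counts, betas = c(0.5, 0.25)) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero: metrics undefined")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- rate(tp, tp + fp)
  sensitivity <- rate(tp, tp + fn)
  fb <- vapply(betas, function(b) f_beta(precision, sensitivity, b),
               numeric(1))
  names(fb) <- paste0("F", betas)
  structure(list(accuracy = rate(tp + tn, total),
                 precision = precision,
                 sensitivity = sensitivity,
                 specificity = rate(tn, fp + tn),
                 f_beta = fb,
                 counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- c(accuracy = x$accuracy, precision = x$precision,
         sensitivity = x$sensitivity, specificity = x$specificity,
         x$f_beta)
  print(round(v, digits))
  invisible(x)
}

#' One-row metrics table for a set of models or schemes
#'
#' @param metric_list named list of `metric_set` objects.
#' @return data.frame, one row per model, columns ordered accuracy,
#'   precision, sensitivity, specificity, then the F-beta columns.
#' @export
metrics_table <- function(metric_list) {
  rows <- lapply(names(metric_list), function(nm) {
    m <- metric_list[[nm]]
    df <- data.frame(model = nm, accuracy = m$accuracy,
                     precision = m$precision, sensitivity = m$sensitivity,
                     specificity = m$specificity, stringsAsFactors = FALSE)
    for (f in names(m$f_beta)) df[[f]] <- m$f_beta[[f]]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
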