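#' Design-based weighted proportion (Hajek form)
#'
#' `sum(w * y) / sum(w)` — the ratio form, invariant to rescaling all
#' weights by a positive constant, which is the appropriate estimator
#' once weights have been rescaled to mean 1 and the population scale
#' discarded.
#'
#' @param values binary (0/1 or logical) respondent values.
#' @param weights positive weights.
#' @return The weighted proportion.
#' @export
weighted_proportion <- function(values, weights) {
  if (length(values) == 0L) stop("empty input")
  stopifnot(length(values) == length(weights))
  values <- as.numeric(values)
  if (any(weights <= 0)) stop("weights must be positive")
  if (!all(values %in% c(0, 1))) stop("values must be binary")
  sum(weights * values) / sum(weights)
}

#' Audit calibrated weights against the benchmark margins
#'
#' Reports, for every targeted margin level, the weighted respondent
#' count, the benchmark count, and the relative error; the maximum
#' relative error over all levels is attached as the audit statistic.
#'
#' @param ws a `svy_weights` set.
#' @param bench benchmark table ([true_margins()] shape).
#' @param spec a [calibration_spec()] naming the margins to audit.
#' @param column which weight column to audit (default `"calibrated"`).
#' @return data.frame with columns `margin`, `level`, `weighted`,
#'   `benchmark`, `rel_error`; attribute `"max_rel_error"`.
#' @export
margin_audit <- function(ws, bench, spec = calibration_spec(),
                         column = "calibrated") {
  stopifnot(inherits(ws, "svy_weights"), column %in% names(ws))
  w <- ws[[column]]
  if (anyNA(w)) stop("column '", column, "' has not been computed")
  bench <- .apply_stratum_collapse(bench, attr(ws, "stratum_collapse"))
  rows <- list()
  for (m in spec$margins) {
    miss <- !as.character(ws[[m]]) %in% as.character(bench[[m]])
    if (any(miss))
      stop("respondent(s) unmapped to benchmark margin '", m, "': ",
           paste(unique(ws[[m]][miss]), collapse = ", "))
    tgt <- tapply(bench$smokers, bench[[m]], sum)
    got <- tapply(w, factor(as.character(ws[[m]]), levels = names(tgt)),
                  sum)
    got[is.na(got)] <- 0
    rows[[m]] <- data.frame(margin = m, level = names(tgt),
                            weighted = as.numeric(got),
                            benchmark = as.numeric(tgt),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$rel_error <- ifelse(out$benchmark > 0,
                          abs(out$weighted / out$benchmark - 1),
                          abs(out$weighted) > 0)
  rownames(out) <- NULL
  attr(out, "max_rel_error") <- max(out$rel_error)
  out
}

#' Point estimate with bootstrap uncertainty
#'
#' Combines the full-sample Hajek estimate with Rao-Wu replicate
#' estimates into a standard error and confidence interval.
#'
#' @param label free-text name of the estimand.
#' @param values respondent values (binary for `"proportion"`).
#' @param ws a `svy_weights` set (the `rescaled` column is used).
#' @param rw a [rao_wu_replicates()] object built from `ws`.
#' @param estimator passed to [replicate_estimates()].
#' @param level confidence level.
#' @param method `"percentile"` or `"normal"` interval.
#' @return An object of class `svy_estimate`: list with
#'   `estimand_label`, `point`, `standard_error`, `ci_low`, `ci_high`,
#'   `B_used`, `method`.
#' @export
svy_estimate <- function(label, values, ws, rw,
                         estimator = c("proportion", "mean", "total"),
                         level = 0.95,
                         method = c("percentile", "normal")) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  w <- ws$rescaled
  point <- if (estimator == "total") sum(w * as.numeric(values))
           else sum(w * as.numeric(values)) / sum(w)
  reps <- replicate_estimates(rw, as.numeric(values), estimator)
  bv <- bootstrap_variance(point, reps, level)
  ci <- if (method == "percentile") bv$ci_percentile else bv$ci_normal
  structure(list(estimand_label = label,
                 point = point,
                 standard_error = bv$standard_error,
                 ci_low = ci[1], ci_high = ci[2],
                 B_used = bv$B_used,
                 method = method),
            class = "svy_estimate")
}

#' @export
print.svy_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f, %s CI [%.4f, %.4f], B = %d)\n",
              x$estimand_label, x$point, x$standard_error, x$method,
              x$ci_low, x$ci_high, x$B_used))
  invisible(x)
}
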