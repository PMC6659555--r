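#' Rao-Wu rescaled bootstrap replicate weights
#'
#' For each replicate and each stratum with `n_h` sampled clusters,
#' `n_h - 1` clusters are drawn with replacement; every respondent in
#' cluster `c` receives base weight times `(n_h / (n_h - 1)) * m_c`,
#' where `m_c` is the number of times their cluster was drawn. The draw
#' multiplicities have mean `(n_h - 1)/n_h`, so the expected replicate
#' weight equals the base weight.
#'
#' Strata with a single sampled cluster cannot be resampled; they are
#' collapsed with the adjacent stratum of the same region (falling back
#' to the nearest stratum in frame order) before replication, and the
#' collapse is recorded.
#'
#' By default each replicate column is then re-calibrated to the
#' benchmark margins (so the variance contribution of the calibration
#' step is captured) and rescaled back to the base column's mean; set
#' `recalibrate = FALSE` to replicate the base weights unadjusted.
#'
#' @param ws a `svy_weights` set.
#' @param sample the [run_fieldwork()] sample the weights came from.
#' @param B number of replicates.
#' @param seed integer seed for the bootstrap stream.
#' @param base which weight column to replicate (default `"rescaled"`).
#' @param recalibrate re-rake each replicate to `bench` margins.
#' @param bench benchmark table, required when `recalibrate = TRUE`.
#' @param spec [calibration_spec()] used for recalibration.
#' @return An object of class `svy_replicates`: list with `weights`
#'   (respondents x B matrix), `B`, `base`, `person_id`, `cluster_id`,
#'   `stratum_of_cluster`, `clusters_per_stratum`, `stratum_collapse`,
#'   `recalibrated`, `seed`.
#' @export
rao_wu_replicates <- function(ws, sample, B, seed,
                              base = c("rescaled", "calibrated", "design",
                                       "initial"),
                              recalibrate = TRUE,
                              bench = NULL,
                              spec = calibration_spec()) {
  stopifnot(inherits(ws, "svy_weights"), B >= 1)
  base <- match.arg(base)
  w0 <- ws[[base]]
  if (anyNA(w0)) stop("base column '", base, "' has not been computed")
  if (recalibrate && is.null(bench))
    stop("recalibrate = TRUE requires a benchmark table")
  seed <- as.integer(seed)
  set.seed(seed)

  cl <- as.character(ws$cluster_id)
  cl_str <- tapply(as.character(ws$stratum_id), cl, function(x) x[1])
  collapse <- .collapse_singleton_strata(cl_str, sample)
  grp_of_cluster <- stats::setNames(collapse$group[as.character(cl_str)],
                                    names(cl_str))

  clusters_by_grp <- split(names(cl_str), grp_of_cluster)
  n_h <- vapply(clusters_by_grp, length, integer(1))
  if (any(n_h < 2))
    stop("stratum group(s) with a single cluster remain after collapsing")

  n <- length(w0)
  Fmat <- matrix(NA_real_, n, B)
  row_of_cluster <- split(seq_len(n), cl)
  for (g in names(clusters_by_grp)) {
    cls <- clusters_by_grp[[g]]
    k <- length(cls)
    m <- stats::rmultinom(B, k - 1L, rep(1 / k, k))  # k x B multiplicities
    fac <- m * (k / (k - 1L))
    for (j in seq_len(k)) {
      rows <- row_of_cluster[[cls[j]]]
      Fmat[rows, ] <- matrix(fac[j, ], length(rows), B, byrow = TRUE)
    }
  }
  W <- w0 * Fmat

  if (recalibrate) {
    bench2 <- .apply_stratum_collapse(bench, attr(ws, "stratum_collapse"))
    mi <- .margin_setup(ws, bench2, spec$margins)
    fit <- rake_weights(W, mi$index, mi$targets,
                        tolerance = spec$tolerance,
                        max_iterations = spec$max_iterations)
    W <- fit$weights
    # back to the base column's scale so replicates stay comparable
    cs <- colSums(W)
    W <- W * rep(sum(w0) / cs, each = n)
  }

  structure(list(weights = W, B = as.integer(B), base = base,
                 person_id = ws$person_id,
                 cluster_id = cl,
                 stratum_of_cluster = cl_str,
                 clusters_per_stratum = n_h,
                 stratum_collapse = collapse$group,
                 recalibrated = isTRUE(recalibrate),
                 seed = seed),
            class = "svy_replicates")
}

# map each (design) stratum to a resampling group with >= 2 clusters;
# singleton groups are merged into the nearest group in frame order (a
# proxy for geographic adjacency) until every group holds >= 2 clusters
.collapse_singleton_strata <- function(cl_str, sample) {
  strata_ids <- unique(as.character(cl_str))
  group <- stats::setNames(strata_ids, strata_ids)
  frame <- unique(as.character(sample$sampled_clusters$stratum_id))
  frame <- c(frame, setdiff(strata_ids, frame))
  repeat {
    n_by_group <- tapply(as.integer(table(cl_str)[strata_ids]),
                         group[strata_ids], sum)
    singles <- names(n_by_group)[n_by_group == 1]
    if (!length(singles)) break
    if (length(n_by_group) == 1L)
      stop("cannot collapse: only one cluster in the whole sample")
    g <- singles[1]
    members <- strata_ids[group[strata_ids] == g]
    pos <- min(match(members, frame))
    others <- setdiff(names(n_by_group), g)
    opos <- vapply(others, function(o)
      min(match(strata_ids[group[strata_ids] == o], frame)), numeric(1))
    donor <- others[which.min(abs(opos - pos))]
    group[group == g] <- donor
  }
  list(group = group)
}

#' Apply an estimator to every bootstrap replicate
#'
#' @param rw a [rao_wu_replicates()] object.
#' @param values numeric vector, one value per respondent (aligned with
#'   `rw$person_id`).
#' @param estimator `"mean"`/`"proportion"` (Hajek weighted mean,
#'   invariant to the weight scale) or `"total"` (Horvitz-Thompson
#'   weighted sum).
#' @return Numeric vector of length `B`. Replicates with zero total
#'   weight (only possible for degenerate inputs) are excluded with a
#'   warning and returned as `NA`.
#' @export
replicate_estimates <- function(rw, values,
                                estimator = c("mean", "proportion",
                                              "total")) {
  stopifnot(inherits(rw, "svy_replicates"),
            length(values) == nrow(rw$weights))
  estimator <- match.arg(estimator)
  W <- rw$weights
  num <- colSums(W * values)
  if (estimator == "total") return(num)
  den <- colSums(W)
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with zero total weight excluded")
    num[bad] <- NA_real_
    den[bad] <- 1
  }
  num / den
}

#' Bootstrap variance, standard error and confidence intervals
#'
#' Variance is the mean squared deviation of the replicate estimates
#' around the full-sample point estimate, `(1/B) * sum((theta_b -
#' theta_hat)^2)`. Percentile intervals use type-7 quantiles of the
#' replicates; normal intervals use `theta_hat +/- z * SE`.
#'
#' @param point full-sample point estimate.
#' @param reps replicate estimates (`NA`s dropped).
#' @param level confidence level (default 0.95).
#' @return List with `variance`, `standard_error`, `ci_percentile`,
#'   `ci_normal`, `B_used`, and `degenerate` (`TRUE` when all
#'   replicates are identical).
#' @export
bootstrap_variance <- function(point, reps, level = 0.95) {
  reps <- reps[!is.na(reps)]
  if (length(reps) < 2L) stop("at least two replicates are required")
  B <- length(reps)
  v <- sum((reps - point)^2) / B
  se <- sqrt(v)
  alpha <- (1 - level) / 2
  z <- stats::qnorm(1 - alpha)
  list(variance = v,
       standard_error = se,
       ci_percentile = unname(stats::quantile(reps, c(alpha, 1 - alpha),
                                              type = 7)),
       ci_normal = c(point - z * se, point + z * se),
       B_used = B,
       degenerate = v == 0)
}

#' Write replicate weights and their sidecar metadata
#'
#' Wide CSV (`respondent_id`, `w_rep_001` ... `w_rep_B`) plus a JSON
#' sidecar recording `B`, the seed, the clusters-per-stratum map and the
#' recalibration flag.
#'
#' @param rw a [rao_wu_replicates()] object.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_replicates <- function(rw, path) {
  stopifnot(inherits(rw, "svy_replicates"))
  tab <- data.frame(respondent_id = rw$person_id, rw$weights)
  names(tab)[-1] <- sprintf("w_rep_%03d", seq_len(rw$B))
  utils::write.csv(tab, path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(B = rw$B, seed = rw$seed, base = rw$base,
         recalibrated = rw$recalibrated,
         clusters_per_stratum = as.list(rw$clusters_per_stratum)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
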