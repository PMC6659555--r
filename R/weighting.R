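#' Calibration specification
#'
#' @param mode `"raking"` (iterative proportional fitting over the
#'   stratum, sex and age-group margins; the default) or `"cell"` (joint
#'   stratum x sex x age post-stratification cells).
#' @param margins which dimensions to calibrate on.
#' @param tolerance maximum relative margin error accepted as converged.
#' @param max_iterations raking sweep cap.
#' @param min_cell_count under cell mode, cells with fewer respondents
#'   are collapsed with the nearest age group within the same
#'   stratum x sex before calibration.
#' @return An object of class `svy_calspec`.
#' @export
calibration_spec <- function(mode = c("raking", "cell"),
                             margins = c("stratum_id", "sex", "age_group"),
                             tolerance = 1e-8,
                             max_iterations = 200L,
                             min_cell_count = 5L) {
  mode <- match.arg(mode)
  stopifnot(tolerance > 0, max_iterations >= 1, length(margins) >= 1,
            all(margins %in% c("stratum_id", "sex", "age_group")))
  structure(list(mode = mode, margins = margins, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 min_cell_count = as.integer(min_cell_count)),
            class = "svy_calspec")
}

#' Start a weight set: within-household inverse selection probability
#'
#' Each respondent's initial weight is the number of same-sex adult
#' smokers in their household: one smoker per sex is drawn uniformly, so
#' the within-household selection probability is `1/k` and its
#' reciprocal is `k`.
#'
#' @param respondents respondent data.frame (from a
#'   [run_fieldwork()] sample) with `person_id`, `stratum_id`,
#'   `cluster_id`, `sex`, `age_group`,
#'   `same_sex_smokers_in_household`.
#' @return A `svy_weights` data.frame with the `initial` column filled
#'   and `design`, `calibrated`, `rescaled` set to `NA` until the later
#'   steps run.
#' @export
initial_weights <- function(respondents) {
  k <- respondents$same_sex_smokers_in_household
  if (is.null(k) || any(k < 1))
    stop("data error: same_sex_smokers_in_household must be >= 1")
  ws <- respondents[, c("person_id", "household_id", "cluster_id",
                        "stratum_id", "sex", "age_group")]
  ws$initial <- as.numeric(k)
  ws$design <- NA_real_
  ws$calibrated <- NA_real_
  ws$rescaled <- NA_real_
  rownames(ws) <- NULL
  class(ws) <- c("svy_weights", "data.frame")
  ws
}

#' Step 2: within-stratum inclusion scaling
#'
#' Household inclusion probabilities are taken as approximately equal
#' within a stratum (the systematic-walk stage gives every dwelling on a
#' route the same chance), so a respondent's inclusion probability within
#' the stratum is proportional to their within-household selection
#' probability. Design weights therefore scale the initial weights by a
#' per-stratum constant chosen so each stratum's weight total equals its
#' adult population.
#'
#' A sampled stratum with population but no respondents is merged into
#' the largest other stratum in the same region (or overall) before
#' scaling; the merge is recorded in the `"stratum_collapse"` attribute.
#'
#' @param ws a [initial_weights()] set.
#' @param strata the population's strata table (`stratum_id`,
#'   `region_id`, `adult_population`).
#' @return `ws` with the `design` column filled.
#' @export
design_weights <- function(ws, strata) {
  stopifnot(inherits(ws, "svy_weights"))
  if (!all(ws$stratum_id %in% strata$stratum_id))
    stop("respondent stratum not present in strata table")
  map <- stats::setNames(strata$stratum_id, strata$stratum_id)
  empty <- setdiff(strata$stratum_id, unique(ws$stratum_id))
  if (length(empty)) {
    for (h in empty) map[h] <- .donor_stratum(h, strata, ws$stratum_id)
    warning("stratum(s) without respondents merged into donors: ",
            paste(empty, "->", map[empty], collapse = "; "))
  }
  grp <- map[ws$stratum_id]
  pop_grp <- tapply(strata$adult_population, map[strata$stratum_id], sum)
  tot <- tapply(ws$initial, grp, sum)
  scale <- pop_grp[names(tot)] / tot
  ws$design <- ws$initial * as.numeric(scale[as.character(grp)])
  attr(ws, "stratum_collapse") <- map
  ws
}

# donor: largest-population non-empty stratum, same region preferred
.donor_stratum <- function(h, strata, sampled_strata) {
  cand <- strata[strata$stratum_id %in% unique(sampled_strata), ]
  same <- cand[cand$region_id == strata$region_id[strata$stratum_id == h], ]
  pick <- if (nrow(same)) same else cand
  if (!nrow(pick)) stop("no donor stratum available")
  pick$stratum_id[which.max(pick$adult_population)]
}

#' Step 3: calibrate weights to benchmark smoker margins
#'
#' Post-stratification adjustment of the design weights so that weighted
#' sample margins over stratum, sex and age group reproduce the
#' benchmark smoker counts. Under raking (the default) the three margins
#' are fitted by iterative proportional fitting; under cell mode each
#' joint stratum x sex x age cell is scaled by benchmark/sample ratio,
#' after collapsing cells below `min_cell_count` respondents into the
#' nearest age group within the same stratum x sex.
#'
#' @param ws a [design_weights()] set (or any `svy_weights` with the
#'   `design` column filled).
#' @param bench a [true_margins()]-shaped benchmark table
#'   (`stratum_id`, `sex`, `age_group`, `smokers`).
#' @param spec a [calibration_spec()].
#' @return `ws` with the `calibrated` column filled; attributes
#'   `"iterations"` and `"max_rel_error"` record the fit.
#' @export
calibrate <- function(ws, bench, spec = calibration_spec()) {
  stopifnot(inherits(ws, "svy_weights"))
  if (anyNA(ws$design)) stop("design weights must be computed first")
  bench <- .apply_stratum_collapse(bench, attr(ws, "stratum_collapse"))

  if (spec$mode == "cell") {
    cal <- .calibrate_cells(ws, bench, spec)
  } else {
    mi <- .margin_setup(ws, bench, spec$margins)
    fit <- rake_weights(ws$design, mi$index, mi$targets,
                        tolerance = spec$tolerance,
                        max_iterations = spec$max_iterations)
    if (!fit$converged)
      stop("raking did not converge in ", spec$max_iterations,
           " sweeps; max relative margin error ",
           format(fit$max_rel_error),
           " (margin errors: ",
           paste(names(mi$targets), vapply(fit$margin_error, format, ""),
                 collapse = ", "), ")")
    cal <- list(w = fit$weights, iterations = fit$iterations,
                err = fit$max_rel_error)
  }
  if (any(cal$w <= 0)) stop("calibration produced non-positive weights")
  ws$calibrated <- cal$w
  attr(ws, "iterations") <- cal$iterations
  attr(ws, "max_rel_error") <- cal$err
  ws
}

.apply_stratum_collapse <- function(bench, map) {
  if (is.null(map) || all(map == names(map))) return(bench)
  bench$stratum_id <- as.character(map[bench$stratum_id])
  agg <- stats::aggregate(smokers ~ stratum_id + sex + age_group, bench, sum)
  agg
}

# per-margin integer level index for each respondent + matching targets
.margin_setup <- function(ws, bench, margins) {
  index <- list(); targets <- list()
  for (m in margins) {
    tgt <- tapply(bench$smokers, bench[[m]], sum)
    tgt <- tgt[tgt > 0]
    lev <- names(tgt)
    idx <- match(as.character(ws[[m]]), lev)
    if (anyNA(idx)) {
      bad <- unique(ws[[m]][is.na(idx)])
      stop("respondent level(s) of margin '", m,
           "' missing or zero in benchmark: ",
           paste(bad, collapse = ", "))
    }
    index[[m]] <- idx
    targets[[m]] <- as.numeric(tgt)
  }
  list(index = index, targets = targets)
}

.calibrate_cells <- function(ws, bench, spec) {
  # joint cells over the configured margins
  cell_of <- function(df) do.call(paste, c(df[spec$margins], sep = "\r"))
  rcell <- cell_of(ws)
  bcell <- cell_of(bench)
  btot <- tapply(bench$smokers, bcell, sum)

  # collapse small cells into the nearest age group in stratum x sex
  if ("age_group" %in% spec$margins) {
    ages <- unique(bench$age_group)
    cnt <- table(rcell)
    repeat {
      small <- names(cnt)[cnt > 0 & cnt < spec$min_cell_count]
      if (!length(small)) break
      cell <- small[1]
      parts <- strsplit(cell, "\r")[[1]]
      a_pos <- match("age_group", spec$margins)
      ai <- match(parts[a_pos], ages)
      # neighbours in age order, nearest first
      cand_ai <- order(abs(seq_along(ages) - ai))
      cand_ai <- cand_ai[cand_ai != ai]
      donor <- NULL
      for (j in cand_ai) {
        p2 <- parts; p2[a_pos] <- ages[j]
        cell2 <- paste(p2, collapse = "\r")
        if (!is.na(cnt[cell2]) && cnt[cell2] > 0) { donor <- cell2; break }
      }
      if (is.null(donor))
        stop("cannot collapse sparse cell: no occupied neighbour age group")
      rcell[rcell == cell] <- donor
      bcell[bcell == cell] <- donor
      cnt <- table(rcell)
      btot <- tapply(bench$smokers, bcell, sum)
    }
    if (any(cnt < spec$min_cell_count))
      warning("cell(s) below min_cell_count remain after collapsing")
  }

  empty <- setdiff(names(btot)[btot > 0], unique(rcell))
  if (length(empty))
    stop("benchmark cell(s) with no respondents after collapsing: ",
         length(empty), " cell(s); supply marginal raking instead")
  stot <- tapply(ws$design, rcell, sum)
  ratio <- btot[names(stot)] / stot
  list(w = ws$design * as.numeric(ratio[rcell]),
       iterations = 1L, err = 0)
}

#' Raking (iterative proportional fitting) core
#'
#' Adjusts weights so the weighted totals over each margin match the
#' targets, cycling margin-by-margin until the largest relative margin
#' error falls below `tolerance`. Accepts a weight vector or an
#' n x B matrix (each column raked independently — used to recalibrate
#' bootstrap replicate weights in one vectorised pass). Margin levels
#' with zero current weighted total are left untouched in that column.
#'
#' @param w positive weights: numeric vector or matrix (rows =
#'   respondents).
#' @param margin_index list of integer vectors, one per margin, giving
#'   each respondent's level index `1..G_m`.
#' @param targets list of positive numeric vectors, one per margin,
#'   aligned with the level indices.
#' @param tolerance,max_iterations convergence control.
#' @return List with `weights` (same shape as `w`), `iterations`,
#'   `max_rel_error`, per-margin `margin_error`, and `converged`.
#' @export
rake_weights <- function(w, margin_index, targets,
                         tolerance = 1e-8, max_iterations = 200L) {
  is_mat <- is.matrix(w)
  W <- if (is_mat) w else matrix(w, ncol = 1L)
  M <- length(margin_index)
  stopifnot(M >= 1, length(targets) == M)
  for (m in seq_len(M)) {
    g <- margin_index[[m]]
    if (!all(seq_along(targets[[m]]) %in% g))
      stop("margin ", m, " has target level(s) with no respondents; ",
           "collapse or drop them before raking")
  }

  margin_err <- function(W) {
    vapply(seq_len(M), function(m) {
      cur <- rowsum(W, margin_index[[m]], reorder = TRUE)
      rel <- abs(cur / targets[[m]] - 1)
      rel[cur == 0] <- 0   # unfixable in this column; flagged by caller
      max(rel)
    }, numeric(1))
  }

  it <- 0L
  repeat {
    errs <- margin_err(W)
    if (max(errs) < tolerance || it >= max_iterations) break
    it <- it + 1L
    for (m in seq_len(M)) {
      g <- margin_index[[m]]
      cur <- rowsum(W, g, reorder = TRUE)
      f <- targets[[m]] / cur
      f[!is.finite(f)] <- 1
      W <- W * f[g, , drop = FALSE]
    }
  }
  dimnames(W) <- NULL
  list(weights = if (is_mat) W else W[, 1L],
       iterations = it,
       max_rel_error = max(errs),
       margin_error = stats::setNames(as.list(errs), names(margin_index)),
       converged = max(errs) < tolerance)
}

#' Step 4: rescale weights to mean one
#'
#' Multiplies each country's calibrated weights by `n / sum(w)` so the
#' weights average exactly 1, leaving all weight ratios unchanged. The
#' mean-1 scale is the analysis convention that makes weights comparable
#' across countries.
#'
#' @param ws a `svy_weights` set with `calibrated` filled (set `from =
#'   "design"` to rescale uncalibrated weights instead).
#' @param from which column to rescale.
#' @return `ws` with the `rescaled` column filled.
#' @export
rescale_mean_one <- function(ws, from = "calibrated") {
  stopifnot(inherits(ws, "svy_weights"), from %in% names(ws))
  w <- ws[[from]]
  if (length(w) == 0L) stop("no respondents to rescale")
  if (anyNA(w)) stop("column '", from, "' has not been computed")
  s <- sum(w)
  if (s <= 0) stop("zero or negative total weight")
  ws$rescaled <- w * (length(w) / s)
  ws
}

#' Run the full four-step weight construction
#'
#' Convenience chain: [initial_weights()] -> [design_weights()] ->
#' [calibrate()] -> [rescale_mean_one()].
#'
#' @param sample a [run_fieldwork()] result.
#' @param strata the population strata table.
#' @param bench benchmark smoker margins ([true_margins()] shape).
#' @param spec a [calibration_spec()].
#' @return A complete `svy_weights` data.frame.
#' @export
build_weights <- function(sample, strata, bench,
                          spec = calibration_spec()) {
  stopifnot(inherits(sample, "svy_fieldsample"))
  ws <- initial_weights(sample$respondents)
  ws <- design_weights(ws, strata)
  ws <- calibrate(ws, bench, spec)
  rescale_mean_one(ws)
}
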