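# The scaled-down simulation study shared by the design-based recovery,
# bootstrap-calibration and coverage checks: one synthetic country of
# ~40,000 adults in 8 strata, 40 sampled clusters, quota 10, full
# response. Built lazily and cached so the expensive parts run once per
# test session.

.study <- new.env(parent = emptyenv())

study_strata <- function() {
  data.frame(stratum_id = paste0("S", 1:8),
             region_id = rep(paste0("R", 1:4), each = 2),
             urbanization = rep(c("urban", "rural"), 4),
             adult_population = c(8000, 4000, 6000, 4000,
                                  6000, 3000, 5000, 4000),
             stringsAsFactors = FALSE)
}

study_population <- function() {
  if (is.null(.study$pop)) {
    cfg <- population_config(study_strata(), demo_prevalence())
    .study$pop <- generate_population(cfg, seed = 20160618L)
    .study$bench <- true_margins(.study$pop)
    sm <- .study$pop$adults[.study$pop$adults$is_smoker, ]
    .study$truth <- c(daily_smoker = mean(sm$daily_smoker),
                      quit_intention = mean(sm$quit_intention))
  }
  .study$pop
}

study_benchmark <- function() { study_population(); .study$bench }
study_truth <- function() { study_population(); .study$truth }

study_design <- function() design_spec(clusters_total = 40,
                                       quota_per_cluster = 10)

# R full-response fieldwork replicates; per run: calibrated and
# design-only estimates for both attributes, plus (for the first
# `n_boot` runs and for every run's primary attribute) a B-replicate
# Rao-Wu bootstrap variance and percentile CI.
study_runs <- function(R = 500L, B = 500L, n_boot_var = 20L) {
  key <- paste(R, B, n_boot_var)
  if (identical(.study$runs_key, key)) return(.study$runs)
  pop <- study_population()
  bench <- study_benchmark()
  des <- study_design()
  out <- vector("list", R)
  for (i in seq_len(R)) {
    s <- suppressWarnings(run_fieldwork(pop, des, seed = 5000L + i))
    ws <- suppressWarnings(build_weights(s, pop$strata, bench))
    y1 <- as.numeric(s$respondents$daily_smoker)
    y2 <- as.numeric(s$respondents$quit_intention)
    est_cal <- c(daily_smoker = weighted_proportion(y1, ws$rescaled),
                 quit_intention = weighted_proportion(y2, ws$rescaled))
    est_des <- c(daily_smoker = weighted_proportion(y1, ws$design),
                 quit_intention = weighted_proportion(y2, ws$design))
    rw <- rao_wu_replicates(ws, s, B = B, seed = 90000L + i,
                            recalibrate = TRUE, bench = bench)
    reps <- replicate_estimates(rw, y1, "proportion")
    bv <- bootstrap_variance(est_cal[["daily_smoker"]], reps)
    out[[i]] <- list(est_cal = est_cal, est_des = est_des,
                     boot_var = bv$variance, ci = bv$ci_percentile)
  }
  .study$runs <- out
  .study$runs_key <- key
  out
}

# runs with sex-differential nonresponse (females cooperate at 0.5)
study_nonresponse_runs <- function(R = 200L) {
  if (!is.null(.study$nr_runs) && length(.study$nr_runs) == R)
    return(.study$nr_runs)
  cfg <- population_config(study_strata(), demo_prevalence(),
                           cooperation = c(male = 1, female = 0.5))
  pop <- generate_population(cfg, seed = 20160618L)
  bench <- true_margins(pop)
  des <- study_design()
  sm <- pop$adults[pop$adults$is_smoker, ]
  truth <- mean(sm$daily_smoker)
  out <- vector("list", R)
  for (i in seq_len(R)) {
    s <- suppressWarnings(run_fieldwork(pop, des, seed = 7000L + i))
    ws <- suppressWarnings(build_weights(s, pop$strata, bench))
    y <- as.numeric(s$respondents$daily_smoker)
    out[[i]] <- c(cal = weighted_proportion(y, ws$rescaled),
                  des = weighted_proportion(y, ws$design))
  }
  .study$nr_truth <- truth
  .study$nr_runs <- out
  out
}

study_nonresponse_truth <- function() .study$nr_truth
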