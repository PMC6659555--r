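respondent_frame <- function(k, sex = rep("male", length(k)),
                             stratum = rep("S1", length(k))) {
  data.frame(person_id = seq_along(k), household_id = seq_along(k),
             cluster_id = paste0(stratum, "_c1"), stratum_id = stratum,
             sex = sex, age_group = "25-39",
             same_sex_smokers_in_household = k,
             stringsAsFactors = FALSE)
}

test_that("initial weights equal the same-sex smoker count", {
  ws <- initial_weights(respondent_frame(c(1, 5)))
  expect_equal(ws$initial, c(1, 5))
  # two male smokers + one female smoker in one household: the selected
  # male carries weight 2, the female weight 1
  hh <- data.frame(person_id = 1:2, household_id = 1L,
                   cluster_id = "S1_c1", stratum_id = "S1",
                   sex = c("male", "female"), age_group = "25-39",
                   same_sex_smokers_in_household = c(2L, 1L))
  ws <- initial_weights(hh)
  expect_equal(ws$initial, c(2, 1))
  bad <- respondent_frame(c(1, 0))
  expect_error(initial_weights(bad), "data error")
})

test_that("design weights scale stratum totals to adult population", {
  strata <- data.frame(stratum_id = c("S1", "S2"),
                       region_id = c("R1", "R1"),
                       adult_population = c(1000, 1000))
  rf <- respondent_frame(rep(1, 30),
                         stratum = rep(c("S1", "S2"), c(10, 20)))
  ws <- design_weights(initial_weights(rf), strata)
  w1 <- unique(ws$design[ws$stratum_id == "S1"])
  w2 <- unique(ws$design[ws$stratum_id == "S2"])
  expect_length(w1, 1); expect_length(w2, 1)
  expect_equal(w1 / w2, 2)                     # 2:1 per-respondent ratio
  expect_equal(sum(ws$design[ws$stratum_id == "S1"]), 1000)

  # single stratum: a constant multiple of the initial weights
  one <- data.frame(stratum_id = "S1", region_id = "R1",
                    adult_population = 500)
  ws1 <- design_weights(initial_weights(respondent_frame(c(1, 2, 2))), one)
  expect_equal(ws1$design / ws1$initial, rep(100, 3))
})

test_that("an unsampled stratum is merged into a donor before scaling", {
  strata <- data.frame(stratum_id = c("S1", "S2"),
                       region_id = c("R1", "R1"),
                       adult_population = c(1000, 400))
  rf <- respondent_frame(rep(1, 10))            # only S1 sampled
  expect_warning(ws <- design_weights(initial_weights(rf), strata),
                 "donor")
  expect_equal(sum(ws$design), 1400)            # S2's population absorbed
})

test_that("raking reproduces the 2x2 worked example", {
  # one unit per sex x age cell, all design weights 1,
  # sex targets (3, 1), age targets (2, 2)
  fit <- rake_weights(rep(1, 4),
                      margin_index = list(sex = c(1L, 1L, 2L, 2L),
                                          age = c(1L, 2L, 1L, 2L)),
                      targets = list(sex = c(3, 1), age = c(2, 2)))
  expect_true(fit$converged)
  expect_equal(fit$weights, c(1.5, 1.5, 0.5, 0.5))
  expect_lte(fit$iterations, 2)

  # same example through the calibrate() surface
  ws <- manual_weights(stratum_id = rep("S1", 4),
                       sex = c("m", "m", "f", "f"),
                       age_group = c("a1", "a2", "a1", "a2"))
  bench <- benchmark_table(rep("S1", 4), c("m", "m", "f", "f"),
                           c("a1", "a2", "a1", "a2"),
                           smokers = c(2, 1, 0, 1))  # margins 3/1 and 2/2
  out <- calibrate(ws, bench,
                   calibration_spec(margins = c("sex", "age_group")))
  expect_equal(out$calibrated, c(1.5, 1.5, 0.5, 0.5))
})

test_that("a benchmark proportional to current margins is a fixed point", {
  ws <- manual_weights(stratum_id = c("S1", "S1", "S2", "S2"),
                       sex = c("m", "f", "m", "f"),
                       age_group = c("a1", "a1", "a2", "a2"),
                       design = c(2, 3, 4, 1))
  bench <- benchmark_table(ws$stratum_id, ws$sex, ws$age_group,
                           smokers = ws$design * 10)
  out <- calibrate(ws, bench)
  expect_equal(out$calibrated, ws$design * 10, tolerance = 1e-8)
})

test_that("cell mode scales each post-stratification cell by its ratio", {
  ws <- manual_weights(stratum_id = rep("S1", 5), sex = rep("m", 5),
                       age_group = rep("a1", 5), design = rep(10, 5))
  bench <- benchmark_table("S1", "m", "a1", smokers = 200)
  out <- calibrate(ws, bench, calibration_spec(mode = "cell"))
  expect_equal(out$calibrated, rep(40, 5))      # all weights x 4
})

test_that("sparse cells collapse into the nearest age group", {
  ws <- manual_weights(stratum_id = rep("S1", 8), sex = rep("m", 8),
                       age_group = c("a1", rep("a2", 7)),
                       design = rep(1, 8))
  bench <- benchmark_table(rep("S1", 2), rep("m", 2), c("a1", "a2"),
                           smokers = c(10, 30))
  out <- calibrate(ws, bench,
                   calibration_spec(mode = "cell", min_cell_count = 5))
  # a1 (1 respondent) merges with a2: one pooled ratio 40/8
  expect_equal(out$calibrated, rep(5, 8))
})

test_that("raking stops with an error on structurally infeasible targets", {
  ws <- manual_weights(stratum_id = c("S1", "S2"), sex = c("m", "f"),
                       age_group = c("a1", "a2"))
  bench <- benchmark_table(c("S1", "S1", "S2", "S2"),
                           c("m", "f", "m", "f"),
                           c("a1", "a2", "a1", "a2"),
                           smokers = c(1, 0, 0, 3))
  # respondents only cover (S1,m,a1) and (S2,f,a2): stratum targets
  # (1, 3) conflict with sex targets (1, 3) vs their cells' ages
  expect_error(
    calibrate(ws, benchmark_table(c("S1", "S2"), c("m", "f"),
                                  c("a2", "a1"), c(1, 3)),
              calibration_spec(max_iterations = 50)))
})

test_that("rescaling sets the mean to one and preserves ratios", {
  ws <- manual_weights(stratum_id = rep("S1", 3), sex = rep("m", 3),
                       age_group = rep("a1", 3))
  ws$calibrated <- c(2, 4, 6)
  out <- rescale_mean_one(ws)
  expect_equal(out$rescaled, c(0.5, 1.0, 1.5))
  ws$calibrated <- rep(7, 3)
  expect_equal(rescale_mean_one(ws)$rescaled, rep(1, 3))
  set.seed(11)
  for (i in 1:5) {
    n <- sample(3:50, 1)
    ws2 <- manual_weights(stratum_id = rep("S1", n), sex = rep("m", n),
                          age_group = rep("a1", n))
    ws2$calibrated <- stats::rlnorm(n)
    out2 <- rescale_mean_one(ws2)
    expect_equal(mean(out2$rescaled), 1, tolerance = 1e-12)
    expect_equal(out2$rescaled / out2$rescaled[1],
                 ws2$calibrated / ws2$calibrated[1], tolerance = 1e-12)
  }
})

test_that("the full chain is invariant to respondent order", {
  pop <- generate_population(demo_config(2, c(6000, 6000)), 21)
  bench <- true_margins(pop)
  des <- design_spec(clusters_total = 6, quota_per_cluster = 8)
  s <- suppressWarnings(run_fieldwork(pop, des, 22))
  ws_a <- build_weights(s, pop$strata, bench)
  s2 <- s
  perm <- sample(nrow(s$respondents))
  s2$respondents <- s$respondents[perm, ]
  ws_b <- build_weights(s2, pop$strata, bench)
  m <- match(ws_a$person_id, ws_b$person_id)
  for (col in c("initial", "design", "calibrated", "rescaled"))
    expect_lt(max(abs(ws_a[[col]] - ws_b[[col]][m])), 1e-10)
})

test_that("calibrated weights reproduce the benchmark margins", {
  pop <- generate_population(demo_config(3, c(5000, 4000, 3000)), 23)
  bench <- true_margins(pop)
  des <- design_spec(clusters_total = 9, quota_per_cluster = 8)
  s <- suppressWarnings(run_fieldwork(pop, des, 24))
  ws <- build_weights(s, pop$strata, bench)
  audit <- margin_audit(ws, bench)
  expect_lt(attr(audit, "max_rel_error"), 1e-8)
  expect_equal(mean(ws$rescaled), 1, tolerance = 1e-12)
  expect_true(all(ws$rescaled > 0))
})
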