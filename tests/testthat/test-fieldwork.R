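# brute-force oracle: all feasible allocations (floor respected) ranked
# by the maximum absolute deviation from the exact proportional share
best_allocation <- function(pop, total, floor_k) {
  share <- total * pop / sum(pop)
  grid <- expand.grid(rep(list(floor_k:total), length(pop)))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  dev <- apply(grid, 1, function(a) max(abs(a - share)))
  as.integer(grid[which.min(dev), ])
}

test_that("cluster allocation is proportional with a floor", {
  des <- design_spec(clusters_total = 100, min_clusters_per_stratum = 2)
  st <- data.frame(stratum_id = c("A", "B", "C"),
                   adult_population = c(50000, 30000, 20000))
  expect_equal(unname(allocate_clusters(st, des)), c(50L, 30L, 20L))

  one <- data.frame(stratum_id = "A", adult_population = 1234)
  expect_equal(unname(allocate_clusters(one, des)), 100L)

  des10 <- design_spec(clusters_total = 10, min_clusters_per_stratum = 2)
  tiny <- data.frame(stratum_id = c("A", "B", "C"),
                     adult_population = c(97, 2, 1))
  got <- allocate_clusters(tiny, des10)
  expect_equal(unname(got), best_allocation(c(97, 2, 1), 10, 2))
  expect_equal(unname(got), c(6L, 2L, 2L))

  expect_error(allocate_clusters(tiny,
                                 design_spec(clusters_total = 5,
                                             min_clusters_per_stratum = 2)),
               "configuration error")
})

test_that("allocation always meets the floor and the total", {
  des <- design_spec(clusters_total = 40, min_clusters_per_stratum = 2)
  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    st <- data.frame(stratum_id = paste0("S", 1:n),
                     adult_population = sample(100:100000, n))
    a <- allocate_clusters(st, des)
    expect_equal(sum(a), 40L)
    expect_true(all(a >= 2L))
  }
})

test_that("a lone same-sex smoker is always selected; none means none", {
  hh <- data.frame(person_id = 1L, sex = "male")
  for (i in 1:10) expect_equal(select_in_household(hh), 1L)
  none <- data.frame(person_id = integer(0), sex = character(0))
  expect_length(select_in_household(none), 0)
  mixed <- data.frame(person_id = 1:3, sex = c("male", "male", "female"))
  set.seed(2)
  sel <- select_in_household(mixed)
  expect_length(sel, 2)
  expect_true(3L %in% sel)           # the only female
  expect_true(any(1:2 %in% sel))     # one of the two males
})

test_that("same-sex smokers are selected with equal probability", {
  hh <- data.frame(person_id = 1:3, sex = rep("male", 3))
  set.seed(314)
  n <- 10000L
  draws <- vapply(seq_len(n), function(i) select_in_household(hh),
                  integer(1))
  freq <- tabulate(draws, 3)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (j in 1:3) expect_lt(abs(freq[j] / n - 1 / 3), 3 * se)
  gof <- stats::chisq.test(freq, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.01)
})

test_that("full response on single-smoker households is deterministic", {
  cfg <- population_config(
    demo_strata(1, 20), smoking_prevalence = 1,
    household_sizes = c(`1` = 1), sex_split = c(male = 1, female = 0),
    cluster_size = 20)
  pop <- generate_population(cfg, 5)
  des <- design_spec(clusters_total = 1, min_clusters_per_stratum = 1,
                     quota_per_cluster = 10, walk_step = 1)
  s <- run_fieldwork(pop, des, 6)
  d <- s$dispositions
  expect_equal(as.numeric(d[["completed_interviews"]]), 10)
  expect_equal(as.numeric(d[["individual_refusals"]]), 0)
  expect_equal(as.numeric(d[["no_eligible"]]), 0)
  expect_equal(nrow(s$respondents), 10)
  expect_true(all(s$respondents$same_sex_smokers_in_household == 1))
})

test_that("zero contact propensity contacts and completes nothing", {
  cfg <- demo_config(1, 2000, contact = 0, cluster_size = 500)
  pop <- generate_population(cfg, 8)
  des <- design_spec(clusters_total = 2, min_clusters_per_stratum = 1,
                     quota_per_cluster = 5)
  expect_warning(s <- run_fieldwork(pop, des, 9), "quota")
  expect_equal(as.numeric(s$dispositions[["addresses_contacted"]]), 0)
  expect_equal(as.numeric(s$dispositions[["completed_interviews"]]), 0)
  expect_gt(as.numeric(s$dispositions[["addresses_attempted"]]), 0)
})

test_that("fieldwork is reproducible given the seed", {
  cfg <- demo_config(2, c(4000, 4000))
  pop <- generate_population(cfg, 10)
  des <- design_spec(clusters_total = 8, quota_per_cluster = 5)
  s1 <- suppressWarnings(run_fieldwork(pop, des, 77))
  s2 <- suppressWarnings(run_fieldwork(pop, des, 77))
  expect_identical(s1$respondents, s2$respondents)
  expect_identical(unclass(s1$dispositions), unclass(s2$dispositions))
})

test_that("dispositions stay internally consistent under nonresponse", {
  # property-style sweep over response regimes and seeds
  regimes <- list(
    list(contact = 0.7, cooperation = 0.8, sr = 0.1, lr = 0.05),
    list(contact = c(2, 1), cooperation = c(5, 2), sr = 0, lr = 0),
    list(contact = 1, cooperation = c(male = 1, female = 0.5),
         sr = 0.2, lr = 0.1))
  for (k in seq_along(regimes)) {
    rg <- regimes[[k]]
    cfg <- demo_config(2, c(5000, 5000), contact = rg$contact,
                       cooperation = rg$cooperation)
    pop <- generate_population(cfg, 100 + k)
    des <- design_spec(clusters_total = 6, quota_per_cluster = 8,
                       screener_refusal = rg$sr,
                       selection_refusal = rg$lr)
    s <- suppressWarnings(run_fieldwork(pop, des, 200 + k))
    expect_true(validate_dispositions(s$dispositions))
    # quota cap
    expect_true(all(s$completed_per_cluster <= des$quota_per_cluster))
    # no substitution: at most one completed respondent per household/sex
    key <- paste(s$respondents$household_id, s$respondents$sex)
    expect_equal(anyDuplicated(key), 0)
  }
})

test_that("respondent counts respect the per-cluster quota exactly", {
  pop <- generate_population(demo_config(2, c(8000, 8000)), 31)
  des <- design_spec(clusters_total = 10, quota_per_cluster = 10)
  s <- suppressWarnings(run_fieldwork(pop, des, 32))
  per_cl <- table(s$respondents$cluster_id)
  expect_true(all(per_cl <= 10))
  expect_equal(sum(s$completed_per_cluster),
               as.numeric(s$dispositions[["completed_interviews"]]))
})
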