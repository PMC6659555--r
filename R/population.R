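#' Synthetic national population configuration
#'
#' Describes a hierarchical sampling frame for one country: geographic
#' strata (region crossed with urbanization level) partitioned into
#' enumeration-area-sized clusters of households, each household holding
#' one or more adults with sex, age group and smoker status.
#'
#' @param strata data.frame with columns `stratum_id`, `region_id`,
#'   `urbanization` (one of `"urban"`, `"semi_urban_rural"`, `"rural"`)
#'   and `adult_population` (adults aged 18+). `(region_id, urbanization)`
#'   must be unique.
#' @param smoking_prevalence either a single probability applied to every
#'   sex-by-age cell, or a data.frame with columns `sex`, `age_group`,
#'   `prevalence` and optionally `stratum_id` for stratum-specific rates.
#'   A smoker is an adult who smokes at least monthly and has smoked more
#'   than 100 cigarettes over their lifetime.
#' @param household_sizes named numeric vector: probability of a household
#'   containing 1, 2, ... adults (names are the counts). Default mass on
#'   1--4 adults.
#' @param sex_split named probabilities for `male` / `female`.
#' @param age_groups character vector of ordinal age-group labels, youngest
#'   first.
#' @param age_probs probabilities for `age_groups` (same length).
#' @param attributes named list of binary smoker attributes; each element
#'   is a named vector `c(male = p, female = p)` giving the attribute
#'   prevalence among smokers of that sex. Used as estimands in recovery
#'   studies.
#' @param contact,cooperation response propensities: a single value in
#'   `[0, 1]`, a named per-sex vector `c(male = , female = )`, or a
#'   length-2 unnamed vector of Beta shape parameters to draw
#'   heterogeneous propensities. Defaults are 1 (full response) so that
#'   design-based properties can be studied without nonresponse.
#' @param cluster_size target number of adults per frame cluster
#'   (enumeration area). Default 400 (roughly 210 households), so that a
#'   systematic walk approaching every 5th dwelling can supply a
#'   10-interview quota at realistic smoker prevalence.
#' @return An object of class `svy_popconfig`.
#' @export
population_config <- function(strata,
                              smoking_prevalence,
                              household_sizes = c(`1` = 0.35, `2` = 0.45,
                                                  `3` = 0.15, `4` = 0.05),
                              sex_split = c(male = 0.5, female = 0.5),
                              age_groups = c("18-24", "25-39", "40-54", "55+"),
                              age_probs = c(0.12, 0.30, 0.28, 0.30),
                              attributes = list(
                                daily_smoker   = c(male = 0.85, female = 0.75),
                                quit_intention = c(male = 0.25, female = 0.35)),
                              contact = 1,
                              cooperation = 1,
                              cluster_size = 400) {
  stopifnot(is.data.frame(strata))
  need <- c("stratum_id", "region_id", "urbanization", "adult_population")
  if (!all(need %in% names(strata)))
    stop("strata must have columns: ", paste(need, collapse = ", "))
  if (nrow(strata) == 0L)
    stop("configuration error: at least one stratum is required")
  if (any(strata$adult_population <= 0))
    stop("configuration error: adult_population must be > 0 in every stratum")
  if (anyDuplicated(strata[, c("region_id", "urbanization")]))
    stop("configuration error: (region_id, urbanization) must be unique")
  if (anyDuplicated(strata$stratum_id))
    stop("configuration error: stratum_id must be unique")
  bad_urb <- setdiff(strata$urbanization,
                     c("urban", "semi_urban_rural", "rural"))
  if (length(bad_urb))
    stop("unknown urbanization level(s): ", paste(bad_urb, collapse = ", "))

  prev <- .expand_prevalence(smoking_prevalence, strata$stratum_id,
                             names(sex_split), age_groups)

  stopifnot(length(age_probs) == length(age_groups),
            abs(sum(age_probs) - 1) < 1e-8,
            abs(sum(sex_split) - 1) < 1e-8,
            abs(sum(household_sizes) - 1) < 1e-8,
            cluster_size >= 1)
  for (a in attributes)
    if (any(a < 0 | a > 1) || !all(c("male", "female") %in% names(a)))
      stop("attribute prevalences must be named male/female probabilities")
  .check_propensity(contact, "contact")
  .check_propensity(cooperation, "cooperation")

  structure(list(strata = strata,
                 smoking_prevalence = prev,
                 household_sizes = household_sizes,
                 sex_split = sex_split,
                 age_groups = age_groups,
                 age_probs = age_probs,
                 attributes = attributes,
                 contact = contact,
                 cooperation = cooperation,
                 cluster_size = cluster_size),
            class = "svy_popconfig")
}

# Normalise the prevalence input to one row per (stratum, sex, age) cell.
.expand_prevalence <- function(p, stratum_ids, sexes, age_groups) {
  grid <- expand.grid(stratum_id = stratum_ids, sex = sexes,
                      age_group = age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.numeric(p) && length(p) == 1L) {
    grid$prevalence <- p
  } else if (is.data.frame(p)) {
    if (!all(c("sex", "age_group", "prevalence") %in% names(p)))
      stop("smoking_prevalence needs columns sex, age_group, prevalence")
    if (!"stratum_id" %in% names(p)) {
      grid <- merge(grid, p, by = c("sex", "age_group"),
                    all.x = TRUE, sort = FALSE)
    } else {
      grid <- merge(grid, p, by = c("stratum_id", "sex", "age_group"),
                    all.x = TRUE, sort = FALSE)
    }
    if (anyNA(grid$prevalence))
      stop("smoking_prevalence does not cover every stratum/sex/age cell")
  } else stop("smoking_prevalence must be a probability or a data.frame")
  if (any(grid$prevalence < 0 | grid$prevalence > 1))
    stop("configuration error: prevalence outside [0, 1]")
  grid[order(grid$stratum_id, grid$sex, grid$age_group), ,
       drop = FALSE]
}

.check_propensity <- function(x, what) {
  ok <- (is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1) ||
    (is.numeric(x) && length(x) == 2L && is.null(names(x)) && all(x > 0)) ||
    (is.numeric(x) && length(x) == 2L &&
       setequal(names(x), c("male", "female")) && all(x >= 0 & x <= 1))
  if (!ok)
    stop(what, " must be a probability, a c(male=, female=) pair, ",
         "or two Beta shape parameters")
  invisible(TRUE)
}

# Draw one propensity per adult according to the three accepted forms.
.draw_propensity <- function(x, sex) {
  n <- length(sex)
  if (length(x) == 1L) return(rep(x, n))
  if (!is.null(names(x))) return(unname(x[sex]))
  stats::rbeta(n, x[1], x[2])
}

#' Generate a synthetic country population
#'
#' Builds the full hierarchical frame: households of 1+ adults grouped
#' into enumeration-area clusters nested in geographic strata. Smoker
#' status is assigned independently per adult from the configured
#' sex-by-age (optionally by-stratum) prevalences; contact and
#' cooperation propensities and binary smoker attributes are attached per
#' adult. Realised stratum adult counts match the configuration exactly.
#'
#' @param config a [population_config()] object.
#' @param seed integer seed; the same `(config, seed)` pair reproduces the
#'   population bit-for-bit.
#' @return An object of class `svy_population`: a list with data.frames
#'   `strata`, `clusters` (`cluster_id`, `stratum_id`), `households`
#'   (`household_id`, `cluster_id`, `stratum_id`) and `adults`
#'   (`person_id`, `household_id`, `cluster_id`, `stratum_id`, `sex`,
#'   `age_group`, `is_smoker`, attribute columns, `contact_propensity`,
#'   `cooperation_propensity`), plus the `seed`.
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "svy_popconfig"))
  seed <- as.integer(seed)
  set.seed(seed)

  sizes_k <- as.integer(names(config$household_sizes))
  sizes_p <- as.numeric(config$household_sizes)
  mean_hh <- sum(sizes_k * sizes_p)

  hh_list <- vector("list", nrow(config$strata))
  for (i in seq_len(nrow(config$strata))) {
    st <- config$strata[i, ]
    n_adults <- st$adult_population
    # oversample household sizes, then trim the last household so the
    # stratum adult count is met exactly
    n_try <- ceiling(n_adults / mean_hh * 1.3) + 10L
    repeat {
      sz <- sample(sizes_k, n_try, replace = TRUE, prob = sizes_p)
      cs <- cumsum(sz)
      if (cs[length(cs)] >= n_adults) break
      n_try <- n_try * 2L
    }
    k <- which(cs >= n_adults)[1L]
    sz <- sz[seq_len(k)]
    sz[k] <- sz[k] - (cs[k] - n_adults)
    if (sz[k] == 0L) sz <- sz[-k]

    n_cl <- max(1L, round(n_adults / config$cluster_size))
    cl_of_hh <- sample(rep_len(seq_len(n_cl), length(sz)))
    hh_list[[i]] <- list(stratum_id = st$stratum_id, sizes = sz,
                         cluster_local = cl_of_hh, n_clusters = n_cl)
  }

  # assemble global ids
  cl_tabs <- lapply(hh_list, function(z)
    data.frame(cluster_id = sprintf("%s_c%03d", z$stratum_id,
                                    seq_len(z$n_clusters)),
               stratum_id = z$stratum_id, stringsAsFactors = FALSE))
  clusters <- do.call(rbind, cl_tabs)

  hh_tabs <- lapply(hh_list, function(z)
    data.frame(cluster_id = sprintf("%s_c%03d", z$stratum_id,
                                    z$cluster_local),
               stratum_id = z$stratum_id,
               size = z$sizes, stringsAsFactors = FALSE))
  households <- do.call(rbind, hh_tabs)
  households$household_id <- seq_len(nrow(households))

  n_tot <- sum(households$size)
  adults <- data.frame(
    person_id    = seq_len(n_tot),
    household_id = rep(households$household_id, households$size),
    cluster_id   = rep(households$cluster_id, households$size),
    stratum_id   = rep(households$stratum_id, households$size),
    stringsAsFactors = FALSE)
  adults$sex <- sample(names(config$sex_split), n_tot, replace = TRUE,
                       prob = config$sex_split)
  adults$age_group <- sample(config$age_groups, n_tot, replace = TRUE,
                             prob = config$age_probs)

  prev <- config$smoking_prevalence
  key <- paste(adults$stratum_id, adults$sex, adults$age_group, sep = "\r")
  pkey <- paste(prev$stratum_id, prev$sex, prev$age_group, sep = "\r")
  p_i <- prev$prevalence[match(key, pkey)]
  adults$is_smoker <- stats::runif(n_tot) < p_i

  for (a in names(config$attributes)) {
    pa <- config$attributes[[a]][adults$sex]
    adults[[a]] <- stats::runif(n_tot) < unname(pa)
  }
  adults$contact_propensity <- .draw_propensity(config$contact, adults$sex)
  adults$cooperation_propensity <- .draw_propensity(config$cooperation,
                                                    adults$sex)

  structure(list(strata = config$strata,
                 clusters = clusters,
                 households = households[, c("household_id", "cluster_id",
                                             "stratum_id", "size")],
                 adults = adults,
                 config = config,
                 seed = seed),
            class = "svy_population")
}

#' @export
print.svy_population <- function(x, ...) {
  cat("Synthetic population:",
      nrow(x$adults), "adults in",
      nrow(x$households), "households,",
      nrow(x$clusters), "clusters,",
      nrow(x$strata), "strata;",
      sum(x$adults$is_smoker), "smokers\n")
  invisible(x)
}

#' Exact smoker benchmark margins of a synthetic population
#'
#' Counts smokers in every (stratum, sex, age group) cell by direct
#' enumeration. The result is the ground-truth stand-in for an external
#' sociodemographic benchmark (population smoker counts by cell) that the
#' calibration step rakes survey weights towards.
#'
#' @param pop a [generate_population()] result.
#' @param source_label free-text provenance tag stored on the table.
#' @return data.frame with columns `stratum_id`, `sex`, `age_group`,
#'   `smokers` covering every cell (zeros included), classed
#'   `svy_benchmark`.
#' @export
true_margins <- function(pop, source_label = "synthetic population census") {
  stopifnot(inherits(pop, "svy_population"))
  ad <- pop$adults[pop$adults$is_smoker, ]
  grid <- expand.grid(stratum_id = pop$strata$stratum_id,
                      sex = names(pop$config$sex_split),
                      age_group = pop$config$age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$stratum_id, grid$sex, grid$age_group, sep = "\r")
  cnt <- table(paste(ad$stratum_id, ad$sex, ad$age_group, sep = "\r"))
  grid$smokers <- as.integer(cnt[key])
  grid$smokers[is.na(grid$smokers)] <- 0L
  grid <- grid[order(grid$stratum_id, grid$sex, grid$age_group), ]
  rownames(grid) <- NULL
  attr(grid, "source_label") <- source_label
  class(grid) <- c("svy_benchmark", "data.frame")
  grid
}

#' Write a population to CSV files
#'
#' Serialises the frame as `strata.csv`, `households.csv` and
#' `adults.csv` (UTF-8, comma-separated, header row, `.` decimal mark),
#' plus `benchmark.csv` holding [true_margins()].
#'
#' @param pop a `svy_population`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "svy_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("strata.csv", "households.csv", "adults.csv",
                            "benchmark.csv"))
  utils::write.csv(pop$strata, paths[1], row.names = FALSE)
  utils::write.csv(pop$households, paths[2], row.names = FALSE)
  utils::write.csv(pop$adults, paths[3], row.names = FALSE)
  utils::write.csv(as.data.frame(true_margins(pop)), paths[4],
                   row.names = FALSE)
  invisible(paths)
}
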