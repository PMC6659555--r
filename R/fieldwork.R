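#' Fieldwork design specification
#'
#' Parameters of the recruitment protocol: how many clusters to sample
#' per country, the per-stratum floor, the per-cluster quota of completed
#' smoker interviews, the systematic-walk step between approached
#' addresses, and the contact-attempt cap.
#'
#' @param clusters_total number of clusters sampled in the country.
#' @param min_clusters_per_stratum minimum clusters allocated to any
#'   stratum.
#' @param quota_per_cluster completed smoker interviews required per
#'   cluster.
#' @param walk_step every `walk_step`-th dwelling along the randomised
#'   route is approached.
#' @param max_contact_attempts contact attempts per dwelling before it is
#'   abandoned.
#' @param select_one_per_sex select (at most) one male and one female
#'   smoker per household; if `FALSE`, a single smoker is selected
#'   regardless of sex.
#' @param screener_refusal probability that a contacted household refuses
#'   the eligibility screener (eligibility undetermined). Default 0.
#' @param selection_refusal probability that an eligible household blocks
#'   member selection. Default 0.
#' @return An object of class `svy_design`.
#' @export
design_spec <- function(clusters_total = 100L,
                        min_clusters_per_stratum = 2L,
                        quota_per_cluster = 10L,
                        walk_step = 5L,
                        max_contact_attempts = 4L,
                        select_one_per_sex = TRUE,
                        screener_refusal = 0,
                        selection_refusal = 0) {
  stopifnot(quota_per_cluster >= 1, walk_step >= 1,
            max_contact_attempts >= 1,
            min_clusters_per_stratum >= 1,
            screener_refusal >= 0, screener_refusal <= 1,
            selection_refusal >= 0, selection_refusal <= 1)
  structure(list(clusters_total = as.integer(clusters_total),
                 min_clusters_per_stratum = as.integer(min_clusters_per_stratum),
                 quota_per_cluster = as.integer(quota_per_cluster),
                 walk_step = as.integer(walk_step),
                 max_contact_attempts = as.integer(max_contact_attempts),
                 select_one_per_sex = isTRUE(select_one_per_sex),
                 screener_refusal = screener_refusal,
                 selection_refusal = selection_refusal),
            class = "svy_design")
}

#' Allocate clusters to strata proportionally with a floor
#'
#' Largest-remainder proportional allocation of `clusters_total` clusters
#' to strata by adult population, subject to every stratum receiving at
#' least `min_clusters_per_stratum`. Strata whose proportional share
#' falls below the floor are fixed at the floor and the remainder is
#' re-allocated proportionally among the rest.
#'
#' @param strata data.frame with `stratum_id` and `adult_population`.
#' @param design a [design_spec()].
#' @return Named integer vector, one count per stratum, summing to
#'   `clusters_total`.
#' @export
allocate_clusters <- function(strata, design) {
  n <- nrow(strata)
  if (design$clusters_total < design$min_clusters_per_stratum * n)
    stop("configuration error: clusters_total (", design$clusters_total,
         ") cannot satisfy a floor of ", design$min_clusters_per_stratum,
         " clusters in each of ", n, " strata")
  pop <- as.numeric(strata$adult_population)
  alloc <- integer(n)
  remaining <- seq_len(n)
  left <- design$clusters_total
  repeat {
    a <- .largest_remainder(pop[remaining], left)
    low <- a < design$min_clusters_per_stratum
    if (!any(low)) {
      alloc[remaining] <- a
      break
    }
    fix <- remaining[low]
    alloc[fix] <- design$min_clusters_per_stratum
    left <- left - design$min_clusters_per_stratum * length(fix)
    remaining <- remaining[!low]
    if (!length(remaining)) break
  }
  stats::setNames(alloc, strata$stratum_id)
}

# Hamilton / largest-remainder apportionment of `total` seats to shares.
.largest_remainder <- function(pop, total) {
  q <- total * pop / sum(pop)
  a <- floor(q)
  r <- total - sum(a)
  if (r > 0) {
    # ties on remainder broken toward the larger population, then index
    ord <- order(q - a, pop, decreasing = TRUE)
    a[ord[seq_len(r)]] <- a[ord[seq_len(r)]] + 1
  }
  as.integer(a)
}

#' Within-household respondent selection
#'
#' Selects interviewees among the eligible adult smokers of one household
#' by the next-birthday rule: among same-sex candidates every smoker is
#' equally likely (birthdays are uniform over the year), so the rule is
#' modelled as a uniform random draw of one smoker per sex. A household
#' with a single smoker of a given sex always yields that smoker.
#'
#' @param smokers data.frame of the household's adult smokers with
#'   columns `person_id` and `sex` (possibly zero rows).
#' @param one_per_sex if `FALSE`, one smoker overall is drawn instead of
#'   one per sex.
#' @return Vector of selected `person_id`s (empty when no smokers).
#' @export
select_in_household <- function(smokers, one_per_sex = TRUE) {
  if (NROW(smokers) == 0L) return(smokers$person_id[0])
  if (!one_per_sex) {
    ids <- smokers$person_id
    return(ids[sample.int(length(ids), 1L)])
  }
  out <- lapply(split(smokers$person_id, smokers$sex), function(ids)
    ids[sample.int(length(ids), 1L)])
  unlist(out, use.names = FALSE)
}

#' Simulate one country's fieldwork
#'
#' Runs the recruitment protocol on a synthetic population: clusters are
#' allocated to strata and drawn by simple random sampling within each
#' stratum; within a cluster the dwellings are randomly permuted (the
#' randomised walk route) and every `walk_step`-th dwelling from a random
#' start is approached; contact succeeds with the household's contact
#' propensity on any of `max_contact_attempts` tries; a screener records
#' the exact counts of male and female adult smokers; one smoker per sex
#' is selected by [select_in_household()]; each selected smoker completes
#' the interview with their cooperation propensity, refusals are never
#' substituted within the household; the cluster stops at
#' `quota_per_cluster` completed interviews or when its route is
#' exhausted (a quota shortfall is recorded and a warning summarised).
#' All fieldwork outcomes are tallied into the standard disposition
#' counts.
#'
#' @param pop a [generate_population()] result.
#' @param design a [design_spec()].
#' @param seed integer seed for the fieldwork randomness (independent of
#'   the population seed).
#' @return An object of class `svy_fieldsample`: list with `respondents`
#'   (one row per completed interview, including
#'   `same_sex_smokers_in_household` and the smoker attribute columns),
#'   `dispositions` ([disposition_counts()]), `cluster_allocation`,
#'   `sampled_clusters`, `completed_per_cluster`, `quota_shortfall`, and
#'   `seed`.
#' @export
run_fieldwork <- function(pop, design, seed) {
  stopifnot(inherits(pop, "svy_population"), inherits(design, "svy_design"))
  seed <- as.integer(seed)
  set.seed(seed)

  alloc <- allocate_clusters(pop$strata, design)

  # sample clusters SRS within stratum
  cl_by_str <- split(pop$clusters$cluster_id, pop$clusters$stratum_id)
  sampled <- lapply(pop$strata$stratum_id, function(h) {
    avail <- cl_by_str[[h]]
    n_h <- alloc[[h]]
    if (length(avail) < n_h) {
      warning("stratum ", h, " has only ", length(avail),
              " frame clusters for an allocation of ", n_h)
      n_h <- length(avail)
    }
    avail[sample.int(length(avail), n_h)]
  })
  sampled_clusters <- data.frame(
    cluster_id = unlist(sampled, use.names = FALSE),
    stratum_id = rep(pop$strata$stratum_id, lengths(sampled)),
    stringsAsFactors = FALSE)

  # fast per-household lookups
  ad <- pop$adults
  H <- nrow(pop$households)
  sm <- ad$is_smoker
  hm_tab <- table(factor(ad$household_id[sm & ad$sex == "male"],
                         levels = seq_len(H)))
  hf_tab <- table(factor(ad$household_id[sm & ad$sex == "female"],
                         levels = seq_len(H)))
  n_male <- as.integer(hm_tab)
  n_female <- as.integer(hf_tab)
  male_ids <- .split_by_household(ad$person_id[sm & ad$sex == "male"],
                                  ad$household_id[sm & ad$sex == "male"], H)
  female_ids <- .split_by_household(ad$person_id[sm & ad$sex == "female"],
                                    ad$household_id[sm & ad$sex == "female"],
                                    H)
  # household contact propensity: the most reachable member answers
  hh_contact <- rep(0, H)
  agg <- tapply(ad$contact_propensity, ad$household_id, max)
  hh_contact[as.integer(names(agg))] <- as.numeric(agg)
  coop <- ad$cooperation_propensity        # indexed by person_id
  sex_of <- ad$sex
  hh_of_cluster <- .split_by_key(pop$households$household_id,
                                 pop$households$cluster_id)

  p_contact <- 1 - (1 - hh_contact)^design$max_contact_attempts

  d <- c(addresses_attempted = 0, addresses_contacted = 0,
         eligibility_determined = 0, no_eligible = 0, with_eligible = 0,
         households_with_selection = 0, individuals_selected = 0,
         individual_refusals = 0, completed_interviews = 0)

  n_cl <- nrow(sampled_clusters)
  cap <- design$quota_per_cluster * n_cl * 2L
  r_pid <- integer(cap); r_hh <- integer(cap); r_cl <- character(cap)
  r_str <- character(cap); r_k <- integer(cap)
  n_resp <- 0L
  completed_per_cluster <- stats::setNames(integer(n_cl),
                                           sampled_clusters$cluster_id)

  for (ci in seq_len(n_cl)) {
    cl <- sampled_clusters$cluster_id[ci]
    hhs <- hh_of_cluster[[cl]]
    route <- hhs[sample.int(length(hhs))]
    start <- sample.int(design$walk_step, 1L)
    if (start > length(route)) next
    approach <- route[seq.int(start, length(route), by = design$walk_step)]
    done <- 0L
    for (h in approach) {
      d[["addresses_attempted"]] <- d[["addresses_attempted"]] + 1
      if (stats::runif(1) >= p_contact[h]) next
      d[["addresses_contacted"]] <- d[["addresses_contacted"]] + 1
      if (design$screener_refusal > 0 &&
          stats::runif(1) < design$screener_refusal) next
      d[["eligibility_determined"]] <- d[["eligibility_determined"]] + 1
      km <- n_male[h]; kf <- n_female[h]
      if (km + kf == 0L) {
        d[["no_eligible"]] <- d[["no_eligible"]] + 1
        next
      }
      d[["with_eligible"]] <- d[["with_eligible"]] + 1
      if (design$selection_refusal > 0 &&
          stats::runif(1) < design$selection_refusal) next
      d[["households_with_selection"]] <-
        d[["households_with_selection"]] + 1
      if (design$select_one_per_sex) {
        sel <- integer(0)
        if (km > 0L) sel <- male_ids[[h]][sample.int(km, 1L)]
        if (kf > 0L) sel <- c(sel, female_ids[[h]][sample.int(kf, 1L)])
      } else {
        all_ids <- c(male_ids[[h]], female_ids[[h]])
        sel <- all_ids[sample.int(length(all_ids), 1L)]
      }
      d[["individuals_selected"]] <- d[["individuals_selected"]] +
        length(sel)
      for (pid in sel) {
        if (done >= design$quota_per_cluster) next  # quota already met
        if (stats::runif(1) < coop[pid]) {
          d[["completed_interviews"]] <- d[["completed_interviews"]] + 1
          done <- done + 1L
          n_resp <- n_resp + 1L
          r_pid[n_resp] <- pid
          r_hh[n_resp] <- h
          r_cl[n_resp] <- cl
          r_str[n_resp] <- sampled_clusters$stratum_id[ci]
          r_k[n_resp] <- if (sex_of[pid] == "male") km else kf
        } else {
          d[["individual_refusals"]] <- d[["individual_refusals"]] + 1
        }
      }
      if (done >= design$quota_per_cluster) break
    }
    completed_per_cluster[ci] <- done
  }

  shortfall <- completed_per_cluster[completed_per_cluster <
                                       design$quota_per_cluster]
  if (length(shortfall))
    warning(length(shortfall), " cluster(s) exhausted their route before ",
            "meeting the quota of ", design$quota_per_cluster,
            " interviews")

  idx <- seq_len(n_resp)
  respondents <- data.frame(person_id = r_pid[idx],
                            household_id = r_hh[idx],
                            cluster_id = r_cl[idx],
                            stratum_id = r_str[idx],
                            stringsAsFactors = FALSE)
  keep <- c("sex", "age_group", names(pop$config$attributes))
  respondents <- cbind(respondents,
                       ad[match(respondents$person_id, ad$person_id), keep,
                          drop = FALSE])
  respondents$same_sex_smokers_in_household <- r_k[idx]
  respondents$interview_complete <- rep(TRUE, n_resp)
  rownames(respondents) <- NULL

  structure(list(respondents = respondents,
                 dispositions = disposition_counts(d),
                 cluster_allocation = alloc,
                 sampled_clusters = sampled_clusters,
                 completed_per_cluster = completed_per_cluster,
                 quota_shortfall = shortfall,
                 design = design,
                 seed = seed),
            class = "svy_fieldsample")
}

#' @export
print.svy_fieldsample <- function(x, ...) {
  cat("Field sample:", nrow(x$respondents), "completed interviews in",
      nrow(x$sampled_clusters), "clusters;",
      length(x$quota_shortfall), "cluster(s) under quota\n")
  invisible(x)
}

# split ids by integer household, returning an O(1)-indexable list of
# length H (NULL where a household has no entries)
.split_by_household <- function(ids, hh, H) {
  out <- vector("list", H)
  if (length(ids)) {
    sp <- split(ids, hh)
    out[as.integer(names(sp))] <- sp
  }
  out
}

.split_by_key <- function(values, keys) split(values, keys)
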