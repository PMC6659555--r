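#' Fieldwork disposition counts
#'
#' The nine raw fieldwork-accounting tallies for one country, validated
#' against their internal consistency rules:
#' contacted <= attempted; determined <= contacted;
#' no_eligible + with_eligible = determined; selection happens only in
#' eligible households; between one and two individuals per selecting
#' household (one per sex); completions plus refusals never exceed
#' selections.
#'
#' @param counts named numeric vector (or list) with entries
#'   `addresses_attempted`, `addresses_contacted`,
#'   `eligibility_determined`, `no_eligible`, `with_eligible`,
#'   `households_with_selection`, `individuals_selected`,
#'   `individual_refusals`, `completed_interviews`.
#' @param check validate the invariants (default `TRUE`).
#' @return Named numeric vector of class `svy_dispositions`.
#' @export
disposition_counts <- function(counts, check = TRUE) {
  counts <- unlist(counts)
  if (!all(disposition_fields %in% names(counts)))
    stop("missing disposition field(s): ",
         paste(setdiff(disposition_fields, names(counts)), collapse = ", "))
  d <- counts[disposition_fields]
  if (check) validate_dispositions(d)
  structure(d, class = "svy_dispositions")
}

#' @rdname disposition_counts
#' @export
disposition_fields <- c(
  "addresses_attempted", "addresses_contacted", "eligibility_determined",
  "no_eligible", "with_eligible", "households_with_selection",
  "individuals_selected", "individual_refusals", "completed_interviews")

#' Validate disposition-count invariants
#'
#' @param d named counts (see [disposition_counts()]).
#' @return Invisibly `TRUE`; stops with a message naming the violated
#'   rule otherwise.
#' @export
validate_dispositions <- function(d) {
  g <- function(f) as.numeric(d[[f]])
  if (any(unlist(d[disposition_fields]) < 0))
    stop("disposition counts must be non-negative")
  if (g("addresses_contacted") > g("addresses_attempted"))
    stop("contacted addresses exceed attempted addresses")
  if (g("eligibility_determined") > g("addresses_contacted"))
    stop("eligibility determinations exceed contacted addresses")
  if (g("no_eligible") + g("with_eligible") != g("eligibility_determined"))
    stop("no_eligible + with_eligible must equal eligibility_determined")
  if (g("households_with_selection") > g("with_eligible"))
    stop("selecting households exceed eligible households")
  if (g("individuals_selected") < g("households_with_selection"))
    stop("fewer individuals selected than selecting households")
  if (g("individuals_selected") > 2 * g("households_with_selection"))
    stop("more than two individuals selected per selecting household")
  if (g("completed_interviews") + g("individual_refusals") >
      g("individuals_selected"))
    stop("completions plus refusals exceed selections")
  invisible(TRUE)
}

#' Round half away from zero
#'
#' Commercial (half-up) rounding, the convention under which the derived
#' outcome rates reproduce their printed reference values; base R's
#' [round()] rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derived fieldwork outcome rates
#'
#' Computes the seven derived quantities of the standard outcome-rate
#' table from the nine raw disposition counts, at full precision:
#' \describe{
#'   \item{eligibility_rate}{eligible households / households with
#'     eligibility determined}
#'   \item{estimated_eligible_households}{eligibility_rate x attempted
#'     addresses — eligibles imputed among addresses whose eligibility
#'     was never determined}
#'   \item{household_contact_rate}{contacted / attempted}
#'   \item{household_cooperation_rate}{selecting households / eligible
#'     households}
#'   \item{household_response_rate}{selecting households / estimated
#'     eligible households (unrounded denominator)}
#'   \item{individual_cooperation_rate}{completed / (completed +
#'     refusals)}
#'   \item{individual_response_rate}{completed / selected}
#' }
#' Reporting (see [rates_report()]) rounds rates half-up to 3 decimals
#' and the estimated eligible count half-up to an integer; all chained
#' quantities use the unrounded values.
#'
#' @param d a [disposition_counts()] record.
#' @return Named numeric vector of class `svy_rates`; a rate whose
#'   denominator is zero is returned as `NA` and listed in the
#'   `"undefined"` attribute rather than raising an error.
#' @export
compute_rates <- function(d) {
  d <- disposition_counts(d)
  g <- function(f) as.numeric(d[[f]])
  ratio <- function(num, den) if (den > 0) num / den else NA_real_

  elig  <- ratio(g("with_eligible"), g("eligibility_determined"))
  est   <- if (is.na(elig)) NA_real_ else elig * g("addresses_attempted")
  out <- c(
    eligibility_rate = elig,
    estimated_eligible_households = est,
    household_contact_rate =
      ratio(g("addresses_contacted"), g("addresses_attempted")),
    household_cooperation_rate =
      ratio(g("households_with_selection"), g("with_eligible")),
    household_response_rate =
      if (is.na(est)) NA_real_
      else ratio(g("households_with_selection"), est),
    individual_cooperation_rate =
      ratio(g("completed_interviews"),
            g("completed_interviews") + g("individual_refusals")),
    individual_response_rate =
      ratio(g("completed_interviews"), g("individuals_selected")))
  structure(out, undefined = names(out)[is.na(out)], class = "svy_rates")
}

#' @export
print.svy_rates <- function(x, ...) {
  y <- stats::setNames(as.numeric(x), names(unclass(x)))
  y["estimated_eligible_households"] <-
    round_half_up(y["estimated_eligible_households"])
  rates <- setdiff(names(y), "estimated_eligible_households")
  y[rates] <- round_half_up(y[rates], 3)
  print(y)
  if (length(attr(x, "undefined")))
    cat("undefined (zero denominator):",
        paste(attr(x, "undefined"), collapse = ", "), "\n")
  invisible(x)
}

# row order and printed labels of the 16-row outcome-rate table
.rate_table_rows <- data.frame(
  row = 1:16,
  field = c("addresses_attempted", "addresses_contacted",
            "eligibility_determined", "no_eligible", "with_eligible",
            "households_with_selection", "eligibility_rate",
            "estimated_eligible_households", "individuals_selected",
            "individual_refusals", "completed_interviews",
            "household_contact_rate", "household_cooperation_rate",
            "household_response_rate", "individual_cooperation_rate",
            "individual_response_rate"),
  label = c(
    "Number of addresses approached/attempted",
    "Number of addresses where contact was made",
    "Number of contacted addresses with eligibility determined",
    "Number of contacted addresses with no eligible respondents",
    "Number of contacted addresses with eligible respondents",
    "Number of addresses with eligible respondents, members selected",
    "Eligibility rate for households, given determination of eligibility (5./3.)",
    "Estimated eligible households among attempted (7.*1.)",
    "Number of individuals selected for interview",
    "Number of individual refusals or break offs",
    "Number of completed interviews",
    "Household contact rate (2./1.)",
    "Household cooperation rate, given eligible (6./5.)",
    "Household response rate (6./8.)",
    "Individual cooperation rate (11./(11.+10.))",
    "Individual response rate, given selection (11./9.)"),
  stringsAsFactors = FALSE)

#' Full 16-row outcome-rate report
#'
#' Assembles raw dispositions and derived rates for one or more
#' countries into the standard 16-row table (raw counts rows 1--6 and
#' 9--11 echoed unchanged; derived rows 7, 8, 12--16 rounded half-up,
#' rates to 3 decimals and row 8 to the nearest integer). The table
#' round-trips losslessly through CSV.
#'
#' @param dlist named list of [disposition_counts()] records; names are
#'   the country labels (duplicates are an error).
#' @return data.frame with columns `row`, `label` and one numeric column
#'   per country.
#' @export
rates_report <- function(dlist) {
  if (length(dlist) < 1L) stop("at least one country is required")
  if (is.null(names(dlist)) || anyDuplicated(names(dlist)) ||
      any(!nzchar(names(dlist))))
    stop("dlist must carry unique, non-empty country labels")
  out <- .rate_table_rows[, c("row", "label")]
  for (country in names(dlist)) {
    d <- disposition_counts(dlist[[country]])
    r <- compute_rates(d)
    v <- numeric(16)
    raw <- .rate_table_rows$field[c(1:6, 9:11)]
    v[c(1:6, 9:11)] <- as.numeric(d[raw])
    v[7]  <- round_half_up(r[["eligibility_rate"]], 3)
    v[8]  <- round_half_up(r[["estimated_eligible_households"]])
    v[12] <- round_half_up(r[["household_contact_rate"]], 3)
    v[13] <- round_half_up(r[["household_cooperation_rate"]], 3)
    v[14] <- round_half_up(r[["household_response_rate"]], 3)
    v[15] <- round_half_up(r[["individual_cooperation_rate"]], 3)
    v[16] <- round_half_up(r[["individual_response_rate"]], 3)
    out[[country]] <- v
  }
  out
}

#' Packaged six-country disposition fixture
#'
#' Raw Wave-1 fieldwork disposition counts (rows 1--6 and 9--11 of the
#' outcome-rate table) for the six-country European smoker survey the
#' package's worked examples reproduce: Germany, Greece, Hungary,
#' Poland, Romania, Spain.
#'
#' @return Named list of [disposition_counts()] records, one per
#'   country.
#' @export
six_country_dispositions <- function() {
  path <- system.file("extdata", "six_country_dispositions.csv",
                      package = "svysmoke", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  countries <- setdiff(names(tab), c("row", "field", "label"))
  out <- lapply(countries, function(cc)
    disposition_counts(stats::setNames(tab[[cc]], tab$field)))
  stats::setNames(out, countries)
}

#' Packaged six-country completed sample sizes
#'
#' Total interviewed respondents per country as released with the survey
#' (these can differ by a respondent or two from the fieldwork
#' disposition tallies; [check_fixture_consistency()] surfaces the
#' discrepancy as a warning).
#'
#' @return data.frame with columns `country`, `sample_size`.
#' @export
six_country_sample_sizes <- function() {
  path <- system.file("extdata", "six_country_sample_sizes.csv",
                      package = "svysmoke", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Cross-check the packaged fixtures
#'
#' Validates every country's disposition invariants and compares the
#' disposition completed-interview counts against the released sample
#' sizes, warning (not failing) on any cross-table discrepancy.
#'
#' @return Invisibly `TRUE`.
#' @export
check_fixture_consistency <- function() {
  disp <- six_country_dispositions()
  for (cc in names(disp)) validate_dispositions(disp[[cc]])
  sizes <- six_country_sample_sizes()
  for (cc in names(disp)) {
    n_rel <- sizes$sample_size[sizes$country == cc]
    n_disp <- as.numeric(disp[[cc]][["completed_interviews"]])
    if (length(n_rel) == 1L && n_rel != n_disp)
      warning("cross-table discrepancy for ", cc,
              ": released sample size ", n_rel,
              " vs disposition completed interviews ", n_disp)
  }
  invisible(TRUE)
}
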