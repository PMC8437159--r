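# Descriptive surfaces: site-stratified characteristic and price/food-security
# frequency tables, per-group consumption-change summaries, and before/during
# score summaries. Percentages always use the non-missing denominator for the
# variable within the stratum (the only rule under which the published
# percentages recompute from their own counts), rounded half-up to 1 decimal.

# internal: tabulate one categorical variable across overall + site strata
tabulate_variable <- function(records, variable, categories) {
  strata <- c("overall", unique(records$site[!is.na(records$site)]))
  out <- list()
  for (st in strata) {
    x <- if (st == "overall") records[[variable]]
         else records[[variable]][!is.na(records$site) & records$site == st]
    den <- sum(!is.na(x))
    for (cat in categories) {
      cnt <- sum(!is.na(x) & x == cat)
      out[[paste(st, cat)]] <- data.frame(
        variable = variable, category = cat, stratum = st, count = cnt,
        denominator = den,
        pct = if (den > 0) round_half_up(100 * cnt / den, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Site-stratified household characteristics table
#'
#' Counts and percentages per category of the socio-demographic variables
#' (overall and per site), plus mean and SD of household size. Percentages
#' use the variable's non-missing denominator within the stratum.
#'
#' @param records survey data.frame.
#' @return list with `frequencies` (data.frame: `variable`, `category`,
#'   `stratum`, `count`, `denominator`, `pct`) and `continuous` (data.frame:
#'   `variable`, `stratum`, `n`, `mean`, `sd`).
#' @export
characteristics_table <- function(records) {
  if (!nrow(records))
    abort("characteristics_table needs at least one record",
          "dietshock_spec_error")
  schema <- survey_schema()
  vars <- c("respondent_sex", "age_band", "education", "head_of_household",
            "occupation", "locality")
  freq <- do.call(rbind, lapply(vars, function(v) {
    levels <- strsplit(schema$levels[schema$column == v], ",")[[1]]
    tabulate_variable(records, v, levels)
  }))
  rownames(freq) <- NULL
  strata <- c("overall", unique(records$site[!is.na(records$site)]))
  cont <- do.call(rbind, lapply(strata, function(st) {
    x <- if (st == "overall") records$household_size
         else records$household_size[!is.na(records$site) &
                                       records$site == st]
    data.frame(variable = "household_size", stratum = st, n = sum(!is.na(x)),
               mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(frequencies = freq, continuous = cont)
}

#' Price-change and food-security frequency table
#'
#' Unchanged/decreased/increased counts and percentages for each of the five
#' food-price categories, yes/no for the three food-insecurity items and
#' social assistance, and the four crop-production levels — per site and
#' overall, with non-missing denominators.
#'
#' @param records survey data.frame.
#' @return data.frame as in [characteristics_table()]'s `frequencies`.
#' @export
price_change_table <- function(records) {
  price_vars <- paste0("price_", c("staples", "pulses", "fruits",
                                   "vegetables", "asf"))
  out <- lapply(price_vars, function(v)
    tabulate_variable(records, v, c("unchanged", "decreased", "increased")))
  for (v in c("worried_food", "skipped_meal", "whole_day_no_food",
              "social_assistance"))
    out[[v]] <- tabulate_variable(records, v, c("no", "yes"))
  out$crop <- tabulate_variable(records, "crop_production",
                                c("unchanged", "decreased", "increased",
                                  "does_not_farm"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-group consumption-change summary (before vs during)
#'
#' For each score group and stratum: the percentage of households whose
#' aggregated days decreased, stayed unchanged, or increased between the two
#' recall periods, among households with the group observed in both periods.
#' Site food-group masks apply.
#'
#' @param records survey data.frame.
#' @param grouping `"mddw"` or `"pdqs"`.
#' @param cb codebook.
#' @param options scoring options.
#' @return data.frame: `group`, `stratum`, `n` (both-period denominator),
#'   `pct_decreased`, `pct_unchanged`, `pct_increased`.
#' @export
consumption_change_summary <- function(records, grouping = c("mddw", "pdqs"),
                                       cb = default_codebook(),
                                       options = scoring_options()) {
  grouping <- match.arg(grouping)
  sites <- unique(records$site[!is.na(records$site)])
  per_site <- list()
  for (site in sites) {
    idx <- which(!is.na(records$site) & records$site == site)
    masked <- site_mask(cb, site)
    rb <- score_core(as.matrix(records[idx, fg_columns(cb, "before")]),
                     cb, masked, options)
    rd <- score_core(as.matrix(records[idx, fg_columns(cb, "during")]),
                     cb, masked, options)
    B <- if (grouping == "mddw") rb$mddw_days else rb$pdqs_servings
    D <- if (grouping == "mddw") rd$mddw_days else rd$pdqs_servings
    per_site[[site]] <- list(B = B, D = D)
  }
  groups <- colnames(per_site[[1]]$B)
  strata <- c("overall", sites)
  out <- list()
  for (st in strata) {
    use <- if (st == "overall") sites else st
    B <- do.call(rbind, lapply(per_site[use], `[[`, "B"))
    D <- do.call(rbind, lapply(per_site[use], `[[`, "D"))
    for (g in groups) {
      ok <- !is.na(B[, g]) & !is.na(D[, g])
      n <- sum(ok)
      pc <- function(cond) if (n > 0) round_half_up(100 * sum(cond[ok]) / n, 1)
                           else NA_real_
      out[[paste(st, g)]] <- data.frame(
        group = g, stratum = st, n = n,
        pct_decreased = pc(D[, g] < B[, g]),
        pct_unchanged = pc(D[, g] == B[, g]),
        pct_increased = pc(D[, g] > B[, g]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Before/during score summaries per site
#'
#' DDS summarized as mean and SD, PDQS as median and interquartile range,
#' per site and overall for both recall periods — the published reporting
#' convention. Requires scored records ([score_survey()]); incomplete
#' periods (NA scores) are excluded from the summaries.
#'
#' @param records scored survey data.frame.
#' @return data.frame: `stratum`, `period`, `n_dds`, `dds_mean`, `dds_sd`,
#'   `n_pdqs`, `pdqs_median`, `pdqs_q1`, `pdqs_q3`.
#' @export
mean_scores_before_during <- function(records) {
  if (!all(c("dds_before", "dds_during", "pdqs_before", "pdqs_during") %in%
           names(records)))
    abort("records are not scored; run score_survey() first",
          "dietshock_spec_error")
  strata <- c("overall", unique(records$site[!is.na(records$site)]))
  out <- list()
  for (st in strata) for (period in c("before", "during")) {
    sel <- if (st == "overall") rep(TRUE, nrow(records))
           else !is.na(records$site) & records$site == st
    dds <- records[[paste0("dds_", period)]][sel]
    pdqs <- records[[paste0("pdqs_", period)]][sel]
    q <- stats::quantile(pdqs, c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE, type = 2)
    out[[paste(st, period)]] <- data.frame(
      stratum = st, period = period,
      n_dds = sum(!is.na(dds)),
      dds_mean = mean(dds, na.rm = TRUE), dds_sd = stats::sd(dds, na.rm = TRUE),
      n_pdqs = sum(!is.na(pdqs)),
      pdqs_median = q[2], pdqs_q1 = q[1], pdqs_q3 = q[3],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
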