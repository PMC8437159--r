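#' Scoring options for DDS and PDQS
#'
#' @param dds_days_threshold days of consumption required for an MDD-W group
#'   to count toward the DDS. The instrument records days out of the past 7
#'   and a group counts when eaten at least once each day, i.e. days/7 >= 1,
#'   which with whole days forces `7`. The threshold is exposed so a
#'   sensitivity variant (e.g. >= 1 day) is a single option change.
#' @param aggregator how days from several survey groups feeding one score
#'   group are combined: `"max"` (default; a day is counted once however many
#'   constituent groups were eaten that day) or `"sum_capped"` (sum, capped
#'   at 7).
#' @param completeness_threshold minimum fraction of unmasked survey groups
#'   that must be observed for a period's scores to be retained; below it the
#'   period is flagged incomplete and its scores set `NA`. Default 1 (any
#'   missing group disqualifies the period).
#' @return list of class `dietshock_scoring_options`.
#' @export
scoring_options <- function(dds_days_threshold = 7,
                            aggregator = c("max", "sum_capped"),
                            completeness_threshold = 1) {
  aggregator <- match.arg(aggregator)
  stopifnot(dds_days_threshold >= 0, dds_days_threshold <= 7,
            completeness_threshold >= 0, completeness_threshold <= 1)
  structure(list(dds_days_threshold = dds_days_threshold,
                 aggregator = aggregator,
                 completeness_threshold = completeness_threshold),
            class = "dietshock_scoring_options")
}

# internal: combine constituent survey-group day columns into one score-group
# day vector. "max" counts a day once however many constituents were eaten;
# "sum_capped" sums days and caps at 7. NA only when every constituent is NA.
aggregate_days <- function(sub, aggregator) {
  if (aggregator == "max") {
    do.call(pmax, c(unname(as.data.frame(sub)), list(na.rm = TRUE)))
  } else {
    all_na <- rowSums(!is.na(sub)) == 0L
    agg <- pmin(7, rowSums(sub, na.rm = TRUE))
    agg[all_na] <- NA_real_
    agg
  }
}

# internal vectorized core. D: n x 20 integer matrix of days, columns in
# codebook survey-group order. masked: character vector of masked survey-group
# ids (one mask for all rows). Returns mddw day matrix, DDS, PDQS, per-group
# pieces, and completeness (no NA among unmasked survey groups).
score_core <- function(D, cb, masked = character(0),
                       options = scoring_options()) {
  sg <- cb$survey_groups
  stopifnot(ncol(D) == nrow(sg))
  colnames(D) <- sg$id
  unmasked <- !(sg$id %in% masked)
  frac_observed <- rowMeans(!is.na(D[, unmasked, drop = FALSE]))
  complete <- frac_observed >= options$completeness_threshold

  # ---- MDD-W ----
  mddw_ids <- cb$mddw_groups$id
  n <- nrow(D)
  mddw_days <- matrix(NA_real_, n, length(mddw_ids),
                      dimnames = list(NULL, mddw_ids))
  mddw_masked <- masked_mddw_groups(cb, masked)
  for (g in mddw_ids) {
    members <- sg$id[sg$mddw_group == g & unmasked]
    if (!length(members)) next  # fully masked group: stays NA, contributes 0
    mddw_days[, g] <- aggregate_days(D[, members, drop = FALSE],
                                     options$aggregator)
  }
  dds_contrib <- (mddw_days >= options$dds_days_threshold) * 1L
  dds_contrib[, mddw_ids %in% mddw_masked] <- 0L
  dds <- as.integer(rowSums(dds_contrib, na.rm = TRUE))

  # ---- PDQS ----
  pdqs_ids <- sg$pdqs_group
  S <- matrix(NA_real_, n, length(unique(pdqs_ids)),
              dimnames = list(NULL, unique(pdqs_ids)))
  for (g in colnames(S)) {
    members <- sg$id[sg$pdqs_group == g & unmasked]
    if (!length(members)) next
    S[, g] <- aggregate_days(D[, members, drop = FALSE], options$aggregator)
  }
  healthy <- sg$pdqs_healthy[match(colnames(S), sg$pdqs_group)]
  pts <- matrix(NA_integer_, n, ncol(S), dimnames = dimnames(S))
  for (j in seq_len(ncol(S))) {
    s <- S[, j]
    p <- if (healthy[j]) ifelse(s <= 1, 0L, ifelse(s <= 3, 1L, 2L))
         else            ifelse(s <= 1, 2L, ifelse(s <= 3, 1L, 0L))
    pts[, j] <- p
  }
  # a PDQS group is masked when all its constituent survey groups are masked
  group_masked <- vapply(colnames(S), function(g) {
    members <- sg$id[sg$pdqs_group == g]
    all(members %in% masked)
  }, logical(1))
  pts[, group_masked] <- 0L
  pdqs <- as.integer(rowSums(pts, na.rm = TRUE))
  pdqs_max <- 2L * sum(!group_masked)

  list(mddw_days = mddw_days, dds_contrib = dds_contrib, dds = dds,
       pdqs_servings = S, pdqs_points = pts, pdqs = pdqs,
       pdqs_max = pdqs_max, mddw_masked = mddw_masked,
       pdqs_masked = colnames(S)[group_masked], complete = complete)
}

# internal: named 20-vector of days -> 1 x 20 matrix in codebook order
days_to_matrix <- function(days, cb) {
  ids <- cb$survey_groups$id
  miss <- setdiff(ids, names(days))
  if (length(miss))
    abort(paste0("food-frequency vector lacks survey group(s): ",
                 paste(miss, collapse = ", ")), "dietshock_codebook_error")
  extra <- setdiff(names(days), ids)
  if (length(extra))
    abort(paste0("unknown survey group(s): ", paste(extra, collapse = ", ")),
          "dietshock_codebook_error")
  matrix(as.numeric(days[ids]), nrow = 1, dimnames = list(NULL, ids))
}

#' Map survey food-group days onto the 10 MDD-W groups
#'
#' Aggregates the 20 survey groups' days-consumed into the 10 MDD-W dietary
#' diversity groups. Groups with the codebook target `"none"` (oils,
#' sugar-sweetened beverages, sweets) do not feed any MDD-W group.
#'
#' @param days named numeric vector: days consumed (0-7) per survey group id.
#' @param cb codebook.
#' @param masked survey-group ids masked at the household's site.
#' @param options scoring options (aggregator).
#' @return named numeric vector of length 10 (days per MDD-W group), with
#'   attribute `"excluded"` listing MDD-W groups fully masked at this site.
#' @export
map_to_mddw_groups <- function(days, cb = default_codebook(),
                               masked = character(0),
                               options = scoring_options()) {
  res <- score_core(days_to_matrix(days, cb), cb, masked, options)
  out <- res$mddw_days[1, ]
  attr(out, "excluded") <- res$mddw_masked
  out
}

#' Compute the dietary diversity score (DDS)
#'
#' Counts the MDD-W groups consumed at or above the daily-consumption
#' threshold; range 0-10 (less for sites with masked groups; the score is not
#' rescaled).
#'
#' @param mddw_days named vector from [map_to_mddw_groups()].
#' @param masked MDD-W group ids excluded at this site.
#' @param options scoring options (threshold).
#' @return list with `dds` (integer) and `contributions` (named 0/1 vector,
#'   `NA` where the group's days are unobserved).
#' @export
compute_dds <- function(mddw_days, masked = character(0),
                        options = scoring_options()) {
  contrib <- (as.numeric(mddw_days) >= options$dds_days_threshold) * 1L
  names(contrib) <- names(mddw_days)
  contrib[names(contrib) %in% masked] <- 0L
  list(dds = as.integer(sum(contrib, na.rm = TRUE)), contributions = contrib)
}

#' Map survey food-group days onto the 20 PDQS groups
#'
#' Weekly servings are proxied by days consumed (the recall collects days,
#' not servings). The shipped codebook's survey groups coincide with the
#' adapted PDQS groups, so the default mapping is one-to-one; the aggregator
#' still applies if a custom codebook maps several survey groups to one PDQS
#' group.
#'
#' @inheritParams map_to_mddw_groups
#' @return named numeric vector of weekly servings per PDQS group, with
#'   attribute `"healthy"` (named logical) and `"excluded"`.
#' @export
map_to_pdqs_groups <- function(days, cb = default_codebook(),
                               masked = character(0),
                               options = scoring_options()) {
  res <- score_core(days_to_matrix(days, cb), cb, masked, options)
  out <- res$pdqs_servings[1, ]
  attr(out, "healthy") <-
    stats::setNames(cb$survey_groups$pdqs_healthy[
      match(names(out), cb$survey_groups$pdqs_group)], names(out))
  attr(out, "excluded") <- res$pdqs_masked
  out
}

#' Compute the Prime Diet Quality Score (PDQS)
#'
#' Healthy groups score 0 points for 0-1 servings/week, 1 point for 2-3 and
#' 2 points for >= 4; unhealthy groups score the reverse (2 points for 0-1,
#' 1 for 2-3, 0 for >= 4). The unmasked range is 0-40; masked groups
#' contribute 0 and shrink the attainable maximum (no rescaling).
#'
#' @param servings named vector from [map_to_pdqs_groups()].
#' @param cb codebook.
#' @param masked PDQS group ids excluded at this site.
#' @return list with `pdqs` (integer), `points` (named vector, `NA` where
#'   unobserved) and `max_attainable`.
#' @export
compute_pdqs <- function(servings, cb = default_codebook(),
                         masked = character(0)) {
  healthy <- cb$survey_groups$pdqs_healthy[
    match(names(servings), cb$survey_groups$pdqs_group)]
  s <- as.numeric(servings)
  pts <- ifelse(healthy,
                ifelse(s <= 1, 0L, ifelse(s <= 3, 1L, 2L)),
                ifelse(s <= 1, 2L, ifelse(s <= 3, 1L, 0L)))
  names(pts) <- names(servings)
  pts[names(pts) %in% masked] <- 0L
  list(pdqs = as.integer(sum(pts, na.rm = TRUE)), points = pts,
       max_attainable = 2L * sum(!names(pts) %in% masked))
}

#' Classify per-group consumption change between recall periods
#'
#' For each mapped group: fewer days during than before is `"decreased"`,
#' equal is `"unchanged"`, more is `"increased"`; if either period is
#' unobserved the change is `"indeterminate"`.
#'
#' @param before,during named day vectors over the survey groups.
#' @param grouping `"mddw"` or `"pdqs"`.
#' @inheritParams map_to_mddw_groups
#' @return named character vector over the chosen grouping's ids.
#' @export
classify_consumption_change <- function(before, during,
                                        grouping = c("mddw", "pdqs"),
                                        cb = default_codebook(),
                                        masked = character(0),
                                        options = scoring_options()) {
  grouping <- match.arg(grouping)
  mapper <- if (grouping == "mddw") map_to_mddw_groups else map_to_pdqs_groups
  b <- mapper(before, cb, masked, options)
  d <- mapper(during, cb, masked, options)
  out <- rep("indeterminate", length(b))
  names(out) <- names(b)
  ok <- !is.na(b) & !is.na(d)
  out[ok & d < b] <- "decreased"
  out[ok & d == b] <- "unchanged"
  out[ok & d > b] <- "increased"
  out
}

#' Score a whole survey table
#'
#' Appends DDS and PDQS for both recall periods plus per-period completeness
#' flags. Site masks from the codebook are applied per household. A period is
#' complete when every unmasked survey group's days are observed; incomplete
#' periods get `NA` scores and are excluded (with a logged count) from
#' downstream score-based analyses.
#'
#' @param records survey data.frame.
#' @param cb codebook.
#' @param options scoring options.
#' @return `records` with columns `dds_before`, `dds_during`, `pdqs_before`,
#'   `pdqs_during`, `complete_before`, `complete_during` appended.
#' @export
score_survey <- function(records, cb = default_codebook(),
                         options = scoring_options()) {
  n <- nrow(records)
  for (col in c("dds_before", "dds_during", "pdqs_before", "pdqs_during"))
    records[[col]] <- NA_integer_
  records$complete_before <- records$complete_during <- NA
  for (site in unique(records$site)) {
    idx <- if (is.na(site)) which(is.na(records$site))
           else which(!is.na(records$site) & records$site == site)
    masked <- if (is.na(site)) character(0) else site_mask(cb, site)
    for (period in c("before", "during")) {
      D <- as.matrix(records[idx, fg_columns(cb, period), drop = FALSE])
      res <- score_core(D, cb, masked, options)
      score_na <- !res$complete
      dds <- res$dds; dds[score_na] <- NA_integer_
      pdqs <- res$pdqs; pdqs[score_na] <- NA_integer_
      records[[paste0("dds_", period)]][idx] <- dds
      records[[paste0("pdqs_", period)]][idx] <- pdqs
      records[[paste0("complete_", period)]][idx] <- res$complete
    }
  }
  records
}
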