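#' Household survey table schema
#'
#' One row per household. Categorical fields are stored as lower-snake-case
#' character codes, food-group recalls as integer days (0-7) with one column
#' per survey group per recall period (`fg_<group>_before`, `fg_<group>_during`).
#' Missing values are `NA` in memory and the empty string in files; missingness
#' is first-class because every published denominator excludes it explicitly.
#'
#' @param cb a codebook (see [default_codebook()]).
#' @return data.frame with columns `column`, `type` (`"id"`, `"enum"`,
#'   `"count"`, `"days"`) and `levels` (comma-separated allowed codes for
#'   enums).
#' @export
survey_schema <- function(cb = default_codebook()) {
  enum <- function(column, levels)
    data.frame(column = column, type = "enum",
               levels = paste(levels, collapse = ","),
               stringsAsFactors = FALSE)
  rows <- list(
    data.frame(column = "household_id", type = "id", levels = "",
               stringsAsFactors = FALSE),
    enum("country", unique(cb$sites$country)),
    enum("site", cb$sites$site),
    enum("locality", c("rural", "urban")),
    enum("respondent_sex", c("female", "male")),
    enum("age_band", c("20_29", "30_39", "40_plus")),
    enum("education", c("none_incomplete_primary",
                        "primary_incomplete_secondary",
                        "secondary_or_higher")),
    enum("head_of_household", c("no", "yes")),
    data.frame(column = "household_size", type = "count", levels = "",
               stringsAsFactors = FALSE),
    enum("occupation", c("unemployed", "farmer_casual_labor", "employed",
                         "student_self_employed_other")),
    enum("price_staples", c("unchanged", "decreased", "increased")),
    enum("price_pulses", c("unchanged", "decreased", "increased")),
    enum("price_fruits", c("unchanged", "decreased", "increased")),
    enum("price_vegetables", c("unchanged", "decreased", "increased")),
    enum("price_asf", c("unchanged", "decreased", "increased")),
    enum("worried_food", c("no", "yes")),
    enum("skipped_meal", c("no", "yes")),
    enum("whole_day_no_food", c("no", "yes")),
    enum("social_assistance", c("no", "yes")),
    enum("assistance_type", c("none", "cash", "food", "school_meals", "other")),
    enum("crop_production", c("unchanged", "decreased", "increased",
                              "does_not_farm"))
  )
  fg <- data.frame(
    column = c(fg_columns(cb, "before"), fg_columns(cb, "during")),
    type = "days", levels = "", stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(fg)))
  rownames(out) <- NULL
  out
}

#' Read a household survey table from CSV
#'
#' Reads a UTF-8 comma-delimited survey table whose header must match the
#' codebook schema exactly (any order is rejected to catch silent column
#' drift). Unparseable or out-of-range cells are flagged missing — never
#' dropped — and tallied in the attached validation report.
#'
#' @param path CSV file path.
#' @param cb codebook.
#' @return data.frame of households with attribute `"report"`: a data.frame
#'   with per-field counts of `n_missing` (empty cells) and `n_invalid`
#'   (cells coerced to missing because they failed a range/enum check).
#' @export
read_survey_table <- function(path, cb = default_codebook()) {
  if (!file.exists(path))
    abort(paste0("survey file not found: ", path), "dietshock_io_error")
  schema <- survey_schema(cb)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  if (!identical(names(raw), schema$column)) {
    extra <- setdiff(names(raw), schema$column)
    miss <- setdiff(schema$column, names(raw))
    msg <- c(if (length(extra)) paste0("unknown column(s): ",
                                       paste(extra, collapse = ", ")),
             if (length(miss)) paste0("missing column(s): ",
                                      paste(miss, collapse = ", ")),
             if (!length(extra) && !length(miss)) "columns out of order")
    abort(paste0("survey header does not match codebook schema; ",
                 paste(msg, collapse = "; ")), "dietshock_schema_error")
  }
  out <- raw
  n_missing <- n_invalid <- integer(nrow(schema))
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    x <- raw[[col]]
    empty <- is.na(x) | x == ""
    if (schema$type[i] == "id") {
      x[empty] <- NA_character_
      out[[col]] <- x
      invalid <- rep(FALSE, length(x))
    } else if (schema$type[i] == "enum") {
      levels <- strsplit(schema$levels[i], ",", fixed = TRUE)[[1]]
      invalid <- !empty & !(x %in% levels)
      x[empty | invalid] <- NA_character_
      out[[col]] <- x
    } else {  # count / days
      v <- suppressWarnings(as.numeric(x))
      bad_num <- !empty & (is.na(v) | v != floor(v))
      v_int <- suppressWarnings(as.integer(v))
      oor <- if (schema$type[i] == "days") !is.na(v_int) & (v_int < 0L | v_int > 7L)
             else !is.na(v_int) & v_int < 0L
      invalid <- bad_num | oor
      v_int[empty | invalid] <- NA_integer_
      out[[col]] <- v_int
    }
    n_missing[i] <- sum(empty)
    n_invalid[i] <- sum(invalid)
  }
  report <- data.frame(field = schema$column, n_missing = n_missing,
                       n_invalid = n_invalid, stringsAsFactors = FALSE)
  attr(out, "report") <- report
  out
}

#' Write a household survey table to CSV
#'
#' Inverse of [read_survey_table()]: `NA` is written as the empty string and
#' round-trips to `NA`.
#'
#' @param records survey data.frame.
#' @param path output path.
#' @param cb codebook.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(records, path, cb = default_codebook()) {
  schema <- survey_schema(cb)
  miss <- setdiff(schema$column, names(records))
  if (length(miss))
    abort(paste0("records lack required column(s): ",
                 paste(miss, collapse = ", ")), "dietshock_schema_error")
  ok <- tryCatch({
    utils::write.csv(records[, schema$column, drop = FALSE], path,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8",
                     quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort(paste0("cannot write survey table: ", conditionMessage(ok)),
          "dietshock_io_error")
  invisible(path)
}

#' Validate survey records against the codebook
#'
#' Reports every invariant violation (value range, enum membership,
#' site/country consistency, locality/site consistency) without raising:
#' content problems are data, not exceptions.
#'
#' @param records survey data.frame (one or more rows).
#' @param cb codebook.
#' @return data.frame with columns `row`, `field`, `problem`; zero rows iff
#'   all records are valid.
#' @export
validate_survey <- function(records, cb = default_codebook()) {
  schema <- survey_schema(cb)
  viol <- list()
  add <- function(rows, field, problem) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows, field = field, problem = problem, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(records)) {
      add(0L, col, "column absent")
      next
    }
    x <- records[[col]]
    if (schema$type[i] == "enum") {
      levels <- strsplit(schema$levels[i], ",", fixed = TRUE)[[1]]
      add(which(!is.na(x) & !(x %in% levels)), col, "value outside enum")
    } else if (schema$type[i] == "days") {
      add(which(!is.na(x) & (x < 0 | x > 7 | x != floor(x))), col,
          "days outside 0-7")
    } else if (schema$type[i] == "count") {
      add(which(!is.na(x) & (x < 0 | x != floor(x))), col,
          "negative or non-integer count")
    }
  }
  if (all(c("site", "country", "locality") %in% names(records))) {
    m <- match(records$site, cb$sites$site)
    bad_country <- which(!is.na(m) & !is.na(records$country) &
                           records$country != cb$sites$country[m])
    add(bad_country, "country", "country inconsistent with site")
    bad_loc <- which(!is.na(m) & !is.na(records$locality) &
                       records$locality != cb$sites$locality[m])
    add(bad_loc, "locality", "locality inconsistent with site")
  }
  if (!length(viol))
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, viol)
  out[order(out$row, out$field), , drop = FALSE]
}

#' @rdname validate_survey
#' @param record a single-row survey data.frame.
#' @export
validate_record <- function(record, cb = default_codebook()) {
  validate_survey(record[1, , drop = FALSE], cb)
}
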