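#' Convert a reported age to years
#'
#' Quarterly files report age as a value plus a unit code. Unit codes:
#' `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY` days, `HR`
#' hours. Anything unparseable yields `NA`.
#'
#' @param age_value Character vector of reported age values.
#' @param age_unit_code Character vector of unit codes (recycled if length 1).
#' @return Numeric vector of ages in years.
#' @export
#' @examples
#' normalize_age(c("24", "50", ""), c("MON", "YR", "YR"))
normalize_age <- function(age_value, age_unit_code) {
  val <- suppressWarnings(as.numeric(age_value))
  unit <- toupper(str_trim(ifelse(is.na(age_unit_code), "YR", age_unit_code)))
  unit[unit == ""] <- "YR"
  div <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52, DY = 365, HR = 8760)[unit]
  out <- val / unname(div)
  out[is.na(val) | is.na(div)] <- NA_real_
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Normalize a reporter-country field to a country code
#'
#' Legacy files spell countries out (`UNITED STATES`); current files use
#' two-letter codes (`US`). Values found in the bundled (or user-supplied)
#' name-to-code table are mapped; other non-empty values pass through
#' upper-cased, so the same true country yields the same code from either
#' dialect.
#'
#' @param raw Character vector of reported country values.
#' @param country_table Optional data frame with columns `name` and `code`;
#'   defaults to the table bundled with the package.
#' @return Character vector of country codes (`NA` where empty).
#' @export
normalize_country <- function(raw, country_table = NULL) {
  tab <- country_table %||% default_country_table()
  key <- str_squish(str_to_upper(ifelse(is.na(raw), "", raw)))
  idx <- match(key, str_to_upper(tab$name))
  out <- ifelse(!is.na(idx), tab$code[idx], key)
  out[key == ""] <- NA_character_
  out
}

#' Bundled country name-to-code table
#' @return Tibble with columns `name`, `code`.
#' @export
default_country_table <- function() {
  path <- system.file("extdata", "country_codes.tsv", package = "faersignal")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Normalize a reported event date
#'
#' Dates arrive as `YYYYMMDD` strings; partial dates (`YYYY` or `YYYYMM`) are
#' retained, padded with `01` components so calendar ordering works, and
#' still count as populated. Anything else is `NA`.
#'
#' @param raw Character vector of reported dates.
#' @return Character vector of 8-digit `YYYYMMDD` strings or `NA`.
#' @export
normalize_event_date <- function(raw) {
  x <- str_trim(ifelse(is.na(raw), "", raw))
  out <- rep(NA_character_, length(x))
  out[str_detect(x, "^[0-9]{8}$")] <- x[str_detect(x, "^[0-9]{8}$")]
  p6 <- str_detect(x, "^[0-9]{6}$")
  out[p6] <- paste0(x[p6], "01")
  p4 <- str_detect(x, "^[0-9]{4}$")
  out[p4] <- paste0(x[p4], "0101")
  out
}

#' Build unified case-version records from a parsed corpus
#'
#' One demographic row is one case version. Each version carries both case
#' identifiers (`isr` for legacy, `primaryid` for current, the other `NA`),
#' the normalized four-field demographic key, and order-invariant signature
#' keys: the alphabetically sorted, `|`-joined upper-case drug-name and
#' reaction preferred-term lists of the version.
#'
#' @param corpus A `faers_corpus` from [read_corpus()].
#' @param country_table Optional country name-to-code table.
#' @return Tibble with one row per case version.
#' @export
build_case_versions <- function(corpus, country_table = NULL) {
  demo <- corpus$demo
  vid <- paste(demo$dialect, demo$case_key, sep = ":")
  list_key <- function(tbl, col) {
    if (nrow(tbl) == 0) {
      return(tibble(version_id = character(0), key = character(0)))
    }
    tbl |>
      mutate(version_id = paste(.data$dialect, .data$case_key, sep = ":"),
             item = str_to_upper(str_squish(.data[[col]]))) |>
      filter(!is.na(.data$item)) |>
      distinct(.data$version_id, .data$item) |>
      arrange(.data$version_id, .data$item) |>
      group_by(.data$version_id) |>
      summarise(key = paste(.data$item, collapse = "|"), .groups = "drop")
  }
  dk <- list_key(corpus$drug, "drugname")
  rk <- list_key(corpus$reac, "pt")
  tibble(
    version_id = vid,
    isr = ifelse(demo$dialect == "LEGACY", demo$case_key, NA_character_),
    primaryid = ifelse(demo$dialect == "CURRENT", demo$case_key, NA_character_),
    caseid = demo$caseid,
    i_f_code = str_to_upper(str_trim(demo$i_f_code)),
    dialect = demo$dialect,
    year = demo$year,
    quarter = demo$quarter,
    event_date = normalize_event_date(demo$event_dt),
    age_years = normalize_age(demo$age, demo$age_cod),
    sex = str_to_upper(str_trim(demo$sex)),
    country = normalize_country(demo$reporter_country, country_table)
  ) |>
    left_join(rename(dk, drug_list_key = "key"), by = "version_id") |>
    left_join(rename(rk, reaction_list_key = "key"), by = "version_id")
}

#' Merge legacy and current case-version sets
#'
#' Pure concatenation: both key fields are preserved (the absent one `NA`)
#' and no record is dropped here — version selection belongs to the
#' de-duplication step.
#'
#' @param legacy,current Case-version tibbles from [build_case_versions()].
#' @return Tibble with `nrow(legacy) + nrow(current)` rows.
#' @export
merge_datasets <- function(legacy, current) {
  stopifnot(all(legacy$dialect %in% "LEGACY") || nrow(legacy) == 0,
            all(current$dialect %in% "CURRENT") || nrow(current) == 0)
  bind_rows(legacy, current)
}

.demo_fields <- c("event_date", "age_years", "sex", "country")

#' Count missing demographic key fields per version
#' @param versions Case-version tibble.
#' @return Integer vector in 0..4.
#' @export
demographic_missing_count <- function(versions) {
  as.integer(rowSums(is.na(as.data.frame(versions[, .demo_fields]))))
}

#' Impute single missing demographic values within each case
#'
#' For each case (shared `caseid`) with at least one version whose four key
#' demographic fields (event date, age, sex, reporter country) are all
#' populated, a donor key is formed from the per-field maxima over the fully
#' populated versions (date by calendar order, age numerically, sex and
#' country lexicographically). Versions missing exactly one field have that
#' field filled from the donor. Versions missing two or more fields are left
#' untouched — only single-value imputation is performed — and populated
#' fields are never altered.
#'
#' @param versions Case-version tibble from [build_case_versions()] (or
#'   [merge_datasets()]).
#' @return The same tibble with single missing values filled.
#' @export
impute_demographics <- function(versions) {
  if (nrow(versions) == 0) return(versions)
  versions |>
    group_by(.data$caseid) |>
    mutate(
      .full = !is.na(.data$event_date) & !is.na(.data$age_years) &
        !is.na(.data$sex) & !is.na(.data$country),
      .nmiss = is.na(.data$event_date) + is.na(.data$age_years) +
        is.na(.data$sex) + is.na(.data$country),
      .donate = any(.full) & .data$.nmiss == 1L,
      event_date = if_else(.data$.donate & is.na(.data$event_date),
                           .max_or_na(.data$event_date[.full]), .data$event_date),
      age_years = if_else(.data$.donate & is.na(.data$age_years),
                          .max_or_na(.data$age_years[.full]), .data$age_years),
      sex = if_else(.data$.donate & is.na(.data$sex),
                    .max_or_na(.data$sex[.full]), .data$sex),
      country = if_else(.data$.donate & is.na(.data$country),
                        .max_or_na(.data$country[.full]), .data$country)
    ) |>
    ungroup() |>
    select(-".full", -".nmiss", -".donate")
}

.max_or_na <- function(x) {
  if (length(x) == 0 || all(is.na(x))) {
    if (is.numeric(x)) NA_real_ else NA_character_
  } else {
    max(x, na.rm = TRUE)
  }
}
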