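#' Precedence ordering of case versions
#'
#' Versions are ranked for recency by: data set (current beats legacy), then
#' the unique case key (`isr`/`primaryid`) descending — compared numerically
#' when fully numeric, lexicographically otherwise — then file year and
#' quarter descending. This is a total order over the versions of a case and
#' is the tie-break whenever "the latest version" must be chosen.
#'
#' @param versions Case-version tibble.
#' @return Integer vector: `1` marks the highest-precedence (most recent)
#'   row, `nrow(versions)` the lowest.
#' @export
precedence_rank <- function(versions) {
  versions <- .with_case_key(versions)
  ck <- versions$case_key
  key_num <- suppressWarnings(as.numeric(ck))
  o <- order(versions$dialect == "CURRENT", key_num, ck,
             versions$year, versions$quarter,
             decreasing = TRUE, method = "radix", na.last = TRUE)
  r <- integer(nrow(versions))
  r[o] <- seq_len(nrow(versions))
  r
}

.with_case_key <- function(versions) {
  if (!"case_key" %in% names(versions)) {
    versions$case_key <- ifelse(versions$dialect == "CURRENT",
                                versions$primaryid, versions$isr)
  }
  versions
}

#' Select the latest version of one case
#'
#' Among the versions sharing one `caseid`, the survivor is the version
#' ranked first by [precedence_rank()]: a current-data version always beats
#' a legacy one, then higher case keys and later file quarters win. Versions
#' with identical signatures (demographic key plus sorted drug and reaction
#' lists) are thereby collapsed to their most recent submission.
#'
#' @param versions_of_one_case Case-version tibble, one `caseid`.
#' @return A one-row tibble.
#' @export
select_latest_version <- function(versions_of_one_case) {
  if (nrow(versions_of_one_case) == 0) {
    stop("select_latest_version: no versions supplied", call. = FALSE)
  }
  stopifnot(n_distinct(versions_of_one_case$caseid) == 1)
  v <- .with_case_key(versions_of_one_case)
  v[precedence_rank(v) == 1L, , drop = FALSE]
}

#' Step 1: keep one (latest) version per case
#'
#' @param versions Merged, imputed case-version tibble.
#' @return Tibble with one row per `caseid`.
#' @export
select_latest_versions <- function(versions) {
  if (nrow(versions) == 0) return(versions)
  v <- .with_case_key(versions)
  v |>
    mutate(.rk = precedence_rank(v)) |>
    arrange(.data$.rk) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    select(-".rk")
}

#' Step 2: collapse duplicates sharing a full demographic key
#'
#' Among latest case versions whose four demographic fields (event date,
#' age, sex, reporter country) are all populated and pairwise equal, only
#' the highest-precedence version survives, regardless of assigned case
#' number. A version with any missing demographic field is never collapsed:
#' missing never matches missing.
#'
#' @param latest_cases Tibble with one version per `caseid`.
#' @return Subset of the input.
#' @export
dedup_by_demographic_key <- function(latest_cases) {
  if (nrow(latest_cases) == 0) return(latest_cases)
  v <- .with_case_key(latest_cases)
  full <- demographic_missing_count(v) == 0L
  keep_partial <- v[!full, , drop = FALSE]
  vf <- v[full, , drop = FALSE]
  if (nrow(vf) > 0) {
    vf <- vf |>
      mutate(.rk = precedence_rank(vf)) |>
      arrange(.data$.rk) |>
      distinct(.data$event_date, .data$age_years, .data$sex, .data$country,
               .keep_all = TRUE) |>
      select(-".rk")
  }
  bind_rows(vf, keep_partial) |> arrange(.data$caseid)
}

#' Two-step case de-duplication
#'
#' Composition of latest-version selection per case and demographic-key
#' collapse across cases. The result has unique case ids and at most one
#' survivor per fully populated demographic key; every output row is an
#' input row. Imputation ([impute_demographics()]) is expected to have run
#' first, since step 2 compares the fields it fills.
#'
#' @param versions Merged, imputed case-version tibble.
#' @return Tibble of surviving case versions, with a `dedup_audit` attribute
#'   (tibble of removed caseids, the step that removed them, and the
#'   surviving case key).
#' @export
deduplicate <- function(versions) {
  if (nrow(versions) == 0) return(versions)
  latest <- select_latest_versions(versions)
  out <- dedup_by_demographic_key(latest)
  removed_step2 <- anti_join(latest, out, by = "caseid")
  audit <- if (nrow(removed_step2) > 0) {
    surv_map <- .with_case_key(out) |>
      mutate(demo_key = paste(.data$event_date, .data$age_years,
                              .data$sex, .data$country, sep = "|"))
    removed_step2 |>
      mutate(demo_key = paste(.data$event_date, .data$age_years,
                              .data$sex, .data$country, sep = "|")) |>
      left_join(select(surv_map, "demo_key", survivor_key = "case_key"),
                by = "demo_key") |>
      transmute(caseid = .data$caseid, step = "demographic_key",
                survivor_key = .data$survivor_key)
  } else {
    tibble(caseid = character(0), step = character(0),
           survivor_key = character(0))
  }
  attr(out, "dedup_audit") <- audit
  out
}
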