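#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join inner_join anti_join distinct rename n
#'   n_distinct if_else first across all_of desc slice row_number transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dfr
#' @importFrom stringr str_squish str_to_upper str_detect str_replace_all
#'   str_remove str_remove_all str_trim str_pad
NULL

#' Detect the source dialect of a quarterly report file
#'
#' Quarterly report tables come in two ASCII dialects: the legacy one keys
#' rows by `ISR`/`CASE`, the current one by `primaryid`/`caseid`. The dialect
#' is a pure function of the header line.
#'
#' @param header_line First line of a quarterly DEMO/DRUG/REAC/INDI/OUTC file.
#' @param delimiter Field delimiter, `"$"` by convention.
#' @param path Optional path, used only to make the error message actionable.
#' @return `"LEGACY"` or `"CURRENT"`.
#' @export
#' @examples
#' detect_dialect("ISR$CASE$I_F_COD")
#' detect_dialect("primaryid$caseid$i_f_cod")
detect_dialect <- function(header_line, delimiter = "$", path = NULL) {
  cols <- toupper(str_trim(strsplit(header_line, delimiter, fixed = TRUE)[[1]]))
  if ("ISR" %in% cols) return("LEGACY")
  if ("PRIMARYID" %in% cols) return("CURRENT")
  stop("unreadable file", if (!is.null(path)) paste0(" '", path, "'"),
       ": header has neither an ISR nor a primaryid column", call. = FALSE)
}

# canonical (unified, lower-case) column names per table kind; the raw files
# use upper-case names in the legacy dialect and lower-case in the current one
.kind_key_cols <- function(kind, dialect) {
  if (dialect == "LEGACY") c(case_key = "ISR", caseid = "CASE")
  else c(case_key = "PRIMARYID", caseid = "CASEID")
}

.kind_from_path <- function(path) {
  m <- regmatches(basename(path), regexpr("^(DEMO|DRUG|REAC|INDI|OUTC|THER|RPSR)",
                                          toupper(basename(path))))
  if (length(m) == 0) NA_character_ else m
}

.quarter_from_path <- function(path) {
  m <- regmatches(basename(path), regexpr("[0-9]{2}Q[1-4]", toupper(basename(path))))
  if (length(m) == 0) return(c(year = NA_integer_, quarter = NA_integer_))
  c(year = 2000L + as.integer(substr(m, 1, 2)), quarter = as.integer(substr(m, 4, 4)))
}

#' Read one quarterly report table
#'
#' Parses a `$`-delimited quarterly ASCII table (either dialect). Fields are
#' whitespace-trimmed; empty strings become `NA` (missing). Rows whose field
#' count disagrees with the header are skipped and counted, not fatal.
#'
#' @param path Path to the file. Table kind and year/quarter are taken from
#'   the conventional `KINDyyQq` file name unless overridden.
#' @param delimiter Field delimiter (default `"$"`).
#' @param table_kind Optional override of the table kind.
#' @return A tibble of character columns named as in the file header
#'   (upper-cased), with attributes `dialect`, `table_kind`, `year`,
#'   `quarter`, and `skipped` (count of malformed rows).
#' @export
read_quarter_table <- function(path, delimiter = "$", table_kind = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  lines <- readr::read_lines(path, locale = readr::locale(encoding = "latin1"))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty file: '", path, "'", call. = FALSE)
  header <- toupper(str_trim(strsplit(lines[1], delimiter, fixed = TRUE)[[1]]))
  dialect <- detect_dialect(lines[1], delimiter, path)
  body <- lines[-1]
  parts <- strsplit(body, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; tolerate one short
  ok <- nf == length(header) | nf == length(header) - 1L
  skipped <- sum(!ok)
  if (skipped > 0) {
    message("read_quarter_table: skipped ", skipped, " malformed row(s) in ",
            basename(path))
  }
  parts <- parts[ok]
  out <- if (length(parts) == 0) {
    as_tibble(stats::setNames(rep(list(character(0)), length(header)), header))
  } else {
    mat <- t(vapply(parts, function(p) {
      str_trim(c(p, rep("", length(header) - length(p))))
    }, character(length(header))))
    colnames(mat) <- header
    as_tibble(mat)
  }
  out[out == ""] <- NA_character_
  yq <- .quarter_from_path(path)
  attr(out, "dialect") <- dialect
  attr(out, "table_kind") <- table_kind %||% .kind_from_path(path)
  attr(out, "year") <- unname(yq["year"])
  attr(out, "quarter") <- unname(yq["quarter"])
  attr(out, "skipped") <- skipped
  out
}

#' Column layouts of the standard output tables
#'
#' The pipeline writes eight tab-delimited `standard_*` tables; this returns
#' their fixed column orders. Both legacy and current case identifiers
#' (`isr`, `primaryid`) are kept in every per-case table so that rows can be
#' traced back to their source distribution.
#'
#' @return Named list of character vectors (column names, in order).
#' @export
standard_schemas <- function() {
  list(
    standard_case_drug = c("primaryid", "isr", "caseid", "drug_seq", "role_cod",
                           "standard_concept_id"),
    standard_case_outcome = c("primaryid", "isr", "caseid", "pt",
                              "outcome_concept_id", "snomed_outcome_concept_id"),
    standard_case_outcome_category = c("primaryid", "isr", "caseid", "outc_code",
                                       "snomed_concept_id"),
    standard_case_indication = c("primaryid", "isr", "caseid", "indi_drug_seq",
                                 "indi_pt", "indication_concept_id",
                                 "snomed_indication_concept_id"),
    standard_drug_outcome_contingency_table =
      c("drug_concept_id", "outcome_concept_id",
        "count_a", "count_b", "count_c", "count_d"),
    standard_drug_outcome_count = c("drug_concept_id", "outcome_concept_id",
                                    "drug_outcome_pair_count"),
    standard_drug_outcome_statistics =
      c("drug_concept_id", "outcome_concept_id", "case_count",
        "prr", "prr_95_percent_lower_confidence_limit",
        "prr_95_percent_upper_confidence_limit",
        "ror", "ror_95_percent_lower_confidence_limit",
        "ror_95_percent_upper_confidence_limit"),
    standard_drug_outcome_drilldown =
      c("drug_concept_id", "outcome_concept_id", "snomed_outcome_concept_id",
        "primaryid", "isr", "caseid")
  )
}

#' Write a standard output table
#'
#' Writes rows tab-delimited with a header, columns in the fixed order of the
#' named schema, missing values as empty strings.
#'
#' @param rows Data frame carrying at least the schema's columns.
#' @param schema_name One of the names of [standard_schemas()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_standard_table <- function(rows, schema_name, path) {
  schemas <- standard_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unknown output schema '", schema_name, "'", call. = FALSE)
  }
  cols <- schemas[[schema_name]]
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0) {
    stop("rows for '", schema_name, "' lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- as_tibble(rows)[, cols]
  out <- mutate(out, across(all_of(cols), as.character))
  readr::write_tsv(out, path, na = "", quote = "none")
  invisible(path)
}

#' Read a standard output table back
#'
#' @param path Path written by [write_standard_table()].
#' @return Tibble of character columns; empty fields are `NA`.
#' @export
read_standard_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  na = "", trim_ws = FALSE, progress = FALSE)
}

#' Read a directory of quarterly report files into a corpus
#'
#' Scans for files named `DEMOyyQq`, `DRUGyyQq`, `REACyyQq`, `INDIyyQq`,
#' `OUTCyyQq` (any extension), parses each with [read_quarter_table()], and
#' stacks both dialects into five unified tibbles with shared columns
#' `dialect`, `year`, `quarter`, `case_key`, `caseid`. THER/RPSR files are
#' parsed but kept as raw pass-through tables: they play no role downstream.
#'
#' @param dir Directory containing the quarterly files.
#' @param delimiter Field delimiter (default `"$"`).
#' @return A list of class `faers_corpus` with elements `demo`, `drug`,
#'   `reac`, `indi`, `outc` (tibbles), `passthrough` (raw THER/RPSR tables)
#'   and `skipped` (malformed-row count).
#' @export
read_corpus <- function(dir, delimiter = "$") {
  paths <- list.files(dir, full.names = TRUE)
  kinds <- vapply(paths, .kind_from_path, character(1))
  paths <- paths[!is.na(kinds)]
  kinds <- kinds[!is.na(kinds)]
  if (length(paths) == 0) stop("no quarterly report files found in '", dir, "'",
                               call. = FALSE)
  main <- c("DEMO", "DRUG", "REAC", "INDI", "OUTC")
  extra_cols <- list(
    DEMO = c("i_f_code", "event_dt", "age", "age_cod", "sex",
             "reporter_country"),
    DRUG = c("drug_seq", "role_cod", "drugname", "prod_ai", "nda_num"),
    REAC = "pt", INDI = c("indi_drug_seq", "indi_pt"), OUTC = "outc_cod")
  tabs <- lapply(stats::setNames(main, tolower(main)), function(k) {
    ps <- paths[kinds == k]
    if (length(ps) == 0) {
      base <- tibble(dialect = character(0), year = integer(0),
                     quarter = integer(0), case_key = character(0),
                     caseid = character(0))
      for (cc in extra_cols[[k]]) base[[cc]] <- character(0)
      return(base)
    }
    bind_rows(lapply(ps, function(p) {
      raw <- read_quarter_table(p, delimiter)
      .unify_quarter_table(raw, k)
    }))
  })
  skipped <- 0L
  passthrough <- list()
  for (k in c("THER", "RPSR")) {
    for (p in paths[kinds == k]) {
      passthrough[[basename(p)]] <- read_quarter_table(p, delimiter)
    }
  }
  structure(c(tabs, list(passthrough = passthrough)), class = "faers_corpus")
}

# map a raw parsed quarterly table onto the unified column set
.unify_quarter_table <- function(raw, kind) {
  dialect <- attr(raw, "dialect")
  keyc <- if (dialect == "LEGACY") "ISR" else "PRIMARYID"
  casec <- if (dialect == "LEGACY") "CASE" else "CASEID"
  get_col <- function(nm) {
    if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }
  base <- tibble(
    dialect = rep(dialect, nrow(raw)),
    year = rep(as.integer(attr(raw, "year")), nrow(raw)),
    quarter = rep(as.integer(attr(raw, "quarter")), nrow(raw)),
    case_key = get_col(keyc),
    caseid = get_col(casec)
  )
  extra <- switch(kind,
    DEMO = tibble(i_f_code = get_col("I_F_COD"),
                  event_dt = get_col("EVENT_DT"),
                  age = get_col("AGE"),
                  age_cod = get_col("AGE_COD"),
                  sex = if (dialect == "LEGACY") get_col("GNDR_COD") else get_col("SEX"),
                  reporter_country = get_col("REPORTER_COUNTRY")),
    DRUG = tibble(drug_seq = get_col("DRUG_SEQ"),
                  role_cod = get_col("ROLE_COD"),
                  drugname = get_col("DRUGNAME"),
                  prod_ai = get_col("PROD_AI"),
                  nda_num = get_col("NDA_NUM")),
    REAC = tibble(pt = get_col("PT")),
    INDI = tibble(indi_drug_seq = if (dialect == "LEGACY") get_col("DRUG_SEQ")
                                  else get_col("INDI_DRUG_SEQ"),
                  indi_pt = get_col("INDI_PT")),
    OUTC = tibble(outc_cod = get_col("OUTC_COD"))
  )
  dplyr::bind_cols(base, extra)
}
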