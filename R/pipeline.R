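#' Pipeline configuration
#'
#' @param input_dir Directory of quarterly report files (both dialects).
#' @param vocab_dir Directory holding the five vocabulary bundle tables.
#' @param output_dir Directory for the eight `standard_*` output tables.
#' @param manual_map_path Optional tab-separated file (columns
#'   `source_text`, `concept_id`) supplying manual drug-name mappings tried
#'   after the automated steps.
#' @param delimiter Input field delimiter (default `"$"`).
#' @param counting_unit `"triple"` (default) counts the (case, drug,
#'   outcome) triple universe; `"case"` counts unique cases per cell.
#' @param haldane Apply the 0.5 continuity correction to the 2x2 cells
#'   before computing statistics (default `FALSE`).
#' @param country_table_path Optional replacement country name-to-code
#'   table (TSV, columns `name`, `code`).
#' @return A list of class `faers_config`.
#' @export
faers_config <- function(input_dir, vocab_dir, output_dir,
                         manual_map_path = NULL, delimiter = "$",
                         counting_unit = c("triple", "case"),
                         haldane = FALSE, country_table_path = NULL) {
  counting_unit <- match.arg(counting_unit)
  for (p in c(input_dir, vocab_dir, manual_map_path, country_table_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("path does not exist: '", p, "'", call. = FALSE)
    }
  }
  structure(list(input_dir = input_dir, vocab_dir = vocab_dir,
                 output_dir = output_dir, manual_map_path = manual_map_path,
                 delimiter = delimiter, counting_unit = counting_unit,
                 haldane = haldane, country_table_path = country_table_path),
            class = "faers_config")
}

#' Run the full curation and signal-detection pipeline
#'
#' Executes read -> merge/normalize -> impute -> de-duplicate -> map ->
#' pair enumeration -> statistics, and writes the eight `standard_*`
#' tab-delimited output tables to `config$output_dir`. Deterministic for
#' fixed inputs: outputs are byte-identical across runs and across
#' record-order permutations of the input files.
#'
#' @param config A [faers_config()].
#' @return An object of class `faers_run`: list with `tables` (the eight
#'   output tibbles), `report` (per-stage record counts), `coverage` (the
#'   [coverage_report()] row), `surviving_cases`, and `stats`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  country_table <- if (!is.null(config$country_table_path)) {
    readr::read_tsv(config$country_table_path, col_types = "cc",
                    progress = FALSE)
  } else NULL

  corpus <- stage("io_faers", read_corpus(config$input_dir, config$delimiter))
  vocab <- stage("vocab_map", read_vocabulary(config$vocab_dir))
  manual_map <- if (!is.null(config$manual_map_path)) {
    readr::read_tsv(config$manual_map_path, col_types = "ci", progress = FALSE)
  } else NULL

  versions <- stage("merge_impute", {
    build_case_versions(corpus, country_table) |> impute_demographics()
  })
  surviving <- stage("dedup", deduplicate(versions))
  surviving <- .with_case_key(surviving)

  # restrict detail tables to surviving (latest) case versions
  keep <- tibble(dialect = surviving$dialect, case_key = surviving$case_key,
                 caseid = surviving$caseid,
                 isr = surviving$isr, primaryid = surviving$primaryid)
  pick <- function(tbl) {
    tbl |>
      select(-dplyr::any_of("caseid")) |>
      inner_join(keep, by = c("dialect", "case_key"))
  }
  drugs <- pick(corpus$drug)
  reacs <- pick(corpus$reac)
  indis <- pick(corpus$indi)
  outcs <- pick(corpus$outc)

  mapped <- stage("vocab_map", {
    drug_map <- map_drug_names(drugs$drugname, drugs$prod_ai, drugs$nda_num,
                               vocab, manual_map)
    reac_map <- map_meddra_pt(reacs$pt, vocab$pt_map)
    indi_map <- map_meddra_pt(indis$indi_pt, vocab$pt_map)
    list(drug = bind_cols(drugs, select(drug_map, -"source_text")),
         reac = bind_cols(reacs, select(reac_map, -"pt")),
         indi = bind_cols(indis, select(indi_map, -"pt")))
  })

  triples <- stage("signal_stats", {
    enumerate_triples(
      select(mapped$drug, "caseid", drug_concept_id = "concept_id"),
      select(mapped$reac, "caseid", "outcome_concept_id"))
  })
  ct <- stage("signal_stats",
              contingency_tables(triples, unit = config$counting_unit))
  stats <- stage("signal_stats", signal_statistics(ct, config$haldane))

  tables <- .assemble_output_tables(surviving, mapped, outcs, triples, stats)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- tryCatch({
    for (nm in names(tables)) {
      write_standard_table(tables[[nm]], nm,
                           file.path(config$output_dir, paste0(nm, ".tsv")))
    }
    TRUE
  }, error = function(e) {
    # remove partial outputs before propagating
    unlink(file.path(config$output_dir,
                     paste0(names(tables), ".tsv")))
    stop("pipeline stage 'io_faers' failed while writing outputs: ",
         conditionMessage(e), call. = FALSE)
  })

  coverage <- coverage_report(
    transmute(mapped$drug, caseid = .data$caseid,
              source_text = .data$drugname, concept_id = .data$concept_id,
              method = .data$method),
    select(mapped$reac, "pt", "snomed_concept_id"),
    select(mapped$indi, pt = "indi_pt", "snomed_concept_id"))

  report <- tibble(
    stage = c("parsed_versions", "merged_versions", "deduplicated_cases",
              "drug_rows_mapped", "triples", "statistics_rows"),
    count = c(nrow(corpus$demo), nrow(versions), nrow(surviving),
              sum(!is.na(mapped$drug$concept_id)), nrow(triples), nrow(stats)))

  structure(list(tables = tables, report = report, coverage = coverage,
                 surviving_cases = sort(unique(surviving$caseid)),
                 stats = stats, config = config),
            class = "faers_run")
}

.assemble_output_tables <- function(surviving, mapped, outcs, triples, stats) {
  blankc <- function(x) ifelse(is.na(x), NA_character_, as.character(x))
  ord <- function(tbl, ...) arrange(tbl, ...)

  case_drug <- mapped$drug |>
    transmute(primaryid = .data$primaryid, isr = .data$isr,
              caseid = .data$caseid,
              drug_seq = .data$drug_seq, role_cod = .data$role_cod,
              standard_concept_id = blankc(.data$concept_id)) |>
    ord(.data$caseid, as.numeric(.data$drug_seq), .data$standard_concept_id)

  case_outcome <- mapped$reac |>
    transmute(primaryid = .data$primaryid, isr = .data$isr,
              caseid = .data$caseid, pt = .data$pt,
              outcome_concept_id = blankc(.data$outcome_concept_id),
              snomed_outcome_concept_id = blankc(.data$snomed_concept_id)) |>
    ord(.data$caseid, .data$pt)

  # SNOMED outcome concepts of the case combined with its OUTC category rows
  case_outcome_category <- outcs |>
    inner_join(mapped$reac |>
                 filter(!is.na(.data$snomed_concept_id)) |>
                 distinct(.data$caseid, .data$snomed_concept_id),
               by = "caseid", relationship = "many-to-many") |>
    transmute(primaryid = .data$primaryid, isr = .data$isr,
              caseid = .data$caseid, outc_code = .data$outc_cod,
              snomed_concept_id = blankc(.data$snomed_concept_id)) |>
    distinct() |>
    ord(.data$caseid, .data$outc_code, .data$snomed_concept_id)

  case_indication <- mapped$indi |>
    transmute(primaryid = .data$primaryid, isr = .data$isr,
              caseid = .data$caseid, indi_drug_seq = .data$indi_drug_seq,
              indi_pt = .data$indi_pt,
              indication_concept_id = blankc(.data$outcome_concept_id),
              snomed_indication_concept_id = blankc(.data$snomed_concept_id)) |>
    ord(.data$caseid, as.numeric(.data$indi_drug_seq), .data$indi_pt)

  contingency <- stats |>
    transmute(drug_concept_id = as.character(.data$drug_concept_id),
              outcome_concept_id = as.character(.data$outcome_concept_id),
              count_a = .data$a, count_b = .data$b, count_c = .data$c,
              count_d = .data$d)

  pair_count <- stats |>
    transmute(drug_concept_id = as.character(.data$drug_concept_id),
              outcome_concept_id = as.character(.data$outcome_concept_id),
              drug_outcome_pair_count = .data$a)

  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.9g", x))
  statistics <- stats |>
    transmute(drug_concept_id = as.character(.data$drug_concept_id),
              outcome_concept_id = as.character(.data$outcome_concept_id),
              case_count = .data$a,
              prr = fmt(.data$prr),
              prr_95_percent_lower_confidence_limit = fmt(.data$prr_ci_low),
              prr_95_percent_upper_confidence_limit = fmt(.data$prr_ci_high),
              ror = fmt(.data$ror),
              ror_95_percent_lower_confidence_limit = fmt(.data$ror_ci_low),
              ror_95_percent_upper_confidence_limit = fmt(.data$ror_ci_high))

  id_cols <- distinct(tibble(caseid = surviving$caseid,
                             primaryid = surviving$primaryid,
                             isr = surviving$isr))
  snomed_of <- mapped$reac |>
    distinct(.data$caseid, .data$outcome_concept_id, .data$snomed_concept_id) |>
    filter(!is.na(.data$outcome_concept_id))
  drilldown <- triples |>
    left_join(snomed_of, by = c("caseid", "outcome_concept_id")) |>
    left_join(id_cols, by = "caseid") |>
    transmute(drug_concept_id = as.character(.data$drug_concept_id),
              outcome_concept_id = as.character(.data$outcome_concept_id),
              snomed_outcome_concept_id = blankc(.data$snomed_concept_id),
              primaryid = .data$primaryid, isr = .data$isr,
              caseid = .data$caseid) |>
    distinct() |>
    ord(.data$drug_concept_id, .data$outcome_concept_id, .data$caseid)

  list(standard_case_drug = case_drug,
       standard_case_outcome = case_outcome,
       standard_case_outcome_category = case_outcome_category,
       standard_case_indication = case_indication,
       standard_drug_outcome_contingency_table = contingency,
       standard_drug_outcome_count = pair_count,
       standard_drug_outcome_statistics = statistics,
       standard_drug_outcome_drilldown = drilldown)
}

#' @export
print.faers_run <- function(x, ...) {
  cat("<faers_run>\n")
  cat(sprintf("  surviving cases: %d\n", length(x$surviving_cases)))
  cat(sprintf("  drug-outcome pairs: %d\n", nrow(x$stats)))
  cat(sprintf("  drug string coverage: %.3f\n",
              x$coverage$drug_string_coverage))
  invisible(x)
}

#' Tidy per-stage record counts of a pipeline run
#' @param x A `faers_run`.
#' @param ... Unused.
#' @return Tibble with columns `stage`, `count`.
#' @method tidy faers_run
#' @export
tidy.faers_run <- function(x, ...) x$report

#' One-row summary of a pipeline run
#' @param x A `faers_run`.
#' @param ... Unused.
#' @return One-row tibble: surviving cases, triple count, pair count,
#'   coverage fractions.
#' @method glance faers_run
#' @export
glance.faers_run <- function(x, ...) {
  tibble(n_surviving_cases = length(x$surviving_cases),
         n_triples = x$report$count[x$report$stage == "triples"],
         n_pairs = nrow(x$stats),
         drug_string_coverage = x$coverage$drug_string_coverage,
         reaction_pt_coverage = x$coverage$reaction_pt_coverage,
         indication_pt_coverage = x$coverage$indication_pt_coverage)
}

#' Plot per-stage record counts of a pipeline run
#' @param object A `faers_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_run
#' @export
autoplot.faers_run <- function(object, ...) {
  df <- mutate(object$report,
               stage = factor(.data$stage, levels = rev(object$report$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "records", y = NULL,
                  title = "Pipeline stage record counts") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
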