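#' Read a vocabulary bundle
#'
#' The bundle is five tab-delimited tables in one directory:
#' \describe{
#'   \item{concept.tsv}{`concept_id`, `concept_code`, `vocabulary`,
#'     `concept_name`, `standard` (Y/N)}
#'   \item{concept_name_lookup.tsv}{`name` (normalized drug string),
#'     `concept_id`}
#'   \item{concept_relationship.tsv}{`concept_id_1` (non-standard),
#'     `concept_id_2` (its standard target)}
#'   \item{pt_snomed_map.tsv}{`pt` (MedDRA preferred term, upper case),
#'     `outcome_concept_id`, `snomed_concept_id`}
#'   \item{nda_ingredient.tsv}{`nda_num`, `concept_id`}
#' }
#' Consistency is enforced at load time: every relationship endpoint and
#' lookup/NDA target must exist in the concept table.
#'
#' @param dir Directory holding the five tables.
#' @return A list of class `faers_vocab`.
#' @export
read_vocabulary <- function(dir) {
  rd <- function(f, types) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("vocabulary bundle incomplete: missing '", f,
                              "' in ", dir, call. = FALSE)
    readr::read_tsv(p, col_types = types, progress = FALSE)
  }
  vocab <- list(
    concept = rd("concept.tsv", "icccc") |>
      mutate(standard = .data$standard %in% c("Y", "TRUE", "T", "1")),
    lookup = rd("concept_name_lookup.tsv", "ci"),
    relationship = rd("concept_relationship.tsv", "ii"),
    pt_map = rd("pt_snomed_map.tsv", "cic"),
    nda = rd("nda_ingredient.tsv", "ci")
  )
  validate_vocabulary(vocab)
}

#' Validate internal consistency of a vocabulary bundle
#' @param vocab A vocabulary bundle (list of the five tables).
#' @return The bundle, classed `faers_vocab`, or an error.
#' @export
validate_vocabulary <- function(vocab) {
  ids <- vocab$concept$concept_id
  if (anyDuplicated(ids)) stop("duplicate concept_id in concept table",
                               call. = FALSE)
  bad <- c(setdiff(vocab$relationship$concept_id_1, ids),
           setdiff(vocab$relationship$concept_id_2, ids),
           setdiff(vocab$lookup$concept_id, ids),
           setdiff(vocab$nda$concept_id, ids))
  if (length(bad) > 0) {
    stop("vocabulary bundle inconsistent: concept id(s) ",
         paste(utils::head(unique(bad), 5), collapse = ", "),
         " referenced but absent from the concept table", call. = FALSE)
  }
  structure(vocab, class = "faers_vocab")
}

# trailing dose/form tokens stripped during drug-name normalization
.dose_form_pattern <- paste0(
  "(\\s+[0-9]+(\\.[0-9]+)?\\s*(MG|MCG|ML|G|GR|IU|%)(/[0-9]*\\s*(MG|MCG|ML|G))?",
  "|\\s+(TABS?|TABLETS?|CAPS?|CAPSULES?|INJ|INJECTION|SOLUTION|SOLN|CREAM",
  "|OINTMENT|SYRUP|SUSPENSION))+$")

#' Normalize a verbatim drug name
#'
#' Deterministic normalization chain applied before exact lookup, in order:
#' upper-case; trim; collapse internal whitespace; strip surrounding quotes;
#' remove parenthesized suffixes; repeatedly remove trailing dose/form
#' tokens (number + unit such as `MG`/`ML`/`MCG`, and the form words
#' `TAB(LET)`, `CAP(SULE)`, `INJ`, `SOLUTION`, etc.); strip trailing
#' punctuation. Each rule is unit-tested individually.
#'
#' @param raw Character vector of verbatim drug names.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_drug_name("Etanercept (50 MG)")
#' normalize_drug_name("  aspirin 81 MG TABLET ")
normalize_drug_name <- function(raw) {
  x <- str_to_upper(str_squish(ifelse(is.na(raw), "", raw)))
  x <- str_replace_all(x, "^[\"']+|[\"']+$", "")
  x <- str_squish(str_remove_all(x, "\\([^()]*\\)"))
  x <- str_remove(x, "[[:punct:]]+$")
  x <- str_remove(x, stringr::regex(.dose_form_pattern))
  x <- str_remove(x, "[[:punct:]]+$")
  str_squish(x)
}

#' Resolve concepts to standard concepts
#'
#' Standard concepts are returned unchanged. Non-standard concepts (brand
#' names, and combination products pointing at their clinical drug form)
#' are followed through the relationship table to their unique standard
#' target. A non-standard concept with zero or more than one standard
#' target is flagged unmappable (`NA`) with a warning rather than resolved
#' arbitrarily.
#'
#' @param concept_id Integer vector of concept ids.
#' @param vocab A `faers_vocab` bundle.
#' @return Integer vector of standard concept ids (`NA` if unresolvable).
#' @export
resolve_to_standard <- function(concept_id, vocab) {
  con <- vocab$concept
  std <- con$standard[match(concept_id, con$concept_id)]
  out <- ifelse(!is.na(std) & std, concept_id, NA_integer_)
  needs <- which(!is.na(concept_id) & !is.na(std) & !std)
  if (length(needs) > 0) {
    rel <- vocab$relationship
    rel_std <- rel[rel$concept_id_2 %in% con$concept_id[con$standard], ]
    tab <- table(rel_std$concept_id_1)
    uniq <- names(tab)[tab == 1]
    m <- match(as.character(concept_id[needs]), as.character(rel_std$concept_id_1))
    ok <- !is.na(m) & as.character(concept_id[needs]) %in% uniq
    out[needs[ok]] <- rel_std$concept_id_2[m[ok]]
    if (any(!ok)) {
      warning(sum(!ok), " non-standard concept(s) without a unique standard ",
              "target left unmapped", call. = FALSE)
    }
  }
  as.integer(out)
}

#' Map verbatim drug strings to standard concepts
#'
#' Applies the stepwise procedure per string, first hit wins:
#' \enumerate{
#'   \item `REGEX_EXACT` — exact lookup of the normalized verbatim name in
#'     the name-lookup table;
#'   \item `ACTIVE_INGREDIENT` — same lookup on the separate active
#'     ingredient field (current-dialect drug rows carry it);
#'   \item `NDA` — New Drug Application number looked up in the
#'     NDA-to-ingredient ("orange book" style) table;
#'   \item `MANUAL` — the user-supplied manual map, keyed on the raw string.
#' }
#' Any non-standard hit is resolved through [resolve_to_standard()]; a hit
#' that cannot be resolved, or no hit at all, is `UNMAPPED`.
#'
#' @param raw Character vector of verbatim drug names.
#' @param active_ingredient Optional character vector (same length) of
#'   active-ingredient strings.
#' @param nda Optional character vector of NDA numbers.
#' @param vocab A `faers_vocab` bundle.
#' @param manual_map Optional data frame with columns `source_text`,
#'   `concept_id`.
#' @return Tibble with columns `source_text`, `concept_id` (standard, or
#'   `NA`), `method` (one of `REGEX_EXACT`, `ACTIVE_INGREDIENT`, `NDA`,
#'   `MANUAL`, `UNMAPPED`).
#' @export
map_drug_names <- function(raw, active_ingredient = NULL, nda = NULL,
                           vocab, manual_map = NULL) {
  n <- length(raw)
  active_ingredient <- active_ingredient %||% rep(NA_character_, n)
  nda <- nda %||% rep(NA_character_, n)
  lk <- vocab$lookup
  lookup_ids <- function(x) lk$concept_id[match(x, lk$name)]

  hit1 <- lookup_ids(normalize_drug_name(raw))
  hit2 <- lookup_ids(normalize_drug_name(active_ingredient))
  hit3 <- vocab$nda$concept_id[match(str_trim(nda), vocab$nda$nda_num)]
  hit4 <- if (!is.null(manual_map)) {
    as.integer(manual_map$concept_id[match(raw, manual_map$source_text)])
  } else rep(NA_integer_, n)

  concept <- dplyr::coalesce(hit1, hit2, hit3, hit4)
  method <- dplyr::case_when(
    !is.na(hit1) ~ "REGEX_EXACT",
    !is.na(hit2) ~ "ACTIVE_INGREDIENT",
    !is.na(hit3) ~ "NDA",
    !is.na(hit4) ~ "MANUAL",
    TRUE ~ "UNMAPPED"
  )
  std <- resolve_to_standard(concept, vocab)
  method[is.na(std)] <- "UNMAPPED"
  tibble(source_text = raw, concept_id = std, method = method)
}

#' Map MedDRA preferred terms to SNOMED-CT
#'
#' Looks up the upper-cased, trimmed preferred term in the simplified
#' MedDRA-to-SNOMED mapping table. Misses return `NA` in both identifier
#' columns and are retained downstream with null concept ids.
#'
#' @param pt Character vector of preferred-term strings.
#' @param pt_map The mapping table (`pt`, `outcome_concept_id`,
#'   `snomed_concept_id`), e.g. `vocab$pt_map`.
#' @return Tibble with columns `pt`, `outcome_concept_id`,
#'   `snomed_concept_id`.
#' @export
map_meddra_pt <- function(pt, pt_map) {
  key <- str_to_upper(str_squish(ifelse(is.na(pt), "", pt)))
  idx <- match(key, str_to_upper(str_squish(pt_map$pt)))
  tibble(pt = pt,
         outcome_concept_id = pt_map$outcome_concept_id[idx],
         snomed_concept_id = pt_map$snomed_concept_id[idx])
}

#' Summarise mapping coverage
#'
#' Reports the fraction of unique drug strings mapped, the fraction of
#' cases whose drugs are all mapped, and the fractions of unique reaction
#' and indication preferred terms mapped. Zero denominators yield `NA`
#' rather than an error.
#'
#' @param drug_results Tibble from [map_drug_names()] (one row per drug
#'   occurrence), optionally with a `caseid` column for the per-case rate.
#' @param reac_results,indi_results Optional tibbles from [map_meddra_pt()].
#' @return One-row tibble of coverage fractions and unique mapped counts.
#' @export
coverage_report <- function(drug_results, reac_results = NULL,
                            indi_results = NULL) {
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  u <- distinct(drug_results, .data$source_text, .keep_all = TRUE)
  drug_unique_frac <- frac(sum(!is.na(u$concept_id)), nrow(u))
  case_frac <- if ("caseid" %in% names(drug_results) && nrow(drug_results) > 0) {
    per_case <- drug_results |>
      group_by(.data$caseid) |>
      summarise(all_mapped = all(!is.na(.data$concept_id)), .groups = "drop")
    frac(sum(per_case$all_mapped), nrow(per_case))
  } else NA_real_
  pt_cov <- function(res) {
    if (is.null(res) || nrow(res) == 0) return(c(NA_real_, 0))
    up <- distinct(res, .data$pt, .keep_all = TRUE)
    c(frac(sum(!is.na(up$snomed_concept_id)), nrow(up)),
      sum(!is.na(up$snomed_concept_id)))
  }
  rc <- pt_cov(reac_results)
  ic <- pt_cov(indi_results)
  tibble(
    drug_string_coverage = drug_unique_frac,
    case_all_drugs_mapped = case_frac,
    reaction_pt_coverage = rc[1],
    indication_pt_coverage = ic[1],
    n_unique_drugs_mapped = dplyr::n_distinct(u$concept_id[!is.na(u$concept_id)]),
    n_unique_reactions_mapped = as.integer(rc[2]),
    n_unique_indications_mapped = as.integer(ic[2])
  )
}
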