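# Seeded synthetic FAERS/LAERS corpus with known ground truth.
#
# The generator emulates the structures the curation pipeline has to cope
# with: multi-version cases (initial 'I' plus follow-up 'F' submissions),
# cases duplicated across the legacy and current distributions, missing
# demographic fields, drug-name variants (brand names, trailing dose/form
# tokens, misspellings, NDA-number strings), MedDRA PT reactions and
# indications, and a miniature internally consistent vocabulary. The
# surviving-case ground truth is computed here by a direct, loop-based
# application of the selection rules — a code path structurally independent
# of the dedup module — so the two can be compared as oracle and subject.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.synth_countries <- function() {
  tibble(
    name = c("UNITED STATES", "UNITED KINGDOM", "JAPAN", "FRANCE", "GERMANY",
             "CANADA", "ITALY", "SPAIN", "BRAZIL", "AUSTRALIA"),
    code = c("US", "GB", "JP", "FR", "DE", "CA", "IT", "ES", "BR", "AU")
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults are the study conditions under which the pipeline's guarantees
#' are exercised; see the methods vignette for the rationale behind each.
#'
#' @param n_cases Number of true cases.
#' @param followup_rate Probability a case gains at least one follow-up
#'   ('F') version (geometric tail, capped at 3 extras).
#' @param cross_dataset_rate Probability a case appears in both the legacy
#'   and the current data set.
#' @param missing_one_rate,missing_two_rate Probabilities that a version is
#'   emitted with exactly one / exactly two demographic fields blanked.
#' @param orphan_duplicate_rate Probability a case spawns a duplicate under
#'   a different case number with an identical, fully populated demographic
#'   key.
#' @param n_ingredients Number of true standard drug (ingredient) concepts.
#' @param variant_rates Named numeric vector with entries `brand`, `dose`,
#'   `misspell`, `nda`: probabilities that a drug string is emitted as a
#'   brand name, with a trailing dose/form token, misspelled (unmappable),
#'   or as an NDA-number string; the remainder are verbatim ingredient
#'   names.
#' @param n_pts Number of MedDRA preferred-term strings.
#' @param pt_mapped_fraction Fraction of PTs given a SNOMED mapping row.
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   corpus.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 1000, followup_rate = 0.3,
                         cross_dataset_rate = 0.1, missing_one_rate = 0.15,
                         missing_two_rate = 0.05, orphan_duplicate_rate = 0.03,
                         n_ingredients = 20,
                         variant_rates = c(brand = 0.25, dose = 0.20,
                                           misspell = 0.07, nda = 0.10),
                         n_pts = 30, pt_mapped_fraction = 0.8, seed = 1) {
  probs <- c(followup_rate, cross_dataset_rate, missing_one_rate,
             missing_two_rate, orphan_duplicate_rate, pt_mapped_fraction,
             variant_rates)
  if (any(probs < 0 | probs > 1)) stop("all rates must lie in [0, 1]",
                                       call. = FALSE)
  if (missing_one_rate + missing_two_rate > 1) {
    stop("missing_one_rate + missing_two_rate must not exceed 1", call. = FALSE)
  }
  if (sum(variant_rates) > 1) stop("variant_rates must sum to at most 1",
                                   call. = FALSE)
  if (n_cases < 1 || n_ingredients < 1 || n_pts < 1) {
    stop("n_cases, n_ingredients and n_pts must be at least 1", call. = FALSE)
  }
  stopifnot(all(c("brand", "dose", "misspell", "nda") %in% names(variant_rates)))
  structure(list(n_cases = as.integer(n_cases), followup_rate = followup_rate,
                 cross_dataset_rate = cross_dataset_rate,
                 missing_one_rate = missing_one_rate,
                 missing_two_rate = missing_two_rate,
                 orphan_duplicate_rate = orphan_duplicate_rate,
                 n_ingredients = as.integer(n_ingredients),
                 variant_rates = variant_rates, n_pts = as.integer(n_pts),
                 pt_mapped_fraction = pt_mapped_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.fake_words <- function(n, seed_offset = 0) {
  syll <- c("VA", "LO", "TRE", "MIR", "ZAN", "QUE", "FOS", "NIB", "DAX", "RU",
            "PEL", "TOR", "GA", "CIM", "BEX", "YLO", "SUN", "KRA", "VEN", "OLM")
  out <- character(n)
  for (i in seq_len(n)) {
    k <- 2 + (i %% 2)
    out[i] <- paste0(paste(sample(syll, k, replace = TRUE), collapse = ""),
                     sprintf("%02d", i))
  }
  out
}

#' Generate the fixture vocabulary bundle
#'
#' Builds a miniature, internally consistent vocabulary: one standard
#' ingredient concept per drug, two non-standard brand concepts per
#' ingredient with relationship rows to their ingredient, a name-lookup
#' table over both, a PT-to-SNOMED mapping covering `pt_mapped_fraction` of
#' the PT list, and an NDA-number-to-ingredient table.
#'
#' @param config A [synth_config()].
#' @return A `faers_vocab` bundle; additionally carries the full `pt_list`
#'   as an attribute.
#' @export
synth_vocabulary <- function(config) {
  .with_seed(config$seed, {
    n <- config$n_ingredients
    ing_names <- .fake_words(n)
    ing_ids <- 1000L + seq_len(n)
    brand_names <- paste0(.fake_words(2 * n), "EX")
    brand_ids <- 5000L + seq_len(2 * n)
    brand_of <- rep(ing_ids, each = 2)
    concept <- bind_rows(
      tibble(concept_id = ing_ids, concept_code = paste0("RX", ing_ids),
             vocabulary = "RxNorm", concept_name = ing_names, standard = TRUE),
      tibble(concept_id = brand_ids, concept_code = paste0("RXB", brand_ids),
             vocabulary = "RxNorm", concept_name = brand_names, standard = FALSE)
    )
    lookup <- tibble(name = c(ing_names, brand_names),
                     concept_id = c(ing_ids, brand_ids))
    relationship <- tibble(concept_id_1 = brand_ids, concept_id_2 = brand_of)
    pts <- paste0(.fake_words(config$n_pts), " DISORDER")
    n_map <- round(config$pt_mapped_fraction * config$n_pts)
    pt_map <- tibble(pt = pts[seq_len(n_map)],
                     outcome_concept_id = 7000L + seq_len(n_map),
                     snomed_concept_id = as.character(44054000L + seq_len(n_map)))
    # SNOMED outcome concepts so every pt_map target exists in the bundle
    concept <- bind_rows(concept,
      tibble(concept_id = 7000L + seq_len(n_map),
             concept_code = pt_map$snomed_concept_id,
             vocabulary = "SNOMED", concept_name = pt_map$pt, standard = TRUE))
    nda <- tibble(nda_num = sprintf("%06d", 20000L + seq_len(n)),
                  concept_id = ing_ids)
    vocab <- validate_vocabulary(list(concept = concept, lookup = lookup,
                                      relationship = relationship,
                                      pt_map = pt_map, nda = nda))
    attr(vocab, "pt_list") <- pts
    vocab
  })
}

#' Write a vocabulary bundle to a directory
#' @param vocab A `faers_vocab` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_vocabulary <- function(vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- mutate(vocab$concept, standard = if_else(.data$standard, "Y", "N"))
  readr::write_tsv(con, file.path(dir, "concept.tsv"), progress = FALSE)
  readr::write_tsv(vocab$lookup, file.path(dir, "concept_name_lookup.tsv"),
                   progress = FALSE)
  readr::write_tsv(vocab$relationship,
                   file.path(dir, "concept_relationship.tsv"), progress = FALSE)
  readr::write_tsv(vocab$pt_map, file.path(dir, "pt_snomed_map.tsv"),
                   progress = FALSE)
  readr::write_tsv(vocab$nda, file.path(dir, "nda_ingredient.tsv"),
                   progress = FALSE)
  invisible(dir)
}

# one misspelling that is guaranteed not to collide with any lookup name
.misspell <- function(name, lookup_names) {
  cand <- paste0(substr(name, 1, 1), substr(name, 3, nchar(name)))
  while (cand %in% lookup_names || cand == name) cand <- paste0(cand, "X")
  cand
}

#' Generate a synthetic quarterly-report corpus with ground truth
#'
#' Emits DEMO/DRUG/REAC/INDI/OUTC content across several synthetic quarters
#' in both source dialects, plus a [GroundTruth]-style list computed by a
#' direct application of the imputation and de-duplication rules that is
#' independent of the pipeline modules.
#'
#' @param config A [synth_config()].
#' @param vocab The matching bundle from [synth_vocabulary()].
#' @param dir Optional directory; when given, the quarterly `$`-delimited
#'   files are written there (byte-identical for identical config + seed).
#' @return List with elements `corpus` (an in-memory `faers_corpus`),
#'   `truth` (list: `latest_version_of_case`, `surviving_cases`,
#'   `drug_string_truth`, `pt_truth`), and `files` (paths written, or
#'   `NULL`).
#' @export
synth_corpus <- function(config, vocab, dir = NULL) {
  .with_seed(config$seed + 1L, {
    countries <- .synth_countries()
    pts <- attr(vocab, "pt_list")
    mapped_pts <- vocab$pt_map$pt
    ing <- filter(vocab$concept, .data$standard, .data$vocabulary == "RxNorm")
    brands <- filter(vocab$concept, !.data$standard)
    brand_target <- vocab$relationship$concept_id_2[
      match(brands$concept_id, vocab$relationship$concept_id_1)]
    lookup_names <- vocab$lookup$name
    lq <- list(c(2011L, 4L), c(2012L, 1L), c(2012L, 2L))
    cq <- list(c(2012L, 4L), c(2013L, 1L), c(2013L, 2L))
    dose_suffixes <- c(" 50 MG", " 100 MG TABLET", " (10 MG)", " CAP.",
                      " SOLUTION", " 2 MG/ML INJ")
    outc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

    isr_counter <- 4000000L
    pid_counter <- 70000000L
    demo <- list(); drug <- list(); reac <- list(); indi <- list(); outc <- list()
    truth_versions <- list()
    drug_truth <- list()

    emit_case <- function(caseid, dialects, n_versions, true_demo, case_drugs,
                          case_pts, case_indi, case_outc, force_full = FALSE) {
      # split versions over dialects, chronology: legacy first
      if (length(dialects) == 2) {
        nl <- max(1L, floor(n_versions / 2)); nc <- max(1L, n_versions - nl)
        vdial <- c(rep("LEGACY", nl), rep("CURRENT", nc))
      } else {
        vdial <- rep(dialects, n_versions)
      }
      nv <- length(vdial)
      if_codes <- c("I", rep("F", nv - 1L))
      for (j in seq_len(nv)) {
        dialect <- vdial[j]
        qs <- if (dialect == "LEGACY") lq else cq
        jq <- if (dialect == "LEGACY") j else j - sum(vdial == "LEGACY")
        yq <- qs[[min(max(jq, 1L), length(qs))]]
        if (dialect == "LEGACY") {
          isr_counter <<- isr_counter + 1L; key <- as.character(isr_counter)
        } else {
          pid_counter <<- pid_counter + 1L; key <- as.character(pid_counter)
        }
        # observed demographic fields: possibly blank one or two
        blank <- character(0)
        if (!force_full) {
          u <- stats::runif(1)
          if (u < config$missing_two_rate) {
            blank <- sample(c("date", "age", "sex", "country"), 2)
          } else if (u < config$missing_two_rate + config$missing_one_rate) {
            blank <- sample(c("date", "age", "sex", "country"), 1)
          }
        }
        partial <- !("date" %in% blank) && stats::runif(1) < 0.05
        date_written <- if ("date" %in% blank) "" else
          if (partial) substr(true_demo$date, 1, 6) else true_demo$date
        age_written <- if ("age" %in% blank) "" else true_demo$age_value
        age_cod <- if ("age" %in% blank) "" else true_demo$age_unit
        sex_written <- if ("sex" %in% blank) "" else true_demo$sex
        country_written <- if ("country" %in% blank) "" else
          if (dialect == "LEGACY") true_demo$country_name else true_demo$country_code
        demo[[length(demo) + 1L]] <<- list(
          dialect = dialect, year = yq[1], quarter = yq[2], case_key = key,
          caseid = caseid, i_f = if_codes[j], event_dt = date_written,
          age = age_written, age_cod = age_cod, sex = sex_written,
          country = country_written)
        truth_versions[[length(truth_versions) + 1L]] <<- list(
          caseid = caseid, dialect = dialect, key = as.numeric(key),
          year = yq[1], quarter = yq[2],
          date = if ("date" %in% blank) NA_character_ else
            if (partial) paste0(substr(true_demo$date, 1, 6), "01") else true_demo$date,
          age = if ("age" %in% blank) NA_real_ else true_demo$age_years,
          sex = if ("sex" %in% blank) NA_character_ else true_demo$sex,
          country = if ("country" %in% blank) NA_character_ else true_demo$country_code)
        for (k in seq_len(nrow(case_drugs))) {
          drug[[length(drug) + 1L]] <<- list(
            dialect = dialect, year = yq[1], quarter = yq[2], case_key = key,
            caseid = caseid, drug_seq = as.character(k),
            role_cod = case_drugs$role[k], drugname = case_drugs$string[k],
            prod_ai = "", nda_num = case_drugs$nda[k])
        }
        for (p in case_pts) {
          reac[[length(reac) + 1L]] <<- list(
            dialect = dialect, year = yq[1], quarter = yq[2], case_key = key,
            caseid = caseid, pt = p)
        }
        if (nrow(case_indi) > 0) {
          for (k in seq_len(nrow(case_indi))) {
            indi[[length(indi) + 1L]] <<- list(
              dialect = dialect, year = yq[1], quarter = yq[2], case_key = key,
              caseid = caseid, indi_drug_seq = case_indi$drug_seq[k],
              indi_pt = case_indi$pt[k])
          }
        }
        for (oc in case_outc) {
          outc[[length(outc) + 1L]] <<- list(
            dialect = dialect, year = yq[1], quarter = yq[2], case_key = key,
            caseid = caseid, outc_cod = oc)
        }
      }
    }

    sample_demo <- function() {
      date <- format(as.Date("2011-01-01") + sample.int(730, 1) - 1L, "%Y%m%d")
      age_years <- sample(0:100, 1)
      unit <- sample(c("YR", "MON", "WK", "DY", "DEC"), 1,
                     prob = c(0.7, 0.1, 0.05, 0.05, 0.1))
      if (unit == "DEC" && age_years %% 10 != 0) unit <- "YR"
      value <- switch(unit, YR = age_years, MON = age_years * 12,
                      WK = age_years * 52, DY = age_years * 365,
                      DEC = age_years %/% 10)
      ci <- sample.int(nrow(countries), 1)
      list(date = date, age_years = as.numeric(age_years),
           age_value = as.character(value), age_unit = unit,
           sex = sample(c("M", "F"), 1),
           country_name = countries$name[ci], country_code = countries$code[ci])
    }

    sample_drugs <- function() {
      nd <- sample.int(5, 1)
      idx <- sample.int(nrow(ing), min(nd, nrow(ing)))
      nd <- length(idx)
      roles <- c("PS", if (nd > 1) sample(c("PS", "SS", "C", "I"), nd - 1,
                                          replace = TRUE))
      vr <- config$variant_rates
      variants <- sample(c("exact", "brand", "dose", "misspell", "nda"), nd,
                         replace = TRUE,
                         prob = c(1 - sum(vr), vr["brand"], vr["dose"],
                                  vr["misspell"], vr["nda"]))
      strings <- character(nd); ndas <- character(nd)
      concepts <- ing$concept_id[idx]
      truth_id <- concepts
      for (k in seq_len(nd)) {
        ing_id <- concepts[k]
        ing_name <- ing$concept_name[match(ing_id, ing$concept_id)]
        bset <- brands$concept_name[brand_target == ing_id]
        strings[k] <- switch(variants[k],
          exact = ing_name,
          brand = sample(bset, 1),
          dose = paste0(if (stats::runif(1) < 0.5) ing_name else sample(bset, 1),
                        sample(dose_suffixes, 1)),
          misspell = .misspell(ing_name, lookup_names),
          nda = paste0("STUDY DRUG ",
                       vocab$nda$nda_num[match(ing_id, vocab$nda$concept_id)]))
        ndas[k] <- if (variants[k] == "nda") {
          vocab$nda$nda_num[match(ing_id, vocab$nda$concept_id)]
        } else ""
        if (variants[k] == "misspell") truth_id[k] <- NA_integer_
        drug_truth[[strings[k]]] <<- truth_id[k]
      }
      tibble(string = strings, role = roles, nda = ndas, concept = truth_id)
    }

    make_case_content <- function() {
      drugs <- sample_drugs()
      case_pts <- sample(pts, sample.int(5, 1))
      indi <- list()
      for (k in seq_len(nrow(drugs))) {
        ni <- sample(0:2, 1)
        if (ni > 0) {
          indi[[length(indi) + 1L]] <- tibble(drug_seq = as.character(k),
                                              pt = sample(pts, ni))
        }
      }
      indi <- if (length(indi) > 0) bind_rows(indi) else
        tibble(drug_seq = character(0), pt = character(0))
      oc <- sample(outc_codes, sample(0:2, 1))
      list(drugs = drugs, pts = case_pts, indi = indi, outc = oc)
    }

    for (i in seq_len(config$n_cases)) {
      caseid <- as.character(3000000L + i)
      both <- stats::runif(1) < config$cross_dataset_rate
      dialects <- if (both) c("LEGACY", "CURRENT") else
        sample(c("LEGACY", "CURRENT"), 1)
      n_extra <- min(stats::rgeom(1, 1 - config$followup_rate), 3L)
      nv <- 1L + n_extra
      td <- sample_demo()
      cc <- make_case_content()
      emit_case(caseid, dialects, nv, td, cc$drugs, cc$pts, cc$indi, cc$outc)
      if (stats::runif(1) < config$orphan_duplicate_rate) {
        ocid <- as.character(8000000L + i)
        occ <- make_case_content()
        emit_case(ocid, sample(c("LEGACY", "CURRENT"), 1), 1L, td,
                  occ$drugs, occ$pts, occ$indi, occ$outc, force_full = TRUE)
      }
    }

    demo_t <- .rows_to_tibble(demo)
    drug_t <- .rows_to_tibble(drug)
    reac_t <- .rows_to_tibble(reac)
    indi_t <- .rows_to_tibble(indi)
    outc_t <- .rows_to_tibble(outc)

    truth <- .truth_from_versions(truth_versions)
    truth$drug_string_truth <- tibble(
      drug_string = names(drug_truth),
      concept_id = as.integer(unlist(lapply(drug_truth, function(x) {
        if (is.na(x)) NA_integer_ else x
      }))))
    truth$pt_truth <- tibble(
      pt = pts,
      snomed_concept_id = vocab$pt_map$snomed_concept_id[
        match(pts, vocab$pt_map$pt)])

    corpus <- .synth_as_corpus(demo_t, drug_t, reac_t, indi_t, outc_t)
    files <- if (!is.null(dir)) .write_synth_files(corpus, dir) else NULL
    list(corpus = corpus, truth = truth, files = files)
  })
}

.rows_to_tibble <- function(rows) {
  if (length(rows) == 0) return(tibble())
  nm <- names(rows[[1]])
  cols <- lapply(nm, function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE))
  names(cols) <- nm
  as_tibble(cols)
}

# shape generator output like read_corpus() output (empty string -> NA)
.synth_as_corpus <- function(demo, drug, reac, indi, outc) {
  base_cols <- c("dialect", "year", "quarter", "case_key", "caseid")
  empty_with <- function(extra) {
    tibble(dialect = character(0), year = integer(0), quarter = integer(0),
           case_key = character(0), caseid = character(0)) |>
      dplyr::bind_cols(as_tibble(stats::setNames(
        rep(list(character(0)), length(extra)), extra)))
  }
  shape <- function(tbl, extra) {
    if (nrow(tbl) == 0) return(empty_with(extra))
    tbl |>
      mutate(across(dplyr::where(is.character),
                    ~ dplyr::na_if(str_trim(.x), ""))) |>
      mutate(year = as.integer(.data$year), quarter = as.integer(.data$quarter))
  }
  demo <- shape(demo, c("i_f", "event_dt", "age", "age_cod", "sex", "country"))
  structure(list(
    demo = tibble(dialect = demo$dialect, year = demo$year,
                  quarter = demo$quarter, case_key = demo$case_key,
                  caseid = demo$caseid, i_f_code = demo$i_f,
                  event_dt = demo$event_dt, age = demo$age,
                  age_cod = demo$age_cod, sex = demo$sex,
                  reporter_country = demo$country),
    drug = shape(drug, c("drug_seq", "role_cod", "drugname", "prod_ai",
                         "nda_num")),
    reac = shape(reac, "pt"),
    indi = shape(indi, c("indi_drug_seq", "indi_pt")),
    outc = shape(outc, "outc_cod"),
    passthrough = list()
  ), class = "faers_corpus")
}

# ---- independent ground-truth oracle ---------------------------------------
# Plain loops, no dplyr, no calls into merge_impute/dedup: single missing
# value imputation from the per-field maxima of fully populated sibling
# versions, then latest-version selection by (current data set, descending
# numeric key, descending file quarter), then collapse of equal fully
# populated demographic keys.
.truth_from_versions <- function(vs) {
  by_case <- split(vs, vapply(vs, `[[`, "", "caseid"))
  # imputation
  for (cid in names(by_case)) {
    group <- by_case[[cid]]
    full <- Filter(function(v) {
      !is.na(v$date) && !is.na(v$age) && !is.na(v$sex) && !is.na(v$country)
    }, group)
    if (length(full) > 0) {
      donor <- list(
        date = max(vapply(full, `[[`, "", "date")),
        age = max(vapply(full, `[[`, 0, "age")),
        sex = max(vapply(full, `[[`, "", "sex")),
        country = max(vapply(full, `[[`, "", "country")))
      for (j in seq_along(group)) {
        v <- group[[j]]
        miss <- c(is.na(v$date), is.na(v$age), is.na(v$sex), is.na(v$country))
        if (sum(miss) == 1) {
          if (miss[1]) v$date <- donor$date
          if (miss[2]) v$age <- donor$age
          if (miss[3]) v$sex <- donor$sex
          if (miss[4]) v$country <- donor$country
          group[[j]] <- v
        }
      }
      by_case[[cid]] <- group
    }
  }
  more_recent <- function(v1, v2) {
    c1 <- if (v1$dialect == "CURRENT") 1 else 0
    c2 <- if (v2$dialect == "CURRENT") 1 else 0
    if (c1 != c2) return(c1 > c2)
    if (v1$key != v2$key) return(v1$key > v2$key)
    if (v1$year != v2$year) return(v1$year > v2$year)
    v1$quarter > v2$quarter
  }
  latest <- list()
  for (cid in names(by_case)) {
    best <- by_case[[cid]][[1]]
    for (v in by_case[[cid]][-1]) if (more_recent(v, best)) best <- v
    latest[[cid]] <- best
  }
  # demographic-key collapse over fully populated keys
  survivors <- character(0)
  groups <- list()
  for (cid in names(latest)) {
    v <- latest[[cid]]
    if (!is.na(v$date) && !is.na(v$age) && !is.na(v$sex) && !is.na(v$country)) {
      k <- paste(v$date, format(v$age, digits = 15), v$sex, v$country, sep = "|")
      if (is.null(groups[[k]]) || more_recent(v, latest[[groups[[k]]]])) {
        groups[[k]] <- cid
      }
    } else {
      survivors <- c(survivors, cid)
    }
  }
  survivors <- sort(c(survivors, unlist(groups, use.names = FALSE)))
  list(
    latest_version_of_case = vapply(latest, function(v) as.character(v$key), ""),
    surviving_cases = survivors
  )
}

# ---- file emission ---------------------------------------------------------
.synth_headers <- list(
  LEGACY = list(
    DEMO = c("ISR", "CASE", "I_F_COD", "EVENT_DT", "AGE", "AGE_COD",
             "GNDR_COD", "REPORTER_COUNTRY"),
    DRUG = c("ISR", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "NDA_NUM"),
    REAC = c("ISR", "PT"),
    INDI = c("ISR", "DRUG_SEQ", "INDI_PT"),
    OUTC = c("ISR", "OUTC_COD")
  ),
  CURRENT = list(
    DEMO = c("primaryid", "caseid", "i_f_cod", "event_dt", "age", "age_cod",
             "sex", "reporter_country"),
    DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
             "prod_ai", "nda_num"),
    REAC = c("primaryid", "caseid", "pt"),
    INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
    OUTC = c("primaryid", "caseid", "outc_cod")
  )
)

.write_synth_files <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cells <- function(tbl, kind, dialect) {
    blank <- function(x) ifelse(is.na(x), "", x)
    switch(kind,
      DEMO = if (dialect == "LEGACY") {
        cbind(tbl$case_key, tbl$caseid, blank(tbl$i_f_code), blank(tbl$event_dt),
              blank(tbl$age), blank(tbl$age_cod), blank(tbl$sex),
              blank(tbl$reporter_country))
      } else {
        cbind(tbl$case_key, tbl$caseid, blank(tbl$i_f_code), blank(tbl$event_dt),
              blank(tbl$age), blank(tbl$age_cod), blank(tbl$sex),
              blank(tbl$reporter_country))
      },
      DRUG = if (dialect == "LEGACY") {
        cbind(tbl$case_key, blank(tbl$drug_seq), blank(tbl$role_cod),
              blank(tbl$drugname), blank(tbl$nda_num))
      } else {
        cbind(tbl$case_key, tbl$caseid, blank(tbl$drug_seq),
              blank(tbl$role_cod), blank(tbl$drugname), blank(tbl$prod_ai),
              blank(tbl$nda_num))
      },
      REAC = if (dialect == "LEGACY") cbind(tbl$case_key, blank(tbl$pt))
             else cbind(tbl$case_key, tbl$caseid, blank(tbl$pt)),
      INDI = if (dialect == "LEGACY") {
        cbind(tbl$case_key, blank(tbl$indi_drug_seq), blank(tbl$indi_pt))
      } else {
        cbind(tbl$case_key, tbl$caseid, blank(tbl$indi_drug_seq),
              blank(tbl$indi_pt))
      },
      OUTC = if (dialect == "LEGACY") cbind(tbl$case_key, blank(tbl$outc_cod))
             else cbind(tbl$case_key, tbl$caseid, blank(tbl$outc_cod))
    )
  }
  for (kind in c("DEMO", "DRUG", "REAC", "INDI", "OUTC")) {
    tbl <- corpus[[tolower(kind)]]
    if (nrow(tbl) == 0) next
    combos <- distinct(tbl, .data$dialect, .data$year, .data$quarter) |>
      arrange(.data$dialect, .data$year, .data$quarter)
    for (r in seq_len(nrow(combos))) {
      sub <- filter(tbl, .data$dialect == combos$dialect[r],
                    .data$year == combos$year[r],
                    .data$quarter == combos$quarter[r]) |>
        arrange(as.numeric(.data$case_key))
      hdr <- .synth_headers[[combos$dialect[r]]][[kind]]
      path <- file.path(dir, sprintf("%s%02dQ%d.txt", kind,
                                     combos$year[r] %% 100, combos$quarter[r]))
      mat <- cells(sub, kind, combos$dialect[r])
      lines <- c(paste(hdr, collapse = "$"),
                 apply(mat, 1, paste, collapse = "$"))
      writeLines(lines, path, useBytes = TRUE)
      files <- c(files, path)
    }
  }
  files
}
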