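test_that("age normalization converts unit codes to years", {
  expect_equal(normalize_age("24", "MON"), 2)
  expect_equal(normalize_age("50", "YR"), 50)
  expect_equal(normalize_age("5", "DEC"), 50)
  expect_equal(normalize_age("104", "WK"), 2)
  expect_equal(normalize_age("730", "DY"), 2)
  expect_equal(normalize_age("8760", "HR"), 1)
  expect_true(is.na(normalize_age("", "YR")))
  expect_true(is.na(normalize_age("abc", "YR")))
  expect_true(is.na(normalize_age("50", "XX")))
  expect_equal(normalize_age("50", NA), 50)  # absent unit treated as years
})

test_that("country normalization is dialect-agnostic", {
  expect_equal(normalize_country("UNITED STATES"), "US")
  expect_equal(normalize_country("US"), "US")
  expect_equal(normalize_country("united states "), "US")
  expect_equal(normalize_country("NARNIA"), "NARNIA")  # unmapped passes upper
  expect_true(is.na(normalize_country("")))
  expect_true(is.na(normalize_country(NA_character_)))
})

test_that("event dates keep partials, padded for ordering", {
  expect_equal(normalize_event_date(c("20120315", "201203", "2012", "bad", "")),
               c("20120315", "20120301", "20120101", NA, NA))
})

test_that("merging concatenates and preserves both key fields", {
  l <- dplyr::bind_rows(version_row("1", "LEGACY", "10"),
                        version_row("2", "LEGACY", "11"))
  c_ <- dplyr::bind_rows(version_row("3", "CURRENT", "900"),
                         version_row("4", "CURRENT", "901"),
                         version_row("5", "CURRENT", "902"))
  m <- merge_datasets(l, c_)
  expect_equal(nrow(m), 5)
  expect_true(all(is.na(m$primaryid[m$dialect == "LEGACY"])))
  expect_true(all(!is.na(m$isr[m$dialect == "LEGACY"])))
  expect_equal(nrow(merge_datasets(l[0, ], c_[0, ])), 0)
  # multiset of (caseid, key) preserved
  expect_setequal(paste(m$caseid, dplyr::coalesce(m$isr, m$primaryid)),
                  c("1 10", "2 11", "3 900", "4 901", "5 902"))
})

test_that("imputation fills a single missing field from the per-field maxima", {
  v <- dplyr::bind_rows(
    version_row("1", key = "1", event_date = "20120101", age_years = 50,
                sex = "F", country = "US"),
    version_row("1", key = "2", event_date = "20120301", age_years = 40,
                sex = "F", country = "US"),
    version_row("1", key = "3", age_years = NA))
  out <- impute_demographics(v)
  # donor age is the max over fully populated versions: 50
  expect_equal(out$age_years[3], 50)
  # donor date would be the later one if date were missing
  v2 <- v; v2$event_date[3] <- NA; v2$age_years[3] <- 30
  out2 <- impute_demographics(v2)
  expect_equal(out2$event_date[3], "20120301")
})

test_that("two or more missing fields are never imputed; no full sibling, no-op", {
  v <- dplyr::bind_rows(
    version_row("1", key = "1"),
    version_row("1", key = "2", age_years = NA, sex = NA_character_))
  out <- impute_demographics(v)
  expect_true(is.na(out$age_years[2]) && is.na(out$sex[2]))
  # no fully populated version: nothing changes
  v2 <- dplyr::bind_rows(
    version_row("2", key = "3", age_years = NA),
    version_row("2", key = "4", sex = NA_character_))
  expect_equal(impute_demographics(v2), v2)
})

test_that("imputation contract holds on randomized version sets", {
  set.seed(11)
  fields <- c("event_date", "age_years", "sex", "country")
  for (rep in 1:40) {
    n_cases <- sample(1:6, 1)
    rows <- list()
    key <- 0
    for (cid in seq_len(n_cases)) {
      for (j in seq_len(sample(1:4, 1))) {
        key <- key + 1
        r <- version_row(as.character(cid), key = as.character(key),
                         event_date = sample(c("20120101", "20120601"), 1),
                         age_years = sample(c(10, 50, 80), 1),
                         sex = sample(c("M", "F"), 1),
                         country = sample(c("US", "JP"), 1))
        for (f in sample(fields, sample(0:3, 1))) {
          r[[f]] <- if (is.numeric(r[[f]])) NA_real_ else NA_character_
        }
        rows[[length(rows) + 1]] <- r
      }
    }
    v <- dplyr::bind_rows(rows)
    out <- impute_demographics(v)
    # idempotence
    expect_equal(impute_demographics(out), out)
    miss_in <- demographic_missing_count(v)
    miss_out <- demographic_missing_count(out)
    # never increases missingness
    expect_true(all(miss_out <= miss_in))
    # populated fields never altered
    for (f in fields) {
      keep <- !is.na(v[[f]])
      expect_identical(out[[f]][keep], v[[f]][keep])
    }
    # versions missing >= 2 fields unchanged
    expect_identical(out[miss_in >= 2, ], v[miss_in >= 2, ])
    # single missing filled exactly when a fully populated sibling exists
    has_full <- tapply(miss_in == 0, v$caseid, any)[v$caseid]
    expect_true(all(miss_out[miss_in == 1 & has_full] == 0))
    expect_true(all(miss_out[miss_in == 1 & !has_full] == 1))
  }
})

test_that("case versions built from a corpus carry order-invariant signatures", {
  d <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$i_f_cod$event_dt$age$age_cod$sex$reporter_country",
               "900$1$I$20120101$24$MON$F$US"),
             file.path(d, "DEMO12Q4.txt"))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname$prod_ai$nda_num",
               "900$1$1$PS$zebra drug$$",
               "900$1$2$C$Alpha Drug$$"),
             file.path(d, "DRUG12Q4.txt"))
  writeLines(c("primaryid$caseid$pt", "900$1$NAUSEA", "900$1$HEADACHE"),
             file.path(d, "REAC12Q4.txt"))
  cv <- build_case_versions(read_corpus(d))
  expect_equal(cv$age_years, 2)
  expect_equal(cv$drug_list_key, "ALPHA DRUG|ZEBRA DRUG")
  expect_equal(cv$reaction_list_key, "HEADACHE|NAUSEA")
})
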