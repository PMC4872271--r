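test_that("each drug-name normalization rule works in isolation", {
  expect_equal(normalize_drug_name("aspirin"), "ASPIRIN")          # case fold
  expect_equal(normalize_drug_name("  aspirin  plus "), "ASPIRIN PLUS") # ws
  expect_equal(normalize_drug_name("\"ASPIRIN\""), "ASPIRIN")      # quotes
  expect_equal(normalize_drug_name("ETANERCEPT (50 MG)"), "ETANERCEPT") # parens
  expect_equal(normalize_drug_name("ASPIRIN 81 MG"), "ASPIRIN")    # dose
  expect_equal(normalize_drug_name("ASPIRIN 81 MG TABLET"), "ASPIRIN")
  expect_equal(normalize_drug_name("ASPIRIN CAP."), "ASPIRIN")     # form + punct
  expect_equal(normalize_drug_name("ASPIRIN 2 MG/ML INJ"), "ASPIRIN")
  expect_equal(normalize_drug_name("ASPIRIN."), "ASPIRIN")         # punct
  expect_equal(normalize_drug_name(""), "")
  expect_equal(normalize_drug_name(NA_character_), "")
  # a dose token inside the name is not stripped
  expect_equal(normalize_drug_name("VITAMIN B12 COMPLEX"), "VITAMIN B12 COMPLEX")
})

test_that("stepwise drug mapping tries name, ingredient, NDA, manual in order", {
  v <- mini_vocab()
  manual <- tibble::tibble(source_text = "weird name 42", concept_id = 1L)
  res <- map_drug_names(
    raw = c("Enbrel 50 MG", "garbage1", "garbage2", "weird name 42", "junk"),
    active_ingredient = c(NA, "etanercept", NA, NA, NA),
    nda = c(NA, NA, "020000", NA, NA),
    vocab = v, manual_map = manual)
  expect_equal(res$method, c("REGEX_EXACT", "ACTIVE_INGREDIENT", "NDA",
                             "MANUAL", "UNMAPPED"))
  # brand hit resolves to its standard ingredient
  expect_equal(res$concept_id, c(2L, 2L, 2L, 1L, NA))
  # method UNMAPPED <=> concept null
  expect_identical(is.na(res$concept_id), res$method == "UNMAPPED")
  # earlier step wins even when later ones would also hit
  res2 <- map_drug_names("ASPIRIN", "ETANERCEPT", "020000", v, manual)
  expect_equal(res2$method, "REGEX_EXACT")
  expect_equal(res2$concept_id, 1L)
})

test_that("standard resolution is identity for standard, relationship for brands", {
  v <- mini_vocab()
  expect_equal(resolve_to_standard(c(1L, 2L), v), c(1L, 2L))
  expect_equal(resolve_to_standard(10L, v), 2L)
  # orphan non-standard concept: unmapped with a warning
  expect_warning(out <- resolve_to_standard(11L, v), "unmapped")
  expect_true(is.na(out))
})

test_that("vocabulary consistency is enforced at load time", {
  v <- mini_vocab()
  broken <- unclass(v)
  broken$relationship <- tibble::tibble(concept_id_1 = 10L, concept_id_2 = 999L)
  expect_error(validate_vocabulary(broken), "inconsistent")
  d <- withr::local_tempdir()
  write_vocabulary(v, d)
  v2 <- read_vocabulary(d)
  expect_equal(v2$lookup, v$lookup)
  expect_equal(v2$concept$standard, v$concept$standard)
  file.remove(file.path(d, "nda_ingredient.tsv"))
  expect_error(read_vocabulary(d), "missing")
})

test_that("preferred terms map case-insensitively; misses stay null", {
  v <- mini_vocab()
  res <- map_meddra_pt(c("Injection Site Pain", "HEADACHE", "UNKNOWN PT", NA),
                       v$pt_map)
  expect_equal(res$snomed_concept_id, c("44054001", "25064002", NA, NA))
  expect_equal(res$outcome_concept_id, c(7001L, 7002L, NA, NA))
})

test_that("coverage report handles full, partial and empty inputs", {
  full <- tibble::tibble(caseid = c("1", "1", "2"),
                         source_text = c("A", "B", "A"),
                         concept_id = c(1L, 2L, 1L), method = "REGEX_EXACT")
  expect_equal(coverage_report(full)$drug_string_coverage, 1)
  part <- full; part$concept_id[2] <- NA
  rep <- coverage_report(part)
  expect_equal(rep$drug_string_coverage, 0.5)
  expect_equal(rep$case_all_drugs_mapped, 0.5)  # case 1 has the unmapped B
  empty <- coverage_report(full[0, ])
  expect_true(is.na(empty$drug_string_coverage))
  expect_equal(empty$n_unique_drugs_mapped, 0L)
})

test_that("mapping recovers the constructed truth on a fixture corpus", {
  cfg <- synth_config(n_cases = 300, seed = 9)
  vocab <- synth_vocabulary(cfg)
  sc <- synth_corpus(cfg, vocab)
  truth <- sc$truth$drug_string_truth
  res <- map_drug_names(truth$drug_string,
                        nda = sc$corpus$drug$nda_num[
                          match(truth$drug_string, sc$corpus$drug$drugname)],
                        vocab = vocab)
  # deterministic lookups recover every mappable string; misspellings stay
  # unmapped (the injected unmappable fraction)
  expect_identical(res$concept_id, truth$concept_id)
})
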