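test_that("triples are the distinct case-drug-outcome combinations", {
  cd <- tibble::tibble(caseid = "1", drug_concept_id = c(1L, 2L))
  co <- tibble::tibble(caseid = "1", outcome_concept_id = c(10L, 11L, 12L))
  expect_equal(nrow(enumerate_triples(cd, co)), 6)  # 2 x 3 product
  # two strings mapping to one concept collapse
  cd2 <- tibble::tibble(caseid = "1", drug_concept_id = c(1L, 1L))
  co2 <- tibble::tibble(caseid = "1", outcome_concept_id = 10L)
  expect_equal(nrow(enumerate_triples(cd2, co2)), 1)
  # unmapped (NA) excluded; empty input -> empty set
  cd3 <- tibble::tibble(caseid = "1", drug_concept_id = NA_integer_)
  expect_equal(nrow(enumerate_triples(cd3, co2)), 0)
  expect_equal(nrow(enumerate_triples(cd[0, ], co[0, ])), 0)
})

test_that("a four-triple universe gives the unit contingency table", {
  tr <- tibble::tibble(caseid = c("1", "2", "3", "4"),
                       drug_concept_id = c(1L, 1L, 2L, 2L),
                       outcome_concept_id = c(10L, 11L, 10L, 11L))
  ct <- build_contingency(tr, 1L, 10L)
  expect_equal(unlist(ct[, c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  # absent drug: a = 0 table
  expect_equal(build_contingency(tr, 99L, 10L)$a, 0)
})

test_that("all emitted cells match the brute-force double loop", {
  for (s in 1:3) {
    cfg <- synth_config(n_cases = 60, seed = 100 + s)
    vocab <- synth_vocabulary(cfg)
    sc <- synth_corpus(cfg, vocab)
    cv <- impute_demographics(build_case_versions(sc$corpus))
    surv <- deduplicate(cv)
    surv <- surv[, c("dialect", "version_id", "caseid")]
    drug <- sc$corpus$drug
    drug$version_id <- paste(drug$dialect, drug$case_key, sep = ":")
    drug <- dplyr::inner_join(drug, surv, by = c("dialect", "version_id"))
    dm <- map_drug_names(drug$drugname, nda = drug$nda_num, vocab = vocab)
    reac <- sc$corpus$reac
    reac$version_id <- paste(reac$dialect, reac$case_key, sep = ":")
    reac <- dplyr::inner_join(reac, surv, by = c("dialect", "version_id"))
    rm_ <- map_meddra_pt(reac$pt, vocab$pt_map)
    tr <- enumerate_triples(
      tibble::tibble(caseid = drug$caseid.y, drug_concept_id = dm$concept_id),
      tibble::tibble(caseid = reac$caseid.y,
                     outcome_concept_id = rm_$outcome_concept_id))
    ct <- contingency_tables(tr)
    expect_true(all(ct$a >= 1))
    expect_true(all(ct$a + ct$b + ct$c + ct$d == nrow(tr)))
    # sum of a-cells equals the universe size
    expect_equal(sum(ct$a), nrow(tr))
    for (i in seq_len(nrow(ct))) {
      bf <- brute_force_cells(tr, ct$drug_concept_id[i], ct$outcome_concept_id[i])
      expect_equal(unlist(ct[i, c("a", "b", "c", "d")]), bf)
    }
  }
})

test_that("PRR and ROR reproduce exact-arithmetic values on printed example cells", {
  # worked-example 2x2 cells (etanercept x injection site pain); the
  # expected values below were frozen from a 50-digit rational/mpmath
  # computation of the same formulas
  p <- compute_prr(30793, 647134, 140853, 61815244)
  expect_equal(p$prr, 19.979610645900654, tolerance = 1e-12)
  expect_equal(p$prr_ci_low, 19.7394032052008, tolerance = 1e-12)
  expect_equal(p$prr_ci_high, 20.2227411544343, tolerance = 1e-12)
  r <- compute_ror(30793, 647134, 140853, 61815244)
  expect_equal(r$ror, 20.882729861734189, tolerance = 1e-12)
  expect_equal(r$ror_ci_low, 20.621857956369, tolerance = 1e-12)
  expect_equal(r$ror_ci_high, 21.1469018650417, tolerance = 1e-12)
})

test_that("algebraic identities and null signalling hold", {
  # equal proportions -> PRR exactly 1
  expect_equal(compute_prr(10, 90, 100, 900)$prr, 1)
  expect_equal(compute_ror(5, 5, 5, 5)$ror, 1)
  # ror(a,b,c,d) * ror(b,a,d,c) = 1
  set.seed(17)
  for (i in 1:50) {
    x <- sample(1:500, 4, replace = TRUE)
    r1 <- compute_ror(x[1], x[2], x[3], x[4])$ror
    r2 <- compute_ror(x[2], x[1], x[4], x[3])$ror
    expect_equal(r1 * r2, 1, tolerance = 1e-12)
  }
  # zero cells -> NA components
  expect_true(all(is.na(compute_prr(0, 10, 10, 10))))
  expect_true(all(is.na(compute_ror(5, 0, 5, 5))))
})

test_that("monotonicity and CI behaviour", {
  a <- 20; b <- 80; c_ <- 50; d <- 850
  p0 <- compute_prr(a, b, c_, d); p1 <- compute_prr(a + 1, b - 1, c_, d)
  r0 <- compute_ror(a, b, c_, d); r1 <- compute_ror(a + 1, b - 1, c_, d)
  expect_gt(p1$prr, p0$prr)
  expect_gt(r1$ror, r0$ror)
  # CI straddles the point estimate
  expect_true(p0$prr_ci_low < p0$prr && p0$prr < p0$prr_ci_high)
  expect_true(r0$ror_ci_low < r0$ror && r0$ror < r0$ror_ci_high)
  # widths shrink when all cells scale up
  p2 <- compute_prr(10 * a, 10 * b, 10 * c_, 10 * d)
  expect_lt(p2$prr_ci_high - p2$prr_ci_low, p0$prr_ci_high - p0$prr_ci_low)
  expect_equal(p2$prr, p0$prr)  # point estimate scale-invariant
})

test_that("statistics table has one row per observed pair; Haldane optional", {
  tr <- tibble::tibble(caseid = as.character(1:5),
                       drug_concept_id = c(1L, 1L, 2L, 2L, 2L),
                       outcome_concept_id = c(10L, 11L, 10L, 10L, 12L))
  st <- signal_statistics(contingency_tables(tr))
  expect_equal(nrow(st), nrow(dplyr::distinct(tr, drug_concept_id,
                                              outcome_concept_id)))
  # zero b cell for (1,10)? compute: a=1,b=1 -> fine; pair (2,12): a=1,b=2,c=0
  expect_true(any(is.na(st$ror)))
  sth <- signal_statistics(contingency_tables(tr), haldane = TRUE)
  expect_true(all(!is.na(sth$ror)))
  # empty universe -> empty table
  expect_equal(nrow(signal_statistics(contingency_tables(tr[0, ]))), 0)
})

test_that("case-level counting unit gives case-denominated tables", {
  tr <- tibble::tibble(caseid = c("1", "1", "2"),
                       drug_concept_id = c(1L, 1L, 1L),
                       outcome_concept_id = c(10L, 11L, 10L))
  ct_t <- contingency_tables(tr, unit = "triple")
  ct_c <- contingency_tables(tr, unit = "case")
  expect_equal(ct_t$n[1], 3L)
  expect_equal(ct_c$n[1], 2L)  # two distinct cases
  expect_equal(ct_c$a[ct_c$outcome_concept_id == 10L], 2L)
})
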