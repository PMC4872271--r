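# shared fixtures built in code

# one case-version row with sensible defaults, overridable per field
version_row <- function(caseid, dialect = "CURRENT", key = "1",
                        event_date = "20120101", age_years = 50,
                        sex = "F", country = "US", year = 2012L,
                        quarter = 4L, i_f_code = "I",
                        drug_list_key = "ASPIRIN",
                        reaction_list_key = "HEADACHE") {
  tibble::tibble(
    version_id = paste(dialect, key, sep = ":"),
    isr = if (dialect == "LEGACY") key else NA_character_,
    primaryid = if (dialect == "CURRENT") key else NA_character_,
    caseid = caseid, i_f_code = i_f_code, dialect = dialect,
    year = year, quarter = quarter,
    event_date = event_date, age_years = age_years, sex = sex,
    country = country, drug_list_key = drug_list_key,
    reaction_list_key = reaction_list_key)
}

# minimal hand-built vocabulary: 2 ingredients, 1 brand, 1 orphan brand,
# 2 mapped PTs, 1 NDA row
mini_vocab <- function() {
  faersignal::validate_vocabulary(list(
    concept = tibble::tibble(
      concept_id = c(1L, 2L, 10L, 11L, 7001L),
      concept_code = c("RX1", "RX2", "RXB10", "RXB11", "44054001"),
      vocabulary = c("RxNorm", "RxNorm", "RxNorm", "RxNorm", "SNOMED"),
      concept_name = c("ASPIRIN", "ETANERCEPT", "ENBREL", "ORPHANBRAND",
                       "INJECTION SITE PAIN"),
      standard = c(TRUE, TRUE, FALSE, FALSE, TRUE)),
    lookup = tibble::tibble(
      name = c("ASPIRIN", "ETANERCEPT", "ENBREL", "ORPHANBRAND"),
      concept_id = c(1L, 2L, 10L, 11L)),
    relationship = tibble::tibble(concept_id_1 = 10L, concept_id_2 = 2L),
    pt_map = tibble::tibble(
      pt = c("INJECTION SITE PAIN", "HEADACHE"),
      outcome_concept_id = c(7001L, 7002L),
      snomed_concept_id = c("44054001", "25064002")),
    nda = tibble::tibble(nda_num = "020000", concept_id = 2L)))
}

# brute-force a,b,c,d for one pair by a double loop over the triple universe
brute_force_cells <- function(triples, drug, outcome) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(triples))) {
    has_d <- triples$drug_concept_id[i] == drug
    has_o <- triples$outcome_concept_id[i] == outcome
    if (has_d && has_o) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_o) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# arbitrary-precision PRR/ROR oracle: an independent mpmath implementation
# invoked through the system python; reads a,b,c,d CSV, writes 50-digit
# results
mpmath_oracle <- function(cells) {
  inp <- tempfile(fileext = ".csv")
  outp <- tempfile(fileext = ".csv")
  utils::write.csv(cells[, c("a", "b", "c", "d")], inp, row.names = FALSE)
  script <- '
import sys, csv
import mpmath as mp
mp.mp.dps = 50
rows = list(csv.DictReader(open(sys.argv[1])))
w = csv.writer(open(sys.argv[2], "w"))
w.writerow(["prr","prr_lo","prr_hi","ror","ror_lo","ror_hi"])
for r in rows:
    a, b, c, d = (mp.mpf(r[k]) for k in "abcd")
    prr = (a / (a + b)) / (c / (c + d))
    se_p = mp.sqrt(1/a - 1/(a + b) + 1/c - 1/(c + d))
    ror = (a * d) / (b * c)
    se_r = mp.sqrt(1/a + 1/b + 1/c + 1/d)
    z = mp.mpf("1.96")
    w.writerow([mp.nstr(x, 25) for x in (
        prr, mp.e**(mp.log(prr) - z*se_p), mp.e**(mp.log(prr) + z*se_p),
        ror, mp.e**(mp.log(ror) - z*se_r), mp.e**(mp.log(ror) + z*se_r))])
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, inp, outp), stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python oracle failed")
  utils::read.csv(outp)
}

# quick end-to-end synthetic run in temp dirs; returns the faers_run
run_synth_pipeline <- function(cfg, root = withr::local_tempdir(.local_envir = parent.frame())) {
  vocab <- synth_vocabulary(cfg)
  write_vocabulary(vocab, file.path(root, "vocab"))
  sc <- synth_corpus(cfg, vocab, dir = file.path(root, "in"))
  run <- run_pipeline(faers_config(file.path(root, "in"),
                                   file.path(root, "vocab"),
                                   file.path(root, "out")))
  list(run = run, truth = sc$truth, root = root, vocab = vocab)
}
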