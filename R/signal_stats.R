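#' Enumerate case-drug-outcome triples
#'
#' Forms the distinct (case, drug concept, outcome concept) combinations
#' from de-duplicated, mapped cases: every mapped drug of a case — all
#' roles, concomitant included — crossed with every mapped outcome of the
#' case. Unmapped entries are excluded; duplicate strings mapping to one
#' concept collapse to one triple. This set is the "triple universe" from
#' which every 2x2 table is counted.
#'
#' @param case_drugs Tibble with columns `caseid`, `drug_concept_id`.
#' @param case_outcomes Tibble with columns `caseid`, `outcome_concept_id`.
#' @return Tibble of distinct triples (`caseid`, `drug_concept_id`,
#'   `outcome_concept_id`).
#' @export
enumerate_triples <- function(case_drugs, case_outcomes) {
  d <- case_drugs |>
    filter(!is.na(.data$drug_concept_id)) |>
    distinct(.data$caseid, .data$drug_concept_id)
  o <- case_outcomes |>
    filter(!is.na(.data$outcome_concept_id)) |>
    distinct(.data$caseid, .data$outcome_concept_id)
  inner_join(d, o, by = "caseid", relationship = "many-to-many") |>
    arrange(.data$caseid, .data$drug_concept_id, .data$outcome_concept_id)
}

#' Build one 2x2 contingency table
#'
#' Over the triple universe `N`: `a` counts triples with this drug and this
#' outcome, `b` triples with this drug and another outcome, `c` other drug
#' with this outcome, `d = N - a - b - c`.
#'
#' @param triples Triple universe from [enumerate_triples()].
#' @param drug_concept,outcome_concept The pair to tabulate.
#' @return One-row tibble with `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(triples, drug_concept, outcome_concept) {
  n_total <- nrow(triples)
  a <- sum(triples$drug_concept_id == drug_concept &
             triples$outcome_concept_id == outcome_concept)
  b <- sum(triples$drug_concept_id == drug_concept) - a
  c_ <- sum(triples$outcome_concept_id == outcome_concept) - a
  tibble(a = a, b = b, c = c_, d = n_total - a - b - c_, n = n_total)
}

#' Contingency tables for every observed drug-outcome pair
#'
#' One row per pair observed at least once (`a >= 1`); for each,
#' `a + b + c + d` equals the same universe total `N`. The default counting
#' unit is the triple universe; `unit = "case"` counts distinct cases
#' instead (then `N` is the number of cases contributing any triple).
#'
#' @param triples Triple universe from [enumerate_triples()].
#' @param unit `"triple"` (default) or `"case"`.
#' @return Tibble with `drug_concept_id`, `outcome_concept_id`, `a`..`d`, `n`.
#' @export
contingency_tables <- function(triples, unit = c("triple", "case")) {
  unit <- match.arg(unit)
  n_total <- if (unit == "triple") nrow(triples) else
    n_distinct(triples$caseid)
  if (nrow(triples) == 0) {
    return(tibble(drug_concept_id = integer(0), outcome_concept_id = integer(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), n = integer(0)))
  }
  drug_tot <- if (unit == "triple") {
    dplyr::count(triples, .data$drug_concept_id, name = "n_drug")
  } else {
    triples |> distinct(.data$caseid, .data$drug_concept_id) |>
      dplyr::count(.data$drug_concept_id, name = "n_drug")
  }
  out_tot <- if (unit == "triple") {
    dplyr::count(triples, .data$outcome_concept_id, name = "n_outcome")
  } else {
    triples |> distinct(.data$caseid, .data$outcome_concept_id) |>
      dplyr::count(.data$outcome_concept_id, name = "n_outcome")
  }
  triples |>
    dplyr::count(.data$drug_concept_id, .data$outcome_concept_id, name = "a") |>
    left_join(drug_tot, by = "drug_concept_id") |>
    left_join(out_tot, by = "outcome_concept_id") |>
    mutate(b = .data$n_drug - .data$a,
           c = .data$n_outcome - .data$a,
           d = n_total - .data$a - .data$b - .data$c,
           n = n_total) |>
    select("drug_concept_id", "outcome_concept_id", "a", "b", "c", "d", "n") |>
    arrange(.data$drug_concept_id, .data$outcome_concept_id)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' \deqn{PRR = \frac{a/(a+b)}{c/(c+d)}}{PRR = (a/(a+b)) / (c/(c+d))}
#' with the interval
#' \deqn{\exp\left(\ln PRR \pm 1.96\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}\right)}
#' A zero in any required cell or denominator (`a`, `c`, `a+b`, `c+d`)
#' yields `NA` components; no continuity correction is applied here.
#'
#' @param a,b,c,d Cell counts (vectors recycle).
#' @return Tibble with `prr`, `prr_ci_low`, `prr_ci_high`.
#' @export
#' @examples
#' compute_prr(10, 90, 100, 900) # equal proportions: PRR = 1
compute_prr <- function(a, b, c, d) {
  ok <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  tibble(prr = prr,
         prr_ci_low = exp(log(prr) - 1.96 * se),
         prr_ci_high = exp(log(prr) + 1.96 * se))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' \deqn{ROR = \frac{a/c}{b/d} = \frac{ad}{bc}}{ROR = ad/(bc)}
#' with the interval
#' \deqn{\exp\left(\ln ROR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}\right)}
#' Any zero cell yields `NA` components.
#'
#' @param a,b,c,d Cell counts (vectors recycle).
#' @return Tibble with `ror`, `ror_ci_low`, `ror_ci_high`.
#' @export
#' @examples
#' compute_ror(5, 5, 5, 5) # ROR = 1
compute_ror <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a / c) / (b / d), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble(ror = ror,
         ror_ci_low = exp(log(ror) - 1.96 * se),
         ror_ci_high = exp(log(ror) + 1.96 * se))
}

#' Disproportionality statistics for every observed pair
#'
#' Adds PRR and ROR point estimates with 95% confidence bounds to the
#' contingency table of every observed drug-outcome pair. With
#' `haldane = TRUE`, 0.5 is added to every cell before the statistics are
#' computed (Haldane-Anscombe correction; off by default — zero cells then
#' simply yield `NA`).
#'
#' @param ct Contingency tibble from [contingency_tables()].
#' @param haldane Apply the 0.5 continuity correction (default `FALSE`).
#' @return `ct` with columns `prr`, `prr_ci_low`, `prr_ci_high`, `ror`,
#'   `ror_ci_low`, `ror_ci_high` appended.
#' @export
signal_statistics <- function(ct, haldane = FALSE) {
  k <- if (haldane) 0.5 else 0
  bind_cols(ct,
            compute_prr(ct$a + k, ct$b + k, ct$c + k, ct$d + k),
            compute_ror(ct$a + k, ct$b + k, ct$c + k, ct$d + k))
}

#' Plot disproportionality signals
#'
#' Scatter of ROR (log scale) against the pair report count `a`, one point
#' per drug-outcome pair; pairs whose 95% CI excludes 1 are highlighted.
#'
#' @param stats Tibble from [signal_statistics()].
#' @return A ggplot object.
#' @export
plot_signals <- function(stats) {
  df <- stats |>
    filter(!is.na(.data$ror)) |>
    mutate(signal = .data$ror_ci_low > 1 | .data$ror_ci_high < 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$ror,
                                   colour = .data$signal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "reports with pair (a)", y = "ROR (95% CI excludes 1 highlighted)",
                  colour = "CI excludes 1") +
    ggplot2::theme_minimal()
}
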