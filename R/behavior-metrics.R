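#' Classify choices as generous
#'
#' A choice is generous if the participant accepted a proposal favouring the
#' partner at their own expense (`offer_self < offer_other`) or rejected one
#' favouring themselves at the partner's expense (`offer_self > offer_other`).
#' Equal-payoff proposals involve no trade-off and are unclassifiable (`NA`);
#' they are excluded from generosity fractions but counted.
#'
#' @param response `"accept"`/`"reject"` (vectorised).
#' @param offer_self,offer_other Proposed payoffs in dollars.
#' @return Integer vector: 1 (generous), 0 (selfish), `NA` (unclassifiable).
#' @examples
#' classify_generous("accept", 13, 35)  # 1
#' classify_generous("accept", 35, 5)   # 0
#' @export
classify_generous <- function(response, offer_self, offer_other) {
  if (!all(response %in% c("accept", "reject"))) {
    abort('`response` must be "accept" or "reject".', class = "socialddm_domain_error")
  }
  dplyr::case_when(
    offer_self == offer_other ~ NA_integer_,
    response == "accept" & offer_self < offer_other ~ 1L,
    response == "reject" & offer_self > offer_other ~ 1L,
    .default = 0L
  )
}

#' Generosity fractions per condition
#'
#' Per-subject fraction of generous choices overall and in each of the six
#' merit-by-need cells, with trial counts and the number of unclassifiable
#' (equal-payoff) trials. Deterministic and invariant to trial order.
#'
#' @param trials Data frame with columns `subject_id`, `partner_merit`,
#'   `need_level`, `offer_self`, `offer_other`, `response`.
#' @return A tibble of class `generosity_table`: one row per subject and
#'   condition (`merit`/`need` set to `"all"` for the overall row), with
#'   `fraction`, `n` (classified trials) and, on the overall row,
#'   `n_unclassifiable`. Empty cells carry `NA` fractions with a warning.
#' @export
generosity_fractions <- function(trials) {
  stopifnot(all(c("subject_id", "partner_merit", "need_level", "offer_self",
                  "offer_other", "response") %in% names(trials)))
  tr <- tibble::as_tibble(trials)
  tr$generous <- classify_generous(tr$response, tr$offer_self, tr$offer_other)

  cells <- tr |>
    dplyr::mutate(partner_merit = factor(.data$partner_merit, merit_levels),
                  need_level = factor(.data$need_level, need_levels)) |>
    dplyr::group_by(.data$subject_id, merit = .data$partner_merit,
                    need = .data$need_level, .drop = FALSE) |>
    dplyr::summarise(fraction = mean(.data$generous, na.rm = TRUE),
                     n = sum(!is.na(.data$generous)),
                     n_unclassifiable = sum(is.na(.data$generous)),
                     .groups = "drop") |>
    dplyr::mutate(merit = as.character(.data$merit),
                  need = as.character(.data$need),
                  fraction = ifelse(.data$n == 0, NA_real_, .data$fraction)) |>
    dplyr::filter(!is.na(.data$merit) & !is.na(.data$need))
  if (any(cells$n == 0)) {
    warn("some merit x need cells contain no classifiable trials; fractions reported as NA.")
  }
  overall <- tr |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(merit = "all", need = "all",
                     fraction = mean(.data$generous, na.rm = TRUE),
                     n = sum(!is.na(.data$generous)),
                     n_unclassifiable = sum(is.na(.data$generous)),
                     .groups = "drop")
  out <- dplyr::arrange(dplyr::bind_rows(overall, cells), .data$subject_id)
  class(out) <- c("generosity_table", class(out))
  out
}

#' Generosity change scores
#'
#' Merit-induced (high-minus-low merit, averaged over need levels) and
#' need-induced (high-minus-low need, averaged over merit levels) differences
#' in each subject's generosity fraction.
#'
#' @param gen_table A [generosity_fractions()] result.
#' @return Tibble with `subject_id`, `overall_generosity`,
#'   `dgen_merit`, `dgen_need`.
#' @export
generosity_change_scores <- function(gen_table) {
  cells <- dplyr::filter(gen_table, .data$merit != "all")
  by_merit <- cells |>
    dplyr::group_by(.data$subject_id, .data$merit) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "merit", values_from = "fraction")
  by_need <- cells |>
    dplyr::group_by(.data$subject_id, .data$need) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "need", values_from = "fraction")
  overall <- gen_table |>
    dplyr::filter(.data$merit == "all") |>
    dplyr::select("subject_id", overall_generosity = "fraction")
  overall |>
    dplyr::left_join(
      dplyr::transmute(by_merit, subject_id = .data$subject_id,
                       dgen_merit = .data$high - .data$low),
      by = "subject_id") |>
    dplyr::left_join(
      dplyr::transmute(by_need, subject_id = .data$subject_id,
                       dgen_need = .data$high - .data$low),
      by = "subject_id")
}

#' Cold-pressor buy-out rule
#'
#' Each dollar a partner spends removes 10 percentage points from their
#' probability of having to perform the painful cold pressor task, floored at
#' 0% (e.g. spending $3 reduces an 80% chance to 50%).
#'
#' @param p0 Initial CPT probability in percent, in \[0, 100\] (vectorised).
#' @param dollars Dollars spent (>= 0).
#' @return Remaining probability in percent.
#' @examples
#' buyout_probability(80, 3)  # 50
#' @export
buyout_probability <- function(p0, dollars) {
  if (any(p0 < 0 | p0 > 100)) {
    abort("`p0` must be a percentage in [0, 100].", class = "socialddm_domain_error")
  }
  if (any(dollars < 0)) {
    abort("`dollars` must be non-negative.", class = "socialddm_domain_error")
  }
  pmax(0, p0 - 10 * dollars)
}

#' Data-quality exclusions
#'
#' Flags subjects with invariant responding — the identical response value on
#' strictly more than `threshold` of their trials (a subject at exactly the
#' threshold is kept) — and subjects with fewer than `min_trials` trials.
#'
#' @param trials Data frame with `subject_id` and a response column.
#' @param response_col Column holding the (button) response, default
#'   `"response"`.
#' @param threshold Invariance threshold as a fraction, default 0.9; the
#'   comparison is strict (`> threshold`).
#' @param min_trials Minimum number of trials required, default 0 (disabled).
#' @return Tibble with `subject_id`, `n_trials`, `max_identical_fraction`,
#'   `keep`, `reason` (`NA` if kept).
#' @export
qc_exclusions <- function(trials, response_col = "response", threshold = 0.9,
                          min_trials = 0) {
  stopifnot("subject_id" %in% names(trials), response_col %in% names(trials))
  tibble::as_tibble(trials) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      max_identical_fraction = max(table(.data[[response_col]])) / dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_trials < min_trials ~ "too few trials",
        .data$max_identical_fraction > threshold ~ "invariant responding",
        .default = NA_character_),
      keep = is.na(.data$reason)
    )
}

#' Export a generosity table as CSV
#'
#' One row per subject and condition (overall plus six cells), mirroring the
#' summary layout of the behavioural generosity analysis.
#'
#' @param gen_table A [generosity_fractions()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_generosity_csv <- function(gen_table, path) {
  utils::write.csv(gen_table, path, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.generosity_table <- function(object, ...) {
  cells <- dplyr::filter(object, .data$merit != "all")
  cohort <- cells |>
    dplyr::group_by(.data$merit, .data$need) |>
    dplyr::summarise(fraction = mean(.data$fraction, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(merit = factor(.data$merit, merit_levels),
                  need = factor(.data$need, need_levels))
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$merit, y = .data$fraction,
                               fill = .data$need)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "partner merit", y = "fraction of generous choices",
                  fill = "partner need") +
    ggplot2::theme_minimal()
}
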