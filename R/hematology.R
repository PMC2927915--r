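#' Derived red-cell indices
#'
#' Standard corpuscular constants from hematocrit, hemoglobin concentration
#' and red-cell count:
#' `MCV = Hct*10/RBC` (fL), `MCH = Hb*10/RBC` (pg),
#' `MCHC = Hb*1000/Hct` (g/L, i.e. g/dL of Hb over the packed-cell
#' fraction). Vectorised.
#'
#' @param hct Hematocrit in percent (> 0).
#' @param hb Hemoglobin concentration in g/dL (>= 0).
#' @param rbc Red-cell count in 10^6 per mm^3 (> 0).
#' @return A tibble with columns `mcv_fL`, `mch_pg`, `mchc_gL`.
#' @examples
#' red_cell_indices(45, 15, 10) # 45 fL, 15 pg, 333 g/L
#' @export
red_cell_indices <- function(hct, hb, rbc) {
  if (any(rbc <= 0) || any(hct <= 0)) {
    abort("`rbc` and `hct` must be > 0.")
  }
  tibble::tibble(
    mcv_fL = hct * 10 / rbc,
    mch_pg = hb * 10 / rbc,
    mchc_gL = hb * 1000 / hct
  )
}

#' Welch's t-test from group summary statistics
#'
#' Unequal-variance two-sample comparison computed directly from reported
#' means, standard errors and sample sizes — the form needed when only a
#' published summary table is available:
#' `t = (m1 - m2) / sqrt(se1^2 + se2^2)`, with Welch-Satterthwaite degrees
#' of freedom `(se1^2 + se2^2)^2 / (se1^4/(n1-1) + se2^4/(n2-1))` and a
#' two-sided p-value.
#'
#' @param mean1,se1,n1 Mean, standard error and size of group 1 (`n1 >= 2`).
#' @param mean2,se2,n2 Likewise for group 2.
#' @return A one-row tibble with `t`, `df`, `p_value`.
#' @examples
#' welch_t(7.09, 0.20, 3, 0.45, 0.06, 4) # t ~ 31.8, p < 0.001
#' @export
welch_t <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, se1 >= 0, se2 >= 0)
  if (se1 == 0 && se2 == 0) abort("degenerate variance: both SEs are zero")
  v <- se1^2 + se2^2
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  tibble::tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Fold ratio and percent difference
#'
#' The summary contrasts used in comparative tables: `fold_ratio(a, b)` is
#' `a / b`; `percent_difference(a, b)` is `100 * (a - b) / b` (how much
#' higher `a` is than the baseline `b`, in percent).
#'
#' @param a Value of interest.
#' @param b Baseline (> 0).
#' @return A number (fold) or percent.
#' @examples
#' fold_ratio(7.09, 0.45)          # 15.76
#' percent_difference(56.4, 46.8)  # 20.5
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) abort("baseline `b` must be > 0")
  a / b
}

#' @rdname fold_ratio
#' @export
percent_difference <- function(a, b) {
  if (any(b <= 0)) abort("baseline `b` must be > 0")
  100 * (a - b) / b
}

#' Compare a two-group blood panel variable by variable
#'
#' Takes a long panel in published-table layout — one row per (variable,
#' group) with `mean`, `se`, `n` — and returns, per variable present in both
#' groups with `n >= 2` on each side, the Welch t statistic and p-value plus
#' the fold ratio and percent difference of group 1 over group 2.
#'
#' @param panel A data frame with columns `variable`, `group`, `mean`, `se`,
#'   `n`.
#' @param group1,group2 The two group labels to compare (`group1` is the
#'   numerator / value of interest).
#' @return A tibble with one row per comparable variable: `variable`,
#'   `mean1`, `mean2`, `t`, `df`, `p_value`, `fold`, `percent_diff`.
#' @export
panel_compare <- function(panel, group1, group2) {
  stopifnot(is.data.frame(panel),
            all(c("variable", "group", "mean", "se", "n") %in% names(panel)))
  wide <- panel |>
    dplyr::filter(.data$group %in% c(group1, group2)) |>
    dplyr::mutate(.side = ifelse(.data$group == group1, "1", "2")) |>
    tidyr::pivot_wider(id_cols = "variable", names_from = ".side",
                       values_from = c("mean", "se", "n"), names_sep = "") |>
    dplyr::filter(!is.na(.data$mean1), !is.na(.data$mean2),
                  .data$n1 >= 2, .data$n2 >= 2)
  wide |>
    dplyr::rowwise() |>
    dplyr::mutate(
      welch_t(.data$mean1, .data$se1, .data$n1,
              .data$mean2, .data$se2, .data$n2),
      fold = fold_ratio(.data$mean1, .data$mean2),
      percent_diff = percent_difference(.data$mean1, .data$mean2)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("variable", "mean1", "mean2", "t", "df", "p_value",
                  "fold", "percent_diff")
}
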