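#' Hill transformation of equilibration steps
#'
#' Maps a `(PO2, Y)` step to Hill-plot coordinates
#' `x = log10(PO2)`, `y = log10(Y / (1 - Y))`. Saturations of exactly 0 or 1
#' (and non-positive PO2) have no finite image and error.
#'
#' @param po2 Oxygen tension(s), mmHg, > 0.
#' @param saturation Fractional saturation(s) strictly inside (0, 1).
#' @return A tibble with columns `x` (log10 mmHg) and `y` (logit10
#'   saturation).
#' @examples
#' hill_transform(10, 0.5)    # (1, 0)
#' hill_transform(100, 0.8)   # (2, log10(4))
#' @export
hill_transform <- function(po2, saturation) {
  if (any(po2 <= 0) || any(saturation <= 0) || any(saturation >= 1)) {
    abort("untransformable step: need po2 > 0 and 0 < saturation < 1")
  }
  tibble::tibble(x = log10(po2),
                 y = log10(saturation / (1 - saturation)))
}

#' Estimate P50 and n50 by Hill-plot regression
#'
#' Fits an ordinary least-squares line through the Hill-transformed steps
#' whose saturations fall inside the fitting window (inclusive bounds,
#' default 30-70%). The slope is the cooperativity coefficient `n50`; the
#' half-saturation pressure is `P50 = 10^(-intercept / slope)`, the PO2 at
#' which the Hill ordinate crosses zero. At least `min_points` steps must lie
#' in the window (the classical interpolation uses at least 4); widening the
#' window is the caller's explicit decision, never done silently.
#'
#' @param data A data frame of equilibration steps; by default the columns
#'   `po2_mmHg` and `saturation` as written by [oec_simulate()] /
#'   [read_oec_csv()].
#' @param window Inclusive saturation bounds used for fitting, default
#'   `c(0.30, 0.70)`.
#' @param min_points Minimum number of in-window steps, default 4.
#' @param po2,saturation Tidy-select columns holding PO2 (mmHg) and
#'   fractional saturation.
#' @return A `"hill_fit"` object; see [tidy.hill_fit()] / [glance.hill_fit()]
#'   for tibble views. Fields: `p50`, `n50`, `intercept`, `slope`, `r2`,
#'   `n_points_used`, `window`, and the in-window `points` used.
#' @examples
#' ref <- conditions(37, 7.2, chloride = 0.1)
#' p <- allosteric_params(log10(13.8), 2.5, ref_conditions = ref)
#' d <- oec_simulate(p, ref, po2_grid_window(13.8, 2.5, 8))
#' hill_fit(d)
#' @export
hill_fit <- function(data, window = c(0.30, 0.70), min_points = 4L,
                     po2 = "po2_mmHg", saturation = "saturation") {
  stopifnot(is.data.frame(data), length(window) == 2L,
            window[1] < window[2], window[1] > 0, window[2] < 1)
  po2_v <- data[[po2]]
  sat_v <- data[[saturation]]
  if (is.null(po2_v) || is.null(sat_v)) {
    abort("`data` must contain the PO2 and saturation columns.")
  }
  in_win <- sat_v >= window[1] & sat_v <= window[2]
  if (sum(in_win) < min_points) {
    abort(sprintf(
      "insufficient steps in saturation window [%g, %g]: %d < %d",
      window[1], window[2], sum(in_win), min_points))
  }
  pts <- hill_transform(po2_v[in_win], sat_v[in_win])
  fit <- lm(y ~ x, data = pts)
  b <- unname(coef(fit))
  sst <- sum((pts$y - mean(pts$y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(
    list(p50 = 10^(-b[1] / b[2]), n50 = b[2],
         intercept = b[1], slope = b[2],
         r2 = r2, n_points_used = nrow(pts), window = window,
         points = tibble::tibble(po2_mmHg = po2_v[in_win],
                                 saturation = sat_v[in_win])),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> P50 = %.4g mmHg, n50 = %.3g (r2 = %.4f, %d steps in [%g, %g])\n",
    x$p50, x$n50, x$r2, x$n_points_used, x$window[1], x$window[2]))
  invisible(x)
}

#' Tidy a Hill-plot fit
#'
#' @param x A `"hill_fit"` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `p50_mmHg`, `n50`, `intercept`,
#'   `slope`; `glance()`: a one-row tibble with `r2`, `n_points_used`,
#'   `window_low`, `window_high`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(p50_mmHg = x$p50, n50 = x$n50,
                 intercept = x$intercept, slope = x$slope)
}

#' @rdname tidy.hill_fit
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n_points_used = x$n_points_used,
                 window_low = x$window[1], window_high = x$window[2])
}

#' Fit Hill regressions to every labelled dataset in a table
#'
#' Convenience wrapper that groups an equilibration table by `label` and
#' returns one [hill_fit()] summary row per dataset.
#'
#' @inheritParams hill_fit
#' @return A tibble with one row per label: `label`, `p50_mmHg`, `n50`, `r2`,
#'   `n_points_used`, plus the condition columns (first value per label).
#' @export
hill_fit_all <- function(data, window = c(0.30, 0.70), min_points = 4L) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  cond_cols <- intersect(
    c("temperature_C", "pH", "chloride_M", "dpg_ratio", "pco2_mmHg"),
    names(data))
  data |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      f <- hill_fit(d, window = window, min_points = min_points)
      dplyr::bind_cols(
        dplyr::summarise(d, dplyr::across(dplyr::all_of(cond_cols),
                                          dplyr::first)),
        tidy(f)[c("p50_mmHg", "n50")], glance(f)[c("r2", "n_points_used")])
    }) |>
    dplyr::ungroup()
}

#' Construct a smooth oxygen equilibration curve
#'
#' Evaluates a continuous saturation curve on a PO2 grid, either from a
#' fitted Hill model (`"hill_fit"` object) or directly through measured
#' points. In the latter case the curve is a monotone piecewise-linear
#' interpolant in Hill-transformed coordinates, with the two terminal
#' segments extrapolated linearly — a smooth sigmoid that passes exactly
#' through the data. The returned saturation is non-decreasing in PO2 and
#' bounded in (0, 1).
#'
#' @param fit_or_points A `"hill_fit"` object, or a data frame of at least 3
#'   transformable steps (`po2_mmHg`, `saturation` columns).
#' @param po2_grid PO2 values (mmHg, > 0) to evaluate at.
#' @return A tibble with columns `po2_mmHg`, `saturation`.
#' @examples
#' f <- structure(list(p50 = 17.7, n50 = 2.84), class = "hill_fit")
#' construct_oec(f, po2_grid = c(5, 17.7, 60))
#' @export
construct_oec <- function(fit_or_points, po2_grid) {
  stopifnot(all(po2_grid > 0))
  if (inherits(fit_or_points, "hill_fit")) {
    y <- saturation_at(po2_grid, fit_or_points$p50, fit_or_points$n50)
    return(tibble::tibble(po2_mmHg = as.numeric(po2_grid), saturation = y))
  }
  pts <- fit_or_points
  stopifnot(is.data.frame(pts), nrow(pts) >= 3)
  pts <- pts[order(pts$po2_mmHg), , drop = FALSE]
  if (is.unsorted(pts$saturation)) {
    abort("input saturations must be non-decreasing in po2")
  }
  h <- hill_transform(pts$po2_mmHg, pts$saturation)
  x_new <- log10(po2_grid)
  y_new <- approx(h$x, h$y, xout = x_new, rule = 2, ties = "ordered")$y
  ## approx() holds values constant outside the data; extend the terminal
  ## segments linearly instead
  k <- nrow(h)
  lo <- x_new < h$x[1]
  hi <- x_new > h$x[k]
  s1 <- (h$y[2] - h$y[1]) / (h$x[2] - h$x[1])
  s2 <- (h$y[k] - h$y[k - 1]) / (h$x[k] - h$x[k - 1])
  y_new[lo] <- h$y[1] + s1 * (x_new[lo] - h$x[1])
  y_new[hi] <- h$y[k] + s2 * (x_new[hi] - h$x[k])
  tibble::tibble(po2_mmHg = as.numeric(po2_grid),
                 saturation = 10^y_new / (1 + 10^y_new))
}

#' Hill plot of a fitted equilibration dataset
#'
#' @param object A `"hill_fit"` object.
#' @param ... Unused.
#' @return A ggplot: in-window steps in Hill coordinates with the fitted
#'   line; the intercept with y = 0 marks log10 P50.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  h <- hill_transform(object$points$po2_mmHg, object$points$saturation)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(log[10] ~ PO[2] ~ "(mmHg)"),
      y = expression(log[10] ~ (Y / (1 - Y))),
      title = sprintf("Hill plot: P50 = %.3g mmHg, n50 = %.3g",
                      object$p50, object$n50))
}

#' Plot one or more oxygen equilibration curves
#'
#' @param data A tibble with columns `po2_mmHg`, `saturation` and optionally
#'   `label` (one curve per label).
#' @return A ggplot of saturation against PO2.
#' @export
plot_oec <- function(data) {
  stopifnot(is.data.frame(data))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$po2_mmHg,
                                          y = .data$saturation))
  if ("label" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = expression(PO[2] ~ "(mmHg)"),
                    y = "Fractional saturation") +
    ggplot2::ylim(0, 1)
}
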