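#' Kendall rank correlation against time
#'
#' The Mann-Kendall trend statistic: Kendall's tau between a series and its
#' time index. Missing entries are dropped; the surviving values keep their
#' original order (time indices are strictly increasing, so there are never
#' ties in time). `tau = 1` for a strictly increasing series, `-1` for
#' strictly decreasing. The default `"b"` convention applies the standard
#' tie correction to the denominator; `"a"` divides by the raw pair count.
#' A series with all surviving values tied has no concordant or discordant
#' pairs and is assigned `tau = 0`.
#'
#' @param x numeric series (may contain `NA`).
#' @param convention `"b"` (tie-corrected, default) or `"a"`.
#' @return list with `tau` and `n_valid` (number of non-missing values);
#'   `tau` is `NA` when `n_valid < 2`.
#' @export
kendall_tau <- function(x, convention = c("b", "a")) {
  convention <- match.arg(convention)
  res <- .kendall_tau_matrix(matrix(as.numeric(x), ncol = 1), convention == "b")
  list(tau = res$tau[1], n_valid = res$n_valid[1])
}

#' Per-pixel trend map
#'
#' Applies [kendall_tau] independently to every pixel of the smoothed
#' anomaly series and attaches the greening/browning classification.
#' Pixels with fewer than `min_points` valid months get a missing tau
#' (gap-dominated series are not trustworthy trend evidence).
#'
#' @param smoothed a [monthly_series], normally from [preprocess_stack].
#' @param min_points minimum valid months for a defined tau (default 24).
#' @param convention tau convention, see [kendall_tau].
#' @param cells optional integer cell indices to restrict computation to
#'   (other pixels are reported missing); useful when only classified
#'   pixels are needed.
#' @return an object of class `trend_map`: grid, `tau`, `n_valid` and
#'   `class_label` vectors over cells.
#' @export
trend_map <- function(smoothed, min_points = 24, convention = c("b", "a"),
                      cells = NULL) {
  convention <- match.arg(convention)
  nc <- nrow(smoothed$values)
  tau <- rep(NA_real_, nc)
  nv <- integer(nc)
  if (is.null(cells)) {
    res <- .kendall_tau_rows(smoothed$values, convention == "b")
    tau <- res$tau; nv <- res$n_valid
  } else {
    res <- .kendall_tau_rows(smoothed$values, convention == "b",
                             rows = as.integer(cells))
    tau[cells] <- res$tau; nv[cells] <- res$n_valid
  }
  tau[nv < min_points] <- NA_real_
  structure(list(grid = smoothed$grid, tau = tau, n_valid = nv,
                 class_label = classify_trend(tau),
                 min_points = as.integer(min_points), convention = convention),
            class = "trend_map")
}

#' @export
print.trend_map <- function(x, ...) {
  ok <- !is.na(x$tau)
  cat(sprintf("<trend_map> %s, tau defined for %d/%d pixels (median %.3f)\n",
              format(x$grid), sum(ok), length(x$tau),
              if (any(ok)) stats::median(x$tau[ok]) else NA_real_))
  print(table(x$class_label))
  invisible(x)
}

#' Greening/browning trend bins
#'
#' Four half-open tau bins: `[-1, -0.4)` strong browning, `[-0.4, 0)`
#' moderate browning, `[0, 0.4)` moderate greening, `[0.4, 1]` strong
#' greening; missing tau is `unclassified`. The literature's bin labels
#' leave `tau = 0` and `|tau| > 0.8` unassigned; here `tau = 0` goes to
#' moderate greening and the strong bins extend to +/-1, so the bins
#' partition `[-1, 1]`.
#'
#' @param tau numeric vector in `[-1, 1]` (or `NA`).
#' @return factor with levels `strong_browning`, `moderate_browning`,
#'   `moderate_greening`, `strong_greening`, `unclassified`.
#' @export
classify_trend <- function(tau) {
  if (any(abs(tau) > 1 + 1e-8, na.rm = TRUE))
    stop("|tau| > 1: corrupt trend input")
  lv <- c("strong_browning", "moderate_browning",
          "moderate_greening", "strong_greening", "unclassified")
  out <- rep("unclassified", length(tau))
  ok <- !is.na(tau)
  out[ok & tau < -0.4] <- "strong_browning"
  out[ok & tau >= -0.4 & tau < 0] <- "moderate_browning"
  out[ok & tau >= 0 & tau < 0.4] <- "moderate_greening"
  out[ok & tau >= 0.4] <- "strong_greening"
  factor(out, levels = lv)
}

#' Greening fraction of a pixel set
#'
#' Fraction of pixels with a positive tau among pixels with a defined tau.
#' `convention = "strict"` counts `tau > 0` (the headline definition);
#' `"inclusive"` counts `tau >= 0`, i.e. the two greening bins of
#' [classify_trend]. The two differ only at exactly `tau = 0`.
#'
#' @param trend a [trend_map].
#' @param cells integer cell indices of the pixel set.
#' @param convention `"strict"` or `"inclusive"`.
#' @return fraction in `[0, 1]`.
#' @export
greening_fraction <- function(trend, cells, convention = c("strict", "inclusive")) {
  convention <- match.arg(convention)
  if (length(cells) == 0) stop("empty pixel set")
  tau <- trend$tau[cells]
  tau <- tau[!is.na(tau)]
  if (length(tau) == 0) stop("no pixels with a defined tau in the set")
  if (convention == "strict") mean(tau > 0) else mean(tau >= 0)
}
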