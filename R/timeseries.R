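# Stationarity testing (augmented Dickey-Fuller) and cross-correlation lag
# analysis.

# Dickey-Fuller tau_mu percentiles (regression with constant, no trend),
# from the standard tabulations (Fuller 1976; Banerjee et al. 1993), by
# sample size. p-values are obtained by interpolating first over sample
# size within each column, then over the statistic, and are clipped to
# [0.01, 0.99].
.adf_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_ns <- c(25, 50, 100, 250, 500, 1e5)
.adf_table <- matrix(c(
  -3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60
), nrow = 6, byrow = TRUE)

adf_pvalue <- function(stat, n) {
  nn <- min(max(n, .adf_ns[1]), .adf_ns[length(.adf_ns)])
  cv <- vapply(seq_along(.adf_probs), function(j) {
    approx(.adf_ns, .adf_table[, j], xout = nn, rule = 2)$y
  }, numeric(1))
  p <- approx(cv, .adf_probs, xout = stat, rule = 2)$y
  min(max(p, 0.01), 0.99)
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test on the regression
#' \deqn{\Delta y_t = \alpha + \beta y_{t-1} + \sum_{i=1}^{p}
#'   \gamma_i \Delta y_{t-i} + \varepsilon_t}
#' (constant term, no trend). The lag order p is selected by AIC on a common
#' sample over `0..max_lags`, with the default ceiling
#' \eqn{\lfloor 12 (n/100)^{1/4} \rfloor}. The test statistic is the t-ratio
#' of \eqn{\beta}; its p-value is interpolated from the standard
#' Dickey-Fuller tau tables for the constant-only case and clipped to
#' `[0.01, 0.99]`. Rejection (small p) indicates a stationary series.
#'
#' @param x Numeric series, length >= 20 after differencing and lagging.
#' @param max_lags Maximum augmentation lag order; default the Schwert rule
#'   above.
#' @param alpha Decision level for the `stationary` flag (default 0.05).
#' @return A one-row tibble: `statistic`, `p_value`, `stationary`, `n_lags`
#'   (selected order), `n_obs` (regression sample size).
#' @examples
#' set.seed(1)
#' adf_test(rnorm(200))$stationary        # TRUE: white noise
#' adf_test(cumsum(rnorm(200)))$p_value   # large: random walk
#' @export
adf_test <- function(x, max_lags = NULL, alpha = 0.05) {
  stopifnot(is.numeric(x), !anyNA(x))
  n <- length(x)
  if (n < 25L) {
    stop_poseagree("ADF test needs at least 25 observations",
                   "poseagree_insufficient_data_error")
  }
  if (sd(x) == 0) {
    stop_poseagree("constant series: ADF regression is degenerate",
                   "poseagree_degenerate_error")
  }
  if (is.null(max_lags)) {
    max_lags <- floor(12 * (n / 100)^0.25)
  }
  max_lags <- max(0L, min(as.integer(max_lags), n - 25L))
  dy <- diff(x)
  # embed: column 1 = dy_t, columns 2.. = dy_{t-1}, ..., dy_{t-pmax}
  z <- stats::embed(dy, max_lags + 1L)
  y <- z[, 1]
  ylag <- x[(max_lags + 1L):(n - 1L)]
  nobs <- length(y)
  regs <- cbind(ylag, if (max_lags > 0) z[, -1, drop = FALSE])
  # standardize the regressors (t-ratios are invariant to this) so the
  # normal-equations lag search can detect ill conditioning via rcond;
  # deterministic series satisfy exact low-order recurrences, making high
  # augmentation orders collinear
  sdv <- apply(regs, 2, sd)
  if (sdv[1] == 0) {
    stop_poseagree("lagged level is constant: ADF regression is degenerate",
                   "poseagree_degenerate_error")
  }
  if (any(sdv == 0)) max_lags <- min(which(sdv == 0)) - 2L
  cols_keep <- seq_len(2L + max_lags)
  x_full <- cbind(1, scale(regs[, seq_len(1L + max_lags), drop = FALSE]))
  xtx <- crossprod(x_full)
  xty <- crossprod(x_full, y)
  yty <- sum(y^2)
  fits <- list()
  for (p in 0:max_lags) {
    cols <- seq_len(2L + p)
    if (rcond(xtx[cols, cols]) < 1e-10) break
    b <- solve(xtx[cols, cols], xty[cols, ])
    rss <- max(yty - sum(b * xty[cols, ]), .Machine$double.eps)
    fits[[p + 1L]] <- list(p = p, b = b, rss = rss,
                           aic = nobs * log(rss / nobs) + 2 * (p + 2))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  cols <- seq_len(2L + best$p)
  sigma2 <- best$rss / (nobs - length(cols))
  xtx_inv <- solve(xtx[cols, cols])
  stat <- best$b[2] / sqrt(sigma2 * xtx_inv[2, 2])
  p <- adf_pvalue(stat, nobs)
  tibble::tibble(
    statistic = as.numeric(stat), p_value = p,
    stationary = p < alpha, n_lags = best$p, n_obs = nobs
  )
}

#' Per-group stationarity tests for a paired data set
#'
#' Applies [adf_test()] within each (video, joint) group to the candidate
#' series, the reference series, and their difference. A degenerate series
#' (for example a constant difference under perfect agreement) is reported
#' with an `error` message without aborting the other groups.
#'
#' @param paired A paired tibble from [pair_angles()].
#' @param series Which series to test; any subset of
#'   `c("candidate", "reference", "difference")`.
#' @param max_lags,alpha Passed to [adf_test()].
#' @return A tibble with one row per (video, joint, series).
#' @export
stationarity_tests <- function(paired,
                               series = c("candidate", "reference", "difference"),
                               max_lags = NULL, alpha = 0.05) {
  check_columns(paired, c("video_id", "joint", "candidate", "reference"),
                "paired tibble")
  series <- match.arg(series, several.ok = TRUE)
  paired |>
    dplyr::group_by(.data$video_id, .data$joint) |>
    dplyr::group_modify(function(g, key) {
      purrr::map_dfr(series, function(s) {
        v <- switch(s,
          candidate = g$candidate,
          reference = g$reference,
          difference = g$candidate - g$reference
        )
        res <- tryCatch(
          dplyr::mutate(adf_test(v, max_lags, alpha), error = NA_character_),
          poseagree_error = function(e) {
            tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                           stationary = NA, n_lags = NA_integer_,
                           n_obs = length(v), error = conditionMessage(e))
          }
        )
        dplyr::mutate(res, series = s, .before = 1)
      })
    }) |>
    dplyr::ungroup()
}

ccf_one <- function(x, y, max_lag) {
  if (sd(x) == 0 || sd(y) == 0) {
    stop_poseagree("zero-variance series: cross-correlation undefined",
                   "poseagree_degenerate_error")
  }
  cc <- ccf(x, y, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = as.integer(cc$lag[, 1, 1]), ccf = as.numeric(cc$acf))
}

#' Cross-correlation lag analysis per joint
#'
#' Computes the cross-correlation function between candidate and reference
#' series at integer lags `-max_lag..max_lag`, per (video, joint), with both
#' series mean-centered and the full-series n-denominator variance
#' normalization (so the value at lag 0 equals the Pearson correlation of
#' the pairs). Multi-video input is pooled per joint as the pair-count
#' weighted mean of the per-video functions. The significance band is
#' `+/- 1.96 / sqrt(n)` with n the pooled pair count.
#'
#' Lag-direction convention: a positive lag means the candidate lags
#' (trails) the reference — i.e. `candidate[t]` tracks `reference[t - lag]`.
#'
#' @param paired A paired tibble from [pair_angles()].
#' @param max_lag Maximum lag in frames; default
#'   `round(min(10 log10(n), n/4))` with n the shortest per-video series.
#' @return A tibble with columns `joint`, `lag`, `ccf`, `n`, `conf_bound`,
#'   `significant`.
#' @seealso [best_lag()]
#' @export
cross_correlation <- function(paired, max_lag = NULL) {
  check_columns(paired, c("video_id", "joint", "candidate", "reference"),
                "paired tibble")
  if (is.null(max_lag)) {
    n_min <- paired |>
      dplyr::count(.data$video_id, .data$joint) |>
      dplyr::pull(.data$n) |>
      min()
    max_lag <- max(1L, round(min(10 * log10(n_min), n_min / 4)))
  }
  stopifnot(max_lag >= 1)
  per_video <- paired |>
    dplyr::group_by(.data$joint, .data$video_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) <= max_lag) {
        stop_poseagree("series shorter than max_lag", "poseagree_parameter_error")
      }
      dplyr::mutate(ccf_one(g$candidate, g$reference, max_lag), n = nrow(g))
    }) |>
    dplyr::ungroup()
  per_video |>
    dplyr::group_by(.data$joint, .data$lag) |>
    dplyr::summarise(
      ccf = sum(.data$ccf * .data$n) / sum(.data$n),
      n = sum(.data$n), .groups = "drop"
    ) |>
    dplyr::mutate(
      conf_bound = 1.96 / sqrt(.data$n),
      significant = abs(.data$ccf) > .data$conf_bound
    )
}

#' Lag of maximum cross-correlation per joint
#'
#' Summarises a [cross_correlation()] table: for each joint, the lag with
#' the maximum correlation (ties broken toward the smallest absolute lag)
#' and the correlation there.
#'
#' @param ccf_table Output of [cross_correlation()].
#' @return A tibble: `joint`, `best_lag`, `best_corr`, `conf_bound`, `n`.
#' @export
best_lag <- function(ccf_table) {
  check_columns(ccf_table, c("joint", "lag", "ccf"), "ccf table")
  ccf_table |>
    dplyr::group_by(.data$joint) |>
    dplyr::arrange(dplyr::desc(.data$ccf), abs(.data$lag), .by_group = TRUE) |>
    dplyr::summarise(
      best_lag = dplyr::first(.data$lag),
      best_corr = dplyr::first(.data$ccf),
      conf_bound = dplyr::first(.data$conf_bound),
      n = dplyr::first(.data$n)
    )
}
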