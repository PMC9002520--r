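#' Estimate the device clock offset from movement channels
#'
#' Scans lags in `[-max_lag, +max_lag]` and returns the lag maximising the
#' normalized cross-correlation between the reference and device movement
#' series. A positive lag means the device clock is behind the reference
#' (device events appear `lag` epochs late); correct it with
#' `apply_offset(x, -lag)`. Ties are broken toward the smallest `|lag|`, then
#' toward the negative lag.
#'
#' @param ref,dev Numeric movement series on the common epoch grid.
#' @param max_lag Maximum absolute lag to scan, epochs.
#' @param ref_covered,dev_covered Optional logical coverage masks; uncovered
#'   epochs are ignored.
#' @return Object of class `alignment_result`: list with `lag`, `correlation`,
#'   `max_lag`.
#' @examples
#' x <- c(rep(0, 10), 5, rep(0, 30), 5, rep(0, 10))
#' estimate_offset(x, c(rep(0, 3), x[1:49]), max_lag = 5)
#' @export
estimate_offset <- function(ref, dev, max_lag = 20L,
                            ref_covered = NULL, dev_covered = NULL) {
  max_lag <- as.integer(max_lag)
  n <- length(ref)
  if (length(dev) != n) {
    abort("`ref` and `dev` must have equal length.", class = "sleepagree_input_error")
  }
  if (n < 2L * max_lag + 1L) {
    abort("Series must span at least 2*max_lag + 1 epochs.",
          class = "sleepagree_input_error")
  }
  ref_covered <- ref_covered %||% !is.na(ref)
  dev_covered <- dev_covered %||% !is.na(dev)
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(l) {
    # positive lag: device delayed, so dev[t] pairs with ref[t - l]
    if (l >= 0) {
      r <- ref[seq_len(n - l)]; d <- dev[seq_len(n - l) + l]
      ok <- ref_covered[seq_len(n - l)] & dev_covered[seq_len(n - l) + l]
    } else {
      r <- ref[seq_len(n + l) - l]; d <- dev[seq_len(n + l)]
      ok <- ref_covered[seq_len(n + l) - l] & dev_covered[seq_len(n + l)]
    }
    r <- r[ok]; d <- d[ok]
    if (length(r) < 3 || sd(r) == 0 || sd(d) == 0) return(NA_real_)
    cor(r, d)
  }, numeric(1))
  if (all(is.na(cors))) {
    abort("Alignment undefined: zero variance in the overlap at every lag.",
          class = "sleepagree_alignment_error")
  }
  # tie-break: smallest |lag| first, then negative before positive
  ord <- order(abs(lags), lags)
  best <- ord[which.max(cors[ord])]
  structure(list(lag = lags[best], correlation = cors[best], max_lag = max_lag),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> lag %+d epochs (r = %.4f, scanned |lag| <= %d)\n",
              x$lag, x$correlation, x$max_lag))
  invisible(x)
}

#' Shift an epoch series by a whole-epoch lag
#'
#' Positive lags delay the series (`lag = +2` turns `a, b, c, d` into
#' `NA, NA, a, b`); epochs shifted out of range are masked as uncovered.
#' Length is preserved.
#'
#' @param x Numeric epoch series.
#' @param lag Signed lag in epochs, `|lag| < length(x)`.
#' @param covered Optional logical coverage mask.
#' @return Tibble with columns `value` and `covered`.
#' @export
apply_offset <- function(x, lag, covered = NULL) {
  lag <- as.integer(lag)
  if (abs(lag) >= length(x)) {
    abort("`|lag|` must be smaller than the series length.",
          class = "sleepagree_input_error")
  }
  covered <- covered %||% !is.na(x)
  tibble::tibble(
    value = shift_vector(x, lag),
    covered = shift_vector(covered, lag, fill = FALSE)
  )
}

#' Smooth an overnight profile
#'
#' Centered moving average over `window_minutes` of 30 s epochs (the default
#' 15 min window spans 30 epochs). Masked entries are ignored and the mean is
#' renormalized over the covered entries in the window; the window shrinks at
#' the edges; a fully masked window yields `NA`.
#'
#' @param x Numeric epoch series.
#' @param window_minutes Window length in minutes (> 0).
#' @param covered Optional logical coverage mask.
#' @param epoch_seconds Epoch duration, seconds.
#' @return Numeric vector of the smoothed profile (`NA` where undefined).
#' @export
smooth_profile <- function(x, window_minutes = 15, covered = NULL,
                           epoch_seconds = 30) {
  if (window_minutes <= 0) {
    abort("`window_minutes` must be positive.", class = "sleepagree_input_error")
  }
  n <- length(x)
  covered <- (covered %||% TRUE) & !is.na(x)
  w <- max(1L, as.integer(round(window_minutes * 60 / epoch_seconds)))
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  vals <- ifelse(covered, x, 0)
  cs <- c(0, cumsum(vals))
  cn <- c(0, cumsum(as.numeric(covered)))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  count <- cn[hi + 1L] - cn[lo]
  out <- (cs[hi + 1L] - cs[lo]) / count
  out[count == 0] <- NA_real_
  out
}

#' Lag-zero correlation of two smoothed profiles
#'
#' Pearson correlation over the jointly covered epochs, with a two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param a,b Numeric epoch series (typically [smooth_profile()] output).
#' @param a_covered,b_covered Optional logical coverage masks.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
profile_xcorr <- function(a, b, a_covered = NULL, b_covered = NULL) {
  ok <- (a_covered %||% TRUE) & (b_covered %||% TRUE) & !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 10) {
    abort("Fewer than 10 jointly covered epochs.",
          class = "sleepagree_overlap_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Correlation undefined: zero variance.",
          class = "sleepagree_degenerate_error")
  }
  r <- cor(a, b)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  tibble::tibble(r = r, p = p, n = n)
}
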