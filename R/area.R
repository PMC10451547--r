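#' Area above the Exp(dE) curve, initial-rate method
#'
#' Trapezoidal integral of `1 - Exp(dE)` from the addition time to the
#' first return of `Exp(dE)` to unity after the post-addition minimum (the
#' moment the potential regains its pre-inhibition value).  The crossing
#' time is located by linear interpolation between the bracketing samples;
#' overshoot above unity inside the integration range is clipped at zero
#' so the statistic stays a true "area above the curve".  The crossing is
#' accepted within `unity_tol` of 1, because the uninhibited potential
#' itself drifts very slightly downward as the initiator depletes, so the
#' series re-approaches unity from below without necessarily touching it.
#'
#' @param expde Output of [exp_delta_e()]: tibble with `t`, `expde` and a
#'   `t_add` attribute.
#' @param t_add Addition time, s (defaults to the attribute).
#' @param unity_tol Tolerance below 1 accepted as the return to unity
#'   (default 1e-3).
#' @return One-row tibble of class `kp_area`: `method`, `s_arc` (s),
#'   `t_start`, `t_end`, `reached_unity`.
#' @export
area_initial_rate <- function(expde, t_add = NULL, unity_tol = 1e-3) {
  t_add <- t_add %||% attr(expde, "t_add")
  if (is.null(t_add)) abort("supply `t_add`.")
  t <- expde$t; y <- expde$expde
  post <- which(t >= t_add)
  if (length(post) < 2L) abort("series does not extend beyond `t_add`.")
  i_min <- post[which.min(y[post])]
  after <- seq(i_min, length(t))
  up <- after[which(y[after] >= 1 - unity_tol)]
  if (length(up) == 0L) {
    abort(paste("Exp(dE) does not return to unity within the record;",
                "use area_fixed_time() (typical for slow antioxidants)."),
          class = "kp_no_unity_crossing")
  }
  j <- up[1L]
  thr <- 1 - unity_tol
  if (j == i_min || y[j] <= thr) {
    t_cross <- t[j]
  } else {
    # linear interpolation of the up-crossing
    t_cross <- t[j - 1L] + (thr - y[j - 1L]) / (y[j] - y[j - 1L]) *
      (t[j] - t[j - 1L])
  }
  s <- .area_above(t, y, t_add, t_cross)
  out <- tibble(method = "initial_rate", s_arc = s, t_start = t_add,
                t_end = t_cross, reached_unity = TRUE)
  class(out) <- c("kp_area", class(out))
  out
}

#' Area above the Exp(dE) curve, fixed-time method
#'
#' Same integrand as [area_initial_rate()] over a fixed window after the
#' addition (default 1200 s, the conventional analysis time for kinetic
#' methods).  Usable for slow antioxidants whose `Exp(dE)` does not return
#' to unity in a practical time.
#'
#' @inheritParams area_initial_rate
#' @param window Integration window, s.
#' @return One-row tibble of class `kp_area`.
#' @export
area_fixed_time <- function(expde, t_add = NULL, window = 1200) {
  t_add <- t_add %||% attr(expde, "t_add")
  if (is.null(t_add)) abort("supply `t_add`.")
  if (max(expde$t) < t_add + window)
    abort("trace shorter than the fixed-time window.")
  s <- .area_above(expde$t, expde$expde, t_add, t_add + window)
  in_win <- expde$t >= t_add & expde$t <= t_add + window
  i_min <- which.min(replace(expde$expde, !in_win, Inf))
  reached <- any(expde$expde >= 1 & in_win & seq_along(expde$t) > i_min)
  out <- tibble(method = "fixed_time", s_arc = s, t_start = t_add,
                t_end = t_add + window, reached_unity = reached)
  class(out) <- c("kp_area", class(out))
  out
}

# trapezoidal integral of max(1 - y, 0) over [t0, t1] with interpolated ends
.area_above <- function(t, y, t0, t1) {
  if (t1 <= t0) return(0)
  yi <- function(tt) approx(t, y, xout = tt, rule = 2)$y
  tt <- t[t > t0 & t < t1]
  tt <- c(t0, tt, t1)
  yy <- c(yi(t0), y[t > t0 & t < t1], yi(t1))
  integ <- pmax(1 - yy, 0)
  sum(diff(tt) * (head(integ, -1) + tail(integ, -1)) / 2)
}

#' Correlation between capacity metrics
#'
#' Pearson product-moment correlation between two capacity measures (for
#' example induction-period ARC versus fixed-time area) over a panel of
#' antioxidants, with a comparison against a critical value.
#'
#' @param pairs Data frame whose first two numeric columns (or `x`/`y`)
#'   hold the paired metrics; >= 3 pairs.
#' @param r_crit Critical correlation value to compare against (default
#'   0.75, the tabulated value for n = 7, p = 0.95).
#' @return One-row tibble: `r`, `n`, `r_crit`, `significant`.
#' @export
method_correlation <- function(pairs, r_crit = 0.75) {
  if (is.data.frame(pairs)) {
    nm <- intersect(c("x", "y"), names(pairs))
    if (length(nm) == 2L) {
      x <- pairs$x; y <- pairs$y
    } else {
      num <- pairs[vapply(pairs, is.numeric, logical(1))]
      if (ncol(num) < 2L) abort("`pairs` needs two numeric columns.")
      x <- num[[1L]]; y <- num[[2L]]
    }
  } else abort("`pairs` must be a data frame.")
  if (length(x) < 3L) abort("need at least 3 pairs.")
  if (var(x) == 0 || var(y) == 0)
    abort("zero variance: correlation undefined.",
          class = "kp_undefined_correlation")
  r <- stats::cor(x, y)
  tibble(r = r, n = length(x), r_crit = r_crit, significant = r > r_crit)
}
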