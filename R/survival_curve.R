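#' Survival curve defined by (time, survival) anchors
#'
#' A `survival_curve` is a monotone non-increasing survival function given by
#' anchor points, typically annual Kaplan-Meier read-offs. Between anchors the
#' package interpolates under a constant-hazard (piecewise exponential)
#' assumption; beyond the last anchor the last value is carried flat.
#'
#' @param time Numeric vector of anchor times in years, strictly increasing,
#'   starting at 0.
#' @param survival Numeric vector of survival probabilities in `[0, 1]`,
#'   non-increasing, with `survival[1] == 1`.
#' @param name Optional label used in messages and plots.
#'
#' @return An object of class `survival_curve`: a list with elements `time`,
#'   `survival` and `name`.
#' @export
#' @examples
#' os <- survival_curve(0:6, c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18), "OS SC")
#' curve_value(os, 1.5)
survival_curve <- function(time, survival, name = "") {
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  x <- structure(list(time = time, survival = survival, name = as.character(name)[1]),
                 class = "survival_curve")
  validate_survival_curve(x)
  x
}

#' @rdname survival_curve
#' @param x Object to validate.
#' @export
validate_survival_curve <- function(x) {
  lbl <- if (nzchar(x$name)) sprintf(" ('%s')", x$name) else ""
  if (length(x$time) != length(x$survival) || length(x$time) < 1) {
    stop("survival_curve", lbl, ": time and survival must be equal-length, non-empty")
  }
  if (anyNA(x$time) || anyNA(x$survival)) {
    stop("survival_curve", lbl, ": anchors must not contain NA")
  }
  if (x$time[1] != 0 || x$survival[1] != 1) {
    stop("survival_curve", lbl, ": first anchor must be (time = 0, survival = 1)")
  }
  if (any(diff(x$time) <= 0)) {
    i <- which(diff(x$time) <= 0)[1]
    stop(sprintf("survival_curve%s: anchor times not strictly increasing at index %d", lbl, i + 1))
  }
  if (any(x$survival < 0 | x$survival > 1)) {
    i <- which(x$survival < 0 | x$survival > 1)[1]
    stop(sprintf("survival_curve%s: survival outside [0, 1] at anchor index %d", lbl, i))
  }
  if (any(diff(x$survival) > 0)) {
    i <- which(diff(x$survival) > 0)[1]
    stop(sprintf("survival_curve%s: survival increases at anchor index %d (%.4g -> %.4g)",
                 lbl, i + 1, x$survival[i], x$survival[i + 1]))
  }
  invisible(x)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve%s: %d anchors over %.3g years, S(end) = %.3g>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              length(x$time), max(x$time), x$survival[length(x$survival)]))
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time_years = x$time, survival = x$survival)
}

#' Evaluate a survival curve at arbitrary times
#'
#' Constant-hazard interpolation between anchors:
#' `S(t) = S(a) * (S(b)/S(a))^((t - a)/(b - a))` for `a <= t <= b`. If the
#' survival at the left anchor is 0, or the right anchor is 0 and `t > a`,
#' the value is 0. Beyond the last anchor the last value is carried flat.
#'
#' @param curve A [survival_curve()].
#' @param t Numeric vector of times in years (non-negative).
#' @return Numeric vector of survival probabilities.
#' @export
curve_value <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t < 0)) stop("curve_value: times must be non-negative")
  tt <- curve$time
  ss <- curve$survival
  n <- length(tt)
  out <- numeric(length(t))
  beyond <- t >= tt[n]
  out[beyond] <- ss[n]
  idx <- which(!beyond)
  if (length(idx)) {
    i <- findInterval(t[idx], tt)
    a <- tt[i]; b <- tt[i + 1]
    sa <- ss[i]; sb <- ss[i + 1]
    th <- (t[idx] - a) / (b - a)
    v <- numeric(length(idx))
    at_anchor <- th == 0
    v[at_anchor] <- sa[at_anchor]
    rest <- !at_anchor
    # sa == 0 or sb == 0 with th > 0 collapses to 0 (infinite hazard)
    zero <- rest & (sa == 0 | sb == 0)
    v[zero] <- 0
    ok <- rest & !zero
    v[ok] <- sa[ok] * (sb[ok] / sa[ok])^th[ok]
    out[idx] <- v
  }
  out
}

#' Expand a survival curve to a monthly grid
#'
#' Evaluates the curve at months `0..horizon_months` (constant-hazard between
#' anchors, flat beyond the last anchor) and returns a `monthly_survival`
#' vector. Every anchor that falls on a whole month is reproduced exactly.
#'
#' @param curve A [survival_curve()].
#' @param horizon_months Positive integer number of monthly cycles.
#' @return A numeric vector of class `monthly_survival`, length
#'   `horizon_months + 1`, element `m + 1` holding survival at month `m`.
#' @export
#' @examples
#' os <- survival_curve(0:6, c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18))
#' interpolate_monthly(os, 72)[13]  # month 12 -> 0.88
interpolate_monthly <- function(curve, horizon_months) {
  if (!is.numeric(horizon_months) || length(horizon_months) != 1 ||
      horizon_months <= 0 || horizon_months != round(horizon_months)) {
    stop("interpolate_monthly: horizon_months must be a positive integer")
  }
  v <- curve_value(curve, (0:horizon_months) / 12)
  structure(v, class = "monthly_survival")
}

#' @export
print.monthly_survival <- function(x, ...) {
  cat(sprintf("<monthly_survival: %d months, S(end) = %.4g>\n", length(x) - 1, x[length(x)]))
  invisible(x)
}

#' Clip progression-free survival to overall survival
#'
#' In a partitioned survival model the progression-free curve must not exceed
#' overall survival (state occupancies OMD = PFS, PMD = OS - PFS must be
#' non-negative). Returns PFS clipped pointwise to `min(pfs, os)` and warns,
#' naming the first violating month, whenever any clipping occurred.
#'
#' @param os,pfs `monthly_survival` vectors of equal length.
#' @return The adjusted PFS (`monthly_survival`).
#' @export
enforce_dominance <- function(os, pfs) {
  if (length(os) != length(pfs)) {
    stop("enforce_dominance: os and pfs must have equal length")
  }
  bad <- which(pfs > os)
  if (length(bad)) {
    warning(sprintf("enforce_dominance: PFS > OS first at month %d; clipping %d value(s)",
                    bad[1] - 1, length(bad)))
    pfs <- pmin(pfs, os)
  }
  structure(as.numeric(pfs), class = "monthly_survival")
}

#' Splice a trial survival curve onto a long-term reference curve
#'
#' Extends a trial curve beyond its follow-up by continuing along a long-term
#' reference (registry) curve: the junction time `t*` on the reference is the
#' earliest time at which the reference passes through the trial's final
#' survival value (solved under the same constant-hazard interpolation rule),
#' and for `t > T` the output is `reference(t* + (t - T))`. The result is
#' continuous at the junction and monotone non-increasing.
#'
#' @param trial A [survival_curve()] covering the trial follow-up.
#' @param reference A [survival_curve()] with long-term support that decreases
#'   through the trial's final survival value.
#' @param horizon_years Total horizon of the extended curve, in years.
#' @return A [survival_curve()] equal to `trial` up to its end and following
#'   the shifted reference afterwards, with anchors up to `horizon_years`.
#' @export
splice_extrapolate <- function(trial, reference, horizon_years) {
  stopifnot(inherits(trial, "survival_curve"), inherits(reference, "survival_curve"))
  t_end <- max(trial$time)
  s_end <- trial$survival[length(trial$survival)]
  if (horizon_years < t_end) {
    stop("splice_extrapolate: horizon_years is shorter than the trial curve")
  }
  if (horizon_years == t_end) return(trial)
  if (s_end <= 0) {
    stop("splice_extrapolate: trial curve ends at 0; nothing to extrapolate from")
  }
  t_star <- .curve_inverse_earliest(reference, s_end)
  if (is.na(t_star)) {
    stop(sprintf(paste0("splice_extrapolate: reference curve never reaches the trial-end ",
                        "survival %.4g; supply a reference with longer support"), s_end))
  }
  need <- horizon_years - t_end          # years of reference beyond t_star
  # anchor the tail at the reference's own anchors (shifted), so constant-hazard
  # re-interpolation reproduces the reference exactly, plus the horizon endpoint
  ref_t <- reference$time
  inner <- ref_t[ref_t > t_star & ref_t < t_star + need]
  tail_t <- c(inner, t_star + need)
  tail_s <- curve_value(reference, tail_t)
  out_t <- c(trial$time, t_end + (tail_t - t_star))
  out_s <- c(trial$survival, pmin(tail_s, s_end))
  out_s <- cummin(out_s)  # guard against round-off at the junction
  survival_curve(out_t, out_s, name = trial$name)
}

# earliest t with curve(t) == level, solved piecewise under constant hazard;
# NA if the curve never reaches `level`
.curve_inverse_earliest <- function(curve, level) {
  tt <- curve$time
  ss <- curve$survival
  n <- length(tt)
  for (i in seq_len(n)) {
    if (ss[i] == level) return(tt[i])
    if (i < n && ss[i] > level && ss[i + 1] < level) {
      if (ss[i + 1] <= 0) return(tt[i + 1])
      th <- log(level / ss[i]) / log(ss[i + 1] / ss[i])
      return(tt[i] + th * (tt[i + 1] - tt[i]))
    }
  }
  NA_real_
}

#' Extend progression-free survival proportionally to extended overall survival
#'
#' Beyond the shared trial end time `T`, the extended PFS is
#' `r * os_extended(t)` with `r = PFS(T) / OS(T)` (and `r = 0` when
#' `PFS(T) = 0`), keeping the trial-period PFS unchanged. This mirrors the
#' common practice of assuming the trial's end-of-follow-up PFS/OS ratio
#' persists during registry-based extrapolation.
#'
#' @param os_extended Extended OS [survival_curve()] (e.g. from
#'   [splice_extrapolate()]).
#' @param trial_pfs,trial_os Trial-period PFS and OS curves sharing end time.
#' @return A [survival_curve()] for the extended PFS.
#' @export
extrapolate_pfs_proportional <- function(os_extended, trial_pfs, trial_os) {
  stopifnot(inherits(os_extended, "survival_curve"),
            inherits(trial_pfs, "survival_curve"),
            inherits(trial_os, "survival_curve"))
  t_end <- max(trial_pfs$time)
  if (!isTRUE(all.equal(t_end, max(trial_os$time)))) {
    stop("extrapolate_pfs_proportional: trial PFS and OS must share their end time")
  }
  pfs_end <- trial_pfs$survival[length(trial_pfs$survival)]
  os_end <- trial_os$survival[length(trial_os$survival)]
  if (os_end == 0 && pfs_end > 0) {
    stop("extrapolate_pfs_proportional: OS(T) = 0 with PFS(T) > 0; ratio undefined")
  }
  r <- if (pfs_end == 0) 0 else pfs_end / os_end
  ext_t <- os_extended$time[os_extended$time > t_end]
  if (!length(ext_t)) return(trial_pfs)
  ext_s <- r * curve_value(os_extended, ext_t)
  out_t <- c(trial_pfs$time, ext_t)
  out_s <- cummin(c(trial_pfs$survival, ext_s))
  survival_curve(out_t, out_s, name = trial_pfs$name)
}

#' Pool survival curves as a weighted mixture
#'
#' Pointwise weighted mean of survival probabilities, e.g. to pool registry
#' curves of several cancer entities in proportion to a study population.
#' Curves that do not share an anchor grid are first resampled onto the union
#' of all anchor times (constant-hazard interpolation).
#'
#' @param curves List of [survival_curve()] objects.
#' @param weights Non-negative weights summing to 1 (within 1e-9).
#' @param name Label for the pooled curve.
#' @return A [survival_curve()].
#' @export
pool_reference_curves <- function(curves, weights, name = "pooled") {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "survival_curve")))
  weights <- as.numeric(weights)
  if (length(weights) != length(curves)) {
    stop("pool_reference_curves: one weight per curve required")
  }
  if (any(weights < 0)) stop("pool_reference_curves: weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("pool_reference_curves: weights sum to %.12g, not 1", sum(weights)))
  }
  grid <- sort(unique(unlist(lapply(curves, `[[`, "time"))))
  vals <- vapply(curves, curve_value, numeric(length(grid)), t = grid)
  pooled <- pmin(as.numeric(vals %*% weights), 1)
  pooled[1] <- 1  # guard against round-off in the weight sum
  survival_curve(grid, pooled, name = name)
}

#' Read or write a survival curve as two-column CSV
#'
#' The CSV dialect is `time_years,survival` with a header row, '.' decimal
#' separator and no thousands separators.
#'
#' @param path File path.
#' @param curve A [survival_curve()] (for writing).
#' @param name Label given to the curve read from file.
#' @return `read_survival_curve_csv()` returns a [survival_curve()];
#'   `write_survival_curve_csv()` returns `path` invisibly.
#' @export
read_survival_curve_csv <- function(path, name = "") {
  df <- utils::read.csv(path)
  if (!all(c("time_years", "survival") %in% names(df))) {
    stop("read_survival_curve_csv: expected columns time_years, survival")
  }
  survival_curve(df$time_years, df$survival, name = name)
}

#' @rdname read_survival_curve_csv
#' @export
write_survival_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
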