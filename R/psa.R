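#' Moment-matched beta parameters from a mean and a 95% range
#'
#' The range is read as a 95% interval, so `sd = (high - low) / (2 * 1.96)`;
#' shape parameters follow by moment matching:
#' `alpha = mean * (mean * (1 - mean) / sd^2 - 1)`,
#' `beta  = (1 - mean) * (mean * (1 - mean) / sd^2 - 1)`.
#'
#' @param mean Mean in (0, 1).
#' @param low,high Range endpoints with `high > low`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' fit_beta_from_mean_range(0.82, 0.70, 0.90)
fit_beta_from_mean_range <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("fit_beta_from_mean_range: mean must lie in (0, 1)")
  if (high <= low) stop("fit_beta_from_mean_range: need high > low")
  sd <- (high - low) / (2 * 1.96)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(paste0("fit_beta_from_mean_range: implied variance %.4g >= mean*(1-mean) ",
                        "= %.4g; no beta distribution has these moments (use family ",
                        "'degenerate' instead)"), v, mean * (1 - mean)))
  }
  k <- mean * (1 - mean) / v - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Moment-matched gamma parameters from a mean and a 95% range
#'
#' With `sd = (high - low) / (2 * 1.96)`: `shape = (mean / sd)^2`,
#' `scale = sd^2 / mean`, so `shape * scale = mean` exactly.
#'
#' @param mean Positive mean.
#' @param low,high Range endpoints with `high > low`.
#' @return Named numeric vector `c(shape, scale)`.
#' @export
#' @examples
#' fit_gamma_from_mean_range(11700, 9360, 14040)
fit_gamma_from_mean_range <- function(mean, low, high) {
  if (mean <= 0) stop("fit_gamma_from_mean_range: mean must be positive")
  sd <- (high - low) / (2 * 1.96)
  if (sd <= 0) {
    stop("fit_gamma_from_mean_range: non-positive sd; use family 'degenerate' instead")
  }
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Distribution assignment for one probabilistic parameter
#'
#' Scalar parameters take their `(mean, low, high)` on the parameter's own
#' scale. Survival-curve parameters (`os_*`, `pfs_*`) take *relative*
#' endpoints around 1 (e.g. `low = 0.85, high = 1.15`): each anchor after
#' time 0 is drawn from a beta distribution moment-matched to
#' `(anchor, low * anchor, high * anchor)`.
#'
#' @param id Parameter id (see [get_model_param()]).
#' @param family `"beta"`, `"gamma"` or `"degenerate"` (no variation).
#' @param mean Base value (ignored for curve parameters, where it is fixed
#'   at 1).
#' @param low,high 95% range endpoints.
#' @return A one-row data frame of class `dist_spec`.
#' @export
dist_spec <- function(id, family = c("beta", "gamma", "degenerate"), mean, low, high) {
  family <- match.arg(family)
  if (is_curve_param(id)) mean <- 1
  if (family != "degenerate") {
    if (!(low <= mean && mean <= high)) {
      stop(sprintf("dist_spec '%s': need low <= mean <= high", id))
    }
    if (!is_curve_param(id)) {
      if (family == "beta" && (mean <= 0 || mean >= 1)) {
        stop(sprintf("dist_spec '%s': beta requires mean in (0, 1)", id))
      }
      if (family == "gamma" && mean <= 0) {
        stop(sprintf("dist_spec '%s': gamma requires mean > 0", id))
      }
    }
  }
  structure(data.frame(id = id, family = family, mean = mean, low = low, high = high),
            class = c("dist_spec", "data.frame"))
}

#' Published probabilistic distribution assignments
#'
#' Gamma distributions for all cost parameters and beta distributions for
#' utilities, adverse-event disutilities and the survival anchors (the latter
#' varied by a relative plus/minus 15% range per anchor), each moment-matched
#' to its published 95% range.
#'
#' @param inputs A [cea_inputs()] object supplying the base values.
#' @return A data frame of [dist_spec()] rows.
#' @export
sabr_comet_psa_specs <- function(inputs = sabr_comet_inputs()) {
  g <- function(id) get_model_param(inputs, id)
  gamma20 <- function(id) dist_spec(id, "gamma", g(id), 0.8 * g(id), 1.2 * g(id))
  rows <- list(
    gamma20("annual_omd_cost"),
    gamma20("annual_pmd_cost"),
    gamma20("end_of_life_cost"),
    gamma20("palliative_rt_unit_cost"),
    dist_spec("sabr_unit_cost", "gamma", g("sabr_unit_cost"),
              0.7 * g("sabr_unit_cost"), 1.2 * g("sabr_unit_cost")),
    dist_spec("utility_omd", "beta", g("utility_omd"), 0.70, 0.90),
    dist_spec("utility_pmd", "beta", g("utility_pmd"), 0.50, 0.70),
    gamma20("ae_cost_intervention"),
    gamma20("ae_cost_comparator"),
    dist_spec("ae_disutility_intervention", "beta", g("ae_disutility_intervention"),
              0.9 * g("ae_disutility_intervention"), 1.1 * g("ae_disutility_intervention")),
    dist_spec("ae_disutility_comparator", "beta", g("ae_disutility_comparator"),
              0.9 * g("ae_disutility_comparator"), 1.1 * g("ae_disutility_comparator")),
    dist_spec("os_intervention", "beta", 1, 0.85, 1.15),
    dist_spec("os_comparator", "beta", 1, 0.85, 1.15),
    dist_spec("pfs_intervention", "beta", 1, 0.85, 1.15),
    dist_spec("pfs_comparator", "beta", 1, 0.85, 1.15))
  do.call(rbind, rows)
}

.draw_scalar <- function(family, mean, low, high) {
  switch(family,
    degenerate = mean,
    beta = { p <- fit_beta_from_mean_range(mean, low, high)
             stats::rbeta(1, p["alpha"], p["beta"]) },
    gamma = { p <- fit_gamma_from_mean_range(mean, low, high)
              stats::rgamma(1, shape = p["shape"], scale = p["scale"]) })
}

# draw one survival curve: independent beta per anchor (time > 0), then repair
# to a valid non-increasing curve. Anchors at 0 or (numerically) too close to
# 1 for the implied beta variance are left unvaried.
.draw_curve <- function(curve, family, rel_low, rel_high, warn_repair = 0.2) {
  if (family == "degenerate") return(curve)
  s <- curve$survival
  draw <- s
  for (i in seq_along(s)[-1]) {
    v <- s[i]
    if (v <= 0 || v >= 1) next
    sd <- v * (rel_high - rel_low) / (2 * 1.96)
    if (sd^2 >= v * (1 - v)) next
    p <- fit_beta_from_mean_range(v, rel_low * v, rel_high * v)
    draw[i] <- stats::rbeta(1, p["alpha"], p["beta"])
  }
  repaired <- cummin(pmin(pmax(draw, 0), 1))
  moved <- abs(repaired - draw)
  if (any(moved > warn_repair)) {
    warning(sprintf("curve repair moved anchor %d of '%s' by %.3g (> %.2g)",
                    which.max(moved), curve$name, max(moved), warn_repair))
  }
  survival_curve(curve$time, repaired, name = curve$name)
}

#' Draw one probabilistic input set
#'
#' Draws every parameter listed in `specs` from its fitted distribution using
#' the current RNG state (seed the RNG for reproducibility): scalars from
#' moment-matched beta/gamma distributions, survival anchors independently
#' from per-anchor beta distributions followed by monotonicity repair
#' (sequential minimum) and anchor-level clipping of PFS to OS, which under
#' constant-hazard interpolation guarantees monthly dominance. Parameters
#' shared by both arms (state costs, utilities) appear once in `specs` and so
#' are drawn once per call. A repair that moves any anchor by more than 0.2
#' raises a warning.
#'
#' @param inputs Base [cea_inputs()] object.
#' @param specs Data frame of [dist_spec()] rows.
#' @return A perturbed [cea_inputs()] object.
#' @export
sample_model_inputs <- function(inputs, specs) {
  stopifnot(inherits(inputs, "cea_inputs"))
  out <- inputs
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (is_curve_param(sp$id)) {
      role <- if (endsWith(sp$id, "intervention")) "intervention" else "comparator"
      field <- if (startsWith(sp$id, "os")) "os" else "pfs"
      out[[role]][[field]] <- .draw_curve(out[[role]][[field]], sp$family, sp$low, sp$high)
    } else {
      out <- set_model_param(out, sp$id, .draw_scalar(sp$family, sp$mean, sp$low, sp$high))
    }
  }
  for (role in c("intervention", "comparator")) {
    pfs <- out[[role]]$pfs
    os <- out[[role]]$os
    clipped <- pmin(pfs$survival, curve_value(os, pfs$time))
    out[[role]]$pfs <- survival_curve(pfs$time, cummin(clipped), name = pfs$name)
  }
  out
}

# fast per-arm evaluation used inside the PSA loop; numerically identical to
# run_arm() (same curve evaluation and the same accrual functions)
.run_arm_values <- function(arm, costs, utilities, settings) {
  h <- settings$horizon_months
  grid <- (0:h) / 12
  os <- curve_value(arm$os, grid)
  pfs <- pmin(curve_value(arm$pfs, grid), os)
  tr <- list(omd = pfs, pmd = os - pfs, dead = 1 - os)
  cost <- accrue_costs(tr, costs, arm, settings)
  qaly <- accrue_qalys(tr, utilities, arm$ae_onetime_disutility, settings)
  c(cost = cost$total, qaly = qaly)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws `n` input sets via [sample_model_inputs()] (shared parameters once
#' per iteration, applied to both arms), runs the full partitioned survival
#' model per draw, and summarizes acceptability (share of iterations with
#' positive incremental net monetary benefit at `wtp`) and the dominant-
#' strategy share (negative incremental cost and positive incremental effect).
#'
#' @param inputs Base [cea_inputs()] object.
#' @param n Number of iterations (>= 1).
#' @param wtp Willingness-to-pay (defaults to the configured setting).
#' @param seed RNG seed recorded in the result; `NULL` uses the current RNG
#'   state.
#' @param specs Distribution assignments; defaults to
#'   [sabr_comet_psa_specs()] evaluated on `inputs`.
#' @return An object of class `psa_result`: list with `iterations` (data
#'   frame: iteration, per-arm cost and QALY, `delta_cost`, `delta_effect`,
#'   `inmb`, `dominant`) and `summary` (list with `n`, `wtp`, `seed`,
#'   `acceptability_pct`, `dominant_pct`, `mean_delta_cost`,
#'   `mean_delta_effect`, `icer_of_means`).
#' @export
#' @examples
#' psa <- run_psa(sabr_comet_inputs(), n = 50, seed = 1)
#' psa$summary$acceptability_pct
run_psa <- function(inputs, n, wtp = inputs$settings$wtp, seed = NULL,
                    specs = sabr_comet_psa_specs(inputs)) {
  stopifnot(inherits(inputs, "cea_inputs"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ci <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("cost", "qaly")))
  cc <- ci
  for (it in seq_len(n)) {
    draw <- tryCatch(sample_model_inputs(inputs, specs), error = function(e) {
      stop(sprintf("run_psa: iteration %d (seed %s) failed during sampling: %s",
                   it, format(seed), conditionMessage(e)), call. = FALSE)
    })
    ci[it, ] <- .run_arm_values(draw$intervention, draw$costs, draw$utilities, draw$settings)
    cc[it, ] <- .run_arm_values(draw$comparator, draw$costs, draw$utilities, draw$settings)
  }
  dc <- ci[, "cost"] - cc[, "cost"]
  de <- ci[, "qaly"] - cc[, "qaly"]
  inmb <- de * wtp - dc
  dominant <- dc < 0 & de > 0
  iters <- data.frame(iteration = seq_len(n),
                      cost_intervention = ci[, "cost"], qaly_intervention = ci[, "qaly"],
                      cost_comparator = cc[, "cost"], qaly_comparator = cc[, "qaly"],
                      delta_cost = dc, delta_effect = de, inmb = inmb,
                      dominant = dominant)
  summary <- list(n = n, wtp = wtp, seed = seed,
                  acceptability_pct = 100 * mean(inmb > 0),
                  dominant_pct = 100 * mean(dominant),
                  mean_delta_cost = mean(dc),
                  mean_delta_effect = mean(de),
                  icer_of_means = mean(dc) / mean(de))
  structure(list(iterations = iters, summary = summary), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<psa_result: %d iterations, acceptability %.2f%% at WTP $%s/QALY, ",
                     "dominant %.1f%%, ICER of means $%s/QALY>\n"),
              s$n, s$acceptability_pct, format(s$wtp, big.mark = ",", scientific = FALSE),
              s$dominant_pct, format(round(s$icer_of_means), big.mark = ",")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Acceptability (share of PSA iterations with positive incremental NMB) over
#' a grid of willingness-to-pay values.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Numeric vector of WTP values.
#' @return Data frame with columns `wtp` and `acceptability_pct`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 5e3)) {
  stopifnot(inherits(psa, "psa_result"))
  it <- psa$iterations
  acc <- vapply(wtp_grid,
                function(w) 100 * mean(it$delta_effect * w - it$delta_cost > 0),
                numeric(1))
  data.frame(wtp = wtp_grid, acceptability_pct = acc)
}
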