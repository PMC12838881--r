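## kinetics: Morrison tight-binding inhibition, initial-velocity
## extraction from progress curves, Ki fitting by nonlinear regression.
##
## All concentrations are converted to pM before the quadratic is
## evaluated: mixing nM enzyme with uM substrate naively makes the
## discriminant ill-conditioned.

#' Assay condition for a tight-binding inhibition experiment
#'
#' @param E_total_nM total enzyme concentration (nM).
#' @param S_total_uM total substrate concentration (uM).
#' @param Km_uM Michaelis constant of the substrate (uM); fixed during Ki
#'   fitting.
#' @param v0 uninhibited initial velocity (fluorescence units/min).
#' @return an `assay_condition` list.
#' @export
assay_condition <- function(E_total_nM = 8, S_total_uM = 20,
                            Km_uM = 7.76, v0 = 1) {
  stopifnot(E_total_nM > 0, S_total_uM > 0, Km_uM > 0, v0 > 0)
  structure(list(E_total_nM = E_total_nM, S_total_uM = S_total_uM,
                 Km_uM = Km_uM, v0 = v0),
            class = "assay_condition")
}

## Fractional velocity v/v0 from Morrison's equation, everything in pM.
morrison_fraction <- function(E_pM, S_pM, Km_pM, I_pM, Ki_pM) {
  Ki_app <- Ki_pM * (1 + S_pM / Km_pM)
  term <- E_pM + I_pM + Ki_app
  disc <- term^2 - 4 * E_pM * I_pM
  if (any(disc < 0)) stop("negative discriminant: numeric fault")
  1 - (term - sqrt(disc)) / (2 * E_pM)
}

#' Morrison tight-binding velocity
#'
#' Velocity of an enzyme reaction in the presence of a tight-binding
#' inhibitor, where free and total inhibitor concentrations differ
#' appreciably:
#' `v = v0 * (1 - (E + I + Ki_app - sqrt((E + I + Ki_app)^2 - 4 E I)) / (2 E))`
#' with `Ki_app = Ki * (1 + S/Km)`. Vectorized over `I_nM` or `Ki_pM`.
#'
#' @param cond an [assay_condition()].
#' @param I_nM total inhibitor concentration(s), nM.
#' @param Ki_pM equilibrium inhibition constant, pM.
#' @return velocity in the units of `cond$v0`, in `[0, v0]`;
#'   `v = v0` exactly at `I = 0`.
#' @export
morrison_velocity <- function(cond, I_nM, Ki_pM) {
  stopifnot(inherits(cond, "assay_condition"), all(I_nM >= 0), all(Ki_pM > 0))
  cond$v0 * morrison_fraction(cond$E_total_nM * 1e3,
                              cond$S_total_uM * 1e6,
                              cond$Km_uM * 1e6,
                              I_nM * 1e3, Ki_pM)
}

#' Initial-velocity extraction policy
#'
#' `fixed_window` fits the least-squares slope over the first `k` points.
#' `best_linear` selects the longest prefix (at least `min_points` points)
#' whose linear fit has `R^2 >= r2` and returns its slope. The default is
#' a short fixed window: on smooth progress curves `R^2` barely penalises
#' gentle curvature, so an `R^2`-screened prefix can extend deep into the
#' substrate-depletion phase and underestimate the initial rate; a short
#' early window bounds that bias. `best_linear` remains useful for noisy
#' traces where a longer window is needed to average out noise.
#'
#' @param type `fixed_window` or `best_linear`.
#' @param k window size in points for `fixed_window`.
#' @param min_points,r2 prefix floor and R-squared threshold for
#'   `best_linear`.
#' @return a `velocity_policy` list.
#' @export
velocity_policy <- function(type = c("fixed_window", "best_linear"),
                            k = 10L, min_points = 5L, r2 = 0.99) {
  type <- match.arg(type)
  stopifnot(k >= 2L, min_points >= 2L, r2 > 0, r2 <= 1)
  structure(list(type = type, k = as.integer(k),
                 min_points = as.integer(min_points), r2 = r2),
            class = "velocity_policy")
}

#' Build a progress curve
#' @param inhibitor_nM total inhibitor concentration for this curve (nM).
#' @param time_min strictly increasing times (minutes), at least 3 points.
#' @param fluorescence fluorescence readings, same length.
#' @return a `progress_curve` data frame.
#' @export
progress_curve <- function(inhibitor_nM, time_min, fluorescence) {
  stopifnot(length(time_min) >= 3L, all(diff(time_min) > 0),
            time_min[1] >= 0, length(fluorescence) == length(time_min))
  structure(data.frame(time_min = time_min, fluorescence = fluorescence),
            inhibitor_nM = inhibitor_nM,
            class = c("progress_curve", "data.frame"))
}

ls_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * y) / sum(tc^2)
}

r_squared <- function(t, y) {
  fit <- lm(y ~ t)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)  # constant curve: linear fit is exact
  1 - sum(fit$residuals^2) / ss_tot
}

#' Initial velocity from a progress curve
#'
#' Least-squares slope of the fluorescence trace over the prefix window
#' selected by the policy (see [velocity_policy()]).
#'
#' @param curve a [progress_curve()].
#' @param policy a [velocity_policy()].
#' @return slope in fluorescence units/min, with attribute `n_points`.
#' @export
initial_velocity <- function(curve, policy = velocity_policy()) {
  t <- curve$time_min; y <- curve$fluorescence
  label <- attr(curve, "inhibitor_nM")
  if (policy$type == "fixed_window") {
    if (length(t) < policy$k) {
      stop("curve at inhibitor ", label, " nM has fewer than ",
           policy$k, " points")
    }
    idx <- seq_len(policy$k)
    return(structure(ls_slope(t[idx], y[idx]), n_points = policy$k))
  }
  for (m in rev(seq(policy$min_points, length(t)))) {
    idx <- seq_len(m)
    if (r_squared(t[idx], y[idx]) >= policy$r2) {
      return(structure(ls_slope(t[idx], y[idx]), n_points = m))
    }
  }
  stop("no prefix of curve at inhibitor ", label, " nM of at least ",
       policy$min_points, " points reaches R^2 >= ", policy$r2)
}

#' Fit the equilibrium inhibition constant Ki
#'
#' Nonlinear least-squares fit of Morrison's tight-binding model to
#' (inhibitor concentration, velocity) pairs, with `Km` fixed at the
#' value in `cond`. By default the uninhibited velocity `v0` is fitted
#' jointly with `Ki`. Starting values are deterministic: `v0` starts at
#' the velocity at the lowest inhibitor concentration, `Ki` at the
#' apparent-IC50 estimate obtained by linear interpolation of the
#' velocity curve (corrected for enzyme depletion and the substrate
#' factor), so repeated fits of the same data are identical.
#'
#' @param velocities data frame with columns `I_nM` (total inhibitor, nM)
#'   and `v` (velocity); at least 4 concentrations, including `I = 0` or
#'   a fixed `v0`.
#' @param cond an [assay_condition()]; `cond$v0` is the fixed value when
#'   `fix_v0 = TRUE`.
#' @param fix_v0 if `TRUE`, only Ki is fitted.
#' @param ki_cap_pM upper bound on Ki (pM); an estimate at the cap marks
#'   the data as uninformative and sets `converged = FALSE`.
#' @return a `ki_fit` list: `Ki_pM`, `stderr_pM`, `v0_hat`,
#'   `residual_norm`, `converged`, `n_points`.
#' @export
fit_ki <- function(velocities, cond, fix_v0 = FALSE, ki_cap_pM = 1e9) {
  stopifnot(all(c("I_nM", "v") %in% names(velocities)))
  velocities <- velocities[order(velocities$I_nM), , drop = FALSE]
  if (length(unique(velocities$I_nM)) < 4L) {
    stop("need at least 4 inhibitor concentrations")
  }
  if (!fix_v0 && velocities$I_nM[1] > 0) {
    stop("need an I = 0 point, or fix_v0 = TRUE with a known v0")
  }
  I_pM <- velocities$I_nM * 1e3
  v <- velocities$v
  E_pM <- cond$E_total_nM * 1e3
  S_pM <- cond$S_total_uM * 1e6
  Km_pM <- cond$Km_uM * 1e6
  sub_factor <- 1 + S_pM / Km_pM

  v0_start <- if (fix_v0) cond$v0 else v[1]
  half <- v0_start / 2
  ic50_pM <- if (any(v <= half) && any(v >= half)) {
    ord <- order(v)
    stats::approx(x = v[ord], y = I_pM[ord], xout = half,
                  ties = "mean")$y
  } else {
    max(I_pM) * 10  # velocity never halves: start weakly binding
  }
  if (is.na(ic50_pM)) ic50_pM <- max(I_pM)
  ki_start <- max((ic50_pM - E_pM / 2) / sub_factor, 1e-3)
  ki_start <- min(ki_start, ki_cap_pM / 2)

  fit <- tryCatch({
    if (fix_v0) {
      minpack.lm::nlsLM(
        v ~ v0_start * morrison_fraction(E_pM, S_pM, Km_pM, I_pM, Ki),
        start = list(Ki = ki_start),
        lower = c(Ki = 1e-6), upper = c(Ki = ki_cap_pM),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        v ~ v0 * morrison_fraction(E_pM, S_pM, Km_pM, I_pM, Ki),
        start = list(Ki = ki_start, v0 = v0_start),
        lower = c(Ki = 1e-6, v0 = 0),
        upper = c(Ki = ki_cap_pM, v0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    warning("Ki fit failed: ", conditionMessage(fit))
    return(structure(list(Ki_pM = NA_real_, stderr_pM = NA_real_,
                          v0_hat = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, n_points = length(v)),
                     class = "ki_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  ki_hat <- unname(est["Ki"])
  converged <- fit$convInfo$isConv && ki_hat < 0.99 * ki_cap_pM
  if (ki_hat >= 0.99 * ki_cap_pM) {
    warning("Ki estimate at the upper cap (", ki_cap_pM,
            " pM): data are uninformative about Ki")
  }
  structure(list(Ki_pM = ki_hat,
                 stderr_pM = unname(se["Ki"]),
                 v0_hat = if (fix_v0) cond$v0 else unname(est["v0"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = converged,
                 n_points = length(v)),
            class = "ki_fit")
}

#' @export
print.ki_fit <- function(x, ...) {
  cat(sprintf("Morrison tight-binding fit: Ki = %.4g pM (SE %.3g), v0 = %.4g, %s (n = %d)\n",
              x$Ki_pM, x$stderr_pM, x$v0_hat,
              if (x$converged) "converged" else "NOT converged",
              x$n_points))
  invisible(x)
}

#' Read/write progress curves as TSV
#'
#' Long format, columns `inhibitor_nM`, `time_min`, `fluorescence`.
#'
#' @param curves a list of [progress_curve()] objects.
#' @param path file path.
#' @return `path` (writer) or a list of progress curves (reader).
#' @export
write_progress_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(inhibitor_nM = attr(cu, "inhibitor_nM"),
               time_min = cu$time_min, fluorescence = cu$fluorescence)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_progress_curves
#' @export
read_progress_curves <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$inhibitor_nM), function(d) {
    progress_curve(d$inhibitor_nM[1], d$time_min, d$fluorescence)
  }) |> unname()
}

#' Write a Ki fit report as JSON
#' @param fit a `ki_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ki_report <- function(fit, path) {
  jsonlite::write_json(list(Ki_pM = fit$Ki_pM, stderr_pM = fit$stderr_pM,
                            v0 = fit$v0_hat, converged = fit$converged,
                            n_points = fit$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
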