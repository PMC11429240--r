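# Non-compartmental analysis of simulated profiles: linear-up/log-down
# trapezoidal AUC with terminal extrapolation, log-linear terminal slope
# over the best adjusted-R^2 window, clearance, moment Vss, and fraction of
# the dose excreted in urine at stated cut-offs.

# trapezoid over one segment: log-down when declining and positive
.trap_segment <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c1 > 0 && c2 > 0 && c2 < c1) (c1 - c2) / log(c1 / c2) * dt
  else (c1 + c2) / 2 * dt
}

.auc_trap <- function(times, conc) {
  s <- 0
  for (i in seq_len(length(times) - 1))
    s <- s + .trap_segment(times[i], times[i + 1], conc[i], conc[i + 1])
  s
}

# first moment (t*C) by linear trapezoid
.aumc_trap <- function(times, conc) {
  m <- times * conc
  sum(diff(times) * (utils::head(m, -1) + utils::tail(m, -1)) / 2)
}

#' Terminal log-linear slope
#'
#' Fits log(C) ~ t over candidate windows of the last 3 to 6 positive
#' concentrations (excluding the observed maximum) and keeps the window
#' with the best adjusted R^2, ties resolved toward more points.
#'
#' @param profile a `concentration_profile` (or data.frame with `time`,
#'   `conc`).
#' @return List with `lambda_z` (1/h), `n_points`, `r2_adj`, `intercept`
#'   (log mg/L).
#' @export
lambda_z <- function(profile) {
  t0 <- max(c(0, attr(profile, "dose_times")))
  keep <- profile$time >= t0 & profile$conc > 0
  tt <- profile$time[keep]
  cc <- profile$conc[keep]
  if (length(tt) < 3) stop("fewer than 3 positive concentrations")
  imax <- which.max(cc)
  best <- NULL
  for (k in 3:6) {
    idx <- utils::tail(seq_along(tt), k)
    idx <- setdiff(idx, imax)
    if (length(idx) < 3) next
    x <- tt[idx]; y <- log(cc[idx])
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    slope <- sum((x - mx) * (y - my)) / sxx
    if (slope >= 0) next
    res <- y - my - slope * (x - mx)
    sst <- sum((y - my)^2)
    r2 <- 1 - sum(res^2) / sst
    r2a <- 1 - (1 - r2) * (length(idx) - 1) / (length(idx) - 2)
    if (is.null(best) || r2a > best$r2_adj + 1e-12 ||
        (abs(r2a - best$r2_adj) <= 1e-12 && length(idx) > best$n_points))
      best <- list(lambda_z = -slope, n_points = length(idx), r2_adj = r2a,
                   intercept = my - slope * mx)
  }
  if (is.null(best)) stop("no valid terminal phase found")
  best
}

#' Area under the plasma concentration curve
#'
#' Linear-up/log-down trapezoid. `"to_infinity"` adds the terminal
#' extrapolation `C_last / lambda_z`; `"last_interval"` integrates over the
#' final dosing interval of a repeated-dose profile.
#'
#' @param profile a `concentration_profile`.
#' @param mode `"to_infinity"` or `"last_interval"`.
#' @return AUC in h*mg/L; for `"to_infinity"` the extrapolated fraction is
#'   attached as attribute `extrapolated`.
#' @export
auc <- function(profile, mode = c("to_infinity", "last_interval")) {
  mode <- match.arg(mode)
  if (nrow(profile) < 3) stop("need at least 3 time points")
  if (mode == "last_interval") {
    tau <- attr(profile, "tau")
    t_last_dose <- max(attr(profile, "dose_times"))
    if (!is.finite(tau)) stop("profile has no dosing interval")
    keep <- profile$time >= t_last_dose - 1e-9 &
      profile$time <= t_last_dose + tau + 1e-9
    return(.auc_trap(profile$time[keep], profile$conc[keep]))
  }
  if (all(profile$conc == 0)) return(0)
  a <- .auc_trap(profile$time, profile$conc)
  lz <- lambda_z(profile)
  c_last <- utils::tail(profile$conc[profile$conc > 0], 1)
  ext <- c_last / lz$lambda_z
  structure(a + ext, extrapolated = ext / (a + ext))
}

#' Terminal half-life
#'
#' `t1/2 = ln(2) / lambda_z` with the slope from [lambda_z()].
#'
#' @param profile a `concentration_profile`.
#' @return Half-life in h.
#' @export
terminal_half_life <- function(profile) log(2) / lambda_z(profile)$lambda_z

#' Fraction of dose excreted in urine by a cut-off time
#'
#' @param profile a `concentration_profile` with a urine series.
#' @param cutoff h; must lie within the simulated span.
#' @return Percent of the administered dose.
#' @export
fraction_excreted <- function(profile, cutoff) {
  if (is.null(profile$urine)) stop("profile has no urine series")
  if (cutoff > max(profile$time) + 1e-9)
    stop(sprintf("cutoff %.1f h beyond simulated span (%.1f h)", cutoff,
                 max(profile$time)))
  u <- stats::approx(profile$time, profile$urine, xout = cutoff)$y
  100 * u / attr(profile, "dose")
}

#' Non-compartmental analysis of one profile
#'
#' For single-dose profiles: AUC to infinity, terminal half-life,
#' clearance `dose/AUC_inf`, moment Vss, and fe at the requested cut-offs
#' plus `fe_inf = 100 * CL_R * AUC_inf / dose`. For repeated-dose profiles
#' the AUC is the final-interval `AUC_tau` and clearance is
#' `dose_per_interval / AUC_tau`.
#'
#' @param profile a `concentration_profile`.
#' @param fe_cutoffs h; cut-offs beyond the simulated span give `NA`.
#' @return One-row data.frame of class `pk_parameters`.
#' @export
nca <- function(profile, fe_cutoffs = c(12, 24)) {
  dose <- attr(profile, "dose")
  multi <- length(attr(profile, "dose_times")) > 1
  lz <- lambda_z(profile)
  hl <- log(2) / lz$lambda_z
  if (multi) {
    auc_tau <- auc(profile, "last_interval")
    auc_inf <- NA_real_
    cl <- attr(profile, "amount_per_dose") / auc_tau
    vss <- NA_real_
  } else {
    auc_inf <- as.numeric(auc(profile, "to_infinity"))
    auc_tau <- NA_real_
    cl <- dose / auc_inf
    aumc <- .aumc_trap(profile$time, profile$conc) +
      utils::tail(profile$conc, 1) *
        (utils::tail(profile$time, 1) / lz$lambda_z + 1 / lz$lambda_z^2)
    vss <- cl * aumc / auc_inf / attr(profile, "weight")
  }
  fe <- vapply(fe_cutoffs, function(ct) {
    if (ct > max(profile$time) + 1e-9) NA_real_
    else fraction_excreted(profile, ct)
  }, numeric(1))
  names(fe) <- if (length(fe_cutoffs)) paste0("fe_", fe_cutoffs, "h")
               else character(0)
  cl_r <- attr(profile, "cl_renal")
  fe_inf <- if (multi || is.null(cl_r)) NA_real_
            else 100 * cl_r * auc_inf / dose
  out <- data.frame(auc_inf = auc_inf, auc_tau = auc_tau, half_life = hl,
                    clearance = cl, vss = vss, t(fe), fe_inf = fe_inf,
                    lambda_z = lz$lambda_z, lambda_z_n_points = lz$n_points,
                    lambda_z_r2 = lz$r2_adj)
  class(out) <- c("pk_parameters", "data.frame")
  out
}

#' Summarize PK parameters across subjects
#'
#' Arithmetic mean, SD, and 5th/95th percentiles per parameter; optionally
#' the pointwise mean and 5th/95th percentile concentration bands across
#' profiles simulated on a common time grid.
#'
#' @param params data.frame of per-subject PK parameters (rows = subjects).
#' @param profiles optional list of `concentration_profile`s on one grid.
#' @return List of class `trial_summary`: `parameters` (data.frame with
#'   mean/sd/p5/p95 per parameter), `n`, and if profiles were given,
#'   `bands` (time, mean, p5, p95).
#' @export
summarize_pk <- function(params, profiles = NULL) {
  if (nrow(params) < 2) stop("need at least 2 subjects")
  num <- params[vapply(params, is.numeric, logical(1))]
  stats_tab <- data.frame(
    parameter = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
    p5 = vapply(num, function(x)
      unname(stats::quantile(x, 0.05, na.rm = TRUE)), numeric(1)),
    p95 = vapply(num, function(x)
      unname(stats::quantile(x, 0.95, na.rm = TRUE)), numeric(1)),
    row.names = NULL
  )
  out <- list(parameters = stats_tab, n = nrow(params))
  if (!is.null(profiles)) {
    cm <- sapply(profiles, function(p) p$conc)
    out$bands <- data.frame(
      time = profiles[[1]]$time,
      mean = rowMeans(cm),
      p5 = apply(cm, 1, stats::quantile, 0.05),
      p95 = apply(cm, 1, stats::quantile, 0.95)
    )
  }
  class(out) <- "trial_summary"
  out
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("PK summary over %d subjects\n", x$n))
  show <- x$parameters[x$parameters$parameter %in%
                         c("auc_inf", "auc_tau", "half_life", "clearance",
                           "vss", "fe_12h", "fe_24h", "fe_inf"), ]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}
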