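# Whole-body perfusion-limited PBPK engine.
#
# Compartments: venous blood, arterial blood, lung, and eleven systemic
# tissues (gut, spleen and pancreas drain into the liver). The system is
# linear and time-invariant within each dosing segment, so it is solved
# exactly by eigendecomposition of the rate matrix; cumulative urine and
# bile are the analytic integrals of the venous and liver states. Renal
# elimination is taken from venous plasma (CL_R * C_plasma), which makes
# fe = CL_R * AUC / Dose an identity; biliary elimination is a well-stirred
# liver acting on the unbound liver water concentration.

.splanchnic <- c("gut", "spleen", "pancreas")
.nonsplanchnic <- c("adipose", "bone", "brain", "heart", "kidney",
                    "muscle", "skin")
.state_names <- c("venous", "arterial", "lung", .nonsplanchnic, .splanchnic,
                  "liver")

#' GFR-proportional renal clearance
#'
#' Passive filtration: an individual's renal clearance is the healthy
#' reference value scaled by the ratio of their CLcr to the reference CLcr.
#'
#' @param cl_renal_ref L/h at `gfr_ref`.
#' @param gfr individual CLcr, mL/min/1.73 m^2 (>= 0).
#' @param gfr_ref reference CLcr (> 0).
#' @return L/h; zero iff `gfr` is zero.
#' @export
scale_renal_clearance <- function(cl_renal_ref, gfr,
                                  gfr_ref = gfr_reference()) {
  stopifnot(all(gfr >= 0), gfr_ref > 0)
  cl_renal_ref * gfr / gfr_ref
}

#' Whole-liver intrinsic biliary clearance
#'
#' Scales the per-hepatocyte intrinsic clearance to the whole organ:
#' `clint * hpgl * liver_mass * 60e-6` L/h at the median, with lognormal
#' inter-individual variability of the stated CV applied through a
#' standard-normal deviate `z` (so cohorts are reproducible).
#'
#' @param clint uL/min per 1e6 hepatocytes.
#' @param hpgl 1e6 hepatocytes per g liver.
#' @param liver_mass g.
#' @param cv percent inter-individual coefficient of variation.
#' @param z standard-normal deviate (0 gives the median individual).
#' @return Unbound intrinsic clearance of the whole liver, L/h.
#' @export
scale_biliary_clearance <- function(clint, hpgl, liver_mass, cv = 0, z = 0) {
  stopifnot(clint >= 0, hpgl >= 0, liver_mass >= 0, cv >= 0)
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  clint * hpgl * liver_mass * 60e-6 * exp(sdlog * z)
}

#' Intravenous dose regimen
#'
#' @param amount mg per administration (> 0); alternatively give
#'   `mg_per_kg` for weight-based dosing.
#' @param kind `"bolus"` or `"infusion"`.
#' @param infusion_duration h (0 for a bolus).
#' @param interval dosing interval, h (`NA` for a single dose).
#' @param n_doses number of administrations (>= 1).
#' @param mg_per_kg optional weight-based dose; resolved against the
#'   individual's weight at simulation time.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(amount = NULL, kind = c("bolus", "infusion"),
                         infusion_duration = 0, interval = NA_real_,
                         n_doses = 1L, mg_per_kg = NULL) {
  kind <- match.arg(kind)
  if (is.null(amount) && is.null(mg_per_kg))
    stop("either amount or mg_per_kg must be given")
  if (!is.null(amount)) stopifnot(amount > 0)
  if (!is.null(mg_per_kg)) stopifnot(mg_per_kg > 0)
  stopifnot(infusion_duration >= 0, n_doses >= 1)
  if (kind == "infusion" && infusion_duration <= 0)
    stop("an infusion needs a positive infusion_duration")
  if (n_doses > 1 && !is.finite(interval))
    stop("multiple doses need a finite interval")
  structure(list(amount = amount, kind = kind,
                 infusion_duration = infusion_duration,
                 interval = interval, n_doses = as.integer(n_doses),
                 mg_per_kg = mg_per_kg),
            class = "dose_regimen")
}

#' Build the per-individual PBPK model
#'
#' Assembles the compartmental rate matrix from the individual's physiology
#' (organ volumes and flows), the drug's predicted tissue partition
#' coefficients, the GFR-scaled renal clearance and the scaled biliary
#' intrinsic clearance.
#'
#' @param individual one-row data.frame as from [sample_population()].
#' @param drug a [drug_parameters()] object.
#' @param kps optional named Kp vector; predicted from the packaged tissue
#'   composition if omitted. Must cover the model's tissue set.
#' @param gfr_ref reference CLcr for renal-clearance scaling.
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(individual, drug = ceftazidime(), kps = NULL,
                       gfr_ref = gfr_reference()) {
  if (is.null(kps))
    kps <- predict_kp(drug, hematocrit = individual$hematocrit)
  tissues <- c(.nonsplanchnic, .splanchnic, "liver", "lung")
  missing <- setdiff(tissues, names(kps))
  if (length(missing))
    stop("kps is missing tissues: ", paste(missing, collapse = ", "))
  phys <- physiology(individual, gfr_ref = gfr_ref)
  bp <- drug$blood_to_plasma
  fu <- drug$fu_plasma
  cl_renal <- scale_renal_clearance(drug$cl_renal_ref, individual$gfr,
                                    gfr_ref)
  z <- if ("z_biliary" %in% names(individual)) individual$z_biliary else 0
  clint_whole <- scale_biliary_clearance(drug$clint_biliary,
                                         individual$hpgl, phys$liver_mass,
                                         drug$clint_biliary_cv, z)
  v <- phys$volumes
  q <- phys$flows
  co <- phys$cardiac_output
  v_ven <- phys$v_venous
  v_art <- phys$v_arterial
  n <- length(.state_names)
  A <- matrix(0, n, n, dimnames = list(.state_names, .state_names))
  A["arterial", "arterial"] <- -co / v_art
  A["lung", "venous"] <- co / v_ven
  A["venous", "venous"] <- -(co + cl_renal / bp) / v_ven
  k_lung <- co * bp / (kps[["lung"]] * v[["lung"]])
  A["arterial", "lung"] <- k_lung
  A["lung", "lung"] <- -k_lung
  for (t in .nonsplanchnic) {
    k <- q[[t]] * bp / (kps[[t]] * v[[t]])
    A[t, "arterial"] <- q[[t]] / v_art
    A[t, t] <- -k
    A["venous", t] <- k
  }
  for (s in .splanchnic) {
    k <- q[[s]] * bp / (kps[[s]] * v[[s]])
    A[s, "arterial"] <- q[[s]] / v_art
    A[s, s] <- -k
    A["liver", s] <- k
  }
  q_hv <- q[["hepatic_artery"]] + sum(q[.splanchnic])
  A["liver", "arterial"] <- q[["hepatic_artery"]] / v_art
  k_liv_out <- q_hv * bp / (kps[["liver"]] * v[["liver"]])
  k_bil <- clint_whole * fu / (kps[["liver"]] * v[["liver"]])
  A["liver", "liver"] <- -(k_liv_out + k_bil)
  A["venous", "liver"] <- k_liv_out
  structure(list(
    individual = individual, drug = drug, kps = kps, physiology = phys,
    A = A, cl_renal = cl_renal, clint_whole = clint_whole,
    urine_coef = (cl_renal / bp) / v_ven, bile_coef = k_bil,
    v_venous = v_ven, blood_to_plasma = bp, gfr_ref = gfr_ref
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  ind <- x$individual
  cat(sprintf("PBPK model: %s, %.0f y, %.1f kg, CLcr %.1f mL/min/1.73m2 (%s)\n",
              ind$sex, ind$age, ind$weight, ind$gfr, ind$renal_class))
  cat(sprintf("  CL_R %.2f L/h; whole-liver biliary CLint %.3f L/h\n",
              x$cl_renal, x$clint_whole))
  cat(sprintf("  %d compartments; cardiac output %.0f L/h\n",
              nrow(x$A), x$physiology$cardiac_output))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  c(cl_renal = object$cl_renal, clint_biliary_whole = object$clint_whole,
    gfr = object$individual$gfr, weight = object$individual$weight,
    object$kps)
}

# exp-based phi functions with series fallback near lambda = 0
.phi1 <- function(lam, dt) {
  out <- ifelse(abs(lam * dt) < 1e-10, dt, (exp(lam * dt) - 1) / lam)
  out
}
.phi2 <- function(lam, dt) {
  ifelse(abs(lam * dt) < 1e-8, dt^2 / 2,
         (exp(lam * dt) - 1 - lam * dt) / lam^2)
}

# Exact piecewise-constant-input solution of dx/dt = A x + b(t), doses and
# infusions entering the venous compartment. Returns states and running
# integrals of the states at the requested times.
.solve_linear <- function(A, doses, infusions, times) {
  n <- nrow(A)
  eg <- eigen(A)
  V <- eg$vectors
  lam <- eg$values
  Vi <- solve(V)
  bps <- sort(unique(c(0, doses$time, infusions$start, infusions$end,
                       times)))
  bps <- bps[bps <= max(times) + 1e-12]
  x <- rep(0 + 0i, n)
  cum <- rep(0 + 0i, n)
  states <- matrix(0, length(times), n)
  integrals <- matrix(0, length(times), n)
  e_ven <- rep(0, n); e_ven[1] <- 1
  record <- function(tq, xt, ct) {
    idx <- which(abs(times - tq) < 1e-9)
    if (length(idx)) {
      states[idx, ] <<- matrix(Re(xt), length(idx), n, byrow = TRUE)
      integrals[idx, ] <<- matrix(Re(ct), length(idx), n, byrow = TRUE)
    }
  }
  for (k in seq_along(bps)) {
    t0 <- bps[k]
    bol <- doses$amount[abs(doses$time - t0) < 1e-9]
    if (length(bol)) x <- x + sum(bol) * e_ven
    record(t0, x, cum)
    if (k == length(bps)) break
    t1 <- bps[k + 1]
    rate <- 0
    if (nrow(infusions))
      rate <- sum(infusions$rate[infusions$start <= t0 + 1e-9 &
                                 infusions$end >= t1 - 1e-9])
    b <- rate * e_ven
    w0 <- Vi %*% x
    bw <- Vi %*% b
    inner <- times[times > t0 + 1e-9 & times < t1 - 1e-9]
    for (tq in inner) {
      dt <- tq - t0
      xt <- V %*% (w0 * exp(lam * dt) + bw * .phi1(lam, dt))
      ct <- cum + V %*% (w0 * .phi1(lam, dt) + bw * .phi2(lam, dt))
      record(tq, xt, ct)
    }
    dt <- t1 - t0
    cum <- cum + V %*% (w0 * .phi1(lam, dt) + bw * .phi2(lam, dt))
    x <- V %*% (w0 * exp(lam * dt) + bw * .phi1(lam, dt))
  }
  list(states = states, integrals = integrals)
}

.default_horizon <- function(renal_class) {
  switch(renal_class, normal = 24, mild = 36, moderate = 48, severe = 72,
         anuric = 240, 24)
}

.base_grid <- c(0, 0.01, 0.02, 0.033, 0.05, 0.075, 0.1, 0.15, 0.25, 0.375,
                0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 12, 16,
                20, 24, 30, 36, 42, 48, 60, 72, 96, 120, 144, 168, 204, 240)

#' Default sampling times for a profile
#'
#' Log-spaced early samples after the (last) dose plus a terminal stretch to
#' the horizon; always includes 12 h and 24 h when the horizon allows, so
#' the urinary-excretion cut-offs are observed directly.
#'
#' @param horizon h after the last dose.
#' @param regimen a [dose_regimen()]; for repeated dosing the grid covers
#'   each interval plus the terminal stretch.
#' @return Numeric vector of times (h).
#' @export
default_times <- function(horizon, regimen = dose_regimen(amount = 1)) {
  grid <- .base_grid[.base_grid <= horizon]
  if (regimen$n_doses == 1) return(grid)
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval
  intra <- .base_grid[.base_grid < regimen$interval]
  sort(unique(c(outer(intra, dose_times, `+`),
                dose_times + regimen$interval - 1e-3,
                max(dose_times) + grid)))
}

#' Simulate a concentration profile
#'
#' Exact solution of the individual's linear PBPK system under the dosing
#' regimen. Returns venous plasma concentration and cumulative amounts
#' excreted in urine and bile.
#'
#' @param object a [pbpk_model()].
#' @param nsim unused (the solution is deterministic given the model).
#' @param seed unused.
#' @param regimen a [dose_regimen()].
#' @param times sampling times (h); defaults to a renal-class-appropriate
#'   grid.
#' @param ... ignored.
#' @return A data.frame of class `concentration_profile` with columns
#'   `time`, `conc` (mg/L, venous plasma), `urine` and `bile` (cumulative
#'   mg), plus attributes `dose` (total mg), `dose_times`, `tau`,
#'   `cl_renal`, `weight`, `amount_per_dose`.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                regimen = dose_regimen(amount = 2000),
                                times = NULL, ...) {
  amount <- regimen$amount
  if (is.null(amount))
    amount <- regimen$mg_per_kg * object$individual$weight
  dose_times <- (seq_len(regimen$n_doses) - 1) *
    ifelse(regimen$n_doses > 1, regimen$interval, 0)
  if (is.null(times)) {
    horizon <- .default_horizon(object$individual$renal_class)
    times <- default_times(horizon, regimen)
  }
  if (regimen$kind == "bolus") {
    doses <- data.frame(time = dose_times, amount = amount)
    infusions <- data.frame(start = numeric(0), end = numeric(0),
                            rate = numeric(0))
  } else {
    doses <- data.frame(time = numeric(0), amount = numeric(0))
    infusions <- data.frame(start = dose_times,
                            end = dose_times + regimen$infusion_duration,
                            rate = amount / regimen$infusion_duration)
  }
  sol <- .solve_linear(object$A, doses, infusions, times)
  conc <- sol$states[, 1] / (object$v_venous * object$blood_to_plasma)
  urine <- object$urine_coef * sol$integrals[, 1]
  bile <- object$bile_coef * sol$integrals[, which(.state_names == "liver")]
  out <- data.frame(time = times, conc = pmax(conc, 0), urine = urine,
                    bile = bile)
  structure(out,
            class = c("concentration_profile", "data.frame"),
            dose = amount * regimen$n_doses,
            amount_per_dose = amount,
            dose_times = dose_times,
            tau = regimen$interval,
            cl_renal = object$cl_renal,
            weight = object$individual$weight,
            body_amount = rowSums(sol$states))
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d samples over %.1f h, dose %.0f mg\n",
              nrow(x), max(x$time), attr(x, "dose")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, log = "y", ...) {
  pos <- x$conc > 0
  graphics::plot(x$time[pos], x$conc[pos], type = "l", log = log,
                 xlab = "Time (h)", ylab = "Plasma concentration (mg/L)",
                 ...)
  invisible(x)
}

#' Predicted plasma concentrations at given times
#'
#' @param object a [pbpk_model()].
#' @param times h.
#' @param regimen a [dose_regimen()].
#' @param ... ignored.
#' @return Numeric vector of venous plasma concentrations (mg/L).
#' @export
predict.pbpk_model <- function(object, times,
                               regimen = dose_regimen(amount = 2000), ...) {
  simulate(object, regimen = regimen, times = times)$conc
}
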