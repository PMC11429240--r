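# Synthetic closed-form profiles used as independent NCA oracles.

# one-compartment IV bolus: C(t) = (dose/V) exp(-(CL/V) t), with a urine
# series from a renal clearance equal to cl_r
mono_profile <- function(dose = 1000, cl = 7, v = 15, cl_r = NULL,
                         times = default_times(24), weight = 70) {
  k <- cl / v
  conc <- dose / v * exp(-k * times)
  if (is.null(cl_r)) cl_r <- cl
  urine <- cl_r / cl * dose * (1 - exp(-k * times))
  structure(data.frame(time = times, conc = conc, urine = urine,
                       bile = 0 * times),
            class = c("concentration_profile", "data.frame"),
            dose = dose, amount_per_dose = dose, dose_times = 0,
            tau = NA_real_, cl_renal = cl_r, weight = weight)
}

quick_individual <- function(age = 30, sex = "male", gfr = NULL) {
  ind <- reference_adult()
  ind$age <- age
  ind$sex <- sex
  if (!is.null(gfr)) {
    ind$gfr <- gfr
    ind$renal_class <- classify_renal(gfr)
  }
  ind
}
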