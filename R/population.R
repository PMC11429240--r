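# Virtual-population generator: demographics, renal function via
# Cockcroft-Gault, renal-impairment staging, and age/sex-scaled physiology.

# Demographic models (config-exposed through population_defaults()):
# weight lognormal, height normal with a mild post-50 decline, serum
# creatinine lognormal with sex-specific medians, flat to age 40 then
# rising slowly (muscle-mass loss largely offsets the GFR decline, so the
# creatinine of healthy aging adults is nearly constant).
.pop_defaults <- list(
  weight_median   = c(male = 78, female = 67),    # kg
  weight_cv       = 0.15,
  height_mean     = c(male = 176, female = 163),  # cm
  height_sd       = 7,
  height_decline  = 0.05,                         # cm per year after 50
  scr_median      = c(male = 80, female = 65),    # umol/L at age <= 40
  scr_slope       = 0.004,                        # relative rise per year > 40
  scr_cv          = 0.15,
  hematocrit      = 0.45,
  hpgl            = 99,        # 1e6 hepatocytes per g liver
  cardiac_index   = 180,       # L/h per m^2 (3 L/min/m^2)
  co_decline      = 0.008,     # fractional decline per year after 25
  liver_ref_mass  = 1600,      # g at BSA 1.86 m^2
  liver_ref_bsa   = 1.86,
  liver_density   = 1.05,      # g/mL
  blood_fraction  = c(male = 0.074, female = 0.068),
  band_anchor_age = 40         # age at which RI stage bands are sampled
)

#' Population-model defaults
#'
#' The parametric demographic and physiological models behind the virtual
#' population: weight/height/serum-creatinine distributions, hematocrit,
#' hepatocellularity, cardiac index and its age decline, liver scaling, and
#' the reference age at which renal-impairment stages are anchored.
#'
#' @return Named list of constants.
#' @export
population_defaults <- function() .pop_defaults

# Organ volumes as fractions of body weight (L/kg, density ~1), by sex;
# liver is scaled by BSA separately. The unassigned remainder of body mass
# (connective tissue etc.) carries negligible drug for a polar acid.
.volume_fractions <- list(
  male = c(adipose = 0.210, bone = 0.086, brain = 0.020, gut = 0.017,
           heart = 0.0047, kidney = 0.0044, muscle = 0.400, skin = 0.037,
           spleen = 0.0026, pancreas = 0.0017, lung = 0.0076),
  female = c(adipose = 0.320, bone = 0.078, brain = 0.021, gut = 0.017,
             heart = 0.0044, kidney = 0.0043, muscle = 0.290, skin = 0.036,
             spleen = 0.0026, pancreas = 0.0017, lung = 0.0076)
)

# Blood-flow fractions of cardiac output; sum to 1 with muscle absorbing
# the non-modelled tissues' return flow. Kidney flow is additionally scaled
# with renal function (reduced renal perfusion), the deficit rerouted to
# muscle so venous/arterial nodes still balance.
.flow_fractions <- c(adipose = 0.050, bone = 0.050, brain = 0.120,
                     gut = 0.150, heart = 0.040, kidney = 0.175,
                     hepatic_artery = 0.065, muscle = 0.260, skin = 0.050,
                     spleen = 0.030, pancreas = 0.010)

#' Body surface area (DuBois-DuBois)
#'
#' @param weight kg (> 0).
#' @param height cm (> 0).
#' @return BSA in m^2: `0.007184 * W^0.425 * H^0.725`.
#' @export
bsa_dubois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  0.007184 * weight^0.425 * height^0.725
}

#' Cockcroft-Gault creatinine clearance, BSA-normalized
#'
#' `GFR = ((140 - age) * WT) / (72 * Scr/88.42) * (1.73/BSA) * (0.82 if
#' female)`, with serum creatinine in umol/L (the 88.42 factor converts to
#' mg/dL). The female factor follows the source convention used throughout
#' this package (0.82).
#'
#' @param age years, in \[18, 140).
#' @param weight kg.
#' @param scr serum creatinine, umol/L (> 0).
#' @param bsa body surface area, m^2.
#' @param sex `"male"` or `"female"` (vectorized).
#' @return CLcr in mL/min/1.73 m^2.
#' @export
cockcroft_gault_gfr <- function(age, weight, scr, bsa, sex) {
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  stopifnot(all(age >= 18))
  over <- age >= 140
  if (any(over)) {
    warning("age >= 140: GFR clamped to 0")
    age <- pmin(age, 140)
  }
  g <- ((140 - age) * weight) / (72 * scr / 88.42) * (1.73 / bsa)
  g <- g * ifelse(sex == "female", 0.82, 1)
  pmax(g, 0)
}

#' Serum creatinine consistent with a target creatinine clearance
#'
#' Inverse of [cockcroft_gault_gfr()]: the creatinine an individual must
#' have for their Cockcroft-Gault CLcr to equal `target_gfr`.
#'
#' @param target_gfr mL/min/1.73 m^2 (> 0).
#' @inheritParams cockcroft_gault_gfr
#' @return Serum creatinine in umol/L.
#' @export
scr_from_gfr <- function(target_gfr, age, weight, bsa, sex) {
  if (any(target_gfr <= 0))
    stop("target_gfr must be positive; use the anuric pathway for GFR 0")
  f <- ifelse(sex == "female", 0.82, 1)
  ((140 - age) * weight) * 88.42 * (1.73 / bsa) * f / (72 * target_gfr)
}

# CLcr bands (mL/min/1.73 m^2); boundary belongs to the milder class.
.ri_bands <- list(mild = c(60, 90), moderate = c(30, 60), severe = c(15, 30))

#' Renal-impairment class from CLcr
#'
#' Normal >= 90, mild 60-90, moderate 30-60, severe 15-30 (values below 15
#' but above 0 are treated as severe); a boundary value belongs to the
#' milder class; CLcr 0 is anuric.
#'
#' @param gfr CLcr in mL/min/1.73 m^2 (>= 0, vectorized).
#' @return Character vector of classes.
#' @export
classify_renal <- function(gfr) {
  stopifnot(all(gfr >= 0))
  ifelse(gfr == 0, "anuric",
  ifelse(gfr >= 90, "normal",
  ifelse(gfr >= 60, "mild",
  ifelse(gfr >= 30, "moderate", "severe"))))
}

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param age_range length-2 numeric, years (adults only, min >= 18).
#' @param proportion_female fraction in \[0, 1\].
#' @param renal renal-function model: `"normal"` (normal-for-age: creatinine
#'   sampled, CLcr computed), one of `"mild"`, `"moderate"`, `"severe"`
#'   (stage-band sampling), `"anuric"`, or a list
#'   `list(clcr_range = c(lo, hi), normalized = TRUE/FALSE)` reproducing a
#'   study's reported CLcr range (`normalized = FALSE` means mL/min, to be
#'   BSA-normalized with the sampled individual's BSA).
#' @param seed master seed for the cohort.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n, age_range, proportion_female = 0.5,
                            renal = "normal", seed = 1L) {
  stopifnot(n >= 1, length(age_range) == 2, age_range[1] >= 18,
            age_range[1] <= age_range[2],
            proportion_female >= 0, proportion_female <= 1)
  if (is.character(renal))
    renal <- match.arg(renal, c("normal", "mild", "moderate", "severe",
                                "anuric"))
  else stopifnot(is.list(renal), length(renal$clcr_range) == 2)
  structure(list(n = as.integer(n), age_range = age_range,
                 proportion_female = proportion_female, renal = renal,
                 seed = as.integer(seed)),
            class = "population_spec")
}

.scr_median <- function(age, sex) {
  d <- .pop_defaults
  d$scr_median[sex] * (1 + d$scr_slope * pmax(0, age - 40))
}

# lognormal with given median and CV
.rlnorm_med <- function(n, median, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  median * exp(stats::rnorm(n, 0, sdlog))
}

#' Sample a virtual population
#'
#' Draws `n` virtual individuals per the specification. The realized female
#' count is exactly `round(n * proportion_female)`. Individuals are grouped
#' into trials of 10; each trial's draws use a child seed derived from the
#' master seed, so any prefix of trials is reproducible.
#'
#' For `renal = "normal"` creatinine is sampled and CLcr computed. For an
#' explicit stage, disease severity is sampled as a CLcr uniform in the
#' stage band at the anchor age (40 y), the implied creatinine is carried to
#' the individual's age through Cockcroft-Gault, and the resulting CLcr is
#' truncated into the band (stage membership is defined by measured CLcr);
#' this reproduces the within-stage decline of renal function with age.
#'
#' @param spec a [population_spec()].
#' @return A data.frame, one row per individual: `id`, `trial`, `age`,
#'   `sex`, `weight`, `height`, `bsa`, `serum_creatinine`, `gfr`,
#'   `renal_class`, `hematocrit`, `hpgl`, `z_biliary` (standard-normal
#'   deviate used for the inter-individual biliary clearance variability).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  d <- .pop_defaults
  n <- spec$n
  n_f <- round(n * spec$proportion_female)
  set.seed(spec$seed)
  sex <- sample(rep(c("female", "male"), c(n_f, n - n_f)))
  trial <- rep(seq_len(ceiling(n / 10)), each = 10)[seq_len(n)]
  out <- vector("list", max(trial))
  for (tr in unique(trial)) {
    idx <- which(trial == tr)
    m <- length(idx)
    set.seed((spec$seed + 7919L * tr) %% .Machine$integer.max)
    sx <- sex[idx]
    age <- stats::runif(m, spec$age_range[1], spec$age_range[2])
    weight <- .rlnorm_med(m, d$weight_median[sx], d$weight_cv)
    height <- stats::rnorm(m, d$height_mean[sx] -
                              d$height_decline * pmax(0, age - 50),
                           d$height_sd)
    bsa <- bsa_dubois(weight, height)
    z_bil <- stats::rnorm(m)
    if (identical(spec$renal, "normal")) {
      scr <- .rlnorm_med(m, .scr_median(age, sx), d$scr_cv)
      gfr <- cockcroft_gault_gfr(age, weight, scr, bsa, sx)
    } else if (identical(spec$renal, "anuric")) {
      scr <- rep(NA_real_, m)
      gfr <- rep(0, m)
    } else if (is.character(spec$renal)) {
      band <- .ri_bands[[spec$renal]]
      g_anchor <- stats::runif(m, band[1], band[2])
      g <- g_anchor * (140 - age) / (140 - d$band_anchor_age)
      gfr <- pmin(pmax(g, band[1]), band[2] - 1e-9)
      scr <- scr_from_gfr(gfr, age, weight, bsa, sx)
    } else {
      g <- stats::runif(m, spec$renal$clcr_range[1], spec$renal$clcr_range[2])
      if (!isTRUE(spec$renal$normalized)) g <- g * 1.73 / bsa
      gfr <- g
      scr <- scr_from_gfr(gfr, age, weight, bsa, sx)
    }
    out[[tr]] <- data.frame(
      id = idx, trial = tr, age = age, sex = sx, weight = weight,
      height = height, bsa = bsa, serum_creatinine = scr, gfr = gfr,
      renal_class = classify_renal(gfr), hematocrit = d$hematocrit,
      hpgl = d$hpgl, z_biliary = z_bil, stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Sample a single virtual individual
#'
#' @param spec a [population_spec()]; its `n` is ignored.
#' @return A one-row data.frame as in [sample_population()].
#' @export
sample_individual <- function(spec) {
  spec$n <- 1L
  sample_population(spec)
}

#' A reference healthy adult
#'
#' Male, 30 years, at the demographic medians; used for mechanistic Vss and
#' as the anchor for clearance scaling.
#'
#' @return One-row individual data.frame.
#' @export
reference_adult <- function() {
  d <- .pop_defaults
  weight <- unname(d$weight_median["male"])
  height <- unname(d$height_mean["male"])
  bsa <- bsa_dubois(weight, height)
  scr <- unname(.scr_median(30, "male"))
  data.frame(id = 1L, trial = 1L, age = 30, sex = "male", weight = weight,
             height = height, bsa = bsa, serum_creatinine = scr,
             gfr = cockcroft_gault_gfr(30, weight, scr, bsa, "male"),
             renal_class = "normal", hematocrit = d$hematocrit,
             hpgl = d$hpgl, z_biliary = 0, stringsAsFactors = FALSE)
}

#' Age- and sex-scaled physiology of an individual
#'
#' Organ volumes (fractions of body weight; liver scaled by BSA), blood
#' flows (fractions of cardiac output, kidney perfusion scaled with renal
#' function), cardiac output from the cardiac index with its age decline,
#' and blood/plasma volumes.
#'
#' @param individual one-row data.frame as from [sample_population()].
#' @param gfr_ref reference CLcr attached to the healthy-adult renal
#'   clearance (mL/min/1.73 m^2).
#' @return List with `volumes` (named, L, includes liver and lung),
#'   `flows` (named, L/h, systemic tissues), `cardiac_output` (L/h),
#'   `liver_mass` (g), `blood_volume`, `plasma_volume`,
#'   `erythrocyte_volume`, `v_venous`, `v_arterial` (L).
#' @export
physiology <- function(individual, gfr_ref = gfr_reference()) {
  d <- .pop_defaults
  sx <- individual$sex
  bw <- individual$weight
  bsa <- individual$bsa
  vols <- .volume_fractions[[sx]] * bw
  liver_mass <- d$liver_ref_mass * bsa / d$liver_ref_bsa
  vols["liver"] <- liver_mass / (d$liver_density * 1000)  # g / (g/L) -> L
  co <- d$cardiac_index * bsa *
    max(0.5, 1 - d$co_decline * max(0, individual$age - 25))
  ff <- .flow_fractions
  renal_scale <- max(0.1, individual$gfr / gfr_ref)
  deficit <- ff["kidney"] * (1 - min(renal_scale, 1))
  ff["kidney"] <- ff["kidney"] * min(renal_scale, 1)
  ff["muscle"] <- ff["muscle"] + deficit
  flows <- ff * co
  blood <- unname(d$blood_fraction[sx]) * bw
  list(volumes = vols, flows = flows, cardiac_output = co,
       liver_mass = liver_mass, blood_volume = blood,
       plasma_volume = blood * (1 - individual$hematocrit),
       erythrocyte_volume = blood * individual$hematocrit,
       v_venous = 0.66 * blood, v_arterial = 0.34 * blood)
}

# Calibrated reference CLcr: the CLcr at which an individual's renal
# clearance equals the drug record's healthy-adult value. Fixed once so the
# simulated 25-35 y healthy cohort reproduces the reference mean total
# clearance; config-exposed via the gfr_ref arguments downstream.
.gfr_ref <- 106

#' Reference CLcr for renal-clearance scaling
#'
#' @return mL/min/1.73 m^2.
#' @export
gfr_reference <- function() .gfr_ref
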