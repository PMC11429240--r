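# Virtual-trial engine: the packaged clinical study library (one YAML per
# study, arms mirroring the published designs), 20 trials x 10 subjects per
# arm, pooled and per-trial summaries, and predicted-vs-observed tables
# with the 2-fold acceptance verdict.

.derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(master) * 1009 + h) %% 2147483629)
}

#' A single virtual-trial design (one study arm)
#'
#' @param study study identifier.
#' @param code arm/trial code.
#' @param age_range years.
#' @param proportion_female fraction.
#' @param renal renal model as in [population_spec()].
#' @param regimen a [dose_regimen()].
#' @param fe_cutoff h for the reported urinary-excretion fraction.
#' @param horizon h of sampling after the last dose (default by renal
#'   class).
#' @param n total subjects (default 200 = 20 trials of 10).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(study, code, age_range, proportion_female, renal,
                         regimen, fe_cutoff = 24, horizon = NULL, n = 200) {
  if (is.null(horizon)) {
    cls <- if (is.character(renal)) renal else
      classify_renal(mean(renal$clcr_range))
    horizon <- .default_horizon(cls)
  }
  structure(list(study = study, code = code, age_range = age_range,
                 proportion_female = proportion_female, renal = renal,
                 regimen = regimen, fe_cutoff = fe_cutoff,
                 horizon = horizon, n = n),
            class = "trial_design")
}

.parse_renal <- function(x) {
  if (is.character(x)) return(x)
  list(clcr_range = as.numeric(x$clcr_range),
       normalized = isTRUE(x$normalized))
}

#' The packaged clinical-study library
#'
#' Reads every study YAML under `inst/extdata/studies` and expands it into
#' one [trial_design()] per arm, keyed `"<study>.<code>"`.
#'
#' @param path directory of study YAML files.
#' @return Named list of `trial_design` objects.
#' @export
study_library <- function(path = system.file("extdata", "studies",
                                             package = "ceftazpbpk",
                                             mustWork = TRUE)) {
  files <- list.files(path, pattern = "\\.yaml$", full.names = TRUE)
  designs <- list()
  for (f in files) {
    st <- yaml::read_yaml(f)
    base_reg <- st$regimen
    for (arm in st$arms) {
      reg <- if (!is.null(arm$regimen)) arm$regimen else base_reg
      regimen <- dose_regimen(
        amount = reg$amount, kind = reg$kind,
        infusion_duration = if (is.null(reg$infusion_duration)) 0
                            else reg$infusion_duration,
        interval = if (is.null(reg$interval)) NA_real_ else reg$interval,
        n_doses = if (is.null(reg$n_doses)) 1L else reg$n_doses,
        mg_per_kg = reg$mg_per_kg)
      pf <- if (!is.null(arm$proportion_female)) arm$proportion_female
            else if (!is.null(st$proportion_female)) st$proportion_female
            else 0.5
      d <- trial_design(
        study = st$study, code = arm$code,
        age_range = as.numeric(arm$age_range),
        proportion_female = pf,
        renal = .parse_renal(arm$renal),
        regimen = regimen,
        fe_cutoff = if (is.null(st$fe_cutoff)) 24 else st$fe_cutoff,
        horizon = arm$horizon)
      designs[[paste(st$study, arm$code, sep = ".")]] <- d
    }
  }
  designs
}

#' Run a study design as virtual trials
#'
#' Samples the arm's population (20 trials of 10 subjects by default),
#' simulates every subject's profile, performs NCA, and pools the results.
#'
#' @param design a [trial_design()], or a `"<study>.<code>"` key into
#'   [study_library()].
#' @param master_seed integer master seed; each arm derives a child seed
#'   from it, so studies are independent and reproducible.
#' @param drug a [drug_parameters()] object.
#' @param gfr_ref reference CLcr for clearance scaling.
#' @return Object of class `virtual_study`: the per-subject parameters
#'   (`parameters`, with `trial`), the pooled `summary` (a
#'   [summarize_pk()] result with concentration bands), per-trial means
#'   (`trial_means`), and the sampled cohort (`population`).
#' @export
run_virtual_study <- function(design, master_seed = 1L,
                              drug = ceftazidime(),
                              gfr_ref = gfr_reference()) {
  if (is.character(design)) {
    lib <- study_library()
    if (!design %in% names(lib))
      stop("unknown study key: ", design)
    design <- lib[[design]]
  }
  spec <- population_spec(design$n, design$age_range,
                          design$proportion_female, design$renal,
                          seed = .derive_seed(master_seed,
                                              paste(design$study,
                                                    design$code)))
  pop <- sample_population(spec)
  kps <- predict_kp(drug)
  times <- default_times(design$horizon, design$regimen)
  profiles <- vector("list", nrow(pop))
  params <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    mod <- pbpk_model(pop[i, ], drug, kps = kps, gfr_ref = gfr_ref)
    prof <- simulate(mod, regimen = design$regimen, times = times)
    profiles[[i]] <- prof
    params[[i]] <- cbind(id = pop$id[i], trial = pop$trial[i],
                         nca(prof, fe_cutoffs = c(12, 24)))
  }
  params <- do.call(rbind, params)
  pooled <- summarize_pk(params[setdiff(names(params), c("id", "trial"))],
                         profiles)
  key_cols <- intersect(c("auc_inf", "auc_tau", "half_life", "clearance"),
                        names(params))
  trial_means <- stats::aggregate(params[key_cols],
                                  by = list(trial = params$trial), mean)
  structure(list(design = design, parameters = params, summary = pooled,
                 trial_means = trial_means, population = pop,
                 master_seed = master_seed),
            class = "virtual_study")
}

#' @export
print.virtual_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("Virtual study %s.%s: %d subjects in %d trials\n",
              d$study, d$code, nrow(x$parameters),
              length(unique(x$parameters$trial))))
  print(x$summary)
  invisible(x)
}

#' @export
summary.virtual_study <- function(object, ...) object$summary

.study_mean <- function(study, parameter) {
  tab <- study$summary$parameters
  tab$mean[match(parameter, tab$parameter)]
}

#' Observed PK fixtures
#'
#' The observed (clinical) summary parameters packaged as plain CSV, keyed
#' by study and trial code.
#'
#' @param table which comparison table, `"elderly"` (healthy/elderly
#'   designs, fe at 12 h except where noted) or `"renal"`
#'   (renal-impairment designs, fe at 24 h).
#' @return data.frame of observed means and SDs.
#' @export
observed_pk <- function(table = c("renal", "elderly")) {
  table <- match.arg(table)
  f <- if (table == "renal") "observed_renal.csv" else "observed_elderly.csv"
  utils::read.csv(system.file("extdata", f, package = "ceftazpbpk",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Predicted-vs-observed comparison for one study arm
#'
#' Ratios of predicted to observed means per PK parameter and the 2-fold
#' acceptance verdict (pass iff `0.5 <= ratio <= 2`, closed interval).
#' Parameters without an observed value are omitted from the verdict, not
#' failed.
#'
#' @param study a [run_virtual_study()] result.
#' @param observed one row of [observed_pk()] (matched on study/code if a
#'   full table is passed).
#' @return data.frame with `parameter`, `obs`, `pred`, `ratio`,
#'   `within_2fold`.
#' @export
predicted_observed_table <- function(study, observed = observed_pk()) {
  d <- study$design
  if (nrow(observed) > 1)
    observed <- observed[observed$study == d$study &
                           observed$code == d$code, ]
  if (nrow(observed) != 1)
    stop("no observed record for ", d$study, ".", d$code)
  auc_param <- if (d$regimen$n_doses > 1) "auc_tau" else "auc_inf"
  fe_param <- paste0("fe_", d$fe_cutoff, "h")
  pred <- c(auc = .study_mean(study, auc_param),
            half_life = .study_mean(study, "half_life"),
            clearance = .study_mean(study, "clearance"),
            fe = .study_mean(study, fe_param))
  obs <- c(auc = observed$auc, half_life = observed$half_life,
           clearance = observed$clearance, fe = observed$fe)
  ratio <- ifelse(is.na(obs) | obs == 0, NA_real_, pred / obs)
  data.frame(parameter = names(pred), obs = unname(obs),
             pred = unname(pred), ratio = unname(ratio),
             within_2fold = ifelse(is.na(ratio), NA,
                                   ratio >= 0.5 & ratio <= 2))
}
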