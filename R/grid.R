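# Model application: the age x renal-impairment grid. A single 2 g IV
# bolus in male cohorts at ages 20-70 that are either normal-for-age or in
# an explicit impairment stage; exposure fold changes are reported against
# the 20-y normal reference and against the age-matched normal reference.

#' Fold change between two cell means
#'
#' @param cell_mean arithmetic mean of a PK parameter in a grid cell.
#' @param reference_mean same for the reference cell (> 0).
#' @return Dimensionless ratio.
#' @export
fold_change <- function(cell_mean, reference_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive")
  cell_mean / reference_mean
}

#' Simulate the age x renal-impairment grid
#'
#' For every combination of age and renal class, simulates `n_per_cell`
#' male subjects receiving a single IV bolus and summarizes AUC to
#' infinity, terminal half-life and clearance. Fold changes are computed
#' from the arithmetic cell means, both against the 20-year normal
#' reference cell and against the age-matched normal cell.
#'
#' @param n_per_cell subjects per cell.
#' @param dose mg, single IV bolus.
#' @param seed master seed; cells derive child seeds.
#' @param ages years.
#' @param classes renal classes (`"normal"` means normal-for-age).
#' @param drug a [drug_parameters()] object.
#' @param gfr_ref reference CLcr for clearance scaling.
#' @return Object of class `age_ri_grid`: `cells` (per-cell means and SDs),
#'   `folds` (long data.frame: parameter, age, class, fold vs the 20-y
#'   normal cell and vs the age-matched normal cell), and `profiles`
#'   (per-cell mean concentration curves, for plotting).
#' @export
run_age_ri_grid <- function(n_per_cell = 200, dose = 2000, seed = 1L,
                            ages = c(20, 30, 40, 50, 60, 70),
                            classes = c("normal", "mild", "moderate",
                                        "severe"),
                            drug = ceftazidime(),
                            gfr_ref = gfr_reference()) {
  regimen <- dose_regimen(amount = dose)
  kps <- predict_kp(drug)
  cells <- list()
  profiles <- list()
  for (cls in classes) {
    horizon <- .default_horizon(cls)
    times <- default_times(horizon, regimen)
    for (age in ages) {
      spec <- population_spec(n_per_cell, c(age, age),
                              proportion_female = 0, renal = cls,
                              seed = .derive_seed(seed,
                                                  paste("grid", age, cls)))
      pop <- sample_population(spec)
      res <- matrix(NA_real_, n_per_cell, 3,
                    dimnames = list(NULL, c("auc_inf", "half_life",
                                            "clearance")))
      cmat <- matrix(NA_real_, length(times), n_per_cell)
      for (i in seq_len(n_per_cell)) {
        mod <- pbpk_model(pop[i, ], drug, kps = kps, gfr_ref = gfr_ref)
        prof <- simulate(mod, regimen = regimen, times = times)
        p <- nca(prof, fe_cutoffs = numeric(0))
        res[i, ] <- c(p$auc_inf, p$half_life, p$clearance)
        cmat[, i] <- prof$conc
      }
      key <- paste(age, cls, sep = "_")
      cells[[key]] <- data.frame(
        age = age, class = cls,
        auc_inf = mean(res[, "auc_inf"]), auc_inf_sd = stats::sd(res[, "auc_inf"]),
        half_life = mean(res[, "half_life"]),
        half_life_sd = stats::sd(res[, "half_life"]),
        clearance = mean(res[, "clearance"]),
        clearance_sd = stats::sd(res[, "clearance"]),
        gfr = mean(pop$gfr), stringsAsFactors = FALSE)
      profiles[[key]] <- data.frame(time = times, mean = rowMeans(cmat))
    }
  }
  cells <- do.call(rbind, c(cells, make.row.names = FALSE))
  ref20 <- cells[cells$age == min(ages) & cells$class == "normal", ]
  folds <- do.call(rbind, lapply(c("auc_inf", "half_life", "clearance"),
    function(par) {
      agematch <- cells[cells$class == "normal", ]
      data.frame(
        parameter = par, age = cells$age, class = cells$class,
        fold_vs_20y_normal = fold_change(cells[[par]], ref20[[par]]),
        fold_vs_age_matched_normal = fold_change(
          cells[[par]],
          agematch[[par]][match(cells$age, agematch$age)]))
    }))
  structure(list(cells = cells, folds = folds, profiles = profiles,
                 dose = dose, n_per_cell = n_per_cell, seed = seed),
            class = "age_ri_grid")
}

#' Extract one fold value from a grid
#'
#' @param grid an [run_age_ri_grid()] result.
#' @param parameter `"auc_inf"`, `"half_life"` or `"clearance"`.
#' @param age years.
#' @param class renal class.
#' @param vs `"20y_normal"` or `"age_matched"`.
#' @return The fold change (numeric scalar).
#' @export
grid_fold <- function(grid, parameter, age, class,
                      vs = c("20y_normal", "age_matched")) {
  vs <- match.arg(vs)
  f <- grid$folds
  row <- f[f$parameter == parameter & f$age == age & f$class == class, ]
  if (nrow(row) != 1) stop("no such cell")
  if (vs == "20y_normal") row$fold_vs_20y_normal
  else row$fold_vs_age_matched_normal
}

#' @export
print.age_ri_grid <- function(x, ...) {
  cat(sprintf("Age x renal-impairment grid: %d mg bolus, %d subjects/cell\n",
              x$dose, x$n_per_cell))
  for (par in c("auc_inf", "half_life", "clearance")) {
    f <- x$folds[x$folds$parameter == par, ]
    tab <- stats::xtabs(fold_vs_20y_normal ~ age + class, data = f)
    cat("\nFold vs 20-y normal -", par, "\n")
    print(round(tab[, intersect(c("normal", "mild", "moderate", "severe"),
                                colnames(tab)), drop = FALSE], 2))
  }
  invisible(x)
}

#' @export
plot.age_ri_grid <- function(x, ages = c(20, 40, 60, 70), ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  classes <- unique(x$cells$class)
  cols <- seq_along(classes)
  for (age in ages) {
    first <- TRUE
    for (k in seq_along(classes)) {
      key <- paste(age, classes[k], sep = "_")
      pr <- x$profiles[[key]]
      if (is.null(pr)) next
      pos <- pr$mean > 1e-3
      if (first) {
        graphics::plot(pr$time[pos], pr$mean[pos], type = "l", log = "y",
                       col = cols[k], xlab = "Time (h)",
                       ylab = "Mean plasma conc (mg/L)",
                       main = paste(age, "years"), ...)
        first <- FALSE
      } else graphics::lines(pr$time[pos], pr$mean[pos], col = cols[k])
    }
    graphics::legend("topright", legend = classes, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
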