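# Demographics, Cockcroft-Gault renal function, staging, sampling.

test_that("DuBois BSA matches hand evaluation and its power law", {
  expect_equal(bsa_dubois(70, 170), 1.810, tolerance = 0.01 / 1.81)
  expect_equal(bsa_dubois(72, 178), 0.007184 * 72^0.425 * 178^0.725)
  k <- 1.3
  expect_equal(bsa_dubois(70 * k, 170) / bsa_dubois(70, 170), k^0.425)
  expect_error(bsa_dubois(-1, 170), "positive")
})

test_that("Cockcroft-Gault clearance reproduces worked examples", {
  # (140-20)*72 / (72*1) * 1 = 120 for Scr 88.42 umol/L (= 1 mg/dL)
  expect_equal(cockcroft_gault_gfr(20, 72, 88.42, 1.73, "male"), 120)
  expect_equal(cockcroft_gault_gfr(20, 72, 88.42, 1.73, "female"),
               120 * 0.82)
  # high creatinine drives clearance to zero
  expect_lt(cockcroft_gault_gfr(20, 72, 1e7, 1.73, "male"), 0.01)
  expect_error(cockcroft_gault_gfr(20, 72, 0, 1.73, "male"), "positive")
  expect_warning(g <- cockcroft_gault_gfr(140, 72, 88.42, 1.73, "male"),
                 "clamped")
  expect_equal(g, 0)
})

test_that("creatinine from target clearance inverts Cockcroft-Gault", {
  expect_equal(scr_from_gfr(120, 20, 72, 1.73, "male"), 88.42,
               tolerance = 1e-9)
  # round trip at assorted covariates
  for (sx in c("male", "female")) {
    scr <- scr_from_gfr(55, 64, 81, 1.9, sx)
    expect_equal(cockcroft_gault_gfr(64, 81, scr, 1.9, sx), 55,
                 tolerance = 1e-9)
  }
  # reciprocal relation
  expect_equal(scr_from_gfr(30, 40, 70, 1.8, "male"),
               2 * scr_from_gfr(60, 40, 70, 1.8, "male"))
  expect_error(scr_from_gfr(0, 40, 70, 1.8, "male"), "anuric")
})

test_that("renal staging bands and tie-breaks", {
  expect_equal(classify_renal(c(105, 75, 45, 22, 0)),
               c("normal", "mild", "moderate", "severe", "anuric"))
  # boundary belongs to the milder class
  expect_equal(classify_renal(c(90, 60, 30, 15, 7)),
               c("normal", "mild", "moderate", "severe", "severe"))
})

test_that("sampling is seed-deterministic with exact sex counts", {
  spec <- population_spec(200, c(20, 60), 0.5, "normal", seed = 11)
  pop <- sample_population(spec)
  expect_equal(nrow(pop), 200)
  expect_equal(sum(pop$sex == "female"), 100)
  expect_equal(sort(unique(pop$trial)), 1:20)
  expect_true(all(table(pop$trial) == 10))
  expect_identical(pop, sample_population(spec))
  spec2 <- spec; spec2$seed <- 12L
  expect_false(identical(pop$weight, sample_population(spec2)$weight))
  one <- sample_individual(spec)
  expect_equal(nrow(one), 1)
})

test_that("explicit-stage cohorts are fully contained in their band", {
  for (cls in c("mild", "moderate", "severe")) {
    band <- switch(cls, mild = c(60, 90), moderate = c(30, 60),
                   severe = c(15, 30))
    for (ages in list(c(20, 20), c(45, 55), c(70, 80))) {
      pop <- sample_population(population_spec(
        150, ages, 0.5, cls, seed = 33))
      expect_true(all(pop$gfr >= band[1] & pop$gfr < band[2]))
      expect_true(all(pop$renal_class == cls))
      # creatinine is consistent with the carried clearance
      expect_equal(cockcroft_gault_gfr(pop$age, pop$weight,
                                       pop$serum_creatinine, pop$bsa,
                                       pop$sex),
                   pop$gfr, tolerance = 1e-9)
    }
  }
  anu <- sample_population(population_spec(20, c(26, 74), 0.5, "anuric",
                                           seed = 3))
  expect_true(all(anu$gfr == 0))
  expect_true(all(anu$renal_class == "anuric"))
})

test_that("renal function declines within a stage and across decades", {
  mean_gfr <- function(age, cls)
    mean(sample_population(population_spec(400, c(age, age), 0, cls,
                                           seed = 7))$gfr)
  # normal-for-age: strictly decreasing decade means 20 -> 70
  g <- vapply(seq(20, 70, 10), mean_gfr, numeric(1), cls = "normal")
  expect_true(all(diff(g) < 0))
  # within the severe stage the 70-y cohort sits lower than the 20-y one
  expect_lt(mean_gfr(70, "severe"), mean_gfr(20, "severe"))
})

test_that("age-specific clearance means match the mixed-sex observed groups", {
  # observed CLcr (mean +/- SD) in the 2 g bolus age-decade study
  obs <- list(list(age = c(18, 39), pf = 2 / 7, m = 112, s = 19),
              list(age = c(60, 79), pf = 3 / 13, m = 79, s = 18),
              list(age = c(80, 88), pf = 4 / 9, m = 56, s = 16))
  for (o in obs) {
    pop <- sample_population(population_spec(400, o$age, o$pf, "normal",
                                             seed = 5))
    expect_lt(abs(mean(pop$gfr) - o$m), o$s)
  }
})

test_that("physiology balances flows and scales organ sizes", {
  ind <- reference_adult()
  ph <- physiology(ind)
  expect_equal(sum(ph$flows), ph$cardiac_output)
  expect_equal(ph$plasma_volume + ph$erythrocyte_volume, ph$blood_volume)
  expect_equal(ph$liver_mass, 1600 * ind$bsa / 1.86)
  # cardiac output declines with age
  old <- ind; old$age <- 75
  expect_lt(physiology(old)$cardiac_output, ph$cardiac_output)
  # reduced renal perfusion in impairment, flows still balanced
  ri <- ind; ri$gfr <- 20
  ph_ri <- physiology(ri)
  expect_lt(ph_ri$flows[["kidney"]], ph$flows[["kidney"]])
  expect_equal(sum(ph_ri$flows), ph_ri$cardiac_output)
})
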