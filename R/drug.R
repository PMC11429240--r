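#' Drug parameter record
#'
#' Construct and validate the drug-specific input set that drives all
#' mechanistic predictions: physicochemistry (for tissue partitioning),
#' plasma binding, the systemic renal clearance of a healthy reference
#' adult, and the per-hepatocyte intrinsic biliary clearance.
#'
#' @param molecular_weight g/mol.
#' @param log_p octanol:buffer partition coefficient of the neutral species
#'   (log10).
#' @param compound_type one of `"monoprotic_acid"`, `"diprotic_acid"`,
#'   `"base"`, `"neutral"`.
#' @param pka1,pka2 acid dissociation constants; `pka2` only for diprotic
#'   acids, and then `pka1 <= pka2`.
#' @param blood_to_plasma blood:plasma concentration ratio (> 0).
#' @param fu_plasma fraction unbound in plasma, in (0, 1].
#' @param binding_protein `"albumin"` or `"AGP"`.
#' @param cl_renal_ref systemic renal clearance of a healthy reference adult,
#'   L/h.
#' @param clint_biliary intrinsic biliary clearance, uL/min per 1e6
#'   hepatocytes.
#' @param clint_biliary_cv inter-individual coefficient of variation of
#'   `clint_biliary`, percent.
#' @param kp_scalar multiplier applied to every predicted tissue:plasma
#'   partition coefficient.
#' @return An object of class `drug_parameters` (a validated named list).
#' @seealso [ceftazidime()] for the packaged ceftazidime record,
#'   [predict_kp()], [predict_vss()].
#' @export
drug_parameters <- function(molecular_weight, log_p, compound_type,
                            pka1 = NA_real_, pka2 = NA_real_,
                            blood_to_plasma, fu_plasma,
                            binding_protein = "albumin",
                            cl_renal_ref, clint_biliary,
                            clint_biliary_cv = 0, kp_scalar = 1.0) {
  compound_type <- match.arg(compound_type,
                             c("monoprotic_acid", "diprotic_acid",
                               "base", "neutral"))
  binding_protein <- match.arg(binding_protein, c("albumin", "AGP"))
  stopifnot(
    molecular_weight > 0,
    is.finite(log_p),
    blood_to_plasma > 0,
    fu_plasma > 0, fu_plasma <= 1,
    cl_renal_ref >= 0,
    clint_biliary >= 0,
    clint_biliary_cv >= 0,
    kp_scalar > 0
  )
  if (compound_type %in% c("monoprotic_acid", "base") && !is.finite(pka1))
    stop("pka1 is required for compound_type '", compound_type, "'")
  if (compound_type == "diprotic_acid") {
    if (!is.finite(pka1) || !is.finite(pka2))
      stop("pka1 and pka2 are required for a diprotic acid")
    if (pka1 > pka2) stop("for a diprotic acid pka1 must be <= pka2")
  }
  structure(list(
    molecular_weight = molecular_weight, log_p = log_p,
    compound_type = compound_type, pka1 = pka1, pka2 = pka2,
    blood_to_plasma = blood_to_plasma, fu_plasma = fu_plasma,
    binding_protein = binding_protein, cl_renal_ref = cl_renal_ref,
    clint_biliary = clint_biliary, clint_biliary_cv = clint_biliary_cv,
    kp_scalar = kp_scalar
  ), class = "drug_parameters")
}

#' Read a drug record from a YAML file
#'
#' The file must carry the fields of [drug_parameters()], one per key.
#'
#' @param path path to a YAML file.
#' @return A `drug_parameters` object.
#' @export
read_drug_parameters <- function(path) {
  rec <- yaml::read_yaml(path)
  do.call(drug_parameters, rec)
}

#' The packaged ceftazidime record
#'
#' Ceftazidime is a strongly hydrophilic diprotic acid (logP -3.75, pKa
#' 2.43/2.89), essentially fully ionized at physiological pH, ~10% bound to
#' albumin, cleared predominantly by passive glomerular filtration with a
#' minor biliary contribution.
#'
#' @return A `drug_parameters` object.
#' @export
ceftazidime <- function() {
  read_drug_parameters(system.file("extdata", "ceftazidime.yaml",
                                   package = "ceftazpbpk", mustWork = TRUE))
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Drug parameters (", x$compound_type, ")\n", sep = "")
  cat(sprintf("  MW %.1f g/mol, logP %.2f, pKa %s\n", x$molecular_weight,
              x$log_p, paste(stats::na.omit(c(x$pka1, x$pka2)),
                             collapse = "/")))
  cat(sprintf("  B:P %.2f, fu %.2f (%s)\n", x$blood_to_plasma, x$fu_plasma,
              x$binding_protein))
  cat(sprintf("  CL_R(ref) %.2f L/h, biliary CLint %.3f uL/min/1e6 cells (CV %.0f%%)\n",
              x$cl_renal_ref, x$clint_biliary, x$clint_biliary_cv))
  cat(sprintf("  Kp scalar %.2f\n", x$kp_scalar))
  invisible(x)
}

#' Henderson-Hasselbalch ionization fractions
#'
#' Fraction of drug in the neutral form at a given pH.
#'
#' @param compound_type see [drug_parameters()].
#' @param pka1,pka2 dissociation constants as appropriate for the type.
#' @param ph pH in \[0, 14\].
#' @return A list with `fraction_neutral` and `fraction_ionized`, each in
#'   \[0, 1\] and summing to 1.
#' @export
ionization_fractions <- function(compound_type, pka1 = NA_real_,
                                 pka2 = NA_real_, ph) {
  stopifnot(ph >= 0, ph <= 14)
  fn <- switch(compound_type,
    neutral = rep(1, length(ph)),
    monoprotic_acid = 1 / (1 + 10^(ph - pka1)),
    diprotic_acid = 1 / (1 + 10^(ph - pka1) + 10^(2 * ph - pka1 - pka2)),
    base = 1 / (1 + 10^(pka1 - ph)),
    stop("unsupported compound_type: ", compound_type)
  )
  list(fraction_neutral = fn, fraction_ionized = 1 - fn)
}

# Plasma neutral-lipid and neutral-phospholipid volume fractions used in the
# albumin-association term of the partition equations.
.plasma_f_nl <- 0.0023
.plasma_f_np <- 0.0013

.tissue_comp_cache <- new.env(parent = emptyenv())

#' Tissue composition table
#'
#' Fractional extracellular/intracellular water, neutral lipid, neutral
#' phospholipid, tissue:plasma albumin ratio and intracellular pH for the
#' twelve systemic tissues of the whole-body model. Shipped as a versioned
#' plain-text constant table (values from the published tissue-composition
#' compilations underlying mechanistic partition prediction).
#'
#' @return A data.frame, one row per tissue.
#' @export
tissue_composition <- function() {
  if (is.null(.tissue_comp_cache$tab)) {
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "ceftazpbpk", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(
      all(tab$f_ew >= 0 & tab$f_ew <= 1),
      all(tab$f_iw >= 0 & tab$f_iw <= 1),
      all(tab$f_ew + tab$f_iw + tab$f_nl + tab$f_np <= 1),
      !anyDuplicated(tab$tissue)
    )
    .tissue_comp_cache$tab <- tab
  }
  .tissue_comp_cache$tab
}

#' Predict tissue:plasma partition coefficients
#'
#' Mechanistic prediction for ionized acids (and neutral compounds) from
#' tissue composition: partitioning into extracellular and intracellular
#' water with Henderson-Hasselbalch correction for the intracellular pH,
#' partitioning into neutral lipid and phospholipid, and association with
#' interstitial albumin scaled by the tissue:plasma albumin ratio. The
#' plasma albumin association constant is back-calculated from `fu_plasma`.
#' The returned Kp is on a total-plasma basis and is multiplied by the
#' drug's `kp_scalar`.
#'
#' @param drug a [drug_parameters()] object. Bases ionized at physiological
#'   pH are outside the scope of this implementation.
#' @param tissue a tissue-composition table (default [tissue_composition()])
#'   or a subset of its rows.
#' @param hematocrit fraction, in (0, 1); unused for acids but part of the
#'   partitioning context.
#' @param plasma_ph plasma pH.
#' @return Named numeric vector of Kp values (tissue:plasma), one per row of
#'   `tissue`.
#' @export
predict_kp <- function(drug, tissue = tissue_composition(),
                       hematocrit = 0.45, plasma_ph = 7.4) {
  stopifnot(inherits(drug, "drug_parameters"),
            hematocrit > 0, hematocrit < 1)
  if (drug$compound_type == "base")
    stop("unsupported compound_type for Kp prediction: base")
  p <- 10^drug$log_p
  ion_p <- ionization_fractions(drug$compound_type, drug$pka1, drug$pka2,
                                plasma_ph)
  y_p <- 1 / ion_p$fraction_neutral        # 1 + 10^(pHp-pKa1) + ...
  ion_t <- ionization_fractions(drug$compound_type, drug$pka1, drug$pka2,
                                tissue$ph_iw)
  x_t <- 1 / ion_t$fraction_neutral
  lipid <- function(f_nl, f_np) (p * f_nl + (0.3 * p + 0.7) * f_np) / y_p
  # plasma-protein association strength from fu, net of plasma lipid
  ka_pr <- 1 / drug$fu_plasma - 1 - lipid(.plasma_f_nl, .plasma_f_np)
  kpu <- tissue$f_ew +
    (x_t / y_p) * tissue$f_iw +
    lipid(tissue$f_nl, tissue$f_np) +
    ka_pr * tissue$albumin_ratio
  kp <- kpu * drug$fu_plasma * drug$kp_scalar
  names(kp) <- tissue$tissue
  kp
}

#' Erythrocyte:plasma partition coefficient implied by the B:P ratio
#'
#' @param blood_to_plasma blood:plasma concentration ratio.
#' @param hematocrit fraction.
#' @return Erythrocyte:plasma concentration ratio (floored at 0).
#' @export
erythrocyte_partition <- function(blood_to_plasma, hematocrit = 0.45) {
  max(0, (blood_to_plasma - (1 - hematocrit)) / hematocrit)
}

#' Mechanistic steady-state volume of distribution
#'
#' `Vss * BW = Vp + Ve * E:P + sum_t V_t * Kp_t`, i.e. plasma, erythrocyte
#' and tissue spaces weighted by their partition coefficients, per kg body
#' weight.
#'
#' @param kps named vector of tissue:plasma Kp values.
#' @param organ_volumes named vector of tissue volumes (L), same tissue set
#'   as `kps`.
#' @param plasma_volume L.
#' @param erythrocyte_volume L.
#' @param erythrocyte_partition erythrocyte:plasma concentration ratio.
#' @param body_weight kg.
#' @return Vss in L/kg.
#' @export
predict_vss <- function(kps, organ_volumes, plasma_volume,
                        erythrocyte_volume, erythrocyte_partition,
                        body_weight) {
  stopifnot(body_weight > 0, plasma_volume > 0)
  if (!setequal(names(kps), names(organ_volumes)))
    stop("tissue sets of kps and organ_volumes differ")
  organ_volumes <- organ_volumes[names(kps)]
  v <- plasma_volume + erythrocyte_volume * erythrocyte_partition +
    sum(organ_volumes * kps)
  v / body_weight
}

#' Vss of a drug in a reference adult
#'
#' Convenience wrapper: predicts per-tissue Kps for the packaged tissue set
#' and evaluates [predict_vss()] on the reference individual's physiology.
#'
#' @param drug a [drug_parameters()] object.
#' @param individual a one-row individual as from [reference_adult()].
#' @return Vss in L/kg.
#' @export
vss_reference <- function(drug = ceftazidime(),
                          individual = reference_adult()) {
  phys <- physiology(individual)
  kps <- predict_kp(drug, hematocrit = individual$hematocrit)
  ep <- erythrocyte_partition(drug$blood_to_plasma, individual$hematocrit)
  predict_vss(kps, phys$volumes[names(kps)],
              plasma_volume = phys$plasma_volume,
              erythrocyte_volume = phys$erythrocyte_volume,
              erythrocyte_partition = ep,
              body_weight = individual$weight)
}
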