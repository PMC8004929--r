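#' Drug-level parameters for the MMAE PBPK model
#'
#' Bundles the drug constants: unbound plasma fraction, blood-cell and
#' per-tissue partition coefficients (on the cellular-space basis, i.e.
#' already adjusted for the fractional cellular volume), permeability-surface
#' area coefficients, hepatic intrinsic clearance, the fast-exchange
#' multiplier G, and the molecular weight.
#'
#' Defaults are the fitted/assembled values for MMAE: `fu_p = 0.8`,
#' `Kp_BC = 5.46`, the adjusted per-tissue Kp set (liver defaults to 25.3,
#' the value corrected for hepatic intrinsic clearance; the uncorrected
#' apparent value 3.80 can be supplied via `Kp`), and the estimated PS set
#' with `CL_int = 137` mL/h. Tissues without observed data (thymus,
#' intestines, carcass/other) carry the spleen Kp (thymus, intestines) or
#' Kp = 1 (other), and a PS equal to the muscle PS scaled by tissue-weight
#' ratio.
#'
#' @param fu_p unbound fraction in plasma, in (0, 1].
#' @param Kp_BC blood-cell partition coefficient.
#' @param PS_BC blood-cell permeability-surface area coefficient, mL/h.
#' @param Kp named numeric vector of per-tissue partition coefficients to
#'   override defaults (names among the model tissues).
#' @param PS named numeric vector of per-tissue permeability coefficients
#'   (mL/h) to override defaults.
#' @param CL_int hepatic intrinsic clearance, mL/h, acting on the liver
#'   interstitial concentration.
#' @param G dimensionless multiplier on tissue plasma flow that makes the
#'   plasma-endothelial-interstitial exchange effectively instantaneous.
#' @param MW molecular weight, g/mol.
#' @return object of class `drug_params` (a list).
#' @examples
#' drug_params()
#' drug_params(Kp = c(liver = 3.80))  # apparent (uncorrected) liver Kp
#' @export
drug_params <- function(fu_p = 0.8, Kp_BC = 5.46, PS_BC = 0.105,
                        Kp = NULL, PS = NULL, CL_int = 137, G = 1000,
                        MW = MMAE_MW) {
  kp_def <- c(lung = 64.9, liver = 25.3, heart = 22.8, kidney = 42.4,
              brain = 0.530, muscle = 1.51, bone = 1.89, skin = 2.87,
              adipose = 3.01, spleen = 47.2, pancreas = 2.93,
              thymus = 47.2, small_intestine = 47.2, large_intestine = 47.2,
              other = 1)
  ps_def <- c(lung = 2.47, liver = 49.2, heart = 1.47, kidney = 14.2,
              brain = 0.00825, muscle = 3.16, bone = 0.568, skin = 0.681,
              adipose = 0.588, spleen = 0.457, pancreas = 0.0657,
              # unobserved tissues: muscle PS scaled by tissue-weight ratio
              thymus = 3.16 * 0.009 / 11.3,
              small_intestine = 3.16 * 0.728 / 11.3,
              large_intestine = 3.16 * 0.314 / 11.3,
              other = 3.16 * 0.60 / 11.3)
  kp_def <- .merge_named(kp_def, Kp, "Kp")
  ps_def <- .merge_named(ps_def, PS, "PS")

  if (fu_p <= 0 || fu_p > 1) stop("fu_p must be in (0, 1]", call. = FALSE)
  if (Kp_BC < 0 || any(kp_def < 0)) stop("Kp must be >= 0", call. = FALSE)
  if (PS_BC < 0 || any(ps_def < 0) || CL_int < 0)
    stop("PS and CL_int must be >= 0", call. = FALSE)
  if (G < 1) stop("G must be >= 1", call. = FALSE)
  if (MW <= 0) stop("MW must be positive", call. = FALSE)

  structure(list(fu_p = fu_p, Kp_BC = Kp_BC, PS_BC = PS_BC,
                 Kp = kp_def[.tissues], PS = ps_def[.tissues],
                 CL_int = CL_int, G = G, MW = MW),
            class = "drug_params")
}

.merge_named <- function(defaults, override, what) {
  if (is.null(override)) return(defaults)
  if (is.null(names(override)) || any(!nzchar(names(override))))
    stop(what, " overrides must be a named vector", call. = FALSE)
  nm <- names(override)
  nm[nm == "fat"] <- "adipose"
  bad <- setdiff(nm, names(defaults))
  if (length(bad))
    stop("unknown ", what, " tissue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  defaults[nm] <- as.numeric(override)
  defaults
}

#' Tumor disposition parameters (Krogh-cylinder model)
#'
#' Geometry, exchange, transport and tubulin-binding constants of the
#' cell-level tumor model. Defaults: capillary radius 8 um and intercapillary
#' half-distance 75 um (stored in cm; cm-scale values sometimes quoted for
#' this geometry are anatomically implausible and are not used), tumor radius
#' 0.7 cm, vascular permeability 87.5 cm/h, diffusivity 0.0104 cm^2/h, void
#' fraction 0.44, cellular influx 0.185 1/h, efflux 0.046 1/h, association
#' rate 0.00187 1/nM/h, dissociation rate 0.545 1/h and total tubulin
#' 2000 nM.
#'
#' @param R_cap capillary radius, cm.
#' @param R_krogh average intercapillary half-distance, cm; must exceed
#'   `R_cap`.
#' @param R_tumor tumor radius, cm.
#' @param P vascular permeability, cm/h.
#' @param D drug diffusivity in tumor, cm^2/h.
#' @param epsilon tumor void (extracellular accessible) volume fraction,
#'   in (0, 1).
#' @param k_in first-order influx rate into tumor cells, 1/h.
#' @param k_out first-order efflux rate out of tumor cells, 1/h.
#' @param k_on second-order MMAE-tubulin association rate, 1/nM/h.
#' @param k_off first-order MMAE-tubulin dissociation rate, 1/h.
#' @param C_tubulin total intracellular tubulin concentration, nM.
#' @return object of class `tumor_params` (a list).
#' @examples
#' tumor_params()
#' @export
tumor_params <- function(R_cap = 8e-4, R_krogh = 75e-4, R_tumor = 0.7,
                         P = 87.5, D = 0.0104, epsilon = 0.44,
                         k_in = 0.185, k_out = 0.046,
                         k_on = 0.00187, k_off = 0.545, C_tubulin = 2000) {
  if (epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be in (0, 1)", call. = FALSE)
  if (R_cap <= 0 || R_krogh <= 0 || R_tumor <= 0)
    stop("radii must be positive", call. = FALSE)
  if (R_cap >= R_krogh) stop("R_cap must be < R_krogh", call. = FALSE)
  rates <- c(P, D, k_in, k_out, k_on, k_off, C_tubulin)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(list(R_cap = R_cap, R_krogh = R_krogh, R_tumor = R_tumor,
                 P = P, D = D, epsilon = epsilon, k_in = k_in,
                 k_out = k_out, k_on = k_on, k_off = k_off,
                 C_tubulin = C_tubulin),
            class = "tumor_params")
}

#' Unbound fraction in blood cells or tissue cellular space
#'
#' Under linear, time-invariant partitioning the unbound fraction in a
#' cellular space is the plasma unbound fraction divided by the partition
#' coefficient of that space: `fu_t = fu_p / Kp`.
#'
#' @param fu_p unbound plasma fraction.
#' @param Kp partition coefficient (> 0).
#' @return unbound fraction in the cellular space.
#' @examples
#' fu_t(0.8, 5.46)
#' @export
fu_t <- function(fu_p, Kp) {
  if (any(Kp <= 0)) stop("Kp must be > 0", call. = FALSE)
  fu_p / Kp
}

#' Association rate constant from equilibrium dissociation constant
#'
#' `k_on = k_off / KD`; used to derive the MMAE-tubulin association rate
#' from the measured equilibrium dissociation constant.
#'
#' @param KD equilibrium dissociation constant, nM (> 0).
#' @param koff dissociation rate constant, 1/h.
#' @return association rate constant, 1/nM/h.
#' @examples
#' kon_from_kd(291, 0.545)  # 0.00187
#' @export
kon_from_kd <- function(KD, koff) {
  if (any(KD <= 0)) stop("KD must be > 0", call. = FALSE)
  koff / KD
}

#' Read drug or tumor parameter overrides from a key-value CSV file
#'
#' The file must have columns `parameter,value`. Drug keys: `fu_p`, `Kp_BC`,
#' `PS_BC`, `CL_int`, `G`, `MW`, `Kp_<tissue>`, `PS_<tissue>`. Tumor keys:
#' the argument names of [tumor_params()].
#'
#' @param path CSV file path.
#' @return for `read_drug_params` a `drug_params` object; for
#'   `read_tumor_params` a `tumor_params` object.
#' @export
read_drug_params <- function(path) {
  kv <- .read_kv(path)
  scalars <- intersect(names(kv), c("fu_p", "Kp_BC", "PS_BC", "CL_int",
                                    "G", "MW"))
  kp <- kv[grepl("^Kp_", names(kv)) & names(kv) != "Kp_BC"]
  names(kp) <- sub("^Kp_", "", names(kp))
  ps <- kv[grepl("^PS_", names(kv)) & names(kv) != "PS_BC"]
  names(ps) <- sub("^PS_", "", names(ps))
  args <- c(as.list(kv[scalars]),
            list(Kp = if (length(kp)) kp else NULL,
                 PS = if (length(ps)) ps else NULL))
  do.call(drug_params, args)
}

#' @rdname read_drug_params
#' @export
read_tumor_params <- function(path) {
  kv <- .read_kv(path)
  known <- names(formals(tumor_params))
  bad <- setdiff(names(kv), known)
  if (length(bad))
    stop("unknown tumor parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(tumor_params, as.list(kv))
}

.read_kv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(tab)))
    stop("expected columns 'parameter,value' in ", path, call. = FALSE)
  setNames(as.numeric(tab$value), tab$parameter)
}

# Apply named estimation parameters ("PS_blood", "PS_<tissue>", "CL_int",
# "k_in") onto (drug, tumor) parameter objects.
.apply_params <- function(values, drug, tum) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm == "PS_blood") {
      drug$PS_BC <- v
    } else if (nm == "CL_int") {
      drug$CL_int <- v
    } else if (nm == "k_in") {
      tum$k_in <- v
    } else if (grepl("^PS_", nm)) {
      tis <- sub("^PS_", "", nm)
      if (tis == "fat") tis <- "adipose"
      if (!tis %in% .tissues)
        stop("unknown parameter: ", nm, call. = FALSE)
      drug$PS[tis] <- v
    } else if (nm == "sigma2" || nm == "sigma1") {
      # variance parameters handled by the caller
    } else {
      stop("unknown parameter: ", nm, call. = FALSE)
    }
  }
  list(drug = drug, tum = tum)
}

# Extract the current value of a named estimation parameter
.get_param <- function(nm, drug, tum) {
  if (nm == "PS_blood") return(drug$PS_BC)
  if (nm == "CL_int") return(drug$CL_int)
  if (nm == "k_in") return(tum$k_in)
  if (grepl("^PS_", nm)) {
    tis <- sub("^PS_", "", nm)
    if (tis == "fat") tis <- "adipose"
    return(unname(drug$PS[tis]))
  }
  stop("unknown parameter: ", nm, call. = FALSE)
}
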