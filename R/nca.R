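#' Terminal log-linear rate constant
#'
#' Fits a log-linear regression to the last `n` positive concentrations and
#' returns the negative slope.
#'
#' @param times sampling times, h, strictly increasing.
#' @param concs concentrations (same length).
#' @param n number of terminal positive points to use (>= 3).
#' @return list with `lambda_z` (1/h), `t_half` (h), `n_points`, and the
#'   intercept on the log scale.
#' @export
lambda_z <- function(times, concs, n = 3) {
  if (n < 3) stop("lambda_z needs at least 3 points", call. = FALSE)
  pos <- which(concs > 0)
  if (length(pos) < n)
    stop("fewer than ", n, " positive concentrations", call. = FALSE)
  use <- utils::tail(pos, n)
  fit <- stats::lm(log(concs[use]) ~ times[use])
  lz <- -unname(coef(fit)[2])
  list(lambda_z = lz, t_half = log(2) / lz, n_points = n,
       intercept = unname(coef(fit)[1]))
}

#' Linear/log trapezoidal AUC
#'
#' Computes the area under the concentration-time curve with the linear
#' trapezoid on rising or flat segments and the log trapezoid on strictly
#' declining segments with positive endpoints (the standard lin-up/log-down
#' rule). With `extrapolate = TRUE` the tail `C_last / lambda_z` is added,
#' with `lambda_z` from the terminal log-linear regression.
#'
#' @param times sampling times, h, strictly increasing.
#' @param concs concentrations, >= 0 (same units as the returned AUC's
#'   concentration factor).
#' @param extrapolate add the extrapolated tail to infinity.
#' @param n_lambda terminal points for the `lambda_z` regression.
#' @return AUC (concentration x h). With `extrapolate = TRUE`, a list with
#'   `AUC_0_t`, `AUC_0_inf` and `lambda_z`.
#' @examples
#' auc_linlog(c(0, 1), c(10, 10))  # 10
#' @export
auc_linlog <- function(times, concs, extrapolate = FALSE, n_lambda = 3) {
  if (length(times) < 2)
    stop("need at least 2 points for an AUC", call. = FALSE)
  if (length(times) != length(concs))
    stop("times and concs must have the same length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)

  c1 <- concs[-length(concs)]; c2 <- concs[-1]
  dt <- diff(times)
  seg <- ifelse(c2 < c1 & c2 > 0,
                (c1 - c2) / log(c1 / c2) * dt,   # log trapezoid
                (c1 + c2) / 2 * dt)              # linear trapezoid
  auc_t <- sum(seg)
  if (!extrapolate) return(auc_t)

  lz <- lambda_z(times, concs, n_lambda)
  if (lz$lambda_z <= 0)
    stop("terminal slope is not positive; cannot extrapolate", call. = FALSE)
  c_last <- concs[max(which(concs > 0))]
  list(AUC_0_t = auc_t, AUC_0_inf = auc_t + c_last / lz$lambda_z,
       lambda_z = lz$lambda_z)
}

# lin-up/log-down AUMC (first-moment area) over the observed range
.aumc_linlog <- function(times, concs) {
  c1 <- concs[-length(concs)]; c2 <- concs[-1]
  t1 <- times[-length(times)]; t2 <- times[-1]
  dt <- diff(times)
  k <- log(c1 / c2) / dt  # only used on log segments
  ifelse(c2 < c1 & c2 > 0,
         (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2,
         dt * (t1 * c1 + t2 * c2) / 2)
}

#' Noncompartmental moment analysis of a plasma profile
#'
#' Computes `AUC(0-t)`, `AUC(0-inf)`, clearance `CL = dose / AUC(0-inf)`,
#' mean residence time `MRT = AUMC / AUC`, steady-state volume
#' `Vss = CL * MRT`, and terminal half-life `ln 2 / lambda_z`.
#'
#' @param times sampling times, h.
#' @param concs plasma concentrations, nM.
#' @param dose_amount dose amount, pmol.
#' @param n_lambda terminal points for the `lambda_z` regression.
#' @return list (`nca_summary`) with `AUC_0_t`, `AUC_0_inf` (h*nM), `CL`
#'   (mL/h), `Vss` (mL), `t_half` (h), `lambda_z` (1/h), `MRT` (h). If no
#'   terminal slope is estimable, extrapolation-dependent entries are `NA`
#'   and `partial` is `TRUE`.
#' @export
moment_analysis <- function(times, concs, dose_amount, n_lambda = 3) {
  auc_t <- auc_linlog(times, concs)
  lz <- tryCatch(lambda_z(times, concs, n_lambda), error = function(e) NULL)
  if (is.null(lz) || lz$lambda_z <= 0) {
    return(structure(list(AUC_0_t = auc_t, AUC_0_inf = NA_real_,
                          CL = NA_real_, Vss = NA_real_, t_half = NA_real_,
                          lambda_z = NA_real_, MRT = NA_real_,
                          partial = TRUE),
                     class = "nca_summary"))
  }
  c_last <- concs[max(which(concs > 0))]
  t_last <- times[max(which(concs > 0))]
  auc_inf <- auc_t + c_last / lz$lambda_z
  aumc_t <- sum(.aumc_linlog(times, concs))
  aumc_inf <- aumc_t + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2
  cl <- dose_amount / auc_inf
  mrt <- aumc_inf / auc_inf
  structure(list(AUC_0_t = auc_t, AUC_0_inf = auc_inf, CL = cl,
                 Vss = cl * mrt, t_half = log(2) / lz$lambda_z,
                 lambda_z = lz$lambda_z, MRT = mrt, partial = FALSE),
            class = "nca_summary")
}

#' @export
print.nca_summary <- function(x, ...) {
  cat("NCA summary:\n")
  for (nm in setdiff(names(x), "partial"))
    cat(sprintf("  %-9s %s\n", nm, signif(x[[nm]], 4)))
  if (isTRUE(x$partial)) cat("  (partial: no estimable terminal slope)\n")
  invisible(x)
}

#' Tissue-to-plasma partition coefficient
#'
#' `Kp = AUC_tissue / AUC_plasma`, both over the same 0-t interval.
#'
#' @param AUC_matrix tissue (or blood-cell, or tumor) AUC, h*nM.
#' @param AUC_plasma plasma AUC, h*nM (> 0).
#' @return partition coefficient.
#' @examples
#' kp(94.6, 75.4)  # muscle, 1.25
#' @export
kp <- function(AUC_matrix, AUC_plasma) {
  if (any(AUC_plasma <= 0)) stop("AUC_plasma must be > 0", call. = FALSE)
  AUC_matrix / AUC_plasma
}

#' Adjust a partition coefficient to the cellular-space basis
#'
#' The drug is assumed to reside mainly in the cellular space, so the
#' apparent whole-tissue Kp is divided by the fractional cellular volume.
#'
#' @param Kp apparent partition coefficient.
#' @param f_cellular cellular volume fraction, in (0, 1].
#' @return adjusted partition coefficient (>= the input).
#' @examples
#' adjust_kp(35.3, 0.5439)  # lung, 64.9
#' @export
adjust_kp <- function(Kp, f_cellular) {
  if (any(f_cellular <= 0) || any(f_cellular > 1))
    stop("f_cellular must be in (0, 1]", call. = FALSE)
  Kp / f_cellular
}

#' Percent predictive error
#'
#' `%PE = |AUC_pred - AUC_obs| / AUC_obs * 100` (absolute value by default;
#' `signed = TRUE` keeps the sign).
#'
#' @param AUC_pred predicted AUC.
#' @param AUC_obs observed AUC (> 0).
#' @param signed keep the sign of the error.
#' @return percent predictive error.
#' @examples
#' percent_pe(81.59, 75.4)  # 8.21
#' @export
percent_pe <- function(AUC_pred, AUC_obs, signed = FALSE) {
  if (any(AUC_obs <= 0)) stop("AUC_obs must be > 0", call. = FALSE)
  pe <- (AUC_pred - AUC_obs) / AUC_obs * 100
  if (signed) pe else abs(pe)
}

#' In vitro-in vivo extrapolation of intrinsic clearance
#'
#' Scales an in vitro intrinsic clearance (uL/min per 10^6 hepatocytes or
#' per mg microsomal protein) to whole-liver metabolic clearance in mL/h,
#' and divides by the metabolic fraction of total clearance to obtain the
#' total intrinsic clearance (metabolism plus biliary excretion; the
#' reference split for MMAE is 40% metabolic / 60% biliary).
#'
#' @param CLint_vitro in vitro intrinsic clearance; uL/min/10^6 cells
#'   (hepatocyte basis) or uL/min/mg protein (microsome basis).
#' @param scaling_factor 10^6 cells/g liver (hepatocyte) or mg protein/g
#'   liver (microsome).
#' @param liver_weight liver weight, g.
#' @param f_metabolic metabolic fraction of total clearance, in (0, 1].
#' @param basis,sf_basis measurement basis of `CLint_vitro` and
#'   `scaling_factor`; must agree.
#' @return list with `CL_metabolic` and `CL_total` (mL/h) and the inputs.
#' @examples
#' ivive(3, 135, 1.0, f_metabolic = 0.4, basis = "hepatocyte",
#'       sf_basis = "hepatocyte")
#' @export
ivive <- function(CLint_vitro, scaling_factor, liver_weight,
                  f_metabolic = 0.4,
                  basis = c("hepatocyte", "microsome"),
                  sf_basis = basis) {
  basis <- match.arg(basis)
  sf_basis <- match.arg(sf_basis, c("hepatocyte", "microsome"))
  if (basis != sf_basis)
    stop("CLint basis (", basis, ") and scaling-factor basis (", sf_basis,
         ") do not match", call. = FALSE)
  if (CLint_vitro <= 0 || scaling_factor <= 0 || liver_weight <= 0)
    stop("all inputs must be positive", call. = FALSE)
  if (f_metabolic <= 0 || f_metabolic > 1)
    stop("f_metabolic must be in (0, 1]", call. = FALSE)
  # uL/min -> mL/h: * 60 / 1000
  cl_met <- CLint_vitro * scaling_factor * liver_weight * 60 / 1000
  list(CL_metabolic = cl_met, CL_total = cl_met / f_metabolic,
       basis = basis, f_metabolic = f_metabolic)
}

#' Allometric scaling of a permeability-surface area coefficient
#'
#' `PS_target = PS_source * (BW_target / BW_source)^exponent`, with the
#' body-surface-area exponent 0.67 by default.
#'
#' @param PS_source PS in the source species, mL/h.
#' @param bw_source,bw_target body weights, g.
#' @param exponent allometric exponent.
#' @return scaled PS, mL/h.
#' @examples
#' scale_ps(1.0, 28, 28000)  # ~102
#' @export
scale_ps <- function(PS_source, bw_source, bw_target, exponent = 0.67) {
  if (any(bw_source <= 0) || any(bw_target <= 0))
    stop("body weights must be positive", call. = FALSE)
  PS_source * (bw_target / bw_source)^exponent
}

# Pooled mean profile for one matrix: average non-BLQ replicates per time,
# drop leading/trailing all-BLQ times, exclude embedded all-BLQ times.
.pooled_profile <- function(dataset, matrix) {
  d <- dataset[dataset$matrix == matrix, , drop = FALSE]
  if (!nrow(d)) stop("no records for matrix ", matrix, call. = FALSE)
  tt <- sort(unique(d$time_h))
  conc <- vapply(tt, function(t) {
    di <- d[d$time_h == t & !d$blq, , drop = FALSE]
    if (nrow(di)) mean(di$conc_nM) else NA_real_
  }, numeric(1))
  ok <- !is.na(conc)
  if (!any(ok)) stop("all records BLQ for matrix ", matrix, call. = FALSE)
  keep <- seq(min(which(ok)), max(which(ok)))
  list(times = tt[keep][ok[keep]], concs = conc[keep][ok[keep]])
}

#' Partition-coefficient table from a biodistribution dataset
#'
#' Pools the replicate concentrations at each time point (mean of non-BLQ
#' records), computes the lin/log trapezoidal `AUC(0-t)` per matrix, and
#' derives apparent and cellular-space-adjusted partition coefficients
#' against plasma. Blood-cell Kp is reported unadjusted; tumor has no
#' cellular-fraction adjustment.
#'
#' @param dataset a `study_dataset` (see [generate_study()] or
#'   [read_dataset()]).
#' @param phys a [load_physiology()] table, for the cellular volume
#'   fractions.
#' @param liver_kp_clint_adjusted the liver row's apparent Kp is reported
#'   raw; this CLint-accounted constant is attached as metadata (attribute
#'   `liver_kp_clint`), since the eliminating tissue's apparent Kp
#'   understates its partitioning. No correction formula is applied.
#' @return data frame with columns `matrix`, `AUC_0_t`, `Kp`, `Kp_adj`.
#' @export
kp_table <- function(dataset, phys, liver_kp_clint_adjusted = 25.3) {
  stopifnot(inherits(phys, "physiology_table"))
  mats <- intersect(.matrices, unique(dataset$matrix))
  if (!"plasma" %in% mats)
    stop("dataset has no plasma records", call. = FALSE)
  prof <- lapply(mats, function(m) .pooled_profile(dataset, m))
  names(prof) <- mats
  auc <- vapply(prof, function(p) auc_linlog(p$times, p$concs), numeric(1))
  auc_p <- auc[["plasma"]]
  out <- data.frame(matrix = mats, AUC_0_t = unname(auc), row.names = NULL)
  out$Kp <- ifelse(out$matrix == "plasma", NA_real_, kp(out$AUC_0_t, auc_p))
  fc <- setNames(phys$table$f_cellular, phys$table$tissue)
  out$Kp_adj <- NA_real_
  tis <- out$matrix %in% .tissues
  out$Kp_adj[tis] <- adjust_kp(out$Kp[tis], fc[out$matrix[tis]])
  out$Kp_adj[out$matrix == "blood"] <- out$Kp[out$matrix == "blood"]
  attr(out, "liver_kp_clint") <- liver_kp_clint_adjusted
  out
}
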