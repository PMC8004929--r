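#' Intravenous bolus dosing event
#'
#' @param dose_per_bw dose normalized to body weight, mg/kg.
#' @param body_weight body weight, g.
#' @param time dose time, h (only 0 is supported by [simulate_pbpk()]).
#' @return object of class `dose_event`.
#' @examples
#' dose_event(0.1, 28)
#' @export
dose_event <- function(dose_per_bw = 0.1, body_weight = 28, time = 0) {
  if (dose_per_bw < 0) stop("dose_per_bw must be >= 0", call. = FALSE)
  if (body_weight <= 0) stop("body_weight must be positive", call. = FALSE)
  if (time != 0) stop("only a dose at t = 0 is supported", call. = FALSE)
  structure(list(route = "iv_bolus", dose_per_bw = dose_per_bw,
                 body_weight = body_weight, time = time),
            class = "dose_event")
}

#' Dose amount in pmol
#'
#' @param dose a [dose_event()].
#' @param MW molecular weight, g/mol.
#' @return dose amount, pmol.
#' @examples
#' dose_amount_pmol(dose_event(0.1, 28))  # ~3900 pmol
#' @export
dose_amount_pmol <- function(dose, MW = MMAE_MW) {
  if (MW <= 0) stop("MW must be positive", call. = FALSE)
  dose_mg <- dose$dose_per_bw * dose$body_weight / 1000
  dose_mg * 1e9 / MW
}

#' Convert between ng/mL and nM
#'
#' @param conc concentration value(s).
#' @param direction `"ng_per_mL_to_nM"` or `"nM_to_ng_per_mL"`.
#' @param MW molecular weight, g/mol.
#' @return converted value(s); `nM = ng/mL * 1000 / MW`.
#' @examples
#' convert_units(54.3, "ng_per_mL_to_nM")  # 75.6
#' @export
convert_units <- function(conc,
                          direction = c("ng_per_mL_to_nM", "nM_to_ng_per_mL"),
                          MW = MMAE_MW) {
  direction <- match.arg(direction)
  if (MW <= 0) stop("MW must be positive", call. = FALSE)
  if (direction == "ng_per_mL_to_nM") conc * 1000 / MW else conc * MW / 1000
}

#' Simulate the PBPK model for an IV bolus
#'
#' Integrates the stiff 81-state system with `deSolve::lsoda`, using the
#' compiled right-hand side and the analytic Jacobian by default. The initial
#' condition places the full dose in central plasma; all other states start
#' at zero.
#'
#' @param dose a [dose_event()].
#' @param phys,drug,tum parameter objects (see [load_physiology()],
#'   [drug_params()], [tumor_params()]); alternatively pass a prebuilt
#'   system via `system`.
#' @param times output times, h (0 is always included).
#' @param rtol,atol relative/absolute integrator tolerances; `atol` is in nM
#'   for the concentration states.
#' @param compiled use the compiled C right-hand side (default) or the pure-R
#'   path (slower; useful for cross-checking).
#' @param system optional prebuilt [build_pbpk_system()] (overrides
#'   `phys`/`drug`/`tum`).
#' @param t_max latest admissible output time, h.
#' @return object of class `pbpk_sim`: list with `times`, the state
#'   trajectory matrix `states` (times x states), observable concentration
#'   matrices `obs_nM` and `obs_ng_mL` (times x matrices), the cumulative
#'   eliminated amount `eliminated_pmol`, the `system` and the `dose`.
#' @examples
#' \donttest{
#' sim <- simulate_pbpk(dose_event(0.1, 28), load_physiology(),
#'                      drug_params(), tumor_params(),
#'                      times = c(5 / 60, 1, 6, 12, 24, 168))
#' sim$obs_ng_mL[, "plasma"]
#' }
#' @export
simulate_pbpk <- function(dose, phys = NULL, drug = NULL, tum = NULL,
                          times = c(5 / 60, 1, 6, 12, 24, 168),
                          rtol = 1e-8, atol = 1e-10, compiled = TRUE,
                          system = NULL, t_max = 200) {
  stopifnot(inherits(dose, "dose_event"))
  if (is.null(system)) system <- build_pbpk_system(phys, drug, tum)
  if (any(times < 0) || any(times > t_max))
    stop("output times must lie within [0, ", t_max, "] h", call. = FALSE)
  tt <- sort(unique(c(0, times)))

  amount <- dose_amount_pmol(dose, system$drug$MW)
  y0 <- setNames(numeric(.n_state), .state_names)
  y0[1] <- amount / system$V_plasma_central
  atol_vec <- c(rep(atol, .n_state - 1L), max(atol * 1e3, 1e-8))

  if (compiled) {
    out <- deSolve::lsoda(
      y0, tt, func = "mmae_derivs",
      parms = c(system$tum$k_on, as.vector(system$A)),
      jacfunc = "mmae_jac", jactype = "fullusr",
      dllname = "mmaepbpk", initfunc = "mmae_initmod",
      rtol = rtol, atol = atol_vec, maxsteps = 50000)
  } else {
    out <- deSolve::lsoda(
      y0, tt,
      func = function(t, y, p) list(pbpk_rhs(t, y, system)),
      jacfunc = function(t, y, p) .pbpk_jac(t, y, system),
      jactype = "fullusr", parms = NULL,
      rtol = rtol, atol = atol_vec, maxsteps = 50000)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration failed (istate = ", istate[1], ") over [0, ",
         max(tt), "] h; last time reached ", max(out[, 1]), " h",
         call. = FALSE)

  states <- out[, -1, drop = FALSE]
  colnames(states) <- .state_names
  rownames(states) <- format(out[, 1], trim = TRUE)
  obs <- states %*% t(system$O)
  obs[obs < 0] <- 0  # integrator round-off can yield tiny negatives
  keep <- out[, 1] %in% times
  res <- list(times = out[keep, 1],
              states = states[keep, , drop = FALSE],
              obs_nM = obs[keep, , drop = FALSE],
              obs_ng_mL = convert_units(obs[keep, , drop = FALSE],
                                        "nM_to_ng_per_mL", system$drug$MW),
              eliminated_pmol = unname(states[keep, "eliminated"]),
              system = system, dose = dose)
  class(res) <- "pbpk_sim"
  res
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("PBPK simulation:", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "] h\n")
  cat("dose:", x$dose$dose_per_bw, "mg/kg IV bolus,",
      signif(dose_amount_pmol(x$dose, x$system$drug$MW), 4), "pmol\n")
  print(round(x$obs_ng_mL, 4))
  invisible(x)
}

#' Homogenate-equivalent observable concentration
#'
#' Maps a full state vector to the concentration a whole-matrix measurement
#' would see: plasma is the central plasma state; whole blood is the
#' hematocrit-weighted mix of central plasma and blood cells; a tissue is the
#' volume-weighted mean over its five sub-compartments; tumor is the sum of
#' the three per-total-volume tumor states (equivalently, the void-fraction
#' weighted mix of the per-space concentrations).
#'
#' @param state state vector (length 81) or trajectory matrix
#'   (times x states).
#' @param system a [build_pbpk_system()] object.
#' @param matrix matrix name (one of plasma, blood, the tissues, tumor;
#'   `"fat"` is accepted for adipose).
#' @return observable concentration(s) in nM.
#' @export
observable_concentration <- function(state, system, matrix) {
  stopifnot(inherits(system, "pbpk_system"))
  matrix <- .canon_matrix(matrix)
  if (is.matrix(state)) {
    drop(state %*% system$O[matrix, ])
  } else {
    sum(system$O[matrix, ] * state)
  }
}

#' Total drug amount in the system
#'
#' Sums compartment amounts (volume times concentration over all states,
#' including the tumor) and, optionally, the cumulative amount eliminated.
#' Used for mass-balance checks.
#'
#' @param sim a [simulate_pbpk()] result.
#' @param include_eliminated add the cumulative eliminated amount.
#' @return numeric vector of amounts (pmol), one per output time.
#' @export
total_amount <- function(sim, include_eliminated = TRUE) {
  stopifnot(inherits(sim, "pbpk_sim"))
  w <- sim$system$w
  if (!include_eliminated) w["eliminated"] <- 0
  drop(sim$states %*% w)
}
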