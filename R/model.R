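#' Assemble the PBPK system for a parameter set
#'
#' Builds the 81-state ODE system: central plasma and blood cells, 15 tissues
#' with plasma/blood-cell/endothelial/interstitial/cellular sub-compartments,
#' three tumor states (extracellular, intracellular free, intracellular
#' tubulin-bound) and a cumulative-elimination bookkeeping state. All flux
#' terms except the bilinear tubulin-binding term are linear in the state, so
#' the system is stored as a dense coefficient matrix `A` (units 1/h on the
#' concentration states) plus the binding nonlinearity; both the R and the
#' compiled integration paths consume this representation.
#'
#' Tumor state convention: the three tumor concentrations are expressed per
#' total tumor volume, so that amounts are `C * V_tumor` and the printed
#' exchange terms conserve mass exactly against the central plasma equation;
#' the extracellular concentration in the accessible (void) space is
#' `C_extra / epsilon`.
#'
#' @param phys a [load_physiology()] table.
#' @param drug a [drug_params()] object.
#' @param tum a [tumor_params()] object.
#' @return object of class `pbpk_system`: list with the coefficient matrix
#'   `A`, amount weights `w` (mL per concentration state; 1 for the
#'   eliminated-amount state), the observable projection matrix `O`
#'   (matrices x states), state names, and the parameter objects.
#' @export
build_pbpk_system <- function(phys, drug, tum) {
  stopifnot(inherits(phys, "physiology_table"), inherits(drug, "drug_params"),
            inherits(tum, "tumor_params"))
  hct <- phys$hematocrit
  tab <- phys$table
  n <- .n_state
  A <- matrix(0, n, n, dimnames = list(.state_names, .state_names))

  Vtot <- setNames(tab$V_total_mL, tab$tissue)
  Vp  <- Vtot * tab$f_vascular * (1 - hct)
  Vbc <- Vtot * tab$f_vascular * hct
  Ve  <- Vtot * tab$f_endothelial
  Vi  <- Vtot * tab$f_interstitial
  Vc  <- Vtot * tab$f_cellular
  names(Vp) <- names(Vbc) <- names(Ve) <- names(Vi) <- names(Vc) <- tab$tissue

  fl <- split_flows(setNames(tab$Q_blood_mL_h, tab$tissue), hct)
  Qp <- fl$Q_plasma
  Qbc <- fl$Q_BC

  fu <- drug$fu_p
  PSBC <- drug$PS_BC
  KpBC <- drug$Kp_BC
  PS <- drug$PS
  Kp <- drug$Kp
  G <- drug$G

  kv <- 2 * tum$P * tum$R_cap / tum$R_krogh^2   # tumor vascular exchange, 1/h
  ks <- 6 * tum$D / tum$R_tumor^2               # tumor surface exchange, 1/h
  Vt <- tumor_volume(tum$R_tumor)
  eps <- tum$epsilon

  Vpc <- Vp[["blood"]]
  Vbcc <- Vbc[["blood"]]
  direct <- setdiff(.tissues, c("lung", "liver", .splanchnic))
  lp <- .i_p("lung"); lbc <- .i_bc("lung")

  # central plasma -----------------------------------------------------------
  for (t in direct) A[1, .i_p(t)] <- A[1, .i_p(t)] + Qp[[t]] / Vpc
  A[1, .i_p("liver")] <- A[1, .i_p("liver")] +
    (Qp[["liver"]] + sum(Qp[.splanchnic])) / Vpc
  A[1, 1] <- A[1, 1] - (Qp[["lung"]] + PSBC * fu + (kv + ks) * Vt) / Vpc
  A[1, 2] <- A[1, 2] + PSBC * fu / KpBC / Vpc
  A[1, .i_extra] <- A[1, .i_extra] + (kv + ks) * Vt / (eps * Vpc)

  # central blood cells -------------------------------------------------------
  for (t in direct) A[2, .i_bc(t)] <- A[2, .i_bc(t)] + Qbc[[t]] / Vbcc
  A[2, .i_bc("liver")] <- A[2, .i_bc("liver")] +
    (Qbc[["liver"]] + sum(Qbc[.splanchnic])) / Vbcc
  A[2, 2] <- A[2, 2] - (Qbc[["lung"]] + PSBC * fu / KpBC) / Vbcc
  A[2, 1] <- A[2, 1] + PSBC * fu / Vbcc

  # tissues -------------------------------------------------------------------
  for (t in .tissues) {
    ip <- .i_p(t); ibc <- .i_bc(t); ie <- .i_endo(t)
    ii <- .i_is(t); ic <- .i_cell(t)
    Qg <- Qp[[t]] * G

    # vascular plasma
    if (t == "lung") {
      A[ip, 1] <- A[ip, 1] + Qp[[t]] / Vp[[t]]
      q_out <- Qp[[t]]
    } else if (t == "liver") {
      A[ip, lp] <- A[ip, lp] + Qp[[t]] / Vp[[t]]
      for (s in .splanchnic)
        A[ip, .i_p(s)] <- A[ip, .i_p(s)] + Qp[[s]] / Vp[[t]]
      q_out <- Qp[[t]] + sum(Qp[.splanchnic])
    } else {
      A[ip, lp] <- A[ip, lp] + Qp[[t]] / Vp[[t]]
      q_out <- Qp[[t]]
    }
    A[ip, ip] <- A[ip, ip] - (q_out + PSBC * fu + Qg * fu) / Vp[[t]]
    A[ip, ibc] <- A[ip, ibc] + PSBC * fu / KpBC / Vp[[t]]
    A[ip, ie] <- A[ip, ie] + Qg / Vp[[t]]

    # vascular blood cells
    if (t == "lung") {
      A[ibc, 2] <- A[ibc, 2] + Qbc[[t]] / Vbc[[t]]
      qbc_out <- Qbc[[t]]
    } else if (t == "liver") {
      A[ibc, lbc] <- A[ibc, lbc] + Qbc[[t]] / Vbc[[t]]
      for (s in .splanchnic)
        A[ibc, .i_bc(s)] <- A[ibc, .i_bc(s)] + Qbc[[s]] / Vbc[[t]]
      qbc_out <- Qbc[[t]] + sum(Qbc[.splanchnic])
    } else {
      A[ibc, lbc] <- A[ibc, lbc] + Qbc[[t]] / Vbc[[t]]
      qbc_out <- Qbc[[t]]
    }
    A[ibc, ibc] <- A[ibc, ibc] - (qbc_out + PSBC * fu / KpBC) / Vbc[[t]]
    A[ibc, ip] <- A[ibc, ip] + PSBC * fu / Vbc[[t]]

    # endothelial
    A[ie, ip] <- A[ie, ip] + Qg * fu / Ve[[t]]
    A[ie, ie] <- A[ie, ie] - 2 * Qg / Ve[[t]]
    A[ie, ii] <- A[ie, ii] + Qg / Ve[[t]]

    # interstitial (hepatic elimination acts here)
    cl <- if (t == "liver") drug$CL_int else 0
    A[ii, ie] <- A[ii, ie] + Qg / Vi[[t]]
    A[ii, ii] <- A[ii, ii] - (Qg + PS[[t]] + cl) / Vi[[t]]
    A[ii, ic] <- A[ii, ic] + PS[[t]] * fu / Kp[[t]] / Vi[[t]]

    # cellular
    A[ic, ii] <- A[ic, ii] + PS[[t]] / Vc[[t]]
    A[ic, ic] <- A[ic, ic] - PS[[t]] * fu / Kp[[t]] / Vc[[t]]
  }

  # tumor ---------------------------------------------------------------------
  A[.i_extra, 1] <- A[.i_extra, 1] + (kv + ks)
  A[.i_extra, .i_extra] <- A[.i_extra, .i_extra] - (kv + ks) / eps - tum$k_in
  A[.i_extra, .i_free] <- A[.i_extra, .i_free] + tum$k_out
  A[.i_free, .i_extra] <- A[.i_free, .i_extra] + tum$k_in
  A[.i_free, .i_free] <- A[.i_free, .i_free] - tum$k_out -
    tum$k_on * tum$C_tubulin
  A[.i_free, .i_bound] <- A[.i_free, .i_bound] + tum$k_off
  A[.i_bound, .i_free] <- A[.i_bound, .i_free] + tum$k_on * tum$C_tubulin
  A[.i_bound, .i_bound] <- A[.i_bound, .i_bound] - tum$k_off

  # eliminated amount (pmol)
  A[.i_elim, .i_is("liver")] <- drug$CL_int

  # amount weights: amount_i = w_i * y_i
  w <- c(Vpc, Vbcc,
         as.vector(rbind(Vp[.tissues], Vbc[.tissues], Ve[.tissues],
                         Vi[.tissues], Vc[.tissues])),
         Vt, Vt, Vt, 1)
  names(w) <- .state_names

  # observable projection: homogenate-equivalent concentration per matrix
  O <- matrix(0, length(.matrices), n,
              dimnames = list(.matrices, .state_names))
  O["plasma", 1] <- 1
  O["blood", 1] <- 1 - hct
  O["blood", 2] <- hct
  for (t in setdiff(.matrices, c("plasma", "blood", "tumor"))) {
    idx <- c(.i_p(t), .i_bc(t), .i_endo(t), .i_is(t), .i_cell(t))
    O[t, idx] <- c(Vp[[t]], Vbc[[t]], Ve[[t]], Vi[[t]], Vc[[t]]) / Vtot[[t]]
  }
  # per-total-volume tumor states: homogenate concentration is their sum
  O["tumor", c(.i_extra, .i_free, .i_bound)] <- 1

  structure(list(A = A, w = w, O = O, state_names = .state_names,
                 phys = phys, drug = drug, tum = tum,
                 V_plasma_central = Vpc, V_tumor = Vt),
            class = "pbpk_system")
}

#' Right-hand side of the PBPK ODE system
#'
#' Evaluates the time derivative of the full state vector. The system is
#' autonomous; `t` is accepted for solver compatibility.
#'
#' @param t time, h (unused; the system is time-invariant).
#' @param y state vector of length 81 (concentrations in nM, eliminated
#'   amount in pmol).
#' @param system a [build_pbpk_system()] object.
#' @return numeric vector of derivatives, same length and order as `y`.
#' @export
pbpk_rhs <- function(t, y, system) {
  stopifnot(inherits(system, "pbpk_system"))
  if (length(y) != .n_state)
    stop("state vector must have length ", .n_state, call. = FALSE)
  if (any(!is.finite(y)))
    stop("non-finite state encountered", call. = FALSE)
  dy <- drop(system$A %*% y)
  nl <- system$tum$k_on * y[.i_free] * y[.i_bound]
  dy[.i_free] <- dy[.i_free] + nl
  dy[.i_bound] <- dy[.i_bound] - nl
  dy
}

# Jacobian of pbpk_rhs (used by the pure-R integration path)
.pbpk_jac <- function(t, y, system) {
  J <- system$A
  kon <- system$tum$k_on
  J[.i_free, .i_free] <- J[.i_free, .i_free] + kon * y[.i_bound]
  J[.i_free, .i_bound] <- J[.i_free, .i_bound] + kon * y[.i_free]
  J[.i_bound, .i_free] <- J[.i_bound, .i_free] - kon * y[.i_bound]
  J[.i_bound, .i_bound] <- J[.i_bound, .i_bound] - kon * y[.i_free]
  J
}

#' Distributional steady state of the closed system
#'
#' With zero hepatic intrinsic clearance the system is closed and mass is
#' conserved; any initial distribution (or a constant-rate infusion, once the
#' input stops growing the ratios) relaxes to a unique stationary
#' distribution. This function computes that stationary state directly, by
#' solving the linear system `A y = 0` (tubulin binding enters through its
#' equilibrium, which is linear at the stationary point only if the bound
#' state satisfies the binding isotherm; see Details) subject to the total
#' amount constraint.
#'
#' @details At a stationary point the net tubulin-binding flux vanishes,
#'   `k_on * C_free * (C_tubulin - C_bound) = k_off * C_bound`, so the bound
#'   state decouples: the remaining states satisfy the linear flux-balance
#'   system with the binding terms removed, the bound concentration follows
#'   the exact binding isotherm at the stationary free concentration, and
#'   the overall scale is fixed by the (mildly nonlinear, monotone) total
#'   amount constraint, solved by 1-D root finding. The returned state is an
#'   exact stationary point of the full nonlinear system up to solver
#'   round-off.
#'
#' @param system a [build_pbpk_system()] object; `CL_int` must be 0.
#' @param total_amount total drug amount in the system, pmol.
#' @return named state vector (length 81) at the stationary distribution.
#' @export
equilibrium_state <- function(system, total_amount) {
  stopifnot(inherits(system, "pbpk_system"))
  if (system$drug$CL_int != 0)
    stop("equilibrium_state requires CL_int = 0 (closed system)",
         call. = FALSE)
  if (total_amount < 0) stop("total_amount must be >= 0", call. = FALSE)
  tum <- system$tum
  kd <- tum$k_off / tum$k_on
  # reduced linear system: all states except tumor-bound and eliminated,
  # with the binding flux (zero at stationarity) removed from the free row
  sel <- setdiff(seq_len(.n_state - 1L), .i_bound)
  Ar <- system$A[sel, sel]
  ifree <- match(.i_free, sel)
  Ar[ifree, ifree] <- Ar[ifree, ifree] + tum$k_on * tum$C_tubulin
  # solve Ar s = 0 with the normalization s[1] = 1 (central plasma)
  con <- numeric(length(sel)); con[1] <- 1
  B <- rbind(Ar, con)
  rs <- apply(abs(B), 1, max)
  rs[rs == 0] <- 1
  s <- qr.solve(B / rs, c(rep(0, length(sel)), 1) / rs)
  if (any(s < -1e-10 * max(abs(s))))
    stop("stationary solve produced negative concentrations", call. = FALSE)
  # amount constraint: alpha * sum(w s) + V_tumor * bound(alpha * s_free)
  wr <- system$w[sel]
  Vt <- system$V_tumor
  amt <- function(alpha) {
    fr <- alpha * s[ifree]
    sum(wr * alpha * s) + Vt * tum$C_tubulin * fr / (kd + fr)
  }
  if (total_amount == 0) {
    alpha <- 0
  } else {
    hi <- total_amount / sum(wr * s)  # amount(hi) >= total_amount
    alpha <- stats::uniroot(function(a) amt(a) - total_amount,
                            c(0, hi), tol = 1e-14 * hi)$root
  }
  y <- setNames(numeric(.n_state), .state_names)
  y[sel] <- alpha * s
  y[.i_bound] <- tum$C_tubulin * y[.i_free] / (kd + y[.i_free])
  y
}
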