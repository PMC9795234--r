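## Reduced-order cardiovascular-renal-RAAS closure.
##
## Slow ODE states: Na_tot (mEq total exchangeable sodium), V_pv (ml
## pulmonary venous volume), PRC, AngI, AngII (concentrations, model units).
## All other hemodynamic and renal observables are algebraic functions of
## the slow state, solved beat-averaged at each time point. Time unit is
## seconds throughout; physiological rates (GFR, HR, sodium fluxes) are kept
## in their clinical per-minute units and converted at the derivative level.

# internal delta(EDV): bell-shaped ejection-enabling function of EDV
.delta_edv <- function(edv, g) {
  rise <- pmax(0, 1 - exp(-(edv - g$V_u_fill) / g$k_rise))
  fall <- 1 - g$k_fall * pmax(0, edv - g$V_crit)
  pmax(0, rise * pmax(fall, 0))
}

#' Bell-shaped ejection function of end-diastolic volume
#'
#' `delta(EDV)` rises from zero above an unstressed filling volume,
#' saturates, and declines past a critical overdistension volume. Stroke
#' volume is `K * SVmax * delta(EDV)` (Frank-Starling with overload
#' depression).
#'
#' @param edv End-diastolic volume, ml (vectorised, `>= 0`).
#' @param V_u_fill,k_rise,V_crit,k_fall Shape constants (ml, ml, ml, 1/ml).
#' @return Dimensionless value in `[0, 1]`.
#' @export
delta_edv <- function(edv, V_u_fill = 10, k_rise = 60, V_crit = 180,
                      k_fall = 0.002) {
  if (any(edv < 0)) stop("edv must be non-negative")
  .delta_edv(edv, list(V_u_fill = V_u_fill, k_rise = k_rise,
                       V_crit = V_crit, k_fall = k_fall))
}

# bounded sympathetic drive s(H) in (-1, 1)
.s_of_h <- function(dH, k_H) 2 / (1 + exp(-k_H * dH)) - 1

#' Sympathetic inotropic sensitivity
#'
#' `sigma(H, K0) = s(H) * (0.8 - K0) / 0.6`, where `s` is a bounded sigmoid
#' of the neurohumoral factor `H` centred at its neutral value. The scaling
#' gives depressed ventricles (`K0` low) the largest adaptive headroom and
#' vanishes at `K0 = 0.8`, so the effective inotropic coefficient
#' `K = K0 + 0.25 * sigma` stays inside (0, 1).
#'
#' @param H Neurohumoral factor (dimensionless).
#' @param K0 Ventricular inotropic state in `[0.2, 0.8]`.
#' @param H0 Neutral value of `H`.
#' @param k_H Sigmoid slope.
#' @return Dimensionless sigma in `(-1, 1)`.
#' @export
sigma_inotropy <- function(H, K0, H0 = 1, k_H = 2) {
  if (any(K0 < 0.2) || any(K0 > 0.8)) stop("K0 must lie in [0.2, 0.8]")
  .s_of_h(H - H0, k_H) * (0.8 - K0) / 0.6
}

#' Frank-Starling stroke volume
#'
#' `SV = (K0 + 0.25 * sigma(H, K0)) * SVmax * delta(EDV)`. At the neutral
#' neurohumoral drive the curve is `K0 * SVmax * delta(EDV)`; increasing
#' `K0` shifts the SV-EDV curve upward pointwise.
#'
#' @param edv End-diastolic volume, ml.
#' @param K0 Inotropic state in `[0.2, 0.8]`.
#' @param H Neurohumoral factor.
#' @param SVmax Theoretical maximum stroke volume, ml (200 ml for 70 kg).
#' @param H0,k_H Neutral value and slope of the sympathetic sigmoid.
#' @return Stroke volume, ml.
#' @export
frank_starling_sv <- function(edv, K0, H = 1, SVmax = 200, H0 = 1, k_H = 2) {
  K <- K0 + 0.25 * sigma_inotropy(H, K0, H0, k_H)
  K * SVmax * delta_edv(edv)
}

# ---------------------------------------------------------------------------
# algebraic closure at a given slow state

# AT1-bound angiotensin II relative to baseline
.at1_ratio <- function(AngII, pd, params) {
  (1 - pd[["ARB"]]) * AngII / params$AngII0
}

# hemodynamic observables for a trial MAP; returns list with residual
.hemo_at_map <- function(MAP, state, params, pd, AT1r) {
  p <- params
  AT1r <- min(max(AT1r, 0.02), 3)
  S <- p$S0 * (1 - pd[["Bblocker"]]) * (1 - pd[["Diureticstress"]]) *
    (1 + p$sl_stress * (AT1r - 1))
  S <- max(S, 0.02 * p$S0)
  dH <- p$g_b * ((p$MAP_set - MAP) / p$MAP_set) *
    (1 + p$sl_baro * (AT1r - 1)) + p$g_s * (S - p$S0) / p$S0
  dH <- p$dH_max * tanh(dH / p$dH_max)
  HR <- max(p$HR_base * (1 + p$alpha_H * dH + p$beta_S * (S - p$S0) / p$S0), 25)
  ECFV <- state[["Na_tot"]] / p$Na_conc                   # L
  Vb   <- 1000 * p$f_plasma * ECFV / (1 - p$Hct)          # ml
  CVP  <- (Vb - p$Ca * MAP - state[["V_pv"]] - p$Vu) / p$Cv
  PVP  <- (state[["V_pv"]] - p$V_pv_u) / p$Cpv
  EDV_L <- p$EDV_cap * (1 - exp(-max(PVP + p$fill_off, 0) / p$Pfill_L))
  EDV_R <- p$EDV_cap * (1 - exp(-max(CVP + p$fill_off, 0) / p$Pfill_R))
  s  <- .s_of_h(dH, p$k_H)
  KL <- min(max(p$KL0 + 0.25 * s * (0.8 - p$KL0) / 0.6, 0.05), 0.95)
  KR <- min(max(p$KR0 + 0.25 * s * (0.8 - p$KR0) / 0.6, 0.05), 0.95)
  SV_L <- KL * p$SVmax * .delta_edv(EDV_L, p)
  SV_R <- KR * p$SVmax * .delta_edv(EDV_R, p)
  auto <- (max(HR * SV_L, 200) / (1000 * p$CO0))^p$a_auto *
    ((max(CVP, -4) + 6) / (p$CVP0 + 6))^p$a_vol
  SVR_eff <- p$R_micro0 * (1 - pd[["CCBsys"]]) * (1 - pd[["Diureticsys"]]) *
    (1 + p$g_H * dH) * max(0.3, 1 + p$g_ANG * (AT1r - 1)) * auto
  SVR_eff <- max(SVR_eff, 1e-4)
  list(residual = MAP - (HR * SV_L * SVR_eff + CVP),
       H = p$H0 + dH, S = S, HR = HR, SVR_eff = SVR_eff,
       ECFV = ECFV, V_blood = Vb / 1000, CVP = CVP, PVP = PVP,
       EDV_L = EDV_L, EDV_R = EDV_R, SV_L = SV_L, SV_R = SV_R,
       KL = KL, KR = KR)
}

# scalar fast path of the closure: returns c(residual, HR, SV_L, SV_R,
# CVP, PVP) without building lists (hot loop of the integrator)
.hemo_core <- function(MAP, state, p, pd, AT1r) {
  AT1r <- min(max(AT1r, 0.02), 3)
  S <- p$S0 * (1 - pd[["Bblocker"]]) * (1 - pd[["Diureticstress"]]) *
    (1 + p$sl_stress * (AT1r - 1))
  if (S < 0.02 * p$S0) S <- 0.02 * p$S0
  dS <- (S - p$S0) / p$S0
  dH <- p$g_b * ((p$MAP_set - MAP) / p$MAP_set) *
    (1 + p$sl_baro * (AT1r - 1)) + p$g_s * dS
  dH <- p$dH_max * tanh(dH / p$dH_max)
  HR <- p$HR_base * (1 + p$alpha_H * dH + p$beta_S * dS)
  if (HR < 25) HR <- 25
  Vb <- 1000 * p$f_plasma * (state[["Na_tot"]] / p$Na_conc) / (1 - p$Hct)
  CVP <- (Vb - p$Ca * MAP - state[["V_pv"]] - p$Vu) / p$Cv
  PVP <- (state[["V_pv"]] - p$V_pv_u) / p$Cpv
  pl <- PVP + p$fill_off; if (pl < 0) pl <- 0
  pr <- CVP + p$fill_off; if (pr < 0) pr <- 0
  EDV_L <- p$EDV_cap * (1 - exp(-pl / p$Pfill_L))
  EDV_R <- p$EDV_cap * (1 - exp(-pr / p$Pfill_R))
  s <- 2 / (1 + exp(-p$k_H * dH)) - 1
  KL <- p$KL0 + 0.25 * s * (0.8 - p$KL0) / 0.6
  if (KL < 0.05) KL <- 0.05 else if (KL > 0.95) KL <- 0.95
  KR <- p$KR0 + 0.25 * s * (0.8 - p$KR0) / 0.6
  if (KR < 0.05) KR <- 0.05 else if (KR > 0.95) KR <- 0.95
  rise <- 1 - exp(-(EDV_L - p$V_u_fill) / p$k_rise)
  if (rise < 0) rise <- 0
  fall <- 1 - p$k_fall * (if (EDV_L > p$V_crit) EDV_L - p$V_crit else 0)
  if (fall < 0) fall <- 0
  SV_L <- KL * p$SVmax * rise * fall
  rise_r <- 1 - exp(-(EDV_R - p$V_u_fill) / p$k_rise)
  if (rise_r < 0) rise_r <- 0
  fall_r <- 1 - p$k_fall * (if (EDV_R > p$V_crit) EDV_R - p$V_crit else 0)
  if (fall_r < 0) fall_r <- 0
  SV_R <- KR * p$SVmax * rise_r * fall_r
  auto <- (max(HR * SV_L, 200) / (1000 * p$CO0))^p$a_auto *
    ((max(CVP, -4) + 6) / (p$CVP0 + 6))^p$a_vol
  SVR_eff <- p$R_micro0 * (1 - pd[["CCBsys"]]) * (1 - pd[["Diureticsys"]]) *
    (1 + p$g_H * dH) * max(0.3, 1 + p$g_ANG * (AT1r - 1)) * auto
  if (SVR_eff < 1e-4) SVR_eff <- 1e-4
  c(MAP - (HR * SV_L * SVR_eff + CVP), HR, SV_L, SV_R, CVP, PVP)
}

.hemo_resid <- function(MAP, state, p, pd, AT1r) {
  .hemo_core(MAP, state, p, pd, AT1r)[1]
}

# solve the MAP root on the fast path; returns the .hemo_core vector
.solve_map_core <- function(state, p, pd, AT1r, hint) {
  m1 <- hint; c1 <- .hemo_core(m1, state, p, pd, AT1r); f1 <- c1[1]
  if (abs(f1) < 1e-9) return(c(c1, m1))
  m2 <- m1 + 1; c2 <- .hemo_core(m2, state, p, pd, AT1r); f2 <- c2[1]
  for (it in 1:25) {
    if (!is.finite(f1) || !is.finite(f2) || f2 == f1) break
    m3 <- m2 - f2 * (m2 - m1) / (f2 - f1)
    if (!is.finite(m3) || m3 < 5 || m3 > 350) break
    m1 <- m2; f1 <- f2
    m2 <- m3; c2 <- .hemo_core(m2, state, p, pd, AT1r); f2 <- c2[1]
    if (abs(f2) < 1e-10 * max(1, abs(m2))) return(c(c2, m2))
  }
  # bracketed fallback
  f <- function(m) .hemo_core(m, state, p, pd, AT1r)[1]
  lo <- 5; hi <- 350
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    # far off the physiological manifold (circulatory collapse): take the
    # pressure with the smallest closure residual so trajectories remain
    # integrable up to and beyond shock detection
    grid <- seq(5, 350, by = 5)
    r <- vapply(grid, f, numeric(1))
    MAP <- grid[which.min(abs(r))]
    return(c(.hemo_core(MAP, state, p, pd, AT1r), MAP))
  }
  MAP <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                        tol = 1e-10)$root
  c(.hemo_core(MAP, state, p, pd, AT1r), MAP)
}

# fast scalar derivatives: numeric d(state)/dt with attr "MAP"
.deriv_fast <- function(state, p, pd, hint) {
  AT1r <- (1 - pd[["ARB"]]) * state[["AngII"]] / p$AngII0
  core <- .solve_map_core(state, p, pd, AT1r, hint)
  HR <- core[2]; SV_L <- core[3]; SV_R <- core[4]; CVP <- core[5]
  MAP <- core[7]
  # renal block
  MAPr <- if (MAP <= p$P_out + 1) p$P_out + 1 else MAP
  AT1c <- min(max(AT1r, 0.02), 8)
  ALD_r <- AT1c^p$p_ald * (1 - pd[["Diureticpotassium"]])^p$q_ald
  myo <- (MAPr / p$MAP_set)^p$a_myo
  R_pre <- p$R_pre0 * (1 - pd[["CCBpreglom"]]) * (1 - pd[["Diureticpreglom"]]) * myo
  R_aa <- p$R_aa0 * (1 - pd[["CCBaa"]]) * (1 - pd[["Diureticaa"]]) * myo * AT1c^p$c_aa
  R_ea <- p$R_ea0 * (1 - pd[["CCBea"]]) * (1 - pd[["Diureticea"]]) * AT1c^p$c_ea
  RBF <- (MAPr - p$P_out) / (R_pre + R_aa + R_ea)
  Pglom <- MAPr - RBF * (R_pre + R_aa)
  GFR <- p$KfG0 * max(0.05, 1 - p$sl_KFG * (AT1r - 1)) * max(Pglom - p$P_filt, 0)
  P_aa <- MAPr - RBF * R_pre
  s_px <- if (AT1c > 1) p$g_px_hi else p$g_px
  u_px <- (1 - p$f_prox0) * min(max(1 - s_px * (AT1c - 1), 0.05), 3)
  NaDel <- max(GFR * p$Na_conc / 1000 * u_px, 1e-9)
  f_thz <- p$f_thz0 * (1 - pd[["DiureticInhibition"]])
  s_ald <- if (ALD_r > 1) p$g_ald_hi else p$g_ald
  u_fine <- (1 - p$f_fine0) * min(max(1 - s_ald * (ALD_r - 1), 0.05), 3)
  Na_exc <- NaDel * (1 - f_thz) * u_fine * (MAPr / p$MAP_set)^p$a_pn
  # RAAS cascade (P_aa >= P_out by the series divider; NaDel floored)
  if (P_aa <= 0) P_aa <- 1e-3
  x <- p$n1 * log(p$P_aa_ref / P_aa) + p$n2 * log(p$NaDel_ref / NaDel) +
    p$n3 * log((p$CVP0 + 6) / (max(CVP, -4) + 6))
  mult <- exp(p$r_cap * tanh(x / p$r_cap))
  R_sec <- p$k_PRC * p$PRC0 * (1 - pd[["Bblocker_rs"]]) *
    (1 + pd[["DiureticStimulation"]]) * mult
  PRA <- (p$PRA0 / p$PRC0) * state[["PRC"]] * (1 - pd[["DRI"]])
  k_angI <- p$PRA0 / p$AngI0
  k_ACE <- 0.9 * k_angI; k_nonACE <- 0.1 * k_angI
  k_angII <- 0.9 * p$PRA0 / p$AngII0
  d <- c(Na_tot = (p$Phi_sod_in - Na_exc) / 60,
         V_pv = HR * (SV_R - SV_L) / 60,
         PRC = R_sec - p$k_PRC * state[["PRC"]],
         AngI = PRA - (k_ACE * (1 - pd[["ACEi"]]) + k_nonACE) * state[["AngI"]],
         AngII = k_ACE * (1 - pd[["ACEi"]]) * state[["AngI"]] -
           (0.25 * k_angII * (1 - pd[["ARB"]]) + 0.75 * k_angII) * state[["AngII"]])
  attr(d, "MAP") <- MAP
  d
}


#' Beat-averaged hemodynamic closure
#'
#' Solves the algebraic fixed point of the systemic circulation at a given
#' slow state: mean arterial pressure is the unique root of
#' `MAP = HR * SV_L * SVR_eff + CVP`, with the baroreflex-driven
#' neurohumoral factor, ventricular filling and Frank-Starling ejection all
#' evaluated consistently at that pressure.
#'
#' @param state Named slow-state vector (see [baseline_state()]).
#' @param params A `vp_params` object.
#' @param pd Pharmacodynamic effect vector (see [pd_zero()]).
#' @param map_hint Optional starting pressure for the warm-started root
#'   iteration.
#' @return List of hemodynamic observables including `MAP`, `HR`, `SV_L`,
#'   `SV_R`, `CVP`, `PVP`, `EDV_L`, `EDV_R`, `H`.
#' @export
hemodynamic_closure <- function(state, params, pd = pd_zero(),
                                map_hint = NULL) {
  AT1r <- .at1_ratio(state[["AngII"]], pd, params)
  f <- function(m) .hemo_resid(m, state, params, pd, AT1r)
  MAP <- NA_real_
  if (!is.null(map_hint) && is.finite(map_hint)) {
    # secant iteration from the hint (residual is smooth and decreasing)
    m1 <- map_hint; m2 <- map_hint + 1
    f1 <- f(m1); f2 <- f(m2)
    for (it in 1:20) {
      if (!is.finite(f1) || !is.finite(f2) || f2 == f1) break
      m3 <- m2 - f2 * (m2 - m1) / (f2 - f1)
      if (!is.finite(m3) || m3 < 5 || m3 > 350) break
      m1 <- m2; f1 <- f2; m2 <- m3; f2 <- f(m3)
      if (abs(f2) < 1e-10 * max(1, abs(m2))) { MAP <- m2; break }
    }
  }
  if (!is.finite(MAP)) {
    # bracketed fallback; residual is decreasing in MAP
    lo <- max(10, params$MAP_set - 70); hi <- params$MAP_set + 70
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      lo <- 5; hi <- 350
      flo <- f(lo); fhi <- f(hi)
    }
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      grid <- seq(5, 350, by = 5)
      r <- vapply(grid, f, numeric(1))
      MAP <- grid[which.min(abs(r))]
    } else {
      MAP <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                            tol = 1e-10)$root
    }
  }
  out <- .hemo_at_map(MAP, state, params, pd, AT1r)
  out$MAP <- MAP
  out$AT1r <- AT1r
  out
}

#' Renal fluxes at a given pressure and state
#'
#' Series resistance divider over preglomerular, afferent and efferent
#' segments with myogenic preglomerular autoregulation and mild AT1
#' sensitivity of the arterioles; glomerular filtration from the net
#' filtration pressure; proximal/distal fractional sodium handling with
#' AT1- and aldosterone-dependent reabsorption and the diuretic inhibition
#' site on the distal fraction.
#'
#' @param state Slow-state vector.
#' @param params `vp_params`.
#' @param pd Effect vector.
#' @param MAP Mean arterial pressure, mmHg.
#' @return List with `GFR`, `RBF` (ml/min), `RVR` (mmHg min/ml),
#'   `Na_excretion`, `NaDel` (mEq/min), `P_aa` (mmHg), `FF` (percent),
#'   `ALD_r`, `f_prox_eff`, `f_dist_eff`.
#' @export
renal_fluxes <- function(state, params, pd = pd_zero(), MAP) {
  p <- params
  if (MAP <= p$P_out + 1) MAP <- p$P_out + 1   # degenerate hypotension guard
  AT1r <- .at1_ratio(state[["AngII"]], pd, params)
  AT1c <- min(max(AT1r, 0.02), 8)
  ALD_r <- AT1c^p$p_ald * (1 - pd[["Diureticpotassium"]])^p$q_ald
  myo  <- (MAP / p$MAP_set)^p$a_myo
  R_pre <- p$R_pre0 * (1 - pd[["CCBpreglom"]]) * (1 - pd[["Diureticpreglom"]]) * myo
  R_aa  <- p$R_aa0 * (1 - pd[["CCBaa"]]) * (1 - pd[["Diureticaa"]]) *
    myo * AT1c^p$c_aa
  R_ea  <- p$R_ea0 * (1 - pd[["CCBea"]]) * (1 - pd[["Diureticea"]]) * AT1c^p$c_ea
  if (R_pre <= 0 || R_aa <= 0 || R_ea <= 0)
    stop("negative renal resistance after drug application")
  RBF  <- (MAP - p$P_out) / (R_pre + R_aa + R_ea)
  Pglom <- MAP - RBF * (R_pre + R_aa)
  GFR  <- p$KfG0 * max(0.05, 1 - p$sl_KFG * (AT1r - 1)) * max(Pglom - p$P_filt, 0)
  P_aa <- MAP - RBF * R_pre
  # AT1 and aldosterone scale the escaping (unreabsorbed) fractions, which
  # keeps their natriuretic loop gains of clinical size
  s_px <- if (AT1c > 1) p$g_px_hi else p$g_px
  u_px <- (1 - p$f_prox0) * min(max(1 - s_px * (AT1c - 1), 0.05), 3)
  f_px <- 1 - u_px
  NaDel <- max(GFR * p$Na_conc / 1000 * u_px, 1e-9)
  # thiazide-sensitive distal segment, then aldosterone-regulated fine
  # tuning; the retention slope for aldosterone excess is flatter than the
  # natriuresis slope for deficit (mineralocorticoid escape)
  f_thz <- p$f_thz0 * (1 - pd[["DiureticInhibition"]])
  s_ald <- if (ALD_r > 1) p$g_ald_hi else p$g_ald
  u_fine <- (1 - p$f_fine0) * min(max(1 - s_ald * (ALD_r - 1), 0.05), 3)
  f_fine <- 1 - u_fine
  f_dist <- 1 - (1 - f_thz) * (1 - f_fine)
  pn <- (MAP / p$MAP_set)^p$a_pn   # direct pressure natriuresis
  list(GFR = GFR, RBF = RBF, RVR = (MAP - p$P_out) / RBF,
       Na_excretion = NaDel * (1 - f_thz) * u_fine * pn, NaDel = NaDel,
       P_aa = P_aa, P_glom = Pglom, R_aa = R_aa,
       FF = GFR / (RBF * (1 - p$Hct)) * 100,
       ALD_r = ALD_r, AT1r = AT1r, f_prox_eff = f_px, f_dist_eff = f_dist)
}

#' Renin-angiotensin-aldosterone cascade rates
#'
#' Renin secretion responds to afferent-arteriolar pressure and distal
#' sodium delivery through a bounded log-linear multiplier and carries the
#' beta-blocker and diuretic secretion effects; plasma renin activity is
#' proportional to renin with the direct renin inhibition site; angiotensin
#' I and II turn over through ACE-dependent (inhibitable) and independent
#' routes. All rate constants are derived from the declared baselines so
#' the drug-free steady state is stationary by construction.
#'
#' @param state Slow-state vector.
#' @param params `vp_params`.
#' @param pd Effect vector.
#' @param signals List with `P_aa` (mmHg) and `NaDel` (mEq/min).
#' @return List with derivatives `dPRC`, `dAngI`, `dAngII` (per second) and
#'   the instantaneous `PRA`, `AT1B`, `ALD`.
#' @export
raas_rates <- function(state, params, pd = pd_zero(), signals) {
  p <- params
  if (signals$P_aa <= 0 || signals$NaDel <= 0)
    stop("renal signals must be positive")
  x <- p$n1 * log(p$P_aa_ref / signals$P_aa) +
       p$n2 * log(p$NaDel_ref / signals$NaDel)
  if (!is.null(signals$CVP)) {
    # cardiopulmonary volume receptors (ANP-like): central filling
    # suppresses renin; shifted log keeps the signal defined at low CVP
    x <- x + p$n3 * log((p$CVP0 + 6) / (max(signals$CVP, -4) + 6))
  }
  mult <- exp(p$r_cap * tanh(x / p$r_cap))
  R_sec <- p$k_PRC * p$PRC0 * (1 - pd[["Bblocker_rs"]]) *
    (1 + pd[["DiureticStimulation"]]) * mult
  k_act <- p$PRA0 / p$PRC0
  PRA <- k_act * state[["PRC"]] * (1 - pd[["DRI"]])
  k_angI <- p$PRA0 / p$AngI0
  k_ACE <- 0.9 * k_angI; k_nonACE <- 0.1 * k_angI
  k_angII <- 0.9 * p$PRA0 / p$AngII0
  k_AT1 <- 0.25 * k_angII; k_deg <- 0.75 * k_angII
  dAngI  <- PRA - (k_ACE * (1 - pd[["ACEi"]]) + k_nonACE) * state[["AngI"]]
  dAngII <- k_ACE * (1 - pd[["ACEi"]]) * state[["AngI"]] -
    (k_AT1 * (1 - pd[["ARB"]]) + k_deg) * state[["AngII"]]
  AT1r <- .at1_ratio(state[["AngII"]], pd, params)
  out <- list(dPRC = R_sec - p$k_PRC * state[["PRC"]],
              dAngI = dAngI, dAngII = dAngII,
              PRA = PRA, AT1B = p$AT1B0 * AT1r,
              ALD = p$ALD0 * min(max(AT1r, 0.02), 8)^p$p_ald *
                (1 - pd[["Diureticpotassium"]])^p$q_ald,
              renin_mult = mult)
  if (any(!is.finite(unlist(out[c("dPRC", "dAngI", "dAngII")]))))
    stop("non-finite RAAS rates; state: ",
         paste(signif(state, 4), collapse = ", "))
  out
}

#' Time derivatives of the slow states
#'
#' Assembles the hemodynamic closure, the renal fluxes and the RAAS cascade
#' into `d(state)/dt` in per-second units: sodium mass balance
#' (`intake - excretion`), pulmonary venous volume balance
#' (`HR * (SV_R - SV_L)`), and the three cascade species.
#'
#' @param state Slow-state vector.
#' @param params `vp_params`.
#' @param pd Effect vector.
#' @param map_hint Optional starting pressure for the hemodynamic root
#'   iteration.
#' @return Named derivative vector (1/s), with the full observable list as
#'   attribute `"obs"`.
#' @export
derivatives <- function(state, params, pd = pd_zero(), map_hint = NULL) {
  h <- hemodynamic_closure(state, params, pd, map_hint = map_hint)
  r <- renal_fluxes(state, params, pd, h$MAP)
  rr <- raas_rates(state, params, pd,
                   signals = list(P_aa = r$P_aa, NaDel = r$NaDel,
                                  CVP = h$CVP))
  d <- c(Na_tot = (params$Phi_sod_in - r$Na_excretion) / 60,
         V_pv   = h$HR * (h$SV_R - h$SV_L) / 60,
         PRC    = rr$dPRC,
         AngI   = rr$dAngI,
         AngII  = rr$dAngII)
  if (any(!is.finite(d)))
    stop("non-finite derivatives; state: ",
         paste(signif(state, 4), collapse = ", "))
  attr(d, "obs") <- list(hemo = h, renal = r, raas = rr)
  d
}

# Full clinical observable set at a slow state.
.observables <- function(state, params, pd = pd_zero(), map_hint = NULL) {
  h <- hemodynamic_closure(state, params, pd, map_hint = map_hint)
  r <- renal_fluxes(state, params, pd, h$MAP)
  rr <- raas_rates(state, params, pd,
                   signals = list(P_aa = r$P_aa, NaDel = r$NaDel,
                                  CVP = h$CVP))
  PP <- h$SV_L / params$Ca
  SBP <- h$MAP + 2 * PP / 3
  DBP <- h$MAP - PP / 3
  CO <- h$HR * h$SV_L / 1000                       # L/min
  c(SBP = SBP, DBP = DBP, MAP = h$MAP, PP = PP,
    CVP = h$CVP, PVP = h$PVP, LVEDP = h$PVP,
    LVPSP = SBP + params$dP_valve,
    HR = h$HR, SV = h$SV_L, EDV = h$EDV_L, ESV = h$EDV_L - h$SV_L,
    EF = h$SV_L / h$EDV_L * 100, CO = CO,
    SVR = 80 * (h$MAP - h$CVP) / CO,               # dyn s / cm^5
    ECFV = h$ECFV, V_blood = h$V_blood,
    GFR = r$GFR, RBF = r$RBF, RVR = r$RVR, FF = r$FF,
    R_aa = r$R_aa,
    PRA = rr$PRA, PRC = state[["PRC"]],
    AngI = state[["AngI"]], AngII = state[["AngII"]],
    AT1B = rr$AT1B, ALD = rr$ALD,
    Na_excretion = r$Na_excretion, H = h$H,
    Urea = params$Urea * (1 + pd[["Diureticurea"]]),
    K_blood = params$K_blood * (1 - pd[["Diureticpotassium"]]))
}

#' Equilibrium state under a drug regimen
#'
#' Solves `derivatives = 0` by damped Newton iteration on the five slow
#' states (finite-difference Jacobian), with the HCTZ systemic ramp at its
#' saturated value. The search is seeded from the supplied state (by default
#' the constructed drug-free baseline). Fails with an error when the
#' residual cannot be brought below tolerance, which the patient generator
#' treats as a rejected draw.
#'
#' @param params `vp_params`.
#' @param regimen A [drug_regimen()] (default untreated).
#' @param start Optional starting slow state.
#' @param gains Optional per-drug gain multipliers.
#' @param tol Residual tolerance on the scaled derivative norm.
#' @param max_iter Newton iteration cap.
#' @param check_physio Reject equilibria on the congested (volume-overload)
#'   branch (default `TRUE`).
#' @return List with `state` (slow states), `obs` (named observable vector)
#'   and `residual`.
#' @export
find_equilibrium <- function(params, regimen = drug_regimen(), start = NULL,
                             gains = NULL, tol = 1e-9, max_iter = 60,
                             check_physio = TRUE) {
  pd <- regimen_effects(regimen, t = Inf, gains = gains)
  x0 <- baseline_state(params)
  x <- if (is.null(start)) x0 else start
  sc <- pmax(abs(x0), 1)                       # state scale for residuals
  hint_env <- new.env(); hint_env$map <- params$MAP_set
  f <- function(x) {
    d <- .deriv_fast(x, params, pd, hint_env$map)
    hint_env$map <- attr(d, "MAP")
    as.numeric(d) * c(60, 60, 1e3, 1e3, 1e3)
  }
  nrm <- function(v) sqrt(mean((v / sc)^2))
  plausible <- function(x) {
    # reject the congested (volume-overloaded, overdistended) branch
    x[["Na_tot"]] < 1.5 * x0[["Na_tot"]] && x[["Na_tot"]] > 0.4 * x0[["Na_tot"]] &&
      (x[["V_pv"]] - params$V_pv_u) / params$Cpv < 30
  }
  newton <- function(x, fx) {
    for (it in seq_len(max_iter)) {
      if (nrm(fx) < tol) break
      J <- matrix(0, 5, 5)
      hstep <- pmax(abs(x), sc * 1e-3) * 1e-6
      for (j in 1:5) {
        xp <- x; xp[j] <- xp[j] + hstep[j]
        fj <- tryCatch(f(xp), error = function(e) NULL)
        if (is.null(fj)) return(list(x = x, fx = fx, ok = FALSE))
        J[, j] <- (fj - fx) / hstep[j]
      }
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, fx = fx, ok = FALSE))
      cap <- 0.1 * sc                          # trust region
      over <- max(abs(step) / cap)
      if (over > 1) step <- step / over
      lambda <- 1; improved <- FALSE
      while (lambda >= 1e-6) {
        xn <- pmax(x + lambda * step, c(1, 0.1, 1e-6, 1e-6, 1e-6))
        fn <- tryCatch(f(xn), error = function(e) NULL)
        if (!is.null(fn) && nrm(fn) < nrm(fx) * (1 - 1e-4 * lambda)) {
          x <- xn; fx <- fn; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!improved) return(list(x = x, fx = fx, ok = FALSE))
    }
    list(x = x, fx = fx, ok = nrm(fx) < tol)
  }
  fx <- f(x)
  sol <- newton(x, fx)
  good <- sol$ok && (!check_physio || plausible(sol$x))
  if (!good) {
    # relax along the physical branch, then polish
    deriv <- function(t, y, parms) {
      d <- .deriv_fast(y, params, pd, hint_env$map)
      hint_env$map <- attr(d, "MAP")
      list(as.numeric(d))
    }
    t_seg <- 2e6
    for (seg in 1:6) {
      ode <- try(suppressWarnings(
        deSolve::lsoda(y = x, times = c(0, t_seg / 2, t_seg),
                       func = deriv, parms = NULL, rtol = 1e-6,
                       atol = c(1e-4, 1e-4, 1e-9, 1e-9, 1e-9),
                       maxsteps = 20000)), silent = TRUE)
      if (inherits(ode, "try-error") || attr(ode, "istate")[1] < 0) break
      x_new <- ode[nrow(ode), -1]
      fx_new <- tryCatch(f(x_new), error = function(e) NULL)
      if (is.null(fx_new)) break
      x <- x_new; fx <- fx_new
      if (nrm(fx) < 1e-7) break
      t_seg <- t_seg * 2
    }
    sol <- newton(x, fx)
    good <- sol$ok && (!check_physio || plausible(sol$x))
  }
  if (!sol$ok)
    stop("no equilibrium found (residual ", signif(nrm(sol$fx), 3), ")")
  if (!good)
    stop("equilibrium rejected: pulmonary congestion / volume overload branch")
  list(state = sol$x, obs = .observables(sol$x, params, pd),
       residual = nrm(sol$fx))
}

#' Simulate the model through time
#'
#' Integrates the slow states with a stiff ODE solver, evaluating the
#' regimen's pharmacodynamic effects at every time point so the HCTZ
#' systemic ramp is time-resolved.
#'
#' @param params `vp_params`.
#' @param regimen A [drug_regimen()].
#' @param t_end End time in seconds (4 weeks = 2,419,200 s).
#' @param n_out Number of output points.
#' @param start Optional starting slow state (default the constructed
#'   baseline).
#' @param gains Optional per-drug gain multipliers.
#' @return Object of class `vp_trajectory`: a data.frame with `time`, the
#'   slow states and all observables.
#' @export
simulate_patient <- function(params, regimen = drug_regimen(),
                             t_end = 2419200, n_out = 101, start = NULL,
                             gains = NULL) {
  if (t_end <= 0) stop("t_end must be positive")
  x0 <- if (is.null(start)) baseline_state(params) else start
  hint_env <- new.env(); hint_env$map <- params$MAP_set
  has_ramp <- !is.null(regimen) && nrow(regimen) > 0 &&
    any(regimen$drug == "hctz" & regimen$indicator == 1)
  pd_const <- regimen_effects(regimen, t = 0, gains = gains)
  deriv <- function(t, y, parms) {
    pd <- if (has_ramp) regimen_effects(regimen, t = t, gains = gains)
          else pd_const
    d <- .deriv_fast(y, params, pd, hint_env$map)
    hint_env$map <- attr(d, "MAP")
    list(as.numeric(d))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsoda(y = x0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-6, atol = c(1e-3, 1e-3, 1e-8, 1e-8, 1e-8))
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, "time"]))
  obs <- t(vapply(seq_len(nrow(sol)), function(i) {
    pd <- if (has_ramp) regimen_effects(regimen, t = sol[i, "time"],
                                        gains = gains) else pd_const
    .observables(sol[i, -1], params, pd, map_hint = hint_env$map)
  }, numeric(length(.observables(x0, params)))))
  out <- cbind(as.data.frame(unclass(sol)), as.data.frame(obs))
  class(out) <- c("vp_trajectory", "data.frame")
  out
}

#' Detect cardiogenic shock on a trajectory
#'
#' Hemodynamic criteria: systolic blood pressure below 90 mmHg continuously
#' for at least 30 minutes, with cardiac index below 2.2 L/min/m^2 and
#' pulmonary venous pressure above 15 mmHg over the same window. Body
#' surface area uses the Du Bois formula
#' `0.007184 * weight^0.425 * height^0.725`.
#'
#' @param traj A `vp_trajectory` covering at least 30 min of model time.
#' @param params `vp_params` (provides weight and height).
#' @return List with `shock` (logical) and `onset` (seconds, `NA` when no
#'   shock), where onset is the end of the first qualifying 30-min window.
#' @export
detect_cardiogenic_shock <- function(traj, params) {
  if (is.null(params$weight) || is.null(params$height))
    stop("weight and height required for body surface area")
  if (max(traj$time) - min(traj$time) < 1800)
    stop("trajectory must cover at least 30 minutes")
  bsa <- 0.007184 * params$weight^0.425 * params$height^0.725
  ci <- traj$CO / bsa
  cond <- traj$SBP < 90 & ci < 2.2 & traj$PVP > 15
  t <- traj$time
  run_start <- NA_real_
  for (i in seq_along(cond)) {
    if (cond[i]) {
      if (is.na(run_start)) run_start <- t[i]
      if (t[i] - run_start >= 1800)
        return(list(shock = TRUE, onset = t[i]))
    } else run_start <- NA_real_
  }
  list(shock = FALSE, onset = NA_real_)
}
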