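#' Nadler total blood volume
#'
#' Classical regression of total blood volume on height and weight:
#' males `0.3669 h^3 + 0.03219 w + 0.6041`, females
#' `0.3561 h^3 + 0.03308 w + 0.1833`, with `h` in metres and `w` in kg.
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @param sex `"M"` or `"F"`.
#' @return Total blood volume in litres.
#' @export
nadler_blood_volume <- function(height_cm, weight_kg, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  h <- height_cm / 100
  if (sex == "M") 0.3669 * h^3 + 0.03219 * weight_kg + 0.6041
  else            0.3561 * h^3 + 0.03308 * weight_kg + 0.1833
}

# Closure constants shared by all patients: feedback gains, cascade
# exponents and shape parameters of the reduced-order model. Baseline values
# were set once, by hand, so that the drug-free model reproduces textbook
# hemodynamics and the calibrated drug layer reproduces the expected
# directional physiology (see the methods vignette).
.default_gains <- function() {
  list(
    g_b     = 2.0,    # baroreflex gain on the neurohumoral factor H
    alpha_H = 0.35,   # chronotropic sensitivity of HR to H
    beta_S  = 0.75,   # direct chronotropic gain of stress-receptor activity
    g_s     = 1.2,    # stress-receptor drive on H
    g_H     = 0.3,    # sympathetic vasoconstriction gain on SVR
    k_H     = 0.8,    # slope of the inotropic sigmoid s(H)
    g_ANG   = 0.40,   # AT1-bound angiotensin II effect on systemic SVR
    g_ald   = 1.4,    # aldosterone-deficit natriuresis slope (escaping distal fraction)
    g_ald_hi = 0.3,   # aldosterone-excess retention slope (escape phenomenon)
    g_px    = 0.3,    # AT1-deficit natriuresis slope (escaping proximal fraction)
    g_px_hi = 0.1,    # AT1-excess retention slope
    p_ald   = 0.70,   # aldosterone ~ AT1B^p_ald
    q_ald   = 8.0,    # aldosterone ~ (K_eff/K_ref)^q_ald (hypokalemia brake)
    n1      = 1.5,    # renin secretion exponent on afferent pressure
    n2      = 0.5,    # renin secretion exponent on distal Na delivery
    n3      = 0.5,    # renin suppression exponent on central venous filling
    r_cap   = 3.0,    # log-scale cap of the renin secretion multiplier
    c_aa    = 0.03,   # afferent resistance ~ AT1r^c_aa
    c_ea    = 0.08,   # efferent resistance ~ AT1r^c_ea (more sensitive)
    a_myo   = 2.0,    # myogenic autoregulation exponent of preglomerular tone
    a_auto  = 0.0,    # whole-body flow autoregulation exponent of systemic tone
    a_vol   = 1.0,    # venous-filling (volume) autoregulation exponent of systemic tone
    a_pn    = 3.5,    # pressure-natriuresis exponent on sodium excretion
    dH_max  = 1.5,    # soft clamp of the neurohumoral excursion
    # Frank-Starling surrogate shape (config-overridable defaults)
    V_u_fill = 10, k_rise = 60, V_crit = 180, k_fall = 0.002,
    EDV_cap = 600,    # saturation of the ventricular filling map, ml
    fill_off = 6,     # filling-pressure offset of the filling map, mmHg
    H0 = 1, S0 = 1,
    P_out = 4,        # renal venous outflow pressure, mmHg
    P_filt = 45,      # Bowman + oncotic opposing pressure, mmHg
    dP_valve = 18,    # LV peak systolic minus systolic arterial pressure
    k_PRC = log(2) / 900   # renin turnover, 1/s (15 min half-life)
  )
}

#' Build a virtual-patient parameter set anchored at an equilibrium
#'
#' Constructs the full parameterization of the reduced-order model such that
#' the drug-free steady state reproduces the supplied clinical targets
#' exactly: resistances, compliances, unstressed volume, inotropic states and
#' tubular fractions are derived from the targets by a fixed-point
#' construction, and the RAAS rate constants are derived from the declared
#' baseline concentrations so that the drug-free cascade is stationary.
#'
#' @param SBP,DBP Systolic/diastolic blood pressure targets, mmHg.
#' @param HR Heart rate target, beats/min.
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @param sex `"M"` or `"F"`.
#' @param Hct Hematocrit (fraction).
#' @param SVR_target Systemic vascular resistance, dyn s/cm^5.
#' @param EF_target Left-ventricular ejection fraction target, percent.
#' @param PVP0,CVP0 Baseline pulmonary venous / central venous pressure, mmHg.
#' @param GFR0 Baseline glomerular filtration rate, ml/min.
#' @param FF0 Baseline filtration fraction (fraction, not percent).
#' @param KfG0 Glomerular filtration coefficient, ml/min/mmHg.
#' @param u_pre Fraction of the preglomerular resistance upstream of the
#'   afferent arteriole.
#' @param f_prox Fractional proximal sodium reabsorption.
#' @param Phi_sod Sodium intake, mEq/min.
#' @param Cv,Cpv Systemic venous / pulmonary venous compliance, ml/mmHg.
#' @param PRA0 Baseline plasma renin activity (model units/s; also the
#'   angiotensin I turnover constant so the cascade is stationary).
#' @param KL0,KR0 Optional ventricular inotropic states; derived from
#'   `EF_target` when `NULL`. Must fall in \[0.2, 0.8\].
#' @param EDV_ratio Right/left end-diastolic volume ratio.
#' @param sl_baro,sl_stress,sl_KFG Neurohumoral sensitivities of the AT1
#'   signal on the baroreflex, the stress receptors and the filtration
#'   coefficient (defaults are the calibrated population means).
#' @param gains Optional list overriding entries of the shared closure
#'   constants.
#' @return An object of class `vp_params`.
#' @export
build_patient <- function(SBP = 160, DBP = 100, HR = 75,
                          weight = 80, height = 170, sex = "M",
                          Hct = 0.43,
                          SVR_target = 1400, EF_target = 62,
                          PVP0 = 8, CVP0 = 4,
                          GFR0 = 105, FF0 = 0.19, KfG0 = 3.5,
                          u_pre = 0.5, f_prox = 0.92, f_thz0 = 0.8, Phi_sod = 0.10,
                          Cv = 120, Cpv = 4.5,
                          PRA0 = log(2) / 60,
                          KL0 = NULL, KR0 = NULL, EDV_ratio = 1,
                          sl_baro = 0.0499, sl_stress = 0.2133,
                          sl_KFG = 0.2015,
                          gains = list()) {
  g <- utils::modifyList(.default_gains(), gains)
  if (DBP >= SBP) stop("DBP must be below SBP")
  PP  <- SBP - DBP
  MAP <- DBP + PP / 3

  # -- systemic hemodynamics ------------------------------------------------
  R_eff <- SVR_target / 80000                 # mmHg * min / ml
  CO_ml <- (MAP - CVP0) / R_eff               # ml/min
  SV    <- CO_ml / HR                         # ml
  Ca    <- SV / PP                            # arterial compliance, ml/mmHg
  SVmax <- 200 * weight / 70
  EDV_L <- SV / (EF_target / 100)
  EDV_R <- EDV_L * EDV_ratio
  dL <- .delta_edv(EDV_L, g); dR <- .delta_edv(EDV_R, g)
  if (is.null(KL0)) KL0 <- SV / (SVmax * dL)
  if (is.null(KR0)) KR0 <- SV / (SVmax * dR)
  if (KL0 < 0.2 || KL0 > 0.8 || KR0 < 0.2 || KR0 > 0.8)
    stop("implied inotropic state outside [0.2, 0.8]; adjust EF_target/SVR_target")
  Pfill_L <- -(PVP0 + g$fill_off) / log(1 - EDV_L / g$EDV_cap)
  Pfill_R <- -(CVP0 + g$fill_off) / log(1 - EDV_R / g$EDV_cap)

  V_blood <- nadler_blood_volume(height, weight, sex)     # L
  ECFV0   <- 0.20 * weight                                # L
  Na_conc <- 142                                          # mEq/L
  f_plasma <- V_blood * (1 - Hct) / ECFV0
  Vb_ml   <- 1000 * V_blood
  V_pv0   <- Cpv * PVP0
  Vu      <- Vb_ml - Ca * MAP - V_pv0 - Cv * CVP0
  if (Vu <= 0) stop("implied unstressed volume non-positive; lower compliances")

  # -- renal block ----------------------------------------------------------
  RBF0  <- GFR0 / (FF0 * (1 - Hct))                       # ml/min
  Pglom <- g$P_filt + GFR0 / KfG0
  if (Pglom >= MAP - 10) stop("implied glomerular pressure too close to MAP")
  R_ea0  <- (Pglom - g$P_out) / RBF0
  R_preg <- (MAP - Pglom) / RBF0
  R_pre0 <- u_pre * R_preg
  R_aa0  <- (1 - u_pre) * R_preg
  NaDel_ref <- GFR0 * Na_conc / 1000 * (1 - f_prox)       # mEq/min
  if (Phi_sod >= NaDel_ref * (1 - f_thz0))
    stop("sodium intake exceeds post-distal delivery")
  f_fine0 <- 1 - Phi_sod / (NaDel_ref * (1 - f_thz0))
  P_aa_ref <- MAP - (MAP - g$P_out) / (R_pre0 + R_aa0 + R_ea0) * R_pre0

  p <- c(list(
    weight = weight, height = height, sex = sex,
    HR_base = HR, MAP_set = MAP, SVmax = SVmax,
    KL0 = KL0, KR0 = KR0, Pfill_L = Pfill_L, Pfill_R = Pfill_R,
    Ca = Ca, Cv = Cv, Cpv = Cpv, Vu = Vu, V_pv_u = 0,
    f_plasma = f_plasma, Hct = Hct, Na_conc = Na_conc,
    K_blood = 4.4, Urea = 30,
    R_micro0 = R_eff,
    R_pre0 = R_pre0, R_aa0 = R_aa0, R_ea0 = R_ea0, KfG0 = KfG0,
    f_prox0 = f_prox, f_thz0 = f_thz0, f_fine0 = f_fine0,
    Phi_sod_in = Phi_sod,
    NaDel_ref = NaDel_ref, P_aa_ref = P_aa_ref,
    PRC0 = 1, PRA0 = PRA0, AngI0 = 1, AngII0 = 1, AT1B0 = 1, ALD0 = 1,
    sl_baro = sl_baro, sl_stress = sl_stress, sl_KFG = sl_KFG,
    # constructed baseline (cached for baseline_state and diagnostics)
    Na_tot0 = ECFV0 * Na_conc, V_pv0 = V_pv0, CVP0 = CVP0, PVP0 = PVP0,
    EDV_L0 = EDV_L, EDV_R0 = EDV_R, SV0 = SV, CO0 = CO_ml / 1000,
    GFR0 = GFR0, RBF0 = RBF0
  ), g)
  class(p) <- "vp_params"
  p
}

#' Baseline model state of a patient
#'
#' The slow states of the model at the constructed drug-free equilibrium:
#' total exchangeable sodium, pulmonary venous volume, and the renin,
#' angiotensin I and angiotensin II concentrations.
#'
#' @param params A `vp_params` object.
#' @return Named numeric vector `c(Na_tot, V_pv, PRC, AngI, AngII)`.
#' @export
baseline_state <- function(params) {
  c(Na_tot = params$Na_tot0,
    V_pv   = params$V_pv0,
    PRC    = params$PRC0,
    AngI   = params$AngI0,
    AngII  = params$AngII0)
}

#' @export
print.vp_params <- function(x, ...) {
  cat("<vp_params> ", x$sex, ", ", x$weight, " kg, ", x$height, " cm; ",
      "MAP_set ", round(x$MAP_set, 1), " mmHg, HR_base ",
      round(x$HR_base, 1), " /min\n", sep = "")
  invisible(x)
}
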