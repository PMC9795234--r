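test_that("delta(EDV) is zero below filling, bounded, and unimodal", {
  expect_identical(delta_edv(c(0, 5, 10)), c(0, 0, 0))
  edv <- seq(0, 400, by = 1)
  d <- delta_edv(edv)
  expect_true(all(d >= 0 & d <= 1))
  # large EDV below the critical volume approaches 1
  expect_gt(delta_edv(179), 0.93)
  # exactly one sign change of the finite-difference slope on [0, 400]
  slope_sign <- sign(diff(d[edv > 10]))
  changes <- sum(diff(slope_sign[slope_sign != 0]) != 0)
  expect_identical(changes, 1L)
})

test_that("sigma vanishes at neutral drive and at K0 = 0.8, grows with H", {
  expect_identical(sigma_inotropy(1, 0.5), 0)
  expect_identical(sigma_inotropy(1.7, 0.8), 0)
  H <- seq(0.2, 1.8, by = 0.05)
  s <- sigma_inotropy(H, 0.4)
  expect_true(all(diff(s) > 0))
  expect_true(all(abs(s) < 1))
  expect_error(sigma_inotropy(1, 0.1), "0.2")
})

test_that("Frank-Starling curves are ordered pointwise by inotropic state", {
  edv <- seq(20, 350, by = 5)
  k0 <- seq(0.2, 0.8, by = 0.1)
  curves <- vapply(k0, function(k) frank_starling_sv(edv, k), numeric(length(edv)))
  for (j in seq_len(length(k0) - 1)) {
    expect_true(all(curves[edv > 12, j + 1] > curves[edv > 12, j]))
  }
  # neutral drive reduces to K0 * SVmax * delta
  expect_equal(frank_starling_sv(150, 0.5, H = 1, SVmax = 200),
               0.5 * 200 * delta_edv(150))
})

test_that("the constructed drug-free baseline is an exact equilibrium", {
  p <- ref_patient()
  d <- derivatives(baseline_state(p), p)
  expect_true(all(abs(as.numeric(d)) < 1e-9))
  eq <- ref_equilibrium()
  expect_lt(eq$residual, 1e-9)
  # construction targets are reproduced exactly
  expect_equal(eq$obs[["SBP"]], 154, tolerance = 1e-8)
  expect_equal(eq$obs[["DBP"]], 101, tolerance = 1e-8)
  expect_equal(eq$obs[["HR"]], 76, tolerance = 1e-8)
})

test_that("equilibrium observables satisfy their defining identities", {
  for (reg in list(drug_regimen(), drug_regimen("enalapril:20"))) {
    eq <- find_equilibrium(ref_patient(), reg,
                           gains = c(enalapril = 0.8),
                           start = ref_equilibrium()$state)
    o <- eq$obs
    expect_equal(o[["EF"]], o[["SV"]] / o[["EDV"]] * 100)
    expect_equal(o[["CO"]], o[["HR"]] * o[["SV"]] / 1000)
    expect_true(o[["DBP"]] < o[["MAP"]] && o[["MAP"]] < o[["SBP"]])
    expect_equal(o[["FF"]], o[["GFR"]] / (o[["RBF"]] * (1 - ref_patient()$Hct)) * 100)
  }
})

test_that("sodium and output balance hold at equilibrium to 1e-6 relative", {
  p <- ref_patient()
  eq <- find_equilibrium(p, drug_regimen("losartan:100"),
                         gains = c(losartan = 0.4),
                         start = ref_equilibrium()$state)
  expect_lt(abs(p$Phi_sod_in - eq$obs[["Na_excretion"]]) / p$Phi_sod_in, 1e-6)
  h <- hemodynamic_closure(eq$state, p,
                           regimen_effects(drug_regimen("losartan:100"), t = Inf,
                                           gains = c(losartan = 0.4)))
  expect_lt(abs(h$SV_L - h$SV_R) / h$SV_L, 1e-6)
})

test_that("RAAS rate constants make the drug-free baseline a fixed point", {
  p <- ref_patient()
  st <- baseline_state(p)
  rr <- raas_rates(st, p, signals = list(P_aa = p$P_aa_ref,
                                         NaDel = p$NaDel_ref, CVP = p$CVP0))
  expect_equal(rr$dPRC, 0, tolerance = 1e-12)
  expect_equal(rr$dAngI, 0, tolerance = 1e-12)
  expect_equal(rr$dAngII, 0, tolerance = 1e-12)
  expect_equal(rr$PRA, p$PRA0)
})

test_that("direct renin inhibition settles PRA at (1-DRI) of baseline at fixed signals", {
  # algebraic steady state of the cascade with signals clamped at reference:
  # secretion is unchanged, so PRC returns to PRC0 and PRA = (1-DRI)*PRA0
  p <- ref_patient()
  pd <- pd_zero(); pd[["DRI"]] <- emax_effect(150)
  st <- baseline_state(p)
  # iterate PRC to its fixed point under clamped signals
  for (i in 1:200) {
    rr <- raas_rates(st, p, pd, signals = list(P_aa = p$P_aa_ref,
                                               NaDel = p$NaDel_ref,
                                               CVP = p$CVP0))
    st[["PRC"]] <- st[["PRC"]] + rr$dPRC / p$k_PRC * 0.5
  }
  rr <- raas_rates(st, p, pd, signals = list(P_aa = p$P_aa_ref,
                                             NaDel = p$NaDel_ref, CVP = p$CVP0))
  expect_equal(rr$PRA / p$PRA0, 1 - emax_effect(150), tolerance = 1e-6)
})

test_that("a drug-free simulation from equilibrium stays constant for 4 weeks", {
  p <- ref_patient()
  tr <- simulate_patient(p, t_end = 2419200, n_out = 15)
  for (v in c("SBP", "DBP", "HR", "MAP", "GFR", "CO"))
    expect_lt(max(abs(tr[[v]] / tr[[v]][1] - 1)), 1e-3)
})

test_that("a 4-week treatment simulation reaches the treated equilibrium", {
  p <- ref_patient()
  g <- c(enalapril = 0.8)
  tr <- simulate_patient(p, drug_regimen("enalapril:20"), t_end = 2419200,
                         n_out = 15, gains = g)
  eq <- find_equilibrium(p, drug_regimen("enalapril:20"), gains = g,
                         start = ref_equilibrium()$state)
  for (v in c("SBP", "DBP", "MAP", "HR"))
    expect_equal(tr[[v]][15], eq$obs[[v]], tolerance = 1e-3)
  # monotone approach of MAP to the lower plateau (tiny solver wiggle aside)
  expect_true(all(diff(tr$MAP) < 0.05))
  expect_lt(tr$MAP[15], tr$MAP[1] - 5)
})

test_that("HCTZ transiently contracts volume which then partially recovers", {
  p <- ref_patient()
  tr <- simulate_patient(p, drug_regimen("hctz:12.5"), t_end = 2419200,
                         n_out = 57, gains = c(hctz = 0.4))
  ecfv <- tr$ECFV
  expect_lt(min(ecfv), ecfv[1])                 # initial contraction
  expect_gt(ecfv[57], min(ecfv))                # partial recovery as the
  expect_lt(ecfv[57], ecfv[1])                  # systemic ramp engages
})

test_that("forced systemic tone steps produce reflex heart-rate changes", {
  # baroreflex sign: at the fast (hemodynamic) fixed point, a vascular tone
  # step changes HR in the opposite direction through the baroreceptors
  p <- ref_patient()
  st <- baseline_state(p)
  base <- hemodynamic_closure(st, p)$HR
  up <- ref_patient(); up$R_micro0 <- p$R_micro0 * 1.1
  dn <- ref_patient(); dn$R_micro0 <- p$R_micro0 * 0.9
  expect_lte(hemodynamic_closure(st, up)$HR, base + 1e-9)
  expect_gte(hemodynamic_closure(st, dn)$HR, base - 1e-9)
})

test_that("cardiogenic shock is detected at critically low contractility only", {
  p <- ref_patient()
  # normal baseline trajectory: no shock
  tr0 <- simulate_patient(p, t_end = 20000, n_out = 41)
  expect_false(detect_cardiogenic_shock(tr0, p)$shock)

  # depressed left ventricle: sustained hypotension, low cardiac index and
  # pulmonary congestion develop in finite time
  ps <- ref_patient()
  ps$KL0 <- 0.2
  trs <- simulate_patient(ps, t_end = 250000, n_out = 301,
                          start = ref_equilibrium()$state)
  det <- detect_cardiogenic_shock(trs, ps)
  expect_true(det$shock)
  expect_true(is.finite(det$onset))
})

test_that("a 29-minute hypotensive dip does not qualify as shock", {
  p <- ref_patient()
  t <- seq(0, 7200, by = 60)
  bsa <- 0.007184 * p$weight^0.425 * p$height^0.725
  dip <- t >= 1800 & t < 1800 + 29 * 60
  traj <- data.frame(time = t,
                     SBP = ifelse(dip, 85, 150),
                     CO = ifelse(dip, 2.0 * bsa, 6),
                     PVP = ifelse(dip, 18, 8))
  expect_false(detect_cardiogenic_shock(traj, p)$shock)
  # the same dip sustained for 31 minutes does qualify
  dip31 <- t >= 1800 & t < 1800 + 31 * 60
  traj31 <- transform(traj, SBP = ifelse(dip31, 85, 150),
                      CO = ifelse(dip31, 2.0 * bsa, 6),
                      PVP = ifelse(dip31, 18, 8))
  expect_true(detect_cardiogenic_shock(traj31, p)$shock)
})

test_that("every monotherapy lowers pressure and renal vascular resistance", {
  p <- ref_patient()
  base <- ref_equilibrium()$obs
  gains <- c(aliskiren = 0.3, enalapril = 0.8, losartan = 0.45,
             amlodipine = 0.6, bisoprolol = 0.25, hctz = 0.3)
  regs <- c("aliskiren:150", "enalapril:20", "losartan:100", "amlodipine:5",
            "bisoprolol:5", "hctz:12.5")
  for (r in regs) {
    eq <- find_equilibrium(p, drug_regimen(r), gains = gains,
                           start = ref_equilibrium()$state)
    o <- eq$obs
    for (v in c("MAP", "SBP", "DBP", "RVR"))
      expect_lt(o[[v]], base[[v]])
  }
})

test_that("the RAAS directionality battery holds for all six monotherapies", {
  p <- ref_patient()
  base <- ref_equilibrium()$obs
  gains <- c(aliskiren = 0.3, enalapril = 0.8, losartan = 0.45,
             amlodipine = 0.6, bisoprolol = 0.25, hctz = 0.3)
  eqs <- lapply(c(aliskiren = "aliskiren:150", enalapril = "enalapril:20",
                  losartan = "losartan:100", amlodipine = "amlodipine:5",
                  bisoprolol = "bisoprolol:5", hctz = "hctz:12.5"),
                function(r) find_equilibrium(p, drug_regimen(r), gains = gains,
                                             start = ref_equilibrium()$state)$obs)
  rel <- function(d, v) eqs[[d]][[v]] / base[[v]]

  # aliskiren: PRA down, renin up, angiotensins and aldosterone down
  expect_lt(rel("aliskiren", "PRA"), 1)
  expect_gt(rel("aliskiren", "PRC"), 1)
  expect_lt(rel("aliskiren", "AngI"), 1)
  expect_lt(rel("aliskiren", "AngII"), 1)
  expect_lt(rel("aliskiren", "ALD"), 1)
  # enalapril: PRA and angiotensin I rise, angiotensin II and aldosterone fall
  expect_gt(rel("enalapril", "PRA"), 1)
  expect_gt(rel("enalapril", "AngI"), 1)
  expect_lt(rel("enalapril", "AngII"), 1)
  expect_lt(rel("enalapril", "ALD"), 1)
  # losartan: whole cascade rises, effective AT1 signal falls
  expect_gt(rel("losartan", "PRA"), 1)
  expect_gt(rel("losartan", "PRC"), 1)
  expect_gt(rel("losartan", "AngI"), 1)
  expect_gt(rel("losartan", "AngII"), 1)
  expect_lt(rel("losartan", "AT1B"), 1)
  expect_lt(rel("losartan", "ALD"), 1)
  # bisoprolol: renin axis suppressed, heart rate down
  expect_lt(rel("bisoprolol", "PRA"), 1)
  expect_lt(rel("bisoprolol", "PRC"), 1)
  expect_lt(rel("bisoprolol", "AngII"), 1)
  expect_lt(rel("bisoprolol", "HR"), 1)
  # HCTZ: renin axis activated
  expect_gt(rel("hctz", "PRA"), 1)
  expect_gt(rel("hctz", "PRC"), 1)
  # amlodipine: RAAS within +/- 5 percent of baseline
  for (v in c("PRA", "PRC", "AngI", "AngII", "ALD"))
    expect_lt(abs(rel("amlodipine", v) - 1), 0.05)
  # amlodipine: heart rate rises (reflex), GFR slightly up
  expect_gt(rel("amlodipine", "HR"), 1)
  expect_gt(rel("amlodipine", "GFR"), 1)
})

test_that("lowering inotropy at fixed state pushes blood toward the lungs", {
  p <- ref_patient()
  st <- baseline_state(p)
  dlow <- local({
    p2 <- ref_patient(); p2$KL0 <- p$KL0 * 0.6
    derivatives(st, p2)
  })
  expect_gt(as.numeric(dlow)[2], 0)   # d(V_pv)/dt > 0
})
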