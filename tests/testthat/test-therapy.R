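test_that("long-term changes classify by the 5/10 percent rule", {
  expect_identical(classify_change(100, 104), "no_change")
  expect_identical(classify_change(100, 112), "increase")
  expect_identical(classify_change(100, 88), "decrease")
  expect_identical(classify_change(100, 93), "transitional_down")
  expect_identical(classify_change(100, 107), "transitional_up")
  expect_error(classify_change(0, 10), "positive")
})

test_that("transitional changes are compatible with their sign and no change", {
  comp <- htnsim:::.compatible
  expect_true(comp("transitional_up", "increase"))
  expect_true(comp("transitional_up", "no_change"))
  expect_false(comp("transitional_up", "decrease"))
  expect_true(comp("transitional_down", "decrease"))
  expect_true(comp("no_change", "no_change"))
  expect_false(comp("increase", "no_change"))
  expect_true(comp("increase", "any"))
})

test_that("an empty regimen leaves every observable unchanged over 4 weeks", {
  oc <- simulate_treatment(ref_vp(), drug_regimen())
  expect_false(oc$shock)
  keep <- !is.na(oc$change_pct)
  expect_lt(max(abs(oc$change_pct[keep])), 0.1)
})

test_that("the validity screen composes outcomes against expectations", {
  gains <- c(aliskiren = 0.3, enalapril = 0.8, losartan = 0.45,
             amlodipine = 0.6, bisoprolol = 0.25, hctz = 0.3)
  regs <- c(aliskiren = "aliskiren:150", amlodipine = "amlodipine:5",
            bisoprolol = "bisoprolol:5", enalapril = "enalapril:20",
            hctz = "hctz:12.5", losartan = "losartan:100")
  ocs <- lapply(regs, function(r)
    simulate_treatment(ref_vp(), drug_regimen(r), gains = gains))
  scr <- validity_screen(ocs)
  expect_type(scr$include, "logical")
  # a patient whose heart rate rises under the beta blocker is excluded
  bad <- ocs
  bad$bisoprolol$classes[["HR"]] <- "increase"
  scr_bad <- validity_screen(bad)
  expect_false(scr_bad$include)
  expect_true(any(grepl("bisoprolol: HR", scr_bad$violations)))
  expect_error(validity_screen(ocs[-1]), "missing monotherapy")
})

test_that("summary statistics agree with the reference implementations", {
  pop <- small_population()
  gains <- c(enalapril = 0.8)
  ocs <- lapply(seq_along(pop), function(i)
    simulate_treatment(pop[[i]], drug_regimen("enalapril:20"), gains = gains))
  sm <- summarize_population(list(E20 = ocs), pop)
  obs0 <- population_observables(pop)
  post <- vapply(ocs, function(o) o$post[["SBP"]], numeric(1))
  row <- sm$table[sm$table$regimen == "E20", ]
  expect_equal(row$SBP_mean, mean(post))
  expect_equal(row$SBP_sd, sd(post))
  expect_equal(row$SBP_P_base,
               suppressWarnings(ks.test(post, obs0$SBP)$p.value))
  dS <- vapply(ocs, function(o) o$pre[["SBP"]] - o$post[["SBP"]], numeric(1))
  expect_equal(sm$correlations$E20["GFR", "SBP_reduction"],
               cor(obs0$GFR, dS))
  expect_true(all(abs(sm$correlations$E20) <= 1, na.rm = TRUE))
})

test_that("identical pre/post populations give KS p near 1 and zero deltas", {
  pop <- small_population()
  ocs <- lapply(seq_along(pop), function(i)
    simulate_treatment(pop[[i]], drug_regimen()))
  sm <- summarize_population(list(none = ocs), pop)
  row <- sm$table[sm$table$regimen == "none", ]
  expect_gt(row$SBP_P_base, 0.95)
  expect_equal(row$SBP_mean, mean(population_observables(pop)$SBP),
               tolerance = 1e-3)
})

test_that("gain calibration is self-consistent at unit multipliers", {
  pop <- small_population()
  # targets produced by the model itself at gain 1 for amlodipine
  post <- htnsim:::.population_post_eq(pop, drug_regimen("amlodipine:5"),
                                       gains = c(amlodipine = 1))
  obs0 <- population_observables(pop)
  base_here <- c(mean(obs0$SBP), mean(obs0$DBP), mean(obs0$HR))
  tgt <- data.frame(drug = "amlodipine", dose = 5,
                    SBP = 154 + post[1] - base_here[1],
                    DBP = 101 + post[2] - base_here[2],
                    HR = 76 + post[3] - base_here[3])
  cal <- calibrate_drug_gains(pop, targets = tgt, drugs = "amlodipine",
                              seed = 2, generations = 8)
  expect_equal(unname(cal$gains[["amlodipine"]]), 1, tolerance = 0.02)
})

test_that("gain calibration recovers a known synthetic multiplier", {
  pop <- small_population()
  g_true <- 0.6
  post <- htnsim:::.population_post_eq(pop, drug_regimen("losartan:100"),
                                       gains = c(losartan = g_true))
  obs0 <- population_observables(pop)
  base_here <- c(mean(obs0$SBP), mean(obs0$DBP), mean(obs0$HR))
  tgt <- data.frame(drug = "losartan", dose = 100,
                    SBP = 154 + post[1] - base_here[1],
                    DBP = 101 + post[2] - base_here[2],
                    HR = 76 + post[3] - base_here[3])
  cal <- calibrate_drug_gains(pop, targets = tgt, drugs = "losartan",
                              seed = 3, generations = 8)
  expect_equal(unname(cal$gains[["losartan"]]), g_true, tolerance = 0.05)
})

test_that("neurohumoral calibration keeps HR and GFR stable under aliskiren", {
  pop <- small_population()
  nh <- calibrate_neurohumoral(pop, gain = 0.3, seed = 4, generations = 5)
  expect_true(all(is.finite(nh$means)))
  expect_true(all(nh$means >= 0))
  pop2 <- apply_neurohumoral(pop, nh$means)
  reg <- drug_regimen("aliskiren:150")
  dHR <- dGFR <- numeric(length(pop2))
  for (i in seq_along(pop2)) {
    eq <- find_equilibrium(pop2[[i]]$params, reg, gains = c(aliskiren = 0.3),
                           start = pop2[[i]]$state)
    dHR[i] <- abs(eq$obs[["HR"]] / pop2[[i]]$obs[["HR"]] - 1)
    dGFR[i] <- abs(eq$obs[["GFR"]] / pop2[[i]]$obs[["GFR"]] - 1)
  }
  expect_lt(mean(dHR), 0.02)
  expect_lt(mean(dGFR), 0.02)
})

test_that("dual combinations dominate their component monotherapies", {
  pop <- small_population()
  gains <- c(aliskiren = 0.3, amlodipine = 0.6)
  mono1 <- htnsim:::.population_post_eq(pop, drug_regimen("aliskiren:150"),
                                        gains = gains)
  mono2 <- htnsim:::.population_post_eq(pop, drug_regimen("amlodipine:5"),
                                        gains = gains)
  duo <- htnsim:::.population_post_eq(
    pop, drug_regimen("aliskiren:150", "amlodipine:5"), gains = gains)
  expect_lt(duo[["SBP"]], min(mono1[["SBP"]], mono2[["SBP"]]))
  # near-additivity: combined reduction within the arithmetic envelope
  obs0 <- population_observables(pop)
  base <- mean(obs0$SBP)
  d1 <- base - mono1[["SBP"]]; d2 <- base - mono2[["SBP"]]
  dd <- base - duo[["SBP"]]
  expect_gte(dd, max(d1, d2))
  expect_lte(dd, d1 + d2 + 4)
})
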