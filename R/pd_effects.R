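#' Saturating Emax dose-response
#'
#' Effect magnitude of a drug dose under the Emax model
#' `E(D) = Emax * D / (D + ED50)`, half-maximal at `ED50`.
#'
#' @param dose Dose in mg/day (scalar or vector, `>= 0`).
#' @param emax Maximum effect, dimensionless in `(0, 1]`.
#' @param ed50 Dose giving half of `emax`, mg/day (`> 0`).
#' @return Dimensionless effect magnitude, bounded above by `emax`.
#' @examples
#' emax_effect(150, 0.99, 20)   # aliskiren 150 mg/day
#' @export
emax_effect <- function(dose, emax = 0.99, ed50 = 20) {
  if (any(dose < 0)) stop("dose must be non-negative")
  if (emax <= 0 || emax > 1) stop("emax must lie in (0, 1]")
  if (ed50 <= 0) stop("ed50 must be positive")
  emax * dose / (dose + ed50)
}

#' Time ramp of the hydrochlorothiazide systemic vasodilation
#'
#' The chronic effect of HCTZ on the conductivity of the systemic
#' microvessels grows linearly from zero and saturates:
#' `min(0.074 * t / 1,950,000, 0.074)` with `t` in seconds since treatment
#' start (1,950,000 s is about 22.6 days, matching the clinical 4-6 week
#' recovery of extracellular fluid volume and cardiac output under chronic
#' thiazide treatment).
#'
#' @param t Seconds since treatment start (`>= 0`, vectorised).
#' @param emax Saturation magnitude (default 0.074).
#' @param duration Time to reach saturation in seconds (default 1,950,000).
#' @return Dimensionless magnitude in `[0, emax]`.
#' @export
hctz_sys_ramp <- function(t, emax = 0.074, duration = 1950000) {
  if (any(t < 0)) stop("t must be non-negative")
  pmin(emax * t / duration, emax)
}

# Names of the aggregate pharmacodynamic effect fields.
.pd_fields <- c(
  "ACEi", "ARB", "DRI",
  "CCBaa", "CCBea", "CCBpreglom", "CCBsys",
  "Bblocker", "Bblocker_rs",
  "DiureticInhibition", "Diureticaa", "Diureticea", "Diureticpreglom",
  "Diureticsys", "DiureticStimulation", "Diureticstress",
  "Diureticpotassium", "Diureticurea"
)

#' Table of drug targets and effect magnitudes
#'
#' One row per (drug, dose, target). Constant magnitudes are stored in
#' `magnitude`; dose-dependent entries carry a `formula` id
#' (`"emax"` for aliskiren, `"ramp"` for the HCTZ systemic effect).
#' `sign` is `"-"` for target inhibition (factor `1 - E`) and `"+"` for
#' stimulation (factor `1 + E`).
#'
#' @return A data.frame with columns `drug`, `dose`, `target`, `sign`,
#'   `magnitude`, `formula`.
#' @export
effect_table <- function() {
  if (!is.null(.htnsim_cache$effect_table)) return(.htnsim_cache$effect_table)
  tab <- rbind(
    data.frame(drug = "aliskiren", dose = 150, target = "DRI", sign = "-",
               magnitude = NA_real_, formula = "emax"),
    data.frame(drug = "aliskiren", dose = 300, target = "DRI", sign = "-",
               magnitude = NA_real_, formula = "emax"),
    data.frame(drug = "amlodipine", dose = 5,
               target = c("CCBaa", "CCBea", "CCBpreglom", "CCBsys"),
               sign = "-", magnitude = c(0.413, 0.107, 0.413, 0.107),
               formula = NA_character_),
    data.frame(drug = "bisoprolol", dose = 5,
               target = c("Bblocker", "Bblocker_rs"),
               sign = "-", magnitude = c(0.371, 0.933),
               formula = NA_character_),
    data.frame(drug = "enalapril", dose = 20, target = "ACEi", sign = "-",
               magnitude = 0.996, formula = NA_character_),
    data.frame(drug = "hctz", dose = 12.5,
               target = c("DiureticInhibition", "DiureticStimulation",
                          "Diureticaa", "Diureticea", "Diureticpreglom",
                          "Diureticsys", "Diureticstress",
                          "Diureticpotassium", "Diureticurea"),
               sign = c("-", "+", "-", "-", "-", "-", "-", "-", "+"),
               magnitude = c(0.304, 1.113, 0.469, 0.302, 0.581, NA, 0.389,
                             0.030, 0.100),
               formula = c(NA, NA, NA, NA, NA, "ramp", NA, NA, NA)),
    data.frame(drug = "losartan", dose = 50, target = "ARB", sign = "-",
               magnitude = 0.886, formula = NA_character_),
    data.frame(drug = "losartan", dose = 100, target = "ARB", sign = "-",
               magnitude = 0.954, formula = NA_character_)
  )
  rownames(tab) <- NULL
  .htnsim_cache$effect_table <- tab
  tab
}

.htnsim_cache <- new.env(parent = emptyenv())

#' Construct a drug regimen
#'
#' A regimen is a set of (drug, dose, indicator) entries. Only the supported
#' dosages are accepted (aliskiren 150/300, amlodipine 5, bisoprolol 5,
#' enalapril 20, HCTZ 12.5, losartan 50/100 mg/day); there is no dose
#' extrapolation. At most one active dosage per drug is allowed, matching the
#' one-dosage-at-a-time design of the pharmacodynamic sums.
#'
#' @param ... Entries either as strings `"drug:dose"` (e.g. `"enalapril:20"`,
#'   `"hctz:12.5"`) or named doses (`enalapril = 20`). All entries given here
#'   have indicator 1; an empty call is the untreated regimen.
#' @return An object of class `drug_regimen`: a data.frame with columns
#'   `drug`, `dose`, `indicator`.
#' @examples
#' drug_regimen("aliskiren:150", "amlodipine:5")
#' drug_regimen()   # untreated
#' @export
drug_regimen <- function(...) {
  entries <- list(...)
  tab <- effect_table()
  drugs <- character(0); doses <- numeric(0)
  nm <- names(entries)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.null(nm) && nzchar(nm[i] %||% "")) {
      drugs <- c(drugs, nm[i]); doses <- c(doses, as.numeric(e))
    } else if (is.character(e)) {
      for (s in e) {
        parts <- strsplit(s, ":", fixed = TRUE)[[1]]
        if (length(parts) != 2) stop("regimen entry must be 'drug:dose': ", s)
        drugs <- c(drugs, parts[1]); doses <- c(doses, as.numeric(parts[2]))
      }
    } else {
      stop("unsupported regimen entry type")
    }
  }
  if (any(is.na(doses)) || any(doses <= 0)) stop("doses must be positive numbers")
  for (i in seq_along(drugs)) {
    ok <- tab$drug == drugs[i] & tab$dose == doses[i]
    if (!any(ok)) {
      supported <- tapply(tab$dose, tab$drug, function(d) paste(unique(d), collapse = "/"))
      stop("unsupported (drug, dose): ", drugs[i], ":", doses[i],
           ". Supported doses (mg/day): ",
           paste(names(supported), supported, sep = " ", collapse = ", "))
    }
  }
  if (anyDuplicated(drugs)) stop("at most one active dosage per drug")
  reg <- data.frame(drug = drugs, dose = doses,
                    indicator = rep(1L, length(drugs)))
  class(reg) <- c("drug_regimen", "data.frame")
  reg
}

#' @export
format.drug_regimen <- function(x, ...) {
  if (nrow(x) == 0) return("untreated")
  paste(paste0(x$drug, ":", x$dose), collapse = " + ")
}

#' @export
print.drug_regimen <- function(x, ...) {
  cat("<drug_regimen> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Zero pharmacodynamic effects
#'
#' The multiplicative identity: every aggregate effect magnitude is zero, so
#' every drug factor `F = 1 +/- effect` equals 1.
#' @return Named numeric vector over all effect fields.
#' @export
pd_zero <- function() {
  stats::setNames(numeric(length(.pd_fields)), .pd_fields)
}

#' Aggregate pharmacodynamic effects of a regimen
#'
#' Sums the effect magnitudes `E(D) * dF` over all active entries of a
#' regimen, per target field. Aliskiren uses the Emax dose-response, the HCTZ
#' systemic effect uses the time ramp [hctz_sys_ramp()], all other
#' magnitudes are the fixed per-dose constants of [effect_table()].
#'
#' @param regimen A [drug_regimen()].
#' @param t Seconds since treatment start (for the HCTZ ramp). Use `Inf` for
#'   the saturated chronic effect.
#' @param gains Optional named numeric vector of per-drug gain multipliers
#'   (defaults to 1 for every drug); each drug's magnitudes are scaled
#'   jointly, with inhibitory magnitudes capped at 0.9995 so multiplicative
#'   factors stay positive.
#' @return Named numeric vector over all effect fields (see [pd_zero()]).
#' @export
regimen_effects <- function(regimen, t = 0, gains = NULL) {
  if (any(t < 0)) stop("t must be non-negative")
  eff <- pd_zero()
  if (is.null(regimen) || nrow(regimen) == 0) return(eff)
  tab <- effect_table()
  for (i in seq_len(nrow(regimen))) {
    if (regimen$indicator[i] == 0) next
    g <- 1
    if (!is.null(gains) && regimen$drug[i] %in% names(gains))
      g <- gains[[regimen$drug[i]]]
    rows <- tab[tab$drug == regimen$drug[i] & tab$dose == regimen$dose[i], ]
    for (j in seq_len(nrow(rows))) {
      m <- if (is.na(rows$formula[j])) {
        rows$magnitude[j]
      } else if (rows$formula[j] == "emax") {
        emax_effect(rows$dose[j])
      } else if (rows$formula[j] == "ramp") {
        hctz_sys_ramp(min(t, 1950000))
      } else stop("unknown formula id: ", rows$formula[j])
      m <- m * g
      if (rows$sign[j] == "-") m <- min(m, 0.9995)
      eff[[rows$target[j]]] <- eff[[rows$target[j]]] + m
    }
  }
  eff
}

#' Apply a pharmacodynamic effect to a target value
#'
#' Multiplies a target quantity by `1 - magnitude` (inhibition, sign `-`) or
#' `1 + magnitude` (stimulation, sign `+`), clamping physically non-negative
#' targets at zero.
#'
#' @param value Target value (any physical unit).
#' @param magnitude Dimensionless effect magnitude (`>= 0`).
#' @param sign `"-"` for inhibition, `"+"` for stimulation.
#' @return Value after the drug factor, same unit.
#' @export
apply_effect <- function(value, magnitude, sign = c("-", "+")) {
  sign <- match.arg(sign)
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  f <- if (sign == "-") 1 - magnitude else 1 + magnitude
  pmax(value * f, 0)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
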