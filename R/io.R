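## Configuration, serialization and report tables.

#' Load a run configuration
#'
#' Reads a YAML configuration with `seed`, `sampling`, `constraints` and
#' `optimizer` sections, validates it against the known schema and returns
#' a normalized config. Unknown keys are rejected by name.
#'
#' @param path Path to a YAML file.
#' @return List of class `run_config` with `seed`, `sampling`
#'   (a [sampling_settings()]), `constraints` (data.frame), `optimizer`
#'   (budgets) and `hash` (digest of the normalized content).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("seed", "sampling", "constraints", "optimizer")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(raw$seed %||% 1)
  samp <- raw$sampling %||% list()
  known_s <- c("SBP", "DBP", "HR", "BMI", "weight", "male_fraction")
  bad <- setdiff(names(samp), known_s)
  if (length(bad)) stop("unknown sampling key(s): ", paste(bad, collapse = ", "))
  args <- lapply(samp[setdiff(names(samp), "male_fraction")], as.numeric)
  if (!is.null(samp$male_fraction)) args$male_fraction <- as.numeric(samp$male_fraction)
  sampling <- do.call(sampling_settings, args)
  constraints <- default_constraints()
  if (!is.null(raw$constraints)) {
    for (nm in names(raw$constraints)) {
      v <- as.numeric(raw$constraints[[nm]])
      if (length(v) != 2 || v[1] >= v[2])
        stop("constraint ", nm, " must be c(lower, upper) with lower < upper")
      i <- match(nm, constraints$name)
      if (is.na(i)) {
        constraints <- rbind(constraints,
                             data.frame(name = nm, lower = v[1], upper = v[2]))
      } else {
        constraints$lower[i] <- v[1]; constraints$upper[i] <- v[2]
      }
    }
  }
  optimizer <- utils::modifyList(list(budget = 6, calibration_generations = 7),
                                 raw$optimizer %||% list())
  cfg <- list(seed = seed, sampling = sampling, constraints = constraints,
              optimizer = optimizer)
  cfg$hash <- .config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# order-independent content hash (no external digest dependency)
.config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg[setdiff(names(cfg), "hash")],
                                              digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2147483647
}

#' Write a population to JSON
#'
#' Serializes parameters, slow state, equilibrium observables and target
#' draws with full double precision so a read round-trip reproduces the
#' population bitwise.
#'
#' @param population A `virtual_population`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  ser <- list(
    format = "htnsim-population",
    version = 1L,
    seed = attr(population, "seed"),
    patients = lapply(population, function(vp) {
      par <- vp$params
      class(par) <- NULL
      list(params = par, state = as.list(vp$state),
           obs = as.list(vp$obs),
           draw = unclass(vp$draw),
           diagnostics = vp$diagnostics,
           sodium_test = vp$sodium_test)
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' Read a population from JSON
#'
#' @param path File written by [write_population()].
#' @return A `virtual_population`.
#' @export
read_population <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse population file: ",
                                           conditionMessage(e)))
  if (!identical(raw$format, "htnsim-population"))
    stop("not a population file: ", path)
  if (!identical(as.integer(raw$version), 1L))
    stop("unsupported population file version: ", raw$version)
  num <- function(v) {
    if (is.list(v)) v <- unlist(v)
    if (is.numeric(v)) as.numeric(v) else v   # whole numbers parse as int
  }
  pats <- lapply(raw$patients, function(pt) {
    par <- lapply(pt$params, num)
    class(par) <- "vp_params"
    vp <- list(params = par,
               state = vapply(pt$state, as.numeric, numeric(1)),
               obs = vapply(pt$obs, as.numeric, numeric(1)),
               draw = structure(pt$draw, class = "target_draw"),
               diagnostics = lapply(pt$diagnostics, function(v)
                 if (is.list(v)) unlist(v) else v),
               sodium_test = pt$sodium_test)
    class(vp) <- "virtual_patient"
    vp
  })
  structure(pats, class = "virtual_population", seed = raw$seed)
}

#' Export population observables as CSV
#'
#' @param population A `virtual_population`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
population_csv <- function(population, path) {
  df <- population_observables(population)
  units <- c(SBP = "mmHg", DBP = "mmHg", MAP = "mmHg", PP = "mmHg",
             CVP = "mmHg", PVP = "mmHg", LVEDP = "mmHg", LVPSP = "mmHg",
             HR = "per_min", SV = "ml", EDV = "ml", ESV = "ml",
             EF = "percent", CO = "L_per_min", SVR = "dyn_s_cm5",
             ECFV = "L", V_blood = "L", GFR = "ml_per_min",
             RBF = "ml_per_min", RVR = "mmHg_min_ml", FF = "percent",
             Na_excretion = "mEq_per_min", BMI = "kg_m2", weight = "kg",
             height = "cm", Phi_sod_in = "mEq_per_min")
  names(df) <- vapply(names(df), function(nm)
    if (nm %in% names(units)) paste0(nm, "_", units[[nm]]) else nm,
    character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Report tables of a population summary
#'
#' Emits the treatment-response table (one row per regimen: mean +/- SD of
#' SBP/DBP/HR with the baseline and component KS p-values) and a baseline
#' characteristics table.
#'
#' @param summary A `population_summary`.
#' @param population The underlying `virtual_population`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the written paths.
#' @export
report <- function(summary, population, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_p <- function(p) ifelse(is.na(p), "-",
                              ifelse(p < 1e-4, "SS", formatC(p, digits = 4,
                                                             format = "f")))
  tab <- summary$table
  out <- data.frame(Regimens = tab$regimen)
  for (v in c("SBP", "DBP", "HR")) {
    out[[v]] <- sprintf("%.0f +/- %.0f", tab[[paste0(v, "_mean")]],
                        tab[[paste0(v, "_sd")]])
    out[[paste0(v, "_P_base")]] <- fmt_p(tab[[paste0(v, "_P_base")]])
    out[[paste0(v, "_P_f")]] <- fmt_p(tab[[paste0(v, "_P_f")]])
    out[[paste0(v, "_P_s")]] <- fmt_p(tab[[paste0(v, "_P_s")]])
  }
  f1 <- file.path(dir, "treatment_response.csv")
  utils::write.csv(out, f1, row.names = FALSE)

  obs <- population_observables(population)
  sexes <- table(factor(obs$sex, levels = c("M", "F")))
  base <- data.frame(
    Variable = c("SBP, mmHg", "DBP, mmHg", "HR, beats/min", "BMI, kg/m2",
                 "Weight, kg", "Height, cm", "Sex, M/F"),
    Value = c(sprintf("%.2f +/- %.2f", mean(obs$SBP), stats::sd(obs$SBP)),
              sprintf("%.2f +/- %.2f", mean(obs$DBP), stats::sd(obs$DBP)),
              sprintf("%.2f +/- %.2f", mean(obs$HR), stats::sd(obs$HR)),
              sprintf("%.2f +/- %.2f", mean(obs$BMI), stats::sd(obs$BMI)),
              sprintf("%.2f +/- %.2f", mean(obs$weight), stats::sd(obs$weight)),
              sprintf("%.2f +/- %.2f", mean(obs$height), stats::sd(obs$height)),
              sprintf("%d/%d", sexes[["M"]], sexes[["F"]]))
  )
  f2 <- file.path(dir, "baseline_characteristics.csv")
  utils::write.csv(base, f2, row.names = FALSE)
  c(f1, f2)
}
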