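# Study orchestration: simulate -> process -> fit -> in-vivo budgets ->
# circulation, from a single seeded configuration.

#' Process a chamber run into fitted pH-O2 curves
#'
#' For each trace: estimate the maximum oxygenation signal and its drift
#' from the oxygen calibration phases; obtain the minimum signal from the
#' reference-wavelength predictor when the trace carries one (the route for
#' incompletely deoxygenating pigments), otherwise from the nitrogen phase;
#' compute the calibrated saturation series; and fit the five-parameter
#' logistic.
#'
#' @param run A `chamber_run` (or plain list of `chamber_trace`s).
#' @param n_boot Bootstrap replicates per curve fit.
#' @param seed Root seed; per-curve seeds are derived from it.
#' @param min_signal_model Linear coefficients `c(intercept, slope)` mapping
#'   the reference-wavelength value to the minimum absorbance.
#' @return A list of `ph_o2_curve` objects, one per PO2 level.
#' @export
process_chamber_run <- function(run, n_boot = 0, seed = 1L,
                                min_signal_model = c(0, 1)) {
  lapply(unclass(run), function(tr) {
    mx <- calibrate_max_signal(tr)
    ref <- attr(tr, "ref_a347")
    mn <- if (!is.null(ref)) {
      predict_min_signal(ref, min_signal_model)
    } else {
      measure_min_signal(tr)
    }
    cal <- calibration_model(amax0 = mx$amax0, amax_drift = mx$amax_drift,
                             amin = mn$amin, source = mn$source)
    series <- compute_saturation(tr, cal)
    fit_5pl(series, n_boot = n_boot,
            seed = derive_seed(seed, sprintf("fit_po2_%g", attr(tr, "po2"))))
  })
}

#' Default study configuration
#'
#' A small, fully seeded synthetic study: one Antarctic-like species
#' (carrying capacity 1.58 mmol O2/L; half-saturation at 2.34 kPa and pH
#' 7.27 at 10 degC; Bohr coefficient -1.22) measured at 0 and 10 degC, with
#' in-vivo budgets at venous PO2 of 4 and 1 kPa and the circulatory
#' comparison between the two temperatures.
#'
#' @return A configuration list accepted by [run_study()].
#' @export
default_study_config <- function() {
  list(
    seed = 1L,
    n_boot = 200,
    species = list(
      list(name = "antarctic_synthetic",
           capacity = 1.58,
           temperatures = c(0, 10),
           pigment = list(p50_ref = 2.34, ph_ref = 7.27,
                          bohr_slope = -1.22, steepness = 8,
                          asymmetry = 1, temp_coeff = 0.193,
                          ref_temp = 10))
    ),
    protocol = list(),
    noise = list(abs_sd = 0.005, ph_sd = 0.005),
    alpha_stat = list(slope = -0.0153, anchor_ph = 7.42, anchor_temp = 0),
    venous_po2 = c(4, 1),
    circulation = list(mo2_ref = 0.63, t_ref = 0, q10 = 2.12,
                       blood_volume_frac = 0.052,
                       include_dissolved = FALSE)
  )
}

study_species_capacity <- function(sp, seed, salinity = 35) {
  if (!is.null(sp$capacity)) return(sp$capacity)
  r <- sp$respirometry
  if (is.null(r) || is.null(r$capacity_true)) {
    stop("species '", sp$name,
         "' needs either a capacity or respirometry inputs")
  }
  ctrl_cap <- o2_solubility(0, salinity) / 1000
  args <- function(cap, label) {
    c(list(capacity = cap, seed = derive_seed(seed, label)),
      r[setdiff(names(r), "capacity_true")])
  }
  # the haemolymph sample liberates bound plus dissolved oxygen; the
  # seawater control carries only its dissolved oxygen, whose step is
  # subtracted by the estimator
  sample_tr <- do.call(simulate_respirometry,
                       args(r$capacity_true + ctrl_cap, "resp_s"))
  control_tr <- do.call(simulate_respirometry, args(ctrl_cap, "resp_c"))
  carrying_capacity_from_respirometry(
    sample_tr, control_tr,
    sample_vol = r$sample_vol %||% 10,
    chamber_vol = r$chamber_vol %||% 2)
}

#' Run a full synthetic study
#'
#' Executes simulate -> process -> fit -> in-vivo -> circulation for every
#' species of the configuration. All randomness flows from `config$seed`
#' through named substreams per species, temperature and stage, so a given
#' configuration is fully reproducible. Failures are collected per species
#' without aborting the others.
#'
#' @param config A configuration list (see [default_study_config()]) or the
#'   path of a YAML file holding one. `config$seed` must be explicit.
#' @return An object of class `run_report`: data frames `binding`,
#'   `budgets`, `circulation`, a per-species `errors` list, and
#'   `provenance` (seed, canonical config JSON and hash, versions).
#' @export
run_study <- function(config = default_study_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed must be set explicitly")
  species <- config$species
  config <- modifyList(default_study_config(), config)
  # species entries replace the default outright (modifyList would merge
  # the unnamed list elements positionally against the default species)
  if (!is.null(species)) config$species <- species
  alpha <- do.call(alpha_stat_model, config$alpha_stat)
  circ <- config$circulation
  binding_rows <- list(); budget_rows <- list(); circ_rows <- list()
  errors <- list()

  for (sp in config$species) {
    res <- tryCatch({
      sp_seed <- derive_seed(config$seed, sp$name)
      capacity <- study_species_capacity(sp, sp_seed)
      pig_args <- modifyList(sp$pigment %||% list(),
                             list(capacity = capacity))
      pigment <- do.call(ground_truth_pigment, pig_args)
      temps <- sort(unlist(sp$temperatures))
      per_temp <- lapply(temps, function(tC) {
        protocol <- do.call(
          chamber_protocol,
          modifyList(config$protocol, list(temperature = tC)))
        noise <- do.call(
          noise_model,
          modifyList(config$noise,
                     list(seed = derive_seed(sp_seed,
                                             sprintf("sim_%g", tC)))))
        run <- simulate_chamber_experiment(pigment, protocol, noise)
        curves <- process_chamber_run(
          run, n_boot = config$n_boot,
          seed = derive_seed(sp_seed, sprintf("fit_%g", tC)))
        vph <- venous_ph(alpha, tC)
        bp <- binding_params(curves, capacity, vph, species = sp$name)
        budgets <- lapply(config$venous_po2, function(vpo2) {
          tryCatch(
            transport_budget(curves, capacity,
                             in_vivo_conditions(temperature = tC,
                                                venous_po2 = vpo2,
                                                venous_ph = vph)),
            error = function(e) NULL)
        })
        list(curves = curves, bp = bp, budgets = budgets, temp = tC)
      })

      all_curves <- unlist(lapply(per_temp, `[[`, "curves"),
                           recursive = FALSE)
      pooled_bohr <- tryCatch(bohr_coefficient(all_curves),
                              error = function(e) NA_real_)
      dp50 <- NA_real_
      if (length(temps) >= 2) {
        p_lo <- per_temp[[1]]$bp$p50
        p_hi <- per_temp[[length(temps)]]$bp$p50
        dp50 <- tryCatch(
          delta_p50_per_degC(p_lo, p_hi, temps[1], temps[length(temps)]),
          error = function(e) NA_real_)
      }

      for (pt in per_temp) {
        bp <- pt$bp
        binding_rows[[length(binding_rows) + 1]] <- data.frame(
          species = sp$name, temp_c = pt$temp,
          capacity_mmol_l = capacity,
          venous_ph = bp$venous_ph,
          p50_kpa = bp$p50,
          p50_status = ifelse(is.finite(bp$p50), "ok", "undefined"),
          p50_lo = bp$p50_ci[["lo"]], p50_hi = bp$p50_ci[["hi"]],
          bohr = bp$bohr,
          bohr_lo = bp$bohr_ci[["lo"]], bohr_hi = bp$bohr_ci[["hi"]],
          cooperativity = bp$cooperativity,
          cooperativity_lo = bp$cooperativity_ci[["lo"]],
          cooperativity_hi = bp$cooperativity_ci[["hi"]],
          pooled_bohr = pooled_bohr,
          dp50_per_degc = dp50,
          stringsAsFactors = FALSE)
        for (i in seq_along(config$venous_po2)) {
          bd <- pt$budgets[[i]]
          if (is.null(bd)) next
          budget_rows[[length(budget_rows) + 1]] <- data.frame(
            species = sp$name, temp_c = pt$temp,
            venous_po2_kpa = config$venous_po2[i],
            s_arterial = bd$s_arterial, s_venous = bd$s_venous,
            bound_release_frac = bd$bound_release_frac,
            bound_release_mmol_l = bd$bound_release,
            dissolved_release_mmol_l = bd$dissolved_release,
            total_release_mmol_l = bd$total_release,
            dissolved_fraction_of_total = bd$dissolved_fraction_of_total,
            dissolved_fraction_of_release =
              bd$dissolved_fraction_of_release,
            stringsAsFactors = FALSE)
        }
      }

      if (length(temps) >= 2 && !is.null(circ$mo2_ref)) {
        delivered <- vapply(
          list(per_temp[[1]], per_temp[[length(temps)]]),
          function(pt) {
            bd <- pt$budgets[[1]]
            if (is.null(bd)) return(NA_real_)
            d <- bd$bound_release
            if (isTRUE(circ$include_dissolved)) d <- bd$total_release
            d
          }, numeric(1))
        t_lo <- temps[1]; t_hi <- temps[length(temps)]
        mo2_lo <- q10_adjust(circ$mo2_ref, circ$t_ref, t_lo, circ$q10)
        mo2_hi <- q10_adjust(circ$mo2_ref, circ$t_ref, t_hi, circ$q10)
        if (all(is.finite(delivered)) && all(delivered > 0)) {
          inc <- circulation_increase(mo2_lo, mo2_hi,
                                      delivered[1], delivered[2])
          to_lo <- required_turnover(mo2_lo, delivered[1],
                                     circ$blood_volume_frac)
          to_hi <- required_turnover(mo2_hi, delivered[2],
                                     circ$blood_volume_frac)
          circ_rows[[length(circ_rows) + 1]] <- data.frame(
            species = sp$name, t_low = t_lo, t_high = t_hi,
            q10 = circ$q10,
            mo2_low = mo2_lo, mo2_high = mo2_hi,
            delivered_low_mmol_l = delivered[1],
            delivered_high_mmol_l = delivered[2],
            constant_supply_increase_pct = inc$constant_supply_pct,
            measured_supply_increase_pct = inc$measured_supply_pct,
            turnover_per_s_low = to_lo$turnover_per_s,
            turnover_per_s_high = to_hi$turnover_per_s,
            stringsAsFactors = FALSE)
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[sp$name]] <- res
  }

  bind_or_empty <- function(rows) {
    if (length(rows) == 0) data.frame() else do.call(rbind, rows)
  }
  config_json <- as.character(
    jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  structure(
    list(binding = bind_or_empty(binding_rows),
         budgets = bind_or_empty(budget_rows),
         circulation = bind_or_empty(circ_rows),
         errors = errors,
         provenance = list(
           seed = config$seed,
           config_hash = rlang::hash(config_json),
           config_json = config_json,
           package_version = as.character(utils::packageVersion("bluesat")),
           r_version = as.character(getRversion()),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Study report\n")
  cat(sprintf("  binding rows    : %d\n", nrow(x$binding)))
  cat(sprintf("  budget rows     : %d\n", nrow(x$budgets)))
  cat(sprintf("  circulation rows: %d\n", nrow(x$circulation)))
  if (length(x$errors)) {
    cat("  errors:\n")
    for (nm in names(x$errors)) cat(sprintf("    %s: %s\n", nm,
                                            x$errors[[nm]]))
  }
  invisible(x)
}

report_csv_schemas <- list(
  binding = c("species", "temp_c", "capacity_mmol_l", "venous_ph",
              "p50_kpa", "p50_status", "p50_lo", "p50_hi", "bohr",
              "bohr_lo", "bohr_hi", "cooperativity", "cooperativity_lo",
              "cooperativity_hi", "pooled_bohr", "dp50_per_degc"),
  budgets = c("species", "temp_c", "venous_po2_kpa", "s_arterial",
              "s_venous", "bound_release_frac", "bound_release_mmol_l",
              "dissolved_release_mmol_l", "total_release_mmol_l",
              "dissolved_fraction_of_total",
              "dissolved_fraction_of_release"),
  circulation = c("species", "t_low", "t_high", "q10", "mo2_low",
                  "mo2_high", "delivered_low_mmol_l",
                  "delivered_high_mmol_l", "constant_supply_increase_pct",
                  "measured_supply_increase_pct", "turnover_per_s_low",
                  "turnover_per_s_high")
)

#' Write a study report to disk
#'
#' CSV tables (`binding.csv`, `budgets.csv`, `circulation.csv`) at full
#' precision with display-rounded copies (`*_display.csv`, 4 significant
#' digits), and/or a single `report.json` serialised at full precision.
#' Column order is stable (see `bluesat:::report_csv_schemas`).
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"csv"`, `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "run_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if ("csv" %in% formats) {
    for (nm in names(report_csv_schemas)) {
      df <- report[[nm]]
      if (nrow(df) == 0) next
      df <- df[, report_csv_schemas[[nm]], drop = FALSE]
      p1 <- file.path(dir, paste0(nm, ".csv"))
      write.csv(df, p1, row.names = FALSE)
      disp <- df
      num <- vapply(disp, is.numeric, logical(1))
      disp[num] <- lapply(disp[num], signif, digits = 4)
      p2 <- file.path(dir, paste0(nm, "_display.csv"))
      write.csv(disp, p2, row.names = FALSE)
      paths <- c(paths, p1, p2)
    }
  }
  if ("json" %in% formats) {
    pj <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), pj, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null",
                         pretty = TRUE)
    paths <- c(paths, pj)
  }
  invisible(paths)
}
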