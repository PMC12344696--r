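# Orchestration: run the analysis stages in dependency order over a single
# config, collect every reported value with its unit into one auditable
# report, and read/write the study fixtures.

#' Assemble a pipeline configuration
#'
#' Stages run when their inputs are present (and are skipped silently when
#' absent), mirroring how the experiments are independent: preprocessing and
#' equilibrium binding feed thermodynamics; lifetimes feed FRET; micelle
#' metrics stand alone. Every physical constant used anywhere downstream
#' (molar mass, tau0, FRET constants, donor lifetime, quantum yield) is
#' carried here explicitly and echoed into the report, so no reported number
#' ever depends on an unstated constant.
#'
#' @param titration Absorbance [titration_series()] (spectra) for
#'   preprocessing + Hill analysis, or NULL.
#' @param mw Molar mass in Da for [convert_kd_to_molar()].
#' @param quench List of scalar-intensity [titration_series()] (one per
#'   temperature, quencher in M, the q = 0 row giving F0), or NULL.
#' @param tau0 Unquenched donor lifetime in seconds for `k_q`.
#' @param decay A [decay_histogram()], or NULL.
#' @param decay_components,decay_mode Passed to [multiexp_fit()].
#' @param lifetime_sv List `(tau0, q, taus)` for [lifetime_stern_volmer()]
#'   (tau0 and taus in ns), or NULL.
#' @param fret List of arguments for [fret_chain()], or NULL.
#' @param pyrene A `ratio_series` (or excitation-spectra
#'   [titration_series()], converted via [pyrene_ratio()]), or NULL.
#' @param cmc_method Passed to [cmc_fit()].
#' @param afm A [height_map()], or NULL.
#' @param run_thermo Force the van't Hoff stage on (`TRUE`), off (`FALSE`),
#'   or automatic when >= 3 quench temperatures are present (`NULL`,
#'   default). Forcing it on without enough temperatures is a validation
#'   error.
#' @param seed Seed recorded in provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(titration = NULL, mw = 22500, quench = NULL,
                            tau0 = NA_real_, decay = NULL,
                            decay_components = 3L, decay_mode = "tail",
                            lifetime_sv = NULL, fret = NULL, pyrene = NULL,
                            cmc_method = "inflection", afm = NULL,
                            run_thermo = NULL, seed = 1L) {
  cfg <- structure(list(titration = titration, mw = mw, quench = quench,
                        tau0 = tau0, decay = decay,
                        decay_components = decay_components,
                        decay_mode = decay_mode,
                        lifetime_sv = lifetime_sv, fret = fret,
                        pyrene = pyrene, cmc_method = cmc_method,
                        afm = afm, run_thermo = run_thermo, seed = seed),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration before execution
#'
#' Fails fast on structurally unrunnable configs (e.g. a thermodynamics
#' stage with fewer than 3 temperatures) instead of failing mid-run.
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly; errors on invalid configs.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$titration) &&
      !inherits(cfg$titration, "titration_series")) {
    stop("titration must be a titration_series", call. = FALSE)
  }
  if (!is.null(cfg$quench)) {
    if (!all(vapply(cfg$quench, inherits, logical(1), "titration_series"))) {
      stop("quench must be a list of titration_series", call. = FALSE)
    }
  }
  nT <- if (is.null(cfg$quench)) 0L else
    length(unique(vapply(cfg$quench, `[[`, numeric(1), "temperature")))
  if (isTRUE(cfg$run_thermo) && nT < 3L) {
    stop("thermodynamics stage enabled but fewer than 3 distinct ",
         "temperatures provided", call. = FALSE)
  }
  if (!is.null(cfg$fret)) {
    need <- c("F_DA", "F_D", "donor_em", "acceptor_eps", "constants",
              "tau_D")
    miss <- setdiff(need, names(cfg$fret))
    if (length(miss)) {
      stop("fret config missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

.report_row <- function(stage, name, value, unit, stderr = NA_real_) {
  data.frame(stage = stage, name = name, value = as.numeric(value),
             unit = unit, stderr = stderr, stringsAsFactors = FALSE)
}

#' Run the spectroscopic binding-analysis pipeline
#'
#' Executes the enabled stages in dependency order — preprocessing, Hill
#' binding, Stern-Volmer quenching, van't Hoff thermodynamics, lifetime
#' fitting, the FRET chain, CMC, roughness — with stage isolation: one
#' failing stage is recorded as a failure and the rest still run. The exit
#' status (`ok`) is TRUE only when every enabled stage converged.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `analysis_report`: `values` (data.frame of
#'   stage, name, value, unit, stderr), `stages` (full per-stage result
#'   objects), `failures` (named character), `provenance`, `ok`.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  values <- list()
  stages <- list()
  failures <- character(0)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[name]] <<- conditionMessage(res)
    } else {
      stages[[name]] <<- res
    }
  }

  # --- preprocess + binding (absorbance titration) ------------------------
  if (!is.null(cfg$titration)) {
    run_stage("preprocess", function() {
      ser <- cfg$titration
      iso <- find_isosbestic(ser)
      prof <- shift_profile(ser)
      first <- band_descriptor(ser$entries[[1L]])
      last <- band_descriptor(ser$entries[[length(ser$entries)]])
      for (k in seq_along(iso)) {
        values[[length(values) + 1L]] <<-
          .report_row("preprocess", sprintf("isosbestic_%d", k), iso[k],
                      "nm")
      }
      values[[length(values) + 1L]] <<-
        .report_row("preprocess", "lambda_max_free", first$lambda_max, "nm")
      values[[length(values) + 1L]] <<-
        .report_row("preprocess", "lambda_max_bound", last$lambda_max, "nm")
      values[[length(values) + 1L]] <<-
        .report_row("preprocess", "fwhm_free", first$fwhm, "nm")
      values[[length(values) + 1L]] <<-
        .report_row("preprocess", "fwhm_bound", last$fwhm, "nm")
      list(isosbestic = iso, shift_profile = prof, band_free = first,
           band_bound = last)
    })
    run_stage("binding_hill", function() {
      ser <- cfg$titration
      # track absorbance around the initial band maximum across the
      # titration; a +-3 nm window mean suppresses single-channel noise
      # without distorting the two-state mixing curve (it stays linear in
      # the bound fraction)
      lam <- band_descriptor(ser$entries[[1L]])$lambda_max
      resp <- vapply(ser$entries, function(s) {
        win <- seq(lam - 3, lam + 3, length.out = 7)
        mean(stats::approx(s$wavelengths, s$values, win)$y)
      }, numeric(1))
      fit <- hill1_fit(ser$concentrations, resp)
      fit$K_b_molar <- convert_kd_to_molar(fit$k_D, cfg$mw)
      values[[length(values) + 1L]] <<-
        .report_row("binding", "k_D", fit$k_D, ser$unit)
      values[[length(values) + 1L]] <<-
        .report_row("binding", "n_hill", fit$n_hill, "1")
      values[[length(values) + 1L]] <<-
        .report_row("binding", "K_b", fit$K_b_molar, "M^-1")
      values[[length(values) + 1L]] <<-
        .report_row("binding", "r_squared", fit$r_squared, "1")
      fit
    })
  }

  # --- quenching + thermodynamics -----------------------------------------
  if (!is.null(cfg$quench)) {
    run_stage("quenching", function() {
      fits <- lapply(cfg$quench, function(ts) {
        q <- ts$concentrations
        F <- ts$entries
        i0 <- which(q == 0)
        F0 <- if (length(i0)) F[i0[1L]] else max(F)
        keep <- q > 0
        sv <- stern_volmer_fit(q[keep], F0, F[keep], tau0 = cfg$tau0)
        lh <- double_log_hill_fit(q[keep], F0, F[keep])
        list(temperature = ts$temperature, sv = sv, log_hill = lh)
      })
      for (f in fits) {
        values[[length(values) + 1L]] <<-
          .report_row("quenching", sprintf("K_sv_T%g", f$temperature),
                      f$sv$K_sv, "M^-1")
        if (!is.na(f$sv$k_q)) {
          values[[length(values) + 1L]] <<-
            .report_row("quenching", sprintf("k_q_T%g", f$temperature),
                        f$sv$k_q, "M^-1 s^-1")
        }
        values[[length(values) + 1L]] <<-
          .report_row("quenching", sprintf("K_a_T%g", f$temperature),
                      f$log_hill$K_a, "M^-1")
        values[[length(values) + 1L]] <<-
          .report_row("quenching", sprintf("n_T%g", f$temperature),
                      f$log_hill$n, "1")
      }
      fits
    })
    thermo_on <- if (is.null(cfg$run_thermo)) {
      !is.null(stages$quenching) && length(stages$quenching) >= 3L
    } else {
      isTRUE(cfg$run_thermo) && !is.null(stages$quenching)
    }
    if (thermo_on) {
      run_stage("thermo", function() {
        T <- vapply(stages$quenching, `[[`, numeric(1), "temperature")
        ka <- vapply(stages$quenching, function(f) f$log_hill$K_a,
                     numeric(1))
        th <- vant_hoff_fit(data.frame(T = T, Ka = ka))
        values[[length(values) + 1L]] <<-
          .report_row("thermo", "delta_H", th$delta_H, "kJ/mol")
        values[[length(values) + 1L]] <<-
          .report_row("thermo", "delta_S", th$delta_S, "J/(mol K)")
        for (nm in names(th$delta_G)) {
          values[[length(values) + 1L]] <<-
            .report_row("thermo", sprintf("delta_G_T%s", nm),
                        th$delta_G[[nm]], "kJ/mol")
        }
        th
      })
    }
  }

  # --- lifetimes -----------------------------------------------------------
  if (!is.null(cfg$decay)) {
    run_stage("lifetime", function() {
      fit <- multiexp_fit(cfg$decay, m = cfg$decay_components,
                          mode = cfg$decay_mode)
      for (i in seq_along(fit$taus)) {
        values[[length(values) + 1L]] <<-
          .report_row("lifetime", sprintf("tau_%d", i), fit$taus[i], "ns")
        values[[length(values) + 1L]] <<-
          .report_row("lifetime", sprintf("alpha_%d", i), fit$alphas[i],
                      "1")
      }
      values[[length(values) + 1L]] <<-
        .report_row("lifetime", "tau_av", fit$tau_av, "ns")
      values[[length(values) + 1L]] <<-
        .report_row("lifetime", "chi2_red", fit$chi2_red, "1")
      fit
    })
  }
  if (!is.null(cfg$lifetime_sv)) {
    run_stage("lifetime_sv", function() {
      f <- lifetime_stern_volmer(cfg$lifetime_sv$tau0, cfg$lifetime_sv$q,
                                 cfg$lifetime_sv$taus)
      values[[length(values) + 1L]] <<-
        .report_row("lifetime", "K_D_dynamic", f$K_D, "M^-1")
      f
    })
  }

  # --- FRET ---------------------------------------------------------------
  if (!is.null(cfg$fret)) {
    run_stage("fret", function() {
      fr <- do.call(fret_chain, cfg$fret)
      for (nm in c("E", "J", "R0", "r", "k_ET", "k_r", "sum_k_nr",
                   "total_k_nr")) {
        un <- switch(nm, E = "1", J = "nm^4 M^-1 cm^-1", R0 = "A", r = "A",
                     "s^-1")
        if (!is.na(fr[[nm]])) {
          values[[length(values) + 1L]] <<- .report_row("fret", nm,
                                                        fr[[nm]], un)
        }
      }
      values[[length(values) + 1L]] <<-
        .report_row("fret", "kappa2", fr$constants$kappa2, "1")
      values[[length(values) + 1L]] <<-
        .report_row("fret", "n_refractive", fr$constants$n_ri, "1")
      values[[length(values) + 1L]] <<-
        .report_row("fret", "Q_D", fr$constants$q_donor, "1")
      fr
    })
  }

  # --- micelle ------------------------------------------------------------
  if (!is.null(cfg$pyrene)) {
    run_stage("cmc", function() {
      rs <- cfg$pyrene
      if (inherits(rs, "titration_series")) rs <- pyrene_ratio(rs)
      fit <- cmc_fit(rs, method = cfg$cmc_method)
      values[[length(values) + 1L]] <<-
        .report_row("micelle", "cmc", fit$cmc, "mg/mL")
      fit
    })
  }
  if (!is.null(cfg$afm)) {
    run_stage("roughness", function() {
      r <- roughness(cfg$afm)
      values[[length(values) + 1L]] <<-
        .report_row("micelle", "Ra", r$Ra, "nm")
      values[[length(values) + 1L]] <<-
        .report_row("micelle", "Rq", r$Rq, "nm")
      r
    })
  }

  vals <- if (length(values)) do.call(rbind, values) else
    data.frame(stage = character(0), name = character(0),
               value = numeric(0), unit = character(0),
               stderr = numeric(0), stringsAsFactors = FALSE)
  structure(list(values = vals, stages = stages, failures = failures,
                 provenance = list(seed = cfg$seed,
                                   constants = list(mw = cfg$mw,
                                                    tau0 = cfg$tau0),
                                   stages_run = names(stages)),
                 ok = length(failures) == 0L),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d stages, %d values, %s\n",
              length(x$stages), nrow(x$values),
              if (x$ok) "ok" else
                paste("FAILURES:", paste(names(x$failures),
                                         collapse = ", "))))
  if (nrow(x$values)) {
    print(x$values, row.names = FALSE)
  }
  invisible(x)
}

#' Write an analysis report
#'
#' Emits a machine-readable JSON document and a human-readable key/value
#' text table. Timestamps are deliberately excluded so identical inputs
#' give byte-identical reports.
#'
#' @param report An `analysis_report`.
#' @param json_path Path for the JSON document (NULL to skip).
#' @param txt_path Path for the text table (NULL to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, txt_path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  if (!is.null(json_path)) {
    doc <- list(values = report$values, failures = as.list(report$failures),
                provenance = report$provenance, ok = report$ok)
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    v <- report$values
    lines <- sprintf("%-12s %-20s %-22.15g %-16s %s", v$stage, v$name,
                     v$value, v$unit,
                     ifelse(is.na(v$stderr), "",
                            sprintf("%.3g", v$stderr)))
    writeLines(c(sprintf("%-12s %-20s %-22s %-16s %s", "stage", "name",
                         "value", "unit", "stderr"), lines), txt_path)
  }
  invisible(report)
}

#' Generate and write a complete synthetic study
#'
#' Produces one coherent set of fixture files — absorbance titration,
#' three-temperature quenching tables, a TCSPC decay with IRF, a pyrene
#' ratio table, and an AFM height map — plus `truth.json` recording every
#' generator parameter, so an end-to-end pipeline run can be checked
#' against the construction.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; per-generator seeds are derived from it.
#' @return Invisibly, a list with the generated objects and their truth
#'   parameters.
#' @export
simulate_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  tit <- gen_absorbance_titration(seed = seed)
  quench <- gen_quench_series(seed = seed + 1L)
  decay <- gen_decay(seed = seed + 2L)
  pyr <- gen_pyrene_ratio(seed = seed + 3L)
  afm <- gen_height_map(seed = seed + 4L)

  write_titration(tit, file.path(dir, "titration.csv"))
  for (i in seq_along(quench)) {
    ts <- quench[[i]]
    writeLines(c("conc_M,intensity",
                 paste(format(ts$concentrations, digits = 17, trim = TRUE),
                       format(ts$entries, digits = 17, trim = TRUE),
                       sep = ",")),
               file.path(dir, sprintf("quench_T%g.csv", ts$temperature)))
  }
  write_decay(decay, file.path(dir, "decay.csv"))
  utils::write.csv(as.data.frame(pyr),
                   file.path(dir, "pyrene_ratio.csv"), row.names = FALSE)
  write_height_map(afm, file.path(dir, "heightmap.csv"))

  truth <- list(titration = attr(tit, "truth"),
                isosbestic = attr(tit, "isosbestic"),
                quench = attr(quench, "truth"),
                decay = attr(decay, "truth"),
                pyrene = attr(pyr, "truth"),
                afm = attr(afm, "truth"),
                seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(titration = tit, quench = quench, decay = decay,
                 pyrene = pyr, afm = afm, truth = truth))
}
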