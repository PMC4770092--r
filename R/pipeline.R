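# End-to-end orchestration: simulate -> detect -> rates -> bellfit ->
# energetics -> fraction, with a machine-readable JSON report.

#' Default pipeline configuration
#'
#' A compact demonstration configuration: passive-mode traces at a grid of
#' trap separations (spanning the working force range) and inhibitor
#' concentrations, HMM detection, dwell rates, global Bell fits with
#' zero-force extrapolation, the closing equilibrium free energy, and a
#' closing-fraction recovery stage. Every stochastic step derives its seed
#' deterministically from the global seed.
#'
#' @param seed Global integer seed.
#' @return A named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    temperature_K = 298,
    simulate = list(
      trap_separations_nm = c(390, 410, 430, 450),
      concentrations = c(0.5, 1),
      conc_unit = "uM",
      k_close0 = 180, delta_x_close_nm = -0.1,
      k_open0 = 1, delta_x_open_nm = 1.5,
      protein_contraction_nm = 1.6,
      duration_s = 6,
      noise_sd_nm = 0.35
    ),
    fraction = list(
      delta_x_nm = 0.5,
      rate_ratio = c(4, 2, 1),
      concentrations_uM = c(100, 300, 1000),
      forces_pN = c(6, 8, 10, 12, 14),
      L_full_nm = 1.6,
      noise_frac = 0.05
    )
  )
}

.stage <- function(report, name, fun) {
  if (!is.null(report$failed) && report$failed) {
    report$stages[[name]] <- list(status = "skipped")
    return(report)
  }
  res <- tryCatch(fun(report), error = function(e) e)
  if (inherits(res, "error")) {
    report$stages[[name]] <- list(status = "failed",
                                  diagnostic = conditionMessage(res))
    report$failed <- TRUE
  } else {
    res$status <- "ok"
    report$stages[[name]] <- res
  }
  report
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order; a stage failure is recorded
#' with its diagnostic and all downstream stages are skipped. The report
#' is deterministic given config and seed (no timestamps), and carries
#' the config hash, seed and package version in its provenance.
#'
#' @param config A configuration list, see [default_pipeline_config()].
#' @param out_json Optional path; if given the report is written as JSON.
#' @return The report list, invisibly when `out_json` is given.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_json = NULL) {
  stopifnot(is.numeric(config$seed))
  cst <- lid_constants(config$temperature_K %||% 298)
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file), add = TRUE)
  saveRDS(config, cfg_file, version = 2)
  report <- list(
    provenance = list(
      package = "lidforce",
      version = as.character(utils::packageVersion("lidforce")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file))
    ),
    config = config,
    stages = list(),
    failed = FALSE
  )

  report <- .stage(report, "simulate", function(rep) {
    sc <- config$simulate
    traces <- list()
    i <- 0L
    for (conc in sc$concentrations) {
      for (sep in sc$trap_separations_nm) {
        i <- i + 1L
        tc <- trace_sim_config(
          k_close0 = sc$k_close0,
          delta_x_close_nm = sc$delta_x_close_nm,
          k_open0 = sc$k_open0, delta_x_open_nm = sc$delta_x_open_nm,
          concentration = conc, conc_unit = sc$conc_unit,
          protein_contraction_nm = sc$protein_contraction_nm,
          trap_separation_nm = sep,
          noise_sd_nm = sc$noise_sd_nm,
          duration_s = sc$duration_s,
          seed = config$seed * 1000L + i)
        traces[[i]] <- simulate_trace(tc)
      }
    }
    list(n_traces = length(traces), traces = I(traces))
  })

  report <- .stage(report, "detect", function(rep) {
    traces <- rep$stages$simulate$traces
    dwells <- lapply(traces, function(tr) {
      hmm <- fit_hmm(tr)
      extract_dwells(viterbi_path(hmm, tr), tr)
    })
    list(n_dwell_sets = length(dwells), dwells = I(dwells),
         total_transitions = sum(vapply(dwells, nrow, 0L)) -
           length(dwells))
  })

  report <- .stage(report, "rates", function(rep) {
    pts <- do.call(rbind, lapply(rep$stages$detect$dwells,
                                 rates_from_dwells,
                                 seed = config$seed))
    rownames(pts) <- NULL
    list(points = pts)
  })

  report <- .stage(report, "bellfit", function(rep) {
    pts <- rep$stages$rates$points
    fc <- fit_bell(pts[pts$direction == "closing", ], "closing",
                   constants = cst)
    fo <- fit_bell(pts[pts$direction == "opening", ], "opening",
                   constants = cst)
    zc <- extrapolate_zero_force(fc, per_concentration = TRUE)
    zo <- extrapolate_zero_force(fo)
    list(closing = list(delta_x_nm = fc$delta_x_nm,
                        delta_x_se_nm = fc$delta_x_se_nm,
                        k0 = as.list(fc$k0),
                        k0_se = as.list(fc$k0_se)),
         opening = list(delta_x_nm = fo$delta_x_nm,
                        delta_x_se_nm = fo$delta_x_se_nm,
                        k0 = unname(fo$k0), k0_se = unname(fo$k0_se)),
         zero_force = list(closing = I(zc), opening = I(zo)),
         fits = I(list(closing = fc, opening = fo)))
  })

  report <- .stage(report, "energetics", function(rep) {
    bf <- rep$stages$bellfit
    k0c <- unlist(bf$closing$k0)
    dG <- dG_from_rates(k0c, bf$opening$k0, cst)
    list(dG_zero_force_kBT = as.list(dG))
  })

  report <- .stage(report, "fraction", function(rep) {
    fr <- config$fraction
    if (is.null(fr)) return(list(note = "no fraction block configured"))
    set.seed(config$seed + 77L)
    pts <- do.call(rbind, lapply(seq_along(fr$concentrations_uM),
                                 function(i) {
      f <- closing_fraction_curve(fr$forces_pN, fr$delta_x_nm,
                                  fr$rate_ratio[i], fr$L_full_nm, cst)
      data.frame(force_pN = fr$forces_pN,
                 fraction = f * (1 + stats::rnorm(length(f),
                                                  sd = fr$noise_frac)),
                 conc = fr$concentrations_uM[i],
                 se = f * fr$noise_frac)
    }))
    ff <- fit_fraction_force(pts, L_full = fr$L_full_nm,
                             constants = cst)
    zf <- lapply(fr$concentrations_uM, function(cc)
      zero_force_fraction(ff, cc))
    list(delta_x_true_nm = fr$delta_x_nm,
         delta_x_nm = ff$delta_x_nm,
         delta_x_se_nm = ff$delta_x_se_nm,
         preferred_model = ff$preferred,
         zero_force_fraction = I(zf))
  })

  report$failed <- NULL
  if (!is.null(out_json)) {
    slim <- report
    slim$stages$simulate$traces <- NULL
    slim$stages$detect$dwells <- NULL
    slim$stages$rates$points <-
      as.data.frame(report$stages$rates$points)
    slim$stages$bellfit$fits <- NULL
    jsonlite::write_json(slim, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
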