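#' Default end-to-end pipeline configuration
#'
#' Nested configuration for [run_pipeline()], serialisable to YAML via
#' [write_config()]/[read_config()]. Physical constants default to the
#' subject-like reference conditions; closure constants are calibrated at
#' run time on the lumbar-drain arm unless `closure$calibrate` is `FALSE`.
#'
#' @return A `csfclear_config` nested list.
#' @export
default_config <- function() {
  structure(
    list(
      schema = 1L,
      seed = 1L,
      geometry = list(
        dz = 0.003, total_length = 0.756, cranial_length = 0.15,
        spinal_volume_ml = 100.3, cranial_volume_ml = 221.6,
        dh_spinal_mean = 5.87e-3
      ),
      waveform = list(
        period = 0.9, shape = "cardiac",
        target_systolic_velocity = -0.047
      ),
      therapy = list(
        aspiration_ml_min = 2.0, return_ml_min = 1.8,
        production_ml_min = 0.2, drain_ml_min = 0.2,
        z_aspiration = -0.44, z_return = -0.15, z_production = 0.10,
        kernel_halfwidth = 0.01, tilt_deg = 30
      ),
      streaming = list(
        interport_uss_neurapheresis = 0.37e-3,
        interport_uss_lumbar_drain = 0.23e-3,
        baseline_uss = 0.15e-3, cranial_attenuation = 50
      ),
      solver = list(
        duration_s = 86400, dt = 0.5, store_every_s = 300,
        initial_fraction = 0.1, slab_thickness = 0.003
      ),
      closure = list(
        k_mix = 0.05, calibrate = TRUE,
        target_global_pct = 6.5, target_cranial_pct = 6.6,
        sweep_efficiency = 0.5, d_cranial = 2e-7
      ),
      imaging = list(
        enabled = TRUE, gain = 1200, noise_sd = 4, bleach_rate = 2e-6,
        distortion = 0.08, n_rows = 32, n_cols = 512
      ),
      dispersion = list(
        nu = 0.89e-6, omega = 6.98, p = 152.6,
        length_cortical = 2e-3, length_spinal = 5.87e-3
      )
    ),
    class = "csfclear_config"
  )
}

#' Read / write a pipeline configuration as YAML
#' @param config A configuration list (see [default_config()]).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (block in names(base)) {
    if (is.list(base[[block]]) && !is.null(cfg[[block]])) {
      base[[block]][names(cfg[[block]])] <- cfg[[block]]
    } else if (!is.null(cfg[[block]])) {
      base[[block]] <- cfg[[block]]
    }
  }
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    rlang::abort(paste(
      "Unknown configuration blocks:", paste(unknown, collapse = ", ")
    ))
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic neuroaxis generation, waveform synthesis
#' and amplitude calibration, axial hydrodynamic characterisation, the
#' dispersion similitude table, parametric streaming profiles for both
#' therapy arms, closure calibration on the lumbar-drain arm, 24-h frozen
#' field transport for both arms, optional imaging emulation with
#' quantification, and agreement statistics between each simulated map and
#' its quantified emulation. All randomness derives from `config$seed`.
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Optional directory; when given, profiles, maps and the
#'   run summary are written as delimited text/YAML.
#' @param quiet Suppress progress messages.
#' @return A `csfclear_run` list with elements `profile`, `waveform`,
#'   `hydro`, `hydro_summary`, `similitude`, `therapies`, `streaming`,
#'   `closure`, `sims`, `maps`, `imaging`, `agreement` and `summary`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
        conditionMessage(e)))
    })
  }

  say("stage: geometry")
  profile <- stage("geometry", do.call(neuraxis_profile, config$geometry))
  fluid <- csf_fluid()

  say("stage: waveform")
  waveform <- stage("waveform", cardiac_waveform(
    period = config$waveform$period, shape = config$waveform$shape,
    profile = profile,
    target_systolic_velocity = config$waveform$target_systolic_velocity
  ))

  say("stage: hydrodynamics")
  hydro <- stage("hydrodynamics",
    characterize_hydrodynamics(profile, waveform, fluid))
  hsum <- hydro_summary(hydro, profile)

  say("stage: dispersion similitude")
  similitude <- stage("dispersion", similitude_table(
    default_dispersion_cases(
      fluid,
      length_cortical = config$dispersion$length_cortical,
      length_spinal = config$dispersion$length_spinal,
      nu = config$dispersion$nu, omega = config$dispersion$omega,
      p = config$dispersion$p
    )
  ))

  therapy_of <- function(mode) {
    therapy_config(
      mode,
      aspiration_ml_min = config$therapy$aspiration_ml_min,
      return_ml_min = config$therapy$return_ml_min,
      production_ml_min = config$therapy$production_ml_min,
      drain_ml_min = config$therapy$drain_ml_min,
      z_aspiration = config$therapy$z_aspiration,
      z_return = config$therapy$z_return,
      z_production = config$therapy$z_production,
      kernel_halfwidth = config$therapy$kernel_halfwidth,
      tilt_deg = config$therapy$tilt_deg
    )
  }
  therapies <- list(
    neurapheresis = therapy_of("neurapheresis"),
    lumbar_drain = therapy_of("lumbar_drain")
  )

  say("stage: streaming")
  streaming <- stage("streaming", purrr::imap(therapies, function(th, nm) {
    parametric_streaming(
      profile, th,
      interport_uss = config$streaming[[paste0("interport_uss_", nm)]],
      baseline_uss = config$streaming$baseline_uss,
      cranial_attenuation = config$streaming$cranial_attenuation
    )
  }))

  if (isTRUE(config$closure$calibrate)) {
    say("stage: closure calibration (lumbar-drain arm)")
    closure <- stage("calibration", calibrate_transport(
      profile, therapies$lumbar_drain, streaming$lumbar_drain,
      k_mix = config$closure$k_mix,
      target_global_pct = config$closure$target_global_pct,
      target_cranial_pct = config$closure$target_cranial_pct,
      duration_s = config$solver$duration_s, dt = config$solver$dt
    ))
  } else {
    closure <- transport_closure(
      k_mix = config$closure$k_mix,
      sweep_efficiency = config$closure$sweep_efficiency,
      d_cranial = config$closure$d_cranial
    )
  }

  say("stage: transport (both arms)")
  sims <- stage("transport", purrr::imap(therapies, function(th, nm) {
    simulate_transport(
      profile, streaming[[nm]], th, closure,
      duration_s = config$solver$duration_s, dt = config$solver$dt,
      store_every_s = config$solver$store_every_s,
      initial_fraction = config$solver$initial_fraction
    )
  }))
  maps <- purrr::map(sims, axial_concentration,
    slab_thickness = config$solver$slab_thickness
  )

  imaging <- NULL
  agreement <- NULL
  if (isTRUE(config$imaging$enabled) &&
    length(sims[[1]]$time_s) >= 3) {
    say("stage: imaging emulation")
    optics <- optics_config(
      gain = config$imaging$gain, noise_sd = config$imaging$noise_sd,
      bleach_rate = config$imaging$bleach_rate,
      distortion = config$imaging$distortion,
      n_rows = config$imaging$n_rows, n_cols = config$imaging$n_cols
    )
    imaging <- stage("imaging", purrr::imap(sims, function(sim, nm) {
      seed <- config$seed + match(nm, names(sims))
      stack <- synthesize_stack(sim, optics, seed = seed)
      list(
        stack = stack,
        map = quantify_stack(stack, z_grid = unique(maps[[nm]]$z_m))
      )
    }))
    say("stage: agreement statistics")
    agreement <- stage("agreement", purrr::imap(sims, function(sim, nm) {
      agreement_stats(paired_flatten(maps[[nm]], imaging[[nm]]$map))
    }))
  }

  endpoints <- purrr::imap_dfr(sims, function(sim, nm) {
    cs <- clearance_summary(sim, profile)
    last <- max(cs$time_s)
    tibble::tibble(
      therapy = nm,
      global_24h_pct = cs$alpha_pct[cs$region == "global" &
        cs$time_s == last],
      cranial_24h_pct = cs$alpha_pct[cs$region == "cranial" &
        cs$time_s == last]
    )
  })
  summary <- list(
    endpoints = endpoints,
    closure = closure,
    ordering_ok = all(
      global_concentration(sims$neurapheresis)[sims$neurapheresis$time_s >=
        3600] <=
        global_concentration(sims$lumbar_drain)[sims$lumbar_drain$time_s >=
          3600] + 1e-12
    )
  )

  run <- structure(
    list(
      config = config, profile = profile, waveform = waveform,
      hydro = hydro, hydro_summary = hsum, similitude = similitude,
      therapies = therapies, streaming = streaming, closure = closure,
      sims = sims, maps = maps, imaging = imaging, agreement = agreement,
      summary = summary
    ),
    class = "csfclear_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.csfclear_run <- function(x, ...) {
  cat("<csfclear_run>\n")
  print(x$summary$endpoints)
  cat(
    "ordering (neurapheresis <= lumbar drain from 1 h):",
    x$summary$ordering_ok, "\n"
  )
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_profile(run$profile, p("profile.tsv"))
  write_waveform(run$waveform, p("waveform.tsv"))
  readr::write_tsv(run$hydro, p("hydro.tsv"))
  readr::write_tsv(run$similitude, p("similitude.tsv"))
  purrr::iwalk(run$streaming, function(s, nm) {
    write_streaming(s, p(paste0("streaming_", nm, ".tsv")))
  })
  purrr::iwalk(run$maps, function(m, nm) {
    readr::write_tsv(m, p(paste0("map_", nm, ".tsv")))
  })
  cal <- attr(run$closure, "calibration")
  summary <- list(
    endpoints = as.list(tidyr::pivot_wider(
      tidyr::pivot_longer(run$summary$endpoints, -"therapy"),
      names_from = c("therapy", "name"), values_from = "value"
    )),
    closure = unclass(run$closure),
    calibration = if (!is.null(cal)) as.list(cal),
    ordering_ok = run$summary$ordering_ok
  )
  yaml::write_yaml(summary, p("summary.yaml"))
  invisible(out_dir)
}

#' Compare the concentration maps of two pipeline runs
#'
#' @param run_a,run_b `csfclear_run` objects (or long concentration maps).
#' @param arm Which therapy arm's map to compare when runs are given.
#' @param mask Optional mask, see [paired_flatten()].
#' @return An [agreement_stats()] object.
#' @export
compare_runs <- function(run_a, run_b, arm = "neurapheresis", mask = NULL) {
  pick <- function(x) {
    if (inherits(x, "csfclear_run")) x$maps[[arm]] else x
  }
  agreement_stats(paired_flatten(pick(run_a), pick(run_b), mask = mask))
}
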