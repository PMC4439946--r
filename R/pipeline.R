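#' Default experiment configuration
#'
#' Nested list of every tunable parameter of the end-to-end experiment with
#' the study defaults: prescription 60 Gy in 30 fractions of 2 Gy, full-arc
#' arrangement, 3 mm spot spacing, 3 mm in-air spot sigma, 1 MeV energy
#' resolution with 1% energy spread, 6 mm energy-margin uncertainty, PTV
#' objectives 58-60 Gy, ring maximum 60 Gy with at most 3% of the ring
#' above 54 Gy, and per-fraction setup shifts with 2 mm sigma, 4 mm
#' per-axis cutoff and 6 mm maximum 3D norm. Any field can be overridden
#' via `overrides` (a nested list merged over the defaults).
#'
#' @param overrides nested list of fields to override.
#' @return nested configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    phantom = list(body_radius = 80, body_height = 112, ctv_radius = 25,
                   cavity_radius = 20, cavity_direction = c(-1, 0, 0),
                   cavity_gap = 0, spacing = c(2, 2, 2), ptv_margin = 5,
                   ring_thickness = 10),
    arrangement = list(kind = "full_arc", start_angle = 0),
    planning = list(spot_spacing = 3, d = 6, shape = "box",
                    sigma_air = 3, energy_spread = 0.01),
    objectives = list(ptv_min = 58, ptv_max = 60, ring_max = 60,
                      ring_dvh_dose = 54, ring_dvh_frac = 0.03),
    optimizer = list(iters = 250, tol = 1e-6, rounds = 5, escalate = 5,
                     tighten = 0.5, body_fraction = 0.1, threshold = 1e-3),
    course = list(n_fractions = 30, sigma = 2, cutoff = 4, max_3d = 6,
                  seed = 1),
    engine = list(alpha = 0.0022, p = 1.77, mcs_frac = 0.02),
    evaluation = list(prescription = 60, dref = 2,
                      alpha_beta = c(ctv = 10, ring = 1.5), bin_width = 0.1)
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config`: the configuration merged over the defaults.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cfg_model <- function(config) {
  beam_model(alpha = config$engine$alpha, p = config$engine$p,
             sigma_air = config$planning$sigma_air,
             energy_spread = config$planning$energy_spread,
             mcs_frac = config$engine$mcs_frac)
}

cfg_phantom_spec <- function(config) {
  ph <- config$phantom
  cavity <- if (is.null(ph$cavity_radius) || ph$cavity_radius <= 0) NULL
            else list(radius = ph$cavity_radius,
                      direction = ph$cavity_direction, gap = ph$cavity_gap)
  phantom_spec(body = list(radius = ph$body_radius, height = ph$body_height),
               ctv = list(center = c(0, 0, 0), radius = ph$ctv_radius),
               cavity = cavity, spacing = ph$spacing,
               ptv_margin = ph$ptv_margin,
               ring_thickness = ph$ring_thickness)
}

#' Run the full planning-and-robustness experiment
#'
#' Executes phantom generation, DET planning (ORG delivering the nominal
#' energies, EM the margined ones), fluence optimization of both plans
#' against the same objectives, a shared-shift fractionated course
#' simulation, and NTD/DVH evaluation. When `out_dir` is given, all
#' artifacts (volumes, plans, shifts, DVHs, reports, config) are written
#' there.
#'
#' @param config a [default_config()] list.
#' @param out_dir optional output directory.
#' @param seed overrides `config$course$seed` when given.
#' @param verbose print stage progress.
#' @return list with the phantom, plans, fits, planned dose grids, shift
#'   set, course, reports (`org` and `em`), and plan summaries.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL, verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  if (!is.null(seed)) config$course$seed <- seed
  model <- cfg_model(config)

  say("stage: phantom")
  ph <- make_phantom(cfg_phantom_spec(config))
  dv <- ph$volume
  ss <- ph$structures
  mm <- assign_materials(dv)

  say("stage: DET planning")
  arr <- make_arrangement(config$arrangement$kind,
                          config$arrangement$start_angle)
  plan <- build_det_plan(dv, mm, ss, arr,
                         spacing = config$planning$spot_spacing,
                         d = config$planning$d,
                         shape = config$planning$shape, model = model)
  info <- plan_info(plan)
  say(sprintf("  %d spots over %d beams; mean E0 %.2f MeV, mean E1 %.2f MeV",
              info$n_spots, info$n_beams, info$mean_E0, info$mean_E1))

  say("stage: optimization")
  obj <- plan_objectives(ptv_min = config$objectives$ptv_min,
                         ptv_max = config$objectives$ptv_max,
                         ring_max = config$objectives$ring_max,
                         ring_dvh_dose = config$objectives$ring_dvh_dose,
                         ring_dvh_frac = config$objectives$ring_dvh_frac)
  fits <- lapply(c(org = "E0", em = "E1"), function(en) {
    infl <- build_influence(dv, mm, plan, ss, energy = en,
                            body_fraction = config$optimizer$body_fraction,
                            threshold = config$optimizer$threshold,
                            model = model)
    optimize_weights(infl, obj, iters = config$optimizer$iters,
                     tol = config$optimizer$tol,
                     rounds = config$optimizer$rounds,
                     escalate = config$optimizer$escalate,
                     tighten = config$optimizer$tighten)
  })
  org_plan <- set_weights(plan, fits$org$weights, "E0")
  em_plan <- set_weights(plan, fits$em$weights, "E1")
  say(sprintf("  objective: ORG %.4g (%d it), EM %.4g (%d it)",
              min(fits$org$objective), fits$org$iterations,
              min(fits$em$objective), fits$em$iterations))

  say("stage: planned dose")
  planned <- list(org = plan_dose(dv, mm, org_plan, model = model),
                  em = plan_dose(dv, mm, em_plan, model = model))

  say("stage: course simulation")
  shifts <- sample_shifts(n = config$course$n_fractions,
                          sigma = config$course$sigma,
                          cutoff = config$course$cutoff,
                          seed = config$course$seed,
                          max_3d = config$course$max_3d)
  eval_mask <- ss$masks$CTV | ss$masks$ring
  course <- simulate_course(dv, mm, org_plan, em_plan, shifts,
                            mask = eval_mask, model = model)

  say("stage: evaluation")
  ev <- config$evaluation
  reports <- list(
    org = variation_report(planned$org, course$org, ss,
                           prescription = ev$prescription,
                           alpha_beta = ev$alpha_beta, dref = ev$dref,
                           bin_width = ev$bin_width),
    em = variation_report(planned$em, course$em, ss,
                          prescription = ev$prescription,
                          alpha_beta = ev$alpha_beta, dref = ev$dref,
                          bin_width = ev$bin_width)
  )

  result <- list(config = config, volume = dv, structures = ss,
                 materials = mm, org_plan = org_plan, em_plan = em_plan,
                 fits = fits, planned = planned, shifts = shifts,
                 course = course, reports = reports, info = info)

  if (!is.null(out_dir)) {
    say("stage: output")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_mhd(dv, file.path(out_dir, "density.mhd"))
    for (nm in names(ss$masks)) {
      write_mhd(ss$masks[[nm]], file.path(out_dir, paste0(nm, ".mhd")),
                spacing = dv$spacing, origin = dv$origin)
    }
    write_spot_plan(org_plan, file.path(out_dir, "plan_org"))
    write_spot_plan(em_plan, file.path(out_dir, "plan_em"))
    write_shifts(shifts, file.path(out_dir, "shifts.csv"))
    write_mhd(planned$org, file.path(out_dir, "planned_org.mhd"))
    write_mhd(planned$em, file.path(out_dir, "planned_em.mhd"))
    for (nm in names(reports)) {
      write_report(reports[[nm]], file.path(out_dir, paste0("report_", nm)))
      write_dvh(compute_dvh(planned[[nm]], ss$masks$CTV),
                file.path(out_dir, paste0("dvh_ctv_planned_", nm, ".csv")))
      write_dvh(compute_dvh(planned[[nm]], ss$masks$ring),
                file.path(out_dir, paste0("dvh_ring_planned_", nm, ".csv")))
    }
    conv <- data.frame(
      plan = rep(names(fits), vapply(fits, function(f) length(f$objective),
                                     0L)),
      iteration = unlist(lapply(fits, function(f)
        seq_along(f$objective) - 1L)),
      objective = unlist(lapply(fits, function(f) f$objective))
    )
    write.csv(conv, file.path(out_dir, "convergence.csv"),
              row.names = FALSE)
  }
  invisible(result)
}
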