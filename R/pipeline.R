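#' Run the full canalization analysis pipeline
#'
#' Executes, for every Bcd profile of an ensemble, the complete analysis
#' chain: median-profile selection; per-nucleus basin partitions over the
#' analysis window (Monte-Carlo plus bisection); basin-boundary spatial
#' profiles and their intersections with the maternal Hb gradient; shorted
#' -model hb border positions; basin-transition, family and (optionally)
#' border-mechanism and solution-class labels; Bcd threshold positions
#' against the median-model reference concentration; the family-stratified
#' positional variance table; response curves; and the
#' intersection/border correlation. Fully deterministic given `seed`.
#'
#' @param params A [circuit_parameters()] object.
#' @param ensemble A [bcd_ensemble()].
#' @param cad_table Cad [external_input_table()] (or constant).
#' @param hb0 Maternal Hb gradient, function of x (e.g.
#'   [gen_maternal_hb()]).
#' @param schedule A [mitosis_schedule()].
#' @param window Analysis window in %EL (default 37-57).
#' @param border_step Spatial step (%EL) of the continuous-x grid on which
#'   the shorted-model solution is evaluated for border extraction. The
#'   per-nucleus equations depend on position only through the Bcd/Cad
#'   inputs, so they extend to real-valued x; a sub-nucleus grid avoids
#'   quantizing border positions to the internuclear spacing (the
#'   step-like artifact of discrete lattices).
#' @param n_samples Monte-Carlo draws per basin partition (fast default
#'   1000; 10 000 reproduces the production setting).
#' @param seed Master seed; every stochastic draw derives from it.
#' @param refine,refine_tol Basin-boundary bisection controls.
#' @param delta_A Attractor capture radius for basin assignment.
#' @param delta_mech `delta_A`/`delta_M` radius for mechanism labels.
#' @param mechanisms Logical: classify border mechanisms (requires manifold
#'   tracing at the border nuclei).
#' @param tll_table Optional Tll [external_input_table()]; when supplied,
#'   full-model solutions are computed per profile and solution classes
#'   I/II/III assigned.
#' @param lattice_domain Full spatial domain for the full-model runs.
#' @param eq_control List of [find_equilibria()] settings used throughout
#'   (default `list(n_grid = 3, n_extra = 60)` — a lighter multistart than
#'   the single-point default, adequate for repeated scanning).
#' @param out_dir Optional directory: all stage artifacts are written as
#'   CSVs.
#' @return Object of class `canalization_run`: list with `records` (per-
#'   profile data frame), `summary` (variance table), `response_intersection`,
#'   `response_border`, `correlation`, `median_profile`,
#'   `threshold_reference`, `partitions`, `boundary_curves`, `settings`.
#' @export
run_pipeline <- function(params, ensemble, cad_table, hb0,
                         schedule = mitosis_schedule(),
                         window = c(37, 57), border_step = 0.25,
                         n_samples = 1000L, seed = 1L,
                         refine = TRUE, refine_tol = 0.01, delta_A = 1.0,
                         delta_mech = 5, mechanisms = TRUE,
                         tll_table = NULL, lattice_domain = c(35, 92),
                         eq_control = list(n_grid = 3L, n_extra = 60L),
                         out_dir = NULL) {
  if (nrow(ensemble) == 0L) .err("empty ensemble",
                                 "gapcanal_invalid_input")
  positions <- build_lattice(window, "13")$positions
  np <- length(positions)
  median_profile <- select_median_profile(ensemble)
  cad_funs <- lapply(positions, function(x) {
    external_input_fun(cad_table, x, schedule)
  })
  cad_T6 <- vapply(cad_funs, function(f) f(schedule$t_T6), numeric(1))
  xgrid <- seq(window[1], window[2], by = border_step)
  cad_grid_fun <- external_input_fun(cad_table, xgrid, schedule)
  hb0_pos <- hb0(positions)
  solution_classes <- !is.null(tll_table)

  run_one <- function(j) {
    prof <- ensemble_member(ensemble, ensemble$embryo_id[j])
    bcd_pos <- eval_bcd(prof, positions)
    # equilibria (attractors + saddles) per position
    eqs <- lapply(seq_len(np), function(i) {
      do.call(find_equilibria,
              c(list(bcd = bcd_pos[i], cad = cad_T6[i], params = params),
                eq_control))
    })
    atts <- lapply(eqs, .label_attractors)
    partitions <- lapply(seq_len(np), function(i) {
      sample_basin_partition(
        bcd_pos[i], cad_funs[[i]], params, schedule,
        n_samples = n_samples, seed = .sub_seed(seed, j, i),
        delta_A = delta_A, refine = refine, refine_tol = refine_tol,
        attractors = atts[[i]])
    })
    names(partitions) <- as.character(positions)
    # shorted-model solution from the biological initial conditions on a
    # continuous-x grid (borders) and at the basin nuclei (mechanisms)
    sol <- integrate_shorted_ensemble(
      cbind(rbind(hb0(xgrid), 0, 0, 0), rbind(hb0_pos, 0, 0, 0)),
      c(eval_bcd(prof, xgrid), bcd_pos),
      local({
        ng <- length(xgrid)
        function(t) c(cad_grid_fun(t),
                      vapply(cad_funs, function(f) f(t), numeric(1)))
      }),
      params, schedule, times = c(schedule$t0, schedule$tau))
    ig <- seq_along(xgrid)
    hb_tau <- sol$states[[2L]]["hb", ig]
    end_pos <- sol$states[[2L]][, -ig, drop = FALSE]
    flags <- character(0)
    border <- tryCatch(
      border_position_shorted(xgrid, hb_tau, window),
      error = function(e) { flags <<- c(flags, "border_absent"); NULL })
    transition <- list(from = NA, to = NA, transition = NA_character_,
                       family = "unclassified")
    x_star <- NA_real_
    mech <- NA_character_
    border_x <- if (is.null(border)) NA_real_ else border$border_x
    if (!is.null(border) &&
        (border_x < positions[1L] || border_x >= positions[np])) {
      flags <- c(flags, "border_outside_lattice")
      border <- NULL
    }
    if (!is.null(border)) {
      # border nuclei: nearest lattice nuclei anterior/posterior to border_x
      ia <- max(which(positions <= border$border_x))
      ip <- min(which(positions > border$border_x))
      transition <- tryCatch(
        classify_basin_transition(partitions[[ia]], partitions[[ip]],
                                  hb0_pos[ia], hb0_pos[ip]),
        error = function(e) {
          flags <<- c(flags, "transition_unresolved")
          list(from = NA, to = NA, transition = NA_character_,
               family = "unclassified")
        })
      if (!is.na(transition$transition) && transition$transition != "none") {
        curve <- tryCatch(
          basin_boundary_profile(partitions,
                                 pair = c(transition$from, transition$to)),
          error = function(e) { flags <<- c(flags, "boundary_absent"); NULL })
        if (!is.null(curve)) {
          hits <- intersect_initial_hb(hb0, curve)
          if (length(hits)) {
            x_star <- hits[which.min(abs(hits - border$border_x))]
          } else flags <- c(flags, "no_intersection")
        }
      } else if (!is.na(transition$transition)) {
        flags <- c(flags, "no_basin_transition")
      }
      if (mechanisms) {
        ends <- list(end_pos[, ia], end_pos[, ip])
        manifolds <- lapply(c(ia, ip), function(i) {
          sads <- Filter(function(e) e$stability == "saddle_1", eqs[[i]])
          lapply(sads, function(s) {
            trace_unstable_manifold(s, bcd_pos[i], cad_T6[i], params,
                                    n_out = 400L)
          })
        })
        mech <- classify_border_mechanism(
          ends[[1L]], ends[[2L]], atts[[ia]], atts[[ip]],
          manifolds[[1L]], manifolds[[2L]],
          delta_A = delta_mech, delta_M = delta_mech)$mechanism
      }
    }
    sclass <- NA_character_
    if (solution_classes) {
      lat13 <- build_lattice(lattice_domain, "13")
      fsol <- integrate_full_circuit(
        hb0, prof, cad_table, tll_table, params, schedule, lat13,
        times = schedule$tau, rtol = 1e-6, atol = 1e-6)
      st <- state_at(fsol, schedule$tau)
      keep <- st$lattice$positions <= 71
      sclass <- classify_solution_class(
        st$lattice$positions[keep], st$state["Kr", keep],
        st$state["gt", keep])$class
    }
    list(record = data.frame(
           profile_id = ensemble$embryo_id[j],
           A = prof$A, l = prof$l,
           border = border_x,
           intersection = x_star,
           transition = if (is.na(transition$transition)) NA_character_
                        else transition$transition,
           family = transition$family,
           mechanism = mech, solution_class = sclass,
           flags = paste(flags, collapse = ";"),
           stringsAsFactors = FALSE),
         partitions = partitions)
  }

  results <- lapply(seq_len(nrow(ensemble)), run_one)
  records <- do.call(rbind, lapply(results, `[[`, "record"))
  partitions_all <- lapply(results, `[[`, "partitions")
  names(partitions_all) <- as.character(ensemble$embryo_id)

  # Bcd threshold positions: reference concentration = the median profile's
  # level at the median-model hb border
  med_border <- records$border[match(median_profile$embryo_id,
                                     records$profile_id)]
  threshold_reference <- NA_real_
  if (!is.na(med_border)) {
    threshold_reference <- eval_bcd(median_profile, med_border)
    records$threshold <- vapply(seq_len(nrow(records)), function(j) {
      tryCatch(threshold_position(
        bcd_exponential(records$A[j], records$l[j]), threshold_reference),
        error = function(e) NA_real_)
    }, numeric(1))
  } else {
    records$threshold <- NA_real_
  }

  summary_df <- family_stratified_summary(records)
  resp_int <- response_curve(ensemble, records$intersection,
                             "intersection",
                             class_tag = records$solution_class)
  resp_bor <- response_curve(ensemble, records$border, "border",
                             class_tag = records$solution_class)
  correlation <- tryCatch(
    correlate_positions(records$intersection, records$border),
    error = function(e) NA_real_)

  out <- structure(list(
    records = records, summary = summary_df,
    response_intersection = resp_int, response_border = resp_bor,
    correlation = correlation, median_profile = median_profile,
    threshold_reference = threshold_reference,
    partitions = partitions_all,
    settings = list(window = window, n_samples = n_samples, seed = seed,
                    refine = refine, refine_tol = refine_tol,
                    delta_A = delta_A, delta_mech = delta_mech,
                    positions = positions)),
    class = "canalization_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    write_summary(summary_df, file.path(out_dir, "summary.csv"))
    utils::write.csv(resp_int,
                     file.path(out_dir, "response_intersection.csv"),
                     row.names = FALSE)
    utils::write.csv(resp_bor, file.path(out_dir, "response_border.csv"),
                     row.names = FALSE)
    cls <- data.frame(profile_id = records$profile_id,
                      mechanism = records$mechanism,
                      transition = records$transition,
                      family = records$family,
                      solution_class = records$solution_class,
                      flags = records$flags)
    write_classification(cls, file.path(out_dir, "classification.csv"))
    for (id in names(partitions_all)) {
      write_partitions(partitions_all[[id]],
                       file.path(out_dir, paste0("partitions_", id,
                                                 ".csv")))
    }
  }
  out
}

#' @export
print.canalization_run <- function(x, ...) {
  cat(sprintf("Canalization analysis: %d profiles, window %g-%g %%EL\n",
              nrow(x$records), x$settings$window[1], x$settings$window[2]))
  cat(sprintf("  families: %s\n",
              paste(names(table(x$records$family)),
                    table(x$records$family), sep = "=", collapse = ", ")))
  ok <- !is.na(x$records$border)
  if (any(ok)) {
    cat(sprintf("  hb border sd: %.3f %%EL over %d profiles\n",
                stats::sd(x$records$border[ok]), sum(ok)))
  }
  ok2 <- !is.na(x$records$threshold)
  if (any(ok2)) {
    cat(sprintf("  Bcd threshold sd: %.3f %%EL\n",
                stats::sd(x$records$threshold[ok2])))
  }
  cat(sprintf("  intersection/border correlation: %.3f\n", x$correlation))
  invisible(x)
}
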