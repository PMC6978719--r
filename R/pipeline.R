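# End-to-end study replica: sample a cohort, apply exclusions, solve each
# lesion, measure the five-point indices, and run the cohort statistics.
# Everything is driven by one validated configuration object and a single
# root seed, so a run is reproducible from (config, seed) alone.

#' Build a validated run configuration
#'
#' Nested configuration for [run_pipeline()]. Every entry has a default;
#' overrides are supplied as nested lists (or loaded from YAML with
#' [read_run_config()]).
#'
#' @param n cohort size (default 55).
#' @param seed root seed (mandatory for cohort runs).
#' @param geometry_mode `"axisymmetric"` (default) or `"eccentric"`.
#' @param population overrides for [cohort_population()].
#' @param solver list: `axial_cells`, `radial_cells`,
#'   `convergence_tolerance`, `max_iterations`, `under_relaxation`
#'   (`vorticity`, `wall`), `psi_sor`, `psi_sweeps`, `reynolds_cap`,
#'   `fluid` (`density`, `dynamic_viscosity`), `outlet` (`kind`,
#'   `distal_pressure`, `distal_resistance`).
#' @param measurement list: `deficit_threshold`, `point_tolerance`.
#' @param stats list: `cutoff_percent`, `alpha`, `posthoc`
#'   (`"wilcoxon"`/`"conover"`).
#' @param verbosity 0 (quiet), 1 (per-stage), 2 (per-case).
#' @return object of class `run_config`.
#' @export
run_config <- function(n = 55L, seed = 1L,
                       geometry_mode = c("axisymmetric", "eccentric"),
                       population = list(), solver = list(),
                       measurement = list(), stats = list(),
                       verbosity = 0L) {
  geometry_mode <- match.arg(geometry_mode)
  if (missing(seed) || is.null(seed)) {
    icas_stop("icasflow_config_error", "config field `seed` is mandatory")
  }
  check_scalar(n, "n", positive = TRUE, class = "icasflow_config_error")
  check_scalar(seed, "seed", class = "icasflow_config_error")

  solver_defaults <- list(
    axial_cells = 256L, radial_cells = 48L,
    convergence_tolerance = 1e-6, max_iterations = 40000L,
    under_relaxation = list(vorticity = 1.0, wall = 0.6),
    psi_sor = 1.8, psi_sweeps = 8L, reynolds_cap = 2000,
    fluid = list(density = 1060, dynamic_viscosity = 3.5e-3),
    outlet = list(kind = "reference_pressure", distal_pressure = 0,
                  distal_resistance = 0))
  solver <- merge_config(solver_defaults, solver, "solver")
  measurement <- merge_config(list(deficit_threshold = 0.02,
                                   point_tolerance = 0.02),
                              measurement, "measurement")
  stats <- merge_config(list(cutoff_percent = 50, alpha = 0.05,
                             posthoc = "wilcoxon"),
                        stats, "stats")
  if (!stats$posthoc %in% c("wilcoxon", "conover")) {
    icas_stop("icasflow_config_error",
              "stats.posthoc must be 'wilcoxon' or 'conover'")
  }
  pop <- do.call(cohort_population, population)

  cfg <- structure(list(n = as.integer(n), seed = as.integer(seed),
                        geometry_mode = geometry_mode,
                        population = pop, solver = solver,
                        measurement = measurement, stats = stats,
                        verbosity = as.integer(verbosity)),
                   class = "run_config")
  # instantiate the solver objects once to validate every field
  cfg_solver_objects(cfg)
  cfg
}

merge_config <- function(defaults, overrides, path) {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) {
    icas_stop("icasflow_config_error",
              sprintf("config field `%s` must be a mapping", path))
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    icas_stop("icasflow_config_error",
              sprintf("unknown config field `%s.%s`", path, unknown[1]))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste(path, nm, sep = "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

cfg_solver_objects <- function(cfg) {
  s <- cfg$solver
  list(numerics = numerics_config(
         axial_cells = s$axial_cells, radial_cells = s$radial_cells,
         convergence_tolerance = s$convergence_tolerance,
         max_iterations = s$max_iterations,
         under_relaxation = c(vorticity = s$under_relaxation$vorticity,
                              wall = s$under_relaxation$wall),
         psi_sor = s$psi_sor, psi_sweeps = s$psi_sweeps,
         reynolds_cap = s$reynolds_cap),
       fluid = fluid_properties(s$fluid$density, s$fluid$dynamic_viscosity),
       outlet = outlet_model(s$outlet$kind, s$outlet$distal_pressure,
                             s$outlet$distal_resistance))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path. Top-level keys mirror the [run_config()]
#'   arguments (`n`, `seed`, `geometry_mode`, `population:`, `solver:`,
#'   `measurement:`, `stats:`, `verbosity`).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    icas_stop("icasflow_config_error", sprintf("no config file at '%s'", path))
  }
  y <- yaml::read_yaml(path)
  known <- c("n", "seed", "geometry_mode", "population", "solver",
             "measurement", "stats", "verbosity")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    icas_stop("icasflow_config_error",
              sprintf("unknown config field `%s`", unknown[1]))
  }
  if (is.null(y$seed)) {
    icas_stop("icasflow_config_error", "config field `seed` is mandatory")
  }
  args <- y[intersect(known, names(y))]
  if (!is.null(args$population)) {
    args$population <- lapply(args$population, function(v)
      if (is.list(v)) unlist(v) else v)
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `run_config` to serialise.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  # named vectors (side_probs) must serialise as YAML maps, not sequences
  y$population <- lapply(as.list(unclass(y$population)), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(y, path)
  invisible(path)
}

# stable polynomial hash of the deparsed config (provenance only)
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Measure one solved lesion
#'
#' Runs the measurement chain (lesion extent, five points, indices) on a
#' solved flow field.
#'
#' @param field a converged `flow_field`.
#' @param deficit_threshold passed to [detect_lesion_extent()].
#' @param point_tolerance passed to [classify_extremum_location()].
#' @return a `lesion_indices` object.
#' @export
measure_lesion <- function(field, deficit_threshold = 0.02,
                           point_tolerance = 0.02) {
  prof <- wall_profile(field)
  ext <- detect_lesion_extent(field$geometry, deficit_threshold)
  pts <- locate_five_points(prof, ext)
  extract_indices(prof, pts)
}

indices_row <- function(ind) {
  data.frame(
    wss_origin_pa = ind$wss_at[["origin"]],
    wss_mup_pa = ind$wss_at[["m_up"]],
    wss_apex_pa = ind$wss_at[["apex"]],
    wss_mdown_pa = ind$wss_at[["m_down"]],
    wss_terminal_pa = ind$wss_at[["terminal"]],
    pressure_origin_pa = ind$pressure_at[["origin"]],
    pressure_mup_pa = ind$pressure_at[["m_up"]],
    pressure_apex_pa = ind$pressure_at[["apex"]],
    pressure_mdown_pa = ind$pressure_at[["m_down"]],
    pressure_terminal_pa = ind$pressure_at[["terminal"]],
    wss_max_pa = ind$wss_max, wss_max_loc = ind$wss_max_loc,
    wss_min_pa = ind$wss_min, wss_min_loc = ind$wss_min_loc,
    pressure_max_pa = ind$pressure_max,
    pressure_max_loc = ind$pressure_max_loc,
    pressure_min_pa = ind$pressure_min,
    pressure_min_loc = ind$pressure_min_loc,
    wss_ratio_max_origin = ind$wss_ratio_max_over_origin,
    wss_ratio_min_origin = ind$wss_ratio_min_over_origin,
    pressure_ratio = ind$pressure_ratio_terminal_over_origin,
    pressure_drop_pa = ind$pressure_drop_total,
    drop_origin_mup_pa = ind$segment_drops[["origin_to_mup"]],
    drop_mup_apex_pa = ind$segment_drops[["mup_to_apex"]],
    drop_apex_mdown_pa = ind$segment_drops[["apex_to_mdown"]],
    drop_mdown_terminal_pa = ind$segment_drops[["mdown_to_terminal"]],
    stringsAsFactors = FALSE)
}

na_indices_row <- function() {
  row <- indices_row(structure(list(
    wss_at = stats::setNames(rep(NA_real_, 5),
                             c("origin", "m_up", "apex", "m_down", "terminal")),
    pressure_at = stats::setNames(rep(NA_real_, 5),
                                  c("origin", "m_up", "apex", "m_down",
                                    "terminal")),
    wss_max = NA_real_, wss_min = NA_real_, pressure_max = NA_real_,
    pressure_min = NA_real_, wss_max_loc = NA_character_,
    wss_min_loc = NA_character_, pressure_max_loc = NA_character_,
    pressure_min_loc = NA_character_,
    wss_ratio_max_over_origin = NA_real_,
    wss_ratio_min_over_origin = NA_real_,
    pressure_ratio_terminal_over_origin = NA_real_,
    pressure_drop_total = NA_real_,
    segment_drops = stats::setNames(rep(NA_real_, 4),
                                    c("origin_to_mup", "mup_to_apex",
                                      "apex_to_mdown", "mdown_to_terminal"))),
    class = "lesion_indices"))
  row
}

#' Run the full study replica
#'
#' Samples the synthetic cohort, applies the exclusion rules, solves the
#' steady flow for every retained lesion, measures the translesional
#' indices, and runs the cohort statistics. Per-case solver refusals
#' (Reynolds regime) and convergence failures are recorded with a reason and
#' excluded from the statistics, never silently dropped.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, the index table, the
#'   statistics tables and a provenance block are written there as
#'   CSV/YAML (see [write_run_report()]).
#' @return object of class `run_report`: `index_table` (one row per sampled
#'   lesion, with exclusion/solve status), `cohort_table` (retained, solved
#'   lesions only), `location_tables`, `correlation_tables`, `friedman`,
#'   `posthoc`, and a `provenance` block.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) {
    icas_stop("icasflow_config_error", "`config` must be a run_config")
  }
  vlog <- function(level, ...) {
    if (config$verbosity >= level) message(sprintf(...))
  }
  objs <- cfg_solver_objects(config)

  vlog(1, "sampling cohort: n = %d, seed = %d", config$n, config$seed)
  cohort <- sample_cohort(config$n, config$seed, config$population)
  excl <- exclusion_filter(cohort)
  vlog(1, "exclusions: %d of %d lesions excluded",
       nrow(excl$excluded), nrow(cohort))

  status <- character(nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))
  if (nrow(excl$excluded) > 0) {
    ix <- match(excl$excluded$case_id, cohort$case_id)
    status[ix] <- "excluded"
    reason[ix] <- excl$excluded$exclusion_reason
  }

  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    if (identical(status[i], "excluded")) {
      rows[[i]] <- na_indices_row()
      next
    }
    case <- cohort[i, ]
    res <- tryCatch({
      geom <- case_geometry(case, objs$numerics$axial_cells,
                            config$geometry_mode)
      ic <- inlet_condition(case$psv_m_s, case$edv_m_s,
                            case$reference_radius_m,
                            case$systolic_bp_mmhg, case$diastolic_bp_mmhg)
      field <- solve_steady_flow(geom, ic, objs$outlet, objs$fluid,
                                 objs$numerics)
      ind <- measure_lesion(field, config$measurement$deficit_threshold,
                            config$measurement$point_tolerance)
      list(ok = TRUE, row = indices_row(ind))
    }, icasflow_regime_error = function(e) {
      list(ok = FALSE, why = "regime_refused", msg = conditionMessage(e))
    }, icasflow_convergence_error = function(e) {
      list(ok = FALSE, why = "not_converged", msg = conditionMessage(e))
    })
    if (res$ok) {
      status[i] <- "solved"
      rows[[i]] <- res$row
      vlog(2, "case %s: solved", case$case_id)
    } else {
      status[i] <- res$why
      reason[i] <- res$msg
      rows[[i]] <- na_indices_row()
      vlog(2, "case %s: %s", case$case_id, res$why)
    }
  }

  index_table <- cbind(as.data.frame(cohort),
                       data.frame(status = status,
                                  status_reason = reason,
                                  stringsAsFactors = FALSE),
                       do.call(rbind, rows))
  solved <- index_table[index_table$status == "solved", , drop = FALSE]
  if (nrow(solved) == 0) {
    icas_stop("icasflow_empty_cohort_error",
              "no lesion could be solved: empty cohort")
  }
  solved$ge50 <- solved$percent_stenosis >= config$stats$cutoff_percent
  vlog(1, "solved %d lesions; running statistics", nrow(solved))

  report <- cohort_statistics(solved, config)
  report$index_table <- index_table
  report$cohort_table <- solved
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("icasflow")),
    config_hash = config_hash(config),
    seed = config$seed, n_sampled = nrow(cohort),
    n_excluded = sum(status == "excluded"),
    n_refused = sum(status == "regime_refused"),
    n_failed = sum(status == "not_converged"),
    n_solved = nrow(solved))
  report$config <- config
  class(report) <- "run_report"
  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

# location-distribution and correlation analyses on the solved cohort
cohort_statistics <- function(solved, config) {
  loc_cols <- c(wss_max = "wss_max_loc", wss_min = "wss_min_loc",
                pressure_max = "pressure_max_loc",
                pressure_min = "pressure_min_loc")
  make_loc_table <- function(sub) {
    do.call(rbind, lapply(names(loc_cols), function(nm) {
      counts <- table(factor(sub[[loc_cols[[nm]]]], levels = FINE_LABELS))
      data.frame(index = nm, location = names(counts),
                 count = as.integer(counts),
                 proportion = as.numeric(counts) / max(1, nrow(sub)),
                 stringsAsFactors = FALSE)
    }))
  }
  location_tables <- list(
    overall = make_loc_table(solved),
    ge50 = make_loc_table(solved[solved$ge50, , drop = FALSE]),
    lt50 = make_loc_table(solved[!solved$ge50, , drop = FALSE]))
  side_levels <- unique(solved$side)
  location_tables$by_side <- lapply(stats::setNames(side_levels, side_levels),
    function(sd) make_loc_table(solved[solved$side == sd, , drop = FALSE]))

  # chi-square: does the modal location depend on the stenosis subgroup?
  chi_tests <- lapply(names(loc_cols), function(nm) {
    locs <- solved[[loc_cols[[nm]]]]
    modal <- names(sort(table(locs), decreasing = TRUE))[1]
    tab <- table(factor(locs == modal, levels = c(TRUE, FALSE)),
                 factor(solved$ge50, levels = c(FALSE, TRUE)))
    res <- tryCatch(chi_square_independence(tab),
                    icasflow_stats_error = function(e) NULL)
    list(index = nm, modal_location = modal, test = res)
  })
  names(chi_tests) <- names(loc_cols)

  # Friedman + post-hoc across the five points
  wss_mat <- as.matrix(solved[, c("wss_origin_pa", "wss_mup_pa",
                                  "wss_apex_pa", "wss_mdown_pa",
                                  "wss_terminal_pa")])
  colnames(wss_mat) <- c("origin", "m_up", "apex", "m_down", "terminal")
  p_mat <- as.matrix(solved[, c("pressure_origin_pa", "pressure_mup_pa",
                                "pressure_apex_pa", "pressure_mdown_pa",
                                "pressure_terminal_pa")])
  colnames(p_mat) <- colnames(wss_mat)
  drop_mat <- as.matrix(solved[, c("drop_origin_mup_pa", "drop_mup_apex_pa",
                                   "drop_apex_mdown_pa",
                                   "drop_mdown_terminal_pa")])
  colnames(drop_mat) <- c("origin_to_mup", "mup_to_apex", "apex_to_mdown",
                          "mdown_to_terminal")
  friedman <- list(wss = friedman_test(wss_mat),
                   pressure = friedman_test(p_mat),
                   segment_drops = friedman_test(drop_mat))
  posthoc <- lapply(list(wss = wss_mat, pressure = p_mat,
                         segment_drops = drop_mat),
                    function(m) tryCatch(
                      pairwise_posthoc(m, alpha = config$stats$alpha,
                                       method = config$stats$posthoc),
                      icasflow_stats_error = function(e) NULL))

  # Table-2-style stenosis correlations, split at the cutoff
  split_indices <- c("wss_ratio_max_origin", "wss_ratio_min_origin",
                     "pressure_ratio")
  correlation_tables <- list()
  correlation_tables$split <- lapply(
    stats::setNames(split_indices, split_indices),
    function(col) tryCatch(
      threshold_split_correlation(solved, col,
                                  cutoff = config$stats$cutoff_percent),
      icasflow_error = function(e) NULL))
  # unsplit stenosis correlations and the force-force correlations
  # (NULL when the solved cohort is too small for the adjusted correlation)
  cov <- solved[, c("age_years", "sex")]
  adj <- function(x, y) tryCatch(partial_spearman(x, y, cov),
                                 icasflow_error = function(e) NULL)
  correlation_tables$overall <- lapply(
    stats::setNames(c(split_indices, "pressure_drop_pa", "wss_max_pa"),
                    c(split_indices, "pressure_drop_pa", "wss_max_pa")),
    function(col) adj(solved$percent_stenosis, solved[[col]]))
  correlation_tables$force_force <- list(
    wss_max_vs_pressure_drop =
      adj(solved$wss_max_pa, solved$pressure_drop_pa),
    wss_max_vs_pressure_ratio =
      adj(solved$wss_max_pa, solved$pressure_ratio))

  list(location_tables = location_tables, chi_tests = chi_tests,
       friedman = friedman, posthoc = posthoc,
       correlation_tables = correlation_tables)
}

#' Write a run report to a directory
#'
#' Writes `index_table.csv` (every sampled lesion with status),
#' `location_distribution.csv`, `stats_tests.csv` (one row per statistical
#' test), and `provenance.yaml`. Output is byte-stable for a fixed config
#' and seed.
#'
#' @param report a `run_report`.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(format(df, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     file.path(output_dir, name), row.names = FALSE,
                     quote = TRUE)
  }
  w(report$index_table, "index_table.csv")
  loc <- rbind(
    cbind(group = "overall", report$location_tables$overall),
    cbind(group = "ge50", report$location_tables$ge50),
    cbind(group = "lt50", report$location_tables$lt50),
    do.call(rbind, lapply(names(report$location_tables$by_side), function(sd)
      cbind(group = paste0("side_", sd),
            report$location_tables$by_side[[sd]]))))
  w(loc, "location_distribution.csv")
  w(stats_tests_table(report), "stats_tests.csv")
  yaml::write_yaml(report$provenance,
                   file.path(output_dir, "provenance.yaml"))
  invisible(output_dir)
}

# flatten every statistical result in the report to one row per test
stats_tests_table <- function(report) {
  rows <- list()
  add <- function(name, group, sr) {
    if (is.null(sr)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      test = name, group = group,
      statistic = if (is.null(sr$statistic)) NA_real_ else sr$statistic,
      df = if (is.null(sr$df)) NA_real_ else sr$df,
      p_value = sr$p_value,
      p_adjusted = if (is.null(sr$adjusted_p)) NA_real_ else sr$adjusted_p,
      r_s = if (is.null(sr$r_s)) NA_real_ else sr$r_s,
      n = sr$n, stringsAsFactors = FALSE)
  }
  for (nm in names(report$friedman)) {
    add(paste0("friedman_", nm), "all", report$friedman[[nm]])
  }
  for (nm in names(report$posthoc)) {
    ph <- report$posthoc[[nm]]
    if (is.null(ph)) next
    for (r in seq_len(nrow(ph$pairwise))) {
      pr <- ph$pairwise[r, ]
      rows[[length(rows) + 1]] <- data.frame(
        test = paste0("posthoc_", nm), group = paste(pr$a, "vs", pr$b),
        statistic = pr$statistic, df = NA_real_, p_value = pr$p_value,
        p_adjusted = pr$p_adjusted, r_s = NA_real_,
        n = report$friedman[[nm]]$n, stringsAsFactors = FALSE)
    }
  }
  for (nm in names(report$chi_tests)) {
    add(paste0("chisq_modal_", nm), report$chi_tests[[nm]]$modal_location,
        report$chi_tests[[nm]]$test)
  }
  ct <- report$correlation_tables
  for (nm in names(ct$split)) {
    if (is.null(ct$split[[nm]])) next
    add(paste0("stenosis_corr_", nm), "lt_cutoff", ct$split[[nm]]$below)
    add(paste0("stenosis_corr_", nm), "ge_cutoff", ct$split[[nm]]$at_or_above)
  }
  for (nm in names(ct$overall)) {
    add(paste0("stenosis_corr_", nm), "all", ct$overall[[nm]])
  }
  for (nm in names(ct$force_force)) add(nm, "all", ct$force_force[[nm]])
  do.call(rbind, rows)
}

#' Re-run the cohort statistics on an existing index table
#'
#' Takes a per-lesion index table (as produced by [run_pipeline()] /
#' [write_run_report()], possibly re-read from CSV), restricts it to solved
#' lesions and recomputes every statistical table.
#'
#' @param index_table data.frame with the cohort and index columns and a
#'   `status` column.
#' @param cutoff percent-stenosis subgroup cutoff.
#' @param alpha significance level for the post-hoc pre-test.
#' @param posthoc `"wilcoxon"` or `"conover"`.
#' @return data.frame with one row per statistical test (name, group,
#'   statistic, df, p, adjusted p, r_s, n).
#' @export
rerun_statistics <- function(index_table, cutoff = 50, alpha = 0.05,
                             posthoc = "wilcoxon") {
  if (!"status" %in% names(index_table)) {
    icas_stop("icasflow_input_error", "index table lacks a `status` column")
  }
  solved <- index_table[index_table$status == "solved", , drop = FALSE]
  if (nrow(solved) == 0) {
    icas_stop("icasflow_empty_cohort_error", "no solved lesions in the table")
  }
  solved$ge50 <- solved$percent_stenosis >= cutoff
  cfg <- list(stats = list(cutoff_percent = cutoff, alpha = alpha,
                           posthoc = posthoc))
  stats_tests_table(cohort_statistics(solved, cfg))
}

#' @export
print.run_report <- function(x, ...) {
  pv <- x$provenance
  cat("<run_report>\n")
  cat(sprintf("  sampled %d lesions: %d excluded, %d regime-refused, %d failed, %d solved\n",
              pv$n_sampled, pv$n_excluded, pv$n_refused, pv$n_failed,
              pv$n_solved))
  ff <- x$correlation_tables$force_force
  rs <- function(sr) if (is.null(sr)) NA_real_ else sr$r_s
  cat(sprintf("  Spearman (adj.) WSS_max vs pressure drop:  r_s = %+.3f\n",
              rs(ff$wss_max_vs_pressure_drop)))
  cat(sprintf("  Spearman (adj.) WSS_max vs pressure ratio: r_s = %+.3f\n",
              rs(ff$wss_max_vs_pressure_ratio)))
  cat(sprintf("  seed %d, config %s\n", pv$seed, pv$config_hash))
  invisible(x)
}

#' Stenosis-severity sweep at fixed inflow
#'
#' Solves the same lesion template across a sequence of percent-stenosis
#' levels at identical inlet conditions and tabulates the severity response
#' of the translesional indices.
#'
#' @param levels percent-stenosis levels (default `c(20, 30, ..., 80)`).
#' @param template named list overriding the lesion template:
#'   `reference_radius` (m), `lesion_length` (m), `psv`, `edv` (m/s),
#'   `systolic_bp`, `diastolic_bp` (mmHg). The default template (1.5 mm
#'   radius, 8 mm lesion, psv 0.45 / edv 0.225 m/s, 130/80 mmHg; mean
#'   velocity 0.3 m/s) keeps the whole default severity range inside the
#'   laminar regime cap and the steady flow regime.
#' @param numerics,fluid,outlet solver settings.
#' @param deficit_threshold,point_tolerance measurement settings.
#' @return object of class `stenosis_sweep`: data.frame with one row per
#'   level (`percent_stenosis`, `wss_max_pa`, `wss_ratio_max_origin`,
#'   `pressure_drop_pa`, `pressure_ratio`, `status`).
#' @export
sweep_stenosis <- function(levels = seq(20, 80, by = 10), template = list(),
                           numerics = numerics_config(),
                           fluid = fluid_properties(),
                           outlet = outlet_model(),
                           deficit_threshold = 0.02,
                           point_tolerance = 0.02) {
  tpl <- merge_config(list(reference_radius = 1.5e-3, lesion_length = 8e-3,
                           psv = 0.45, edv = 0.225,
                           systolic_bp = 130, diastolic_bp = 80),
                      template, "template")
  ic <- inlet_condition(tpl$psv, tpl$edv, tpl$reference_radius,
                        tpl$systolic_bp, tpl$diastolic_bp)
  rows <- lapply(levels, function(s) {
    out <- data.frame(percent_stenosis = s, wss_max_pa = NA_real_,
                      wss_ratio_max_origin = NA_real_,
                      pressure_drop_pa = NA_real_, pressure_ratio = NA_real_,
                      mass_error_frac = NA_real_,
                      status = "solved", stringsAsFactors = FALSE)
    res <- tryCatch({
      vessel_length <- tpl$lesion_length + 20 * tpl$reference_radius
      spec <- stenosis_spec(tpl$reference_radius, s, tpl$lesion_length,
                            vessel_length / 2)
      geom <- make_stenosis_profile(spec, vessel_length,
                                    numerics$axial_cells)
      field <- solve_steady_flow(geom, ic, outlet, fluid, numerics)
      ind <- if (s == 0) {
        # unstenosed reference level: measure over the nominal lesion window
        prof <- wall_profile(field)
        ext <- c(vessel_length / 2 - tpl$lesion_length / 2,
                 vessel_length / 2,
                 vessel_length / 2 + tpl$lesion_length / 2)
        extract_indices(prof, locate_five_points(prof, ext))
      } else {
        measure_lesion(field, deficit_threshold, point_tolerance)
      }
      list(ind = ind, mass_error = field$mass_error)
    }, icasflow_regime_error = function(e) "regime_refused",
       icasflow_convergence_error = function(e) "not_converged",
       icasflow_nolesion_error = function(e) "no_lesion")
    if (is.character(res)) {
      out$status <- res
    } else {
      out$wss_max_pa <- res$ind$wss_max
      out$wss_ratio_max_origin <- res$ind$wss_ratio_max_over_origin
      out$pressure_drop_pa <- res$ind$pressure_drop_total
      out$pressure_ratio <- res$ind$pressure_ratio_terminal_over_origin
      out$mass_error_frac <- res$mass_error
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stenosis_sweep", "data.frame")
  out
}

#' @export
plot.stenosis_sweep <- function(x, ...) {
  ok <- x$status == "solved"
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$percent_stenosis[ok], x$wss_ratio_max_origin[ok],
                 type = "b", xlab = "percent stenosis [%]",
                 ylab = "WSS ratio (max/origin)", main = "WSS response", ...)
  graphics::plot(x$percent_stenosis[ok], x$pressure_ratio[ok], type = "b",
                 xlab = "percent stenosis [%]",
                 ylab = "pressure ratio (terminal/origin)",
                 main = "Pressure response", ...)
  invisible(x)
}
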