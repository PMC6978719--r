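# Measurement scheme along the prominent side: the five measuring points
# (origin, M_up, apex, M_down, terminal), WSS/pressure indices at and
# between them, extremum-location classification, and lesion exclusion
# rules.

FINE_LABELS <- c("Origin", "Origin-to-Mup", "Mup", "Mup-to-apex", "Apex",
                 "Apex-to-Mdown", "Mdown", "Mdown-to-terminal", "Terminal")

#' Locate the five measuring points on a wall profile
#'
#' Given the lesion extent (entrance, apex, exit), places the five measuring
#' points along the longitudinal axis: the origin and terminal at the lesion
#' entrance/exit, the apex at the point of maximal luminal encroachment, and
#' M_up / M_down at the midpoints of the upstream (origin-to-apex) and
#' downstream (apex-to-terminal) sections.
#'
#' @param profile a [wall_profile()] (used to validate that the extent lies
#'   inside the profiled arc range).
#' @param extent numeric `c(z_origin, z_apex, z_terminal)` from
#'   [detect_lesion_extent()] (for axisymmetric and planar modes the axial
#'   coordinate is used as the arc coordinate of the point definitions).
#' @return object of class `five_points`: named numeric vector with elements
#'   `origin`, `m_up`, `apex`, `m_down`, `terminal` (arc positions, m).
#' @export
locate_five_points <- function(profile, extent) {
  if (!is.numeric(extent) || length(extent) != 3L || any(!is.finite(extent))) {
    icas_stop("icasflow_input_error",
              "`extent` must be numeric (z_origin, z_apex, z_terminal)")
  }
  z0 <- extent[[1]]; za <- extent[[2]]; zt <- extent[[3]]
  if (!(z0 < za && za < zt)) {
    icas_stop("icasflow_invalid_lesion_error",
              "degenerate lesion extent: need z_origin < z_apex < z_terminal")
  }
  if (!inherits(profile, "wall_profile")) {
    icas_stop("icasflow_input_error", "`profile` must be a wall_profile")
  }
  if (z0 < min(profile$s) - 1e-12 || zt > max(profile$s) + 1e-12) {
    icas_stop("icasflow_input_error",
              "lesion extent lies outside the profiled arc range")
  }
  pts <- c(origin = z0, m_up = (z0 + za) / 2, apex = za,
           m_down = (za + zt) / 2, terminal = zt)
  class(pts) <- "five_points"
  pts
}

#' @export
print.five_points <- function(x, ...) {
  cat("<five_points> [mm]:",
      paste(sprintf("%s=%.2f", names(unclass(x)), unclass(x) * 1e3),
            collapse = "  "), "\n")
  invisible(x)
}

# linear interpolation of a profile column at arc positions
profile_at <- function(profile, column, s) {
  stats::approx(profile$s, profile[[column]], s, rule = 2)$y
}

#' Translesional WSS and pressure indices
#'
#' Computes every derived index of the measurement scheme from a
#' prominent-side wall profile and the five measuring points: WSS and
#' pressure at each point (linearly interpolated), the extrema over the
#' lesion (searched over the profile samples in `[origin, terminal]`, ties
#' broken toward the most upstream position), the relative indices
#' `WSS ratio (max/origin)`, `WSS ratio (min/origin)` and the FFR-like
#' `pressure ratio (terminal/origin)`, the total origin-to-terminal pressure
#' drop and the four segmental drops.
#'
#' @param profile a [wall_profile()].
#' @param points a [locate_five_points()] result.
#' @return object of class `lesion_indices` (a list; see Details in the
#'   vignette for the column dictionary used when tabulated).
#' @export
extract_indices <- function(profile, points) {
  if (!inherits(points, "five_points")) {
    icas_stop("icasflow_input_error", "`points` must be a five_points object")
  }
  p <- unclass(points)
  if (p[["origin"]] < min(profile$s) - 1e-12 ||
      p[["terminal"]] > max(profile$s) + 1e-12) {
    icas_stop("icasflow_input_error",
              "profile does not cover the [origin, terminal] range")
  }
  wss_at <- profile_at(profile, "wss", p)
  names(wss_at) <- names(p)
  pressure_at <- profile_at(profile, "pressure", p)
  names(pressure_at) <- names(p)

  idx <- which(profile$s >= p[["origin"]] - 1e-12 &
               profile$s <= p[["terminal"]] + 1e-12)
  ss <- profile$s[idx]
  w <- profile$wss[idx]
  pr <- profile$pressure[idx]
  i_wmax <- idx[which.max(w)]; i_wmin <- idx[which.min(w)]
  i_pmax <- idx[which.max(pr)]; i_pmin <- idx[which.min(pr)]

  seg_drop <- -diff(pressure_at)
  names(seg_drop) <- c("origin_to_mup", "mup_to_apex", "apex_to_mdown",
                       "mdown_to_terminal")

  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  wss_origin <- wss_at[["origin"]]
  p_origin <- pressure_at[["origin"]]

  out <- list(
    points = points,
    wss_at = wss_at, pressure_at = pressure_at,
    wss_max = profile$wss[i_wmax], wss_max_s = profile$s[i_wmax],
    wss_min = profile$wss[i_wmin], wss_min_s = profile$s[i_wmin],
    pressure_max = profile$pressure[i_pmax],
    pressure_max_s = profile$s[i_pmax],
    pressure_min = profile$pressure[i_pmin],
    pressure_min_s = profile$s[i_pmin],
    wss_ratio_max_over_origin = ratio_or_na(profile$wss[i_wmax], wss_origin),
    wss_ratio_min_over_origin = ratio_or_na(profile$wss[i_wmin], wss_origin),
    pressure_ratio_terminal_over_origin =
      ratio_or_na(pressure_at[["terminal"]], p_origin),
    pressure_drop_total = p_origin - pressure_at[["terminal"]],
    segment_drops = seg_drop)
  if (wss_origin <= 0 || p_origin <= 0) {
    # ratio-undefined: absolute indices are still returned
    out$ratio_defined <- FALSE
  } else {
    out$ratio_defined <- TRUE
  }
  out$wss_max_loc <- classify_extremum_location(out$wss_max_s, points)
  out$wss_min_loc <- classify_extremum_location(out$wss_min_s, points)
  out$pressure_max_loc <- classify_extremum_location(out$pressure_max_s, points)
  out$pressure_min_loc <- classify_extremum_location(out$pressure_min_s, points)
  class(out) <- "lesion_indices"
  out
}

#' @export
print.lesion_indices <- function(x, ...) {
  cat("<lesion_indices>\n")
  cat(sprintf("  WSS_max  %.3g Pa at %s; WSS_min %.3g Pa at %s\n",
              x$wss_max, x$wss_max_loc, x$wss_min, x$wss_min_loc))
  cat(sprintf("  pressure_max at %s; pressure_min at %s\n",
              x$pressure_max_loc, x$pressure_min_loc))
  cat(sprintf("  WSS ratio (max/origin)        %.3g\n",
              x$wss_ratio_max_over_origin))
  cat(sprintf("  pressure ratio (term/origin)  %.4g\n",
              x$pressure_ratio_terminal_over_origin))
  cat(sprintf("  pressure drop (origin-to-terminal) %.3g Pa\n",
              x$pressure_drop_total))
  invisible(x)
}

#' Classify an arc position into the section vocabulary
#'
#' Assigns an extremum position either to one of the five named points (when
#' within `point_tolerance` of it, as a fraction of lesion length) or to the
#' enclosing open section (`Origin-to-Mup`, `Mup-to-apex`, `Apex-to-Mdown`,
#' `Mdown-to-terminal`). Coarse aliases: `Upstream` covers origin-to-apex and
#' `Downstream` apex-to-terminal (see [coarse_location()]).
#'
#' @param s arc position (m), inside `[origin, terminal]`.
#' @param points a [locate_five_points()] result.
#' @param point_tolerance snap distance to a named point, as a fraction of
#'   the lesion length (default 0.02).
#' @return a single label, one of the nine fine section labels.
#' @export
classify_extremum_location <- function(s, points, point_tolerance = 0.02) {
  p <- unclass(points)
  check_scalar(s, "s")
  if (s < p[["origin"]] - 1e-12 || s > p[["terminal"]] + 1e-12) {
    icas_stop("icasflow_out_of_range_error",
              "arc position lies outside the lesion")
  }
  tol <- point_tolerance * (p[["terminal"]] - p[["origin"]])
  named <- c(Origin = p[["origin"]], Mup = p[["m_up"]], Apex = p[["apex"]],
             Mdown = p[["m_down"]], Terminal = p[["terminal"]])
  d <- abs(s - named)
  if (min(d) <= tol) return(names(named)[which.min(d)])
  if (s < p[["m_up"]]) "Origin-to-Mup"
  else if (s < p[["apex"]]) "Mup-to-apex"
  else if (s < p[["m_down"]]) "Apex-to-Mdown"
  else "Mdown-to-terminal"
}

#' Coarse location alias for a fine section label
#'
#' `Upstream` = origin through apex, `Downstream` = beyond apex through
#' terminal (the apex itself is kept as `Apex`).
#'
#' @param label a fine label from [classify_extremum_location()].
#' @return `"Upstream"`, `"Apex"` or `"Downstream"`.
#' @export
coarse_location <- function(label) {
  up <- c("Origin", "Origin-to-Mup", "Mup", "Mup-to-apex")
  down <- c("Apex-to-Mdown", "Mdown", "Mdown-to-terminal", "Terminal")
  vapply(label, function(l) {
    if (l %in% up) "Upstream" else if (l == "Apex") "Apex"
    else if (l %in% down) "Downstream"
    else icas_stop("icasflow_input_error", sprintf("unknown label '%s'", l))
  }, character(1), USE.NAMES = FALSE)
}

#' Apply the lesion exclusion rules to a cohort
#'
#' Excludes tandem lesions whose distance to the nearest lesion is below
#' 2 cm (hemodynamic interference) and lesions at an arterial bifurcation or
#' branch opening. A missing distance is treated as "no neighbouring lesion".
#'
#' @param cases a `lesion_cohort` data.frame.
#' @param tandem_distance exclusion threshold for tandem spacing (m,
#'   default 0.02).
#' @return list with `retained` (a `lesion_cohort`) and `excluded` (the
#'   excluded rows plus a machine-readable `exclusion_reason` column:
#'   `"tandem"`, `"bifurcation"` or `"tandem+bifurcation"`).
#' @export
exclusion_filter <- function(cases, tandem_distance = 0.02) {
  if (!is.data.frame(cases)) {
    icas_stop("icasflow_input_error", "`cases` must be a cohort data.frame")
  }
  d <- cases$distance_to_nearest_lesion_m
  tandem <- !is.na(d) & d < tandem_distance
  bifur <- isTRUE_vec(cases$at_bifurcation)
  reason <- rep(NA_character_, nrow(cases))
  reason[tandem] <- "tandem"
  reason[bifur] <- "bifurcation"
  reason[tandem & bifur] <- "tandem+bifurcation"
  excluded <- cases[!is.na(reason), , drop = FALSE]
  if (nrow(excluded) > 0) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  retained <- cases[is.na(reason), , drop = FALSE]
  class(retained) <- c("lesion_cohort", "data.frame")
  list(retained = retained, excluded = excluded)
}

isTRUE_vec <- function(x) !is.na(x) & x
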