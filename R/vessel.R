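# Parametric stenosed-vessel geometry: WASID percent stenosis, cosine lesion
# profiles, lesion-extent detection. Stands in for patient angiographic
# reconstructions at desk scale.

LESION_SIDES <- c("axisymmetric", "upper", "lower", "both")

#' WASID percent stenosis
#'
#' Severity of a stenosis by the trial-standard diameter criterion:
#' `(1 - d_stenosed / d_reference) * 100`, where the reference diameter is the
#' normal lumen proximal to the lesion.
#'
#' @param d_stenosed narrowest lumen diameter (m, or any unit shared with
#'   `d_reference`).
#' @param d_reference reference (unstenosed) diameter, same unit.
#' @return percent stenosis in `[0, 100)`. Vectorised.
#' @examples
#' percent_stenosis_wasid(1.5e-3, 3.0e-3)  # 50
#' @export
percent_stenosis_wasid <- function(d_stenosed, d_reference) {
  if (!is.numeric(d_stenosed) || !is.numeric(d_reference) ||
      any(!is.finite(d_stenosed)) || any(!is.finite(d_reference))) {
    icas_stop("icasflow_geometry_error", "diameters must be finite numbers")
  }
  if (any(d_stenosed <= 0) || any(d_reference <= 0)) {
    icas_stop("icasflow_geometry_error", "diameters must be strictly positive")
  }
  if (any(d_stenosed > d_reference)) {
    icas_stop("icasflow_geometry_error",
              "stenosed diameter exceeds reference diameter")
  }
  (1 - d_stenosed / d_reference) * 100
}

#' Parametric stenosis specification
#'
#' Describes one lesion: the unstenosed reference radius, WASID percent
#' stenosis, lesion length, axial centre position and which wall carries the
#' plaque. The default lesion shape is a smooth cosine bump, the standard
#' idealisation in stenosis CFD benchmarks.
#'
#' @param reference_radius unstenosed lumen radius (m).
#' @param percent_stenosis WASID percent diameter stenosis, in `[0, 100)`.
#' @param lesion_length axial extent of the lesion (m).
#' @param center_position axial coordinate of the lesion centre (m, origin at
#'   the vessel inlet).
#' @param side which wall carries the plaque: `"axisymmetric"` (default),
#'   `"upper"`, `"lower"` or `"both"` (eccentric sides use the planar mode of
#'   [make_stenosis_profile()]).
#' @param shape lesion shape identifier; only `"cosine"` is implemented.
#' @return an object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(reference_radius, percent_stenosis, lesion_length,
                          center_position, side = "axisymmetric",
                          shape = "cosine") {
  check_scalar(reference_radius, "reference_radius", positive = TRUE,
               class = "icasflow_geometry_error")
  check_scalar(percent_stenosis, "percent_stenosis",
               class = "icasflow_geometry_error")
  check_scalar(lesion_length, "lesion_length", positive = TRUE,
               class = "icasflow_geometry_error")
  check_scalar(center_position, "center_position",
               class = "icasflow_geometry_error")
  if (percent_stenosis < 0 || percent_stenosis >= 100) {
    icas_stop("icasflow_geometry_error",
              "percent_stenosis must lie in [0, 100)")
  }
  side <- match.arg(side, LESION_SIDES)
  if (!identical(shape, "cosine")) {
    icas_stop("icasflow_geometry_error",
              sprintf("unknown lesion shape '%s'", shape))
  }
  structure(list(reference_radius = reference_radius,
                 percent_stenosis = percent_stenosis,
                 lesion_length = lesion_length,
                 center_position = center_position,
                 side = side, shape = shape),
            class = "stenosis_spec")
}

#' @export
print.stenosis_spec <- function(x, ...) {
  cat(sprintf(
    "<stenosis_spec> %.1f%% WASID, R=%.3g mm, L=%.3g mm at z=%.3g mm, side=%s\n",
    x$percent_stenosis, x$reference_radius * 1e3, x$lesion_length * 1e3,
    x$center_position * 1e3, x$side))
  invisible(x)
}

# fractional diameter deficit of the cosine bump at axial positions z
cosine_deficit <- function(z, s, z0, L) {
  f <- numeric(length(z))
  inside <- abs(z - z0) <= L / 2
  f[inside] <- (s / 2) * (1 + cos(2 * pi * (z[inside] - z0) / L))
  f
}

#' Discretise a stenosed lumen boundary
#'
#' Builds the lumen boundary of a straight vessel carrying one cosine-shaped
#' lesion. In `axisymmetric` mode (side `"axisymmetric"` or `"both"`) the
#' boundary is a single radius profile `R(z) = R0 * (1 - f(z))` with
#' `f(z) = (s/2) * (1 + cos(2*pi*(z - z0)/L))` inside the lesion, so the
#' narrowest diameter reproduces the WASID fraction `1 - s` exactly and the
#' profile is C1 at the lesion edges. Eccentric sides (`"upper"`, `"lower"`)
#' use a planar-channel mode where the whole diameter deficit is carved out of
#' one wall's half-height.
#'
#' @param spec a [stenosis_spec()].
#' @param vessel_length total vessel length (m); must accommodate the lesion
#'   plus at least five reference diameters of unstenosed inlet and outlet
#'   segment on each side.
#' @param axial_resolution number of axial grid cells (default 256).
#' @return an object of class `vessel_geometry`: axial samples `z`, wall
#'   offsets (`wall` in axisymmetric mode; `wall_upper`/`wall_lower`
#'   half-heights in planar mode), the mode, the generating spec and the total
#'   length.
#' @export
make_stenosis_profile <- function(spec, vessel_length = NULL,
                                  axial_resolution = 256L) {
  if (!inherits(spec, "stenosis_spec")) {
    icas_stop("icasflow_geometry_error", "`spec` must be a stenosis_spec")
  }
  R0 <- spec$reference_radius
  D0 <- 2 * R0
  if (is.null(vessel_length)) {
    vessel_length <- spec$lesion_length + 10 * D0
  }
  check_scalar(vessel_length, "vessel_length", positive = TRUE,
               class = "icasflow_geometry_error")
  s <- spec$percent_stenosis / 100
  # buffer requirements are vacuous for an unstenosed tube
  if (s > 0 && vessel_length < spec$lesion_length + 10 * D0 - 1e-12) {
    icas_stop("icasflow_geometry_error", paste(
      "vessel_length must cover the lesion plus 5 reference diameters of",
      "unstenosed segment at each end"))
  }
  buffer <- 5 * D0
  z_lo <- spec$center_position - spec$lesion_length / 2
  z_hi <- spec$center_position + spec$lesion_length / 2
  if (s > 0 &&
      (z_lo < buffer - 1e-12 || z_hi > vessel_length - buffer + 1e-12)) {
    icas_stop("icasflow_geometry_error",
              "lesion extends into the inlet/outlet buffer segments")
  }
  n <- as.integer(axial_resolution)
  if (n < 16L) {
    icas_stop("icasflow_geometry_error", "axial_resolution must be >= 16")
  }
  z <- seq(0, vessel_length, length.out = n + 1L)
  f <- cosine_deficit(z, s, spec$center_position, spec$lesion_length)

  mode <- if (spec$side %in% c("upper", "lower")) "planar" else "axisymmetric"
  geom <- list(z = z, mode = mode, spec = spec, total_length = vessel_length,
               reference_radius = R0)
  if (mode == "axisymmetric") {
    geom$wall <- R0 * (1 - f)
  } else {
    # full diameter deficit carved from one wall's half-height
    deficit <- D0 * f
    if (max(deficit) >= R0 * (1 + 1e-12) && s > 0) {
      # half-height of the plaqued wall would cross the centreline
      if (s >= 0.5) {
        icas_stop("icasflow_geometry_error", paste(
          "single-sided planar lesions support < 50% stenosis;",
          "use side = 'both' or 'axisymmetric' for severe lesions"))
      }
    }
    if (spec$side == "upper") {
      geom$wall_upper <- R0 - deficit
      geom$wall_lower <- rep(R0, length(z))
    } else {
      geom$wall_upper <- rep(R0, length(z))
      geom$wall_lower <- R0 - deficit
    }
  }
  class(geom) <- "vessel_geometry"
  geom
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> %s, L=%.1f mm, %d axial samples, R0=%.3g mm\n",
              x$mode, x$total_length * 1e3, length(x$z),
              x$reference_radius * 1e3))
  invisible(x)
}

# lumen gap (diameter in axisymmetric mode, wall-to-wall height in planar)
lumen_gap <- function(geom) {
  if (geom$mode == "axisymmetric") 2 * geom$wall
  else geom$wall_upper + geom$wall_lower
}

# half-height profile of the prominent (more stenosed) wall
prominent_wall <- function(geom) {
  if (geom$mode == "axisymmetric") return(geom$wall)
  up <- min(geom$wall_upper); lo <- min(geom$wall_lower)
  # deeper wall wins; tie broken toward the upper wall
  if (up <= lo) geom$wall_upper else geom$wall_lower
}

#' Locate the extent of a single lesion on a discretised lumen
#'
#' Finds the entrance (origin), the point of maximal luminal encroachment
#' (apex) and the exit (terminal) of the lesion. The entrance/exit are the
#' first and last axial samples whose relative diameter deficit, with respect
#' to the reference lumen, exceeds `deficit_threshold`; the apex is the
#' narrowest sample (ties broken toward the most upstream position).
#'
#' @param geometry a [make_stenosis_profile()] result.
#' @param deficit_threshold relative lumen deficit defining the lesion edge,
#'   in `(0, 0.5)`; default 0.02.
#' @return named numeric vector `c(z_origin, z_apex, z_terminal)` (m).
#' @export
detect_lesion_extent <- function(geometry, deficit_threshold = 0.02) {
  if (!inherits(geometry, "vessel_geometry")) {
    icas_stop("icasflow_geometry_error", "`geometry` must be a vessel_geometry")
  }
  check_scalar(deficit_threshold, "deficit_threshold", positive = TRUE,
               class = "icasflow_input_error")
  if (deficit_threshold >= 0.5) {
    icas_stop("icasflow_input_error", "deficit_threshold must lie in (0, 0.5)")
  }
  gap <- lumen_gap(geometry)
  ref <- 2 * geometry$reference_radius
  deficit <- 1 - gap / ref
  inside <- deficit > deficit_threshold
  if (!any(inside)) {
    icas_stop("icasflow_nolesion_error",
              "no sample exceeds the deficit threshold: no lesion detected")
  }
  runs <- rle(inside)
  if (sum(runs$values) > 1L) {
    icas_stop("icasflow_ambiguity_error",
              "multiple disjoint lesions detected; expected exactly one")
  }
  idx <- which(inside)
  i_apex <- idx[which.min(gap[idx])]  # which.min -> most upstream tie-break
  c(z_origin = geometry$z[idx[1L]],
    z_apex = geometry$z[i_apex],
    z_terminal = geometry$z[idx[length(idx)]])
}

#' Default synthetic cohort population parameters
#'
#' Distribution parameters for the synthetic lesion cohort. Percent stenosis,
#' mean age and sex ratio follow the study population the generator emulates
#' (stenosis 43.2 +/- 17.3 %, clipped to 10--85 %; age 65.5 y; 54.5 % male);
#' the remaining entries are physiological defaults for middle-cerebral-artery
#' lesions and duplex ultrasonography, all overridable.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of class `cohort_population`.
#' @export
cohort_population <- function(...) {
  pop <- list(
    stenosis_mean = 43.2, stenosis_sd = 17.3, stenosis_range = c(10, 85),
    radius_mean = 1.5e-3, radius_sd = 0.15e-3, radius_range = c(1e-3, 2e-3),
    lesion_length_mean = 8e-3, lesion_length_sd = 1.5e-3,
    lesion_length_range = c(4e-3, 14e-3),
    psv_mean = 0.9, psv_sd = 0.2, psv_range = c(0.4, 1.6),
    edv_frac_range = c(0.3, 0.6),
    sbp_mean = 130, sbp_sd = 15, dbp_mean = 80, dbp_sd = 10,
    age_mean = 65.5, age_sd = 8, age_range = c(18, 80),
    male_p = 0.545,
    tandem_p = 0.1, tandem_near_range = c(0.005, 0.019),
    tandem_far_range = c(0.02, 0.08),
    bifurcation_p = 0.1,
    side_probs = c(upper = 0.45, lower = 0.35, both = 0.20))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(pop))
  if (length(unknown) > 0) {
    icas_stop("icasflow_config_error",
              paste("unknown population parameter(s):",
                    paste(unknown, collapse = ", ")))
  }
  pop[names(dots)] <- dots
  validate_population(pop)
  structure(pop, class = "cohort_population")
}

validate_population <- function(pop) {
  sds <- c("stenosis_sd", "radius_sd", "lesion_length_sd", "psv_sd",
           "sbp_sd", "dbp_sd", "age_sd")
  for (nm in sds) {
    if (!is_scalar_number(pop[[nm]]) || pop[[nm]] < 0) {
      icas_stop("icasflow_config_error", sprintf("`%s` must be >= 0", nm))
    }
  }
  rngs <- c("stenosis_range", "radius_range", "lesion_length_range",
            "psv_range", "edv_frac_range", "tandem_near_range",
            "tandem_far_range", "age_range")
  for (nm in rngs) {
    r <- pop[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] >= r[2]) {
      icas_stop("icasflow_config_error",
                sprintf("`%s` must be an increasing pair", nm))
    }
  }
  for (nm in c("male_p", "tandem_p", "bifurcation_p")) {
    if (!is_scalar_number(pop[[nm]]) || pop[[nm]] < 0 || pop[[nm]] > 1) {
      icas_stop("icasflow_config_error", sprintf("`%s` must be in [0, 1]", nm))
    }
  }
  if (pop$stenosis_range[1] < 0 || pop$stenosis_range[2] >= 100) {
    icas_stop("icasflow_config_error", "stenosis_range must lie in [0, 100)")
  }
  sp <- pop$side_probs
  if (!is.numeric(sp) || is.null(names(sp)) ||
      !all(names(sp) %in% c("axisymmetric", "upper", "lower", "both")) ||
      any(sp < 0) || sum(sp) <= 0) {
    icas_stop("icasflow_config_error",
              "side_probs must be non-negative with side names")
  }
  invisible(pop)
}

#' Sample a synthetic lesion cohort
#'
#' Draws `n` independent synthetic lesion cases (geometry parameters, duplex
#' velocities, brachial blood pressure, demographics, tandem-lesion spacing
#' and bifurcation flags) from the population model, reproducibly for a fixed
#' seed. Draws are made column-wise from a dedicated RNG substream so results
#' are bit-reproducible and unaffected by other pipeline stages.
#'
#' @param n number of lesions (default 55, the cohort size the generator
#'   emulates).
#' @param seed integer root seed.
#' @param population a [cohort_population()].
#' @return a `data.frame` of class `lesion_cohort`, one row per case.
#'   Columns (units in names): `case_id`, `percent_stenosis`,
#'   `reference_radius_m`, `lesion_length_m`, `side`, `psv_m_s`, `edv_m_s`,
#'   `systolic_bp_mmhg`, `diastolic_bp_mmhg`, `age_years`, `sex`,
#'   `distance_to_nearest_lesion_m` (NA when no neighbouring lesion),
#'   `at_bifurcation`.
#' @export
sample_cohort <- function(n = 55L, seed = 1L,
                          population = cohort_population()) {
  if (!is_scalar_number(n) || n < 1) {
    icas_stop("icasflow_config_error", "`n` must be >= 1")
  }
  n <- as.integer(n)
  check_scalar(seed, "seed", class = "icasflow_config_error")
  if (!inherits(population, "cohort_population")) {
    population <- do.call(cohort_population, as.list(population))
  }
  pop <- population
  with_seed(substream_seed(seed, "cohort"), {
    stenosis <- rnorm_clipped(n, pop$stenosis_mean, pop$stenosis_sd,
                              pop$stenosis_range[1], pop$stenosis_range[2])
    radius <- rnorm_clipped(n, pop$radius_mean, pop$radius_sd,
                            pop$radius_range[1], pop$radius_range[2])
    lesion_length <- rnorm_clipped(n, pop$lesion_length_mean,
                                   pop$lesion_length_sd,
                                   pop$lesion_length_range[1],
                                   pop$lesion_length_range[2])
    psv <- rnorm_clipped(n, pop$psv_mean, pop$psv_sd,
                         pop$psv_range[1], pop$psv_range[2])
    edv <- psv * stats::runif(n, pop$edv_frac_range[1], pop$edv_frac_range[2])
    sbp <- rnorm_clipped(n, pop$sbp_mean, pop$sbp_sd, 90, 200)
    dbp <- rnorm_clipped(n, pop$dbp_mean, pop$dbp_sd, 50, 120)
    dbp <- pmin(dbp, sbp - 10)  # keep pulse pressure physiological
    age <- rnorm_clipped(n, pop$age_mean, pop$age_sd,
                         pop$age_range[1], pop$age_range[2])
    sex <- ifelse(stats::runif(n) < pop$male_p, "M", "F")
    sp <- pop$side_probs / sum(pop$side_probs)
    side <- sample(names(sp), n, replace = TRUE, prob = sp)
    tandem <- stats::runif(n) < pop$tandem_p
    dist_near <- stats::runif(n, pop$tandem_near_range[1],
                              pop$tandem_near_range[2])
    dist_far <- stats::runif(n, pop$tandem_far_range[1],
                             pop$tandem_far_range[2])
    has_far_neighbour <- stats::runif(n) < 0.5
    distance <- ifelse(tandem, dist_near,
                       ifelse(has_far_neighbour, dist_far, NA_real_))
    at_bifurcation <- stats::runif(n) < pop$bifurcation_p
    out <- data.frame(
      case_id = sprintf("L%03d", seq_len(n)),
      percent_stenosis = stenosis,
      reference_radius_m = radius,
      lesion_length_m = lesion_length,
      side = side,
      psv_m_s = psv,
      edv_m_s = edv,
      systolic_bp_mmhg = sbp,
      diastolic_bp_mmhg = dbp,
      age_years = age,
      sex = sex,
      distance_to_nearest_lesion_m = distance,
      at_bifurcation = at_bifurcation,
      stringsAsFactors = FALSE)
    class(out) <- c("lesion_cohort", "data.frame")
    out
  })
}

#' Build the vessel geometry for one cohort case
#'
#' @param case one row of a [sample_cohort()] table (data.frame with the
#'   cohort columns).
#' @param axial_resolution axial cells passed to [make_stenosis_profile()].
#' @param geometry_mode `"axisymmetric"` (default: the case's total percent
#'   stenosis is realised as an axisymmetric narrowing regardless of the
#'   plaque-side label, which is retained for reporting) or `"eccentric"`
#'   (honour the side label; falls back to axisymmetric for `side = "both"`
#'   at >= 50% where a single-sided planar lesion is impossible).
#' @return a `vessel_geometry`.
#' @export
case_geometry <- function(case, axial_resolution = 256L,
                          geometry_mode = c("axisymmetric", "eccentric")) {
  geometry_mode <- match.arg(geometry_mode)
  side <- as.character(case$side)
  if (geometry_mode == "axisymmetric" || side %in% c("axisymmetric", "both")) {
    side <- if (side == "both" && geometry_mode == "eccentric") "both"
            else "axisymmetric"
  }
  R0 <- case$reference_radius_m
  L <- case$lesion_length_m
  vessel_length <- L + 10 * 2 * R0
  spec <- stenosis_spec(reference_radius = R0,
                        percent_stenosis = case$percent_stenosis,
                        lesion_length = L,
                        center_position = vessel_length / 2,
                        side = side)
  make_stenosis_profile(spec, vessel_length, axial_resolution)
}

#' Write / read a lesion cohort as CSV
#'
#' Flat one-row-per-case table with the documented cohort columns; the
#' round-trip is value-exact at 15 significant digits.
#'
#' @param cohort a `lesion_cohort` data.frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `lesion_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("percent_stenosis", "reference_radius_m", "lesion_length_m",
           "psv_m_s", "edv_m_s", "systolic_bp_mmhg", "diastolic_bp_mmhg",
           "age_years", "distance_to_nearest_lesion_m")
  for (nm in intersect(num, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  if ("at_bifurcation" %in% names(df)) {
    df$at_bifurcation <- as.logical(df$at_bifurcation)
  }
  class(df) <- c("lesion_cohort", "data.frame")
  df
}

#' Export a vessel geometry
#'
#' `write_geometry_csv` writes the two-column `(z_m, wall_offset_m)` boundary
#' table (planar mode: `z_m, wall_upper_m, wall_lower_m`).
#'
#' @param geometry a `vessel_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geometry, path) {
  df <- if (geometry$mode == "axisymmetric") {
    data.frame(z_m = geometry$z, wall_offset_m = geometry$wall)
  } else {
    data.frame(z_m = geometry$z, wall_upper_m = geometry$wall_upper,
               wall_lower_m = geometry$wall_lower)
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
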