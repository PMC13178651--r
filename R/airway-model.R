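#' Canonical Weibel "model A" generation diameters
#'
#' Returns the regularized average airway diameters of Weibel's symmetric
#' dichotomous "model A" of the human tracheobronchial tree, one diameter
#' per generation `z` (0 = trachea, through 23), in millimetres at total
#' lung capacity (TLC). The table ships with the package as a plain TSV
#' (`system.file("extdata", "weibel_model_a.tsv", package = "gltr")`) and
#' can be replaced by any user table via the `diameters` argument of
#' [build_weibel_tree()].
#'
#' @return A data.frame with columns `generation` (integer, 0-23) and
#'   `diameter_mm` (numeric, mm at TLC).
#' @export
#' @examples
#' head(weibel_diameters())
weibel_diameters <- function() {
  path <- system.file("extdata", "weibel_model_a.tsv", package = "gltr")
  d <- utils::read.delim(path)
  d$generation <- as.integer(d$generation)
  d
}

#' Humidified-air gas properties
#'
#' Gas density and dynamic viscosity used in Reynolds-number calculations.
#' The `"body"` preset is humidified air at body temperature (37 C,
#' saturated); `"room"` is dry room air at 20 C.
#'
#' @param preset `"body"` (default) or `"room"`, or ignored when both
#'   `density` and `viscosity` are supplied.
#' @param density gas density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return A list of class `gas_properties` with elements `density`,
#'   `viscosity`, `preset`.
#' @export
#' @examples
#' gas_properties()
#' gas_properties(density = 1.2, viscosity = 1.81e-5)
gas_properties <- function(preset = c("body", "room"),
                           density = NULL, viscosity = NULL) {
  if (is.null(density) != is.null(viscosity)) {
    stop("supply both `density` and `viscosity`, or neither", call. = FALSE)
  }
  if (!is.null(density)) {
    label <- "custom"
  } else {
    preset <- match.arg(preset)
    vals <- switch(preset,
      body = c(1.12, 1.87e-5),
      room = c(1.20, 1.81e-5)
    )
    density <- vals[1]
    viscosity <- vals[2]
    label <- preset
  }
  if (!is.numeric(density) || density <= 0 || !is.numeric(viscosity) || viscosity <= 0) {
    stop("gas density and viscosity must be strictly positive", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity, preset = label),
            class = "gas_properties")
}

#' @export
print.gas_properties <- function(x, ...) {
  cat(sprintf("Gas properties (%s): density %.3g kg/m^3, viscosity %.3g Pa s\n",
              x$preset, x$density, x$viscosity))
  invisible(x)
}

#' Expiratory airway diameter from the TLC diameter
#'
#' Applies the bronchographically measured percentage decrease in airway
#' caliber from inhalation to exhalation, bracketed by airway size: 13%
#' for airways < 1.7 mm, 16% for 1.7-3.5 mm, 10% for 3.5-7 mm, and 7% for
#' airways >= 7 mm. Brackets are half-open (`[1.7, 3.5)`, `[3.5, 7)`) so
#' the map is total and single-valued for every positive diameter.
#'
#' @param d_tlc airway diameter(s) at TLC, mm; must be > 0.
#' @return Exhalation diameter(s), mm: `d_tlc * (1 - f)`.
#' @export
#' @examples
#' exhale_diameter(c(1.0, 2.0, 5.0, 10.0))
exhale_diameter <- function(d_tlc) {
  if (!is.numeric(d_tlc) || any(!is.finite(d_tlc)) || any(d_tlc <= 0)) {
    stop("`d_tlc` must be finite and strictly positive (mm)", call. = FALSE)
  }
  f <- ifelse(d_tlc < 1.7, 0.13,
       ifelse(d_tlc < 3.5, 0.16,
       ifelse(d_tlc < 7.0, 0.10, 0.07)))
  d_tlc * (1 - f)
}

#' Convert a minute flow in L/min to m^3/s
#'
#' @param q volumetric flow(s), L/min; must be >= 0.
#' @return Flow(s) in m^3/s (`q / 60000`).
#' @export
#' @examples
#' lpm_to_m3s(c(15, 75))   # 0.00025, 0.00125
lpm_to_m3s <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    stop("`q` must be finite and non-negative (L/min)", call. = FALSE)
  }
  q / 60000
}

#' Build a symmetric dichotomous (Weibel) airway tree
#'
#' Constructs the per-generation geometry table of a symmetric dichotomous
#' airway tree: generation index `z`, branch count `2^z`, inhalation
#' diameter (the TLC diameter), and exhalation diameter obtained by
#' [exhale_diameter()]. With no `diameters` table the embedded canonical
#' Weibel "model A" 24-generation table is used (see [weibel_diameters()]).
#'
#' @param diameters optional data.frame with columns `generation` (unique
#'   non-negative integers, at most 24 rows) and `diameter_mm` (> 0, mm at
#'   TLC). Default: the embedded Weibel model A table.
#' @param lung_volume_scale optional global multiplicative scale applied to
#'   all TLC diameters before the expiratory narrowing, for sensitivity
#'   analysis of the TLC-referenced geometry. Default 1.
#' @return A data.frame of class `airway_tree` with columns `generation`,
#'   `branch_count`, `d_inhale_mm`, `d_exhale_mm`, ordered by generation.
#' @export
#' @examples
#' tree <- build_weibel_tree()
#' tree[tree$generation == 10, ]
build_weibel_tree <- function(diameters = NULL, lung_volume_scale = 1) {
  source_label <- "weibel_model_a"
  if (is.null(diameters)) {
    diameters <- weibel_diameters()
  } else {
    source_label <- "user"
  }
  if (!is.data.frame(diameters) ||
      !all(c("generation", "diameter_mm") %in% names(diameters))) {
    stop("`diameters` must have columns `generation` and `diameter_mm`",
         call. = FALSE)
  }
  z <- as.integer(diameters$generation)
  d <- as.numeric(diameters$diameter_mm)
  if (nrow(diameters) < 1 || nrow(diameters) > 24) {
    stop("`diameters` must have between 1 and 24 rows", call. = FALSE)
  }
  if (anyDuplicated(z)) {
    stop("duplicate generation index in diameter table", call. = FALSE)
  }
  if (any(is.na(z)) || any(z < 0) || any(z > 23)) {
    stop("generation indices must be integers in 0..23", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("all diameters must be finite and strictly positive", call. = FALSE)
  }
  if (!is.numeric(lung_volume_scale) || lung_volume_scale <= 0) {
    stop("`lung_volume_scale` must be > 0", call. = FALSE)
  }
  o <- order(z)
  z <- z[o]
  d <- d[o] * lung_volume_scale
  tree <- data.frame(
    generation = z,
    branch_count = 2^z,
    d_inhale_mm = d,
    d_exhale_mm = exhale_diameter(d)
  )
  attr(tree, "diameter_source") <- source_label
  class(tree) <- c("airway_tree", "data.frame")
  tree
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("Airway tree: %d generation(s), diameters from '%s'\n",
              nrow(x), attr(x, "diameter_source")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean airflow velocity in one airway generation
#'
#' Computes `v = Q / A(z)` under incompressible flow with constant volume
#' flow across generations and uniform velocity within a generation, where
#' `A(z) = branch_count * pi * d^2 / 4` is the summed cross-sectional area
#' of all parallel branches at generation `z`.
#'
#' @param q_m3s tracheal volumetric flow, m^3/s (>= 0).
#' @param d_mm branch diameter, mm.
#' @param branch_count number of parallel branches (`2^z` for a symmetric
#'   dichotomous tree). Default 1.
#' @return Velocity, m/s. Vectorized over all arguments.
#' @export
#' @examples
#' generation_velocity(lpm_to_m3s(15), 18)     # trachea, quiet breathing
generation_velocity <- function(q_m3s, d_mm, branch_count = 1) {
  if (any(!is.finite(q_m3s)) || any(q_m3s < 0)) {
    stop("`q_m3s` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(d_mm)) || any(d_mm <= 0)) {
    stop("`d_mm` must be finite and strictly positive", call. = FALSE)
  }
  d_m <- d_mm / 1000
  area <- branch_count * pi * d_m^2 / 4
  q_m3s / area
}

#' Reynolds number of airflow in a circular airway
#'
#' `Re = rho * v * d / mu` with the diameter converted to metres. Values
#' below ~2000 indicate laminar flow in a circular duct.
#'
#' @param v airflow velocity, m/s (>= 0).
#' @param d_mm airway diameter, mm (> 0).
#' @param gas a [gas_properties()] object.
#' @return Dimensionless Reynolds number. Vectorized over `v` and `d_mm`.
#' @export
#' @examples
#' reynolds_number(1.0, 18)
reynolds_number <- function(v, d_mm, gas = gas_properties()) {
  stopifnot(inherits(gas, "gas_properties"))
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("`v` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(d_mm)) || any(d_mm <= 0)) {
    stop("`d_mm` must be finite and strictly positive", call. = FALSE)
  }
  gas$density * v * (d_mm / 1000) / gas$viscosity
}

#' Per-generation airflow table for one flow condition
#'
#' Evaluates the airway airflow model over every generation of a tree at a
#' given tracheal minute flow: inhalation and exhalation velocities from
#' the phase-appropriate diameters, their difference (the expiratory
#' velocity excess driving gas-liquid transport), Reynolds numbers for both
#' phases, and a laminarity flag (`max(Re) < 2000`).
#'
#' @param tree an [build_weibel_tree()] airway tree.
#' @param flow_lpm tracheal volumetric flow, L/min (e.g. 15 at rest, 75
#'   during moderate exercise).
#' @param gas a [gas_properties()] object.
#' @param label optional free-text label for the flow condition.
#' @return A data.frame of class `flow_table` with one row per generation
#'   and columns `generation`, `branch_count`, `d_inhale_mm`, `d_exhale_mm`,
#'   `v_inhale`, `v_exhale`, `delta_v`, `re_inhale`, `re_exhale`, `laminar`.
#' @export
#' @examples
#' ft <- flow_table(build_weibel_tree(), flow_lpm = 15)
#' all(ft$laminar)
flow_table <- function(tree, flow_lpm, gas = gas_properties(), label = NULL) {
  if (!inherits(tree, "airway_tree")) {
    stop("`tree` must be an airway_tree (see build_weibel_tree())", call. = FALSE)
  }
  q <- lpm_to_m3s(flow_lpm)
  v_in <- generation_velocity(q, tree$d_inhale_mm, tree$branch_count)
  v_ex <- generation_velocity(q, tree$d_exhale_mm, tree$branch_count)
  re_in <- reynolds_number(v_in, tree$d_inhale_mm, gas)
  re_ex <- reynolds_number(v_ex, tree$d_exhale_mm, gas)
  out <- data.frame(
    generation = tree$generation,
    branch_count = tree$branch_count,
    d_inhale_mm = tree$d_inhale_mm,
    d_exhale_mm = tree$d_exhale_mm,
    v_inhale = v_in,
    v_exhale = v_ex,
    delta_v = v_ex - v_in,
    re_inhale = re_in,
    re_exhale = re_ex,
    laminar = pmax(re_in, re_ex) < 2000
  )
  attr(out, "flow_lpm") <- flow_lpm
  attr(out, "flow_label") <- label
  attr(out, "gas") <- gas
  attr(out, "diameter_source") <- attr(tree, "diameter_source")
  class(out) <- c("flow_table", "data.frame")
  out
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("Airway airflow table at %g L/min (diameters: '%s')\n",
              attr(x, "flow_lpm"), attr(x, "diameter_source")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Deepest generation with a sustained expiratory velocity excess
#'
#' Finds the largest generation `z` such that the expiratory-minus-
#' inspiratory velocity difference `delta_v` is at least `threshold` for
#' every generation from the trachea down to `z` (a contiguous run starting
#' at generation 0). Returns `NA` if the condition already fails at the
#' trachea.
#'
#' @param ft a [flow_table()] result, ordered by generation.
#' @param threshold velocity-difference threshold, m/s. Default 1.
#' @return Integer generation index, or `NA_integer_`.
#' @export
#' @examples
#' deepest_asymmetric_generation(flow_table(build_weibel_tree(), 75))
deepest_asymmetric_generation <- function(ft, threshold = 1) {
  if (!is.data.frame(ft) || nrow(ft) == 0 || is.null(ft$delta_v)) {
    stop("`ft` must be a non-empty flow table with a `delta_v` column",
         call. = FALSE)
  }
  ok <- ft$delta_v >= threshold
  if (!ok[1]) return(NA_integer_)
  run <- which(!ok)
  last <- if (length(run) == 0) nrow(ft) else run[1] - 1
  as.integer(ft$generation[last])
}

#' Write a flow table as TSV
#'
#' @param ft a [flow_table()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flow_table <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
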