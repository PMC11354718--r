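#' Material definition
#'
#' A named material with an electrical conductivity and a relative
#' permittivity. The permittivity is parsed and stored for completeness but
#' is not used by the stationary conduction solve: the DC steady state of
#' `div(sigma grad phi) = 0` has no permittivity dependence.
#'
#' @param name Label, e.g. `"tyrode"`.
#' @param conductivity Electrical conductivity in S/m; must be finite and
#'   strictly positive.
#' @param relative_permittivity Dimensionless, `>= 1`.
#' @return A `pfa_material` list.
#' @export
material <- function(name, conductivity, relative_permittivity = 1) {
  if (!is.finite(conductivity) || conductivity <= 0) {
    stop(sprintf("material '%s': conductivity must be finite and > 0 (got %s)",
                 name, format(conductivity)), call. = FALSE)
  }
  if (!is.finite(relative_permittivity) || relative_permittivity < 1) {
    stop(sprintf("material '%s': relative_permittivity must be >= 1", name),
         call. = FALSE)
  }
  structure(list(name = name, conductivity = conductivity,
                 relative_permittivity = relative_permittivity),
            class = "pfa_material")
}

#' Bench scene geometry
#'
#' Physical dimensions of the ablation bench: a glass dish filled with Tyrode
#' buffer, a tuber slab submerged with its top face a few mm below the bath
#' surface, and two parallel needle electrodes whose tips touch the slab top
#' surface. All lengths in mm. Defaults are the bench values of the potato
#' PFA model (dish 96 mm x 30 mm, slab 40 x 40 x 20 mm submerged 4 mm,
#' electrodes 0.63 mm diameter with a 1.37 mm inner gap).
#'
#' Coordinates are right-handed with the origin at the midpoint between the
#' two electrode axes on the slab top surface; z increases downward into the
#' slab, the electrode pair lies along x.
#'
#' @param dish_inner_diameter,dish_height,dish_wall_thickness Dish, mm.
#' @param slab_length,slab_width,slab_height Tuber slab, mm.
#' @param slab_top_offset Depth of the slab top below the bath surface, mm.
#' @param electrode_diameter,electrode_length Needle electrodes, mm.
#' @param electrode_gap Inner-boundary (surface to surface) distance, mm.
#' @param electrode_tip_contact Tips touch the slab top surface.
#' @return A `pfa_geometry` list.
#' @export
scene_geometry <- function(dish_inner_diameter = 96, dish_height = 30,
                           dish_wall_thickness = 2,
                           slab_length = 40, slab_width = 40, slab_height = 20,
                           slab_top_offset = 4,
                           electrode_diameter = 0.63, electrode_length = 8,
                           electrode_gap = 1.37, electrode_tip_contact = TRUE) {
  g <- list(dish_inner_diameter = dish_inner_diameter, dish_height = dish_height,
            dish_wall_thickness = dish_wall_thickness,
            slab_length = slab_length, slab_width = slab_width,
            slab_height = slab_height, slab_top_offset = slab_top_offset,
            electrode_diameter = electrode_diameter,
            electrode_length = electrode_length, electrode_gap = electrode_gap,
            electrode_tip_contact = electrode_tip_contact)
  lens <- g[setdiff(names(g), "electrode_tip_contact")]
  bad <- names(lens)[!vapply(lens, function(v) is.finite(v) && v > 0, logical(1))]
  if (length(bad) > 0) {
    stop(sprintf("geometry: non-positive length field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (g$electrode_gap + g$electrode_diameter >= g$slab_length) {
    stop("geometry: electrode span must be smaller than slab_length", call. = FALSE)
  }
  if (sqrt(g$slab_length^2 + g$slab_width^2) > g$dish_inner_diameter) {
    stop("geometry: slab does not fit inside the dish footprint", call. = FALSE)
  }
  structure(g, class = "pfa_geometry")
}

#' Pulse recipe metadata
#'
#' The pulse train applied between the electrodes. The waveform itself is
#' metadata only: lesion prediction uses the stationary field at the pulse
#' amplitude, and thresholds are reported for the recipe they were measured
#' under (the reference recipe is 100 biphasic 10 us pulses at 10 Hz with a
#' 500 ns interphase delay).
#'
#' @param amplitude Phase amplitude, V.
#' @param phase_duration Single-phase duration, microseconds.
#' @param frequency Pulse repetition frequency, Hz.
#' @param pulse_count Number of pulses in the train.
#' @param interphase_delay Delay between phases of a biphasic pulse, ns.
#' @param polarity `"biphasic"` or `"monophasic"`.
#' @return A `pfa_recipe` list.
#' @export
pulse_recipe <- function(amplitude = 300, phase_duration = 10, frequency = 10,
                         pulse_count = 100, interphase_delay = 500,
                         polarity = c("biphasic", "monophasic")) {
  polarity <- match.arg(polarity)
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("recipe: amplitude must be > 0", call. = FALSE)
  }
  if (pulse_count < 1 || pulse_count != trunc(pulse_count)) {
    stop("recipe: pulse_count must be a positive integer", call. = FALSE)
  }
  structure(list(amplitude = amplitude, phase_duration = phase_duration,
                 frequency = frequency, pulse_count = pulse_count,
                 interphase_delay = interphase_delay, polarity = polarity),
            class = "pfa_recipe")
}

#' Total energized on-time of a pulse recipe
#'
#' `pulse_count * phases * phase_duration`, in microseconds; a biphasic pulse
#' has two phases.
#'
#' @param recipe A [pulse_recipe()].
#' @return On-time in microseconds.
#' @export
pulse_on_time <- function(recipe) {
  phases <- if (recipe$polarity == "biphasic") 2 else 1
  recipe$pulse_count * phases * recipe$phase_duration
}

default_solver_options <- function() {
  list(spacing = 0.1, tolerance = 1e-8, max_iterations = 20000,
       domain = "local", lateral_half_extent = 8, slab_depth_extent = 8,
       bath_margin = 10, electrode_mode = "equipotential")
}

default_materials <- function() {
  list(bath = material("tyrode", 1.8, 1),
       slab = material("tuber", 0.04, 1),
       electrode_a = material("electrode", 1.74e-3, 1),
       electrode_b = material("electrode", 1.74e-3, 1))
}

#' Assemble a scene configuration
#'
#' Bundles geometry, region materials, the pulse recipe, and solver options.
#' The four named regions `bath`, `slab`, `electrode_a`, `electrode_b` must
#' all carry a material. By default the electrodes are treated as
#' equipotential Dirichlet surfaces (`electrode_mode = "equipotential"`) and
#' their stored conductivity is unused; `electrode_mode = "volumetric"`
#' keeps them as finite-conductivity volumes for sensitivity studies.
#'
#' @param geometry A [scene_geometry()].
#' @param materials Named list of [material()] for regions
#'   `bath`, `slab`, `electrode_a`, `electrode_b`.
#' @param recipe A [pulse_recipe()].
#' @param solver Named list of solver options (see
#'   [rasterize_materials()] and [solve_potential()]); missing entries are
#'   filled with defaults (spacing 0.1 mm, tolerance 1e-8, local domain with
#'   8 mm lateral half-extent).
#' @return A `pfa_scene` list.
#' @export
scene_config <- function(geometry = scene_geometry(),
                         materials = default_materials(),
                         recipe = pulse_recipe(),
                         solver = list()) {
  need <- c("bath", "slab", "electrode_a", "electrode_b")
  miss <- setdiff(need, names(materials))
  if (length(miss) > 0) {
    stop(sprintf("scene_config: missing material for region(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  solver <- utils::modifyList(default_solver_options(), solver)
  structure(list(geometry = geometry, materials = materials[need],
                 recipe = recipe, solver = solver),
            class = "pfa_scene")
}

#' The built-in default scene
#'
#' The two-needle bench scene with Tyrode bath (1.8 S/m), tuber slab
#' (0.04 S/m), 0.63 mm electrodes at 1.37 mm inner gap, and the reference
#' pulse recipe.
#'
#' @return A `pfa_scene`.
#' @export
default_scene <- function() scene_config()

scene_to_list <- function(config) {
  list(geometry = unclass(config$geometry),
       materials = lapply(config$materials, unclass),
       recipe = unclass(config$recipe),
       solver = config$solver)
}

scene_from_list <- function(x) {
  defaults <- scene_to_list(default_scene())
  merged <- utils::modifyList(defaults, x)
  mats <- lapply(merged$materials, function(m) {
    material(m$name, m$conductivity, m$relative_permittivity)
  })
  scene_config(geometry = do.call(scene_geometry, merged$geometry),
               materials = mats,
               recipe = do.call(pulse_recipe, merged$recipe),
               solver = merged$solver)
}

#' Load a scene configuration from TOML or JSON
#'
#' Reads a (possibly partial) configuration file; any field not present is
#' filled with the built-in default. An empty file therefore yields the
#' default scene. The format is chosen by extension: `.toml` (primary) or
#' `.json`. The packaged default file is
#' `system.file("extdata", "paper_defaults.toml", package = "pfalesion")`.
#'
#' @param path Path to a `.toml` or `.json` file.
#' @return A validated `pfa_scene`.
#' @export
load_scene_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    toml = parse_toml(path),
    json = {
      txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
      if (!nzchar(trimws(txt))) list() else
        jsonlite::fromJSON(txt, simplifyVector = TRUE)
    },
    stop(sprintf("unsupported config extension '.%s' (use .toml or .json)", ext),
         call. = FALSE))
  scene_from_list(raw)
}

#' Save a scene configuration
#'
#' Writes the fully resolved configuration (all defaults filled in) as TOML
#' or JSON, chosen by extension. `load_scene_config(save_scene_config(x, p))`
#' reproduces `x` exactly.
#'
#' @param config A `pfa_scene`.
#' @param path Output path ending in `.toml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_scene_config <- function(config, path) {
  x <- scene_to_list(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    toml = write_toml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop(sprintf("unsupported config extension '.%s'", ext), call. = FALSE))
  invisible(path)
}

#' @export
print.pfa_scene <- function(x, ...) {
  g <- x$geometry
  cat("PFA bench scene\n")
  cat(sprintf("  slab: %g x %g x %g mm (top %g mm below bath surface)\n",
              g$slab_length, g$slab_width, g$slab_height, g$slab_top_offset))
  cat(sprintf("  electrodes: d = %g mm, gap = %g mm (centers %g mm apart)\n",
              g$electrode_diameter, g$electrode_gap,
              g$electrode_gap + g$electrode_diameter))
  cat(sprintf("  materials: bath %g S/m, slab %g S/m [%s electrodes]\n",
              x$materials$bath$conductivity, x$materials$slab$conductivity,
              x$solver$electrode_mode))
  cat(sprintf("  recipe: %d %s pulses, %g us, %g Hz, %g V\n",
              x$recipe$pulse_count, x$recipe$polarity, x$recipe$phase_duration,
              x$recipe$frequency, x$recipe$amplitude))
  invisible(x)
}
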