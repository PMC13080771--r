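#' Read a model configuration file
#'
#' Reads a YAML configuration with `geometry`, `materials`, `load` and
#' `solver` blocks and converts it into the package's parameter objects.
#' Geometry keys mirror the model's physical parameters
#' (`cell_diameter_um`, `nucleus_diam_planar_um`, ...); material blocks map
#' region names to `{law, E_kPa, nu, prony: {...}, visco_mode}`; the load
#' block is `{force_nN, config, angle_deg, ramp_s, hold_s}`. Units are fixed
#' to kPa / um / nN / s (1 nN/um^2 = 1 kPa). Missing blocks fall back to the
#' package defaults.
#'
#' @param path Path to a YAML file.
#' @return List with `params` ([geometry_params()]), `materials`,
#'   `load` ([load_case()]) and `settings` ([solver_settings()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- if (is.null(cfg$geometry)) geometry_params() else {
    g <- cfg$geometry
    pick <- function(key, default) if (is.null(g[[key]])) default else g[[key]]
    geometry_params(
      cell_diameter = pick("cell_diameter_um", 20),
      nucleus_diam_planar = pick("nucleus_diam_planar_um", 6),
      nucleus_diam_vertical = pick("nucleus_diam_vertical_um", 8),
      gel_radius = pick("gel_radius_um", 225),
      gel_thickness = pick("gel_thickness_um", 300),
      contact_disc_diameter = pick("contact_disc_diameter_um", 6),
      nucleus_center_height = pick("nucleus_center_height_um",
                                   pick("cell_diameter_um", 20) / 4),
      band_width = pick("band_width_um", 1))
  }
  materials <- if (is.null(cfg$materials)) default_materials() else {
    lapply(cfg$materials, function(m) {
      prony <- if (!is.null(m$prony))
        do.call(prony_constants, m$prony) else NULL
      material_spec(law = m$law, E = m$E_kPa, nu = m$nu, prony = prony,
                    visco_mode = if (is.null(m$visco_mode)) "equilibrium"
                    else m$visco_mode)
    })
  }
  load <- if (is.null(cfg$load)) load_case(300, "top") else {
    l <- cfg$load
    load_case(F_normal = l$force_nN,
              config = if (is.null(l$config)) "top" else l$config,
              angle = if (is.null(l$angle_deg)) 50 else l$angle_deg,
              ramp_time = if (is.null(l$ramp_s)) 1 else l$ramp_s,
              hold_time = if (is.null(l$hold_s)) 10 else l$hold_s)
  }
  settings <- if (is.null(cfg$solver)) solver_settings() else
    do.call(solver_settings, cfg$solver)
  list(params = params, materials = materials, load = load,
       settings = settings)
}
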