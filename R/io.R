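#' Write a frame set to a snapshot file
#'
#' Serializes a `frame_set` to a single-file snapshot: a versioned list
#' holding the run configuration (grid, model, integrator settings, seed),
#' per-frame field arrays with their time/step attributes, and the
#' diagnostics table.  The format is self-describing, so the analysis side
#' can operate on stored frames without access to the code that produced
#' them.
#'
#' @param fs a `frame_set` from [adaptive_integrate()] (optionally carrying
#'   a `seed` attribute).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "frame_set"))
  m <- fs$model
  payload <- list(
    schema = "mapcrystal-frames",
    version = 1L,
    config = list(
      grid = m$grid[c("nx", "ny", "lx", "ly")],
      r_z = m$r_z,
      fields = m$fields,
      couplings = lapply(m$couplings, unclass),
      integrator = unclass(fs$config),
      seed = attr(fs, "seed")),
    times = fs$times,
    frames = lapply(fs$frames, function(st)
      list(t = st$t, z_re = Re(st$z), z_im = Im(st$z), o = st$o)),
    diagnostics = fs$diagnostics,
    stop_reason = fs$stop_reason,
    n_steps = fs$n_steps)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a frame set from a snapshot file
#'
#' @param path snapshot file written by [write_frames()].
#' @return the reconstructed `frame_set`.
#' @export
read_frames <- function(path) {
  p <- readRDS(path)
  if (!identical(p$schema, "mapcrystal-frames"))
    stop("not a mapcrystal snapshot file")
  if (p$version > 1L)
    warning("snapshot written by a newer format version; attempting to read")
  cfgi <- p$config$integrator
  grid <- grid_spec(p$config$grid$nx, p$config$grid$ny,
                    p$config$grid$lx, p$config$grid$ly)
  model <- model_spec(grid, p$config$r_z, p$config$fields,
                      lapply(p$config$couplings, function(cp)
                        coupling(cp$kind, cp$strength, cp$pair)))
  frames <- lapply(p$frames, function(fr)
    field_state(matrix(complex(real = fr$z_re, imaginary = fr$z_im),
                       grid$ny, grid$nx),
                fr$o, fr$t, grid))
  fs <- structure(list(frames = frames, times = p$times,
                       diagnostics = p$diagnostics, model = model,
                       config = do.call(integrator_config,
                                        cfgi[names(cfgi) != ""]),
                       stop_reason = p$stop_reason, n_steps = p$n_steps),
                  class = "frame_set")
  attr(fs, "seed") <- p$config$seed
  fs
}

#' Read a run configuration
#'
#' Run configurations are YAML (or TOML-like `key = value`; YAML is the
#' native format) documents with blocks `grid`, `model` (with `fields` and
#' `couplings` lists), `integrator`, `init` (one entry per field) and a
#' master `seed`.  See the package vignette for a complete example.
#'
#' @param path YAML file.
#' @return a `run_config` object (named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list with the configuration blocks.
#' @export
as_run_config <- function(cfg) {
  # explicit block-wise merge: unnamed sublists (fields, couplings) must be
  # taken verbatim, which rules out a naive recursive modifyList
  grid <- utils::modifyList(list(nx = 64, ny = 64, lx = 8, ly = 8),
                            if (is.null(cfg$grid)) list() else cfg$grid)
  model <- list(
    r_z = if (is.null(cfg$model$r_z)) 0.05 else cfg$model$r_z,
    fields = if (is.null(cfg$model$fields)) list() else cfg$model$fields,
    couplings = if (is.null(cfg$model$couplings)) list() else cfg$model$couplings)
  init <- if (is.null(cfg$init)) list() else cfg$init
  if (is.null(init$z))
    init$z <- list(kind = "bandpass_noise", power_frac = 0.02, bandwidth = 0.2)
  structure(list(grid = grid, model = model,
                 integrator = if (is.null(cfg$integrator)) list()
                              else cfg$integrator,
                 init = init,
                 seed = if (is.null(cfg$seed)) 1L else cfg$seed),
            class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Configuration hash
#'
#' A stable MD5 digest of the canonicalized configuration, recorded in run
#' outputs so results can be traced back to their exact settings.
#'
#' @param cfg a `run_config` (or any serializable list).
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # canonical text rendering -> platform-independent digest
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

# ---- building model/initial state from a run_config -------------------------

build_model <- function(cfg) {
  g <- cfg$grid
  grid <- grid_spec(g$nx, g$ny, g$lx, g$ly)
  cps <- lapply(cfg$model$couplings, function(cp)
    coupling(cp$kind, cp$strength, if (is.null(cp$pair)) c(0, 1) else cp$pair))
  model_spec(grid, cfg$model$r_z, cfg$model$fields, cps)
}

build_init <- function(cfg, model) {
  grid <- model$grid
  seed <- cfg$seed
  mk <- function(spec, kc, field_seed, real) {
    kind <- spec$kind
    if (is.null(kind)) kind <- "bandpass_noise"
    base <- switch(
      kind,
      bandpass_noise = {
        pow <- if (!is.null(spec$target_power)) spec$target_power
               else spec$power_frac * model$r_z
        bandpass_gwn(grid, kc,
                     if (is.null(spec$bandwidth)) 0.2 else spec$bandwidth,
                     pow, seed = field_seed, real = real)
      },
      stripes = {
        k <- if (is.null(spec$k)) c(kc, 0) else spec$k
        s <- stripes(grid, k,
                     if (is.null(spec$amplitude)) sqrt(model$r_z) else spec$amplitude,
                     if (is.null(spec$phase)) 0 else spec$phase)
        if (real) Re(s) else s
      },
      hexagons = hexagons(grid, kc, spec$amplitude,
                          if (is.null(spec$phases)) c(0, 0, 0) else spec$phases,
                          if (is.null(spec$mean_offset)) 0 else spec$mean_offset),
      constant = matrix(if (is.null(spec$value)) 0 else spec$value,
                        grid$ny, grid$nx),
      stop("unknown init kind: ", kind))
    if (!is.null(spec$noise_power) && spec$noise_power > 0)
      base <- base + bandpass_gwn(grid, kc, 0.2, spec$noise_power,
                                  seed = field_seed + 500L, real = real)
    base
  }
  z <- mk(cfg$init$z, 2 * pi, seed * 1000L + 1L, real = FALSE)
  o <- lapply(seq_along(model$fields), function(i) {
    spec <- cfg$init[[paste0("o", i)]]
    if (is.null(spec)) spec <- list(kind = "bandpass_noise", power_frac = 0.02)
    Re(mk(spec, 2 * pi * model$fields[[i]]$w, seed * 1000L + 1L + i, real = TRUE))
  })
  field_state(z, o, 0, grid)
}

#' Run a full simulation from a configuration
#'
#' Builds the model and initial condition from a run configuration,
#' integrates to the final time (or stationarity), and optionally writes
#' the frames to a snapshot file.  The master seed determines every random
#' choice; a run is reproducible from (config, seed) alone.
#'
#' @param cfg a `run_config` (see [read_run_config()]), or path to one.
#' @param out optional snapshot output path.
#' @return the `frame_set`, with the seed and config hash attached as
#'   attributes.
#' @export
run_simulation <- function(cfg, out = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  model <- build_model(cfg)
  ic <- build_init(cfg, model)
  icfg <- do.call(integrator_config, cfg$integrator)
  fs <- adaptive_integrate(ic, model, icfg)
  attr(fs, "seed") <- cfg$seed
  attr(fs, "config_hash") <- config_hash(cfg)
  if (!is.null(out)) write_frames(fs, out)
  fs
}
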