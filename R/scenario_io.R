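# YAML scenario files: a human-editable surface over scenario().
# Units are SI with temperatures in degrees C throughout.

.scenario_keys <- c("name", "dt", "cadence", "method", "seed", "clothing",
                    "body_overrides", "active_system", "flags", "stages")
.stage_keys <- c("duration", "t_air", "rh", "p_air", "t_mrt",
                 "h_c", "h_r", "h_e", "panels")
.panel_keys <- c("t_r", "width", "height", "distance", "z0", "x_offset",
                 "side", "targets", "emissivity")

#' Load a scenario from a YAML file
#'
#' Validates the document against the scenario schema (unknown keys are
#' errors) and builds a [scenario()]. See the packaged fixtures under
#' `inst/extdata` for the format.
#'
#' @param path YAML file path.
#' @return a `bioheat_scenario`.
#' @export
load_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  extra <- setdiff(names(doc), .scenario_keys)
  if (length(extra))
    stop("unknown scenario key(s): ", paste(extra, collapse = ", "))
  if (is.null(doc$stages) || !length(doc$stages))
    stop("scenario must define at least one stage")
  body <- default_body(overrides = doc$body_overrides)
  if (!is.null(doc$active_system)) {
    extra <- setdiff(names(doc$active_system), names(body$thermo$gains))
    if (length(extra))
      stop("unknown active_system gain(s): ", paste(extra, collapse = ", "))
    body$thermo$gains[names(doc$active_system)] <- doc$active_system
  }
  clothing <- clothing_spec()
  if (!is.null(doc$clothing)) {
    cl <- do.call(rbind, lapply(doc$clothing, function(x)
      data.frame(segment = x$segment,
                 i_cl = x$i_cl %||% 0, r_ecl = x$r_ecl %||% 0,
                 stringsAsFactors = FALSE)))
    clothing <- clothing_spec(cl$segment, cl$i_cl, cl$r_ecl)
  }
  stages <- lapply(doc$stages, .stage_from_yaml)
  scenario(stages, body = body, clothing = clothing,
           flags = doc$flags %||% list(),
           dt = doc$dt %||% 1, cadence = doc$cadence %||% 60,
           method = doc$method %||% "rk4", seed = doc$seed %||% 1L,
           name = doc$name %||% basename(path))
}

.stage_from_yaml <- function(s) {
  extra <- setdiff(names(s), .stage_keys)
  if (length(extra))
    stop("unknown stage key(s): ", paste(extra, collapse = ", "))
  panels <- lapply(s$panels %||% list(), function(p) {
    extra <- setdiff(names(p), .panel_keys)
    if (length(extra))
      stop("unknown panel key(s): ", paste(extra, collapse = ", "))
    targets <- if (!is.null(p$targets))
      do.call(rbind, lapply(p$targets, function(t)
        data.frame(segment = t$segment, sector = t$sector,
                   stringsAsFactors = FALSE)))
    radiant_panel(p$t_r, p$width, p$height, p$distance,
                  z0 = p$z0 %||% 0, x_offset = p$x_offset %||% 0,
                  side = p$side, targets = targets)
  })
  args <- list(duration = s$duration, t_air = unlist(s$t_air),
               panels = panels)
  for (k in c("rh", "p_air", "t_mrt", "h_c", "h_r", "h_e"))
    if (!is.null(s[[k]])) args[[k]] <- unlist(s[[k]])
  do.call(environment_stage, args)
}

#' Write a scenario to a YAML file
#'
#' @param scn a `bioheat_scenario`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  doc <- list(name = scn$name, dt = scn$dt, cadence = scn$cadence,
              method = scn$method, seed = scn$seed)
  if (nrow(scn$clothing))
    doc$clothing <- lapply(seq_len(nrow(scn$clothing)), function(i)
      as.list(scn$clothing[i, ]))
  if (length(scn$flags)) doc$flags <- scn$flags
  doc$stages <- lapply(scn$stages, function(s) {
    out <- list(duration = s$duration,
                t_air = if (length(unique(s$t_air)) == 1) s$t_air[1] else
                  as.list(s$t_air),
                p_air = if (length(unique(s$p_air)) == 1) s$p_air[1] else
                  as.list(s$p_air),
                t_mrt = s$t_mrt, h_c = s$h_c, h_r = s$h_r, h_e = s$h_e)
    if (length(s$panels))
      out$panels <- lapply(s$panels, function(p) {
        pl <- list(t_r = p$t_r, width = p$width, height = p$height,
                   distance = p$distance, z0 = p$z0, x_offset = p$x_offset)
        pl$targets <- lapply(seq_len(nrow(p$targets)), function(k)
          list(segment = p$targets$segment[k], sector = p$targets$sector[k]))
        pl
      })
    out
  })
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
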