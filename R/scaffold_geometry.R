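#' Scaffold geometry parameters
#'
#' Parameter set for the multi-spiked connecting scaffold: truncated-cone
#' spikes arranged in concentric rings around a central spike, with a fixed
#' clearance between neighbouring spike bases both circumferentially and
#' radially. Defaults follow the prototype: 5 mm spike height, 0.5 mm base
#' diameter, 0.35 mm inter-spike gap (the scale of cancellous trabeculae),
#' and a maximum embedding depth of 3 mm. The apex tip diameter is not fixed
#' by the prototype drawings; the 0.1 mm default keeps the apex footprint
#' finite for finite-element loading.
#'
#' @param spike_height Spike height in mm.
#' @param base_diameter Diameter of the spike base in mm.
#' @param apex_diameter Diameter of the truncated apex in mm.
#' @param inter_spike_gap Clearance between neighbouring spike bases in mm.
#' @param n_rings Number of concentric rings around the central spike.
#' @param embed_depth_max Maximum embedding depth in mm.
#' @return An object of class `scaffold_params`.
#' @export
scaffold_params <- function(spike_height = 5,
                            base_diameter = 0.5,
                            apex_diameter = 0.1,
                            inter_spike_gap = 0.35,
                            n_rings = 1L,
                            embed_depth_max = 3) {
  stopifnot(length(n_rings) == 1L, n_rings >= 0, n_rings == round(n_rings))
  lens <- c(spike_height = spike_height, base_diameter = base_diameter,
            apex_diameter = apex_diameter, inter_spike_gap = inter_spike_gap,
            embed_depth_max = embed_depth_max)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all scaffold lengths must be positive and finite")
  }
  if (apex_diameter >= base_diameter) {
    stop("apex_diameter must be smaller than base_diameter")
  }
  if (embed_depth_max > spike_height) {
    stop("embed_depth_max cannot exceed spike_height")
  }
  structure(list(spike_height = spike_height,
                 base_diameter = base_diameter,
                 apex_diameter = apex_diameter,
                 inter_spike_gap = inter_spike_gap,
                 n_rings = as.integer(n_rings),
                 embed_depth_max = embed_depth_max),
            class = "scaffold_params")
}

#' Build the spike layout
#'
#' Places the central spike at the origin and `n_rings` concentric rings at a
#' radial pitch of `base_diameter + inter_spike_gap`. Within ring k the number
#' of spikes is the largest m for which the arc gap between neighbouring bases
#' is at least `inter_spike_gap`, i.e. the largest m with
#' 2*pi*R_k / m >= radial pitch; spikes sit at equal angular spacing starting
#' on the +x axis. All spike axes are parallel (the embedding axis).
#'
#' @param params A [scaffold_params()] object.
#' @return An object of class `spike_layout`: a list with `spikes` (a
#'   data.frame with columns `ring`, `center_x`, `center_y`, `base_radius`,
#'   `apex_radius`, `height`, all lengths in mm) and `radial_pitch` (mm).
#' @export
build_spike_layout <- function(params) {
  stopifnot(inherits(params, "scaffold_params"))
  pitch <- params$base_diameter + params$inter_spike_gap
  rings <- lapply(seq_len(params$n_rings), function(k) {
    radius <- k * pitch
    # arc between neighbouring centers must be >= pitch
    m <- floor(2 * pi * radius / pitch)
    theta <- 2 * pi * (seq_len(m) - 1L) / m
    data.frame(ring = k, center_x = radius * cos(theta),
               center_y = radius * sin(theta))
  })
  spikes <- rbind(data.frame(ring = 0L, center_x = 0, center_y = 0),
                  do.call(rbind, rings))
  spikes$base_radius <- params$base_diameter / 2
  spikes$apex_radius <- params$apex_diameter / 2
  spikes$height <- params$spike_height
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, radial_pitch = pitch, params = params),
            class = "spike_layout")
}

#' Spike cross-section radius at a depth below the apex
#'
#' The truncated cone interpolates linearly between the apex radius (depth 0)
#' and the base radius (depth = spike height).
#'
#' @param layout A `spike_layout`.
#' @param depth_from_apex Depth below the apex plane, mm.
#' @return Numeric vector of section radii (mm), one per spike.
#' @export
spike_section_radius <- function(layout, depth_from_apex) {
  stopifnot(inherits(layout, "spike_layout"), length(depth_from_apex) == 1L)
  sp <- layout$spikes
  if (depth_from_apex < 0 || any(depth_from_apex > sp$height)) {
    stop("depth_from_apex must lie in [0, spike height]")
  }
  frac <- depth_from_apex / sp$height
  sp$apex_radius + frac * (sp$base_radius - sp$apex_radius)
}

#' Export a spike layout as JSON
#'
#' @param layout A `spike_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_layout <- function(layout, path) {
  stopifnot(inherits(layout, "spike_layout"))
  obj <- list(radial_pitch = layout$radial_pitch,
              params = unclass(layout$params),
              spikes = layout$spikes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike layout from JSON
#'
#' @param path File written by [write_spike_layout()].
#' @return A `spike_layout`.
#' @export
read_spike_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(scaffold_params, obj$params)
  structure(list(spikes = as.data.frame(obj$spikes),
                 radial_pitch = obj$radial_pitch,
                 params = params),
            class = "spike_layout")
}

#' @export
print.spike_layout <- function(x, ...) {
  cat(sprintf("spike layout: %d spikes (%d rings), radial pitch %.3f mm\n",
              nrow(x$spikes), max(x$spikes$ring), x$radial_pitch))
  invisible(x)
}
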