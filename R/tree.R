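# Murray's-law bifurcating MCA tree with Poiseuille flow: construction,
# exact series-parallel flow solves, and the embolus lodging criterion.
#
# Vessels are stored in binary-heap order: vessel 1 is the root (the MCA
# itself, generation 0); vessel i has daughters 2i and 2i+1; generation
# g(i) = floor(log2(i)). A tree with `generations` bifurcation levels below
# the root has 2^generations terminal arterioles.

#' Build a Murray's-law vessel tree
#'
#' Constructs a symmetric bifurcating tree in which daughter diameters
#' shrink by a factor of 2^(1/3) per generation (Murray's law) and vessel
#' length is a fixed multiple of diameter. Flow is Poiseuille throughout,
#' driven by the pressure difference between the root inlet and the shared
#' terminal outlet.
#'
#' @param root_diameter Root (MCA) diameter in mm.
#' @param generations Number of bifurcation generations below the root
#'   (default 19, giving 524,288 terminal arterioles).
#' @param length_to_diameter Vessel length as a multiple of its diameter
#'   (default 20).
#' @param viscosity Blood dynamic viscosity in Pa s (default 3.5e-3).
#' @param input_pressure Root inlet pressure in mmHg (default 100).
#' @param outlet_pressure Terminal outlet pressure in mmHg (default 0).
#' @return An object of class `vessel_tree`.
#' @examples
#' tree <- build_tree(3.0, generations = 6)
#' tree$diameters_m[1:3] * 1e3 # root and generation-1 diameters in mm
#' @export
build_tree <- function(root_diameter, generations = 19,
                       length_to_diameter = 20, viscosity = 3.5e-3,
                       input_pressure = 100, outlet_pressure = 0) {
  stopifnot(
    "root_diameter must be > 0" = root_diameter > 0,
    "generations must be >= 1" = generations >= 1,
    "length_to_diameter must be > 0" = length_to_diameter > 0,
    "viscosity must be > 0" = viscosity > 0
  )
  if (generations > 24) {
    stop("generations > 24 would allocate over 33M vessels; refusing",
         call. = FALSE)
  }
  g <- 0:generations
  d <- root_diameter * 1e-3 * 2^(-g / 3)
  len <- length_to_diameter * d
  structure(
    list(
      generations = as.integer(generations),
      root_diameter = root_diameter,
      diameters_m = d,        # per generation
      lengths_m = len,        # per generation
      resistances = vessel_resistance(d, len, viscosity), # per generation
      viscosity = viscosity,
      input_pressure_pa = input_pressure * 133.322,
      outlet_pressure_pa = outlet_pressure * 133.322,
      n_vessels = as.integer(2^(generations + 1) - 1),
      n_terminals = as.integer(2^generations)
    ),
    class = "vessel_tree"
  )
}

#' Poiseuille resistance of a cylindrical vessel
#'
#' `R = 128 * mu * L / (pi * d^4)`.
#'
#' @param diameter Vessel diameter in m (vector allowed), > 0.
#' @param length Vessel length in m, > 0.
#' @param viscosity Dynamic viscosity in Pa s, > 0.
#' @return Hydraulic resistance in Pa s / m^3.
#' @examples
#' vessel_resistance(1e-3, 20e-3, 3.5e-3)
#' @export
vessel_resistance <- function(diameter, length, viscosity) {
  if (any(diameter <= 0) || any(length <= 0) || any(viscosity <= 0)) {
    stop("diameter, length and viscosity must all be > 0", call. = FALSE)
  }
  128 * viscosity * length / (pi * diameter^4)
}

# generation of each heap index (1-based)
.generation_of <- function(i) floor(log2(i))

#' Solve flows and pressures in a (possibly blocked) vessel tree
#'
#' Exact two-pass series-parallel solve: equivalent downstream resistances
#' are collapsed leaf-to-root, then pressures and flows distributed
#' root-to-leaf. Blocked vessels carry infinite resistance and zero flow;
#' stagnant open regions equilibrate (no flow, no pressure drop), and the
#' region downstream of a blockage sits at outlet pressure. Flow is
#' conserved exactly at every bifurcation.
#'
#' @param tree A [build_tree()] object.
#' @param blocked Logical vector over heap-ordered vessel indices (length
#'   `tree$n_vessels`), or an integer vector of blocked vessel indices.
#' @return A list of class `flow_state` with heap-ordered vectors `flow`
#'   (m^3/s), `p_top` and `p_bottom` (Pa, at vessel entry/exit), and the
#'   fraction `unperfused` of terminals with zero flow.
#' @examples
#' tree <- build_tree(3.0, generations = 4)
#' fs <- solve_flow(tree)
#' sum(fs$flow[16:31]) / fs$flow[1] # terminal flows sum to root flow
#' @export
solve_flow <- function(tree, blocked = NULL) {
  stopifnot(inherits(tree, "vessel_tree"))
  n <- tree$n_vessels
  G <- tree$generations
  blk <- logical(n)
  if (!is.null(blocked)) {
    if (is.logical(blocked)) {
      stopifnot(length(blocked) == n)
      blk <- blocked
    } else {
      blk[blocked] <- TRUE
    }
  }
  req <- numeric(n)
  # leaf -> root collapse
  idx <- seq.int(2^G, 2^(G + 1) - 1)
  req[idx] <- tree$resistances[G + 1]
  req[idx[blk[idx]]] <- Inf
  if (G >= 1) {
    for (g in (G - 1):0) {
      idx <- seq.int(2^g, 2^(g + 1) - 1)
      cond <- .colSums(1 / req[seq.int(2^(g + 1), 2^(g + 2) - 1)],
                       2L, length(idx))
      r <- tree$resistances[g + 1] + 1 / cond # cond 0 -> Inf, as required
      r[blk[idx]] <- Inf
      req[idx] <- r
    }
  }
  # root -> leaf distribution
  p_top <- numeric(n)
  p_bottom <- numeric(n)
  flow <- numeric(n)
  p_out <- tree$outlet_pressure_pa
  p_top[1] <- tree$input_pressure_pa
  for (g in 0:G) {
    idx <- seq.int(2^g, 2^(g + 1) - 1)
    q <- (p_top[idx] - p_out) / req[idx]
    q[!is.finite(q)] <- 0
    flow[idx] <- q
    pb <- p_top[idx] - q * tree$resistances[g + 1]
    pb[blk[idx]] <- p_out
    p_bottom[idx] <- pb
    if (g < G) {
      p_top[seq.int(2^(g + 1), 2^(g + 2) - 1)] <- rep(pb, each = 2)
    }
  }
  term <- 2^G:(2^(G + 1) - 1)
  structure(
    list(flow = flow, p_top = p_top, p_bottom = p_bottom,
         req = req, blocked = blk,
         unperfused = mean(flow[term] <= 0)),
    class = "flow_state"
  )
}

#' Probabilistic routing of an embolus at a bifurcation
#'
#' An embolus entering a bifurcation follows a daughter vessel with
#' probability proportional to the flow it carries:
#' `P(left) = Q_left / (Q_left + Q_right)` (0.5 on an exact tie). If both
#' daughters are stagnant the embolus halts (`NA` is returned).
#'
#' @param flow_left,flow_right Daughter flows in m^3/s, >= 0.
#' @return `"left"`, `"right"`, or `NA` if both flows are zero.
#' @export
route_at_bifurcation <- function(flow_left, flow_right) {
  if (flow_left < 0 || flow_right < 0) {
    stop("daughter flows must be >= 0", call. = FALSE)
  }
  total <- flow_left + flow_right
  if (total == 0) return(NA_character_)
  p_left <- flow_left / total
  if (stats::runif(1) < p_left) "left" else "right"
}

#' Bubble-wall contact area in a vessel
#'
#' A bubble whose spherical-equivalent diameter does not exceed the vessel
#' diameter touches the wall nowhere (contact area 0). A larger bubble is
#' modelled as a cylinder with hemispherical caps filling the vessel lumen:
#' the cylindrical contact length is
#' `L_c = (V - (4/3) pi r^3) / (pi r^2)` and the wall contact area
#' `A_wall = 2 pi r L_c`, with `r` the vessel radius.
#'
#' @param volume Bubble volume in m^3 (vector allowed), > 0.
#' @param vessel_radius Vessel radius in m, > 0.
#' @return Contact area in m^2 (0 for undeformed bubbles).
#' @export
contact_area <- function(volume, vessel_radius) {
  if (any(volume <= 0) || any(vessel_radius <= 0)) {
    stop("volume and vessel_radius must be > 0", call. = FALSE)
  }
  excess <- volume - (4 / 3) * pi * vessel_radius^3
  ifelse(excess <= 0, 0, 2 * excess / vessel_radius)
}

#' Stiction lodging criterion
#'
#' A deformed embolus lodges when the limiting static friction against the
#' wall, `F = K * A_wall`, is at least the force exerted by the pressure
#' differential over the embolus, `F = dp * pi * r^2` (with `r` the vessel
#' radius). An undeformed bubble (`A_wall = 0`) never lodges; a deformed
#' bubble with no driving pressure always does.
#'
#' @param a_wall Bubble-wall contact area, m^2 (vector allowed).
#' @param vessel_radius Vessel radius, m.
#' @param pressure_drop Pressure differential over the embolus, Pa, >= 0.
#' @param stiction_coefficient Stiction coefficient K in N/m^2 (default 10,
#'   from experimental measurements).
#' @return Logical: `TRUE` where the embolus lodges.
#' @export
is_lodged <- function(a_wall, vessel_radius, pressure_drop,
                      stiction_coefficient = 10) {
  if (any(pressure_drop < 0)) {
    stop("pressure_drop must be >= 0", call. = FALSE)
  }
  a_wall > 0 & stiction_coefficient * a_wall >=
    pressure_drop * pi * vessel_radius^2
}
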