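# Independent oracles and fixtures used across tests.

# Dense Kirchhoff solve of the tree network: assembles the node-pressure
# linear system over all bifurcation nodes and solves it with base solve().
# Completely independent of the package's series-parallel algorithm.
# Returns per-vessel flows and entry pressures.
dense_flow_oracle <- function(tree, blocked = integer(0)) {
  G <- tree$generations
  n <- tree$n_vessels
  n_int <- 2^G - 1 # non-terminal vessels; node j = bottom of vessel j
  g_of <- function(i) floor(log2(i))
  cond <- 1 / tree$resistances[g_of(1:n) + 1]
  cond[blocked] <- 0
  p_in <- tree$input_pressure_pa
  p_out <- tree$outlet_pressure_pa
  A <- matrix(0, n_int, n_int)
  b <- numeric(n_int)
  for (j in seq_len(n_int)) {
    c1 <- 2 * j; c2 <- 2 * j + 1
    # inflow: vessel j from its parent node (or the inlet)
    A[j, j] <- A[j, j] - cond[j]
    if (j == 1) b[j] <- b[j] - cond[j] * p_in else {
      A[j, j %/% 2] <- A[j, j %/% 2] + cond[j]
    }
    for (c in c(c1, c2)) {
      A[j, j] <- A[j, j] - cond[c]
      if (c <= n_int) A[j, c] <- A[j, c] + cond[c] else {
        b[j] <- b[j] - cond[c] * p_out
      }
    }
  }
  # stagnant nodes (all adjacent conductances zero) are pinned to outlet
  dead <- which(abs(diag(A)) == 0)
  for (j in dead) { A[j, j] <- 1; b[j] <- p_out }
  p_node <- solve(A, b)
  p_top <- numeric(n)
  p_top[1] <- p_in
  for (i in 2:n) p_top[i] <- p_node[i %/% 2]
  p_bottom <- ifelse(seq_len(n) <= n_int, c(p_node, numeric(n - n_int)),
                     p_out)
  p_bottom[seq_len(n_int)] <- p_node
  flow <- cond * (p_top - p_bottom)
  list(flow = flow, p_top = p_top, p_bottom = p_bottom)
}

# Lodging-generation oracle for a single bubble descending a symmetric,
# otherwise empty tree with dissolution switched off: at each generation
# where the bubble deforms, evaluate the stiction criterion with the entry
# pressure taken from a dense solve with that vessel blocked. Returns the
# first generation where it holds (NA if the bubble reaches the terminal
# outlet and leaves).
dense_lodge_oracle <- function(tree, diameter_um, K = 10) {
  vol <- (4 / 3) * pi * (diameter_um * 1e-6 / 2)^3
  G <- tree$generations
  vessel <- 1L
  for (g in 0:G) {
    rv <- tree$diameters_m[g + 1] / 2
    if (2 * (3 * vol / (4 * pi))^(1 / 3) > tree$diameters_m[g + 1]) {
      o <- dense_flow_oracle(tree, blocked = vessel)
      dp <- max(o$p_top[vessel] - tree$outlet_pressure_pa, 0)
      if (is_lodged(contact_area(vol, rv), rv, dp, K)) return(g)
    }
    vessel <- 2L * vessel # symmetric tree: either daughter is equivalent
  }
  NA_integer_
}

# gas parameters with dissolution switched off (saturated, no surface
# tension): bubbles keep their volume exactly
frozen_gas <- function() {
  gas_params(saturation_fraction = 1, surface_tension = 0)
}

# small synthetic patient with fixed context
fixture_patient <- function(hct = 0.30, mca_left = 3.0, mca_right = 3.0) {
  patient_record(
    id = "fixture",
    mca_diameter_left = mca_left,
    mca_diameter_right = mca_right,
    procedure = "CABG",
    haematocrit_samples = data.frame(time_s = 0, fraction = hct),
    monitoring_duration = 6000
  )
}

# Minnaert resonance radius of an air bubble (undamped, used as the
# closed-form Rayleigh-regime reference for the modal series)
minnaert_radius <- function(frequency, gamma = 1.4, p0 = 101325,
                            rho = 1050) {
  sqrt(3 * gamma * p0 / rho) / (2 * pi * frequency)
}
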