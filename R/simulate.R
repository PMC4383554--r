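# Monte-Carlo transport of sized bubbles through the vessel tree: advection
# at local mean flow speed, probabilistic routing, stiction lodging,
# dissolution-driven shrinkage and remobilisation, and ensemble summaries.

#' Simulation parameters
#'
#' @param stiction_coefficient Stiction coefficient K in N/m^2 (default 10).
#' @param time_step Simulation time step in s (default 0.1).
#' @param ensemble_size Number of Monte-Carlo repetitions (default 30).
#' @param radius_noise_rel_sd Relative standard deviation of the log-normal
#'   multiplicative noise applied once to each bubble radius per run
#'   (default 0.40, the assumed sizing uncertainty).
#' @param rng_seed Integer seed; per-run seeds are derived from it.
#' @param clearance_window Time simulated after the last injected bubble, s
#'   (default 60).
#' @param min_radius Bubbles shrinking below this radius (m) are removed
#'   (default 1e-6).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(stiction_coefficient = 10, time_step = 0.1,
                       ensemble_size = 30, radius_noise_rel_sd = 0.40,
                       rng_seed = 1L, clearance_window = 60,
                       min_radius = 1e-6) {
  stopifnot(
    "stiction_coefficient must be > 0" = stiction_coefficient > 0,
    "time_step must be > 0" = time_step > 0,
    "ensemble_size must be >= 2" = ensemble_size >= 2,
    "radius_noise_rel_sd must be >= 0" = radius_noise_rel_sd >= 0,
    "clearance_window must be >= 0" = clearance_window >= 0
  )
  structure(
    list(stiction_coefficient = stiction_coefficient,
         time_step = time_step,
         ensemble_size = as.integer(ensemble_size),
         radius_noise_rel_sd = radius_noise_rel_sd,
         rng_seed = as.integer(rng_seed),
         clearance_window = clearance_window,
         min_radius = min_radius),
    class = "sim_params"
  )
}

# piecewise-constant blood-pressure lookup (mmHg -> Pa); NULL = tree default
.bp_fun <- function(bp_trace, tree) {
  if (is.null(bp_trace)) {
    p <- tree$input_pressure_pa
    return(function(t) rep(p, length(t)))
  }
  stopifnot(all(c("time_s", "mmhg") %in% names(bp_trace)))
  sf <- stats::approxfun(bp_trace$time_s, bp_trace$mmhg * 133.322,
                         method = "constant", rule = 2, f = 0)
  function(t) sf(t)
}

#' Simulate one Monte-Carlo run of emboli through a vessel tree
#'
#' Injects each scheduled bubble at the tree root at its event time (radius
#' multiplied once by log-normal noise of relative SD
#' `params$radius_noise_rel_sd`, mean-preserving). On every time step free
#' emboli advance at the local mean flow speed `Q/A`; crossing a bifurcation
#' routes them probabilistically by daughter flows, and entering a vessel
#' narrower than the bubble triggers the stiction lodging check with the
#' pressure differential evaluated over the tentatively blocked vessel
#' (entry-node pressure minus outlet). All bubbles shrink by the
#' quasi-static dissolution law; lodged bubbles are re-checked after
#' shrinkage and remobilise when stiction no longer holds. Bubbles reaching
#' the distal end of a terminal arteriole without lodging leave the tree.
#' Flows are re-solved whenever the blocked set changes.
#'
#' @param schedule Data frame with columns `time_s` and `diameter_um`
#'   (injection time and bubble diameter), time-sorted.
#' @param tree A [build_tree()] object.
#' @param params A [sim_params()] object.
#' @param gas A [gas_params()] object governing dissolution.
#' @param bp_trace Optional data frame (`time_s`, `mmhg`) of input blood
#'   pressure; defaults to the tree's constant input pressure.
#' @return A data frame of class `obstruction_run` with columns `time_s` and
#'   `pct_unperfused` (percentage of terminal arterioles without flow), and
#'   an `emboli` attribute logging, per injected bubble, the noisy radius,
#'   whether and where it first lodged, and its fate.
#' @export
run_simulation <- function(schedule, tree, params = sim_params(),
                           gas = gas_params(), bp_trace = NULL) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(params, "sim_params"))
  if (nrow(schedule) > 0 && is.unsorted(schedule$time_s)) {
    stop("schedule must be sorted by time_s", call. = FALSE)
  }
  dt <- params$time_step
  G <- tree$generations
  gen_area <- pi * (tree$diameters_m / 2)^2
  gen_len <- tree$lengths_m
  gen_rad <- tree$diameters_m / 2
  p_out <- tree$outlet_pressure_pa
  p_ref <- tree$input_pressure_pa - p_out
  bp <- .bp_fun(bp_trace, tree)
  n_ev <- nrow(schedule)

  # per-bubble log-normal radius noise, mean-preserving
  sdlog <- sqrt(log(1 + params$radius_noise_rel_sd^2))
  mult <- if (sdlog > 0) {
    exp(stats::rnorm(n_ev, -sdlog^2 / 2, sdlog))
  } else rep(1, n_ev)
  r0 <- pmax(schedule$diameter_um * 1e-6 / 2 * mult, params$min_radius * 1.01)

  t_end <- if (n_ev > 0) max(schedule$time_s) + params$clearance_window else
    params$clearance_window
  times <- seq(0, t_end, by = dt)

  # embolus state (parallel vectors)
  vol <- (4 / 3) * pi * r0^3
  vessel <- integer(n_ev)
  axial <- numeric(n_ev)
  active <- logical(n_ev)
  lodged <- logical(n_ev)
  injected <- logical(n_ev)
  first_lodge_gen <- rep(NA_integer_, n_ev)
  fate <- rep(NA_character_, n_ev)

  blocked_n <- integer(tree$n_vessels)
  blk <- logical(tree$n_vessels)
  fs <- solve_flow(tree)
  req <- fs$req
  Rg <- tree$resistances
  p_in_ref <- tree$input_pressure_pa
  dirty <- FALSE
  pct <- numeric(length(times))
  next_ev <- 1L

  # recompute equivalent resistances at v and its ancestors (after v's
  # blocked status changed); O(generations)
  path_req_update <- function(v) {
    a <- v
    while (a >= 1) {
      g <- .generation_of(a)
      req[a] <<- if (blk[a]) Inf else if (g == G) Rg[g + 1] else
        Rg[g + 1] + 1 / (1 / req[2 * a] + 1 / req[2 * a + 1])
      a <- a %/% 2
    }
  }

  # entry-node pressure at vessel v if v were blocked, relative to outlet
  # and unscaled by blood pressure: O(generations) walk along the root path,
  # exactly reproducing a full series-parallel solve with v blocked
  dp_if_blocked <- function(v) {
    depth <- .generation_of(v)
    path <- integer(depth + 1)
    a <- v
    for (k in (depth + 1):1) { path[k] <- a; a <- a %/% 2L }
    nr <- numeric(depth + 1)
    nr[depth + 1] <- Inf
    if (depth >= 1) {
      for (k in depth:1) {
        a <- path[k]
        child <- path[k + 1]
        sib <- if (child %% 2L == 0L) child + 1L else child - 1L
        nr[k] <- if (blk[a]) Inf else
          Rg[k] + 1 / (1 / req[sib] + 1 / nr[k + 1])
      }
    }
    p <- p_in_ref
    for (k in seq_len(depth)) {
      if (blk[path[k]]) { p <- p_out; break }
      q <- (p - p_out) / nr[k]
      if (!is.finite(q)) q <- 0
      p <- p - q * Rg[k]
    }
    p - p_out
  }

  # stiction check for embolus i on entry into its current vessel, against
  # the tree state with that vessel tentatively blocked; commits the
  # blockage and returns TRUE if the embolus lodges
  check_embolus <- function(i) {
    v <- vessel[i]
    g <- .generation_of(v)
    rv <- gen_rad[g + 1]
    aw <- contact_area(vol[i], rv)
    if (aw <= 0) return(FALSE)
    dp <- max(dp_if_blocked(v) * scale_t, 0)
    if (!is_lodged(aw, rv, dp, params$stiction_coefficient)) return(FALSE)
    lodged[i] <<- TRUE
    if (is.na(first_lodge_gen[i])) first_lodge_gen[i] <<- as.integer(g)
    fate[i] <<- "lodged"
    blocked_n[v] <<- blocked_n[v] + 1L
    if (!blk[v]) {
      blk[v] <<- TRUE
      path_req_update(v)
    }
    dirty <<- TRUE
    TRUE
  }

  unblock <- function(vs) {
    # decrement lodged-embolus counts; reopen vessels that emptied
    for (v in vs) {
      blocked_n[v] <<- blocked_n[v] - 1L
      if (blocked_n[v] == 0L && blk[v]) {
        blk[v] <<- FALSE
        path_req_update(v)
      }
    }
    dirty <<- TRUE
  }

  for (s in seq_along(times)) {
    t_now <- times[s]
    scale_t <- (bp(t_now) - p_out) / p_ref

    # inject due events at the root (with an entry stiction check)
    while (next_ev <= n_ev && schedule$time_s[next_ev] <= t_now) {
      i <- next_ev
      injected[i] <- TRUE; active[i] <- TRUE
      vessel[i] <- 1L; axial[i] <- 0
      check_embolus(i)
      next_ev <- next_ev + 1L
    }

    # advect free emboli
    free <- which(active & !lodged)
    if (length(free) > 0) {
      g <- .generation_of(vessel[free])
      v <- fs$flow[vessel[free]] * scale_t / gen_area[g + 1]
      axial[free] <- axial[free] + v * dt / gen_len[g + 1]
      # process bifurcation crossings (possibly several per step); the
      # stiction check runs at vessel entry, before further advection
      repeat {
        cross <- free[axial[free] >= 1 & !lodged[free] & active[free]]
        if (length(cross) == 0) break
        for (i in cross) {
          gi <- .generation_of(vessel[i])
          if (gi == G) { # distal end of a terminal arteriole: leaves tree
            active[i] <- FALSE
            fate[i] <- "cleared_terminal"
            next
          }
          c1 <- 2L * vessel[i]
          q1 <- fs$flow[c1]; q2 <- fs$flow[c1 + 1L]
          if (q1 + q2 <= 0) { axial[i] <- 1; next } # halted
          side <- route_at_bifurcation(q1, q2)
          child <- if (side == "left") c1 else c1 + 1L
          excess_m <- (axial[i] - 1) * gen_len[gi + 1]
          vessel[i] <- child
          axial[i] <- min(excess_m / gen_len[gi + 2], 1)
          check_embolus(i)
        }
      }
    }

    # dissolution shrinkage for all active bubbles
    act <- which(active)
    if (length(act) > 0) {
      r <- (3 * vol[act] / (4 * pi))^(1 / 3)
      r2 <- pmax(r + shrink_rate(r, gas) * dt, 0)
      vol[act] <- (4 / 3) * pi * r2^3
      gone <- act[r2 < params$min_radius]
      if (length(gone) > 0) {
        was_lodged <- gone[lodged[gone]]
        if (length(was_lodged) > 0) unblock(vessel[was_lodged])
        active[gone] <- FALSE; lodged[gone] <- FALSE
        fate[gone] <- "dissolved"
      }
    }

    # re-check lodged bubbles after shrinkage; remobilise failures
    ldg <- which(active & lodged)
    if (length(ldg) > 0) {
      g <- .generation_of(vessel[ldg])
      rv <- gen_rad[g + 1]
      aw <- contact_area(vol[ldg], rv)
      dp <- pmax((fs$p_top[vessel[ldg]] - p_out) * scale_t, 0)
      hold <- is_lodged(aw, rv, dp, params$stiction_coefficient)
      loose <- ldg[!hold]
      if (length(loose) > 0) {
        unblock(vessel[loose])
        lodged[loose] <- FALSE
        fate[loose] <- "remobilised"
      }
    }

    if (dirty) {
      fs <- solve_flow(tree, blk)
      req <- fs$req
      dirty <- FALSE
    }
    pct[s] <- fs$unperfused * 100
  }

  out <- data.frame(time_s = times, pct_unperfused = pct)
  attr(out, "emboli") <- data.frame(
    time_s = schedule$time_s,
    diameter_um = schedule$diameter_um,
    noisy_radius_m = r0,
    first_lodge_generation = first_lodge_gen,
    fate = fate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("obstruction_run", "data.frame")
  out
}

#' Ensemble Monte-Carlo simulation with 95% confidence band
#'
#' Repeats [run_simulation()] `params$ensemble_size` times with
#' deterministically derived seeds and summarises, at each time point, the
#' ensemble mean and percentile-based 95% confidence interval (2.5th and
#' 97.5th ensemble percentiles) of the percentage of unperfused terminal
#' arterioles.
#'
#' @inheritParams run_simulation
#' @return A data frame of class `obstruction_series` with columns `time_s`,
#'   `mean_pct`, `ci_low`, `ci_high`.
#' @export
run_ensemble <- function(schedule, tree, params = sim_params(),
                         gas = gas_params(), bp_trace = NULL) {
  stopifnot(params$ensemble_size >= 2)
  runs <- lapply(seq_len(params$ensemble_size), function(k) {
    set.seed(params$rng_seed + k)
    run_simulation(schedule, tree, params, gas, bp_trace)
  })
  m <- do.call(cbind, lapply(runs, function(r) r$pct_unperfused))
  mean_pct <- rowMeans(m)
  qs <- apply(m, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(
    time_s = runs[[1]]$time_s,
    mean_pct = mean_pct,
    ci_low = pmin(qs[1, ], mean_pct),
    ci_high = pmax(qs[2, ], mean_pct)
  )
  class(out) <- c("obstruction_series", "data.frame")
  out
}

#' Plot an obstruction time series
#'
#' @param x An `obstruction_series` from [run_ensemble()].
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.obstruction_series <- function(x, ...) {
  graphics::plot(x$time_s, x$mean_pct, type = "l",
                 xlab = "time (s)", ylab = "unperfused terminals (%)", ...)
  graphics::polygon(c(x$time_s, rev(x$time_s)), c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$time_s, x$mean_pct)
  invisible(x)
}
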