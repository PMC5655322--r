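#' Rest-volume inflation schedule
#'
#' The internal pressure of the closed primordium surface is emulated by
#' growing the rest volume of the stress-free state with time:
#' \deqn{V_0(t) = 3 V_{init} (1 - \tfrac{2}{3} e^{-t})}
#' so that \eqn{V_0(0) = V_{init}} and \eqn{V_0 \to 3 V_{init}} as the
#' relaxation proceeds. The expansion factor 3 and decay shape 2/3 are the
#' model's fixed protocol constants, stored explicitly.
#'
#' @param V_init initial enclosed volume (> 0).
#' @return an object of class `inflation_schedule`.
#' @export
inflation_schedule <- function(V_init) {
  if (!is.numeric(V_init) || length(V_init) != 1L || !is.finite(V_init) ||
        V_init <= 0) {
    stop("V_init must be a positive scalar")
  }
  structure(list(V_init = V_init, expansion_factor = 3,
                 decay_shape = 2 / 3),
            class = "inflation_schedule")
}

#' @rdname inflation_schedule
#' @param schedule an `inflation_schedule`.
#' @param t simulation time (>= 0); vectorised.
#' @return `rest_volume_at`: the rest volume V0(t), strictly increasing in
#'   `t` and bounded above by `3 * V_init`.
#' @examples
#' sch <- inflation_schedule(V_init = 2)
#' rest_volume_at(sch, c(0, log(2), 10))   # 2, 4, ~6
#' @export
rest_volume_at <- function(schedule, t) {
  if (!inherits(schedule, "inflation_schedule")) {
    stop("schedule must be an inflation_schedule")
  }
  if (any(t < 0)) stop("t must be >= 0")
  schedule$expansion_factor * schedule$V_init *
    (1 - schedule$decay_shape * exp(-t))
}

#' Solver settings for steepest-descent relaxation
#'
#' @param dt initial (and nominal maximum resolution) time step.
#' @param max_steps step budget.
#' @param grad_tol convergence threshold on the max-norm of the gradient.
#' @param energy_tol relative energy-change threshold over a 100-step
#'   window (either criterion stops the run).
#' @param checkpoint_every log/checkpoint cadence in steps.
#' @param dt_max upper bound for the adaptive step (the safeguard halves
#'   `dt` whenever a step would increase the energy, and grows it again by
#'   10\% per accepted step).
#' @param pin_boundary hold boundary vertices fixed (patch protocol only).
#' @param keep_states store vertex positions at every checkpoint.
#' @param method step-size rule for the descent direction: `"euler"` is
#'   explicit Euler on the friction dynamics with adaptive `dt` (physical
#'   time; the inflation protocol needs it because the rest-volume
#'   schedule is a function of `t`), `"bb"` is the Barzilai-Borwein
#'   spectral step for pure energy minimisation, typically orders of
#'   magnitude faster to the minimum. Both move along the negative
#'   gradient and both are safeguarded: a step that would increase the
#'   energy is halved until it does not.
#' @param schedule_pace with `method = "bb"` under an inflation schedule,
#'   the schedule clock advances by this amount per relaxation iteration
#'   (a quasi-static sweep: the rest volume creeps, the surface keeps
#'   relaxing); ignored otherwise.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.002, max_steps = 20000L, grad_tol = 1e-3,
                            energy_tol = 1e-9, checkpoint_every = 100L,
                            dt_max = 50 * dt, pin_boundary = FALSE,
                            keep_states = FALSE,
                            method = c("euler", "bb"),
                            schedule_pace = 0.02) {
  if (dt <= 0 || dt_max < dt) stop("need 0 < dt <= dt_max")
  if (grad_tol <= 0 || energy_tol <= 0) stop("tolerances must be positive")
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 grad_tol = grad_tol, energy_tol = energy_tol,
                 checkpoint_every = as.integer(checkpoint_every),
                 dt_max = dt_max, pin_boundary = isTRUE(pin_boundary),
                 keep_states = isTRUE(keep_states),
                 method = match.arg(method),
                 schedule_pace = schedule_pace),
            class = "solver_settings")
}

#' Simulation state
#'
#' Current mesh, simulation time, energy breakdown and gradient max-norm.
#'
#' @param mesh a [triangle_mesh()].
#' @param t simulation time.
#' @return an object of class `simulation_state`.
#' @export
simulation_state <- function(mesh, t = 0) {
  stopifnot_mesh(mesh)
  structure(list(mesh = mesh, t = t, energy = NULL, grad_norm = NA_real_),
            class = "simulation_state")
}

#' One explicit-Euler steepest-descent step
#'
#' Overdamped dynamics `gamma dr_i/dt = -dU/dr_i` discretised as
#' `r_i <- r_i - (dt / gamma) * dU/dr_i`; the simulation time advances by
#' `dt`. Only the ratio `dt / gamma` affects the update.
#'
#' @param state a [simulation_state()].
#' @param topology topology of the state's mesh.
#' @param ref reference state (with the rest volume already set for this
#'   step when the volume term is active).
#' @param params [elastic_parameters()].
#' @param dt time step (> 0).
#' @return the advanced `simulation_state` (energy and `grad_norm` refer to
#'   the pre-step configuration).
#' @export
descent_step <- function(state, topology, ref, params, dt) {
  if (!inherits(state, "simulation_state")) stop("not a simulation_state")
  if (dt <= 0) stop("dt must be positive")
  r <- energy_call(state$mesh, topology, ref, params, want_grad = TRUE)
  g <- r$gradient
  if (!all(is.finite(g))) {
    stop("non-finite gradient at t = ", format(state$t))
  }
  state$mesh$vertices <- state$mesh$vertices - (dt / params$gamma) * g
  state$t <- state$t + dt
  state$energy <- structure(r[setdiff(names(r), "gradient")],
                            class = "energy_breakdown")
  state$grad_norm <- max(abs(g))
  state
}

# shared relaxation loop: V0_fun(t) returns the rest volume for the step
# (NULL keeps ref$V0 fixed / volume term off); free_mask marks movable rows
relax_loop <- function(mesh, topology, ref, params, settings, V0_fun = NULL,
                       free_mask = NULL, stop_after_t = NULL) {
  gam <- params$gamma
  dt <- settings$dt
  log_rows <- list()
  states <- list()
  window <- numeric(0)   # recent energies for the relative-change test
  converged <- FALSE
  halvings <- 0L
  step <- 0L
  t <- 0
  m2 <- mesh
  if (!is.null(V0_fun)) ref$V0 <- V0_fun(0)
  r <- energy_call(m2, topology, ref, params, want_grad = TRUE)
  repeat {
    if (step >= settings$max_steps) break
    g <- r$gradient
    if (!all(is.finite(g))) {
      stop("solver error: non-finite gradient at step ", step)
    }
    if (!is.null(free_mask)) g[!free_mask, ] <- 0
    gn <- max(abs(g))
    if (step %% settings$checkpoint_every == 0L) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, t = t, dt = dt, U_total = r$total, U_volume = r$volume,
        U_area = r$area, U_edge = r$edge, U_angle = r$angle,
        grad_norm = gn, V = r$enclosed_volume,
        area = sum(facet_areas(m2)),
        V0 = if (!is.null(V0_fun)) ref$V0 else NA_real_)
      if (settings$keep_states) {
        states[[length(states) + 1L]] <- m2$vertices
      }
    }
    # convergence tests (gradient, then windowed relative energy change);
    # inflation runs additionally wait until the schedule has saturated
    sched_done <- is.null(stop_after_t) || t >= stop_after_t
    if (sched_done && gn < settings$grad_tol) { converged <- TRUE; break }
    window <- c(window, r$total)
    if (length(window) > 100L) window <- window[-1L]
    if (sched_done && length(window) == 100L) {
      lo <- min(window); hi <- max(window)
      if (hi - lo <= settings$energy_tol * max(hi, 1e-300)) {
        converged <- TRUE
        break
      }
    }
    # gradient step with monotone-energy safeguard at fixed V0; the
    # energy+gradient of the accepted position seeds the next step
    v_old <- m2$vertices
    repeat {
      vt <- v_old - (dt / gam) * g
      m2$vertices <- vt
      rt <- energy_call(m2, topology, ref, params, want_grad = TRUE)
      if (rt$total <= r$total || dt <= 1e-12) break
      dt <- dt / 2
      halvings <- halvings + 1L
    }
    if (settings$method == "bb") {
      # quasi-static sweep: the schedule clock advances at a fixed pace,
      # one spectral relaxation iteration per increment
      t <- t + if (is.null(V0_fun)) dt else settings$schedule_pace
      # Barzilai-Borwein spectral step from the accepted displacement
      dv <- vt - v_old
      dg <- rt$gradient - r$gradient
      den <- sum(dv * dg)
      dt <- if (den > 0) {
        gam * min(max(sum(dv * dv) / den, 1e-10), 1e3)
      } else {
        dt * 2
      }
    } else {
      t <- t + dt
      dt <- min(dt * 1.1, settings$dt_max)
    }
    step <- step + 1L
    r <- rt
    if (!is.null(V0_fun)) {
      v0_new <- V0_fun(t)
      if (v0_new != ref$V0) {
        ref$V0 <- v0_new
        r <- energy_call(m2, topology, ref, params, want_grad = TRUE)
      }
    }
  }
  g <- r$gradient
  if (!is.null(free_mask)) g[!free_mask, ] <- 0
  log_rows[[length(log_rows) + 1L]] <- data.frame(
    step = step, t = t, dt = dt, U_total = r$total, U_volume = r$volume,
    U_area = r$area, U_edge = r$edge, U_angle = r$angle,
    grad_norm = max(abs(g)), V = r$enclosed_volume,
    area = sum(facet_areas(m2)),
    V0 = if (!is.null(V0_fun)) ref$V0 else NA_real_)
  structure(list(mesh = m2, log = do.call(rbind, log_rows),
                 states = states, converged = converged, steps = step,
                 t = t, dt_halvings = halvings,
                 final_energy = structure(
                   r[setdiff(names(r), "gradient")],
                   class = "energy_breakdown"),
                 ref = ref, params = params, settings = settings),
            class = "unfold_run")
}

#' @export
print.unfold_run <- function(x, ...) {
  cat(sprintf(
    "unfold_run: %d steps (t = %.3f), U = %.6g, grad max-norm = %.3g, %s\n",
    x$steps, x$t, x$final_energy$total,
    utils::tail(x$log$grad_norm, 1L),
    if (x$converged) "converged" else "step budget reached"))
  invisible(x)
}

#' Whole-primordium inflation protocol
#'
#' Unfolds a closed, furrowed surface by volume expansion under area
#' constraint: the stress-free state is captured from the input, then the
#' rest volume follows the [inflation_schedule()] while steepest descent
#' relaxes the vertices. Facet-area and edge-length stiffnesses are kept
#' high so the size of each triangular plate stays almost fixed and the
#' surface gains volume by unfolding its furrows, not by stretching.
#'
#' @param mesh a closed, outward-oriented [triangle_mesh()].
#' @param params [elastic_parameters()] with `k_volume > 0`. The default
#'   drives the inflation with a volume stiffness equal to the area/edge
#'   stiffness: opening a closed fold is a snap-through (its circumference
#'   must stretch transiently while it everts), so the pressure term has
#'   to be comparable to the membrane terms or the furrows stay locked;
#'   the stored furrow area, not membrane stretching, still supplies
#'   essentially all of the volume gain.
#' @param settings [solver_settings()].
#' @param t_end schedule time after which convergence tests are applied
#'   (by then `exp(-t)` has decayed to ~1e-3 of the rest-volume gap).
#' @return an `unfold_run`: final mesh, per-checkpoint log (`step`, `t`,
#'   energy terms, `grad_norm`, `V`, `V0`), convergence diagnostics.
#' @export
run_inflation <- function(mesh,
                          params = elastic_parameters(k_volume = 100),
                          settings = solver_settings(method = "bb"),
                          t_end = 7) {
  stopifnot_mesh(mesh)
  topology <- build_topology(mesh)
  if (any(topology$boundary)) {
    stop("protocol error: inflation requires a closed mesh")
  }
  if (params$k_volume <= 0) stop("inflation requires k_volume > 0")
  ref <- capture_reference(mesh, include_volume = TRUE, topology = topology)
  schedule <- inflation_schedule(ref$V0)
  out <- relax_loop(mesh, topology, ref, params, settings,
                    V0_fun = function(t) rest_volume_at(schedule, t),
                    stop_after_t = t_end)
  out$schedule <- schedule
  out
}

#' Local furrow-patch flattening protocol
#'
#' Unfolds an open sheet with a local furrow pattern by setting the
#' stress-free inter-facet angle to pi on every interior edge and
#' minimising the energy: rest areas and edge lengths are taken from the
#' input geometry, the volume term is off, and relaxation drives every
#' dihedral towards the flat state.
#'
#' @param mesh an open [triangle_mesh()] (must have boundary edges).
#' @param params [elastic_parameters()]; `k_volume` is ignored (forced 0).
#'   The default uses a gentler area/edge stiffness than the inflation
#'   protocol (10 vs 100): the sheet still unfolds near-isometrically,
#'   while the explicit descent can take usefully large time steps.
#' @param settings [solver_settings()]; `pin_boundary = TRUE` holds the
#'   boundary frame fixed (default free).
#' @return an `unfold_run` (see [run_inflation()]).
#' @export
run_patch_flatten <- function(mesh,
                              params = elastic_parameters(k_volume = 0,
                                                          k_area = 10,
                                                          k_edge = 10),
                              settings = solver_settings(method = "bb")) {
  stopifnot_mesh(mesh)
  topology <- build_topology(mesh)
  if (!any(topology$boundary)) {
    stop("protocol error: patch flattening requires an open mesh")
  }
  params$k_volume <- 0
  ref <- capture_reference(mesh, include_volume = FALSE,
                           topology = topology, rest_angle = pi)
  free_mask <- NULL
  if (settings$pin_boundary) {
    free_mask <- rep(TRUE, nrow(mesh$vertices))
    bverts <- unique(as.vector(
      topology$edges[topology$boundary, , drop = FALSE]))
    free_mask[bverts] <- FALSE
  }
  relax_loop(mesh, topology, ref, params, settings, free_mask = free_mask)
}
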