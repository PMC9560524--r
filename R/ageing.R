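#' Damage-accumulation parameters
#'
#' Protein damage accumulates from a metabolic source proportional to the
#' unneutralised ROS flux (rate `f_m`), a non-metabolic baseline (`f0`), and
#' is repaired at first order (`r0`).  Damage feeds back on the metabolism
#' by shrinking the functional enzyme pool and raising the non-growth
#' associated maintenance (NGAM) demand, and is segregated asymmetrically at
#' division.
#'
#' @param f_m metabolic damage formation per unit ROS flux (gDW/mmol).
#' @param f0 non-metabolic damage formation rate (1/h); reference 0.0001.
#' @param r0 damage repair rate (1/h); reference 0.0005.
#' @param retention fraction of the damage mass kept by the mother at
#'   division (0-1).
#' @param division_biomass biomass units required per division.
#' @param ngam0 baseline NGAM flux (mmol ATP/gDW/h).
#' @param ngam_slope NGAM increase per unit damaged fraction.
#' @param dt integrator step in h (forward Euler).
#' @return An `agefba_damage_parameters`.
#' @export
damage_parameters <- function(f_m = 0, f0 = 1e-4, r0 = 5e-4, retention = 0.5,
                              division_biomass = 1, ngam0 = 1,
                              ngam_slope = 0, dt = 0.01) {
  stopifnot(f_m >= 0, f0 >= 0, r0 >= 0, retention >= 0, retention <= 1,
            division_biomass > 0, ngam0 >= 0, ngam_slope >= 0, dt > 0)
  structure(list(f_m = f_m, f0 = f0, r0 = r0, retention = retention,
                 division_biomass = division_biomass, ngam0 = ngam0,
                 ngam_slope = ngam_slope, dt = dt),
            class = "agefba_damage_parameters")
}

#' Fresh cell state
#'
#' @param intact initial functional protein fraction (default 1).
#' @return An `agefba_cell_state` with fields `intact`, `damaged`,
#'   `biomass_progress`, `divisions`, `t`, `division_times`.
#' @export
cell_state <- function(intact = 1) {
  stopifnot(intact >= 0, intact <= 1)
  structure(list(intact = intact, damaged = 1 - intact,
                 biomass_progress = 0, divisions = 0L, t = 0,
                 division_times = numeric(0)),
            class = "agefba_cell_state")
}

#' Unneutralised ROS flux of a solution
#'
#' Stoichiometry-weighted ROS production over the `ros_producing` set minus
#' ROS consumption by the `antioxidant` set, floored at zero.  At steady
#' state this equals the flux of spontaneous (enzyme-free) ROS decay, i.e.
#' the ROS that escapes the antioxidant system and attacks proteins.
#'
#' @param model an `agefba_model`.
#' @param solution an optimal `agefba_flux_solution`.
#' @return ROS damage flux in mmol/gDW/h.
#' @export
ros_damage_flux <- function(model, solution) {
  S <- stoich_matrix(model)
  if (!"ROS" %in% rownames(S)) return(0)
  prod <- sum(vapply(model$reaction_sets$ros_producing %||% character(0),
                     function(id) max(S["ROS", id], 0) * solution$v[[id]], 0))
  neut <- sum(vapply(model$reaction_sets$antioxidant %||% character(0),
                     function(id) max(-S["ROS", id], 0) * solution$v[[id]], 0))
  max(prod - neut, 0)
}

#' One forward-Euler step of the damage/growth dynamics
#'
#' Integrates `dD/dt = f_m J_ROS P + f0 P - r0 D` and `dP/dt = -dD/dt` for
#' one step of size `dt`, accumulates biomass progress from the growth flux,
#' and advances the cell's age.  Fractions are clamped to `[0, 1]`.
#'
#' @param state an `agefba_cell_state`.
#' @param solution the step's optimal `agefba_flux_solution`.
#' @param params an [damage_parameters()].
#' @param dt step size in h (defaults to `params$dt`).
#' @param model the model (for the ROS bookkeeping sets).
#' @return The advanced state.
#' @export
damage_step <- function(state, solution, params, dt = params$dt,
                        model = NULL) {
  if (dt <= 0) stop("dt must be positive")
  J <- if (is.null(model)) 0 else ros_damage_flux(model, solution)
  dD <- (params$f_m * J * state$intact + params$f0 * state$intact -
           params$r0 * state$damaged) * dt
  D <- min(max(state$damaged + dD, 0), 1)
  state$damaged <- D
  state$intact <- 1 - D
  growth <- solution$v[[model_growth_id(model, solution)]]
  state$biomass_progress <- state$biomass_progress + growth * dt
  state$t <- state$t + dt
  state
}

model_growth_id <- function(model, solution) {
  if (!is.null(model)) {
    id <- model$named_reactions$biomass
    if (!is.null(id)) return(id)
  }
  names(solution$v)[1]
}

#' Division with asymmetric damage segregation
#'
#' When accumulated biomass reaches the division threshold the division
#' count and time are recorded and the threshold is subtracted.  The damage
#' mass is split so the mother retains fraction `retention` while the intact
#' protein splits evenly; the mother's fractions are then renormalised:
#' `D' = retention * D / (retention * D + (1 - D) / 2)`.  `retention = 0.5`
#' leaves the damaged fraction unchanged.
#'
#' @param state an `agefba_cell_state`.
#' @param params an [damage_parameters()].
#' @return The (possibly divided) state.
#' @export
maybe_divide <- function(state, params) {
  while (state$biomass_progress >= params$division_biomass) {
    state$biomass_progress <- state$biomass_progress - params$division_biomass
    state$divisions <- state$divisions + 1L
    state$division_times <- c(state$division_times, state$t)
    dm <- params$retention * state$damaged
    ip <- state$intact / 2
    tot <- dm + ip
    if (tot > 0) {
      state$damaged <- dm / tot
      state$intact <- ip / tot
    }
  }
  state
}

#' Damage-dependent NGAM lower bound
#'
#' @param state an `agefba_cell_state`.
#' @param params an [damage_parameters()].
#' @return `ngam0 + ngam_slope * D`, installed as the NGAM reaction's lower
#'   bound before each optimisation.
#' @export
ngam_bound <- function(state, params) {
  params$ngam0 + params$ngam_slope * state$damaged
}

#' Damage-scaled enzyme pool bound
#'
#' @param state an `agefba_cell_state`.
#' @param model an `agefba_model`.
#' @return `sigma * f * P_tot * intact`, replacing the pool upper bound for
#'   the current time step.
#' @export
effective_pool <- function(state, model) {
  enzyme_pool(model) * state$intact
}

# Install the damage-adjusted bounds of a cell state into a prebuilt LP.
apply_state_bounds <- function(problem, model, state, params) {
  problem <- lp_set_bounds(problem, ".pool", upper = effective_pool(state, model))
  ngam_id <- model$named_reactions$ngam
  if (!is.null(ngam_id)) {
    # a demand above the reaction's upper bound is an infeasible (empty) box,
    # which is exactly the death-by-maintenance signal
    problem <- lp_set_bounds(problem, ngam_id, lower = ngam_bound(state, params))
  }
  problem
}

#' Death by infeasibility
#'
#' A cell is dead when the stage-1 LP with the current damage-adjusted
#' bounds (shrunken pool, raised NGAM) has no feasible flux distribution.
#'
#' @param model an `agefba_model`.
#' @param state an `agefba_cell_state`.
#' @param strategy an [optimization_strategy()] (its first objective defines
#'   the stage-1 LP).
#' @param params an [damage_parameters()].
#' @param problem optional prebuilt `agefba_lp`.
#' @return `TRUE` iff the LP is infeasible.
#' @export
is_dead <- function(model, state, strategy, params, problem = NULL) {
  if (is.null(problem)) problem <- build_lp(model)
  problem <- apply_state_bounds(problem, model, state, params)
  obj <- make_objective(model, strategy$first)
  s <- solve_lp(problem, obj)
  s$status == "infeasible"
}
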