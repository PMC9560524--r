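#' Simulate the replicative lifespan of a single cell
#'
#' Runs the multi-scale loop: lexicographic (optionally parsimonious)
#' optimisation of the enzyme-constrained FBA model with damage-adjusted
#' bounds, a Boolean regulation step tightening enzyme bounds followed by an
#' epsilon2-relaxed re-optimisation, forward-Euler integration of the damage
#' and growth dynamics, division bookkeeping with asymmetric damage
#' segregation, and death when the stage-1 LP becomes infeasible.
#'
#' @param model an `agefba_model` in irreversible form.
#' @param strategy an [optimization_strategy()].
#' @param ageing an [damage_parameters()].
#' @param regulation an [regulation_config()], or `NULL` to disable the
#'   regulation layer.
#' @param max_time simulation horizon in h (non-termination guard; results
#'   hitting it carry `truncated = TRUE`).
#' @param record keep the full trajectory (default `TRUE`).
#' @param verbose emit a message per LP failure, division and death event.
#' @return An `agefba_lifespan` with fields `rls`, `generation_times`,
#'   `mean_generation_time`, `division_times`, `death_time`,
#'   `phase_boundary`, `divisions_per_phase`, `damage_at_phase_end`,
#'   `truncated` and (when recorded) `trajectory`: one row per time step
#'   with `t`, `growth`, `D`, `intact`, `ros_flux` and every reaction flux.
#' @export
simulate_lifespan <- function(model, strategy, ageing,
                              regulation = regulation_config(),
                              max_time = 200, record = TRUE,
                              verbose = FALSE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  problem0 <- build_lp(model)
  labels <- unique(c(strategy$first, strategy$second))
  objectives <- setNames(lapply(labels, make_objective, model = model), labels)
  obj1 <- objectives[[strategy$first]]
  obj2 <- if (!is.null(strategy$second)) objectives[[strategy$second]]
  ctx <- step_context(model)
  state <- cell_state()
  reg_state <- regulation_state()
  prev_sol <- NULL
  rows <- list()
  step <- 0L
  truncated <- FALSE
  death_time <- NA_real_
  repeat {
    if (state$t >= max_time) {
      truncated <- TRUE
      death_time <- state$t
      break
    }
    prob <- apply_state_bounds(problem0, model, state, ageing)
    sol <- lexicographic_solve(model, strategy, prob, objectives)
    if (sol$status != "optimal") {
      death_time <- state$t
      log_msg("t=%.2f h: stage-1 LP %s -> death (D = %.4f)", state$t,
              sol$status, state$damaged)
      break
    }
    if (!is.null(regulation)) {
      inputs <- ctx$inputs(sol$v, regulation$thresholds)
      reg_state <- update_state(reg_state, inputs, regulation)
      # anchoring at the previous step's final (regulated) solution lets a
      # sustained transcriptional response compound over time
      bounds <- constrain_enzymes(model, reg_state, regulation,
                                  prev_sol %||% sol)
      if (nrow(bounds) > 0) {
        sol2 <- resolve_regulated(prob, model, strategy, sol, bounds,
                                  obj1, obj2)
        if (is.null(sol2)) {
          log_msg("t=%.2f h: regulated re-solve infeasible, keeping the unregulated solution",
                  state$t)
        } else {
          sol <- sol2
        }
      }
    }
    prev_sol <- sol
    growth <- unname(sol$v[[ctx$biomass_id]])
    ros <- ctx$ros_flux(sol$v)
    if (record) {
      step <- step + 1L
      rows[[step]] <- c(t = state$t, growth = growth,
                        D = state$damaged, intact = state$intact,
                        ros_flux = ros, sol$v)
    }
    state <- damage_step_fast(state, growth, ros, ageing)
    n_before <- state$divisions
    state <- maybe_divide(state, ageing)
    if (state$divisions > n_before) {
      log_msg("t=%.2f h: division %d (D = %.4f)", state$t, state$divisions,
              state$damaged)
    }
  }
  trajectory <- if (record && length(rows) > 0) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  gen <- diff(c(0, state$division_times))
  res <- structure(
    list(rls = state$divisions, generation_times = gen,
         mean_generation_time = if (length(gen) > 0) mean(gen) else NA_real_,
         division_times = state$division_times, death_time = death_time,
         final_damage = state$damaged, truncated = truncated,
         trajectory = trajectory),
    class = "agefba_lifespan")
  if (!is.null(trajectory)) {
    ph <- detect_phases(trajectory)
    res$phase_boundary <- ph$boundary
    res$phase2_empty <- ph$phase2_empty
    res$divisions_per_phase <- c(
      phase1 = sum(state$division_times <= ph$boundary),
      phase2 = sum(state$division_times > ph$boundary))
    d_end1 <- trajectory$D[max(which(trajectory$t <= ph$boundary))]
    res$damage_at_phase_end <- c(phase1 = d_end1, phase2 = state$damaged)
  }
  res
}

# Precomputed per-model quantities for the inner loop: stoichiometric
# weights for ATP/ROS production, the respiratory-ATP mask, and antioxidant
# consumption weights.  Mirrors derive_inputs()/ros_damage_flux() without
# rebuilding the stoichiometric matrix at every time step.
step_context <- function(model) {
  S <- stoich_matrix(model)
  pick <- function(species, ids, produce = TRUE) {
    if (length(ids) == 0 || !species %in% rownames(S)) {
      return(setNames(numeric(0), character(0)))
    }
    w <- if (produce) pmax(S[species, ids], 0) else pmax(-S[species, ids], 0)
    setNames(as.numeric(w), ids)
  }
  atp_w <- pick("ATP", model$reaction_sets$atp_producing %||% character(0))
  pathways <- vapply(model$reactions[names(atp_w)], `[[`, "", "pathway")
  resp <- pathways %in% c("oxidative phosphorylation", "TCA")
  ros_w <- pick("ROS", model$reaction_sets$ros_producing %||% character(0))
  anti_w <- pick("ROS", model$reaction_sets$antioxidant %||% character(0),
                 produce = FALSE)
  uptake_id <- model$named_reactions$glucose_uptake
  list(
    biomass_id = model$named_reactions$biomass,
    inputs = function(v, thresholds) {
      atp <- atp_w * v[names(atp_w)]
      tot <- sum(atp)
      share <- if (tot > 0) sum(atp[resp]) / tot else 0
      list(glucose_high = unname(v[uptake_id]) > thresholds$glucose,
           respiring = share > thresholds$respiring_share,
           ros_high = sum(ros_w * v[names(ros_w)]) > thresholds$ros)
    },
    ros_flux = function(v) {
      max(sum(ros_w * v[names(ros_w)]) - sum(anti_w * v[names(anti_w)]), 0)
    })
}

# damage_step() with precomputed growth and ROS fluxes.
damage_step_fast <- function(state, growth, ros, params) {
  dD <- (params$f_m * ros * state$intact + params$f0 * state$intact -
           params$r0 * state$damaged) * params$dt
  D <- min(max(state$damaged + dD, 0), 1)
  state$damaged <- D
  state$intact <- 1 - D
  state$biomass_progress <- state$biomass_progress + growth * params$dt
  state$t <- state$t + params$dt
  state
}

# epsilon2-relaxed re-optimisation after the regulation step: the stage-1
# lock keeps epsilon1 (composed with epsilon2 when it is the final stage),
# the stage-2 lock is relaxed from solver precision to epsilon2, and the
# final objective (parsimony when enabled) is re-optimised under the
# regulated enzyme bounds.  Returns NULL when the regulated problem is
# infeasible, in which case the caller keeps the unregulated solution.
resolve_regulated <- function(prob, model, strategy, sol, bounds, obj1,
                              obj2) {
  prob <- lp_set_bounds(prob, paste0(".e.", bounds$enzyme),
                        lower = bounds$lower, upper = bounds$upper)
  z1 <- sol$stage_values[1]
  if (is.null(strategy$second)) {
    eps1 <- 1 - (1 - strategy$epsilon1) * (1 - strategy$epsilon2)
    locked <- lock_stage(prob, obj1, z1, eps1)
    final_obj <- obj1
  } else {
    locked <- lock_stage(prob, obj1, z1, strategy$epsilon1)
    z2 <- sol$stage_values[2]
    locked <- lock_stage(locked, obj2, z2, strategy$epsilon2)
    final_obj <- obj2
  }
  s <- if (strategy$parsimonious) {
    parsimonious_solve(locked, model)
  } else {
    solve_lp(locked, final_obj)
  }
  if (s$status != "optimal") return(NULL)
  s$stage_values <- sol$stage_values
  s
}

#' @export
print.agefba_lifespan <- function(x, ...) {
  cat(sprintf("<agefba_lifespan> rls = %d, mean generation time = %.3g h, death at %.3g h%s\n",
              x$rls, x$mean_generation_time, x$death_time,
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

#' Detect the metabolic phase boundary of a trajectory
#'
#' Phase I is the early maximal-growth (fermentation-dominated) phase; phase
#' II starts when the growth flux first falls below `(1 - delta)` of its
#' initial plateau, defined as the mean growth flux over the first
#' `plateau_frac` of the lifetime.
#'
#' @param trajectory data frame with columns `t` and `growth`.
#' @param delta relative drop defining the phase switch (default 0.05).
#' @param plateau_frac fraction of the lifetime averaged for the plateau
#'   (default 0.05).
#' @return List with `boundary` (time in h) and `phase2_empty` (`TRUE` when
#'   growth never drops, in which case the boundary is the death time).
#' @export
detect_phases <- function(trajectory, delta = 0.05, plateau_frac = 0.05) {
  stopifnot(nrow(trajectory) > 0)
  t_end <- trajectory$t[nrow(trajectory)]
  sel <- trajectory$t <= plateau_frac * t_end
  if (!any(sel)) sel[1] <- TRUE
  plateau <- mean(trajectory$growth[sel])
  below <- which(trajectory$growth < (1 - delta) * plateau)
  if (length(below) == 0) {
    list(boundary = t_end, phase2_empty = TRUE)
  } else {
    list(boundary = trajectory$t[below[1]], phase2_empty = FALSE)
  }
}

#' Wildtype classification
#'
#' A simulated cell counts as wildtype when it divides between 20 and 30
#' times with a mean generation time between 1.5 and 2.3 h (inclusive).
#'
#' @param result an `agefba_lifespan` (or any list with `rls` and
#'   `mean_generation_time`).
#' @return Logical.
#' @export
classify_wildtype <- function(result) {
  rls <- result$rls
  gt <- result$mean_generation_time
  !is.na(gt) && rls >= 20 && rls <= 30 && gt >= 1.5 && gt <= 2.3
}

#' Objective/flexibility sweep of lifespan simulations
#'
#' Simulates every combination of objective pair, `epsilon1`, `epsilon2` and
#' parsimony flag, and tabulates replicative lifespan, mean generation time
#' and the wildtype classification.  Deterministic given the model and
#' configurations; failures of individual runs are recorded in `status` and
#' the sweep continues.
#'
#' @param model an `agefba_model`.
#' @param objective_pairs list of one- or two-element character vectors
#'   (first objective, optional second).
#' @param epsilon1,epsilon2 numeric grids (defaults `seq(0, 0.5, 0.05)`).
#' @param parsimony_options logical vector (default `c(FALSE, TRUE)`).
#' @param ageing an [damage_parameters()].
#' @param regulation an [regulation_config()] or `NULL`.
#' @param max_time simulation horizon per run.
#' @return Data frame with columns `first`, `second`, `epsilon1`,
#'   `epsilon2`, `parsimonious`, `rls`, `mean_generation_time`, `wildtype`,
#'   `status`.
#' @export
run_sweep <- function(model, objective_pairs, epsilon1 = seq(0, 0.5, 0.05),
                      epsilon2 = seq(0, 0.5, 0.05),
                      parsimony_options = c(FALSE, TRUE), ageing,
                      regulation = regulation_config(), max_time = 200) {
  grid <- expand.grid(pair = seq_along(objective_pairs), e1 = epsilon1,
                      e2 = epsilon2, pars = parsimony_options,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    pair <- objective_pairs[[grid$pair[i]]]
    second <- if (length(pair) > 1) pair[2] else NA_character_
    rec <- data.frame(first = pair[1], second = second,
                      epsilon1 = grid$e1[i], epsilon2 = grid$e2[i],
                      parsimonious = grid$pars[i], rls = NA_integer_,
                      mean_generation_time = NA_real_, wildtype = FALSE,
                      status = "ok", stringsAsFactors = FALSE)
    strategy <- optimization_strategy(
      first = pair[1], second = if (!is.na(second)) second,
      epsilon1 = grid$e1[i], epsilon2 = grid$e2[i],
      parsimonious = grid$pars[i])
    res <- tryCatch(
      simulate_lifespan(model, strategy, ageing, regulation,
                        max_time = max_time, record = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) {
      rec$status <- paste("error:", conditionMessage(res))
    } else {
      rec$rls <- res$rls
      rec$mean_generation_time <- res$mean_generation_time
      rec$wildtype <- classify_wildtype(res)
      if (isTRUE(res$truncated)) rec$status <- "truncated"
    }
    rec
  })
  do.call(rbind, out)
}
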