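#' Objective library
#'
#' Builds the coefficient vector of a named objective from the model's
#' `named_reactions` roles and `reaction_sets`:
#'
#' * `max_growth` / `min_glucose_uptake` / `max_ngam` - single named
#'   reaction flux (roles `biomass`, `glucose_uptake`, `ngam`);
#' * `max_atp_production` / `min_atp_production` - stoichiometry-weighted
#'   sum over the `atp_producing` set;
#' * `min_nadh_production` - weighted sum over the `nadh_producing` set.
#'
#' Production sums are stoichiometry-weighted by default so that the
#' objective is a true production rate; `weighted = FALSE` switches to an
#' unweighted flux sum for sensitivity checks.
#'
#' @param model an `agefba_model` in irreversible form.
#' @param label objective label (see above).
#' @param weighted weight set objectives by stoichiometric coefficients.
#' @return An `agefba_objective` with fields `label`, `direction`,
#'   `coefficients`.
#' @export
make_objective <- function(model, label, weighted = TRUE) {
  labels <- c("max_growth", "min_glucose_uptake", "max_atp_production",
              "min_atp_production", "min_nadh_production", "max_ngam")
  label <- match.arg(label, labels)
  direction <- if (startsWith(label, "max")) "max" else "min"
  need_role <- function(role) {
    id <- model$named_reactions[[role]]
    if (is.null(id)) stop("model lacks named reaction role '", role, "'")
    id
  }
  set_coefficients <- function(set, species) {
    ids <- model$reaction_sets[[set]]
    if (is.null(ids)) stop("model lacks reaction set '", set, "'")
    S <- stoich_matrix(model)
    w <- vapply(ids, function(id) max(S[species, id], 0), 0)
    if (!weighted) w[] <- as.numeric(w > 0)
    w[w > 0]
  }
  coefficients <- switch(
    label,
    max_growth = setNames(1, need_role("biomass")),
    min_glucose_uptake = setNames(1, need_role("glucose_uptake")),
    max_ngam = setNames(1, need_role("ngam")),
    max_atp_production = set_coefficients("atp_producing", "ATP"),
    min_atp_production = set_coefficients("atp_producing", "ATP"),
    min_nadh_production = set_coefficients("nadh_producing", "NADH_c")
  )
  if (length(coefficients) == 0) stop("objective '", label, "' has no coefficients")
  structure(list(label = label, direction = direction,
                 coefficients = coefficients),
            class = "agefba_objective")
}

#' Optimisation strategy
#'
#' An ordered pair of objectives with flexibilities and a parsimony flag.
#' `epsilon1` relaxes the locked first-stage optimum for the second stage
#' (and for parsimony); `epsilon2` relaxes the final stage's optimum for the
#' regulation re-optimisation inside the lifespan loop.
#'
#' @param first,second objective labels (see [make_objective()]); `second`
#'   may be `NULL`.
#' @param epsilon1,epsilon2 fractional flexibilities in `[0, 1]`.
#' @param parsimonious run the parsimonious post-optimisation.
#' @return An `agefba_strategy`.
#' @export
optimization_strategy <- function(first, second = NULL, epsilon1 = 0,
                                  epsilon2 = 0, parsimonious = FALSE) {
  stopifnot(epsilon1 >= 0, epsilon1 <= 1, epsilon2 >= 0, epsilon2 <= 1)
  if (!is.null(second) && (is.na(second) || identical(second, "none"))) {
    second <- NULL
  }
  structure(list(first = first, second = second, epsilon1 = epsilon1,
                 epsilon2 = epsilon2, parsimonious = isTRUE(parsimonious)),
            class = "agefba_strategy")
}

#' Lock an achieved stage optimum into the problem
#'
#' Appends the flexibility constraint of the lexicographic method:
#' `c'v >= z (1 - epsilon)` if the stage was maximised, `c'v <= z (1 +
#' epsilon)` if it was minimised.  With a negative `z` the multiplicative
#' relaxation inverts direction; a warning is emitted.
#'
#' @param problem an `agefba_lp`.
#' @param objective the stage objective.
#' @param z the achieved stage optimum.
#' @param epsilon fractional flexibility in `[0, 1]`.
#' @return The problem with the locked constraint appended.
#' @export
lock_stage <- function(problem, objective, z, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (z < -1e-6) {
    warning("locking a negative stage value: the multiplicative relaxation ",
            "inverts direction")
  }
  if (objective$direction == "max") {
    lp_add_constraint(problem, objective$coefficients, ">=", z * (1 - epsilon),
                      name = paste0("lock:", objective$label))
  } else {
    lp_add_constraint(problem, objective$coefficients, "<=", z * (1 + epsilon),
                      name = paste0("lock:", objective$label))
  }
}

parsimony_coefficients <- function(problem, weight_by_MW = FALSE,
                                   enzyme_MW = NULL) {
  ids <- problem$var_id[problem$var_kind %in% c("v", "e")]
  w <- setNames(rep(1, length(ids)), ids)
  if (weight_by_MW && !is.null(enzyme_MW)) {
    eids <- problem$var_id[problem$var_kind == "e"]
    w[eids] <- enzyme_MW[sub("^\\.e\\.", "", eids)]
  }
  w
}

#' Parsimonious post-optimisation
#'
#' Minimises the sum of all fluxes plus the sum of all enzyme usages over a
#' problem whose stages have already been locked.  In irreversible form all
#' fluxes are nonnegative, so the sum is the L1 norm of `(v, e)`.  Fluxes
#' and usages carry unit weight by default; `weight_by_MW` weights each
#' enzyme by its molecular weight as a sensitivity variant.
#'
#' @param problem an `agefba_lp` with locked stage constraints.
#' @param model optionally, the model (needed for `weight_by_MW`).
#' @param weight_by_MW weight enzyme usages by MW (default `FALSE`).
#' @return An `agefba_flux_solution`; `stage_values[1]` is the attained
#'   parsimony value.
#' @export
parsimonious_solve <- function(problem, model = NULL, weight_by_MW = FALSE) {
  MW <- if (!is.null(model)) {
    vapply(model$enzymes, `[[`, 0, "MW")
  }
  w <- parsimony_coefficients(problem, weight_by_MW, MW)
  res <- lp_optimize(problem, w, maximize = FALSE)
  new_flux_solution(problem, res, stage_values = res$objective)
}

#' Lexicographic two-stage optimisation with parsimony
#'
#' Solves the first objective over the enzyme-constrained polytope, locks
#' its optimum with flexibility `epsilon1`, solves the second objective if
#' present, and - if `parsimonious` - locks the final stage at solver
#' precision (the second stage when present, otherwise the `epsilon1` lock
#' stands alone) and minimises the sum of fluxes and enzyme usages.
#'
#' @param model an `agefba_model` in irreversible form.
#' @param strategy an [optimization_strategy()].
#' @param problem optionally a prebuilt/adjusted `agefba_lp` for `model`
#'   (the lifespan loop passes one with damage-adjusted bounds).
#' @param objectives optionally a prebuilt list of objectives keyed by label.
#' @return An `agefba_flux_solution` whose `stage_values` holds `z1`, then
#'   `z2` when a second stage ran, then the parsimony value when computed.
#'   Stage-1 infeasibility is propagated as `status = "infeasible"` (the
#'   lifespan loop's death signal).
#' @export
lexicographic_solve <- function(model, strategy, problem = NULL,
                                objectives = NULL) {
  stopifnot(inherits(strategy, "agefba_strategy"))
  if (is.null(problem)) problem <- build_lp(model)
  get_obj <- function(label) {
    if (!is.null(objectives) && !is.null(objectives[[label]])) {
      objectives[[label]]
    } else {
      make_objective(model, label)
    }
  }
  obj1 <- get_obj(strategy$first)
  s1 <- solve_lp(problem, obj1)
  if (s1$status != "optimal") return(s1)
  z1 <- s1$stage_values[1]
  stage_values <- z1
  locked <- lock_stage(problem, obj1, z1, strategy$epsilon1)
  final <- s1
  if (!is.null(strategy$second)) {
    obj2 <- get_obj(strategy$second)
    s2 <- solve_lp(locked, obj2)
    if (s2$status != "optimal") {
      stop("internal error: stage 2 infeasible after a valid stage-1 lock")
    }
    z2 <- s2$stage_values[1]
    stage_values <- c(stage_values, z2)
    locked <- lock_stage(locked, obj2, z2, AGEFBA_TOL)
    final <- s2
  }
  if (strategy$parsimonious) {
    sp <- parsimonious_solve(locked, model)
    if (sp$status != "optimal") {
      stop("internal error: parsimonious stage infeasible after locking")
    }
    stage_values <- c(stage_values, sp$stage_values[1])
    final <- sp
  }
  final$stage_values <- stage_values
  final$locked_problem <- locked
  final
}
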