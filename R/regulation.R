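#' Boolean regulation layer
#'
#' A simplified, pluggable stand-in for the nutrient- and stress-signalling
#' network (Snf1, PKA, TOR, Yap1, Sln1) that sits between the metabolic
#' optimisation and the final re-optimisation of every simulation step.
#' Optimal fluxes are discretised into Boolean inputs, the five pathways are
#' updated synchronously from a rule table, and active pathways tighten the
#' usage bounds of their target enzymes by a multiplicative regulation
#' factor.  The default rule content is a minimal glucose/stress wiring
#' (glucose activates PKA/TOR and silences Snf1; reactive oxygen species
#' activate Yap1, which induces antioxidant enzymes; respiratory activity
#' flips Sln1); arbitrary rule tables can be loaded from configuration so a
#' published wiring can be dropped in unchanged.
#'
#' @name regulation
NULL

REGULATION_PATHWAYS <- c("Snf1", "PKA", "TOR", "Yap1", "Sln1")

default_regulation_rules <- function() {
  list(Snf1 = "!glucose_high",
       PKA  = "glucose_high",
       TOR  = "glucose_high",
       Yap1 = "ros_high",
       Sln1 = "respiring")
}

default_regulation_targets <- function() {
  # pathway -> list of (enzyme id, direction); defaults name the enzymes of
  # the generated reference network and are simply inert on models that lack
  # them.  Only the stress-response (Yap1 -> antioxidants) and glucose
  # derepression (Snf1 -> respiratory chain) arms carry transcriptional
  # targets in the default toy wiring; PKA/TOR/Sln1 are wired but
  # targetless.
  list(Yap1 = list(list(enzyme = "CTT1", direction = "up"),
                   list(enzyme = "GPX1", direction = "up")),
       Snf1 = list(list(enzyme = "CPLX1", direction = "up")))
}

#' Regulation configuration
#'
#' @param regulation_factor fractional tightening of targeted enzyme bounds
#'   (default 0.04, the reference value).
#' @param rules named list mapping each of the five pathways to a Boolean
#'   expression (as a string) over the input names `glucose_high`,
#'   `respiring`, `ros_high`.
#' @param targets named list mapping pathways to lists of
#'   `list(enzyme=, direction=)` with direction `"up"` or `"down"`.
#' @param thresholds named list with elements `glucose` (uptake flux),
#'   `respiring_share` (respiratory share of ATP production) and `ros`
#'   (ROS production flux).  Comparisons are strict (`>`).
#' @param bootstrap minimal expression anchor (mmol/gDW) from which an
#'   up-regulated enzyme compounds even when its current usage is zero;
#'   transcriptional induction cannot act multiplicatively on a silent
#'   gene without it.
#' @return An `agefba_regulation_config`.
#' @export
regulation_config <- function(regulation_factor = 0.04,
                              rules = default_regulation_rules(),
                              targets = default_regulation_targets(),
                              thresholds = list(glucose = 0.5,
                                                respiring_share = 0.2,
                                                ros = 0.05),
                              bootstrap = 1e-5) {
  stopifnot(regulation_factor >= 0, regulation_factor <= 1, bootstrap >= 0)
  missing <- setdiff(REGULATION_PATHWAYS, names(rules))
  if (length(missing) > 0) {
    stop("rules missing for pathway(s): ", paste(missing, collapse = ", "))
  }
  structure(list(regulation_factor = regulation_factor, rules = rules,
                 targets = targets, thresholds = thresholds,
                 bootstrap = bootstrap),
            class = "agefba_regulation_config")
}

#' Fresh regulation state (all pathways inactive)
#'
#' @return An `agefba_regulation_state` with `pathway_activity` and `inputs`.
#' @export
regulation_state <- function() {
  structure(list(
    pathway_activity = setNames(rep(FALSE, 5), REGULATION_PATHWAYS),
    inputs = list()), class = "agefba_regulation_state")
}

#' Derive Boolean inputs from an optimal flux distribution
#'
#' `glucose_high`: glucose uptake above threshold; `respiring`: respiratory
#' share of total (stoichiometry-weighted) ATP production above threshold,
#' where respiratory means reactions of the `atp_producing` set labelled
#' `"oxidative phosphorylation"` or `"TCA"`; `ros_high`: total ROS
#' production above threshold.  All comparisons are strict.
#'
#' @param model an `agefba_model`.
#' @param solution an optimal `agefba_flux_solution`.
#' @param thresholds threshold list, see [regulation_config()].
#' @return Named list of three logicals.
#' @export
derive_inputs <- function(model, solution,
                          thresholds = regulation_config()$thresholds) {
  if (solution$status != "optimal") stop("solution must be optimal")
  for (set in c("atp_producing", "ros_producing")) {
    if (is.null(model$reaction_sets[[set]])) {
      stop("model lacks reaction set '", set, "'")
    }
  }
  uptake <- solution$v[[model$named_reactions$glucose_uptake]]
  S <- stoich_matrix(model)
  weight <- function(species, id) {
    if (!species %in% rownames(S)) return(0)
    max(S[species, id], 0)
  }
  atp_ids <- model$reaction_sets$atp_producing
  atp_by_rxn <- vapply(atp_ids, function(id) {
    weight("ATP", id) * solution$v[[id]]
  }, 0)
  total_atp <- sum(atp_by_rxn)
  pathways <- vapply(model$reactions[atp_ids], `[[`, "", "pathway")
  resp <- pathways %in% c("oxidative phosphorylation", "TCA")
  share <- if (total_atp > 0) sum(atp_by_rxn[resp]) / total_atp else 0
  ros_prod <- sum(vapply(model$reaction_sets$ros_producing, function(id) {
    weight("ROS", id) * solution$v[[id]]
  }, 0))
  if (length(atp_ids) == 0) share <- 0
  list(glucose_high = uptake > thresholds$glucose,
       respiring = share > thresholds$respiring_share,
       ros_high = ros_prod > thresholds$ros)
}

#' Synchronous Boolean update of the pathway activities
#'
#' @param state an `agefba_regulation_state`.
#' @param inputs named list of Boolean inputs from [derive_inputs()].
#' @param config an [regulation_config()].
#' @return The updated state (deterministic; rules are evaluated against
#'   the inputs only, so the update is idempotent for constant inputs).
#' @export
update_state <- function(state, inputs, config) {
  env <- list2env(lapply(inputs, isTRUE), parent = baseenv())
  activity <- vapply(REGULATION_PATHWAYS, function(p) {
    rule <- config$rules[[p]]
    if (is.null(rule)) stop("undefined rule for pathway '", p, "'")
    val <- try(eval(parse(text = rule), envir = env), silent = TRUE)
    if (inherits(val, "try-error") || !is.logical(val) || is.na(val)) {
      stop("rule for pathway '", p, "' did not evaluate to TRUE/FALSE: ", rule)
    }
    val
  }, logical(1))
  state$pathway_activity <- activity
  state$inputs <- inputs
  state
}

#' Enzyme-usage bounds imposed by the active pathways
#'
#' For every `(enzyme, direction)` target of an active pathway, with current
#' optimal usage `e*`: direction `"down"` sets `e_max = e* (1 - factor)`;
#' direction `"up"` sets `e_min = max(e*, bootstrap) (1 + factor)`, capped
#' at the pool-feasible level `pool / MW` (the bootstrap anchor lets
#' induction start from a silent gene).  Conflicting bounds are clamped to
#' `e_min = e_max` with a warning.  Untargeted enzymes are unchanged.
#' Anchoring at the final solution of the previous time step (as the
#' lifespan loop does) makes sustained activation compound across steps,
#' emulating a transcriptional response that builds up over time.
#'
#' @param model an `agefba_model`.
#' @param state an updated `agefba_regulation_state`.
#' @param config an [regulation_config()].
#' @param solution the solution whose usages `e*` anchor the bounds.
#' @return Data frame with columns `enzyme`, `lower`, `upper` (one row per
#'   affected enzyme); zero rows when no pathway is active or the factor is
#'   zero.
#' @export
constrain_enzymes <- function(model, state, config, solution) {
  factor <- config$regulation_factor
  active <- names(state$pathway_activity)[state$pathway_activity]
  out <- list()
  if (factor == 0 || length(active) == 0) {
    return(data.frame(enzyme = character(0), lower = numeric(0),
                      upper = numeric(0), stringsAsFactors = FALSE))
  }
  pool <- enzyme_pool(model)
  lower <- upper <- list()
  for (p in active) {
    for (tg in config$targets[[p]] %||% list()) {
      id <- tg$enzyme
      if (!id %in% names(model$enzymes)) next
      e_star <- solution$e[[id]]
      if (is.null(e_star) || is.na(e_star)) next
      if (tg$direction == "up") {
        en <- model$enzymes[[id]]
        # feasible ceiling: the whole pool, or the usage at which every
        # catalysed reaction saturates its flux upper bound
        flux_cap <- sum(en$n / en$kcat *
                          vapply(model$reactions[names(en$kcat)], `[[`, 0,
                                 "upper_bound"))
        cap <- min(pool / en$MW, flux_cap)
        val <- min(max(e_star, config$bootstrap %||% 0) * (1 + factor), cap)
        lower[[id]] <- max(lower[[id]] %||% 0, val)
      } else {
        upper[[id]] <- min(upper[[id]] %||% Inf, e_star * (1 - factor))
      }
    }
  }
  ids <- union(names(lower), names(upper))
  if (length(ids) == 0) {
    return(data.frame(enzyme = character(0), lower = numeric(0),
                      upper = numeric(0), stringsAsFactors = FALSE))
  }
  lo <- vapply(ids, function(id) lower[[id]] %||% model$enzymes[[id]]$lower_bound, 0)
  hi <- vapply(ids, function(id) upper[[id]] %||% model$enzymes[[id]]$upper_bound, 0)
  bad <- lo > hi
  if (any(bad)) {
    warning("conflicting regulation bounds for enzyme(s) ",
            paste(ids[bad], collapse = ", "), "; clamped to e_min = e_max")
    lo[bad] <- hi[bad]
  }
  data.frame(enzyme = ids, lower = unname(lo), upper = unname(hi),
             stringsAsFactors = FALSE)
}
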