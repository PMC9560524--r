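#' Reactions, enzymes and enzyme-constrained metabolic models
#'
#' The model container mirrors the standard enzyme-constrained FBA (ecFBA)
#' formulation: steady-state mass balance `S v = 0`, flux box bounds, one
#' usage variable per enzyme coupled to its reactions through
#' `e_i = sum_j (n_ij / kcat_ij) v_j`, a mass coupling
#' `e_pool = sum_i MW_i e_i`, and a total pool bound
#' `0 <= e_pool <= sigma * f * P_tot`.
#'
#' Models are stored and solved in irreversible (split) form; reversible
#' reactions read from file are split into forward/backward columns with
#' `reversible_parent` recorded so that "reactions producing a metabolite"
#' has a fixed sign per column.
#'
#' @name model_core
NULL

#' Construct a reaction
#'
#' @param id,name identifiers (name defaults to id).
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = consumed).  May be empty for pure exchange placeholders.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param pathway pathway label used by the flux analytics.
#' @param reversible_parent id of the reversible reaction this direction was
#'   split from, or `NULL`.
#' @param isoenzyme_group label shared by reactions catalysed by isoenzymes,
#'   or `NULL`.
#' @return A list of class `agefba_reaction`.
#' @export
reaction <- function(id, stoich, lower_bound = 0, upper_bound = Inf,
                     name = id, pathway = "other", reversible_parent = NULL,
                     isoenzyme_group = NULL) {
  stopifnot(is.character(id), length(id) == 1, lower_bound <= upper_bound)
  stoich <- unlist(stoich)
  if (length(stoich) > 0) stopifnot(!is.null(names(stoich)))
  structure(list(id = id, name = name, stoich = stoich,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 pathway = pathway, reversible_parent = reversible_parent,
                 isoenzyme_group = isoenzyme_group),
            class = "agefba_reaction")
}

#' Construct an enzyme
#'
#' @param id identifier.
#' @param MW molecular weight in kDa (= g/mmol).
#' @param kcat named numeric vector, reaction id -> turnover number (1/h).
#' @param n named numeric vector, reaction id -> subunit stoichiometry;
#'   defaults to 1 for every catalysed reaction.
#' @param lower_bound,upper_bound usage bounds in mmol/gDW.
#' @return A list of class `agefba_enzyme`.
#' @export
enzyme <- function(id, MW, kcat, n = NULL, lower_bound = 0,
                   upper_bound = Inf) {
  stopifnot(is.character(id), length(id) == 1, MW > 0,
            lower_bound <= upper_bound)
  kcat <- unlist(kcat)
  stopifnot(length(kcat) > 0, !is.null(names(kcat)))
  if (is.null(n)) n <- setNames(rep(1, length(kcat)), names(kcat))
  n <- unlist(n)[names(kcat)]
  structure(list(id = id, MW = MW, kcat = kcat, n = n,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "agefba_enzyme")
}

#' Construct an enzyme-constrained metabolic model
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   (or a character vector of ids).
#' @param reactions list of [reaction()] objects.
#' @param enzymes list of [enzyme()] objects.
#' @param sigma average enzyme saturation (0-1).
#' @param f fraction of the proteome covered by the model's enzymes (0-1).
#' @param P_tot total protein content in g/gDW.
#' @param named_reactions named list mapping the roles `biomass`,
#'   `glucose_uptake` and `ngam` to reaction ids.
#' @param reaction_sets named list of reaction-id vectors for the sets
#'   `atp_producing`, `nadh_producing`, `ros_producing` and `antioxidant`.
#' @param validate check invariants and fail on errors (default `TRUE`).
#' @return An object of class `agefba_model`.
#' @export
metabolic_model <- function(metabolites, reactions, enzymes = list(),
                            sigma = 1, f = 1, P_tot = 1,
                            named_reactions = list(),
                            reaction_sets = list(), validate = TRUE) {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, name = metabolites,
                              compartment = rep("c", length(metabolites)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id") %in% names(metabolites)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  names(enzymes) <- vapply(enzymes, `[[`, "", "id")
  model <- structure(
    list(metabolites = metabolites, reactions = reactions, enzymes = enzymes,
         sigma = sigma, f = f, P_tot = P_tot,
         named_reactions = named_reactions, reaction_sets = reaction_sets),
    class = "agefba_model")
  if (validate) {
    issues <- validate_model(model)
    if (nrow(issues) > 0 && any(issues$severity == "error")) {
      stop("invalid model:\n", paste(issues$message[issues$severity == "error"],
                                     collapse = "\n"))
    }
  }
  model
}

#' @export
print.agefba_model <- function(x, ...) {
  cat(sprintf("<agefba_model> %d metabolites, %d reactions, %d enzymes\n",
              nrow(x$metabolites), length(x$reactions), length(x$enzymes)))
  cat(sprintf("  enzyme pool sigma*f*P_tot = %.4g g/gDW\n", enzyme_pool(x)))
  invisible(x)
}

#' Total enzyme pool bound sigma * f * P_tot
#'
#' @param model an `agefba_model`.
#' @return The pool bound in g/gDW.
#' @export
enzyme_pool <- function(model) model$sigma * model$f * model$P_tot

#' Stoichiometric matrix of a model
#'
#' @param model an `agefba_model`.
#' @return Dense matrix with one row per metabolite and one column per
#'   reaction.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (r in model$reactions) {
    if (length(r$stoich) > 0) S[names(r$stoich), r$id] <- r$stoich
  }
  S
}

#' Split reversible reactions into irreversible pairs
#'
#' Reactions with a negative lower bound are replaced by a forward copy
#' (`<id>_fwd`, bounds `[0, ub]`) and a backward copy (`<id>_bwd`, negated
#' stoichiometry, bounds `[0, -lb]`), both carrying `reversible_parent`.
#' Enzymes catalysing the parent catalyse both directions with the same
#' kcat.  Named roles and reaction sets pointing at the parent are remapped
#' to the forward copy.
#'
#' @param model an `agefba_model`.
#' @return The irreversible model.
#' @export
split_reversible <- function(model) {
  rev_ids <- names(model$reactions)[vapply(model$reactions,
                                           function(r) r$lower_bound < 0,
                                           logical(1))]
  if (length(rev_ids) == 0) return(model)
  new_rxns <- list()
  for (r in model$reactions) {
    if (!(r$id %in% rev_ids)) {
      new_rxns[[r$id]] <- r
      next
    }
    fwd <- r; bwd <- r
    fwd$id <- paste0(r$id, "_fwd")
    fwd$lower_bound <- 0
    fwd$reversible_parent <- r$id
    bwd$id <- paste0(r$id, "_bwd")
    bwd$stoich <- -r$stoich
    bwd$lower_bound <- 0
    bwd$upper_bound <- -r$lower_bound
    bwd$reversible_parent <- r$id
    new_rxns[[fwd$id]] <- fwd
    new_rxns[[bwd$id]] <- bwd
  }
  remap <- function(ids) {
    unlist(lapply(ids, function(id) {
      if (id %in% rev_ids) paste0(id, "_fwd") else id
    }))
  }
  new_enz <- lapply(model$enzymes, function(en) {
    hit <- intersect(names(en$kcat), rev_ids)
    if (length(hit) == 0) return(en)
    kcat <- en$kcat; n <- en$n
    for (id in hit) {
      kcat[paste0(id, c("_fwd", "_bwd"))] <- kcat[[id]]
      n[paste0(id, c("_fwd", "_bwd"))] <- n[[id]]
    }
    keep <- setdiff(names(kcat), rev_ids)
    en$kcat <- kcat[keep]; en$n <- n[keep]
    en
  })
  model$reactions <- new_rxns
  model$enzymes <- new_enz
  model$named_reactions <- lapply(model$named_reactions, remap)
  model$reaction_sets <- lapply(model$reaction_sets, remap)
  model
}

#' Validate a metabolic model
#'
#' Reports dangling metabolite references, kcat entries for unknown
#' reactions, non-positive kcat or MW, bound violations, missing named
#' roles, internal reactions without an enzyme, and a non-positive pool.
#'
#' @param model an `agefba_model`.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `where` and `message`; zero rows iff all invariants hold.
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(severity, where, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)
  }
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), mets)
    if (length(bad) > 0) {
      add("error", r$id, sprintf("reaction '%s' references unknown metabolite(s): %s",
                                 r$id, paste(bad, collapse = ", ")))
    }
    if (r$lower_bound > r$upper_bound) {
      add("error", r$id, sprintf("reaction '%s' has lower_bound > upper_bound", r$id))
    }
  }
  enzymatic <- character(0)
  for (en in model$enzymes) {
    bad <- setdiff(names(en$kcat), rids)
    if (length(bad) > 0) {
      add("error", en$id, sprintf("enzyme '%s' has kcat for unknown reaction(s): %s",
                                  en$id, paste(bad, collapse = ", ")))
    }
    if (any(en$kcat <= 0)) {
      add("error", en$id, sprintf("enzyme '%s' has non-positive kcat", en$id))
    }
    if (any(en$n < 1)) {
      add("error", en$id, sprintf("enzyme '%s' has subunit stoichiometry < 1", en$id))
    }
    if (en$MW <= 0) add("error", en$id, sprintf("enzyme '%s' has MW <= 0", en$id))
    if (en$lower_bound > en$upper_bound) {
      add("error", en$id, sprintf("enzyme '%s' has lower_bound > upper_bound", en$id))
    }
    enzymatic <- union(enzymatic, names(en$kcat))
  }
  for (role in names(model$named_reactions)) {
    id <- model$named_reactions[[role]]
    if (!id %in% rids) {
      add("error", role, sprintf("named role '%s' points at unknown reaction '%s'",
                                 role, id))
    }
  }
  for (set in names(model$reaction_sets)) {
    bad <- setdiff(model$reaction_sets[[set]], rids)
    if (length(bad) > 0) {
      add("error", set, sprintf("reaction set '%s' contains unknown reaction(s): %s",
                                set, paste(bad, collapse = ", ")))
    }
  }
  if (enzyme_pool(model) <= 0) {
    add("error", "pool", "sigma * f * P_tot must be positive")
  }
  structurally_sound <- length(issues) == 0 ||
    !any(vapply(issues, function(i) i$severity == "error", logical(1)))
  if (length(model$reactions) > 0 && structurally_sound) {
    S <- stoich_matrix(model)
    orphan <- rownames(S)[rowSums(S != 0) == 0]
    for (m in orphan) {
      add("warning", m, sprintf("metabolite '%s' participates in no reaction", m))
    }
    exch <- vapply(model$reactions, function(r) {
      length(r$stoich) == 0 || all(r$stoich > 0) || all(r$stoich < 0)
    }, logical(1))
    for (r in model$reactions) {
      if (!exch[[r$id]] && !(r$id %in% enzymatic)) {
        add("warning", r$id,
            sprintf("internal reaction '%s' has no enzyme and no exchange tag", r$id))
      }
    }
  }
  if (length(issues) == 0) {
    data.frame(severity = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Build the enzyme-constrained LP of a model
#'
#' Creates the linear problem with variables `(v, e, e_pool)`, mass-balance
#' equalities `S v = 0`, per-enzyme coupling rows
#' `-sum_j (n_ij/kcat_ij) v_j + e_i = 0`, the pool coupling
#' `-sum_i MW_i e_i + e_pool = 0`, and box bounds on fluxes, usages and the
#' pool.  No objective is attached.
#'
#' @param model a valid `agefba_model` in irreversible form.
#' @return An `agefba_lp`.
#' @export
build_lp <- function(model) {
  issues <- validate_model(model)
  if (any(issues$severity == "error")) {
    stop("model-integrity error:\n",
         paste(issues$message[issues$severity == "error"], collapse = "\n"))
  }
  rids <- names(model$reactions) %||% character(0)
  eids <- names(model$enzymes) %||% character(0)
  var_id <- c(rids, if (length(eids)) paste0(".e.", eids), ".pool")
  var_kind <- c(rep("v", length(rids)), rep("e", length(eids)), "pool")
  lb <- c(vapply(model$reactions, `[[`, 0, "lower_bound"),
          vapply(model$enzymes, `[[`, 0, "lower_bound"), 0)
  ub <- c(vapply(model$reactions, `[[`, 0, "upper_bound"),
          vapply(model$enzymes, `[[`, 0, "upper_bound"), enzyme_pool(model))
  nvar <- length(var_id)
  mets <- model$metabolites$id
  # without enzymes the pool-coupling equality would pin e_pool to zero;
  # the degenerate LP keeps only the pool box
  n_rows <- length(mets) + length(eids) + (length(eids) > 0)
  A <- matrix(0, nrow = n_rows, ncol = nvar,
              dimnames = list(NULL, var_id))
  if (length(mets) > 0 && length(rids) > 0) {
    A[seq_along(mets), seq_along(rids)] <- stoich_matrix(model)
  }
  for (k in seq_along(eids)) {
    en <- model$enzymes[[k]]
    i <- length(mets) + k
    A[i, names(en$kcat)] <- -en$n / en$kcat
    A[i, paste0(".e.", en$id)] <- 1
  }
  if (length(eids) > 0) {
    A[n_rows, paste0(".e.", eids)] <- -vapply(model$enzymes, `[[`, 0, "MW")
    A[n_rows, ".pool"] <- 1
  }
  new_linear_problem(
    var_id = var_id, var_kind = var_kind, lb = unname(lb), ub = unname(ub),
    A = A, sense = rep("=", n_rows),
    rhs = rep(0, n_rows),
    row_name = c(if (length(mets)) paste0("mass_balance:", mets),
                 if (length(eids)) paste0("enzyme_coupling:", eids),
                 if (length(eids)) "pool_coupling"))
}

#' Total production rate of a metabolite in a flux solution
#'
#' Sums `max(S[metabolite, j], 0) * v_j` over all reactions (stoichiometry-
#' weighted production).  With `weighted = FALSE` the raw fluxes of producing
#' reactions are summed instead, as an unweighted sensitivity variant.
#'
#' @param model an `agefba_model` in irreversible form.
#' @param metabolite a metabolite id.
#' @param solution an optimal `agefba_flux_solution`.
#' @param weighted weight fluxes by the stoichiometric coefficient
#'   (default `TRUE`).
#' @return The production flux in mmol/gDW/h.
#' @export
total_production_flux <- function(model, metabolite, solution,
                                  weighted = TRUE) {
  if (!metabolite %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite)
  }
  S <- stoich_matrix(model)
  coef <- pmax(S[metabolite, ], 0)
  if (!weighted) coef <- as.numeric(coef > 0)
  sum(coef * solution$v[colnames(S)])
}
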