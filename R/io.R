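#' Read and write models in the package JSON format
#'
#' The schema has top-level keys `metabolites` (array of `{id, name,
#' compartment}`), `reactions` (array of `{id, name, stoich, lower_bound,
#' upper_bound, pathway, reversible_parent, isoenzyme_group}` with `stoich`
#' as `{metabolite_id: coefficient}`), `enzymes` (array of `{id, MW, kcat,
#' n, lower_bound, upper_bound}`), `pool` (`{sigma, f, P_tot}`),
#' `named_reactions` and `reaction_sets`.  Round-tripping a model through
#' [write_model_json()] and [read_model_json()] is lossless.
#'
#' @param model an `agefba_model`.
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns an `agefba_model`.
#' @name model_json
NULL

num_or_inf <- function(x) {
  # JSON has no Inf; encode as the string "inf"/"-inf".
  if (is.infinite(x)) ifelse(x > 0, "inf", "-inf") else x
}

parse_num <- function(x) {
  if (is.character(x)) {
    switch(x, inf = Inf, `-inf` = -Inf, as.numeric(x))
  } else {
    as.numeric(x)
  }
}

model_to_list <- function(model) {
  obj <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = lapply(model$reactions, function(r) {
      out <- list(id = r$id, name = r$name, stoich = as.list(r$stoich),
                  lower_bound = num_or_inf(r$lower_bound),
                  upper_bound = num_or_inf(r$upper_bound),
                  pathway = r$pathway)
      if (!is.null(r$reversible_parent)) out$reversible_parent <- r$reversible_parent
      if (!is.null(r$isoenzyme_group)) out$isoenzyme_group <- r$isoenzyme_group
      out
    }),
    enzymes = lapply(model$enzymes, function(en) {
      list(id = en$id, MW = en$MW, kcat = as.list(en$kcat), n = as.list(en$n),
           lower_bound = num_or_inf(en$lower_bound),
           upper_bound = num_or_inf(en$upper_bound))
    }),
    pool = list(sigma = model$sigma, f = model$f, P_tot = model$P_tot),
    named_reactions = model$named_reactions,
    reaction_sets = model$reaction_sets
  )
  names(obj$reactions) <- NULL
  names(obj$enzymes) <- NULL
  obj
}

model_from_list <- function(obj) {
  metabolites <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c", stringsAsFactors = FALSE)
  }))
  reactions <- lapply(obj$reactions, function(r) {
    reaction(id = r$id, name = r$name %||% r$id,
             stoich = vapply(r$stoich, as.numeric, 0),
             lower_bound = parse_num(r$lower_bound %||% 0),
             upper_bound = parse_num(r$upper_bound %||% "inf"),
             pathway = r$pathway %||% "other",
             reversible_parent = r$reversible_parent,
             isoenzyme_group = r$isoenzyme_group)
  })
  enzymes <- lapply(obj$enzymes, function(en) {
    enzyme(id = en$id, MW = as.numeric(en$MW),
           kcat = vapply(en$kcat, as.numeric, 0),
           n = if (is.null(en$n)) NULL else vapply(en$n, as.numeric, 0),
           lower_bound = parse_num(en$lower_bound %||% 0),
           upper_bound = parse_num(en$upper_bound %||% "inf"))
  })
  metabolic_model(
    metabolites = metabolites, reactions = reactions, enzymes = enzymes,
    sigma = as.numeric(obj$pool$sigma), f = as.numeric(obj$pool$f),
    P_tot = as.numeric(obj$pool$P_tot),
    named_reactions = lapply(obj$named_reactions, as.character),
    reaction_sets = lapply(obj$reaction_sets, function(s) {
      vapply(s, as.character, "", USE.NAMES = FALSE)
    }))
}

#' @rdname model_json
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model_json
#' @param irreversible split reversible reactions on load (default `TRUE`).
#' @export
read_model_json <- function(path, irreversible = TRUE) {
  model <- model_from_list(jsonlite::read_json(path))
  if (irreversible) model <- split_reversible(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration (YAML)
#'
#' A run configuration may hold blocks `strategy` (`first`, `second`,
#' `epsilon1`, `epsilon2`, `parsimonious`), `ageing` (see
#' [damage_parameters()]) and `regulation` (see [regulation_config()]).
#' Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `strategy`, `ageing`, `regulation`,
#'   `max_time`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  strategy <- do.call(optimization_strategy, cfg$strategy %||% list(first = "max_growth"))
  ageing <- do.call(damage_parameters, cfg$ageing %||% list())
  regulation <- if (is.null(cfg$regulation)) {
    regulation_config()
  } else {
    do.call(regulation_config, cfg$regulation)
  }
  list(strategy = strategy, ageing = ageing, regulation = regulation,
       max_time = cfg$max_time %||% 200)
}
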