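#' Linear problems over (v, e, e_pool)
#'
#' A `agefba_lp` is a dense linear problem holding one variable per
#' (irreversible) reaction flux, one per enzyme usage, and one pool variable,
#' together with equality/inequality rows and box bounds.  [build_lp()]
#' creates one from a metabolic model; the optimiser adds locked-stage rows
#' to it.
#'
#' @param var_id character vector of variable identifiers.
#' @param var_kind one of `"v"`, `"e"`, `"pool"` per variable.
#' @param lb,ub numeric bounds per variable (`ub` may be `Inf`).
#' @param A constraint matrix (rows = constraints, columns = variables).
#' @param sense character vector of `"="`, `"<="`, `">="` per row.
#' @param rhs numeric right-hand sides.
#' @param row_name character row labels.
#' @return An object of class `agefba_lp`.
#' @keywords internal
new_linear_problem <- function(var_id, var_kind, lb, ub, A, sense, rhs,
                               row_name) {
  stopifnot(length(var_id) == length(var_kind),
            length(lb) == length(var_id), length(ub) == length(var_id),
            ncol(A) == length(var_id), nrow(A) == length(sense),
            length(rhs) == length(sense), length(row_name) == length(sense))
  colnames(A) <- var_id
  structure(
    list(var_id = var_id, var_kind = var_kind, lb = lb, ub = ub,
         A = A, sense = sense, rhs = rhs, row_name = row_name),
    class = "agefba_lp"
  )
}

#' @export
print.agefba_lp <- function(x, ...) {
  cat(sprintf("<agefba_lp> %d variables (%d fluxes, %d enzymes), %d rows (%d equalities)\n",
              length(x$var_id), sum(x$var_kind == "v"), sum(x$var_kind == "e"),
              length(x$sense), sum(x$sense == "=")))
  invisible(x)
}

#' Append a linear constraint to a problem
#'
#' @param problem an `agefba_lp`.
#' @param coefficients named numeric vector over existing variable ids.
#' @param sense one of `"="`, `"<="`, `">="`.
#' @param rhs right-hand side.
#' @param name row label.
#' @return The problem with one extra row.
#' @export
lp_add_constraint <- function(problem, coefficients, sense, rhs,
                              name = "constraint") {
  stopifnot(inherits(problem, "agefba_lp"), sense %in% c("=", "<=", ">="))
  unknown <- setdiff(names(coefficients), problem$var_id)
  if (length(unknown) > 0) {
    stop("unknown variable id(s): ", paste(unknown, collapse = ", "))
  }
  row <- setNames(numeric(length(problem$var_id)), problem$var_id)
  row[names(coefficients)] <- as.numeric(coefficients)
  problem$A <- rbind(problem$A, row, deparse.level = 0)
  problem$sense <- c(problem$sense, sense)
  problem$rhs <- c(problem$rhs, rhs)
  problem$row_name <- c(problem$row_name, name)
  problem
}

#' Set box bounds on problem variables
#'
#' @param problem an `agefba_lp`.
#' @param ids variable ids to modify.
#' @param lower,upper replacement bounds (recycled); `NULL` leaves a side
#'   untouched.
#' @return The modified problem.
#' @export
lp_set_bounds <- function(problem, ids, lower = NULL, upper = NULL) {
  stopifnot(inherits(problem, "agefba_lp"))
  idx <- match(ids, problem$var_id)
  if (anyNA(idx)) {
    stop("unknown variable id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  if (!is.null(lower)) problem$lb[idx] <- rep_len(lower, length(idx))
  if (!is.null(upper)) problem$ub[idx] <- rep_len(upper, length(idx))
  problem
}

sense_to_int <- function(sense) {
  unname(c("<=" = -1L, "=" = 0L, ">=" = 1L)[sense])
}

# Raw solver access: minimise/maximise a named coefficient vector over the
# problem polytope.  Returns list(status, x, objective) with status one of
# "optimal", "infeasible", "unbounded".
lp_optimize <- function(problem, coefficients, maximize = TRUE,
                        tol = AGEFBA_TOL) {
  obj <- setNames(numeric(length(problem$var_id)), problem$var_id)
  unknown <- setdiff(names(coefficients), problem$var_id)
  if (length(unknown) > 0) {
    stop("objective references unknown variable id(s): ",
         paste(unknown, collapse = ", "))
  }
  obj[names(coefficients)] <- as.numeric(coefficients)
  res <- .simplex_lp(problem$A, problem$rhs, sense_to_int(problem$sense),
                     problem$lb, problem$ub, unname(obj), maximize, tol)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                   stop("solver error: unknown status ", res$status))
  list(status = status, x = setNames(res$x, problem$var_id),
       objective = res$objective)
}

#' Solve a linear problem under a single objective
#'
#' Runs the deterministic simplex solver and packages the optimum as a flux
#' solution with one stage value.  Used directly for single-stage FBA;
#' [lexicographic_solve()] chains several calls.
#'
#' @param problem an `agefba_lp` from [build_lp()].
#' @param objective an objective from [make_objective()], or any named
#'   coefficient vector plus a direction via `list(coefficients=, direction=)`.
#' @return A `agefba_flux_solution` with fields `v`, `e`, `e_pool`,
#'   `stage_values` and `status`.
#' @export
solve_lp <- function(problem, objective) {
  stopifnot(inherits(problem, "agefba_lp"))
  dir <- objective$direction
  stopifnot(dir %in% c("max", "min"))
  res <- lp_optimize(problem, objective$coefficients, maximize = dir == "max")
  new_flux_solution(problem, res, stage_values = res$objective)
}

new_flux_solution <- function(problem, res, stage_values) {
  x <- res$x
  if (res$status != "optimal") {
    x[] <- NA_real_
    stage_values <- numeric(0)
  }
  structure(
    list(v = x[problem$var_kind == "v"],
         e = setNames(x[problem$var_kind == "e"],
                      sub("^\\.e\\.", "", problem$var_id[problem$var_kind == "e"])),
         e_pool = unname(x[problem$var_kind == "pool"][1]),
         stage_values = stage_values,
         status = res$status),
    class = "agefba_flux_solution"
  )
}

#' @export
print.agefba_flux_solution <- function(x, ...) {
  cat(sprintf("<agefba_flux_solution> status: %s\n", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  stage values: %s\n",
                paste(signif(x$stage_values, 6), collapse = ", ")))
    cat(sprintf("  e_pool: %s; %d fluxes, %d enzymes\n",
                signif(x$e_pool, 6), length(x$v), length(x$e)))
  }
  invisible(x)
}
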