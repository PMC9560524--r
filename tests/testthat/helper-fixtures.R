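# Small hand-built fixtures and an exhaustive vertex-enumeration oracle.

# T1: one metabolite, uptake [0, 10], biomass drain catalysed by E1
# (kcat = 1/h, MW = 1 kDa), pool bound 5 g/gDW.
make_t1 <- function(pool = 5, kcat = 1) {
  metabolic_model(
    metabolites = "X",
    reactions = list(reaction("R_up", c(X = 1), 0, 10),
                     reaction("R_bio", c(X = -1))),
    enzymes = list(enzyme("E1", MW = 1, kcat = c(R_bio = kcat))),
    sigma = 1, f = 1, P_tot = pool,
    named_reactions = list(biomass = "R_bio", glucose_uptake = "R_up",
                           ngam = "R_up"))
}

# T2: T1 plus an NGAM drain with a twice-as-fast enzyme.
make_t2 <- function() {
  metabolic_model(
    metabolites = "X",
    reactions = list(reaction("R_up", c(X = 1), 0, 10),
                     reaction("R_bio", c(X = -1)),
                     reaction("R_ngam", c(X = -1))),
    enzymes = list(enzyme("E_bio", MW = 1, kcat = c(R_bio = 1)),
                   enzyme("E_ngam", MW = 1, kcat = c(R_ngam = 2))),
    sigma = 1, f = 1, P_tot = 5,
    named_reactions = list(biomass = "R_bio", glucose_uptake = "R_up",
                           ngam = "R_ngam"))
}

# Two redundant parallel routes for the same conversion; route B has the
# cheaper enzyme (higher kcat), so a parsimonious solution should use it.
make_parallel <- function() {
  metabolic_model(
    metabolites = c("X", "Y"),
    reactions = list(reaction("R_up", c(X = 1), 0, 10),
                     reaction("R_a", c(X = -1, Y = 1)),
                     reaction("R_b", c(X = -1, Y = 1)),
                     reaction("R_bio", c(Y = -1))),
    enzymes = list(enzyme("E_a", MW = 1, kcat = c(R_a = 1)),
                   enzyme("E_b", MW = 1, kcat = c(R_b = 4)),
                   enzyme("E_bio", MW = 0.1, kcat = c(R_bio = 10))),
    sigma = 1, f = 1, P_tot = 5,
    named_reactions = list(biomass = "R_bio", glucose_uptake = "R_up",
                           ngam = "R_up"))
}

# Exhaustive vertex enumeration over the full (v, e, e_pool) space of an
# agefba_lp: every vertex is the solution of the equality rows plus a
# choice of active inequalities (inequality rows and finite box bounds).
# Independent of the simplex path by construction.
oracle_optimum <- function(problem, coefficients, maximize = TRUE,
                           tol = 1e-7) {
  n <- length(problem$var_id)
  obj <- setNames(numeric(n), problem$var_id)
  obj[names(coefficients)] <- coefficients

  eq <- problem$sense == "="
  A_eq <- problem$A[eq, , drop = FALSE]
  b_eq <- problem$rhs[eq]
  # normalise every inequality to a x <= b
  A_in <- NULL
  b_in <- numeric(0)
  add_in <- function(a, b) {
    A_in <<- rbind(A_in, a)
    b_in <<- c(b_in, b)
  }
  for (i in which(!eq)) {
    s <- if (problem$sense[i] == "<=") 1 else -1
    add_in(s * problem$A[i, ], s * problem$rhs[i])
  }
  for (j in seq_len(n)) {
    a <- numeric(n)
    a[j] <- -1
    add_in(a, -problem$lb[j])
    if (is.finite(problem$ub[j])) {
      a[j] <- 1
      add_in(a, problem$ub[j])
    }
  }
  r_eq <- qr(A_eq)$rank
  k <- n - r_eq
  best <- NULL
  for (act in utils::combn(nrow(A_in), k, simplify = FALSE)) {
    A <- rbind(A_eq, A_in[act, , drop = FALSE])
    b <- c(b_eq, b_in[act])
    qr_A <- qr(A)
    if (qr_A$rank < n) next
    x <- tryCatch(qr.coef(qr_A, b), error = function(e) NULL)
    if (is.null(x) || anyNA(x)) next
    if (max(abs(A %*% x - b)) > tol) next
    if (any(A_in %*% x - b_in > tol)) next
    z <- sum(obj * x)
    if (is.null(best) || (maximize && z > best) || (!maximize && z < best)) {
      best <- z
    }
  }
  best
}

# Memoised expensive simulations, shared across test files.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

ref_bundle <- function() cached("ref", reference_cell())

# The reference-cell simulation (with trajectory) used by several files.
ref_run <- function() {
  cached("ref_run", {
    ref <- ref_bundle()
    suppressWarnings(simulate_lifespan(ref$model, ref$strategy, ref$ageing,
                                       ref$regulation, max_time = 150))
  })
}

# parsimonious / plain maximal growth at epsilon1 = 0.3 on the reference
# network, both on the same 80 h horizon
relaxed_run <- function(parsimonious) {
  key <- paste0("relaxed_", parsimonious)
  cached(key, {
    ref <- ref_bundle()
    st <- optimization_strategy("max_growth", epsilon1 = 0.3,
                                epsilon2 = 0.05,
                                parsimonious = parsimonious)
    suppressWarnings(simulate_lifespan(ref$model, st, ref$ageing,
                                       ref$regulation, max_time = 80))
  })
}

ngam_run <- function() {
  cached("ngam_run", {
    ref <- ref_bundle()
    st <- optimization_strategy("max_growth", "max_ngam", epsilon1 = 0.3,
                                epsilon2 = 0.05, parsimonious = TRUE)
    suppressWarnings(simulate_lifespan(ref$model, st, ref$ageing,
                                       ref$regulation, max_time = 80))
  })
}
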