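test_that("the objective library reads roles and stoichiometric weights", {
  m <- make_t2()
  o <- make_objective(m, "max_growth")
  expect_equal(o$coefficients, c(R_bio = 1))
  expect_identical(o$direction, "max")
  o2 <- make_objective(m, "max_ngam")
  expect_equal(o2$coefficients, c(R_ngam = 1))
  expect_identical(make_objective(m, "min_glucose_uptake")$direction, "min")

  # stoichiometry-weighted ATP production set
  matp <- metabolic_model(
    metabolites = c("X", "ATP"),
    reactions = list(reaction("R_up", c(X = 1), 0, 10),
                     reaction("r1", c(X = -1, ATP = 2)),
                     reaction("r2", c(X = -1, ATP = 1)),
                     reaction("R_use", c(ATP = -1))),
    sigma = 1, f = 1, P_tot = 1,
    named_reactions = list(biomass = "R_use", glucose_uptake = "R_up",
                           ngam = "R_use"),
    reaction_sets = list(atp_producing = c("r1", "r2")))
  o3 <- make_objective(matp, "max_atp_production")
  expect_equal(o3$coefficients, c(r1 = 2, r2 = 1))
  expect_equal(make_objective(matp, "max_atp_production",
                              weighted = FALSE)$coefficients,
               c(r1 = 1, r2 = 1))
  expect_error(make_objective(matp, "min_nadh_production"),
               "lacks reaction set")
})

test_that("lock_stage reproduces the flexibility constraint arithmetic", {
  m <- make_t2()
  lp <- build_lp(m)
  obj <- make_objective(m, "max_growth")
  locked <- lock_stage(lp, obj, 5, 0.2)
  i <- nrow(locked$A)
  expect_identical(locked$sense[i], ">=")
  expect_equal(locked$rhs[i], 4) # 5 * (1 - 0.2)
  expect_equal(unname(locked$A[i, "R_bio"]), 1)

  omin <- make_objective(m, "min_glucose_uptake")
  locked2 <- lock_stage(lp, omin, 0, 0.5)
  expect_identical(locked2$sense[nrow(locked2$A)], "<=")
  expect_equal(locked2$rhs[nrow(locked2$A)], 0) # zero is scale-free

  locked3 <- lock_stage(lp, obj, 5, 1)
  expect_equal(locked3$rhs[nrow(locked3$A)], 0) # vacuous at epsilon = 1
  expect_error(lock_stage(lp, obj, 5, 1.5), "epsilon")
})

test_that("two-stage lexicographic optima match hand-enumerated vertices", {
  m <- make_t2()
  s <- lexicographic_solve(
    m, optimization_strategy("max_growth", "max_ngam", epsilon1 = 0.4))
  expect_equal(unname(s$v[c("R_bio", "R_ngam")]), c(3, 4), tolerance = 1e-9)
  expect_equal(s$stage_values, c(5, 4), tolerance = 1e-9)

  s0 <- lexicographic_solve(
    m, optimization_strategy("max_growth", "max_ngam", epsilon1 = 0))
  expect_equal(unname(s0$v[c("R_bio", "R_ngam")]), c(5, 0), tolerance = 1e-9)

  smin <- lexicographic_solve(m, optimization_strategy("min_glucose_uptake"))
  expect_equal(unname(smin$v), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the parsimonious solution is the flux/enzyme-minimal point", {
  m <- make_t2()
  s <- lexicographic_solve(
    m, optimization_strategy("max_growth", "max_ngam", epsilon1 = 0.4,
                             parsimonious = TRUE))
  # unique point after locking: v_up = 7, sum v = 14, sum e = 5
  expect_equal(unname(s$v[["R_up"]]), 7, tolerance = 1e-6)
  expect_equal(sum(s$v), 14, tolerance = 1e-6)
  expect_equal(sum(s$e), 5, tolerance = 1e-6)
  expect_equal(tail(s$stage_values, 1), 19, tolerance = 1e-6)

  # T1 locked at its optimum has a single feasible point
  t1 <- make_t1()
  s1 <- lexicographic_solve(
    t1, optimization_strategy("max_growth", parsimonious = TRUE))
  expect_equal(unname(s1$v), c(5, 5), tolerance = 1e-6)

  # redundant parallel routes: all flux goes through the cheaper enzyme
  pm <- make_parallel()
  sp <- lexicographic_solve(
    pm, optimization_strategy("max_growth", parsimonious = TRUE))
  expect_gt(sp$v[["R_b"]], 1)
  expect_equal(unname(sp$v[["R_a"]]), 0, tolerance = 1e-9)
})

test_that("parsimony value dominates the plain stage solution and random feasible points", {
  m <- make_t2()
  strategy <- optimization_strategy("max_growth", "max_ngam",
                                    epsilon1 = 0.4, parsimonious = TRUE)
  plain <- lexicographic_solve(
    m, optimization_strategy("max_growth", "max_ngam", epsilon1 = 0.4))
  pars <- lexicographic_solve(m, strategy)
  p_val <- tail(pars$stage_values, 1)
  expect_lte(p_val, sum(plain$v) + sum(plain$e) + 1e-9)

  # single-stage lock (v_bio >= 3): sample 100 feasible points of the
  # locked polytope by rejection and check none beats the parsimony value
  pars1 <- lexicographic_solve(
    m, optimization_strategy("max_growth", epsilon1 = 0.4,
                             parsimonious = TRUE))
  p1_val <- tail(pars1$stage_values, 1)
  set.seed(1)
  n_ok <- 0
  while (n_ok < 100) {
    v_bio <- runif(1, 3, 5)
    v_ngam <- runif(1, 0, 2 * (5 - v_bio))
    v_up <- v_bio + v_ngam
    if (v_up > 10) next
    n_ok <- n_ok + 1
    total <- v_up + v_bio + v_ngam + (v_bio + v_ngam / 2)
    expect_lte(p1_val, total + 1e-9)
  }

  # idempotence: re-minimising at the parsimonious point changes nothing
  again <- parsimonious_solve(pars$locked_problem)
  expect_equal(tail(again$stage_values, 1), p_val, tolerance = 1e-9)
})

test_that("stage-1 locks hold after stage 2 and parsimony across the epsilon grid", {
  m <- make_t2()
  z2_prev <- -Inf
  for (eps1 in seq(0, 0.5, 0.1)) {
    s <- lexicographic_solve(
      m, optimization_strategy("max_growth", "max_ngam", epsilon1 = eps1,
                               parsimonious = TRUE))
    z1 <- s$stage_values[1]
    expect_gte(s$v[["R_bio"]], z1 * (1 - eps1) - 1e-9)
    expect_gte(s$v[["R_ngam"]], s$stage_values[2] * (1 - 1e-9) - 1e-9)
    # z2 is non-decreasing in eps1 (larger relaxation, larger feasible set)
    expect_gte(s$stage_values[2], z2_prev - 1e-9)
    z2_prev <- s$stage_values[2]
  }
})

test_that("infeasible stage 1 is propagated as the death signal", {
  m <- make_t1()
  lp <- lp_set_bounds(build_lp(m), ".pool", upper = 0)
  lp <- lp_set_bounds(lp, "R_bio", lower = 1)
  s <- lexicographic_solve(m, optimization_strategy("max_growth"), lp)
  expect_identical(s$status, "infeasible")
})
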