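sol_with <- function(v) {
  structure(list(v = v, status = "optimal"), class = "agefba_flux_solution")
}

test_that("the damage step integrates formation, repair and growth bookkeeping", {
  m <- make_t2()
  p0 <- damage_parameters(f_m = 0, f0 = 0, r0 = 0)
  s <- cell_state()
  sol <- sol_with(c(R_up = 5, R_bio = 5, R_ngam = 0))
  s1 <- damage_step(s, sol, p0, dt = 1, model = m)
  expect_equal(s1$damaged, 0)
  expect_equal(s1$biomass_progress, 5)
  expect_equal(s1$t, 1)

  # one Euler step of the baseline formation alone
  p1 <- damage_parameters(f_m = 0, f0 = 1e-4, r0 = 0)
  s2 <- damage_step(cell_state(), sol, p1, dt = 1, model = m)
  expect_equal(s2$damaged, 1e-4)
  expect_equal(s2$intact + s2$damaged, 1)
  expect_error(damage_step(s, sol, p1, dt = 0, model = m), "dt")
})

test_that("Euler drift from the damage fixed point shrinks as O(dt^2)", {
  p <- damage_parameters(f_m = 0, f0 = 1e-2, r0 = 5e-2)
  D_star <- p$f0 / (p$f0 + p$r0) # dD/dt = 0 at f0 P = r0 D with P = 1 - D
  m <- make_t2()
  sol <- sol_with(c(R_up = 0, R_bio = 0, R_ngam = 0))
  drift <- function(dt) {
    s <- cell_state(intact = 1 - D_star)
    s <- damage_step(s, sol, p, dt = dt, model = m)
    abs(s$damaged - D_star)
  }
  # at the stationary point the Euler update vanishes identically, so the
  # one-step drift is far below any O(dt^2) bound
  expect_lt(drift(0.1), 1e-12)
  expect_lt(drift(0.01), 1e-12)
  # away from it, accumulate many steps to expose the discretisation error
  total_drift <- function(dt, horizon = 1) {
    s <- cell_state() # start away from the fixed point
    for (i in seq_len(round(horizon / dt))) {
      s <- damage_step(s, sol, p, dt = dt, model = m)
    }
    s$damaged
  }
  fine <- total_drift(1e-4)
  err1 <- abs(total_drift(0.02) - fine)
  err2 <- abs(total_drift(0.01) - fine)
  # halving dt roughly halves the global error (first-order global,
  # second-order local); allow generous slack around the factor 2
  expect_gt(err1 / err2, 1.5)
  expect_lt(err1 / err2, 2.5)
})

test_that("division splits damage asymmetrically and renormalises", {
  p <- damage_parameters(retention = 0.5, division_biomass = 1)
  s <- cell_state(intact = 0.9)
  s$biomass_progress <- 1.2
  s1 <- maybe_divide(s, p)
  expect_identical(s1$divisions, 1L)
  expect_equal(s1$damaged, 0.1) # retention 0.5 leaves D unchanged
  expect_equal(s1$biomass_progress, 0.2)

  p2 <- damage_parameters(retention = 1, division_biomass = 1)
  s2 <- cell_state(intact = 0.9)
  s2$biomass_progress <- 1
  s2 <- maybe_divide(s2, p2)
  expect_equal(s2$damaged, 0.2 / 1.1, tolerance = 1e-12)
  expect_equal(s2$intact + s2$damaged, 1)

  s3 <- cell_state(intact = 0.9)
  s3$biomass_progress <- 0.99
  expect_identical(maybe_divide(s3, p), s3) # below threshold: no division
})

test_that("damage feeds back through the NGAM bound and the shrinking pool", {
  p <- damage_parameters(ngam0 = 1, ngam_slope = 2)
  expect_equal(ngam_bound(cell_state(), p), 1)
  expect_equal(ngam_bound(cell_state(intact = 0.5), p), 2)
  p0 <- damage_parameters(ngam0 = 1, ngam_slope = 0)
  expect_equal(ngam_bound(cell_state(intact = 0.2), p0), 1)

  m <- make_t1()
  expect_equal(effective_pool(cell_state(), m), 5)
  expect_equal(effective_pool(cell_state(intact = 0.5), m), 2.5)
  expect_equal(effective_pool(cell_state(intact = 0), m), 0)
})

test_that("death is LP infeasibility and is permanent in damage", {
  m <- make_t2()
  strategy <- optimization_strategy("max_growth")
  p <- damage_parameters(ngam0 = 1, ngam_slope = 0)
  expect_false(is_dead(m, cell_state(), strategy, p))
  expect_true(is_dead(m, cell_state(intact = 0), strategy, p))

  # bisect the infeasibility frontier in D: max NGAM flux is 10 intact
  # (pool 5 intact * kcat 2), so the cell dies when 1 > 10 (1 - D)
  ps <- damage_parameters(ngam0 = 1, ngam_slope = 0)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (is_dead(m, cell_state(intact = 1 - mid), strategy, ps)) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  expect_equal(hi, 0.9, tolerance = 1e-6)
  # monotone: everything past the frontier stays dead
  for (D in seq(hi + 1e-6, 1, length.out = 5)) {
    expect_true(is_dead(m, cell_state(intact = 1 - D), strategy, ps))
  }
})

test_that("conservation of intact + damaged holds along random dynamics", {
  set.seed(7)
  m <- make_t2()
  p <- damage_parameters(f_m = 0.3, f0 = 1e-3, r0 = 5e-3, retention = 0.7,
                         division_biomass = 0.5)
  s <- cell_state()
  for (i in 1:200) {
    sol <- sol_with(c(R_up = runif(1, 0, 10), R_bio = runif(1, 0, 5),
                      R_ngam = 0))
    s <- damage_step(s, sol, p, model = m)
    s <- maybe_divide(s, p)
    expect_equal(s$intact + s$damaged, 1, tolerance = 1e-12)
  }
  expect_gt(s$divisions, 0)
})

test_that("a damage-free cell never dies and divides at a constant rhythm", {
  m <- make_t2()
  # division_biomass is an exact multiple of growth * dt so that the
  # discretised division rhythm is strictly constant
  ag <- damage_parameters(f_m = 0, f0 = 0, r0 = 5e-4, retention = 0.7,
                          division_biomass = 2.25, ngam0 = 1,
                          ngam_slope = 10, dt = 0.05)
  st <- optimization_strategy("max_growth", parsimonious = TRUE)
  r <- simulate_lifespan(m, st, ag, regulation = NULL, max_time = 20,
                         record = FALSE)
  expect_true(r$truncated) # alive at the horizon
  expect_gt(r$rls, 10)
  expect_lt(diff(range(r$generation_times)), 1e-9)
})
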