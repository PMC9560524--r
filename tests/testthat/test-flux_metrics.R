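# a small irreversible model with one split reversible pair and one
# isoenzyme pair, for the collapse/rewiring machinery
make_collapse_model <- function() {
  m <- metabolic_model(
    metabolites = c("A", "B"),
    reactions = list(
      reaction("R_up", c(A = 1), 0, 10, pathway = "exchange"),
      reaction("R_rev", c(A = -1, B = 1), -5, 5, pathway = "core"),
      reaction("iso1", c(B = -1), pathway = "core", isoenzyme_group = "ISO"),
      reaction("iso2", c(B = -1), pathway = "core", isoenzyme_group = "ISO")),
    sigma = 1, f = 1, P_tot = 1,
    named_reactions = list(biomass = "iso1", glucose_uptake = "R_up",
                           ngam = "iso1"))
  split_reversible(m)
}

cfv <- function(values, pathway = NULL) {
  if (is.null(pathway)) {
    pathway <- setNames(rep("core", length(values)), names(values))
  }
  structure(list(values = values, pathway = pathway),
            class = "agefba_collapsed_fluxes")
}

test_that("collapse merges split pairs and isoenzyme groups and is idempotent", {
  m <- make_collapse_model()
  v <- c(R_up = 2, R_rev_fwd = 3, R_rev_bwd = 1, iso1 = 1, iso2 = 2)
  cv <- collapse_fluxes(m, v)
  expect_equal(cv$values[["R_rev"]], 2) # fwd - bwd
  expect_equal(cv$values[["ISO"]], 3)   # summed isoenzymes
  expect_equal(cv$values[["R_up"]], 2)  # untouched reaction
  expect_identical(unname(cv$pathway[c("R_rev", "ISO")]), c("core", "core"))
  expect_length(cv$values, 3)

  # backward-dominated pair gives a negative collapsed flux
  v2 <- replace(v, "R_rev_bwd", 4)
  expect_equal(collapse_fluxes(m, v2)$values[["R_rev"]], -1)

  # a model with no splits or groups collapses to the identity
  t2 <- make_t2()
  v3 <- c(R_up = 1, R_bio = 2, R_ngam = 3)
  expect_equal(collapse_fluxes(t2, v3)$values, v3)

  # inconsistent pathway labels within a group are an error
  bad <- make_collapse_model()
  bad$reactions$iso2$pathway <- "elsewhere"
  expect_error(collapse_fluxes(bad, v), "inconsistent pathway")
})

test_that("relative changes follow the |v_p - v| / |v| rule with its sentinels", {
  a <- cfv(c(r1 = 2, r2 = -1, r3 = 1, r4 = 0, r5 = 1, r6 = 0))
  b <- cfv(c(r1 = 1, r2 = 1, r3 = 1, r4 = 0, r5 = 0, r6 = 2))
  ch <- relative_change(a, b)
  expect_equal(ch$delta[ch$id == "r1"], 0.5)
  expect_equal(ch$delta[ch$id == "r2"], 2)
  expect_equal(ch$delta[ch$id == "r3"], 0)
  expect_equal(ch$delta[ch$id == "r4"], 0) # both zero
  expect_identical(ch$class[ch$id == "r3"], "unchanged")
  expect_identical(ch$class[ch$id == "r4"], "unchanged")
  # switched off: decreased with delta 1; switched on: flagged, no delta
  expect_identical(ch$class[ch$id == "r5"], "decreased")
  expect_equal(ch$delta[ch$id == "r5"], 1)
  expect_identical(ch$class[ch$id == "r6"], "switched_on")
  expect_true(is.na(ch$delta[ch$id == "r6"]))
  expect_identical(ch$class[ch$id == "r1"], "decreased")

  # identity comparison: all zero and unchanged
  ch0 <- relative_change(a, a)
  expect_true(all(ch0$delta[!is.na(ch0$delta)] == 0))
  expect_true(all(ch0$class %in% c("unchanged")))

  expect_error(relative_change(a, cfv(c(r1 = 1))), "mismatch")
})

test_that("glucose normalisation divides or flags depending on uptake", {
  v <- cfv(c(r1 = 4, r2 = -2))
  expect_equal(normalize_by_glucose(v, 2)$values, c(r1 = 2, r2 = -1))
  expect_equal(normalize_by_glucose(v, 1)$values, v$values)
  expect_true(all(is.na(normalize_by_glucose(v, 0)$values)))
})

test_that("phase averages match closed forms on step and ramp trajectories", {
  t2 <- make_t2()
  # step trajectory: flux 1 for 2 h, then 3 for 2 h (uniform dt)
  dt <- 0.1
  tt <- seq(0, 4 - dt, by = dt)
  phase1 <- seq_along(tt) <= 20 # avoids floating-grid edge effects
  traj <- data.frame(t = tt, growth = 1,
                     R_up = ifelse(phase1, 1, 3), R_bio = 2, R_ngam = 0)
  pa <- phase_average(traj, phase_boundary = mean(tt[20:21]), model = t2)
  expect_equal(pa$phase1$values[["R_up"]], 1)
  expect_equal(pa$phase2$values[["R_up"]], 3)
  expect_equal(pa$phase1$values[["R_bio"]], 2)
  expect_equal(pa$phase2$values[["R_bio"]], 2) # constant flux: both phases

  # linear ramp 0 -> 1 across one phase: time-weighted mean 0.5 +/- dt/2
  traj2 <- data.frame(t = tt, growth = 1, R_up = tt / 4, R_bio = 0,
                      R_ngam = 0)
  pa2 <- phase_average(traj2, phase_boundary = 4, model = t2)
  expect_equal(pa2$phase1$values[["R_up"]], 0.5, tolerance = dt / 2)
  expect_true(all(is.na(pa2$phase2$values))) # empty phase is flagged

  # normalised averages exclude zero-uptake steps
  traj3 <- data.frame(t = tt, growth = 1,
                      R_up = ifelse(tt < 2, 0, 2), R_bio = 1, R_ngam = 0)
  pa3 <- phase_average(traj3, phase_boundary = 4, model = t2,
                       normalise = TRUE)
  expect_equal(pa3$phase1$values[["R_bio"]], 0.5)
})

test_that("per-pathway tabulation sums fractions to one and counts big changes", {
  ch <- data.frame(
    id = paste0("r", 1:6),
    pathway = c("p1", "p1", "p1", "p2", "p2", "p2"),
    v = c(1, 1, 1, 1, 1, 0), v_p = c(3, 1, 0.5, 1, 1, 2),
    delta = c(2, 0, 0.5, 0, 0, NA),
    class = c("increased", "unchanged", "decreased", "unchanged",
              "unchanged", "switched_on"),
    stringsAsFactors = FALSE)
  tab <- classify_and_tabulate(ch)
  p1 <- tab[tab$pathway == "p1", ]
  expect_equal(p1$frac_increased + p1$frac_unchanged + p1$frac_decreased, 1)
  expect_equal(p1$frac_delta_gt_1, 1 / 3)
  p2 <- tab[tab$pathway == "p2", ]
  expect_equal(p2$frac_unchanged, 1)
  expect_identical(p2$n_switched_on, 1L)
  expect_equal(p2$frac_delta_gt_1, 0)

  # all-delta-zero input is 100% unchanged everywhere
  ch0 <- ch
  ch0$delta <- 0
  ch0$class <- "unchanged"
  expect_true(all(classify_and_tabulate(ch0)$frac_unchanged == 1))
})

test_that("normalisation then de-normalisation preserves phase averages", {
  t2 <- make_t2()
  dt <- 0.1
  tt <- seq(0, 2 - dt, by = dt)
  traj <- data.frame(t = tt, growth = 1, R_up = 2, R_bio = 1.5, R_ngam = 0.5)
  pa_abs <- phase_average(traj, 2, t2)
  pa_norm <- phase_average(traj, 2, t2, normalise = TRUE)
  expect_equal(pa_norm$phase1$values * 2, pa_abs$phase1$values)
})
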