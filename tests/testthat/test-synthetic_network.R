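test_that("generated networks validate and are byte-identical per seed", {
  p <- network_preset(seed = 11L)
  m <- generate_network(p)
  expect_identical(nrow(validate_model(m)), 0L)

  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_model_json(generate_network(p), f1)
  write_model_json(generate_network(network_preset(seed = 11L)), f2)
  expect_identical(readLines(f1), readLines(f2))

  # a different seed perturbs kcat/MW but not the topology
  m2 <- generate_network(network_preset(seed = 12L))
  expect_identical(names(m2$reactions), names(m$reactions))
  expect_false(identical(m2$enzymes$HXT$kcat, m$enzymes$HXT$kcat))

  # preset invariants are enforced
  expect_error(network_preset(respiration_atp_yield = 1.5),
               "respiration_atp_yield")
  expect_error(network_preset(enzyme_cost_respiration = 1e-5))
})

test_that("the maximal-growth optimum is Crabtree-like", {
  m <- generate_network(network_preset())
  s <- lexicographic_solve(
    m, optimization_strategy("max_growth", parsimonious = TRUE))
  # fermentation runs (at its capacity) even though glucose is unbounded
  expect_gt(s$v[["pdc"]], 0)
  expect_equal(s$v[["pdc"]], network_preset()$fermentation_capacity,
               tolerance = 1e-6)
  # respiration covers the remaining ATP demand and produces ROS
  expect_gt(s$v[["etc1"]], 0)
  S <- stoich_matrix(m)
  expect_gt(total_production_flux(m, "ROS", s), 0)
  # the enzyme pool is the binding resource
  expect_equal(s$e_pool, enzyme_pool(m), tolerance = 1e-6)
})

test_that("generation emulates the documented pathway structure", {
  m <- generate_network(network_preset())
  pw <- vapply(m$reactions, `[[`, "", "pathway")
  for (need in c("exchange", "glycolysis", "fermentation", "TCA",
                 "oxidative phosphorylation", "oxidative stress",
                 "anaplerotic", "mitochondrial transport", "biomass",
                 "maintenance")) {
    expect_true(need %in% pw, label = paste("pathway", need))
  }
  # the NADH shuttle ships as a split reversible pair, ADH as isoenzymes
  expect_identical(m$reactions$nadh_shuttle_fwd$reversible_parent,
                   "nadh_shuttle")
  expect_identical(m$reactions$adh1$isoenzyme_group, "ADH")
  # every internal (non-exchange) reaction except spontaneous ROS decay is
  # enzyme-coupled
  catalysed <- unique(unlist(lapply(m$enzymes, function(e) names(e$kcat))))
  internal <- setdiff(names(m$reactions),
                      c("ex_glc", "ex_etoh", "ros_leak"))
  expect_true(all(internal %in% catalysed))
  # chain lengths follow the preset
  m4 <- generate_network(network_preset(n_glycolysis_steps = 4,
                                        n_tca_steps = 3))
  expect_true(all(c("glyc3", "glyc4", "tca3") %in% names(m4$reactions)))
  expect_identical(nrow(validate_model(m4)), 0L)
})

test_that("calibration searches the grid and rejects hopeless windows", {
  p <- network_preset()
  ag <- damage_parameters(f_m = 0.022, retention = 0.52,
                          division_biomass = 1.05, ngam0 = 1,
                          ngam_slope = 85)
  # with the wildtype window widened to [1, Inf) the very first grid point
  # succeeds
  cal <- calibrate_wildtype(p, ag, grid = list(),
                            rls_window = c(1, Inf), gt_window = c(0, Inf),
                            max_time = 40)
  expect_gte(cal$result$rls, 1)
  expect_identical(cal$ageing$f_m, ag$f_m)

  # an unreachable window exhausts the grid with diagnostics
  expect_error(
    calibrate_wildtype(p, ag, grid = list(f_m = 10),
                       rls_window = c(20, 30), max_time = 5),
    "calibration error")
})

test_that("heavy damage parameters break the wildtype phenotype", {
  ref <- ref_bundle()
  ag <- ref$ageing
  ag$f_m <- ag$f_m * 10
  ag$retention <- 0.5
  r <- suppressWarnings(
    simulate_lifespan(ref$model, ref$strategy, ag, ref$regulation,
                      max_time = 80, record = FALSE))
  expect_false(classify_wildtype(r))
  expect_lt(r$rls, 20)
})

test_that("the packaged reference bundle matches its generating preset", {
  ref <- ref_bundle()
  expect_identical(nrow(validate_model(ref$model)), 0L)
  regen <- generate_network(network_preset())
  expect_equal(ref$model, regen)
  expect_true(ref$strategy$parsimonious)
  expect_identical(ref$strategy$first, "max_growth")
  expect_equal(ref$ageing$f0, 1e-4)
  expect_equal(ref$ageing$r0, 5e-4)
  expect_equal(ref$regulation$regulation_factor, 0.04)
})
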