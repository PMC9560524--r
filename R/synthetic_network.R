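#' Presets for miniature enzyme-constrained central-carbon networks
#'
#' The generated networks are deliberately small (about 25 reactions, 16
#' metabolites, 20 enzymes) but carry the structural features that the
#' lifespan simulations probe: a glucose exchange and a glycolysis chain to
#' pyruvate; a fermentation branch (pyruvate decarboxylase + two alcohol
#' dehydrogenase isoenzymes exporting ethanol; low ATP yield, no ROS); a
#' respiration branch (mitochondrial pyruvate import, a TCA chain and
#' oxidative phosphorylation; high ATP yield, ROS production proportional
#' to the electron-transport flux); catalase-like and glutathione-like
#' antioxidant reactions plus an uncatalysed ROS decay that represents the
#' protein-damaging fraction; a biomass reaction consuming precursors and
#' ATP through a ribosome-like enzyme; an NGAM reaction consuming ATP; and
#' a reversible cytosolic/mitochondrial NADH shuttle that exercises the
#' reversible-split machinery.
#'
#' Two orderings are structural: respiration yields more ATP per glucose
#' than fermentation, while its enzymes cost more of the protein pool per
#' unit flux.  Together with a finite fermentation (pyruvate-decarboxylase)
#' capacity this makes the maximal-growth optimum Crabtree-like: the cheap
#' fermentation route saturates first and respiration covers the remaining
#' ATP demand, producing ROS.
#'
#' @param name preset name.
#' @param n_glycolysis_steps,n_tca_steps chain lengths (>= 2).
#' @param fermentation_atp_yield net ATP per glucose through fermentation.
#' @param respiration_atp_yield net ATP per glucose through full
#'   respiration (must exceed the fermentation yield; the default is an
#'   effective yield, i.e. it already discounts proton leak and transport
#'   costs).
#' @param ros_per_respiration ROS produced per unit electron-transport
#'   (NADH oxidation) flux.
#' @param antioxidant_capacity upper flux bound of the catalase-like
#'   reaction (the glutathione route gets half of it).
#' @param fermentation_capacity upper flux bound of the pyruvate
#'   decarboxylase step (mmol/gDW/h).
#' @param enzyme_cost_fermentation,enzyme_cost_respiration mean enzyme cost
#'   MW*n/kcat (g h/mmol) of the fermentation branch enzymes and of the
#'   electron-transport chain; respiration must be costlier.
#' @param sigma,f,P_tot enzyme-pool parameters (saturation, covered mass
#'   fraction, total protein g/gDW).
#' @param seed integer seed for the +/-20% kcat/MW perturbation.
#' @return An `agefba_network_preset`.
#' @export
network_preset <- function(name = "wildtype", n_glycolysis_steps = 2,
                           n_tca_steps = 2, fermentation_atp_yield = 2,
                           respiration_atp_yield = 12,
                           ros_per_respiration = 0.05,
                           antioxidant_capacity = 1,
                           fermentation_capacity = 8,
                           enzyme_cost_fermentation = 7.5e-5,
                           enzyme_cost_respiration = 1.5e-3,
                           sigma = 0.35, f = 0.3, P_tot = 0.46, seed = 1L) {
  stopifnot(n_glycolysis_steps >= 2, n_tca_steps >= 2,
            respiration_atp_yield > fermentation_atp_yield,
            enzyme_cost_respiration > enzyme_cost_fermentation,
            ros_per_respiration >= 0, antioxidant_capacity >= 0,
            fermentation_capacity > 0)
  structure(as.list(environment()), class = "agefba_network_preset")
}

# reference enzyme table: MW in kDa, kcat in 1/h.  PDC/ADH and ETC kcats are
# derived from the preset's branch cost parameters.
base_enzyme_table <- function(preset) {
  tab <- data.frame(
    id   = c("HXT", "GLK", "PFK", "PDC", "ADH1", "ADH2", "MPC", "PDH",
             "PYC", "CIT1", "KGD", "NDE", "CPLX1", "CPLX3", "CPLX4",
             "ATPSYN", "RIB", "MAINT", "CTT1", "GPX1"),
    MW   = c(0.06, 0.055, 0.12, 0.06, 0.04, 0.04, 0.03, 0.10,
             0.13, 0.05, 0.10, 0.06, 0.90, 0.50, 0.40,
             0.60, 2.00, 0.05, 0.06, 0.03),
    kcat = c(600, 600, 1200, NA, NA, NA, 200, 300,
             200, 300, 300, 400, NA, NA, NA,
             NA, 60, 1000, 500, 300),
    stringsAsFactors = FALSE)
  tab$kcat[tab$id == "PDC"] <- tab$MW[tab$id == "PDC"] / preset$enzyme_cost_fermentation
  tab$kcat[tab$id == "ADH1"] <- tab$MW[tab$id == "ADH1"] / preset$enzyme_cost_fermentation
  tab$kcat[tab$id == "ADH2"] <- 0.8 * tab$kcat[tab$id == "ADH1"]
  # the respiratory-chain cost is split evenly over the four complexes
  for (cx in c("CPLX1", "CPLX3", "CPLX4", "ATPSYN")) {
    tab$kcat[tab$id == cx] <- tab$MW[tab$id == cx] /
      (preset$enzyme_cost_respiration / 4)
  }
  tab
}

with_preset_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a miniature central-carbon network from a preset
#'
#' Topology is fixed per preset; the seed only perturbs kcat and MW values
#' within +/-20% of the reference table, so pathway-level behaviour is
#' stable across seeds and the output is byte-identical for identical
#' presets.
#'
#' @param preset an [network_preset()].
#' @return A valid `agefba_model` in irreversible form.
#' @export
generate_network <- function(preset) {
  stopifnot(inherits(preset, "agefba_network_preset"))
  Yf <- preset$fermentation_atp_yield
  p_atp <- (preset$respiration_atp_yield - Yf - 2) / 12
  if (p_atp <= 0) stop("respiration_atp_yield too low for the fixed TCA/ETC topology")
  rho <- preset$ros_per_respiration

  ngly <- preset$n_glycolysis_steps
  gly_int <- c("G6P", if (ngly > 2) paste0("GLY_I", seq_len(ngly - 2)))
  ntca <- preset$n_tca_steps
  tca_int <- c("CIT_m", if (ntca > 2) paste0("TCA_I", seq_len(ntca - 2)))

  mets <- data.frame(
    id = c("GLC", gly_int, "PYR_c", "ACA", "ETOH", "PYR_m", "ACCOA_m",
           "OAA_m", tca_int, "NADH_c", "NADH_m", "QH2_m", "CYTC_m", "PMF_m",
           "ATP", "ROS"),
    stringsAsFactors = FALSE)
  mets$name <- mets$id
  mets$compartment <- ifelse(grepl("_m$", mets$id), "m", "c")

  rxns <- list(
    reaction("ex_glc", c(GLC = 1), pathway = "exchange",
             name = "glucose uptake"),
    reaction("ex_etoh", c(ETOH = -1), pathway = "exchange",
             name = "ethanol export"))
  # glycolysis chain: GLC + ATP -> ... -> 2 PYR + (1 + Yf) ATP + 2 NADH_c
  gly_nodes <- c("GLC", gly_int)
  for (k in seq_len(ngly)) {
    id <- paste0("glyc", k)
    if (k == 1) {
      st <- setNames(c(-1, -1, 1), c("GLC", "ATP", gly_int[1]))
    } else if (k < ngly) {
      st <- setNames(c(-1, 1), c(gly_int[k - 1], gly_int[k]))
    } else {
      st <- setNames(c(-1, 2, 1 + Yf, 2),
                     c(gly_int[ngly - 1], "PYR_c", "ATP", "NADH_c"))
    }
    rxns <- c(rxns, list(reaction(id, st, pathway = "glycolysis")))
  }
  rxns <- c(rxns, list(
    reaction("pdc", c(PYR_c = -1, ACA = 1), pathway = "fermentation",
             upper_bound = preset$fermentation_capacity,
             name = "pyruvate decarboxylase"),
    reaction("adh1", c(ACA = -1, NADH_c = -1, ETOH = 1),
             pathway = "fermentation", isoenzyme_group = "ADH",
             name = "alcohol dehydrogenase 1"),
    reaction("adh2", c(ACA = -1, NADH_c = -1, ETOH = 1),
             pathway = "fermentation", isoenzyme_group = "ADH",
             name = "alcohol dehydrogenase 2"),
    reaction("mpc", c(PYR_c = -1, PYR_m = 1),
             pathway = "mitochondrial transport",
             name = "mitochondrial pyruvate carrier"),
    reaction("pdh", c(PYR_m = -1, ACCOA_m = 1, NADH_m = 1), pathway = "TCA",
             name = "pyruvate dehydrogenase"),
    reaction("pyc", c(PYR_m = -1, ATP = -1, OAA_m = 1),
             pathway = "anaplerotic", name = "pyruvate carboxylase"),
    reaction("nadh_shuttle", c(NADH_c = -1, NADH_m = 1),
             lower_bound = -1000, upper_bound = 1000,
             pathway = "mitochondrial transport",
             name = "cytosolic/mitochondrial NADH shuttle")))
  # TCA chain: ACCOA + OAA -> ... -> OAA + 4 NADH_m + 1 ATP
  tca_nodes <- tca_int
  for (k in seq_len(ntca)) {
    id <- paste0("tca", k)
    if (k == 1) {
      st <- setNames(c(-1, -1, 1), c("ACCOA_m", "OAA_m", tca_int[1]))
    } else if (k < ntca) {
      st <- setNames(c(-1, 1), c(tca_int[k - 1], tca_int[k]))
    } else {
      st <- setNames(c(-1, 1, 4, 1),
                     c(tca_int[ntca - 1], "OAA_m", "NADH_m", "ATP"))
    }
    rxns <- c(rxns, list(reaction(id, st, pathway = "TCA")))
  }
  # oxidative phosphorylation as the complex chain I -> III -> IV -> ATP
  # synthase; ROS arises at complex I, proportional to the electron flux
  rxns <- c(rxns, list(
    reaction("etc1", setNames(c(-1, 1, rho), c("NADH_m", "QH2_m", "ROS")),
             pathway = "oxidative phosphorylation",
             name = "NADH dehydrogenase (complex I-like)"),
    reaction("etc3", c(QH2_m = -1, CYTC_m = 1),
             pathway = "oxidative phosphorylation",
             name = "cytochrome bc1 (complex III-like)"),
    reaction("etc4", c(CYTC_m = -1, PMF_m = 1),
             pathway = "oxidative phosphorylation",
             name = "cytochrome c oxidase (complex IV-like)"),
    reaction("atp_synthase", setNames(c(-1, p_atp), c("PMF_m", "ATP")),
             pathway = "oxidative phosphorylation",
             name = "ATP synthase"),
    reaction("ctt", c(ROS = -1), pathway = "oxidative stress",
             upper_bound = preset$antioxidant_capacity,
             name = "catalase-like ROS removal"),
    reaction("gpx", c(ROS = -1, NADH_c = -0.5), pathway = "oxidative stress",
             upper_bound = preset$antioxidant_capacity / 2,
             name = "glutathione-like ROS removal"),
    reaction("ros_leak", c(ROS = -1), pathway = "oxidative stress",
             name = "spontaneous (protein-damaging) ROS decay"),
    reaction("biomass",
             c(G6P = -0.3, PYR_c = -0.2, ACCOA_m = -0.1, OAA_m = -0.05,
               ATP = -25), pathway = "biomass", name = "biomass synthesis"),
    reaction("ngam", c(ATP = -1), pathway = "maintenance",
             name = "non-growth associated maintenance")))

  tab <- base_enzyme_table(preset)
  with_preset_seed(preset$seed, {
    pert <- function(x) x * runif(length(x), 0.8, 1.2)
    tab$kcat <- pert(tab$kcat)
    tab$MW <- pert(tab$MW)
  })
  catalysed <- list(
    HXT = "ex_glc", GLK = "glyc1", PFK = paste0("glyc", 2:ngly),
    PDC = "pdc", ADH1 = "adh1", ADH2 = "adh2", MPC = "mpc", PDH = "pdh",
    PYC = "pyc", CIT1 = "tca1", KGD = paste0("tca", 2:ntca),
    NDE = "nadh_shuttle", CPLX1 = "etc1", CPLX3 = "etc3", CPLX4 = "etc4",
    ATPSYN = "atp_synthase", RIB = "biomass", MAINT = "ngam",
    CTT1 = "ctt", GPX1 = "gpx")
  enzymes <- lapply(tab$id, function(id) {
    row <- tab[tab$id == id, ]
    rids <- catalysed[[id]]
    enzyme(id, MW = row$MW, kcat = setNames(rep(row$kcat, length(rids)), rids))
  })

  model <- metabolic_model(
    metabolites = mets, reactions = rxns, enzymes = enzymes,
    sigma = preset$sigma, f = preset$f, P_tot = preset$P_tot,
    named_reactions = list(biomass = "biomass", glucose_uptake = "ex_glc",
                           ngam = "ngam"),
    reaction_sets = list(
      atp_producing = c(paste0("glyc", ngly), paste0("tca", ntca),
                        "atp_synthase"),
      nadh_producing = paste0("glyc", ngly),
      ros_producing = "etc1",
      antioxidant = c("ctt", "gpx")))
  model <- split_reversible(model)
  issues <- validate_model(model)
  if (any(issues$severity == "error")) {
    stop("generation error: preset yields an invalid model:\n",
         paste(issues$message[issues$severity == "error"], collapse = "\n"))
  }
  model
}

#' Calibrate a wildtype-producing parameter set
#'
#' Grid search over the free ageing parameters (`f_m`, `division_biomass`,
#' `ngam_slope`, `retention`) until the simulated cell falls into the
#' wildtype window: 20-30 divisions with a mean generation time of
#' 1.5-2.3 h.  The search is deterministic; the first grid point inside the
#' window (in grid order) is returned together with its simulation.
#'
#' @param preset an [network_preset()].
#' @param ageing starting [damage_parameters()]; grid values override its
#'   fields.
#' @param strategy reference strategy (default parsimonious maximal
#'   growth).
#' @param grid named list of candidate vectors for any of `f_m`,
#'   `division_biomass`, `ngam_slope`, `retention`.
#' @param regulation an [regulation_config()] or `NULL`.
#' @param max_time horizon per candidate simulation.
#' @param rls_window,gt_window acceptance windows (defaults 20-30 divisions
#'   and 1.5-2.3 h).
#' @return List with `preset`, `ageing` (calibrated), `result` (the
#'   calibrated simulation) and `trace` (per-candidate diagnostics).
#'   Exhausting the grid without a hit is an error carrying the best-found
#'   diagnostics.
#' @export
calibrate_wildtype <- function(preset, ageing = damage_parameters(),
                               strategy = optimization_strategy(
                                 "max_growth", parsimonious = TRUE),
                               grid = list(),
                               regulation = regulation_config(),
                               max_time = 200,
                               rls_window = c(20, 30),
                               gt_window = c(1.5, 2.3)) {
  model <- generate_network(preset)
  fields <- c("f_m", "division_biomass", "ngam_slope", "retention")
  cand <- lapply(fields, function(f) grid[[f]] %||% ageing[[f]])
  names(cand) <- fields
  combos <- do.call(expand.grid, c(cand, KEEP.OUT.ATTRS = FALSE))
  trace <- list()
  best <- NULL
  best_score <- Inf
  for (i in seq_len(nrow(combos))) {
    params <- ageing
    for (f in fields) params[[f]] <- combos[[f]][i]
    res <- simulate_lifespan(model, strategy, params, regulation,
                             max_time = max_time, record = FALSE)
    gt <- res$mean_generation_time
    ok <- !is.na(gt) && res$rls >= rls_window[1] && res$rls <= rls_window[2] &&
      gt >= gt_window[1] && gt <= gt_window[2]
    trace[[i]] <- cbind(combos[i, , drop = FALSE],
                        data.frame(rls = res$rls,
                                   mean_generation_time = gt,
                                   wildtype = ok))
    if (ok) {
      return(list(preset = preset, ageing = params, result = res,
                  trace = do.call(rbind, trace)))
    }
    score <- abs(res$rls - mean(rls_window)) / diff(rls_window) +
      if (is.na(gt)) 10 else abs(gt - mean(gt_window)) / diff(gt_window)
    if (score < best_score) {
      best_score <- score
      best <- trace[[i]]
    }
  }
  stop("calibration error: no grid point reached the wildtype window; ",
       "best candidate: ",
       paste(sprintf("%s=%g", names(best), unlist(best[1, ])), collapse = ", "))
}

#' The packaged calibrated reference cell
#'
#' Loads the calibrated synthetic network and parameter bundle shipped with
#' the package: a cell that, simulated under the parsimonious
#' maximal-growth strategy, divides 20-30 times with a mean generation time
#' of 1.5-2.3 h.
#'
#' @return List with `model`, `ageing`, `strategy`, `regulation`.
#' @export
reference_cell <- function() {
  path <- system.file("extdata", "reference_cell.json", package = "agefba",
                      mustWork = TRUE)
  obj <- jsonlite::read_json(path)
  model <- model_from_list(obj$model)
  ageing <- do.call(damage_parameters, lapply(obj$ageing, as.numeric))
  strategy <- do.call(optimization_strategy, obj$strategy)
  list(model = model, ageing = ageing, strategy = strategy,
       regulation = regulation_config())
}

#' Write a reference-cell bundle (model + parameters) to JSON
#'
#' @param model an `agefba_model` (irreversible form).
#' @param ageing an [damage_parameters()].
#' @param strategy an [optimization_strategy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_cell <- function(model, ageing, strategy, path) {
  obj <- list(model = model_to_list(model),
              ageing = unclass(ageing),
              strategy = Filter(Negate(is.null), unclass(strategy)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
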