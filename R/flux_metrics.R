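#' Collapse split reversible pairs and isoenzyme groups
#'
#' Maps an irreversible flux vector back to the reversible network:
#' forward/backward split pairs are merged as `v_fwd - v_bwd` (so collapsed
#' fluxes may be negative), and reactions sharing an `isoenzyme_group` are
#' summed into a single entry to avoid double-counting.  Pathway labels are
#' carried over; a group with inconsistent labels is an error.  The
#' operation is idempotent.
#'
#' @param model an `agefba_model` in irreversible form.
#' @param v named flux vector (e.g. `solution$v`), or an
#'   `agefba_flux_solution`.
#' @return An `agefba_collapsed_fluxes`: list with `values` (named numeric)
#'   and `pathway` (named character).
#' @export
collapse_fluxes <- function(model, v) {
  if (inherits(v, "agefba_flux_solution")) v <- v$v
  key <- vapply(model$reactions, function(r) {
    if (!is.null(r$isoenzyme_group)) r$isoenzyme_group
    else if (!is.null(r$reversible_parent)) r$reversible_parent
    else r$id
  }, "")
  sign <- vapply(model$reactions, function(r) {
    if (!is.null(r$reversible_parent) && endsWith(r$id, "_bwd")) -1 else 1
  }, 0)
  pathway <- vapply(model$reactions, `[[`, "", "pathway")
  ids <- unique(key)
  if (!all(names(key) %in% names(v)) && all(ids %in% names(v))) {
    # already-collapsed input: the operation is idempotent
    values <- v[ids]
  } else {
    values <- vapply(ids, function(k) {
      sum(sign[key == k] * v[names(key)[key == k]])
    }, 0)
  }
  pw <- vapply(ids, function(k) {
    labs <- unique(pathway[key == k])
    if (length(labs) > 1) {
      stop("inconsistent pathway labels within collapsed group '", k, "'")
    }
    labs
  }, "")
  structure(list(values = values, pathway = pw),
            class = "agefba_collapsed_fluxes")
}

#' Relative flux change between two solutions
#'
#' Computes `Delta_i = |v_i^p - v_i| / |v_i|` per collapsed reaction.  Both
#' zero gives `Delta = 0` (`unchanged`); a flux switched off (`v_i != 0`,
#' `v_i^p = 0`) is classified `decreased` with `Delta = 1`; a flux switched
#' on (`v_i = 0`, `v_i^p != 0`) has no defined `Delta` and is flagged
#' `switched_on` (excluded from distributions, counted separately).
#' Direction (`increased`/`decreased`) is read off the signed fluxes;
#' `unchanged` means `Delta` at or below the tie tolerance.
#'
#' @param v,v_p `agefba_collapsed_fluxes` for the reference and the
#'   comparison solution (identical id sets).
#' @param tie_tol relative tie tolerance for `unchanged` (default 1e-6).
#' @return Data frame with columns `id`, `pathway`, `v`, `v_p`, `delta`
#'   (`NA` where undefined) and `class` in
#'   `{increased, unchanged, decreased, switched_on}`.
#' @export
relative_change <- function(v, v_p, tie_tol = 1e-6) {
  if (!identical(sort(names(v$values)), sort(names(v_p$values)))) {
    stop("collapsed flux vectors have mismatching id sets")
  }
  ids <- names(v$values)
  a <- v$values[ids]
  b <- v_p$values[ids]
  delta <- ifelse(a == 0 & b == 0, 0, abs(b - a) / abs(a))
  cls <- character(length(ids))
  for (i in seq_along(ids)) {
    if (a[i] == 0 && b[i] != 0) {
      # undefined by the formula; reported separately, never given a Delta
      cls[i] <- "switched_on"
      delta[i] <- NA_real_
    } else if (a[i] != 0 && b[i] == 0) {
      # the switched-off sentinel: signed change -1, i.e. decreased, Delta 1
      cls[i] <- "decreased"
      delta[i] <- 1
    } else if (delta[i] <= tie_tol) {
      cls[i] <- "unchanged"
    } else {
      # signed relative change (v_p - v)/|v|: positive means increase
      cls[i] <- if ((b[i] - a[i]) / abs(a[i]) > 0) "increased" else "decreased"
    }
  }
  data.frame(id = ids, pathway = unname(v$pathway[ids]), v = unname(a),
             v_p = unname(b), delta = unname(delta), class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalise collapsed fluxes by the glucose uptake rate
#'
#' @param v an `agefba_collapsed_fluxes`.
#' @param glucose_uptake nonnegative uptake flux.  Zero uptake flags every
#'   value as undefined (`NA`), to be excluded from phase averages.
#' @return The normalised `agefba_collapsed_fluxes`.
#' @export
normalize_by_glucose <- function(v, glucose_uptake) {
  stopifnot(glucose_uptake >= 0)
  v$values <- if (glucose_uptake == 0) {
    setNames(rep(NA_real_, length(v$values)), names(v$values))
  } else {
    v$values / glucose_uptake
  }
  v
}

#' Time-weighted phase averages of a flux trajectory
#'
#' Averages every reaction flux of a lifespan trajectory within phase I
#' (`t <= boundary`) and phase II (`t > boundary`) separately, either
#' time-weighted (default) or per-step unweighted, and either absolute or
#' normalised by the per-step glucose uptake (steps with zero uptake are
#' excluded from the normalised average).
#'
#' @param trajectory a lifespan trajectory (data frame with `t` and one
#'   column per reaction id).
#' @param phase_boundary phase-I/II boundary in h.
#' @param model an `agefba_model` (identifies reaction columns and the
#'   glucose uptake reaction).
#' @param normalise divide each step's fluxes by its glucose uptake.
#' @param time_weighted weight steps by their duration (default `TRUE`).
#' @return List of two `agefba_collapsed_fluxes` (`phase1`, `phase2`); an
#'   empty phase yields `NA` values.
#' @export
phase_average <- function(trajectory, phase_boundary, model,
                          normalise = FALSE, time_weighted = TRUE) {
  rids <- intersect(names(model$reactions), colnames(trajectory))
  t <- trajectory$t
  w <- if (time_weighted) c(diff(t), tail(diff(t), 1)) else rep(1, length(t))
  if (length(t) == 1) w <- 1
  V <- as.matrix(trajectory[, rids, drop = FALSE])
  if (normalise) {
    upt <- trajectory[[model$named_reactions$glucose_uptake]]
    ok <- upt > 0
    V <- sweep(V, 1, ifelse(ok, upt, NA_real_), "/")
  }
  avg_phase <- function(sel) {
    if (!any(sel)) {
      return(setNames(rep(NA_real_, length(rids)), rids))
    }
    apply(V[sel, , drop = FALSE], 2, function(col) {
      keep <- !is.na(col)
      if (!any(keep)) return(NA_real_)
      sum(col[keep] * w[sel][keep]) / sum(w[sel][keep])
    })
  }
  mk <- function(vals) collapse_fluxes(model, vals)
  list(phase1 = mk(avg_phase(t <= phase_boundary)),
       phase2 = mk(avg_phase(t > phase_boundary)))
}

#' Per-pathway summary of flux changes
#'
#' Tabulates, per pathway, the fractions of (defined) fluxes that are
#' increased, unchanged or decreased, the quartiles of the `Delta`
#' distribution, and the fraction with `Delta > 1` (changed by more than
#' 100%).  Switched-on entries are counted separately and excluded from the
#' fractions and quartiles.
#'
#' @param changes a data frame from [relative_change()].
#' @return Data frame with one row per pathway.
#' @export
classify_and_tabulate <- function(changes) {
  split_rows <- split(changes, changes$pathway)
  out <- lapply(names(split_rows), function(pw) {
    ch <- split_rows[[pw]]
    defined <- ch[ch$class != "switched_on", , drop = FALSE]
    n <- nrow(defined)
    q <- if (n > 0) {
      quantile(defined$delta, c(0.25, 0.5, 0.75), na.rm = TRUE)
    } else {
      rep(NA_real_, 3)
    }
    data.frame(
      pathway = pw, n = n, n_switched_on = sum(ch$class == "switched_on"),
      frac_increased = if (n > 0) mean(defined$class == "increased") else NA,
      frac_unchanged = if (n > 0) mean(defined$class == "unchanged") else NA,
      frac_decreased = if (n > 0) mean(defined$class == "decreased") else NA,
      delta_q25 = unname(q[1]), delta_median = unname(q[2]),
      delta_q75 = unname(q[3]),
      frac_delta_gt_1 = if (n > 0) mean(defined$delta > 1) else NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Phase-resolved flux-rewiring comparison of two lifespan simulations
#'
#' The full comparison pipeline: phase-average both trajectories (fluxes
#' normalised by the glucose uptake rate per step), collapse to the
#' reversible/isoenzyme-free network, compute relative changes per phase,
#' and return the long table that the per-pathway summaries are built from.
#'
#' @param result_a,result_b `agefba_lifespan` results (a = reference, b =
#'   comparison, e.g. non-parsimonious vs parsimonious).
#' @param model the common `agefba_model`.
#' @param normalise normalise fluxes by glucose uptake (default `TRUE`).
#' @return Data frame with columns `id`, `pathway`, `phase`, `v`, `v_p`,
#'   `delta`, `class`.
#' @export
compare_flux_rewiring <- function(result_a, result_b, model,
                                  normalise = TRUE) {
  pa <- phase_average(result_a$trajectory, result_a$phase_boundary, model,
                      normalise = normalise)
  pb <- phase_average(result_b$trajectory, result_b$phase_boundary, model,
                      normalise = normalise)
  out <- lapply(c("phase1", "phase2"), function(ph) {
    a <- pa[[ph]]
    b <- pb[[ph]]
    keep <- !is.na(a$values) & !is.na(b$values)
    a$values <- a$values[keep]; a$pathway <- a$pathway[keep]
    b$values <- b$values[keep]; b$pathway <- b$pathway[keep]
    if (length(a$values) == 0) return(NULL)
    ch <- relative_change(a, b)
    ch$phase <- ph
    ch
  })
  out <- do.call(rbind, out)
  out[, c("id", "pathway", "phase", "v", "v_p", "delta", "class")]
}
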