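#' Simulation configuration
#'
#' Collects the tunable parameters of a dynamic simulation.
#'
#' @param dt Time step (hours). Default 1.
#' @param t_end Simulation horizon (hours).
#' @param death_rate First-order biomass death rate `d` (1/hr), default
#'   0.06.
#' @param volume Working volume (liters), default 1: concentrations in mM
#'   then equal mmol pools.
#' @param clamp Named numeric vector of metabolite concentrations (mM) held
#'   fixed, reset at every step (e.g. `c(o2 = 10)` for controlled dissolved
#'   oxygen).
#' @param rmf_mode How the required biomass flux is derived:
#'   `"od_derived"` uses the measured growth curve via
#'   [biomass_rmf_bound()]; `"fraction_of_max"` requires a fraction
#'   `rmf_fraction` of the FBA maximum.
#' @param rmf_fraction Fraction `p` in (0, 1] for `"fraction_of_max"`,
#'   default 0.5.
#' @param rmf_bound `"pin"` fixes the biomass flux to the derived value
#'   (growth measurements impose a magnitude, the default in od_derived
#'   mode); `"floor"` only bounds it from below (classic behavior,
#'   the default for fraction_of_max).
#' @param death_in_update Apply the death term `-d * BM * dt` in the
#'   biomass update (default `TRUE`).
#' @param od_scale Conversion factor OD -> gDW (default 1: biomass carried
#'   in OD units).
#' @param epsilon_lock Relative slack when the stage-1 optimum is locked in
#'   stage 2, default `1e-9`.
#' @param solver_tolerance Feasibility tolerance for reported solutions,
#'   default `1e-9`.
#' @param infeasible_action When the required biomass flux exceeds model
#'   capacity: `"relax"` (default) lowers it to the achievable maximum and
#'   flags the step `"relaxed"`; `"error"` aborts.
#' @return Object of class `team_config`.
#' @export
team_config <- function(dt = 1, t_end = 50, death_rate = 0.06, volume = 1,
                        clamp = c(), rmf_mode = c("od_derived",
                                                  "fraction_of_max"),
                        rmf_fraction = 0.5, rmf_bound = NULL,
                        death_in_update = TRUE, od_scale = 1,
                        epsilon_lock = 1e-9, solver_tolerance = 1e-9,
                        infeasible_action = c("relax", "error")) {
  rmf_mode <- match.arg(rmf_mode)
  infeasible_action <- match.arg(infeasible_action)
  if (is.null(rmf_bound)) {
    rmf_bound <- if (rmf_mode == "od_derived") "pin" else "floor"
  }
  rmf_bound <- match.arg(rmf_bound, c("pin", "floor"))
  stopifnot(dt > 0, t_end >= 0, death_rate >= 0, volume > 0,
            rmf_fraction > 0, rmf_fraction <= 1, od_scale > 0,
            epsilon_lock >= 0)
  structure(list(dt = dt, t_end = t_end, death_rate = death_rate,
                 volume = volume, clamp = clamp, rmf_mode = rmf_mode,
                 rmf_fraction = rmf_fraction, rmf_bound = rmf_bound,
                 death_in_update = death_in_update, od_scale = od_scale,
                 epsilon_lock = epsilon_lock,
                 solver_tolerance = solver_tolerance,
                 infeasible_action = infeasible_action),
            class = "team_config")
}

#' Initialize the simulation state
#'
#' Sets extracellular concentrations from the starting media (unlisted
#' metabolites start at 0), applies clamps, and sets the initial biomass
#' from the initial optical density.
#'
#' @param model A [stoich_model()].
#' @param media Named numeric vector or `data.frame(metabolite, mM)` of
#'   initial concentrations.
#' @param od0 Initial optical density (> 0).
#' @param config A [team_config()].
#' @return `list(t, e, BM)` of class `team_state`.
#' @export
initialize_state <- function(model, media, od0, config = team_config()) {
  stopifnot(inherits(model, "stoich_model"))
  if (is.data.frame(media)) {
    media <- stats::setNames(as.numeric(media[[2]]),
                             as.character(media[[1]]))
  }
  if (!is.numeric(od0) || length(od0) != 1 || od0 <= 0) {
    stop("od0 must be a single positive number", call. = FALSE)
  }
  unknown <- setdiff(names(media), model$met_ids)
  if (length(unknown) > 0) {
    stop("unknown metabolite id(s) in media: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  e <- stats::setNames(numeric(length(model$met_ids)), model$met_ids)
  e[names(media)] <- as.numeric(media)
  if (length(config$clamp) > 0) {
    unknown <- setdiff(names(config$clamp), model$met_ids)
    if (length(unknown) > 0) {
      stop("unknown clamped metabolite id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    e[names(config$clamp)] <- as.numeric(config$clamp)
  }
  if (any(e < 0)) stop("negative media concentration", call. = FALSE)
  structure(list(t = 0, e = e, BM = od0 * config$od_scale),
            class = "team_state")
}

#' Exchange-flux bounds from the current media pools
#'
#' Uptake of a metabolite in one step cannot exceed its extracellular pool:
#' the exchange flux of metabolite `i` is bounded below by
#' `-e_i * volume / dt` (mmol/hr). Clamped metabolites use their clamp
#' concentration every step. Model default exchange bounds are kept where
#' tighter.
#'
#' @param model A [stoich_model()].
#' @param state A `team_state` (or any list with element `e`).
#' @param config A [team_config()].
#' @param lb,ub Current full bound vectors to refine (default: the model's
#'   specific bounds).
#' @return `list(lb, ub)` over all reactions.
#' @export
media_exchange_bounds <- function(model, state, config = team_config(),
                                  lb = model$lb0, ub = model$ub0) {
  e <- state$e
  if (length(config$clamp) > 0) e[names(config$clamp)] <- config$clamp
  pool_rate <- e * config$volume / config$dt
  for (j in which(model$exchange)) {
    i <- model$exchange_met[[model$rxn_ids[j]]]
    s <- model$S[i, j]
    if (s < 0) {        # positive flux secretes: uptake limited from below
      lb[j] <- max(lb[j], -pool_rate[i])
      if (lb[j] > ub[j]) ub[j] <- lb[j]
    } else {            # positive flux takes up
      ub[j] <- min(ub[j], pool_rate[i])
      if (ub[j] < lb[j]) lb[j] <- ub[j]
    }
  }
  list(lb = lb, ub = ub)
}

#' Convert specific flux bounds to total bounds
#'
#' Biological reaction bounds are specific (mmol/gDW/hr); multiplying by
#' the current biomass gives total bounds (mmol/hr) so that media pools and
#' fluxes share units. Exchange bounds are already total and are left
#' unscaled.
#'
#' @param model A [stoich_model()].
#' @param BM Current biomass (gDW), > 0.
#' @return `list(lb, ub)` over all reactions.
#' @export
scale_bounds_to_total <- function(model, BM) {
  stopifnot(BM > 0)
  lb <- model$lb0
  ub <- model$ub0
  bio <- !model$exchange
  lb[bio] <- lb[bio] * BM
  ub[bio] <- ub[bio] * BM
  list(lb = lb, ub = ub)
}

#' Required biomass flux from growth measurements
#'
#' With a measured growth curve (od_derived mode), the biomass flux over
#' `[t, t + dt]` must at least reproduce the observed net growth plus the
#' replacement of death losses:
#' `lb_BM = (OD(t+dt) - OD(t)) / dt + d * BM(t)`, floored at 0.
#' In fraction_of_max mode the requirement is `p` times the FBA maximum of
#' the biomass flux under the current bounds.
#'
#' @param od A function of time, or `data.frame(time, od)` interpolated
#'   piecewise-linearly; must cover `[t, t + dt]`.
#' @param t Current time (hours).
#' @param BM Current simulated biomass.
#' @param config A [team_config()].
#' @param model,lb,ub Needed for `"fraction_of_max"` mode only.
#' @return Scalar required biomass flux (mmol/hr equivalent).
#' @export
biomass_rmf_bound <- function(od, t, BM, config = team_config(),
                              model = NULL, lb = NULL, ub = NULL) {
  if (config$rmf_mode == "fraction_of_max") {
    stopifnot(!is.null(model))
    vmax <- fba_max_flux(model$S, lb, ub, model$biomass)
    if (is.na(vmax)) stop("infeasible model while computing max biomass",
                          call. = FALSE)
    return(config$rmf_fraction * vmax)
  }
  od_fun <- if (is.function(od)) od else {
    tt <- as.numeric(od[[1]]); vv <- as.numeric(od[[2]])
    function(x) stats::approx(tt, vv, xout = x, rule = 1)$y
  }
  o1 <- od_fun(t); o2 <- od_fun(t + config$dt)
  if (is.na(o1) || is.na(o2)) {
    stop("growth curve does not cover [", t, ", ", t + config$dt, "]",
         call. = FALSE)
  }
  max(0, (o2 - o1) / config$dt * config$od_scale +
        config$death_rate * BM)
}

#' Stage 1: minimize inconsistency with gene expression
#'
#' Solves `min sum_i c_i |V_i|` subject to `S V = 0` and the current
#' bounds. Reactions penalized by low expression of their genes are used as
#' little as possible while meeting the required metabolic functionality
#' encoded in the bounds (notably the biomass requirement).
#'
#' @param model A [stoich_model()].
#' @param lb,ub Current total-flux bounds.
#' @param c_pen Per-reaction penalties `c_i >= 0`.
#' @return `list(V, inconsistency, total_flux, status)` (class
#'   `flux_solution`).
#' @export
solve_min_inconsistency <- function(model, lb, ub, c_pen) {
  stopifnot(all(c_pen >= 0), length(c_pen) == length(model$rxn_ids))
  res <- solve_flux_lp(model$S, lb, ub, abs_w = c_pen)
  structure(list(V = stats::setNames(res$V, model$rxn_ids),
                 inconsistency = sum(c_pen * abs(res$V)),
                 total_flux = sum(abs(res$V)),
                 status = res$status), class = "flux_solution")
}

#' Stage 2: minimize total flux at fixed inconsistency
#'
#' Among the (typically many) flux distributions attaining the stage-1
#' optimum, selects a parsimonious one: `min sum_i |V_i|` subject to
#' `S V = 0`, bounds, and `sum_i c_i |V_i| <= inconsistency_star +
#' epsilon_lock`. Futile cycles are suppressed because they add total flux
#' without changing mass balance.
#'
#' @inheritParams solve_min_inconsistency
#' @param inconsistency_star Stage-1 optimal inconsistency.
#' @param epsilon_lock Relative lock slack (default from [team_config()]).
#' @return `list(V, inconsistency, total_flux, status)`.
#' @export
solve_min_total_flux <- function(model, lb, ub, c_pen, inconsistency_star,
                                 epsilon_lock = 1e-9) {
  slack <- epsilon_lock * (1 + abs(inconsistency_star))
  res <- solve_flux_lp(model$S, lb, ub,
                       abs_w = rep(1, length(model$rxn_ids)),
                       lock_w = c_pen,
                       lock_rhs = inconsistency_star + slack)
  structure(list(V = stats::setNames(res$V, model$rxn_ids),
                 inconsistency = sum(c_pen * abs(res$V)),
                 total_flux = sum(abs(res$V)),
                 status = res$status), class = "flux_solution")
}

#' Advance media concentrations and biomass by one step
#'
#' Forward-Euler update: each exchanged metabolite changes by its net
#' secretion rate times `dt / volume`; concentrations are floored at 0
#' (flooring events counted); clamped metabolites are reset. Biomass is
#' updated with the realized biomass flux minus death losses:
#' `BM' = BM + V_BM dt - d BM dt`.
#'
#' @param state A `team_state`.
#' @param model A [stoich_model()].
#' @param V Named flux vector from the current step's solution.
#' @param config A [team_config()].
#' @return Updated `team_state` with attribute `floored` (metabolite ids
#'   floored this step).
#' @export
update_state <- function(state, model, V, config = team_config()) {
  e <- state$e
  for (j in which(model$exchange)) {
    i <- model$exchange_met[[model$rxn_ids[j]]]
    secretion <- -model$S[i, j] * V[[model$rxn_ids[j]]]
    e[i] <- e[i] + secretion * config$dt / config$volume
  }
  floored <- names(e)[e < 0]
  e[e < 0] <- 0
  if (length(config$clamp) > 0) e[names(config$clamp)] <- config$clamp
  v_bm <- V[[model$rxn_ids[model$biomass]]]
  BM <- state$BM + v_bm * config$dt -
    (if (config$death_in_update) config$death_rate * state$BM * config$dt
     else 0)
  structure(list(t = state$t + config$dt, e = e, BM = BM),
            class = "team_state", floored = floored)
}

# Shared stepping loop for run_team and run_dfba. `penalty_fun(t_index)`
# returns list(p_g, c) or NULL (dFBA).
run_dynamic <- function(model, od, media, config, penalty_fun = NULL,
                        objective = c("inconsistency", "max_biomass"),
                        od0 = NULL) {
  objective <- match.arg(objective)
  stopifnot(inherits(model, "stoich_model"), !is.na(model$biomass))
  grid <- seq(0, config$t_end, by = config$dt)
  n_steps <- length(grid) - 1L
  od_fun <- if (is.function(od)) od else if (!is.null(od)) {
    tt <- as.numeric(od[[1]]); vv <- as.numeric(od[[2]])
    function(x) stats::approx(tt, vv, xout = x, rule = 1)$y
  } else NULL
  if (is.null(od0)) {
    od0 <- if (!is.null(od_fun)) od_fun(0) else 1
  }
  state <- initialize_state(model, media, od0, config)
  nr <- length(model$rxn_ids)
  conc <- matrix(NA_real_, n_steps + 1L, length(model$met_ids),
                 dimnames = list(NULL, model$met_ids))
  biomass <- numeric(n_steps + 1L)
  flux <- matrix(NA_real_, max(n_steps, 0L), nr,
                 dimnames = list(NULL, model$rxn_ids))
  cmat <- flux
  inconsistency <- rep(NA_real_, n_steps)
  total_flux <- rep(NA_real_, n_steps)
  rmf <- rep(NA_real_, n_steps)
  status <- rep(NA_character_, n_steps)
  p_list <- vector("list", n_steps)
  conc[1L, ] <- state$e
  biomass[1L] <- state$BM
  floored <- character(0)
  for (k in seq_len(n_steps)) {
    t <- grid[k]
    b <- scale_bounds_to_total(model, state$BM)
    b <- media_exchange_bounds(model, state, config, b$lb, b$ub)
    lb <- b$lb; ub <- b$ub
    target <- biomass_rmf_bound(od_fun, t, state$BM, config,
                                model = model, lb = lb, ub = ub)
    st <- "optimal"
    vmax <- fba_max_flux(model$S, lb, ub, model$biomass)
    if (is.na(vmax)) {
      stop("infeasible step at t = ", t, " (no feasible flux state)",
           call. = FALSE)
    }
    if (target > vmax + config$solver_tolerance) {
      if (config$infeasible_action == "error") {
        stop("required biomass flux ", signif(target, 6),
             " exceeds achievable maximum ", signif(vmax, 6), " at t = ", t,
             call. = FALSE)
      }
      target <- max(vmax, 0)
      st <- "relaxed"
    }
    bm <- model$biomass
    if (config$rmf_bound == "pin") {
      lb[bm] <- target
      ub[bm] <- max(target, min(ub[bm], target))
    } else {
      lb[bm] <- max(lb[bm], target)
    }
    pen <- if (is.null(penalty_fun)) NULL else penalty_fun(k)
    c_pen <- if (is.null(pen)) numeric(nr) else pen$c
    if (objective == "inconsistency") {
      s1 <- solve_min_inconsistency(model, lb, ub, c_pen)
    } else {
      res <- solve_flux_lp(model$S, lb, ub,
                           lin_w = replace(numeric(nr), bm, 1),
                           maximize = TRUE)
      s1 <- structure(list(V = stats::setNames(res$V, model$rxn_ids),
                           inconsistency = 0,
                           total_flux = sum(abs(res$V)),
                           status = res$status), class = "flux_solution")
      # lock the growth optimum before flux minimization
      lb[bm] <- max(lb[bm], res$V[bm] - config$epsilon_lock *
                      (1 + abs(res$V[bm])))
    }
    if (s1$status != "optimal") {
      stop("stage-1 LP ", s1$status, " at t = ", t, call. = FALSE)
    }
    s2 <- if (objective == "inconsistency") {
      solve_min_total_flux(model, lb, ub, c_pen, s1$inconsistency,
                           config$epsilon_lock)
    } else {
      solve_min_total_flux(model, lb, ub, numeric(nr), 0,
                           config$epsilon_lock)
    }
    if (s2$status != "optimal") {
      stop("stage-2 LP ", s2$status, " at t = ", t, call. = FALSE)
    }
    state <- update_state(state, model, s2$V, config)
    floored <- union(floored, attr(state, "floored"))
    conc[k + 1L, ] <- state$e
    biomass[k + 1L] <- state$BM
    flux[k, ] <- s2$V
    cmat[k, ] <- c_pen
    inconsistency[k] <- s2$inconsistency
    total_flux[k] <- s2$total_flux
    rmf[k] <- target
    status[k] <- st
    p_list[[k]] <- if (is.null(pen)) NULL else pen$p_g
  }
  p_g <- if (n_steps > 0 && !is.null(p_list[[1]])) {
    do.call(rbind, p_list)
  } else NULL
  structure(list(times = grid, conc = conc, biomass = biomass,
                 flux = flux, penalties = cmat, p_g = p_g,
                 inconsistency = inconsistency, total_flux = total_flux,
                 rmf = rmf, status = status, floored = floored,
                 exchangeable = unname(model$met_ids[model$exchange_met]),
                 model_id = paste(model$rxn_ids, collapse = ","),
                 config = config),
            class = "team_trajectory")
}

#' Run a TEAM simulation
#'
#' The main loop: per time step, interpolate the expression data, compute
#' gene penalties against the thresholds, propagate them to reactions
#' through the GPR rules, build bounds (media pools, biomass scaling,
#' required biomass flux), solve the two-stage LP (minimize inconsistency,
#' then minimize total flux at the locked inconsistency), and update media
#' and biomass for the next step.
#'
#' @param model A [stoich_model()].
#' @param expression_ts An [expression_timeseries()] covering
#'   `[0, t_end]`.
#' @param compendium An [build_compendium()] object (used to derive
#'   thresholds unless `thresholds` is given).
#' @param od Growth curve: `data.frame(time, od)` or a function of time.
#' @param media Initial media composition (named vector or
#'   `data.frame(metabolite, mM)`).
#' @param config A [team_config()].
#' @param type Threshold type (1, 2 or 3), see [compute_thresholds()].
#' @param theta Threshold percentile.
#' @param thresholds Optional precomputed [compute_thresholds()] object.
#' @return A `team_trajectory`: times, concentrations, biomass, per-step
#'   fluxes, penalties, objective values and statuses.
#' @seealso [run_dfba()], [sweep_thresholds()]
#' @export
run_team <- function(model, expression_ts, compendium, od, media,
                     config = team_config(), type = 2, theta = 70,
                     thresholds = NULL) {
  stopifnot(inherits(expression_ts, "expr_timeseries"))
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(compendium, type = type, theta = theta)
  }
  grid <- seq(0, config$t_end, by = config$dt)
  expr_grid <- if (length(grid) > 1) {
    interpolate_timeseries(expression_ts$times, expression_ts$values,
                           grid[-length(grid)])
  } else NULL
  genes <- union(model$genes, rownames(expression_ts$values))
  penalty_fun <- function(k) {
    expr_t <- stats::setNames(expr_grid[, k], rownames(expression_ts$values))
    p_g <- compute_gene_penalties(expr_t, thresholds, genes = genes)
    list(p_g = p_g, c = propagate_reaction_penalties(p_g, model))
  }
  traj <- run_dynamic(model, od, media, config, penalty_fun = penalty_fun,
                      objective = "inconsistency")
  traj$thresholds <- thresholds
  traj
}

#' Run a plain dFBA baseline
#'
#' The same dynamic loop as [run_team()] but expression-blind: stage 1
#' maximizes the biomass flux, stage 2 minimizes total flux at the locked
#' growth optimum. In the default od_derived/pin configuration the biomass
#' flux is fixed to the measured growth value in both engines, so this
#' baseline is "what a metabolically efficient cell would do to achieve
#' the observed growth" and [run_team()] with all-zero penalties
#' reproduces it exactly.
#'
#' @inheritParams run_team
#' @return A `team_trajectory`.
#' @export
run_dfba <- function(model, od, media, config = team_config()) {
  run_dynamic(model, od, media, config, penalty_fun = NULL,
              objective = "max_biomass")
}

#' Single TEAM iteration (static)
#'
#' One two-stage optimization without media updates, in the style of the
#' fraction-of-max validation runs: bounds come from the media and a
#' required biomass flux of `rmf_fraction` times the FBA maximum; the
#' returned solution carries its penalties for downstream inconsistency
#' scoring.
#'
#' @param model A [stoich_model()].
#' @param expr Named expression vector (one time point).
#' @param thresholds A [compute_thresholds()] object.
#' @param media Initial media composition.
#' @param config A [team_config()]; `rmf_mode` is forced to
#'   `"fraction_of_max"`.
#' @param BM Biomass used to scale biological bounds (default 1).
#' @return `list(solution, p_g, c, rmf)`.
#' @export
team_step <- function(model, expr, thresholds, media,
                      config = team_config(rmf_mode = "fraction_of_max"),
                      BM = 1) {
  b <- scale_bounds_to_total(model, BM)
  state <- initialize_state(model, media, BM, config)
  b <- media_exchange_bounds(model, state, config, b$lb, b$ub)
  lb <- b$lb; ub <- b$ub
  vmax <- fba_max_flux(model$S, lb, ub, model$biomass)
  if (is.na(vmax)) stop("infeasible bounds in team_step", call. = FALSE)
  target <- config$rmf_fraction * vmax
  bm <- model$biomass
  if (config$rmf_bound == "pin") {
    lb[bm] <- target; ub[bm] <- max(ub[bm], target)
  } else {
    lb[bm] <- max(lb[bm], target)
  }
  genes <- union(model$genes, names(expr))
  p_g <- compute_gene_penalties(expr, thresholds, genes = genes)
  c_pen <- propagate_reaction_penalties(p_g, model)
  s1 <- solve_min_inconsistency(model, lb, ub, c_pen)
  if (s1$status != "optimal") stop("stage-1 LP ", s1$status, call. = FALSE)
  s2 <- solve_min_total_flux(model, lb, ub, c_pen, s1$inconsistency,
                             config$epsilon_lock)
  if (s2$status != "optimal") stop("stage-2 LP ", s2$status, call. = FALSE)
  list(solution = s2, p_g = p_g, c = c_pen, rmf = target)
}

#' @export
print.team_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<team_trajectory> ", n, " time points (dt = ", x$config$dt,
      " hr), biomass ", signif(x$biomass[1], 4), " -> ",
      signif(x$biomass[n], 4), "\n", sep = "")
  if (any(x$status == "relaxed", na.rm = TRUE)) {
    cat("  ", sum(x$status == "relaxed", na.rm = TRUE),
        "step(s) with relaxed biomass requirement\n")
  }
  invisible(x)
}
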