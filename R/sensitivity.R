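#' Sweep the threshold percentile
#'
#' Runs [run_team()] once per value of `theta_grid` and summarizes each
#' trajectory: total secreted carbon per initially-absent metabolite,
#' extinction times of the initial nutrients, the summed inconsistency
#' score, and (optionally) prediction error against observed concentration
#' series. Per-theta results are independent; failures are recorded and the
#' sweep continues.
#'
#' @inheritParams run_team
#' @param theta_grid Percentiles to sweep (default `1:99`).
#' @param observed Optional named list of `data.frame(time, value)`
#'   concentration series, keyed by metabolite id, for RSS scoring.
#' @param secretion_tol Concentration above which a metabolite counts as
#'   secreted (mM), default `1e-6`.
#' @param extinction_tol Concentration at or below which a nutrient counts
#'   as extinct (mM), default `1e-6`.
#' @param keep_trajectories Keep the full per-theta trajectories (memory
#'   heavy; default `FALSE`).
#' @return Object of class `team_sweep`: `summary` data.frame (one row per
#'   theta), `secreted` theta x metabolite matrix of total secreted
#'   concentration, `extinction` theta x nutrient matrix, `zones` from
#'   [classify_zones()], and `errors` (per-theta failure messages, if any).
#' @export
sweep_thresholds <- function(model, expression_ts, compendium, od, media,
                             config = team_config(), type = 2,
                             theta_grid = 1:99, observed = NULL,
                             secretion_tol = 1e-6, extinction_tol = 1e-6,
                             keep_trajectories = FALSE) {
  stopifnot(all(theta_grid >= 0), all(theta_grid <= 100))
  media_vec <- if (is.data.frame(media)) {
    stats::setNames(as.numeric(media[[2]]), as.character(media[[1]]))
  } else media
  exch_mets <- model$met_ids[model$exchange_met]
  absent <- setdiff(exch_mets, names(media_vec)[media_vec > 0])
  absent <- setdiff(absent, names(config$clamp))
  nutrients <- intersect(names(media_vec)[media_vec > 0], exch_mets)
  nutrients <- setdiff(nutrients, names(config$clamp))
  n <- length(theta_grid)
  secreted <- matrix(NA_real_, n, length(absent),
                     dimnames = list(NULL, absent))
  extinction <- matrix(NA_real_, n, length(nutrients),
                       dimnames = list(NULL, nutrients))
  is_sum <- rep(NA_real_, n)
  rss <- if (!is.null(observed)) {
    matrix(NA_real_, n, length(observed),
           dimnames = list(NULL, names(observed)))
  } else NULL
  errors <- rep(NA_character_, n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    th <- theta_grid[i]
    traj <- tryCatch(
      run_team(model, expression_ts, compendium, od, media_vec, config,
               type = type, theta = th),
      error = function(e) e)
    if (inherits(traj, "error")) {
      errors[i] <- conditionMessage(traj)
      next
    }
    if (keep_trajectories) trajs[[i]] <- traj
    for (m in absent) secreted[i, m] <- total_secreted_carbon(traj, m)
    for (m in nutrients) {
      ext <- extinction_time(traj, m, tol = extinction_tol)
      extinction[i, m] <- if (is.na(ext)) Inf else ext
    }
    is_sum[i] <- trajectory_inconsistency_score(traj)
    if (!is.null(observed)) {
      for (m in names(observed)) {
        rss[i, m] <- prediction_rss(traj, observed[[m]], m)
      }
    }
  }
  summary <- data.frame(theta = theta_grid,
                        inconsistency_score = is_sum,
                        failed = !is.na(errors))
  res <- structure(list(theta_grid = theta_grid, summary = summary,
                        secreted = secreted, extinction = extinction,
                        rss = rss, errors = errors, type = type,
                        secretion_tol = secretion_tol,
                        trajectories = trajs),
                   class = "team_sweep")
  res$zones <- classify_zones(res, tol = secretion_tol)
  res
}

#' @export
print.team_sweep <- function(x, ...) {
  cat("<team_sweep> type", x$type, "thresholds,", length(x$theta_grid),
      "theta values,", nrow(x$zones), "secretion zone(s)\n")
  print(x$zones)
  invisible(x)
}

#' Total secreted concentration of a metabolite over a trajectory
#'
#' Sums the metabolite's media concentration over all grid time points —
#' the quantity plotted per threshold in sensitivity heatmaps. Intended for
#' metabolites absent from the initial media (secreted intermediates), for
#' which any nonzero value indicates secretion. With `carbon_weights`, the
#' sum is weighted by the metabolite's carbon count (carbon-mole mode).
#'
#' @param traj A `team_trajectory`.
#' @param metabolite Metabolite id; must have an exchange reaction.
#' @param carbon_weights Optional named vector of carbon atoms per
#'   metabolite.
#' @return Scalar (mM summed over time points).
#' @export
total_secreted_carbon <- function(traj, metabolite, carbon_weights = NULL) {
  stopifnot(inherits(traj, "team_trajectory"))
  if (!metabolite %in% colnames(traj$conc)) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  if (!is.null(traj$exchangeable) &&
      !metabolite %in% traj$exchangeable) {
    stop("metabolite has no exchange reaction: ", metabolite, call. = FALSE)
  }
  w <- if (is.null(carbon_weights)) 1 else {
    if (!metabolite %in% names(carbon_weights)) {
      stop("no carbon count for metabolite: ", metabolite, call. = FALSE)
    }
    carbon_weights[[metabolite]]
  }
  w * sum(traj$conc[, metabolite])
}

#' Extinction time of a nutrient
#'
#' First simulation grid time at which the nutrient's concentration is at
#' or below `tol`; `NA` ("never") if it stays above throughout.
#'
#' @param traj A `team_trajectory`.
#' @param nutrient Metabolite id present in the initial media.
#' @param tol Extinction tolerance (mM), default `1e-6`.
#' @return Time in hours, or `NA` if never extinct.
#' @export
extinction_time <- function(traj, nutrient, tol = 1e-6) {
  stopifnot(inherits(traj, "team_trajectory"))
  if (!nutrient %in% colnames(traj$conc)) {
    stop("unknown metabolite: ", nutrient, call. = FALSE)
  }
  if (traj$conc[1, nutrient] <= tol) {
    stop("metabolite '", nutrient, "' absent from the initial media",
         call. = FALSE)
  }
  hit <- which(traj$conc[, nutrient] <= tol)
  if (length(hit) == 0) NA_real_ else traj$times[hit[1]]
}

#' Classify secretion zones along a threshold sweep
#'
#' Labels each theta by the set of metabolites it secretes (total secreted
#' concentration above `tol`) and reports the maximal contiguous theta
#' intervals sharing a label — the machinery used to locate qualitatively
#' distinct regimes and an "optimal range" of thresholds.
#'
#' @param sweep A [sweep_thresholds()] result.
#' @param tol Secretion tolerance, default `1e-6`.
#' @return `data.frame(zone, theta_min, theta_max, label, n)`; failed
#'   thetas are labeled `"<failed>"`.
#' @export
classify_zones <- function(sweep, tol = 1e-6) {
  stopifnot(inherits(sweep, "team_sweep"))
  labels <- apply(sweep$secreted, 1, function(row) {
    if (all(is.na(row))) return("<failed>")
    s <- colnames(sweep$secreted)[!is.na(row) & row > tol]
    if (length(s) == 0) "none" else paste(sort(s), collapse = "+")
  })
  if (ncol(sweep$secreted) == 0) labels <- rep("none", nrow(sweep$secreted))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(zone = seq_along(r$values),
             theta_min = sweep$theta_grid[starts],
             theta_max = sweep$theta_grid[ends],
             label = r$values, n = r$lengths,
             stringsAsFactors = FALSE)
}

#' Residual sum of squares against observed concentrations
#'
#' `sum_t (predicted_t - observed_t)^2` over the simulation grid, the
#' observed series interpolated piecewise-linearly onto it. Grid points
#' outside the observed time range are refused.
#'
#' @param traj A `team_trajectory`.
#' @param observed `data.frame(time, value)` of measured concentrations.
#' @param metabolite Metabolite id.
#' @return Scalar RSS (mM^2).
#' @export
prediction_rss <- function(traj, observed, metabolite) {
  stopifnot(inherits(traj, "team_trajectory"))
  if (!metabolite %in% colnames(traj$conc)) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  obs <- interpolate_timeseries(observed[[1]], as.numeric(observed[[2]]),
                                traj$times)
  sum((traj$conc[, metabolite] - obs)^2)
}

#' Normalized inconsistency score of a flux solution
#'
#' `IS = sum_i c_i |V_i| / mean_g(p_g)`: the total penalty carried by the
#' solution, normalized by the average gene penalty so that uniformly
#' scaling all penalties leaves the score unchanged. Defined as 0 when the
#' numerator is 0 (no penalized flux).
#'
#' @param solution A `flux_solution` (or any list with element `V`).
#' @param c_pen Per-reaction penalties used in the solve.
#' @param p_g Per-gene penalties behind `c_pen`.
#' @return Scalar score.
#' @export
inconsistency_score <- function(solution, c_pen, p_g) {
  num <- sum(c_pen * abs(solution$V))
  if (num <= 0) return(0)
  denom <- mean(p_g)
  if (denom <= 0) {
    stop("nonzero penalized flux with zero mean gene penalty", call. = FALSE)
  }
  num / denom
}

# Summed per-step inconsistency score over a trajectory.
trajectory_inconsistency_score <- function(traj) {
  if (is.null(traj$p_g)) return(0)
  n <- nrow(traj$flux)
  total <- 0
  for (k in seq_len(n)) {
    num <- traj$inconsistency[k]
    if (num > 0) {
      denom <- mean(traj$p_g[k, ])
      if (denom > 0) total <- total + num / denom
    }
  }
  total
}

#' Compare thresholding strategies by inconsistency score
#'
#' For each theta on a grid, completes a single TEAM iteration (see
#' [team_step()]) per thresholding type and records the normalized
#' inconsistency score — the comparison used to argue that gene-specific
#' thresholds produce flux distributions more consistent with expression
#' than a global threshold.
#'
#' @param model A [stoich_model()].
#' @param expr Named expression vector (one time point).
#' @param compendium An [build_compendium()] object.
#' @param media Initial media composition.
#' @param theta_grid Percentiles (default `1:99`).
#' @param types Threshold types to compare (default `c(1, 2)`).
#' @param config A [team_config()]; defaults to fraction-of-max mode with
#'   `p = 0.5`.
#' @return `data.frame(theta, type, inconsistency_score)`.
#' @export
inconsistency_profile <- function(model, expr, compendium, media,
                                  theta_grid = 1:99, types = c(1, 2),
                                  config = team_config(
                                    rmf_mode = "fraction_of_max")) {
  out <- expand.grid(theta = theta_grid, type = types)
  out$inconsistency_score <- NA_real_
  for (r in seq_len(nrow(out))) {
    spec <- compute_thresholds(compendium, type = out$type[r],
                               theta = out$theta[r])
    step <- team_step(model, expr, spec, media, config)
    out$inconsistency_score[r] <-
      inconsistency_score(step$solution, step$c, step$p_g)
  }
  out
}
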