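# Self-contained synthetic inputs: a toy overflow-capable metabolic model
# plus expression, compendium, growth-curve and media generators with the
# statistical structure the method assumes (gene-individual expression
# distributions spanning orders of magnitude; a respiratory gene repressed
# mid-course; uptake/consumption genes induced late).

#' Scenario specification for the synthetic generators
#'
#' Defaults define the package's reference "overflow" scenario: batch
#' growth on a single carbon source (lactate-like, 20 mM) under clamped
#' oxygen, with a respiratory (TCA-like) gene repressed mid-course and an
#' acetate-consumption gene induced late, so that expression-constrained
#' simulations at mid-range thresholds secrete the acetate-like
#' intermediate and re-import it after substrate exhaustion, while the
#' expression-blind baseline never secretes.
#'
#' Per-gene expression is lognormal with gene means spanning over two
#' orders of magnitude (0.9 to 220): gene-specific thresholds see each
#' gene's regulation on its own scale, while a global threshold
#' misclassifies the low-mean (lactate-dehydrogenase-like) gene as "off".
#' Time profiles are written in quantile space (`base_q`, `alt_q`): a
#' profile at quantile q of the gene's own stationary distribution crosses
#' below its gene-specific threshold exactly when the sweep percentile
#' theta exceeds 100 q, which is what positions the secretion zones.
#'
#' @param seed Integer seed; fixed seed gives identical outputs
#'   (Mersenne-Twister).
#' @param t_end,dt Simulation horizon and step (hours).
#' @param n_ref Reference compendium size (samples).
#' @param expr_times Measurement times of the experiment's arrays.
#' @param noise `"lognormal"` (multiplicative, default) or `"normal"`
#'   (additive) measurement noise.
#' @param noise_sd Multiplicative noise sd (log scale) for the time series.
#' @param genes Gene parameter table; see Details in the package vignette.
#' @param media Named initial media concentrations (mM).
#' @param clamp Named clamped concentrations (mM).
#' @param od Growth-curve parameters: `od0` initial OD, `A` plateau rise,
#'   `r` exponential rate (1/hr), `tm` inflection time (hr).
#' @param death_rate Death rate used in the matching config (1/hr).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 42, t_end = 50, dt = 1, n_ref = 60,
                          expr_times = seq(0, 50, length.out = 19),
                          noise = c("lognormal", "normal"),
                          noise_sd = 0.05,
                          genes = NULL,
                          media = c(lac = 14),
                          clamp = c(o2 = 10),
                          od = list(od0 = 0.25, A = 5, r = 0.3, tm = 18),
                          death_rate = 0.06) {
  noise <- match.arg(noise)
  if (is.null(genes)) {
    genes <- data.frame(
      gene  = c("gLDH", "gTCA", "gPOX", "gPFL", "gACS", "gFDH"),
      mean  = c(0.9, 220, 80, 120, 200, 60),
      sdlog = c(0.25, 0.3, 0.3, 0.3, 0.3, 0.3),
      shape = c("flat", "dip", "dip", "dip", "rise", "rise"),
      base_q = c(0.5, 0.80, 0.80, 0.88, 0.85, 0.85),
      alt_q  = c(0.5, 0.06, 0.60, 0.06, 0.03, 0.10),
      t1 = c(NA, 14, 14, 14, 28, 28),
      t2 = c(NA, 26, 26, 26, 32, 32),
      ramp = c(0, 2, 2, 2, NA, NA),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(genes$sdlog > 0), n_ref >= 2, dt > 0, t_end > 0)
  structure(list(seed = seed, t_end = t_end, dt = dt, n_ref = n_ref,
                 expr_times = expr_times, noise = noise,
                 noise_sd = noise_sd, genes = genes, media = media,
                 clamp = clamp, od = od, death_rate = death_rate),
            class = "scenario_spec")
}

with_scenario_seed <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed + offset, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Quantile-space regulation profile of one gene row at times t.
profile_quantile <- function(row, t) {
  q <- rep(row$base_q, length(t))
  if (row$shape == "dip") {
    lo <- row$t1; hi <- row$t2; ramp <- row$ramp
    inside <- t > lo & t < hi
    core <- t >= lo + ramp & t <= hi - ramp
    q[core] <- row$alt_q
    ramp_in <- inside & t < lo + ramp
    q[ramp_in] <- row$base_q +
      (row$alt_q - row$base_q) * (t[ramp_in] - lo) / ramp
    ramp_out <- inside & t > hi - ramp
    q[ramp_out] <- row$alt_q +
      (row$base_q - row$alt_q) * (t[ramp_out] - (hi - ramp)) / ramp
  } else if (row$shape == "rise") {
    q[t <= row$t1] <- row$alt_q
    mid <- t > row$t1 & t < row$t2
    q[mid] <- row$alt_q +
      (row$base_q - row$alt_q) * (t[mid] - row$t1) / (row$t2 - row$t1)
  }
  q
}

# Noise-free expression value of one gene at times t (quantile of its own
# stationary distribution).
profile_value <- function(row, t, noise = "lognormal") {
  q <- profile_quantile(row, t)
  if (noise == "normal") {
    stats::qnorm(q, mean = row$mean, sd = row$sdlog * row$mean)
  } else {
    stats::qlnorm(q, meanlog = log(row$mean), sdlog = row$sdlog)
  }
}

#' Toy overflow-capable metabolic model
#'
#' A ~10-reaction single-compartment model of central-carbon overflow:
#' a lactate-like substrate is oxidized to a pyruvate-like node; energy
#' (`atp`) comes from an efficient respiratory branch (TCA-like, oxygen
#' dependent, 3 atp) or from low-yield valves producing secretable
#' acetate-like (`ac`, 1 atp) or formate-like (`form`, 1 atp)
#' intermediates, both re-importable and consumable (ACS-/FDH-like,
#' oxygen dependent). Biomass consumes the carbon node plus energy. Every
#' biological reaction carries a 1-gene GPR; carbon counts are attached as
#' the `"carbon"` attribute.
#'
#' @param spec A [scenario_spec()] (unused fields ignored; present so
#'   generators share a signature).
#' @return A [stoich_model()].
#' @export
make_toy_overflow_model <- function(spec = scenario_spec()) {
  rx <- data.frame(
    id = c("EX_lac", "EX_ac", "EX_form", "EX_o2",
           "LDH", "TCA", "POX", "PFL", "ACS", "FDH", "BM"),
    formula = c("lac ->", "ac ->", "form ->", "o2 ->",
                "lac -> pyr",
                "pyr + o2 -> 3 atp",
                "pyr -> ac + atp",
                "pyr -> form + atp",
                "ac + o2 -> 2 atp",
                "form + o2 -> atp",
                "o2 + 3 atp ->"),
    lb = c(-1000, -1000, -1000, -1000, 0, 0, 0, 0, 0, 0, 0),
    ub = c(1000, 1000, 1000, 1000, 2, 2, 0.1, 0.1, 2, 2, 1000),
    gpr = c("", "", "", "",
            "gLDH", "gTCA", "gPOX", "gPFL", "gACS", "gFDH", ""),
    stringsAsFactors = FALSE)
  mets <- data.frame(id = c("lac", "pyr", "ac", "form", "o2", "atp"),
                     name = c("lactate-like substrate", "pyruvate node",
                              "acetate-like intermediate",
                              "formate-like intermediate",
                              "oxygen", "energy currency"))
  m <- stoich_model(rx, mets, biomass = "BM")
  attr(m, "carbon") <- c(lac = 3, pyr = 3, ac = 2, form = 1, o2 = 0,
                         atp = 0)
  m
}

#' Simulate the experiment's expression time series
#'
#' Per gene, values follow the regulation profile (a quantile trajectory
#' through the gene's own stationary distribution) with multiplicative
#' lognormal (or additive normal) measurement noise. With `noise_sd = 0`
#' values equal the profiles exactly.
#'
#' @param spec A [scenario_spec()].
#' @return An [expression_timeseries()].
#' @export
simulate_expression_timeseries <- function(spec = scenario_spec()) {
  t <- spec$expr_times
  vals <- with_scenario_seed(spec, 1, {
    m <- t(vapply(seq_len(nrow(spec$genes)), function(i) {
      base <- profile_value(spec$genes[i, ], t, spec$noise)
      if (spec$noise_sd > 0) {
        if (spec$noise == "normal") {
          base + stats::rnorm(length(t), 0,
                              spec$noise_sd * spec$genes$mean[i])
        } else {
          base * exp(stats::rnorm(length(t), 0, spec$noise_sd))
        }
      } else base
    }, numeric(length(t))))
    rownames(m) <- spec$genes$gene
    m
  })
  expression_timeseries(vals, t)
}

#' Simulate the reference expression compendium
#'
#' Per-gene samples from the gene's stationary distribution (lognormal by
#' default); gene means span over two orders of magnitude, reproducing the
#' heterogeneity regime that motivates gene-specific thresholds.
#'
#' @param spec A [scenario_spec()].
#' @param experiment Optional [expression_timeseries()] whose columns are
#'   pooled in as experimental arrays (default: simulated from `spec`).
#' @return An [build_compendium()] object.
#' @export
simulate_compendium <- function(spec = scenario_spec(),
                                experiment = simulate_expression_timeseries(spec)) {
  ref <- with_scenario_seed(spec, 2, {
    m <- t(vapply(seq_len(nrow(spec$genes)), function(i) {
      g <- spec$genes[i, ]
      if (spec$noise == "normal") {
        stats::rnorm(spec$n_ref, g$mean, g$sdlog * g$mean)
      } else {
        stats::rlnorm(spec$n_ref, log(g$mean), g$sdlog)
      }
    }, numeric(spec$n_ref)))
    rownames(m) <- spec$genes$gene
    colnames(m) <- paste0("ref", seq_len(spec$n_ref))
    m
  })
  exp_m <- NULL
  if (!is.null(experiment)) {
    exp_m <- experiment$values
    colnames(exp_m) <- paste0("exp", seq_len(ncol(exp_m)))
  }
  build_compendium(ref, exp_m)
}

#' Simulate a growth (OD) curve
#'
#' Lag-exponential-plateau curve `OD(t) = od0 + A / (1 + exp(-r (t - tm)))`
#' sampled on the simulation grid; strictly positive for all documented
#' parameter ranges (`od0 > 0`, `A >= 0`, `r >= 0`). With `r = 0` the curve
#' is flat at `od0 + A/2`.
#'
#' @param spec A [scenario_spec()].
#' @return `data.frame(time, od)`.
#' @export
simulate_od_curve <- function(spec = scenario_spec()) {
  p <- spec$od
  stopifnot(p$od0 > 0, p$A >= 0, p$r >= 0)
  t <- seq(0, spec$t_end, by = spec$dt)
  data.frame(time = t, od = p$od0 + p$A / (1 + exp(-p$r * (t - p$tm))))
}

#' Build a complete synthetic scenario
#'
#' Bundles a mutually consistent input set — model, expression time
#' series, compendium, growth curve, media and configuration — and
#' optionally writes it to a directory in the exact formats the loaders
#' consume (tabular model, expression/OD/media TSVs, YAML config).
#'
#' @param spec A [scenario_spec()].
#' @param dir Optional output directory.
#' @return List with elements `model`, `expression_ts`, `compendium`,
#'   `od`, `media`, `config`, `spec` (class `team_scenario`).
#' @export
make_scenario <- function(spec = scenario_spec(), dir = NULL) {
  model <- make_toy_overflow_model(spec)
  expression_ts <- simulate_expression_timeseries(spec)
  compendium <- simulate_compendium(spec, expression_ts)
  od <- simulate_od_curve(spec)
  config <- team_config(dt = spec$dt, t_end = spec$t_end,
                        death_rate = spec$death_rate, clamp = spec$clamp)
  bundle <- structure(list(model = model, expression_ts = expression_ts,
                           compendium = compendium, od = od,
                           media = spec$media, config = config,
                           spec = spec),
                      class = "team_scenario")
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

#' Write a scenario bundle to disk
#'
#' @param bundle A [make_scenario()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_tabular(bundle$model, file.path(dir, "model"))
  write_matrix_tsv <- function(m, first_col, path) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(first_col, colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ev <- bundle$expression_ts$values
  colnames(ev) <- bundle$expression_ts$times
  write_matrix_tsv(ev, "gene", file.path(dir, "expression.tsv"))
  write_matrix_tsv(bundle$compendium$values, "gene",
                   file.path(dir, "compendium.tsv"))
  utils::write.table(bundle$od, file.path(dir, "od.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(metabolite = names(bundle$media),
               mM = as.numeric(bundle$media)),
    file.path(dir, "media.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- bundle$config
  yaml::write_yaml(list(
    dt = cfg$dt, t_end = cfg$t_end, death_rate = cfg$death_rate,
    volume = cfg$volume, clamp = as.list(cfg$clamp),
    rmf_mode = cfg$rmf_mode, rmf_bound = cfg$rmf_bound,
    seed = bundle$spec$seed), file.path(dir, "config.yaml"))
  invisible(dir)
}
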