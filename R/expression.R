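#' Read an expression matrix (genes x samples) from TSV/CSV
#'
#' First column must hold gene ids; the header row holds sample ids (or
#' time points, for a time series). The delimiter is inferred from the file
#' extension (`.csv` = comma, otherwise tab).
#'
#' @param path File path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Assemble a reference + experiment expression compendium
#'
#' Pools a reference expression matrix (e.g. public microarray compendium)
#' with the experiment's own time-course arrays, column-wise, on the
#' intersection of their gene sets (optionally restricted to the genes of a
#' model). Per-gene pooled sample counts are the sum of reference and
#' experiment columns. Provenance of each column is kept.
#'
#' @param reference Genes x samples numeric matrix (rownames = gene ids),
#'   or a file path accepted by [read_expression_matrix()].
#' @param experiment Like `reference`; the experiment's arrays. May be
#'   `NULL` to use the reference alone.
#' @param genes Optional character vector restricting the gene set (e.g.
#'   model genes); genes absent from the data are dropped with a warning.
#' @param include_experiment Include the experiment columns in the pooled
#'   distributions (default `TRUE`, matching threshold estimation from the
#'   union of reference and experimental arrays).
#' @return Object of class `expr_compendium`: list with `values` (genes x
#'   samples matrix) and `source` (per-column `"reference"`/`"experiment"`).
#' @export
build_compendium <- function(reference, experiment = NULL, genes = NULL,
                             include_experiment = TRUE) {
  if (is.character(reference)) reference <- read_expression_matrix(reference)
  if (is.character(experiment)) experiment <- read_expression_matrix(experiment)
  stopifnot(is.matrix(reference))
  common <- rownames(reference)
  if (!is.null(experiment) && include_experiment) {
    common <- intersect(common, rownames(experiment))
    if (length(common) == 0) {
      stop("reference and experiment share no genes", call. = FALSE)
    }
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, common)
    if (length(missing) > 0) {
      warning("gene(s) without compendium data dropped: ",
              paste(missing, collapse = ", "))
    }
    common <- intersect(genes, common)
    if (length(common) == 0) {
      stop("no overlap between requested genes and compendium",
           call. = FALSE)
    }
  }
  vals <- reference[common, , drop = FALSE]
  src <- rep("reference", ncol(vals))
  if (!is.null(experiment) && include_experiment) {
    vals <- cbind(vals, experiment[common, , drop = FALSE])
    src <- c(src, rep("experiment", ncol(experiment)))
  }
  if (anyNA(vals)) stop("compendium contains missing values", call. = FALSE)
  structure(list(values = vals, source = src), class = "expr_compendium")
}

#' @export
print.expr_compendium <- function(x, ...) {
  cat("<expr_compendium> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$source == "reference"), " reference, ",
      sum(x$source == "experiment"), " experiment)\n", sep = "")
  invisible(x)
}

#' Construct an expression time series
#'
#' @param values Genes x timepoints numeric matrix (rownames = gene ids).
#' @param times Numeric vector of measurement times (hours), strictly
#'   increasing, one per column.
#' @return Object of class `expr_timeseries`.
#' @export
expression_timeseries <- function(values, times) {
  stopifnot(is.matrix(values), length(times) == ncol(values))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, times = times), class = "expr_timeseries")
}

#' Empirical quantile under the nearest-rank convention
#'
#' `theta` is a percentile in `[0, 100]`. The value returned is
#' `sorted[ceiling(theta/100 * n)]`, with `theta = 0` mapped to the minimum
#' and `theta = 100` to the maximum. This convention is monotone
#' nondecreasing in `theta` and always returns an observed value.
#'
#' @param values Nonempty numeric vector, finite.
#' @param theta Percentile in `[0, 100]`.
#' @return Scalar threshold.
#' @export
empirical_quantile <- function(values, theta) {
  if (length(values) == 0) stop("empty sample vector", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite sample values", call. = FALSE)
  stopifnot(theta >= 0, theta <= 100)
  s <- sort(values)
  k <- max(1L, ceiling(theta / 100 * length(s)))
  s[k]
}

#' Derive penalty thresholds from a compendium
#'
#' Three thresholding strategies:
#' * Type 1 (global): one threshold `x_global`, the `theta`-th percentile of
#'   all expression values pooled across genes and samples.
#' * Type 2 (gene-specific): per-gene threshold `x_g`, the `theta`-th
#'   percentile of that gene's own pooled samples.
#' * Type 3 (gene-specific, scaled): as Type 2, additionally storing each
#'   gene's standard deviation `sigma_g` over the same pool; penalties are
#'   later divided by `sigma_g`.
#'
#' Near-constant genes get `sigma_g` floored at `sigma_floor_frac` times the
#' median gene standard deviation to avoid division blow-up.
#'
#' @param comp An [build_compendium()] object.
#' @param type 1, 2 or 3.
#' @param theta Percentile in `[0, 100]`.
#' @param sigma_floor_frac Floor fraction for Type 3 (default `1e-3`).
#' @return Object of class `threshold_spec` with fields `type`, `theta`,
#'   `x_global` (Type 1) or `x_g` (Types 2-3) and `sigma_g` (Type 3).
#' @export
compute_thresholds <- function(comp, type = 2, theta = 70,
                               sigma_floor_frac = 1e-3) {
  stopifnot(inherits(comp, "expr_compendium"), type %in% 1:3,
            theta >= 0, theta <= 100)
  out <- list(type = as.integer(type), theta = theta,
              x_global = NULL, x_g = NULL, sigma_g = NULL)
  if (type == 1) {
    out$x_global <- empirical_quantile(as.numeric(comp$values), theta)
  } else {
    if (type == 3 && ncol(comp$values) < 2) {
      stop("Type 3 thresholds need >= 2 samples per gene", call. = FALSE)
    }
    out$x_g <- apply(comp$values, 1, empirical_quantile, theta = theta)
    if (type == 3) {
      sg <- apply(comp$values, 1, stats::sd)
      floor_val <- sigma_floor_frac * stats::median(sg)
      floored <- sg < floor_val
      if (any(floored)) {
        message("sigma floored for gene(s): ",
                paste(rownames(comp$values)[floored], collapse = ", "))
        sg <- pmax(sg, floor_val)
      }
      if (any(sg <= 0)) {
        stop("nonpositive gene standard deviation after floor",
             call. = FALSE)
      }
      out$sigma_g <- sg
    }
  }
  structure(out, class = "threshold_spec")
}

#' Per-gene penalties at one time point
#'
#' A gene whose expression is at or above its threshold gets penalty 0;
#' below threshold the penalty is the shortfall (threshold minus
#' expression), for Type 3 divided by the gene's standard deviation.
#' Genes missing from `expr` get penalty 0.
#'
#' @param expr Named numeric vector of expression values at one time.
#' @param spec A [compute_thresholds()] object.
#' @param genes Genes to score (default: all with a threshold, or all of
#'   `expr` for Type 1).
#' @return Named numeric vector of penalties `p_g >= 0`.
#' @export
compute_gene_penalties <- function(expr, spec, genes = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (is.null(genes)) {
    genes <- if (spec$type == 1) names(expr) else names(spec$x_g)
  }
  thr <- if (spec$type == 1) {
    stats::setNames(rep(spec$x_global, length(genes)), genes)
  } else {
    th <- spec$x_g[genes]
    th[is.na(th)] <- -Inf   # no threshold known -> never penalized
    stats::setNames(th, genes)
  }
  e <- expr[genes]
  e[is.na(e)] <- Inf        # no expression data -> penalty 0
  p <- pmax(0, thr - e)
  if (spec$type == 3) {
    sg <- spec$sigma_g[genes]
    sg[is.na(sg)] <- 1
    p <- p / sg
  }
  stats::setNames(as.numeric(p), genes)
}

#' Propagate gene penalties to reaction penalties through GPR rules
#'
#' Each reaction's Boolean rule is evaluated with `AND = max` (the worst
#' subunit of a complex limits the reaction) and `OR = min` (the best
#' isoenzyme carries it). Reactions without a rule get penalty 0; a
#' single-gene rule passes the gene penalty through unchanged.
#'
#' @param p_g Named numeric vector of gene penalties.
#' @param model A [stoich_model()].
#' @return Named numeric vector `c_i` over all reactions.
#' @export
propagate_reaction_penalties <- function(p_g, model) {
  stopifnot(inherits(model, "stoich_model"))
  ci <- vapply(model$gpr, eval_gpr, numeric(1), p = p_g)
  stats::setNames(as.numeric(ci), model$rxn_ids)
}

#' Piecewise-linear interpolation onto a simulation grid
#'
#' Applied uniformly to growth (OD), expression and media series. Values at
#' sampled times are reproduced exactly; extrapolation outside the sampled
#' range is refused.
#'
#' @param times Strictly increasing sample times.
#' @param values Numeric vector (one series) or matrix with one column per
#'   sample time (e.g. genes x timepoints).
#' @param grid Query times, all within `[min(times), max(times)]`.
#' @return Vector or matrix of interpolated values at `grid`.
#' @export
interpolate_timeseries <- function(times, values, grid) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(grid < min(times) - 1e-12 | grid > max(times) + 1e-12)) {
    stop("grid point outside the sampled time range (no extrapolation)",
         call. = FALSE)
  }
  interp1 <- function(v) {
    stats::approx(times, v, xout = grid, method = "linear", rule = 1)$y
  }
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(times))
    out <- matrix(apply(values, 1, interp1), nrow = nrow(values),
                  byrow = TRUE,
                  dimnames = list(rownames(values), grid))
    out
  } else {
    stopifnot(length(values) == length(times))
    interp1(values)
  }
}
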