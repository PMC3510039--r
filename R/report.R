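#' Tidy views of a trajectory
#'
#' @param x A `team_trajectory`.
#' @param row.names,optional Ignored (base-R method signature).
#' @param what `"concentrations"` (time, metabolite, concentration),
#'   `"fluxes"` (time, reaction, flux, penalty) or `"biomass"`.
#' @param ... Unused.
#' @return A long-format `data.frame`.
#' @export
as.data.frame.team_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE,
                                          what = c("concentrations",
                                                   "fluxes", "biomass"),
                                          ...) {
  what <- match.arg(what)
  if (what == "concentrations") {
    data.frame(
      time = rep(x$times, ncol(x$conc)),
      metabolite = rep(colnames(x$conc), each = nrow(x$conc)),
      concentration = as.numeric(x$conc),
      stringsAsFactors = FALSE)
  } else if (what == "fluxes") {
    n <- nrow(x$flux)
    data.frame(
      time = rep(x$times[seq_len(n)], ncol(x$flux)),
      reaction = rep(colnames(x$flux), each = n),
      flux = as.numeric(x$flux),
      penalty = as.numeric(x$penalties),
      stringsAsFactors = FALSE)
  } else {
    data.frame(time = x$times, biomass = x$biomass)
  }
}

#' Write run outputs and a human-readable report
#'
#' For a trajectory: tidy TSVs of concentrations, fluxes (with penalties)
#' and biomass, a JSON run manifest (configuration snapshot, package
#' version, solver identity, per-step statuses, input checksums) and a
#' markdown summary with extinction times and secreted metabolites. For a
#' sweep: the per-theta summary, secreted/extinction matrices in long
#' format, and the zone table.
#'
#' @param x A `team_trajectory` or `team_sweep`.
#' @param dir Output directory (created if needed).
#' @param inputs Optional named character vector of input file paths whose
#'   md5 checksums go into the manifest.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir, inputs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (inherits(x, "team_trajectory")) {
    tsv(as.data.frame(x, what = "concentrations"), "concentrations.tsv")
    tsv(as.data.frame(x, what = "fluxes"), "fluxes.tsv")
    tsv(as.data.frame(x, what = "biomass"), "biomass.tsv")
    write_manifest(x$config, x$status, dir, inputs)
    nutrients <- colnames(x$conc)[x$conc[1, ] > 0]
    lines <- c("# Run summary", "",
               paste0("- time points: ", length(x$times),
                      " (dt = ", x$config$dt, " hr)"),
               paste0("- final biomass: ",
                      signif(x$biomass[length(x$biomass)], 5)),
               paste0("- relaxed steps: ",
                      sum(x$status == "relaxed", na.rm = TRUE)),
               "", "## Nutrient extinction times", "")
    for (m in setdiff(nutrients, names(x$config$clamp))) {
      ext <- extinction_time(x, m)
      lines <- c(lines, paste0("- ", m, ": ",
                               if (is.na(ext)) "never" else
                                 paste0(ext, " hr")))
    }
    secreted <- setdiff(colnames(x$conc)[apply(x$conc, 2, max) > 1e-6],
                        union(nutrients, names(x$config$clamp)))
    lines <- c(lines, "", "## Secreted metabolites", "",
               if (length(secreted) == 0) "- none" else
                 paste0("- ", secreted))
    writeLines(lines, file.path(dir, "summary.md"))
  } else if (inherits(x, "team_sweep")) {
    tsv(x$summary, "sweep_summary.tsv")
    long <- function(m, value_name) {
      data.frame(theta = rep(x$theta_grid, ncol(m)),
                 metabolite = rep(colnames(m), each = nrow(m)),
                 value = as.numeric(m), stringsAsFactors = FALSE,
                 check.names = FALSE) |>
        stats::setNames(c("theta", "metabolite", value_name))
    }
    if (ncol(x$secreted) > 0) {
      tsv(long(x$secreted, "total_secreted"), "secreted.tsv")
    }
    if (ncol(x$extinction) > 0) {
      tsv(long(x$extinction, "extinction_time"), "extinction.tsv")
    }
    tsv(x$zones, "zones.tsv")
    lines <- c("# Sweep summary", "",
               paste0("- theta values: ", length(x$theta_grid)),
               paste0("- failed runs: ", sum(!is.na(x$errors))),
               "", "## Secretion zones", "",
               utils::capture.output(print(x$zones)))
    writeLines(lines, file.path(dir, "summary.md"))
  } else {
    stop("unsupported object for write_report", call. = FALSE)
  }
  invisible(dir)
}

write_manifest <- function(config, status, dir, inputs = NULL) {
  manifest <- list(
    package = "teamflux",
    version = as.character(utils::packageVersion("teamflux")),
    solver = "boot::simplex (two-phase simplex)",
    config = unclass(config),
    step_status = table(factor(status)) |> as.list(),
    inputs = if (!is.null(inputs)) {
      lapply(as.list(inputs), function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    } else NULL,
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
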