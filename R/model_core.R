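#' Construct a stoichiometric model
#'
#' Builds a validated model object from a reaction table. Reaction formulas
#' use the dialect `"2 a + b -> c"` (irreversible) or `"a <-> b"`
#' (reversible); an empty side denotes an exchange with the environment,
#' e.g. `"lac ->"` is the exchange reaction of `lac` (positive flux =
#' secretion, negative = uptake). Exchange reactions are auto-detected as
#' reactions touching exactly one metabolite.
#'
#' @param reactions `data.frame` with columns `id`, `formula`, `lb`, `ub`
#'   and optionally `gpr` (Boolean rule text, see [parse_gpr()]).
#' @param metabolites Optional `data.frame` with columns `id` and `name`;
#'   defaults to the metabolites appearing in the formulas.
#' @param biomass Reaction id of the biomass (growth) reaction.
#' @param exchange_override Optional character vector of reaction ids to
#'   treat as exchange reactions regardless of auto-detection.
#' @return An object of class `stoich_model` with fields `met_ids`,
#'   `rxn_ids`, `S` (metabolites x reactions), `lb0`/`ub0` (specific bounds,
#'   mmol/gDW/hr), `reversible`, `exchange` (logical), `exchange_met`
#'   (exchange reaction -> metabolite index), `biomass` (index), `gpr`
#'   (named list of parsed rules), `genes`.
#' @examples
#' rx <- data.frame(id = c("EX_a", "T_a", "BM"),
#'                  formula = c("a ->", "a -> b", "b ->"),
#'                  lb = c(-10, 0, 0), ub = c(10, 10, 10),
#'                  gpr = c("", "g1", ""))
#' m <- stoich_model(rx, biomass = "BM")
#' @export
stoich_model <- function(reactions, metabolites = NULL, biomass = NULL,
                         exchange_override = NULL) {
  stopifnot(is.data.frame(reactions),
            all(c("id", "formula", "lb", "ub") %in% names(reactions)))
  rxn_ids <- as.character(reactions$id)
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(reactions$formula, parse_reaction_formula)
  met_in_formulas <- unique(unlist(lapply(parsed, function(p) names(p$coef))))
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = met_in_formulas, name = met_in_formulas)
  }
  met_ids <- as.character(metabolites$id)
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(met_in_formulas, met_ids)
  if (length(unknown) > 0) {
    stop("metabolite(s) in formulas but not in metabolite table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(rxn_ids)
  S <- matrix(0, nrow = length(met_ids), ncol = n,
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_len(n)) {
    cf <- parsed[[j]]$coef
    if (length(cf) == 0) {
      stop("reaction '", rxn_ids[j], "' has no metabolites", call. = FALSE)
    }
    S[names(cf), j] <- cf
  }
  lb0 <- as.numeric(reactions$lb)
  ub0 <- as.numeric(reactions$ub)
  bad <- which(lb0 > ub0)
  if (length(bad) > 0) {
    stop("lb > ub for reaction(s): ", paste(rxn_ids[bad], collapse = ", "),
         call. = FALSE)
  }
  reversible <- vapply(parsed, `[[`, logical(1), "reversible") | lb0 < 0
  gpr_text <- if ("gpr" %in% names(reactions)) {
    as.character(reactions$gpr)
  } else {
    rep("", n)
  }
  gpr_text[is.na(gpr_text)] <- ""
  gpr <- lapply(gpr_text, parse_gpr)
  names(gpr) <- rxn_ids
  n_met <- colSums(S != 0)
  exchange <- n_met == 1L
  if (!is.null(exchange_override)) {
    stopifnot(all(exchange_override %in% rxn_ids))
    exchange <- exchange | rxn_ids %in% exchange_override
  }
  bm_idx <- NA_integer_
  if (!is.null(biomass)) {
    bm_idx <- match(biomass, rxn_ids)
    if (is.na(bm_idx)) {
      stop("biomass reaction '", biomass, "' not in model", call. = FALSE)
    }
    # the designated biomass reaction is biological by definition, even if
    # it touches a single metabolite
    exchange[bm_idx] <- FALSE
  }
  exchange_met <- vapply(which(exchange), function(j) {
    nz <- which(S[, j] != 0)
    nz[which.max(abs(S[nz, j]))]
  }, integer(1))
  names(exchange_met) <- rxn_ids[exchange]
  structure(list(
    met_ids = met_ids,
    met_names = as.character(metabolites$name),
    rxn_ids = rxn_ids,
    formulas = as.character(reactions$formula),
    S = S,
    lb0 = lb0, ub0 = ub0,
    reversible = reversible,
    exchange = exchange,
    exchange_met = exchange_met,
    biomass = bm_idx,
    gpr = gpr,
    genes = sort(unique(unlist(lapply(gpr, gpr_genes))))
  ), class = "stoich_model")
}

# Parse "2 a + b -> c" into list(coef = named numeric, reversible = logical).
parse_reaction_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  rev <- grepl("<->|<=>", formula)
  sides <- strsplit(formula, "<->|<=>|-->|->", perl = TRUE)[[1]]
  if (length(sides) > 2) {
    stop("malformed reaction formula (multiple arrows): ", formula,
         call. = FALSE)
  }
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) == 2) sides[2] else ""
  coef <- numeric(0)
  add_terms <- function(side, sign, coef) {
    side <- trimws(side)
    if (!nzchar(side)) return(coef)
    for (term in strsplit(side, "\\+")[[1]]) {
      term <- trimws(term)
      if (!nzchar(term)) next
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        k <- as.numeric(parts[1]); met <- parts[2]
      } else if (length(parts) == 1) {
        k <- 1; met <- parts[1]
      } else {
        stop("malformed term '", term, "' in formula: ", side, call. = FALSE)
      }
      coef[met] <- (if (met %in% names(coef)) coef[[met]] else 0) + sign * k
      coef
    }
    coef
  }
  coef <- add_terms(lhs, -1, coef)
  coef <- add_terms(rhs, +1, coef)
  coef <- coef[coef != 0]
  list(coef = coef, reversible = rev)
}

#' Load a stoichiometric model from disk
#'
#' Two formats are supported. `"tabular"` (read/write) expects a directory
#' holding `reactions.tsv` (columns `id`, `formula`, `lb`, `ub`, `gpr`),
#' `metabolites.tsv` (`id`, `name`) and optionally `biomass.txt` (a single
#' reaction id). `"sbml"` (read-only) accepts an SBML Level 3 file with the
#' fbc extension for bounds and gene-product associations.
#'
#' @param path Directory (tabular) or file (SBML).
#' @param format `"tabular"` or `"sbml"`.
#' @param biomass Biomass reaction id; overrides `biomass.txt` / the SBML
#'   objective if given.
#' @return A [stoich_model()].
#' @seealso [write_model_tabular()]
#' @export
load_model <- function(path, format = c("tabular", "sbml"), biomass = NULL) {
  format <- match.arg(format)
  if (format == "tabular") {
    rx_path <- file.path(path, "reactions.tsv")
    met_path <- file.path(path, "metabolites.tsv")
    if (!file.exists(rx_path)) stop("missing file: ", rx_path, call. = FALSE)
    if (!file.exists(met_path)) stop("missing file: ", met_path, call. = FALSE)
    rx <- utils::read.delim(rx_path, stringsAsFactors = FALSE,
                            colClasses = c(gpr = "character"))
    mets <- utils::read.delim(met_path, stringsAsFactors = FALSE)
    bm_path <- file.path(path, "biomass.txt")
    if (is.null(biomass) && file.exists(bm_path)) {
      biomass <- trimws(readLines(bm_path, warn = FALSE))[1]
    }
    if (is.null(biomass)) {
      stop("no biomass reaction configured (pass `biomass` or provide ",
           "biomass.txt)", call. = FALSE)
    }
    stoich_model(rx, mets, biomass = biomass)
  } else {
    read_model_sbml(path, biomass = biomass)
  }
}

#' Write a model in the tabular dialect
#'
#' Emits `reactions.tsv`, `metabolites.tsv` and `biomass.txt` so that
#' `load_model(dir, "tabular")` reconstructs an identical model
#' (round-trip property).
#'
#' @param model A [stoich_model()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_model_tabular <- function(model, dir) {
  stopifnot(inherits(model, "stoich_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rx <- data.frame(
    id = model$rxn_ids,
    formula = vapply(seq_along(model$rxn_ids), function(j) {
      deparse_reaction_formula(model$S[, j], model$reversible[j])
    }, character(1)),
    lb = model$lb0, ub = model$ub0,
    gpr = vapply(model$gpr, function(g) {
      if (is.null(g)) "" else format.gpr(g)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = model$met_ids, name = model$met_names),
    file.path(dir, "metabolites.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  if (!is.na(model$biomass)) {
    writeLines(model$rxn_ids[model$biomass], file.path(dir, "biomass.txt"))
  }
  invisible(dir)
}

deparse_reaction_formula <- function(scol, reversible) {
  fmt_side <- function(idx) {
    paste(vapply(idx, function(i) {
      k <- abs(scol[i])
      if (k == 1) names(scol)[i] else paste(format(k), names(scol)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt_side(which(scol < 0))
  rhs <- fmt_side(which(scol > 0))
  arrow <- if (reversible) "<->" else "->"
  trimws(paste(lhs, arrow, rhs))
}

#' Partition reactions into exchange and biological sets
#'
#' Exchange reactions touch exactly one metabolite and act as its source and
#' sink; by convention a positive exchange flux secretes the metabolite and
#' a negative flux takes it up. All remaining reactions are biological
#' (enzyme-catalyzed or transport).
#'
#' @param model A [stoich_model()].
#' @return `list(exchange =, biological =)` of reaction id vectors.
#' @export
classify_reactions <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  list(exchange = model$rxn_ids[model$exchange],
       biological = model$rxn_ids[!model$exchange])
}

#' Validate a model's structural invariants
#'
#' Checks bound sanity, the exchange/biological partition, exchange
#' single-metabolite structure, empty reactions, and the biomass placement.
#' Warnings flag genes present in GPR rules but absent from supplied
#' expression data (these receive penalty 0), and a structurally blocked
#' biomass reaction (no feasible positive growth under default bounds).
#'
#' @param model A [stoich_model()].
#' @param expression_genes Optional character vector of genes with
#'   expression data, used for the orphan-gene check.
#' @return `list(errors =, warnings =)` of messages (class
#'   `team_validation`).
#' @export
validate_model <- function(model, expression_genes = NULL) {
  stopifnot(inherits(model, "stoich_model"))
  errors <- character(0)
  warnings <- character(0)
  if (any(model$lb0 > model$ub0)) {
    errors <- c(errors, paste0("lb > ub for: ",
      paste(model$rxn_ids[model$lb0 > model$ub0], collapse = ", ")))
  }
  if (any(!model$reversible & model$lb0 < 0)) {
    errors <- c(errors, "irreversible reaction with negative lower bound")
  }
  nz <- colSums(model$S != 0)
  if (any(nz == 0)) {
    errors <- c(errors, paste0("reaction with no metabolites: ",
      paste(model$rxn_ids[nz == 0], collapse = ", ")))
  }
  if (any(model$exchange & nz != 1)) {
    errors <- c(errors, "exchange reaction touching more than one metabolite")
  }
  if (is.na(model$biomass)) {
    errors <- c(errors, "no biomass reaction configured")
  } else if (model$exchange[model$biomass]) {
    errors <- c(errors, "biomass reaction is in the exchange set")
  }
  if (!is.null(expression_genes)) {
    orphan <- setdiff(model$genes, expression_genes)
    if (length(orphan) > 0) {
      warnings <- c(warnings, paste0(
        "gene(s) in GPR rules without expression data (penalty 0): ",
        paste(orphan, collapse = ", ")))
    }
  }
  if (!is.na(model$biomass) && length(errors) == 0) {
    vmax <- fba_max_flux(model$S, model$lb0, model$ub0, model$biomass)
    if (is.na(vmax) || vmax <= 1e-9) {
      warnings <- c(warnings,
                    "biomass reaction is blocked under default bounds")
    }
  }
  structure(list(errors = errors, warnings = warnings),
            class = "team_validation")
}

#' @export
print.team_validation <- function(x, ...) {
  cat("Model validation:", length(x$errors), "error(s),",
      length(x$warnings), "warning(s)\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", length(x$rxn_ids), " reactions (",
      sum(x$exchange), " exchange), ", length(x$met_ids), " metabolites, ",
      length(x$genes), " genes\n", sep = "")
  if (!is.na(x$biomass)) cat("  biomass:", x$rxn_ids[x$biomass], "\n")
  invisible(x)
}

# Minimal SBML Level 3 (+fbc) reader; read-only support. Elements are
# matched by local name so that fbc-prefixed nodes resolve without
# namespace bookkeeping.
read_model_sbml <- function(path, biomass = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  by_name <- function(node, name) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
  }
  attr_of <- function(node, name) {
    a <- xml2::xml_attrs(node)
    hit <- which(sub(".*:", "", names(a)) == name)
    if (length(hit)) a[[hit[1]]] else NA_character_
  }
  sp <- by_name(doc, "species")
  met_ids <- xml2::xml_attr(sp, "id")
  met_names <- xml2::xml_attr(sp, "name")
  met_names[is.na(met_names)] <- met_ids[is.na(met_names)]
  params <- by_name(doc, "parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gp <- by_name(doc, "geneProduct")
  glabel <- stats::setNames(
    vapply(gp, attr_of, character(1), "label"),
    vapply(gp, attr_of, character(1), "id"))
  rx_nodes <- by_name(doc, "reaction")
  if (length(rx_nodes) == 0) stop("no reactions found in ", path,
                                  call. = FALSE)
  gpa_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      g <- attr_of(node, "geneProduct")
      if (g %in% names(glabel) && !is.na(glabel[g])) glabel[[g]] else g
    } else if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      paste0("(", paste(vapply(kids, gpa_to_text, character(1)),
                        collapse = paste0(" ", nm, " ")), ")")
    } else {
      kids <- xml2::xml_children(node)
      if (length(kids) == 1) gpa_to_text(kids[[1]]) else ""
    }
  }
  rows <- lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    reversible <- identical(xml2::xml_attr(nd, "reversible"), "true")
    get_side <- function(container) {
      refs <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='", container,
        "']/*[local-name()='speciesReference']"))
      s <- xml2::xml_attr(refs, "stoichiometry")
      s <- ifelse(is.na(s), 1, as.numeric(s))
      stats::setNames(s, xml2::xml_attr(refs, "species"))
    }
    rr <- get_side("listOfReactants")
    pp <- get_side("listOfProducts")
    lb_ref <- attr_of(nd, "lowerFluxBound")
    ub_ref <- attr_of(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
          else if (reversible) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]]
          else 1000
    gpa <- xml2::xml_find_first(
      nd, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) "" else gpa_to_text(kids[[1]])
    }
    fmt <- function(x) paste(
      vapply(seq_along(x), function(i) {
        if (x[i] == 1) names(x)[i] else paste(format(x[i]), names(x)[i])
      }, character(1)), collapse = " + ")
    formula <- trimws(paste(fmt(rr), if (reversible) "<->" else "->",
                            fmt(pp)))
    data.frame(id = id, formula = formula, lb = lb, ub = ub, gpr = gpr,
               stringsAsFactors = FALSE)
  })
  rx <- do.call(rbind, rows)
  if (is.null(biomass)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) biomass <- attr_of(fo, "reaction")
  }
  if (is.null(biomass) || is.na(biomass)) {
    hit <- grep("biomass", rx$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 1) biomass <- hit
  }
  if (is.null(biomass)) {
    stop("no biomass reaction configured (no fbc objective found; pass ",
         "`biomass`)", call. = FALSE)
  }
  stoich_model(rx, data.frame(id = met_ids, name = met_names),
               biomass = biomass)
}
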