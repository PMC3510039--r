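# Test oracles, independent of the package implementations.

# ---- random GPR trees + independent recursive evaluator ----

# Random Boolean tree over `genes`, in a representation unrelated to the
# package's: list(kind = "leaf", gene =) / list(kind = "node", op =, kids =).
random_tree <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(list(kind = "leaf", gene = sample(genes, 1)))
  }
  k <- sample(2:3, 1)
  list(kind = "node", op = sample(c("and", "or"), 1),
       kids = lapply(seq_len(k), function(i) random_tree(genes, depth - 1)))
}

tree_to_text <- function(tree) {
  if (tree$kind == "leaf") return(tree$gene)
  inner <- vapply(tree$kids, tree_to_text, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", toupper(tree$op), " ")),
         ")")
}

# Oracle evaluation: AND = max, OR = min, straight recursion.
tree_eval <- function(tree, p) {
  if (tree$kind == "leaf") {
    return(if (tree$gene %in% names(p)) p[[tree$gene]] else 0)
  }
  vals <- vapply(tree$kids, tree_eval, numeric(1), p = p)
  if (tree$op == "and") max(vals) else min(vals)
}

# ---- scipy (HiGHS) LP oracle ----

# Solve a batch of flux LPs with an entirely separate solver. Each problem
# is a list with S, lb, ub and optionally abs_w, lin_w, lock_w, lock_rhs,
# maximize. Returns a list of list(status, objective, V).
scipy_lp_batch <- function(problems) {
  script <- test_path("oracle_lp.py")
  fin <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) {
    p$S <- apply(unname(as.matrix(p$S)), 1, as.numeric, simplify = FALSE)
    p
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), fin)
  out <- system2("python", script, stdout = TRUE, stdin = fin)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# ---- random toy networks with a forced flux ----

# Random small stoichiometric system with bounded fluxes and one reaction
# forced on (so the penalty-minimizing optimum is nontrivial). Feasibility
# is ensured by construction: column j2 = -column j1 for the forced pair.
random_flux_problem <- function(n_rxn = 8, n_met = 4) {
  repeat {
    S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), n_met * n_rxn,
                       replace = TRUE), n_met, n_rxn)
    bad <- colSums(S != 0) == 0
    if (any(bad)) S[1, bad] <- 1
    # guarantee feasibility of the forced flux: make reaction 2 undo
    # reaction 1
    S[, 2] <- -S[, 1]
    lb <- ifelse(stats::runif(n_rxn) < 0.5, -5, 0)
    ub <- rep(5, n_rxn)
    lb[1] <- 1        # forced flux
    lb[2] <- -5
    c_pen <- round(stats::runif(n_rxn) * 4 * (stats::runif(n_rxn) < 0.6), 2)
    return(list(S = S, lb = lb, ub = ub, c_pen = c_pen))
  }
}

# ---- misc ----

toy_chain_model <- function() {
  rx <- data.frame(
    id = c("EX_a", "T_ab", "BM"),
    formula = c("a ->", "a -> b", "b ->"),
    lb = c(-10, 0, 0), ub = c(10, 10, 10),
    gpr = c("", "g1", ""), stringsAsFactors = FALSE)
  stoich_model(rx, biomass = "BM")
}

# Random model in the tabular dialect (for round-trip tests): integer
# stoichiometry, random GPR rules, a guaranteed biomass reaction.
random_tab_model <- function(n_rxn = 20, n_met = 8, genes = paste0("g", 1:6)) {
  met_ids <- paste0("m", seq_len(n_met))
  formulas <- character(n_rxn)
  gprs <- character(n_rxn)
  for (j in seq_len(n_rxn)) {
    k <- sample(1:3, 1)
    mets <- sample(met_ids, k + sample(0:2, 1), replace = FALSE)
    lhs <- mets[seq_len(k)]
    rhs <- setdiff(mets, lhs)
    coef <- function(ids) paste(
      vapply(ids, function(m) {
        cf <- sample(1:3, 1)
        if (cf == 1) m else paste(cf, m)
      }, character(1)), collapse = " + ")
    arrow <- if (stats::runif(1) < 0.4) "<->" else "->"
    formulas[j] <- trimws(paste(coef(lhs), arrow,
                                if (length(rhs)) coef(rhs) else ""))
    gprs[j] <- if (stats::runif(1) < 0.6) {
      tree_to_text(random_tree(genes, depth = 2))
    } else ""
  }
  lb <- ifelse(grepl("<->", formulas), -10, 0)
  rx <- data.frame(id = paste0("R", seq_len(n_rxn)), formula = formulas,
                   lb = lb, ub = rep(10, n_rxn), gpr = gprs,
                   stringsAsFactors = FALSE)
  stoich_model(rx, data.frame(id = met_ids, name = met_ids),
               biomass = "R1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
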