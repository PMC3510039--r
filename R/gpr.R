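#' Parse a gene-protein-reaction (GPR) Boolean rule
#'
#' GPR rules map gene states to reactions: `AND` joins genes that form an
#' enzyme complex, `OR` joins isoenzymes. `AND` binds tighter than `OR`,
#' so `"A OR B AND C"` parses as `OR(A, AND(B, C))`; parentheses override
#' precedence. Keywords are case-insensitive; `&` and `|` are accepted as
#' synonyms. An empty or whitespace-only string returns `NULL` (no rule).
#'
#' @param text GPR rule as a single character string, e.g.
#'   `"g1 and (g2 or g3)"`.
#' @return An object of class `gpr`: a nested list with elements
#'   `op` (`"and"`/`"or"`) and `args`, or `gene` at the leaves. `NULL` for
#'   an empty rule.
#' @examples
#' parse_gpr("A AND B")
#' parse_gpr("A OR B AND C")  # OR(A, AND(B, C))
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error near token ", st$pos, " ('",
         st$toks[st$pos], "') in rule: ", text, call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("&", " and ", text, fixed = TRUE)
  text <- gsub("|", " or ", text, fixed = TRUE)
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else
    structure(list(op = "or", args = args), class = "gpr")
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else
    structure(list(op = "and", args = args), class = "gpr")
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) {
    stop("GPR parse error: unexpected end of rule (dangling operator?)",
         call. = FALSE)
  }
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: unbalanced parentheses at token ", st$pos,
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected '", tk, "' at token ", st$pos,
         call. = FALSE)
  }
  st$pos <- st$pos + 1L
  structure(list(gene = tk), class = "gpr")
}

#' Serialize a GPR rule back to text
#'
#' Emits a string that [parse_gpr()] parses back to an identical tree
#' (print/parse round trip). Parentheses are inserted only where `OR`
#' appears under `AND`.
#'
#' @param x A `gpr` object.
#' @param ... Unused.
#' @return A character string, or `""` for `NULL`.
#' @export
format.gpr <- function(x, ...) {
  if (is.null(x)) return("")
  if (!is.null(x$gene)) return(x$gene)
  parts <- vapply(x$args, function(a) {
    s <- format.gpr(a)
    # parenthesize every operator child so nesting survives re-parsing
    if (is.null(a$gene)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", x$op, " "))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", format.gpr(x), "\n", sep = "")
  invisible(x)
}

#' List the gene identifiers appearing in a GPR rule
#'
#' @param x A `gpr` object (or `NULL`).
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(x) {
  if (is.null(x)) return(character(0))
  if (!is.null(x$gene)) return(x$gene)
  unique(unlist(lapply(x$args, gpr_genes)))
}

#' Evaluate a GPR rule over per-gene penalty values
#'
#' `AND` (enzyme complex) takes the maximum child penalty: the least
#' expressed subunit limits the reaction. `OR` (isoenzymes) takes the
#' minimum: the most available isoenzyme carries the flux. Genes missing
#' from `p` evaluate to `default` (0 = unpenalized: absence of evidence
#' does not block flux).
#'
#' @param x A `gpr` object or `NULL`.
#' @param p Named numeric vector of gene penalties.
#' @param default Value for genes absent from `p` (default 0).
#' @return A single numeric penalty; 0 for `NULL` rules.
#' @export
eval_gpr <- function(x, p, default = 0) {
  if (is.null(x)) return(0)
  if (!is.null(x$gene)) {
    v <- p[x$gene]
    return(if (is.na(v) || !x$gene %in% names(p)) default else unname(v))
  }
  vals <- vapply(x$args, eval_gpr, numeric(1), p = p, default = default)
  if (x$op == "and") max(vals) else min(vals)
}
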