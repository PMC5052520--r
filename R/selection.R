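# Atom selection mini-language. Grammar:
#   expr   := term ('or' term)*
#   term   := factor ('and' factor)*
#   factor := '(' expr ')' | key value
#   key    := resid | resname | name | chain | element
# Values are bare tokens; matching is case-insensitive for names and
# elements, numeric for resid. Resolution is deterministic and returns
# indices in topology order.

selection_keys <- c("resid", "resname", "name", "chain", "element")

tokenize_selection <- function(expression) {
  toks <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(expression, i, n),
                    regexpr("^[^\\s()]+", substr(expression, i, n), perl = TRUE))
    toks[[length(toks) + 1L]] <- list(text = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

#' Select atoms by expression
#'
#' Resolves a selection expression such as `"resid 169 and name SG"` or
#' `"element Cl"` against a trajectory's topology. Clauses (`resid`,
#' `resname`, `name`, `chain`, `element`) combine with `and`/`or` and
#' parentheses. An empty match is allowed but raises a warning.
#'
#' @param traj An [xtraj()].
#' @param expression Selection string.
#' @return An object of class `atom_selection`: list with `expression`
#'   and integer `indices` into the topology.
#' @export
#' @examples
#' \dontrun{
#' select_atoms(traj, "resid 169 and name SG")
#' }
select_atoms <- function(traj, expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  toks <- tokenize_selection(expression)
  if (!length(toks)) stop("syntax error at position 1: empty selection")
  top <- traj$topology
  pos <- 1L  # token cursor, shared via environment
  env <- environment()

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; assign("pos", pos + 1L, envir = env); t }
  syntax_error <- function(tok, what) {
    at <- if (is.null(tok)) nchar(expression) + 1L else tok$pos
    stop("syntax error at position ", at, ": ", what, call. = FALSE)
  }

  parse_clause <- function() {
    tok <- peek()
    if (is.null(tok)) syntax_error(tok, "expected a clause")
    if (tok$text == "(") {
      advance()
      v <- parse_expr()
      cl <- peek()
      if (is.null(cl) || cl$text != ")") syntax_error(cl, "expected ')'")
      advance()
      return(v)
    }
    key <- tolower(tok$text)
    if (!key %in% selection_keys)
      syntax_error(tok, paste0("unknown clause '", tok$text, "'"))
    advance()
    val <- peek()
    if (is.null(val) || val$text %in% c("(", ")") ||
        tolower(val$text) %in% c("and", "or"))
      syntax_error(val, paste0("expected a value after '", key, "'"))
    advance()
    eval_clause(key, val, top, syntax_error)
  }

  parse_term <- function() {
    v <- parse_clause()
    repeat {
      tok <- peek()
      if (is.null(tok) || tolower(tok$text) != "and") return(v)
      advance()
      v <- v & parse_clause()
    }
  }

  parse_expr <- function() {
    v <- parse_term()
    repeat {
      tok <- peek()
      if (is.null(tok) || tolower(tok$text) != "or") return(v)
      advance()
      v <- v | parse_term()
    }
  }

  mask <- parse_expr()
  left <- peek()
  if (!is.null(left)) syntax_error(left, paste0("unexpected token '", left$text, "'"))
  idx <- which(mask)
  if (!length(idx)) warning("selection '", expression, "' matched no atoms")
  structure(list(expression = expression, indices = idx),
            class = "atom_selection")
}

eval_clause <- function(key, val, top, syntax_error) {
  v <- val$text
  switch(key,
    resid = {
      num <- suppressWarnings(as.integer(v))
      if (is.na(num)) syntax_error(val, paste0("resid expects an integer, got '", v, "'"))
      top$residue_number == num
    },
    resname = toupper(top$residue_name) == toupper(v),
    name = toupper(top$atom_name) == toupper(v),
    chain = top$chain_id == v,
    element = {
      el <- canonical_element(v)
      if (is.na(el)) syntax_error(val, paste0("unknown element '", v, "'"))
      !is.na(top$element) & top$element == el
    }
  )
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> '", x$expression, "': ", length(x$indices),
      " atom(s)\n", sep = "")
  invisible(x)
}

# resolve a selection argument that may be an expression string, an
# atom_selection, or raw indices; optionally require exactly one atom
resolve_selection <- function(traj, sel, what = "selection", exactly_one = FALSE) {
  idx <- if (inherits(sel, "atom_selection")) sel$indices
         else if (is.character(sel)) suppressWarnings(select_atoms(traj, sel)$indices)
         else as.integer(sel)
  if (any(idx < 1L | idx > n_atoms(traj)))
    stop(what, " resolves outside the topology")
  if (exactly_one && length(idx) != 1L) {
    lab <- if (is.character(sel)) sel
           else if (inherits(sel, "atom_selection")) sel$expression
           else paste(idx, collapse = ",")
    stop("specification error: ", what, " '", lab, "' must resolve to exactly 1 atom, got ",
         length(idx), call. = FALSE)
  }
  idx
}
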