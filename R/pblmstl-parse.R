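# Parser for probabilistic bounded linear multiscale spatial temporal logic.
#
# A query has the shape  P <cmp> theta [ formula ]  with theta in (0, 1).
# Formulas combine comparisons of numeric expressions with Boolean
# connectives and the bounded temporal operators G[a,b], F[a,b] and the
# binary U[a,b]. Numeric expressions reference numeric state variables
# ({name}(scaleAndSubsystem = scale.subsystem)), apply arithmetic functions,
# or apply statistical functions to collections; a collection is either the
# values of a spatial measure over an entity-set expression at the current
# time, or a numeric expression sampled over a time window ([a,b] expr).
# Entity sets are built from filter(type, constraint) with union /
# intersection / difference operators.
#
# Surface syntax is ASCII with Unicode aliases accepted for the logical and
# set operators. All scale.subsystem literals are bound against the MA
# graph and all entity types / measure names against the spatial registry
# at parse time, so typos fail fast instead of silently evaluating false.

UNARY_STAT_FNS <- c("count", "sum", "avg", "mean", "min", "max", "median",
                    "mode", "product", "stdev", "var", "skew", "kurtosis",
                    "geomean", "harmean")
BINARY_STAT_FNS <- c("covariance")
QUANTILE_FNS <- c("percentile", "quartile")
UNARY_ARITH_FNS <- c("abs", "ceil", "floor", "round", "sign", "sqrt", "trunc")
BINARY_ARITH_FNS <- c("add", "div", "log", "mod", "multiply", "power",
                      "subtract")
COMPARATORS <- c("<", "<=", "=", ">=", ">")

# --- tokenizer --------------------------------------------------------------

UNICODE_ALIASES <- c("∧" = "and", "∨" = "or", "¬" = "not",
                     "⇒" = "=>", "≤" = "<=", "≥" = ">=",
                     "∩" = "intersection", "∪" = "union")

tokenize_pblmstl <- function(text) {
  tokens <- list()
  line <- 1L
  col <- 1L
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line, col = col)
  }
  advance <- function(k) {
    chunk <- substr(text, i, i + k - 1L)
    nl <- gregexpr("\n", chunk, fixed = TRUE)[[1L]]
    if (nl[1L] != -1L) {
      line <<- line + length(nl)
      col <<- k - max(nl) + 1L
    } else {
      col <<- col + k
    }
    i <<- i + k
  }
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(rest, 1L, 1L)
    if (grepl("^[[:space:]]", ch)) { advance(1L); next }
    if (ch == "#") {                      # comment to end of line
      len <- regexpr("\n", rest, fixed = TRUE)
      if (len == -1L) break
      advance(len - 1L)
      next
    }
    m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))
    if (length(m)) {
      push("NUMBER", as.numeric(m))
      advance(nchar(m))
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m)) {
      push("IDENT", m)
      advance(nchar(m))
      next
    }
    two <- substr(rest, 1L, 2L)
    if (two %in% c("<=", ">=", "=>")) {
      push("OP", two)
      advance(2L)
      next
    }
    if (ch %in% names(UNICODE_ALIASES)) {
      alias <- UNICODE_ALIASES[[ch]]
      push(if (alias %in% c("and", "or", "not", "union", "intersection"))
        "IDENT" else "OP", alias)
      advance(1L)
      next
    }
    if (ch %in% c("(", ")", "[", "]", "{", "}", ",", ".", "<", ">", "=",
                  "^", "\\", "!", "-", ";")) {
      push("OP", ch)
      advance(1L)
      next
    }
    abort_syntax(sprintf("unexpected character '%s' at line %d, column %d",
                         ch, line, col))
  }
  tokens[[length(tokens) + 1L]] <- list(type = "EOF", value = "",
                                        line = line, col = col)
  tokens
}

# --- parser state -----------------------------------------------------------

new_parser <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env
}

peek <- function(ps, offset = 0L) ps$tokens[[ps$pos + offset]]

peek_is <- function(ps, type, value = NULL) {
  tok <- peek(ps)
  tok$type == type && (is.null(value) || tok$value %in% value)
}

take <- function(ps) {
  tok <- ps$tokens[[ps$pos]]
  ps$pos <- ps$pos + 1L
  tok
}

expect <- function(ps, type, value = NULL, what = NULL) {
  tok <- peek(ps)
  if (tok$type != type || (!is.null(value) && !tok$value %in% value)) {
    want <- if (!is.null(what)) what else if (!is.null(value))
      paste0("'", paste(value, collapse = "' or '"), "'") else type
    abort_syntax(sprintf("expected %s but found '%s' at line %d, column %d",
                         want, tok$value, tok$line, tok$col))
  }
  take(ps)
}

parse_error_here <- function(ps, msg) {
  tok <- peek(ps)
  abort_syntax(sprintf("%s at line %d, column %d", msg, tok$line, tok$col))
}

# --- grammar ----------------------------------------------------------------

node <- function(type, ...) c(list(type = type), list(...))

p_query <- function(ps) {
  tok <- expect(ps, "IDENT", "P", "'P'")
  cmp_tok <- expect(ps, "OP", c("<", "<=", ">=", ">"),
                    "probability comparator")
  theta <- expect(ps, "NUMBER")$value
  if (theta <= 0 || theta >= 1)
    abort_range(sprintf("probability threshold must lie strictly in (0, 1), got %g",
                        theta))
  expect(ps, "OP", "[")
  body <- p_formula(ps)
  expect(ps, "OP", "]")
  structure(node("query", cmp = cmp_tok$value, theta = theta, body = body),
            class = "pblmstl_query")
}

p_formula <- function(ps) {
  lhs <- p_or(ps)
  if (peek_is(ps, "OP", "=>")) {
    take(ps)
    rhs <- p_formula(ps)   # right-associative
    return(node("implies", lhs = lhs, rhs = rhs))
  }
  lhs
}

p_or <- function(ps) {
  lhs <- p_and(ps)
  while (peek_is(ps, "IDENT", c("or", "V"))) {
    take(ps)
    lhs <- node("or", lhs = lhs, rhs = p_and(ps))
  }
  lhs
}

p_and <- function(ps) {
  lhs <- p_until(ps)
  while (peek_is(ps, "IDENT", "and") || peek_is(ps, "OP", "^")) {
    take(ps)
    lhs <- node("and", lhs = lhs, rhs = p_until(ps))
  }
  lhs
}

p_until <- function(ps) {
  lhs <- p_unary(ps)
  if (peek_is(ps, "IDENT", "U")) {
    take(ps)
    b <- p_bounds(ps)
    rhs <- p_unary(ps)
    return(node("U", a = b[1], b = b[2], lhs = lhs, rhs = rhs))
  }
  lhs
}

p_bounds <- function(ps) {
  expect(ps, "OP", "[")
  a <- p_signed_number(ps)
  expect(ps, "OP", ",")
  b <- p_signed_number(ps)
  expect(ps, "OP", "]")
  if (a < 0 || b < a)
    abort_range(sprintf("invalid time bounds [%g, %g]: need 0 <= a <= b", a, b))
  c(a, b)
}

p_signed_number <- function(ps) {
  neg <- FALSE
  if (peek_is(ps, "OP", "-")) { take(ps); neg <- TRUE }
  v <- expect(ps, "NUMBER")$value
  if (neg) -v else v
}

p_unary <- function(ps) {
  if (peek_is(ps, "IDENT", "not") || peek_is(ps, "OP", "!")) {
    take(ps)
    return(node("not", body = p_unary(ps)))
  }
  if (peek_is(ps, "IDENT", c("G", "F")) &&
      peek(ps, 1L)$type == "OP" && peek(ps, 1L)$value == "[") {
    op <- take(ps)$value
    b <- p_bounds(ps)
    return(node(op, a = b[1], b = b[2], body = p_unary(ps)))
  }
  p_primary(ps)
}

p_primary <- function(ps) {
  if (peek_is(ps, "OP", "(")) {
    # '(' may open a parenthesized formula or a parenthesized numeric
    # expression inside a comparison; resolve by backtracking.
    mark <- ps$pos
    take(ps)
    res <- tryCatch({
      f <- p_formula(ps)
      expect(ps, "OP", ")")
      # a comparator here means '(...)' was the lhs numeric expression of a
      # comparison, e.g. "(1) > 0"; reject the formula interpretation
      if (peek_is(ps, "OP", COMPARATORS)) NULL else f
    }, mstmc_error_syntax = function(e) NULL)
    if (!is.null(res)) return(res)
    ps$pos <- mark
  }
  p_comparison(ps)
}

p_comparison <- function(ps) {
  lhs <- p_numexpr(ps)
  cmp <- expect(ps, "OP", COMPARATORS, "comparator")$value
  rhs <- p_numexpr(ps)
  node("cmp", cmp = cmp, lhs = lhs, rhs = rhs)
}

p_ss_literal <- function(ps) {
  scale <- expect(ps, "IDENT", what = "scale identifier")$value
  expect(ps, "OP", ".")
  subsys <- expect(ps, "IDENT", what = "subsystem identifier")$value
  ss_key(scale_subsystem(scale, subsys))
}

p_numexpr <- function(ps) {
  if (peek_is(ps, "OP", "(")) {
    take(ps)
    e <- p_numexpr(ps)
    expect(ps, "OP", ")")
    return(e)
  }
  if (peek_is(ps, "OP", "-") || peek_is(ps, "NUMBER"))
    return(node("num", value = p_signed_number(ps)))
  if (peek_is(ps, "OP", "{")) {
    take(ps)
    name <- expect(ps, "IDENT", what = "state variable name")$value
    expect(ps, "OP", "}")
    expect(ps, "OP", "(")
    expect(ps, "IDENT", "scaleAndSubsystem")
    expect(ps, "OP", "=")
    ss <- p_ss_literal(ps)
    expect(ps, "OP", ")")
    return(node("var", name = name, ss = ss))
  }
  if (!peek_is(ps, "IDENT"))
    parse_error_here(ps, "expected a numeric expression")
  name <- peek(ps)$value
  if (name == "d") {
    take(ps); expect(ps, "OP", "(")
    e <- p_numexpr(ps)
    expect(ps, "OP", ")")
    return(node("d", body = e))
  }
  if (name %in% UNARY_ARITH_FNS) {
    take(ps); expect(ps, "OP", "(")
    e <- p_numexpr(ps)
    expect(ps, "OP", ")")
    return(node("arith1", fn = name, body = e))
  }
  if (name %in% BINARY_ARITH_FNS) {
    take(ps); expect(ps, "OP", "(")
    e1 <- p_numexpr(ps)
    expect(ps, "OP", ",")
    e2 <- p_numexpr(ps)
    expect(ps, "OP", ")")
    return(node("arith2", fn = name, lhs = e1, rhs = e2))
  }
  if (name %in% UNARY_STAT_FNS) {
    take(ps); expect(ps, "OP", "(")
    coll <- p_collection(ps)
    expect(ps, "OP", ")")
    return(node("stat1", fn = if (name == "mean") "avg" else name,
                coll = coll))
  }
  if (name %in% BINARY_STAT_FNS) {
    take(ps); expect(ps, "OP", "(")
    c1 <- p_collection(ps)
    expect(ps, "OP", ",")
    c2 <- p_collection(ps)
    expect(ps, "OP", ")")
    return(node("stat2", fn = name, c1 = c1, c2 = c2))
  }
  if (name %in% QUANTILE_FNS) {
    take(ps); expect(ps, "OP", "(")
    coll <- p_collection(ps)
    expect(ps, "OP", ",")
    q <- p_signed_number(ps)
    expect(ps, "OP", ")")
    return(node("quantile", fn = name, coll = coll, q = q))
  }
  parse_error_here(ps, sprintf("unknown function or expression '%s'", name))
}

p_collection <- function(ps) {
  if (peek_is(ps, "OP", "[")) {
    b <- p_bounds(ps)
    e <- p_numexpr(ps)
    return(node("temporal_coll", a = b[1], b = b[2], body = e))
  }
  measure <- expect(ps, "IDENT", what = "spatial measure name")$value
  expect(ps, "OP", "(")
  set <- p_setexpr(ps)
  expect(ps, "OP", ")")
  node("spatial_coll", measure = measure, set = set)
}

p_setexpr <- function(ps) {
  lhs <- p_setterm(ps)
  repeat {
    if (peek_is(ps, "IDENT", c("union", "intersection", "difference"))) {
      op <- take(ps)$value
      lhs <- node("setop", op = op, lhs = lhs, rhs = p_setterm(ps))
    } else if (peek_is(ps, "OP", "\\")) {
      take(ps)
      lhs <- node("setop", op = "difference", lhs = lhs, rhs = p_setterm(ps))
    } else {
      return(lhs)
    }
  }
}

p_setterm <- function(ps) {
  if (peek_is(ps, "OP", "(")) {
    take(ps)
    s <- p_setexpr(ps)
    expect(ps, "OP", ")")
    return(s)
  }
  if (peek_is(ps, "IDENT", "filter")) {
    take(ps); expect(ps, "OP", "(")
    etype <- expect(ps, "IDENT", what = "entity type")$value
    constraints <- list()
    if (peek_is(ps, "OP", ",")) {
      take(ps)
      constraints <- p_constraint(ps)
    }
    expect(ps, "OP", ")")
    return(node("filter", etype = etype, constraints = constraints))
  }
  etype <- expect(ps, "IDENT", what = "entity type or filter(...)")$value
  node("filter", etype = etype, constraints = list())
}

# A constraint is a conjunction of measure comparisons and scaleAndSubsystem
# comparisons; returns a flat list of constraint items.
p_constraint <- function(ps) {
  items <- list(p_constraint_term(ps))
  while (peek_is(ps, "IDENT", "and") || peek_is(ps, "OP", "^")) {
    take(ps)
    items <- c(items, list(p_constraint_term(ps)))
  }
  items
}

p_constraint_term <- function(ps) {
  if (peek_is(ps, "OP", "(")) {
    take(ps)
    items <- p_constraint(ps)
    expect(ps, "OP", ")")
    return(node("group", items = items))
  }
  name <- expect(ps, "IDENT", what = "measure or scaleAndSubsystem")$value
  if (name == "scaleAndSubsystem") {
    cmp <- expect(ps, "OP", c("=", "<", "<="),
                  "scaleAndSubsystem comparator (=, < or <=)")$value
    ss <- p_ss_literal(ps)
    return(node("ss_constraint", cmp = cmp, ss = ss))
  }
  cmp <- expect(ps, "OP", COMPARATORS, "comparator")$value
  value <- p_signed_number(ps)
  node("measure_constraint", name = name, cmp = cmp, value = value)
}

# --- binding validation -----------------------------------------------------

bind_query <- function(q, g, registry) {
  walk <- function(x) {
    if (!is.list(x) || is.null(x$type)) return(invisible())
    switch(x$type,
      var = {
        if (!x$ss %in% g$vertices)
          abort_binding(sprintf(
            "scale.subsystem '%s' is not a vertex of the multiscale architecture",
            x$ss))
      },
      filter = {
        if (is.na(match(x$etype, registry$entity_types$name)))
          abort_binding(sprintf("entity type '%s' is not registered", x$etype))
        lapply(x$constraints, walk)
      },
      ss_constraint = {
        if (!x$ss %in% g$vertices)
          abort_binding(sprintf(
            "scale.subsystem '%s' is not a vertex of the multiscale architecture",
            x$ss))
      },
      measure_constraint = {
        if (is.na(match(x$name, registry$measures$name)))
          abort_binding(sprintf("spatial measure '%s' is not registered", x$name))
      },
      spatial_coll = {
        if (is.na(match(x$measure, registry$measures$name)))
          abort_binding(sprintf("spatial measure '%s' is not registered",
                                x$measure))
        walk(x$set)
      },
      group = lapply(x$items, walk),
      { # default: recurse into list children
        for (child in x) if (is.list(child)) walk(child)
      })
    invisible()
  }
  walk(if (inherits(q, "pblmstl_query")) q$body else q)
  invisible(q)
}

#' Parse a probabilistic spatio-temporal logic statement
#'
#' Parses text of the form \code{P > 0.99 [ ... ]} into a query AST,
#' binding every \code{scale.subsystem} literal against the multiscale
#' architecture and every entity type / spatial measure against the
#' registry.
#'
#' @param text Statement text (one statement).
#' @param g \code{ma_graph} used for binding.
#' @param registry \code{spatial_registry} used for binding.
#' @return A \code{pblmstl_query} with fields \code{cmp} (one of
#'   \code{<, <=, >=, >}), \code{theta} and \code{body} (formula AST).
#' @examples
#' g <- ma_graph_single("Organ", "Liver")
#' parse_query("P > 0.5 [G[0, 0] (1 = 1)]", g)
#' @export
parse_query <- function(text, g, registry = default_spatial_registry()) {
  ps <- new_parser(tokenize_pblmstl(text))
  q <- p_query(ps)
  if (!peek_is(ps, "EOF"))
    parse_error_here(ps, "trailing input after statement")
  bind_query(q, g, registry)
  q
}

#' Parse a formula (without the probabilistic wrapper)
#'
#' @inheritParams parse_query
#' @return A formula AST.
#' @export
parse_formula <- function(text, g, registry = default_spatial_registry()) {
  ps <- new_parser(tokenize_pblmstl(text))
  f <- p_formula(ps)
  if (!peek_is(ps, "EOF"))
    parse_error_here(ps, "trailing input after formula")
  bind_query(f, g, registry)
  f
}

#' Parse a specification file into individual statements
#'
#' Statements are separated by \code{';'}; \code{'#'} starts a line comment.
#'
#' @param text Full file text (or a path to a file).
#' @param g,registry Passed to [parse_query()].
#' @return List of \code{pblmstl_query} objects; the character attribute
#'   \code{"sources"} holds the statement texts.
#' @export
parse_specification <- function(text, g, registry = default_spatial_registry()) {
  if (length(text) == 1L && !grepl("[\\[\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  text <- paste(text, collapse = "\n")
  # strip comments, then split on ';'
  stripped <- gsub("#[^\n]*", "", text)
  pieces <- strsplit(stripped, ";", fixed = TRUE)[[1L]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  queries <- lapply(pieces, parse_query, g = g, registry = registry)
  attr(queries, "sources") <- pieces
  queries
}

#' Single-vertex multiscale architecture helper
#'
#' @param scale,subsystem Tokens of the single (root) vertex.
#' @return An \code{ma_graph} with one vertex.
#' @export
ma_graph_single <- function(scale, subsystem) {
  new_ma_graph(ss_key(scale_subsystem(scale, subsystem)), character(0))
}

# --- pretty printer ---------------------------------------------------------

#' Render an AST back to canonical statement text
#'
#' \code{format_query(parse_query(s, ...))} re-parses to an identical AST.
#'
#' @param x A \code{pblmstl_query} or formula AST.
#' @return Character scalar.
#' @export
format_query <- function(x) {
  if (inherits(x, "pblmstl_query"))
    return(sprintf("P %s %s [%s]", x$cmp, format_num_token(x$theta),
                   format_ast(x$body)))
  format_ast(x)
}

format_num_token <- function(v) {
  if (v < 0) sprintf("- %s", format_mstml_number(-v)) else format_mstml_number(v)
}

format_ast <- function(x) {
  switch(x$type,
    implies = sprintf("(%s) => (%s)", format_ast(x$lhs), format_ast(x$rhs)),
    or = sprintf("(%s) or (%s)", format_ast(x$lhs), format_ast(x$rhs)),
    and = sprintf("(%s) and (%s)", format_ast(x$lhs), format_ast(x$rhs)),
    not = sprintf("not (%s)", format_ast(x$body)),
    G = sprintf("G [%s, %s] (%s)", format_mstml_number(x$a),
                format_mstml_number(x$b), format_ast(x$body)),
    F = sprintf("F [%s, %s] (%s)", format_mstml_number(x$a),
                format_mstml_number(x$b), format_ast(x$body)),
    U = sprintf("(%s) U [%s, %s] (%s)", format_ast(x$lhs),
                format_mstml_number(x$a), format_mstml_number(x$b),
                format_ast(x$rhs)),
    cmp = sprintf("%s %s %s", format_ast(x$lhs), x$cmp, format_ast(x$rhs)),
    num = format_num_token(x$value),
    var = sprintf("{%s}(scaleAndSubsystem = %s)", x$name, x$ss),
    d = sprintf("d(%s)", format_ast(x$body)),
    arith1 = sprintf("%s(%s)", x$fn, format_ast(x$body)),
    arith2 = sprintf("%s(%s, %s)", x$fn, format_ast(x$lhs), format_ast(x$rhs)),
    stat1 = sprintf("%s(%s)", x$fn, format_ast(x$coll)),
    stat2 = sprintf("%s(%s, %s)", x$fn, format_ast(x$c1), format_ast(x$c2)),
    quantile = sprintf("%s(%s, %s)", x$fn, format_ast(x$coll),
                       format_num_token(x$q)),
    temporal_coll = sprintf("[%s, %s] %s", format_mstml_number(x$a),
                            format_mstml_number(x$b), format_ast(x$body)),
    spatial_coll = sprintf("%s(%s)", x$measure, format_ast(x$set)),
    setop = sprintf("(%s) %s (%s)", format_ast(x$lhs), x$op, format_ast(x$rhs)),
    filter = {
      if (length(x$constraints)) {
        sprintf("filter(%s, %s)", x$etype,
                paste(vapply(x$constraints, format_constraint, character(1)),
                      collapse = " and "))
      } else {
        sprintf("filter(%s)", x$etype)
      }
    },
    stop(sprintf("unknown AST node type '%s'", x$type)))
}

format_constraint <- function(x) {
  switch(x$type,
    ss_constraint = sprintf("scaleAndSubsystem %s %s", x$cmp, x$ss),
    measure_constraint = sprintf("%s %s %s", x$name, x$cmp,
                                 format_num_token(x$value)),
    group = sprintf("(%s)",
                    paste(vapply(x$items, format_constraint, character(1)),
                          collapse = " and ")))
}

#' @export
print.pblmstl_query <- function(x, ...) {
  cat("<pblmstl_query>", format_query(x), "\n")
  invisible(x)
}
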