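# Sample-based evaluation of the spatio-temporal logic against one trace.
#
# Semantics: only observed timepoints are quantified over (offline
# monitoring of a recorded trace; no interpolation between samples).
# Evaluation starts at the first timepoint, whose timestamp is the temporal
# origin. G[a,b] f holds at time t iff f holds at every observed timepoint
# with timestamp in [t+a, t+b]; F[a,b] at some such timepoint; f1 U[a,b] f2
# iff some observed t' in [t+a, t+b] satisfies f2 and every observed
# timepoint in [t, t') satisfies f1. All interval ends are inclusive except
# the U left-closure shown. d(e) is the forward difference e(i+1) - e(i)
# (a sign detector, not a rate). Equality of reals uses a relative
# tolerance of 1e-9. A statistical function other than count() applied to
# an empty collection makes the smallest enclosing comparison false and
# emits a warning (a trace with no detected entities should falsify claims
# about them rather than crash a long run).

REL_EQ_TOL <- 1e-9

approx_equal <- function(a, b) {
  abs(a - b) <= REL_EQ_TOL * max(1, abs(a), abs(b))
}

apply_comparator <- function(cmp, a, b) {
  switch(cmp,
    "<" = a < b && !approx_equal(a, b),
    "<=" = a < b || approx_equal(a, b),
    "=" = approx_equal(a, b),
    ">=" = a > b || approx_equal(a, b),
    ">" = a > b && !approx_equal(a, b),
    stop(sprintf("unknown comparator '%s'", cmp)))
}

eval_context <- function(trace, g, registry = default_spatial_registry(),
                         locf = FALSE) {
  list(trace = trace, times = trace_times(trace), g = g,
       registry = registry, locf = locf)
}

#' Least trace duration required to evaluate a formula
#'
#' Sums nested upper temporal bounds (temporal operators and temporal
#' collections). \code{d()} itself needs one extra sample beyond the
#' current timepoint; pass the trace's sampling step as \code{sample_step}
#' to include that requirement in time units (the evaluator additionally
#' checks for a missing successor dynamically).
#'
#' @param f Formula AST (or \code{pblmstl_query}).
#' @param sample_step Time charged per nested \code{d()} application.
#' @return Non-negative real.
#' @export
required_horizon <- function(f, sample_step = 0) {
  if (inherits(f, "pblmstl_query")) f <- f$body
  h <- function(x) {
    if (!is.list(x) || is.null(x$type)) return(0)
    switch(x$type,
      G = ,
      F = x$b + h(x$body),
      U = x$b + max(h(x$lhs), h(x$rhs)),
      temporal_coll = x$b + h(x$body),
      d = sample_step + h(x$body),
      { # max over list children
        vals <- vapply(x, function(child)
          if (is.list(child)) h(child) else 0, numeric(1))
        if (length(vals)) max(vals) else 0
      })
  }
  h(f)
}

window_indices <- function(ctx, lo, hi) {
  which(ctx$times >= lo - REL_EQ_TOL & ctx$times <= hi + REL_EQ_TOL)
}

#' Evaluate a formula on a trace
#'
#' @param f Formula AST from [parse_formula()] (or a \code{pblmstl_query},
#'   whose body is used).
#' @param trace An \code{mst_trace} (non-empty).
#' @param g \code{ma_graph}.
#' @param registry Active \code{spatial_registry}.
#' @param at Timepoint index at which evaluation starts (default: first).
#' @param locf Carry numeric variables forward over gaps (see
#'   [trace_lookup_numeric()]).
#' @return Logical scalar.
#' @export
evaluate_formula <- function(f, trace, g,
                             registry = default_spatial_registry(),
                             at = 1L, locf = FALSE) {
  if (inherits(f, "pblmstl_query")) f <- f$body
  if (!length(trace$timepoints))
    abort_format("cannot evaluate a formula on an empty trace")
  ctx <- eval_context(trace, g, registry, locf)
  duration <- ctx$times[length(ctx$times)] - ctx$times[1L]
  need <- required_horizon(f)
  if (need > duration + REL_EQ_TOL)
    abort_horizon(sprintf(
      "formula requires a trace of duration >= %g but the trace spans %g (deficit %g)",
      need, duration, need - duration))
  eval_f(f, at, ctx)
}

eval_f <- function(x, i, ctx) {
  switch(x$type,
    cmp = eval_comparison(x, i, ctx),
    not = !eval_f(x$body, i, ctx),
    and = eval_f(x$lhs, i, ctx) && eval_f(x$rhs, i, ctx),
    or = eval_f(x$lhs, i, ctx) || eval_f(x$rhs, i, ctx),
    implies = !eval_f(x$lhs, i, ctx) || eval_f(x$rhs, i, ctx),
    G = {
      t <- ctx$times[i]
      all(vapply(window_indices(ctx, t + x$a, t + x$b),
                 function(j) eval_f(x$body, j, ctx), logical(1)))
    },
    F = {
      t <- ctx$times[i]
      any(vapply(window_indices(ctx, t + x$a, t + x$b),
                 function(j) eval_f(x$body, j, ctx), logical(1)))
    },
    U = {
      t <- ctx$times[i]
      for (j in window_indices(ctx, t + x$a, t + x$b)) {
        if (eval_f(x$rhs, j, ctx)) {
          prefix <- which(ctx$times >= t - REL_EQ_TOL &
                            ctx$times < ctx$times[j] - REL_EQ_TOL)
          if (all(vapply(prefix, function(k) eval_f(x$lhs, k, ctx),
                         logical(1))))
            return(TRUE)
        }
      }
      FALSE
    },
    stop(sprintf("unknown formula node '%s'", x$type)))
}

eval_comparison <- function(x, i, ctx) {
  tryCatch({
    a <- eval_num(x$lhs, i, ctx)
    b <- eval_num(x$rhs, i, ctx)
    apply_comparator(x$cmp, a, b)
  }, mstmc_empty_collection = function(cond) {
    warning(sprintf("%s; comparison treated as false", conditionMessage(cond)),
            call. = FALSE)
    FALSE
  })
}

#' Evaluate a numeric expression at one timepoint
#'
#' @param e Numeric-expression AST.
#' @param at Timepoint index.
#' @inheritParams evaluate_formula
#' @return Numeric scalar.
#' @export
evaluate_numeric <- function(e, trace, g,
                             registry = default_spatial_registry(),
                             at = 1L, locf = FALSE) {
  eval_num(e, at, eval_context(trace, g, registry, locf))
}

eval_num <- function(x, i, ctx) {
  switch(x$type,
    num = x$value,
    var = trace_lookup_numeric(ctx$trace, i, x$name, x$ss, ctx$locf),
    d = {
      if (i + 1L > length(ctx$times))
        abort_horizon(sprintf(
          "d() at the final timepoint t = %g needs a successor sample",
          ctx$times[i]))
      eval_num(x$body, i + 1L, ctx) - eval_num(x$body, i, ctx)
    },
    arith1 = apply_arith1(x$fn, eval_num(x$body, i, ctx)),
    arith2 = apply_arith2(x$fn, eval_num(x$lhs, i, ctx),
                          eval_num(x$rhs, i, ctx)),
    stat1 = apply_stat1(x$fn, eval_collection(x$coll, i, ctx)),
    stat2 = apply_stat2(x$fn, eval_collection(x$c1, i, ctx),
                        eval_collection(x$c2, i, ctx)),
    quantile = apply_quantile(x$fn, eval_collection(x$coll, i, ctx), x$q),
    stop(sprintf("unknown numeric node '%s'", x$type)))
}

eval_collection <- function(x, i, ctx) {
  if (x$type == "temporal_coll") {
    t <- ctx$times[i]
    idx <- window_indices(ctx, t + x$a, t + x$b)
    return(vapply(idx, function(j) eval_num(x$body, j, ctx), numeric(1)))
  }
  entities <- eval_set(x$set, i, ctx)
  vapply(entities, function(ent) {
    if (!x$measure %in% names(ent$measures))
      abort_registry(sprintf("entity lacks measure '%s'", x$measure))
    ent$measures[[x$measure]]
  }, numeric(1))
}

#' Resolve an entity-set expression at one timepoint
#'
#' \code{filter} keeps entities of the named type whose measures satisfy
#' every constraint and whose scale.subsystem satisfies the
#' \code{scaleAndSubsystem} constraint under the MA graph's partial order;
#' set operations work by entity identity within the timepoint, preserving
#' trace order.
#'
#' @param x Entity-set AST.
#' @param at Timepoint index.
#' @inheritParams evaluate_formula
#' @return List of \code{spatial_entity_record}s.
#' @export
resolve_entity_set <- function(x, trace, g,
                               registry = default_spatial_registry(),
                               at = 1L) {
  eval_set(x, at, eval_context(trace, g, registry))
}

eval_set <- function(x, i, ctx) {
  if (x$type == "setop") {
    lhs <- eval_set(x$lhs, i, ctx)
    rhs <- eval_set(x$rhs, i, ctx)
    # identity within the timepoint: position in the timepoint's entity list
    all_ents <- ctx$trace$timepoints[[i]]$entities
    id_of <- function(set) which(vapply(all_ents, function(e)
      any(vapply(set, identical, logical(1), e)), logical(1)))
    lid <- id_of(lhs); rid <- id_of(rhs)
    keep <- switch(x$op,
      union = sort(union(lid, rid)),
      intersection = sort(intersect(lid, rid)),
      difference = sort(setdiff(lid, rid)))
    return(all_ents[keep])
  }
  stopifnot(x$type == "filter")
  entities <- ctx$trace$timepoints[[i]]$entities
  keep <- vapply(entities, function(ent) {
    ent$entity_type == x$etype && entity_satisfies(ent, x$constraints, ctx)
  }, logical(1))
  entities[keep]
}

entity_satisfies <- function(ent, constraints, ctx) {
  for (con in constraints) {
    ok <- switch(con$type,
      group = entity_satisfies(ent, con$items, ctx),
      ss_constraint = {
        switch(con$cmp,
          "=" = ent$scale_subsystem == con$ss,
          "<" = ma_lt(ctx$g, ent$scale_subsystem, con$ss),
          "<=" = ma_leq(ctx$g, ent$scale_subsystem, con$ss))
      },
      measure_constraint = {
        if (!con$name %in% names(ent$measures))
          abort_registry(sprintf("entity lacks measure '%s'", con$name))
        apply_comparator(con$cmp, ent$measures[[con$name]], con$value)
      })
    if (!ok) return(FALSE)
  }
  TRUE
}

# --- arithmetic and statistical function tables -----------------------------

apply_arith1 <- function(fn, v) {
  switch(fn,
    abs = abs(v),
    ceil = ceiling(v),
    floor = floor(v),
    round = round(v),
    sign = sign(v),
    sqrt = {
      if (v < 0) abort_numeric(sprintf("sqrt of negative value %g", v))
      sqrt(v)
    },
    trunc = trunc(v))
}

apply_arith2 <- function(fn, a, b) {
  switch(fn,
    add = a + b,
    subtract = a - b,
    multiply = a * b,
    div = {
      if (b == 0) abort_numeric("division by zero")
      a / b
    },
    mod = {
      if (b == 0) abort_numeric("modulo by zero")
      a %% b
    },
    power = a^b,
    log = {
      if (a <= 0 || b <= 0 || b == 1)
        abort_numeric(sprintf("log(%g, base %g) undefined", a, b))
      log(a, base = b)
    })
}

# Unary statistical functions; empty input other than count() raises the
# empty-collection condition handled at the enclosing comparison.
apply_stat1 <- function(fn, v) {
  if (fn == "count") return(length(v))
  if (!length(v)) signal_empty_collection(fn)
  switch(fn,
    sum = sum(v),
    avg = mean(v),
    min = min(v),
    max = max(v),
    median = stats::median(v),
    mode = {
      tab <- table(v)
      best <- names(tab)[tab == max(tab)]
      min(as.numeric(best))   # ties break to the smallest value
    },
    product = prod(v),
    stdev = {
      if (length(v) < 2L) abort_numeric("stdev needs at least 2 values")
      stats::sd(v)
    },
    var = {
      if (length(v) < 2L) abort_numeric("var needs at least 2 values")
      stats::var(v)
    },
    skew = {
      m2 <- mean((v - mean(v))^2)
      if (m2 == 0) abort_numeric("skew undefined for constant collection")
      mean((v - mean(v))^3) / m2^1.5
    },
    kurtosis = {
      m2 <- mean((v - mean(v))^2)
      if (m2 == 0) abort_numeric("kurtosis undefined for constant collection")
      mean((v - mean(v))^4) / m2^2
    },
    geomean = {
      if (any(v <= 0)) abort_numeric("geometric mean needs positive values")
      exp(mean(log(v)))
    },
    harmean = {
      if (any(v == 0)) abort_numeric("harmonic mean undefined with zeros")
      length(v) / sum(1 / v)
    })
}

apply_stat2 <- function(fn, a, b) {
  if (!length(a) || !length(b)) signal_empty_collection(fn)
  switch(fn,
    covariance = {
      if (length(a) != length(b))
        abort_numeric(sprintf("covariance over collections of unequal size (%d vs %d)",
                              length(a), length(b)))
      if (length(a) < 2L) abort_numeric("covariance needs at least 2 values")
      stats::cov(a, b)
    })
}

apply_quantile <- function(fn, v, q) {
  if (!length(v)) signal_empty_collection(fn)
  p <- switch(fn,
    percentile = {
      if (q < 0 || q > 100) abort_range("percentile rank must be in [0, 100]")
      q / 100
    },
    quartile = {
      if (!q %in% 0:4) abort_range("quartile index must be in 0..4")
      q / 4
    })
  # linear interpolation between closest ranks
  unname(stats::quantile(v, p, type = 7))
}

#' Evaluate a probabilistic query on one trace
#'
#' Evaluates the query body at the trace's first timepoint.
#'
#' @param q \code{pblmstl_query}.
#' @inheritParams evaluate_formula
#' @return Logical scalar: does the body hold on this trace?
#' @export
evaluate_query_on_trace <- function(q, trace, g,
                                    registry = default_spatial_registry(),
                                    locf = FALSE) {
  stopifnot(inherits(q, "pblmstl_query"))
  evaluate_formula(q$body, trace, g, registry, at = 1L, locf = locf)
}
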