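# Independent oracles, deliberately implemented with different algorithms
# than the package: label propagation instead of BFS flood fill, boolean
# matrix closure instead of incremental DBSCAN expansion, and a direct
# recursive evaluator over plain vectors instead of the AST walker.

# 8-connected component partition by iterated min-label propagation.
# Returns a list of cell matrices (0-based row/col), ordered by the
# row-major position of each component's first cell.
oracle_components8 <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(0L, m, n)
  lab[mask] <- seq_len(sum(mask))
  pad <- function(mat, dr, dc) {
    out <- matrix(0L, m, n)
    rs <- max(1, 1 + dr):min(m, m + dr)
    cs <- max(1, 1 + dc):min(n, n + dc)
    out[rs, cs] <- mat[rs - dr, cs - dc]
    out
  }
  repeat {
    new_lab <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- pad(lab, dr, dc)
      take <- mask & shifted > 0L & (new_lab == 0L | shifted < new_lab)
      new_lab[take] <- shifted[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  ids <- unique(lab[lab > 0L])
  comps <- lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE) - 1L
    colnames(cells) <- c("row", "col")
    cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  })
  seeds <- vapply(comps, function(cc) cc[1, 1] * n + cc[1, 2], numeric(1))
  comps[order(seeds)]
}

# DBSCAN by explicit density-reachability closure over the core adjacency
# matrix. Returns list(assignment = integer vector (NA = noise), clusters =
# list of member index vectors ordered by earliest member).
oracle_dbscan <- function(centroids, eps, min_regions) {
  n <- nrow(centroids)
  if (n == 0L) return(list(assignment = integer(0), clusters = list()))
  D <- as.matrix(stats::dist(centroids))
  nb <- D <= eps
  core <- rowSums(nb) >= min_regions
  # reachability closure among cores: boolean transitive closure
  A <- nb & outer(core, core, `&`)
  diag(A) <- core
  R <- A
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  assignment <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(assignment[i])) next
    cid <- cid + 1L
    assignment[which(core & R[i, ])] <- cid
  }
  for (i in seq_len(n)) {
    if (core[i]) next
    adj <- which(nb[i, ] & core)
    if (length(adj)) assignment[i] <- assignment[min(adj)]
  }
  ids <- unique(assignment[!is.na(assignment)])
  clusters <- lapply(ids, function(id) which(assignment == id))
  first <- vapply(clusters, min, integer(1))
  list(assignment = assignment, clusters = clusters[order(first)])
}

# --- direct recursive logic oracle ------------------------------------------

# Oracle formulas are plain lists; traces are list(times = numeric,
# values = named list of numeric vectors).
o_atom <- function(var, cmp, const) list(k = "atom", var = var, cmp = cmp,
                                         const = const)
o_not <- function(f) list(k = "not", f = f)
o_and <- function(a, b) list(k = "and", a = a, b = b)
o_or <- function(a, b) list(k = "or", a = a, b = b)
o_imp <- function(a, b) list(k = "imp", a = a, b = b)
o_G <- function(a, b, f) list(k = "G", a = a, b = b, f = f)
o_F <- function(a, b, f) list(k = "F", a = a, b = b, f = f)
o_U <- function(a, b, f1, f2) list(k = "U", a = a, b = b, f1 = f1, f2 = f2)

oracle_eval <- function(f, i, tr) {
  t <- tr$times[i]
  win <- function(a, b) which(tr$times >= t + a & tr$times <= t + b)
  switch(f$k,
    atom = {
      v <- tr$values[[f$var]][i]
      switch(f$cmp, "<" = v < f$const, "<=" = v <= f$const,
             "=" = v == f$const, ">=" = v >= f$const, ">" = v > f$const)
    },
    not = !oracle_eval(f$f, i, tr),
    and = oracle_eval(f$a, i, tr) && oracle_eval(f$b, i, tr),
    or = oracle_eval(f$a, i, tr) || oracle_eval(f$b, i, tr),
    imp = !oracle_eval(f$a, i, tr) || oracle_eval(f$b, i, tr),
    G = all(vapply(win(f$a, f$b), function(j) oracle_eval(f$f, j, tr),
                   logical(1))),
    F = any(vapply(win(f$a, f$b), function(j) oracle_eval(f$f, j, tr),
                   logical(1))),
    U = {
      for (j in win(f$a, f$b)) {
        if (oracle_eval(f$f2, j, tr)) {
          pre <- which(tr$times >= t & tr$times < tr$times[j])
          if (all(vapply(pre, function(k) oracle_eval(f$f1, k, tr),
                         logical(1))))
            return(TRUE)
        }
      }
      FALSE
    })
}

# Render an oracle formula as statement text for the package parser.
oracle_to_text <- function(f, ss) {
  switch(f$k,
    atom = sprintf("({%s}(scaleAndSubsystem = %s) %s %s)", f$var, ss, f$cmp,
                   if (f$const < 0) sprintf("- %g", -f$const) else
                     sprintf("%g", f$const)),
    not = sprintf("not %s", oracle_to_text(f$f, ss)),
    and = sprintf("(%s and %s)", oracle_to_text(f$a, ss),
                  oracle_to_text(f$b, ss)),
    or = sprintf("(%s or %s)", oracle_to_text(f$a, ss),
                 oracle_to_text(f$b, ss)),
    imp = sprintf("(%s => %s)", oracle_to_text(f$a, ss),
                  oracle_to_text(f$b, ss)),
    G = sprintf("G[%g, %g] %s", f$a, f$b, oracle_to_text(f$f, ss)),
    F = sprintf("F[%g, %g] %s", f$a, f$b, oracle_to_text(f$f, ss)),
    U = sprintf("(%s U[%g, %g] %s)", oracle_to_text(f$f1, ss), f$a, f$b,
                oracle_to_text(f$f2, ss)))
}

# Random formula over variables x, y with nested-bound budget so that the
# horizon never exceeds the trace span.
random_oracle_formula <- function(depth, budget) {
  atom <- function() o_atom(sample(c("x", "y"), 1L),
                            sample(c("<", "<=", "=", ">=", ">"), 1L),
                            sample(0:3, 1L))
  if (depth <= 0L || budget <= 0L || stats::runif(1) < 0.3) return(atom())
  pick <- sample(c("not", "and", "or", "imp", "G", "F", "U"), 1L)
  bounds <- function() {
    b <- sample(0:min(3L, budget), 1L)
    a <- sample(0:b, 1L)
    c(a, b)
  }
  switch(pick,
    not = o_not(random_oracle_formula(depth - 1L, budget)),
    and = o_and(random_oracle_formula(depth - 1L, budget),
                random_oracle_formula(depth - 1L, budget)),
    or = o_or(random_oracle_formula(depth - 1L, budget),
              random_oracle_formula(depth - 1L, budget)),
    imp = o_imp(random_oracle_formula(depth - 1L, budget),
                random_oracle_formula(depth - 1L, budget)),
    G = { b <- bounds(); o_G(b[1], b[2],
                             random_oracle_formula(depth - 1L, budget - b[2])) },
    F = { b <- bounds(); o_F(b[1], b[2],
                             random_oracle_formula(depth - 1L, budget - b[2])) },
    U = { b <- bounds(); o_U(b[1], b[2],
                             random_oracle_formula(depth - 1L, budget - b[2]),
                             random_oracle_formula(depth - 1L, budget - b[2])) })
}

# Random integer-valued trace on integer timestamps 0..(n-1), both for the
# oracle (plain vectors) and the package (mst_trace).
random_logic_trace <- function(n, ss) {
  x <- sample(0:3, n, replace = TRUE)
  y <- sample(0:3, n, replace = TRUE)
  tr <- mst_trace(lapply(seq_len(n), function(i)
    timepoint(i - 1, list(numeric_observation("x", x[i], ss),
                          numeric_observation("y", y[i], ss)))))
  list(oracle = list(times = 0:(n - 1), values = list(x = x, y = y)),
       trace = tr)
}
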