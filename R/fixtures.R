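# Test-input generators. The centrepiece is a fully enumerable toy
# multiscale model: a unicellular microorganism moving on a 2x2 grid
# (von Neumann neighbourhood), which assimilates an extracellular nutrient A
# from its current position, converts intracellular A to energy
# (A -> Energy) and spends one energy unit per move. Action weights are
# 20% move, 30% convert, 50% assimilate, renormalized over the actions
# enabled in the current state; with no action enabled the cell is dormant
# and the state terminal. The model's state space (27 states from the
# initial configuration) and every transition probability are computed with
# exact rational arithmetic, which makes the simulator checkable against an
# exhaustive enumeration.
#
# Also provided: rasterized shape grids with exact ground truth for the
# spatial-analysis tests, and reproducible Bernoulli outcome streams for
# checker validation.

TOY_WEIGHTS <- c(move = 2L, convert = 3L, assimilate = 5L)  # tenths

#' The toy multiscale model
#'
#' @return A list of class \code{toy_model} with the action weights (move
#'   0.20, convert 0.30, assimilate 0.50), the grid size and the initial
#'   state: cell in the lower-right position, nutrient A present at every
#'   grid position, zero intracellular A and zero energy.
#' @export
toy_model <- function() {
  structure(list(weights = TOY_WEIGHTS, nrow = 2L, ncol = 2L),
            class = "toy_model")
}

#' Construct a toy-model state
#'
#' @param pos Integer pair (row, col), 1-based, of the cell position.
#' @param a_ext 2x2 0/1 matrix: extracellular nutrient distribution.
#' @param a_int Non-negative integer: intracellular nutrient units.
#' @param energy Non-negative integer: energy units.
#' @return A list of class \code{toy_state}.
#' @export
toy_state <- function(pos, a_ext, a_int = 0L, energy = 0L) {
  stopifnot(length(pos) == 2L, is.matrix(a_ext), all(dim(a_ext) == 2L),
            all(a_ext %in% c(0L, 1L)), a_int >= 0L, energy >= 0L)
  structure(list(pos = as.integer(pos),
                 a_ext = matrix(as.integer(a_ext), 2L, 2L),
                 a_int = as.integer(a_int), energy = as.integer(energy)),
            class = "toy_state")
}

#' @rdname toy_state
#' @export
toy_initial_state <- function() {
  toy_state(c(2L, 2L), matrix(1L, 2L, 2L), 0L, 0L)
}

toy_state_key <- function(s) {
  paste(s$pos[1], s$pos[2], paste(s$a_ext, collapse = ""), s$a_int, s$energy,
        sep = "|")
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

reduce_fraction <- function(num, den) {
  g <- gcd2(as.integer(num), as.integer(den))
  c(num = as.integer(num / g), den = as.integer(den / g))
}

# von Neumann move targets, fixed enumeration order: up, left, down, right
TOY_MOVE_OFFSETS <- matrix(c(-1L, 0L, 0L, -1L, 1L, 0L, 0L, 1L),
                           ncol = 2, byrow = TRUE)

#' Enabled actions of a toy state with exact probabilities
#'
#' move is enabled iff energy > 0 (one uniformly chosen in-bounds von
#' Neumann neighbour), convert iff intracellular A > 0, assimilate iff A
#' is present at the cell's position. Weights are renormalized over the
#' enabled actions; with none enabled the state is terminal.
#'
#' @param s \code{toy_state}.
#' @param m \code{toy_model}.
#' @return List of actions, each \code{list(action, target, num, den)} with
#'   probability \code{num/den} in lowest terms; empty list for a terminal
#'   state.
#' @export
enabled_actions <- function(s, m = toy_model()) {
  enabled <- c(
    move = s$energy > 0L,
    convert = s$a_int > 0L,
    assimilate = s$a_ext[s$pos[1], s$pos[2]] == 1L)
  total <- sum(m$weights[enabled])
  if (total == 0L) return(list())
  out <- list()
  if (enabled[["assimilate"]]) {
    fr <- reduce_fraction(m$weights[["assimilate"]], total)
    out[[length(out) + 1L]] <- list(action = "assimilate", target = NULL,
                                    num = fr[["num"]], den = fr[["den"]])
  }
  if (enabled[["convert"]]) {
    fr <- reduce_fraction(m$weights[["convert"]], total)
    out[[length(out) + 1L]] <- list(action = "convert", target = NULL,
                                    num = fr[["num"]], den = fr[["den"]])
  }
  if (enabled[["move"]]) {
    targets <- list()
    for (k in seq_len(nrow(TOY_MOVE_OFFSETS))) {
      tgt <- s$pos + TOY_MOVE_OFFSETS[k, ]
      if (tgt[1] >= 1L && tgt[1] <= m$nrow && tgt[2] >= 1L && tgt[2] <= m$ncol)
        targets[[length(targets) + 1L]] <- tgt
    }
    for (tgt in targets) {
      fr <- reduce_fraction(m$weights[["move"]],
                            total * length(targets))
      out[[length(out) + 1L]] <- list(action = "move", target = tgt,
                                      num = fr[["num"]], den = fr[["den"]])
    }
  }
  out
}

#' Apply an action to a toy state
#'
#' @param s \code{toy_state}.
#' @param action One element of [enabled_actions()] output.
#' @return The successor \code{toy_state}.
#' @export
toy_apply <- function(s, action) {
  switch(action$action,
    assimilate = {
      a_ext <- s$a_ext
      a_ext[s$pos[1], s$pos[2]] <- 0L
      toy_state(s$pos, a_ext, s$a_int + 1L, s$energy)
    },
    convert = toy_state(s$pos, s$a_ext, s$a_int - 1L, s$energy + 1L),
    move = toy_state(action$target, s$a_ext, s$a_int, s$energy - 1L))
}

#' Enumerate the toy model's reachable state space
#'
#' Breadth-first closure from the initial state. Outgoing probabilities of
#' every non-terminal state sum to exactly 1 (rational arithmetic).
#'
#' @param m \code{toy_model}.
#' @return A list of class \code{toy_transition_system}: \code{states}
#'   (list, BFS order; the initial state is first), \code{edges} (data
#'   frame: from, to, num, den, action) and \code{terminal} (logical
#'   vector).
#' @export
enumerate_toy_state_space <- function(m = toy_model()) {
  init <- toy_initial_state()
  states <- list(init)
  index <- structure(1L, names = toy_state_key(init))
  edges <- list()
  queue <- 1L
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    acts <- enabled_actions(states[[i]], m)
    for (a in acts) {
      nxt <- toy_apply(states[[i]], a)
      key <- toy_state_key(nxt)
      j <- index[key]
      if (is.na(j)) {
        states[[length(states) + 1L]] <- nxt
        j <- length(states)
        index[key] <- j
        queue <- c(queue, j)
      }
      edges[[length(edges) + 1L]] <- data.frame(
        from = i, to = unname(j), num = a$num, den = a$den,
        action = a$action, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), num = integer(0),
               den = integer(0), action = character(0))
  terminal <- !seq_along(states) %in% edges$from
  structure(list(states = states, edges = edges, terminal = terminal,
                 index = index),
            class = "toy_transition_system")
}

#' Index of a state in an enumerated transition system
#'
#' @param ts \code{toy_transition_system}.
#' @param s \code{toy_state}.
#' @return Integer index, or \code{NA} if unreachable.
#' @export
toy_state_index <- function(ts, s) {
  i <- ts$index[toy_state_key(s)]
  if (is.na(i)) NA_integer_ else unname(i)
}

#' Probability of a finite path through the transition system
#'
#' Product of the transition probabilities along consecutive state pairs,
#' kept exact as a fraction.
#'
#' @param ts \code{toy_transition_system}.
#' @param path Integer vector of state indices, or a list of
#'   \code{toy_state}s.
#' @return Numeric probability with attributes \code{num} and \code{den}
#'   (exact fraction).
#' @export
toy_path_probability <- function(ts, path) {
  if (is.list(path))
    path <- vapply(path, function(s) toy_state_index(ts, s), integer(1))
  if (anyNA(path)) abort_path("path contains a state outside the reachable set")
  num <- 1
  den <- 1
  for (k in seq_len(length(path) - 1L)) {
    hit <- ts$edges$from == path[k] & ts$edges$to == path[k + 1L]
    if (!any(hit))
      abort_path(sprintf("no transition from state %d to state %d",
                         path[k], path[k + 1L]))
    num <- num * ts$edges$num[hit][1L]
    den <- den * ts$edges$den[hit][1L]
  }
  structure(num / den, num = num, den = den)
}

#' Multiscale architecture of the toy model
#'
#' Environment.GrowthMedia -> Cellular.Microorganism ->
#' Intracellular.EnergyProductionReactionNetwork.
#'
#' @return An \code{ma_graph}.
#' @export
toy_ma_graph <- function() {
  new_ma_graph(
    c("Environment.GrowthMedia", "Cellular.Microorganism",
      "Intracellular.EnergyProductionReactionNetwork"),
    c("Cellular.Microorganism" = "Environment.GrowthMedia",
      "Intracellular.EnergyProductionReactionNetwork" = "Cellular.Microorganism"))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate the toy model
#'
#' Discrete timestamps 0, 1, 2, ...; each timepoint records the numeric
#' state variables \code{A_intracellular} and \code{Energy} at
#' Intracellular.EnergyProductionReactionNetwork. The spatial state
#' variables \code{Cell} (Cellular.Microorganism) and
#' \code{A_extracellular} (Environment.GrowthMedia) are returned as grid
#' snapshots in the \code{"grids"} attribute (one list of snapshots per
#' timepoint); the visited states are in the \code{"states"} attribute.
#' The run stops at a terminal (dormant) state or after \code{max_steps}
#' transitions.
#'
#' @param m \code{toy_model}.
#' @param seed RNG seed (restored afterwards).
#' @param max_steps Maximum number of transitions (>= 1).
#' @return An \code{mst_trace}.
#' @export
simulate_toy <- function(m = toy_model(), seed = 1L, max_steps = 20L) {
  if (max_steps < 1L) abort_parameter("max_steps must be >= 1")
  with_seed(seed, {
    s <- toy_initial_state()
    states <- list(s)
    for (step in seq_len(max_steps)) {
      acts <- enabled_actions(s, m)
      if (!length(acts)) break
      probs <- vapply(acts, function(a) a$num / a$den, numeric(1))
      pick <- sample.int(length(acts), 1L, prob = probs)
      s <- toy_apply(s, acts[[pick]])
      states[[length(states) + 1L]] <- s
    }
    ss_intra <- "Intracellular.EnergyProductionReactionNetwork"
    tps <- lapply(seq_along(states), function(i) {
      st <- states[[i]]
      timepoint(i - 1L, list(
        numeric_observation("A_intracellular", st$a_int, ss_intra),
        numeric_observation("Energy", st$energy, ss_intra)))
    })
    grids <- lapply(seq_along(states), function(i) {
      st <- states[[i]]
      cell <- matrix(0, 2L, 2L)
      cell[st$pos[1], st$pos[2]] <- 1
      list(
        grid_snapshot(cell, "Cellular.Microorganism", "Cell", i - 1L),
        grid_snapshot(st$a_ext + 0, "Environment.GrowthMedia",
                      "A_extracellular", i - 1L))
    })
    tr <- mst_trace(tps)
    attr(tr, "grids") <- grids
    attr(tr, "states") <- states
    tr
  })
}

#' Write seeded toy traces as MSTML files
#'
#' @param n Number of traces.
#' @param dir Output directory (created if needed).
#' @param seed Base seed; trace i uses \code{seed + i - 1}.
#' @param max_steps Per-trace step cap.
#' @return Character vector of written file paths, invisibly.
#' @export
toy_traces_to_dir <- function(n, dir, seed = 1L, max_steps = 20L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(n), function(i) {
    tr <- simulate_toy(seed = seed + i - 1L, max_steps = max_steps)
    path <- file.path(dir, sprintf("toy-%04d.xml", i))
    write_mstml(tr, path)
    path
  }, character(1))
  invisible(paths)
}

# --- synthetic shape grids --------------------------------------------------

#' Rasterize shapes onto a grid with exact ground truth
#'
#' Supported shape descriptors (lists): \code{type = "rect"} with
#' \code{row, col, height, width}; \code{type = "disc"} with \code{row,
#' col, radius}; \code{type = "ring"} with \code{row, col, outer, inner}.
#' All rows/cols 1-based; every shape takes a fill \code{value} in (0, 1].
#' Overlapping shapes are rejected (the ground truth would be ambiguous).
#'
#' @param shapes List of shape descriptors (empty list gives an all-zero
#'   grid).
#' @param nrow,ncol Grid size.
#' @param scale_subsystem,variable,time Snapshot annotation.
#' @return A \code{grid_snapshot}; the attribute \code{"ground_truth"} is a
#'   data frame with one row per shape: exact \code{area},
#'   \code{centroid_row}/\code{centroid_col} (0-based mask centroid) and
#'   \code{density} (the fill value).
#' @export
make_shape_grid <- function(shapes, nrow = 30L, ncol = 30L,
                            scale_subsystem = "Scale.Subsystem",
                            variable = "value", time = 0) {
  values <- matrix(0, nrow, ncol)
  truth <- list()
  for (sh in shapes) {
    value <- if (is.null(sh$value)) 1 else sh$value
    if (value <= 0 || value > 1)
      abort_spec("shape fill value must lie in (0, 1]")
    cells <- switch(sh$type,
      rect = {
        rows <- sh$row:(sh$row + sh$height - 1L)
        cols <- sh$col:(sh$col + sh$width - 1L)
        as.matrix(expand.grid(row = rows, col = cols))
      },
      disc = {
        grid <- as.matrix(expand.grid(row = seq_len(nrow), col = seq_len(ncol)))
        d2 <- (grid[, 1] - sh$row)^2 + (grid[, 2] - sh$col)^2
        grid[d2 <= sh$radius^2, , drop = FALSE]
      },
      ring = {
        grid <- as.matrix(expand.grid(row = seq_len(nrow), col = seq_len(ncol)))
        d2 <- (grid[, 1] - sh$row)^2 + (grid[, 2] - sh$col)^2
        grid[d2 <= sh$outer^2 & d2 >= sh$inner^2, , drop = FALSE]
      },
      abort_spec(sprintf("unknown shape type '%s'", sh$type)))
    if (nrow(cells) == 0L) abort_spec("shape rasterizes to zero cells")
    if (any(cells[, 1] < 1L | cells[, 1] > nrow |
            cells[, 2] < 1L | cells[, 2] > ncol))
      abort_spec("shape exceeds the grid bounds")
    if (any(values[cells] != 0))
      abort_spec("shapes overlap; ground truth would be ambiguous")
    values[cells] <- value
    truth[[length(truth) + 1L]] <- data.frame(
      type = sh$type, area = nrow(cells),
      centroid_row = mean(cells[, 1]) - 1,
      centroid_col = mean(cells[, 2]) - 1,
      density = value)
  }
  gs <- grid_snapshot(values, scale_subsystem, variable, time)
  attr(gs, "ground_truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), area = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               density = numeric(0))
  gs
}

#' Reproducible Bernoulli outcome stream
#'
#' @param p Success probability in [0, 1].
#' @param n Stream length.
#' @param seed RNG seed (restored afterwards).
#' @return Logical vector of length \code{n}.
#' @export
bernoulli_outcomes <- function(p, n, seed = 1L) {
  if (!is.numeric(p) || p < 0 || p > 1)
    abort_parameter("p must lie in [0, 1]")
  with_seed(seed, stats::runif(n) < p)
}
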