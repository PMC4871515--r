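# Shared fixture builders: documents and objects assembled in code.

# Example trace document: one timepoint holding one cluster at Organ.Liver
# (all eleven measures) and one numeric state variable at
# Cellular.Hepatocyte.
listing_trace_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    "<experiment>\n",
    '  <timepoint value="1">\n',
    '    <spatialEntity spatialType="cluster" scaleAndSubsystem="Organ.Liver">\n',
    "      <clusteredness>0.01</clusteredness>\n",
    "      <density>0.4</density>\n",
    "      <area>15</area>\n",
    "      <perimeter>28</perimeter>\n",
    "      <distanceFromOrigin>81</distanceFromOrigin>\n",
    "      <angle>10.5</angle>\n",
    "      <triangleMeasure>0.5</triangleMeasure>\n",
    "      <rectangleMeasure>1.0</rectangleMeasure>\n",
    "      <circleMeasure>0.1</circleMeasure>\n",
    "      <centroidX>703.4999</centroidX>\n",
    "      <centroidY>118.087</centroidY>\n",
    "    </spatialEntity>\n",
    '    <numericStateVariable scaleAndSubsystem="Cellular.Hepatocyte">\n',
    "      <name>dysfunction</name>\n",
    "      <value>0.1</value>\n",
    "    </numericStateVariable>\n",
    "  </timepoint>\n",
    "</experiment>\n")
}

# MA graph shaped like the gut/lung inflammation hierarchy: organism root,
# two organs, tissues and cells below.
organ_tree <- function() {
  read_ma_graph(paste0(
    '<multiscaleArchitecture rootScale="Organism" rootSubsystem="Human">',
    '<vertex scale="Organ" subsystem="Gut">',
    '<vertex scale="Tissue" subsystem="GutTissue">',
    '<vertex scale="Cellular" subsystem="GutEndothelial"/>',
    "</vertex></vertex>",
    '<vertex scale="Organ" subsystem="Lung">',
    '<vertex scale="Tissue" subsystem="LungTissue">',
    '<vertex scale="Cellular" subsystem="LungEndothelial"/>',
    "</vertex></vertex>",
    "</multiscaleArchitecture>"))
}

# MA graph with the Listing-style vertices plus a damaged-liver subtree
# with two children.
liver_tree <- function() {
  read_ma_graph(paste0(
    '<multiscaleArchitecture rootScale="Organism" rootSubsystem="Human">',
    '<vertex scale="Organ" subsystem="Liver">',
    '<vertex scale="Tissue" subsystem="DamagedLiverTissue">',
    '<vertex scale="Cellular" subsystem="Hepatocyte"/>',
    '<vertex scale="Cellular" subsystem="Stellate"/>',
    "</vertex></vertex>",
    "</multiscaleArchitecture>"))
}

# Single-variable numeric trace: x(t_i) = values[i] at vertex ss.
value_trace <- function(values, ss, times = seq_along(values) - 1,
                        name = "x") {
  mst_trace(lapply(seq_along(values), function(i)
    timepoint(times[[i]], list(numeric_observation(name, values[[i]], ss)))))
}

# Random rooted tree over n vertices as an ma_graph; vertex i's parent is a
# uniform earlier vertex.
random_ma_tree <- function(n) {
  labels <- sprintf("S%d.V%d", seq_len(n), seq_len(n))
  parent <- character(0)
  if (n > 1L) {
    for (i in 2:n) parent[labels[i]] <- labels[sample.int(i - 1L, 1L)]
  }
  mstmc:::new_ma_graph(labels, parent)
}

# Minimal hand-built detected_region at a single grid cell (row, col
# 0-based); used to feed detect_clusters with known centroids (clustering
# only reads cells/contour, never the mask).
point_region <- function(row, col) {
  cells <- matrix(c(row, col), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  structure(list(mask = NULL, cells = cells, contour = cells),
            class = "detected_region")
}

# The printed Example-1 chain: 27 concrete states in the published label
# order and the 28 printed non-zero transition probabilities. State
# contents are reconstructed from the published narrative (positions BR =
# lower-right start, BL, TL, TR; consumed nutrient positions; intracellular
# units; energy units).
reference_toy_chain <- function() {
  BR <- c(2L, 2L); BL <- c(2L, 1L); TL <- c(1L, 1L); TR <- c(1L, 2L)
  aex <- function(...) {
    m <- matrix(1L, 2, 2)
    for (p in list(...)) m[p[1], p[2]] <- 0L
    m
  }
  states <- list(
    toy_initial_state(),                                  # S0
    toy_state(BR, aex(BR), 1L, 0L),                       # S1
    toy_state(BR, aex(BR), 0L, 1L),                       # S2
    toy_state(BL, aex(BR), 0L, 0L),                       # S3  moved left
    toy_state(TR, aex(BR), 0L, 0L),                       # S4  moved up
    toy_state(BL, aex(BR, BL), 1L, 0L),                   # S5
    toy_state(TR, aex(BR, TR), 1L, 0L),                   # S6
    toy_state(BL, aex(BR, BL), 0L, 1L),                   # S7
    toy_state(TR, aex(BR, TR), 0L, 1L),                   # S8
    toy_state(TL, aex(BR, BL), 0L, 0L),                   # S9
    toy_state(BR, aex(BR, BL), 0L, 0L),                   # S10 terminal
    toy_state(BR, aex(BR, TR), 0L, 0L),                   # S11 terminal
    toy_state(TL, aex(BR, TR), 0L, 0L),                   # S12
    toy_state(TL, aex(BR, BL, TL), 1L, 0L),               # S13
    toy_state(TL, aex(BR, TR, TL), 1L, 0L),               # S14
    toy_state(TL, aex(BR, BL, TL), 0L, 1L),               # S15
    toy_state(TL, aex(BR, TR, TL), 0L, 1L),               # S16
    toy_state(TR, aex(BR, BL, TL), 0L, 0L),               # S17
    toy_state(BL, aex(BR, BL, TL), 0L, 0L),               # S18 terminal
    toy_state(TR, aex(BR, TR, TL), 0L, 0L),               # S19 terminal
    toy_state(BL, aex(BR, TR, TL), 0L, 0L),               # S20
    toy_state(TR, aex(BR, BL, TL, TR), 1L, 0L),           # S21
    toy_state(BL, aex(BR, TR, TL, BL), 1L, 0L),           # S22
    toy_state(TR, aex(BR, BL, TL, TR), 0L, 1L),           # S23
    toy_state(BL, aex(BR, TR, TL, BL), 0L, 1L),           # S24
    toy_state(TL, aex(BR, BL, TL, TR), 0L, 0L),           # S25 terminal
    toy_state(BR, aex(BR, BL, TL, TR), 0L, 0L))           # S26 terminal
  edges <- data.frame(
    from = c(0, 1, 2, 2, 3, 4, 5, 6, 7, 7, 8, 8, 9, 12, 13, 14, 15, 15,
             16, 16, 17, 20, 21, 22, 23, 23, 24, 24),
    to = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18,
           19, 20, 21, 22, 23, 24, 25, 26, 25, 26),
    prob = c(1, 1, 0.5, 0.5, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 1, 1, 1, 1,
             0.5, 0.5, 0.5, 0.5, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5))
  terminal <- c(10, 11, 18, 19, 25, 26)
  list(states = states, edges = edges, terminal = terminal)
}
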