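test_that("the published example statements parse and bind", {
  g <- read_ma_graph(paste0(
    '<multiscaleArchitecture rootScale="Organism" rootSubsystem="Human">',
    '<vertex scale="Intracellular" subsystem="RasERKPathway"/>',
    '<vertex scale="Cellular" subsystem="Cancerous"/>',
    '<vertex scale="Organism2" subsystem="Human2"/>',
    '<vertex scale="OrganSystem" subsystem="Aorta"/>',
    '<vertex scale="Organ" subsystem="Liver">',
    '<vertex scale="Tissue" subsystem="DamagedLiverTissue"/></vertex>',
    "</multiscaleArchitecture>"))

  q <- parse_query(paste0(
    "P > 0.99 [G[0, 95] (({EGFR}(scaleAndSubsystem = Intracellular.RasERKPathway) > 20)",
    " => (d(count(density(filter(regions, scaleAndSubsystem = Cellular.Cancerous)))) > 0))]"),
    g)
  expect_s3_class(q, "pblmstl_query")
  expect_identical(q$cmp, ">")
  expect_identical(q$theta, 0.99)
  expect_identical(q$body$type, "G")
  expect_identical(q$body$b, 95)
  expect_identical(q$body$body$type, "implies")
  expect_identical(required_horizon(q), 95)

  f2 <- parse_formula(paste0(
    "(F[5, 10] d({X}(scaleAndSubsystem = Organism.Human)) > 0) => ",
    "(min([10, 30] min(area(filter(regions, scaleAndSubsystem = OrganSystem.Aorta)))) > ",
    "max([0, 10] max(area(filter(regions, scaleAndSubsystem = OrganSystem.Aorta)))))"),
    g)
  expect_identical(f2$type, "implies")
  expect_identical(required_horizon(f2), 30)

  f3 <- parse_formula(paste0(
    "G[0, 100] ({LiverDysfunction}(scaleAndSubsystem = Organ.Liver) = ",
    "avg(density(filter(regions, scaleAndSubsystem <= Tissue.DamagedLiverTissue))))"),
    g)
  expect_identical(f3$type, "G")
  expect_identical(required_horizon(f3), 100)
})

test_that("parse errors carry position and class information", {
  g <- ma_graph_single("A", "B")
  expect_error(parse_query("P > 0.5 [G[0,0] (1 =]", g),
               class = "mstmc_error_syntax")
  expect_error(parse_query("P > 1 [G[0,0] (1 = 1)]", g),
               class = "mstmc_error_range")
  expect_error(parse_query("P > 0.5 [G[0,0] (1 = 1)] junk", g),
               class = "mstmc_error_syntax")
  expect_error(parse_query("P > 0.5 [G[2,1] (1 = 1)]", g),
               class = "mstmc_error_range")
  expect_error(
    parse_query("P > 0.5 [G[0,0] ({x}(scaleAndSubsystem = No.Such) > 0)]", g),
    class = "mstmc_error_binding")
  expect_error(
    parse_query("P > 0.5 [G[0,0] (count(volume(filter(regions))) > 0)]", g),
    class = "mstmc_error_binding")
  expect_error(
    parse_query("P > 0.5 [G[0,0] (count(area(filter(blobs))) > 0)]", g),
    class = "mstmc_error_binding")
  err <- tryCatch(parse_query("P > 0.5 [G[0,0]\n (1 @ 1)]", g),
                  error = identity)
  expect_match(conditionMessage(err), "line 2")
})

test_that("Unicode aliases parse to the same ASTs as ASCII", {
  g <- ma_graph_single("A", "B")
  ascii <- parse_formula("((1 = 1) and (2 > 1)) => (not (1 < 0))", g)
  uni <- parse_formula("((1 = 1) ∧ (2 > 1)) ⇒ (¬ (1 < 0))", g)
  expect_identical(ascii, uni)
  le1 <- parse_formula("count(area(filter(regions, scaleAndSubsystem ≤ A.B))) >= 0", g)
  le2 <- parse_formula("count(area(filter(regions, scaleAndSubsystem <= A.B))) >= 0", g)
  expect_identical(le1, le2)
})

test_that("pretty-printing re-parses to an identical AST (fuzzed)", {
  g <- ma_graph_single("A", "B")
  set.seed(606)
  for (rep in 1:500) {
    f <- random_oracle_formula(3L, 9L)
    parsed <- parse_formula(oracle_to_text(f, "A.B"), g)
    reparsed <- parse_formula(format_query(parsed), g)
    expect_identical(reparsed, parsed)
  }
  # numeric-function surface forms round-trip too
  texts <- c(
    "avg([0, 5] add({x}(scaleAndSubsystem = A.B), 1)) > sqrt(2)",
    "covariance([0, 3] {x}(scaleAndSubsystem = A.B), [0, 3] {x}(scaleAndSubsystem = A.B)) >= 0",
    "percentile([0, 9] {x}(scaleAndSubsystem = A.B), 90) = 90.1",
    "quartile(area(filter(regions) union filter(clusters)), 2) < 10",
    "count(area((filter(regions) intersection filter(regions)) \\ filter(clusters))) = 0",
    "mode([0, 4] mod({x}(scaleAndSubsystem = A.B), 3)) <= 2")
  for (s in texts) {
    parsed <- parse_formula(s, g)
    expect_identical(parse_formula(format_query(parsed), g), parsed)
  }
})

test_that("evaluation agrees with the direct recursive oracle", {
  g <- ma_graph_single("A", "B")
  set.seed(707)
  for (rep in 1:300) {
    rt <- random_logic_trace(10L, "A.B")
    f <- random_oracle_formula(3L, 9L)
    parsed <- parse_formula(oracle_to_text(f, "A.B"), g)
    expect_identical(evaluate_formula(parsed, rt$trace, g),
                     oracle_eval(f, 1L, rt$oracle))
  }
})

test_that("temporal dualities hold on random traces", {
  g <- ma_graph_single("A", "B")
  set.seed(808)
  for (rep in 1:100) {
    rt <- random_logic_trace(10L, "A.B")
    f <- random_oracle_formula(2L, 5L)
    b <- sort(sample(0:4, 2L, replace = TRUE))
    notG <- parse_formula(
      sprintf("not G[%d, %d] %s", b[1], b[2], oracle_to_text(f, "A.B")), g)
    Fnot <- parse_formula(
      sprintf("F[%d, %d] not %s", b[1], b[2], oracle_to_text(f, "A.B")), g)
    expect_identical(evaluate_formula(notG, rt$trace, g),
                     evaluate_formula(Fnot, rt$trace, g))
    # G distributes over conjunction
    f2 <- random_oracle_formula(2L, 5L)
    Gboth <- parse_formula(sprintf("G[%d, %d] (%s and %s)", b[1], b[2],
                                   oracle_to_text(f, "A.B"),
                                   oracle_to_text(f2, "A.B")), g)
    GG <- parse_formula(sprintf("(G[%d, %d] %s) and (G[%d, %d] %s)",
                                b[1], b[2], oracle_to_text(f, "A.B"),
                                b[1], b[2], oracle_to_text(f2, "A.B")), g)
    expect_identical(evaluate_formula(Gboth, rt$trace, g),
                     evaluate_formula(GG, rt$trace, g))
  }
})

test_that("bounded-until follows the stated semantics", {
  g <- ma_graph_single("A", "B")
  tr <- value_trace(c(0, 0, 1), "A.B")
  atom0 <- "({x}(scaleAndSubsystem = A.B) = 0)"
  atom1 <- "({x}(scaleAndSubsystem = A.B) = 1)"
  u1 <- parse_formula(sprintf("%s U[0, 2] %s", atom0, atom1), g)
  expect_true(evaluate_formula(u1, tr, g))
  # phi2 already holds at the start, with an empty phi1-prefix
  u2 <- parse_formula(sprintf("%s U[0, 2] %s", atom1, atom0), g)
  expect_true(evaluate_formula(u2, tr, g))
  # shifting the window past the initial satisfaction flips it
  u3 <- parse_formula(sprintf("%s U[1, 2] %s", atom1, atom0), g)
  expect_false(evaluate_formula(u3, tr, g))
  # no phi2 in window at all
  u4 <- parse_formula(sprintf("%s U[0, 1] %s", atom0, atom1), g)
  expect_false(evaluate_formula(u4, tr, g))
})

test_that("horizon accounting matches the bound-summation rule", {
  g <- ma_graph_single("A", "B")
  expect_identical(required_horizon(parse_formula("1 = 1", g)), 0)
  expect_identical(required_horizon(parse_formula("G[0,95] (1 = 1)", g)), 95)
  expect_identical(
    required_horizon(parse_formula("G[0,10] F[0,5] (1 = 1)", g)), 15)
  expect_identical(
    required_horizon(parse_formula(
      "G[0,4] (avg([0, 3] {x}(scaleAndSubsystem = A.B)) > 0)", g)), 7)
  expect_identical(
    required_horizon(parse_formula("d({x}(scaleAndSubsystem = A.B)) > 0", g),
                     sample_step = 1), 1)

  tr <- value_trace(c(1, 1, 1), "A.B")
  expect_error(
    evaluate_formula(parse_formula("G[0,10] ({x}(scaleAndSubsystem = A.B) > 0)", g),
                     tr, g),
    class = "mstmc_error_horizon")
  # d() at the last timepoint needs a successor
  expect_error(
    evaluate_formula(parse_formula("G[0,2] (d({x}(scaleAndSubsystem = A.B)) = 0)", g),
                     tr, g),
    class = "mstmc_error_horizon")
})

test_that("numeric evaluation: differences, arithmetic guards, quantiles", {
  g <- ma_graph_single("A", "B")
  tr <- value_trace(c(3, 5, 9), "A.B")
  dexpr <- parse_formula("d({x}(scaleAndSubsystem = A.B)) = 2", g)
  expect_true(evaluate_formula(dexpr, tr, g))

  tr100 <- value_trace(1:100, "A.B", times = 0:99)
  pct <- parse_formula(
    "percentile([0, 99] {x}(scaleAndSubsystem = A.B), 90) = 90.1", g)
  expect_true(evaluate_formula(pct, tr100, g))
  qrt <- parse_formula(
    "quartile([0, 99] {x}(scaleAndSubsystem = A.B), 2) = 50.5", g)
  expect_true(evaluate_formula(qrt, tr100, g))

  expect_error(
    evaluate_formula(parse_formula("div(1, 0) > 0", g),
                     value_trace(1, "A.B"), g),
    class = "mstmc_error_numeric")
  expect_error(
    evaluate_formula(parse_formula("log(0, 2) > 0", g),
                     value_trace(1, "A.B"), g),
    class = "mstmc_error_numeric")
  expect_error(
    evaluate_formula(parse_formula("sqrt(subtract(0, 4)) > 0", g),
                     value_trace(1, "A.B"), g),
    class = "mstmc_error_numeric")
})

test_that("statistical functions match textbook definitions", {
  g <- ma_graph_single("A", "B")
  v <- c(2, 7, 1, 7, 4, 9, 7, 1)
  tr <- value_trace(v, "A.B", times = 0:7)
  coll <- "[0, 7] {x}(scaleAndSubsystem = A.B)"
  checks <- c(
    count = length(v), sum = sum(v), avg = mean(v), min = min(v),
    max = max(v), median = median(v), mode = 7, product = prod(v),
    stdev = sd(v), var = var(v),
    skew = mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5,
    kurtosis = mean((v - mean(v))^4) / mean((v - mean(v))^2)^2,
    geomean = exp(mean(log(v))), harmean = length(v) / sum(1 / v))
  for (fn in names(checks)) {
    e <- mstmc:::p_numexpr(mstmc:::new_parser(mstmc:::tokenize_pblmstl(
      sprintf("%s(%s)", fn, coll))))
    expect_equal(evaluate_numeric(e, tr, g), unname(checks[[fn]]),
                 tolerance = 1e-12, label = fn)
  }
  # mean is an alias for avg; mode ties break to the smallest value
  tie <- value_trace(c(5, 5, 2, 2, 9), "A.B", times = 0:4)
  e <- mstmc:::p_numexpr(mstmc:::new_parser(mstmc:::tokenize_pblmstl(
    "mode([0, 4] {x}(scaleAndSubsystem = A.B))")))
  expect_identical(evaluate_numeric(e, tie, g), 2)
  # covariance
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  tr2 <- mst_trace(lapply(1:8, function(i)
    timepoint(i - 1, list(numeric_observation("x", v[i], "A.B"),
                          numeric_observation("y", y[i], "A.B")))))
  e <- mstmc:::p_numexpr(mstmc:::new_parser(mstmc:::tokenize_pblmstl(
    "covariance([0, 7] {x}(scaleAndSubsystem = A.B), [0, 7] {y}(scaleAndSubsystem = A.B))")))
  expect_equal(evaluate_numeric(e, tr2, g), cov(v, y), tolerance = 1e-12)
})

test_that("entity-set resolution respects constraints and the partial order", {
  lt <- liver_tree()
  registry <- default_spatial_registry()
  meas <- function(area) {
    m <- stats::setNames(rep(0.5, nrow(registry$measures)),
                         registry$measures$name)
    m["area"] <- area
    m["angle"] <- 10
    m["perimeter"] <- 4
    m["distanceFromOrigin"] <- 1
    m["centroidX"] <- 2; m["centroidY"] <- 3
    m
  }
  tr <- mst_trace(list(timepoint(0, list(), list(
    spatial_entity_record("regions", "Tissue.DamagedLiverTissue", meas(20)),
    spatial_entity_record("regions", "Cellular.Hepatocyte", meas(5)),
    spatial_entity_record("regions", "Organ.Liver", meas(30)),
    spatial_entity_record("clusters", "Organ.Liver", meas(15))))))

  resolve <- function(text) {
    ast <- mstmc:::p_setexpr(mstmc:::new_parser(mstmc:::tokenize_pblmstl(text)))
    resolve_entity_set(ast, tr, lt)
  }
  below <- resolve("filter(regions, scaleAndSubsystem <= Tissue.DamagedLiverTissue)")
  expect_identical(vapply(below, `[[`, character(1), "scale_subsystem"),
                   c("Tissue.DamagedLiverTissue", "Cellular.Hepatocyte"))
  strict <- resolve("filter(regions, scaleAndSubsystem < Tissue.DamagedLiverTissue)")
  expect_identical(vapply(strict, `[[`, character(1), "scale_subsystem"),
                   "Cellular.Hepatocyte")
  big <- resolve("filter(regions, area > 10)")
  expect_length(big, 2L)
  # the cluster with area 15 passes an area > 10 filter
  cl <- resolve("filter(clusters, area > 10)")
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$entity_type, "clusters")
  # set algebra: A \ A is empty, union keeps trace order, intersection works
  expect_length(resolve("filter(regions) \\ filter(regions)"), 0L)
  expect_length(resolve("filter(regions) union filter(clusters)"), 4L)
  expect_length(
    resolve("filter(regions) intersection filter(regions, area > 10)"), 2L)
})

test_that("empty collections falsify the enclosing comparison with a warning", {
  g <- ma_graph_single("A", "B")
  tr <- value_trace(c(1, 1), "A.B")
  f <- parse_formula("avg(density(filter(regions))) > 0", g)
  expect_warning(res <- evaluate_formula(f, tr, g), "empty collection")
  expect_false(res)
  # count is total over the empty set
  fc <- parse_formula("count(density(filter(regions))) = 0", g)
  expect_true(evaluate_formula(fc, tr, g))
  # the falsification is local: an enclosing negation sees FALSE -> TRUE
  fn <- parse_formula("not (max(density(filter(regions))) > 0)", g)
  expect_true(suppressWarnings(evaluate_formula(fn, tr, g)))
})
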