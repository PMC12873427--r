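analyze_one_frame <- function(fx, f = 1) {
  traj <- fx$trajectory
  top <- traj$topology
  fr <- frame_coords(traj, f)
  water_o <- top$atoms$atom_id[top$atoms$role == "water" &
                                 top$atoms$element == "O"]
  src <- resolve_region(fx$endpoints$source, top, fr, fx$membrane)
  g <- detect_hbonds(fr, top, sort(union(water_o, src)), frame_index = f)
  list(graph = g, frame = fr, top = top)
}

test_that("a planted chain yields exactly one wire with the planted waters", {
  fx <- make_wire_fixture(n_frames = 2, chain_length = 5,
                          wire_probability = 1, n_decoys = 50, seed = 21)
  env <- analyze_one_frame(fx)
  ws <- find_wires(env$graph, fx$endpoints, env$frame, env$top, fx$membrane)
  expect_length(ws, 1)
  expect_identical(ws[[1]]$n_waters, 5L)
  expect_identical(ws[[1]]$nodes[-1], fx$chain_ids)
  expect_true(validate_wire(ws[[1]], env$graph))
})

test_that("a broken chain yields no wires", {
  fx <- make_wire_fixture(n_frames = 3, chain_length = 5,
                          wire_probability = 0, n_decoys = 30, seed = 22)
  env <- analyze_one_frame(fx)
  expect_length(find_wires(env$graph, fx$endpoints, env$frame, env$top,
                           fx$membrane), 0)
})

test_that("overlapping endpoints are a configuration error", {
  fx <- make_wire_fixture(n_frames = 1, chain_length = 4,
                          wire_probability = 1, n_decoys = 5, seed = 1)
  env <- analyze_one_frame(fx)
  ep <- wire_endpoints(region_spec("all-waters", role = "water",
                                   element = "O"),
                       fx$sink_region)
  expect_error(find_wires(env$graph, ep, env$frame, env$top, fx$membrane),
               "overlap")
})

test_that("BFS path length matches the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  fx <- make_wire_fixture(n_frames = 6, chain_length = 6,
                          wire_probability = 0.7, n_decoys = 40, seed = 23)
  for (f in seq_len(6)) {
    env <- analyze_one_frame(fx, f)
    ws <- find_wires(env$graph, fx$endpoints, env$frame, env$top,
                     fx$membrane)
    # oracle: igraph over water-relay-legal edges
    top <- env$top
    nodes <- env$graph$nodes
    role <- top$atoms$role[match(nodes, top$atoms$atom_id)]
    src <- resolve_region(fx$endpoints$source, top, env$frame, fx$membrane)
    snk <- resolve_region(fx$sink_region, top, env$frame, fx$membrane)
    keep <- function(a, b) {
      ok <- function(x) x %in% src | role[match(x, nodes)] == "water"
      ok(a) & ok(b)
    }
    e <- env$graph$edges
    e <- e[keep(e$i, e$j), ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$i), to = as.character(e$j)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes)))
    dmat <- igraph::distances(g, v = as.character(intersect(src, nodes)),
                              to = as.character(intersect(snk, nodes)))
    oracle_min <- suppressWarnings(min(dmat))
    if (length(ws) == 0) {
      expect_true(!is.finite(oracle_min))
    } else {
      expect_equal(length(ws[[1]]$nodes) - 1, oracle_min)
    }
  }
})

test_that("wires route through the planted class shell and are so classified", {
  for (route in 1:3) {
    fx <- make_wire_fixture(n_frames = 1, chain_length = 6,
                            wire_probability = 1, n_decoys = 20,
                            class_route = route, seed = 30 + route)
    env <- analyze_one_frame(fx)
    ws <- find_wires(env$graph, fx$endpoints, env$frame, env$top,
                     fx$membrane)
    expect_length(ws, 1)
    lab <- classify_wire(ws[[1]], fx$class_defs, env$frame, env$top,
                         fx$membrane)
    expect_identical(lab, as.character(route))
  }
})

test_that("a wire contacting no shell is unclassified", {
  fx <- make_wire_fixture(n_frames = 1, chain_length = 5,
                          wire_probability = 1, n_decoys = 10, seed = 40)
  env <- analyze_one_frame(fx)
  ws <- find_wires(env$graph, fx$endpoints, env$frame, env$top, fx$membrane)
  far_defs <- lapply(fx$class_defs, function(d) {
    d$contact_radius <- 0.01       # no water can touch any shell
    d
  })
  expect_identical(classify_wire(ws[[1]], far_defs, env$frame, env$top,
                                 fx$membrane), "unclassified")
})

test_that("wire_fraction handles extremes and matches the planted rate", {
  none <- rep(list(list()), 100)
  expect_identical(wire_fraction(none), 0)
  all_wired <- rep(list(list(1)), 100)
  expect_identical(wire_fraction(all_wired), 1)
  expect_error(wire_fraction(list()), "zero frames")
  fx <- make_wire_fixture(n_frames = 400, chain_length = 4,
                          wire_probability = 0.3, n_decoys = 15, seed = 41)
  res <- analyze_wires(fx$trajectory, fx$endpoints, NULL, fx$membrane)
  expect_identical(res$fraction, mean(fx$truth$wired))
  # within 3 binomial SDs of the programmed probability
  expect_lt(abs(res$fraction - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  # invariant under frame-order permutation
  set.seed(1)
  expect_identical(wire_fraction(sample(res$per_frame_wires)), res$fraction)
})

test_that("box summaries follow the linear-interpolation quartile convention", {
  b <- summarize_box(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(b$median, 0.5)
  expect_equal(b$q1, 0.35)
  expect_equal(b$q3, 0.65)
  expect_equal(b$whisker_low, 0.2)
  expect_equal(b$whisker_high, 0.8)
  expect_length(b$outliers, 0)
  # all-equal inputs: zero-width box, whiskers at the value
  b2 <- summarize_box(rep(0.4, 5))
  expect_equal(unlist(b2[c("median", "q1", "q3", "whisker_low",
                           "whisker_high")]),
               setNames(rep(0.4, 5), c("median", "q1", "q3", "whisker_low",
                                       "whisker_high")))
  # a point beyond 1.5 x IQR is an outlier; whisker stops at last in-range
  x <- c(0.30, 0.32, 0.34, 0.36, 0.38, 1.5)
  b3 <- summarize_box(x)
  expect_equal(b3$outliers, 1.5)
  expect_equal(b3$whisker_high, 0.38)
  expect_equal(b3$whisker_low, 0.30)
  expect_error(summarize_box(0.5), "at least 2")
})
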