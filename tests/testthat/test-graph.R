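test_that("weight-to-distance mapping is reciprocal with absent zero edges", {
  w <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  dm <- weight_to_distance(w)
  expect_equal(dm$distances[1, 2], 2.0)
  expect_identical(dm$distances[2, 1], Inf)
  expect_equal(diag(dm$distances), c(0, 0))
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  d1 <- weight_to_distance(ones)$distances
  expect_true(all(d1[row(d1) != col(d1)] == 1))
  expect_error(weight_to_distance(matrix(c(0, -1, 0, 0), 2)), "nonnegative")
})

test_that("betweenness matches hand-enumerated path graphs", {
  # A -> B -> C, unit distances: B carries the single A->C path
  w <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  w["B", "A"] <- 1; w["C", "B"] <- 1
  bc <- betweenness_centrality(weight_to_distance(w))
  expect_equal(unname(bc), c(0, 0.5, 0))

  # complete digraph: every pair is directly connected
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(unname(betweenness_centrality(weight_to_distance(full))),
               rep(0, 5))
  expect_error(betweenness_centrality(weight_to_distance(matrix(0, 2, 2))),
               "at least 3")
})

test_that("betweenness and path length agree with the enumeration oracle", {
  for (s in 1:20) {
    cm <- random_connectivity(sample(4:6, 1), seed = 1000 + s)
    dm <- weight_to_distance(cm)
    oracle <- bc_oracle(dm$distances)
    expect_equal(unname(betweenness_centrality(dm)), oracle$bc,
                 tolerance = 1e-8)
    expect_equal(suppressMessages(characteristic_path_length(dm)),
                 oracle$cpl, tolerance = 1e-8)
  }
})

test_that("characteristic path length matches hand enumeration and scales", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(characteristic_path_length(weight_to_distance(full)), 1)

  # 3-cycle: d = 1 forward, 2 around
  cyc <- matrix(0, 3, 3)
  cyc[2, 1] <- 1; cyc[3, 2] <- 1; cyc[1, 3] <- 1
  expect_equal(characteristic_path_length(weight_to_distance(cyc)), 1.5)

  cm <- random_connectivity(6, seed = 41)
  l1 <- suppressMessages(characteristic_path_length(weight_to_distance(cm)))
  cm2 <- cm; cm2$weights <- cm$weights * 3
  expect_equal(suppressMessages(
    characteristic_path_length(weight_to_distance(cm2))), l1 / 3,
    tolerance = 1e-12)
  expect_error(characteristic_path_length(weight_to_distance(matrix(0, 3, 3))),
               "disconnected")
})

test_that("betweenness is invariant to uniform weight scaling", {
  cm <- random_connectivity(6, seed = 42)
  bc1 <- betweenness_centrality(weight_to_distance(cm))
  cm$weights <- cm$weights * 7.3
  expect_equal(betweenness_centrality(weight_to_distance(cm)), bc1,
               tolerance = 1e-12)
})

test_that("hub identification flags separated nodes and none under the null", {
  bc <- cbind(A = rep(0.9, 20), B = rep(0.1, 20) + rnorm(20, 0, 1e-3),
              C = rep(0.1, 20) + rnorm(20, 0, 1e-3))
  hubs <- identify_hubs(bc, 0.05)
  expect_true(hubs$is_hub[hubs$node == "A"])
  expect_false(any(hubs$is_hub[hubs$node != "A"]))
  expect_error(identify_hubs(bc[1, , drop = FALSE]), "at least 2")

  # exchangeable null: per-node rejection rate near alpha
  set.seed(43)
  n_rep <- 300
  hits <- 0; tests <- 0
  for (r in seq_len(n_rep)) {
    bc_null <- matrix(runif(10 * 8), 10, 8)
    h <- identify_hubs(bc_null, 0.05)
    hits <- hits + sum(h$is_hub); tests <- tests + nrow(h)
  }
  rate <- hits / tests
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("removal impact is zero for isolated nodes, large for star centers", {
  n <- 5
  w <- matrix(1, n, n); diag(w) <- 0
  w[n, ] <- 0; w[, n] <- 0         # node 5 isolated
  labels <- LETTERS[1:n]
  dimnames(w) <- list(labels, labels)
  cm <- structure(list(weights = w, channel_labels = labels,
                       params = analysis_config(), condition = ""),
                  class = "connectivity_matrix")
  expect_equal(suppressMessages(removal_impact(cm, "E")), 0)

  # star: center relays periphery traffic both ways, periphery also has
  # weak direct links so removal leaves the graph connected but slower
  ws <- matrix(0.05, n, n); diag(ws) <- 0
  ws[1, ] <- 1; ws[, 1] <- 1; diag(ws) <- 0
  dimnames(ws) <- list(labels, labels)
  cms <- structure(list(weights = ws, channel_labels = labels,
                        params = analysis_config(), condition = ""),
                   class = "connectivity_matrix")
  expect_gt(suppressMessages(removal_impact(cms, "A")), 100)
  expect_error(removal_impact(cms, "Z"), "unknown node")
  expect_error(removal_impact(cms, labels[-1]), "at least 2")
})

test_that("removing a planted source disturbs paths more than a peripheral node", {
  wins <- 0
  for (s in 1:5) {
    spec <- plant_hub_network(seed = 4000 + s,
                              snk_in_strength = 0.12, snk_out_deg = 0)
    roles <- attr(spec, "roles")
    rec <- simulate_var(spec)
    cm <- connectivity_matrix(rec, analysis_config(seed = 4000 + s))
    src <- sprintf("N%02d", which(roles == "source")[1])
    # peripheral = background node with the least total incident coupling
    e <- spec$edges
    strength_of <- vapply(which(roles == "background"), function(v)
      sum(e$strength[e$source == v | e$target == v]), 0)
    per <- sprintf("N%02d", which(roles == "background")[which.min(strength_of)])
    # signed contrast: removing a broadcast hub lengthens the remaining
    # shortest paths (positive impact); removing a weakly coupled node
    # only deletes its own expensive pairs and the average drops
    i_src <- suppressMessages(removal_impact(cm, src))
    i_per <- suppressMessages(removal_impact(cm, per))
    wins <- wins + (i_src > 0 && i_src > i_per)
  }
  expect_gte(wins, 4)
})
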