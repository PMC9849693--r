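test_that("persistence counting matches frame occupancy", {
  rec <- interaction_records(
    frame = c(0:36, 5, 5, 5),
    residue_i = c(rep("E31", 37), "L10", "L10", "L10"),
    residue_j = c(rep("K20", 37), "V40", "V40", "V40"),
    interaction_class = c(rep("hbond", 37), rep("hydrophobic", 3)))
  pm <- persistence_from_records(rec, n_frames = 100)
  p <- setNames(pm$pairs$persistence,
                paste(pm$pairs$residue_i, pm$pairs$residue_j))
  expect_equal(unname(p["E31 K20"]), 0.37)     # 37 of 100 frames
  expect_equal(unname(p["L10 V40"]), 0.01)     # same-frame duplicates once
  ## always-present and absent pairs
  full <- interaction_records(0:9, rep("A1", 10), rep("B2", 10),
                              rep("hbond", 10))
  expect_equal(persistence_from_records(full, 10)$pairs$persistence, 1)
  empty <- interaction_records(integer(), character(), character(), character())
  expect_equal(nrow(persistence_from_records(empty, 10)$pairs), 0)
  expect_error(persistence_from_records(full, 5), "out of range")
})

test_that("interaction records canonicalise pairs and reject bad input", {
  rec <- interaction_records(c(0, 0), c("Z9", "A1"), c("A1", "Z9"),
                             c("hbond", "hbond"))
  expect_equal(nrow(rec), 1)                    # unordered pair stored once
  expect_equal(rec$residue_i, "A1")
  expect_error(interaction_records(0, "A1", "A1", "hbond"), "self-interactions")
  expect_error(interaction_records(0, "A1", "B2", "vanderwaals"),
               "unknown interaction class")
})

test_that("threshold scanning finds the planted dissolution knee", {
  ## dense hydrophobic cluster whose edges all sit at persistence 0.45
  tpl <- ef_route_template("wt", cluster_persistence = 0.45)
  exact <- structure(list(pairs = tpl, nodes = unique(c(tpl$residue_i,
                                                        tpl$residue_j)),
                          n_frames = 1L), class = "persistence_matrix")
  sel <- select_pt(exact)
  expect_false(sel$fallback_used)
  expect_lte(abs(sel$pt - 0.45), 0.05)          # within one grid step
  ## sampled occupancy at 400 frames still lands within one grid step
  sim <- gen_interaction_records(tpl, n_frames = 400, seed = 21)
  pm <- persistence_from_records(sim$records, 400)
  sel2 <- select_pt(pm)
  expect_lte(abs(sel2$pt - 0.45), 0.05)

  ## flat curve (all persistences 1) falls back with a warning
  flat <- data.frame(residue_i = c("L1", "L2", "L3"),
                     residue_j = c("L2", "L3", "L1"),
                     interaction_class = "hydrophobic", persistence = 1)
  pmf <- structure(list(pairs = flat, nodes = paste0("L", 1:3), n_frames = 1L),
                   class = "persistence_matrix")
  expect_warning(self <- select_pt(pmf), "flat or degenerate")
  expect_equal(self$pt, 0.2)
  expect_true(self$fallback_used)

  ## two-node network exercises the degenerate fallback path
  tiny <- structure(list(pairs = data.frame(residue_i = "A1", residue_j = "B2",
                                            interaction_class = "hydrophobic",
                                            persistence = 0.5),
                         nodes = c("A1", "B2"), n_frames = 1L),
                    class = "persistence_matrix")
  expect_warning(st <- select_pt(tiny), "flat or degenerate")
  expect_equal(st$pt, 0.2)
  expect_error(select_pt(exact, scan_grid = c(0.2, 0.4)), "at least 10")
})

test_that("network construction filters pairs exactly at the threshold", {
  pairs <- data.frame(residue_i = c("a", "a", "b", "c"),
                      residue_j = c("b", "c", "c", "d"),
                      interaction_class = "hbond",
                      persistence = c(0.1, 0.25, 0.4, 0.2))
  pm <- structure(list(pairs = pairs, nodes = letters[1:5], n_frames = 1L),
                  class = "persistence_matrix")
  psn <- build_psn(pm, pt = 0.2)
  got <- sort(paste(psn$edges$residue_i, psn$edges$residue_j))
  expect_equal(got, sort(c("a c", "b c", "c d")))   # >= 0.2 kept, 0.1 dropped
  expect_equal(psn$pt, 0.2)
  ## isolated node survives as a vertex
  expect_true("e" %in% igraph::V(psn$graph)$name)
  ## threshold above the maximum persistence empties the edge set
  expect_equal(igraph::ecount(build_psn(pm, 0.5)$graph), 0)
  expect_error(build_psn(pm, 0), "in \\(0, 1\\)")
  ## raising pt never adds edges (monotone filtering)
  counts <- vapply(seq(0.05, 0.95, by = 0.05), function(p)
    igraph::ecount(build_psn(pm, p)$graph), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-class merging uses the maximum by default and sum on request", {
  pairs <- data.frame(residue_i = c("a", "a"), residue_j = c("b", "b"),
                      interaction_class = c("hbond", "hydrophobic"),
                      persistence = c(0.3, 0.5))
  pm <- structure(list(pairs = pairs, nodes = c("a", "b"), n_frames = 1L),
                  class = "persistence_matrix")
  expect_equal(build_psn(pm, 0.1)$edges$persistence, 0.5)
  expect_equal(build_psn(pm, 0.1, merge = "sum")$edges$persistence, 0.8)
})

test_that("hub identification follows degree centrality", {
  ## star with 6 leaves: centre is a hub in both sets, leaves in neither
  star <- cbind(rep("hub", 6), paste0("leaf", 1:6))
  psn <- psn_from_edges(star, c("hub", paste0("leaf", 1:6)))
  h <- hubs(psn)
  expect_equal(unname(h$degrees["hub"]), 6)
  expect_true("hub" %in% h$hubs)
  expect_true("hub" %in% h$reporting_set)
  expect_false(any(paste0("leaf", 1:6) %in% h$hubs))
  ## empty graph: no hubs
  e <- psn_from_edges(star[0, , drop = FALSE], c("x", "y"))
  expect_equal(length(hubs(e)$hubs), 0)
  ## degrees equal adjacency row sums on a random planted network
  g <- random_test_graph(10, 0.4, seed = 31)
  psn2 <- psn_from_edges(g$edges, g$nodes)
  adj <- as.matrix(igraph::as_adjacency_matrix(psn2$graph))
  expect_equal(hubs(psn2)$degrees[rownames(adj)], rowSums(adj))
  ## reporting set unions across compared graphs
  h2 <- hubs(e, others = list(psn))
  expect_true("hub" %in% h2$reporting_set)
})

test_that("degree differences between networks obey the handshake identity", {
  g <- random_test_graph(8, 0.4, seed = 32)
  psn <- psn_from_edges(g$edges, g$nodes)
  dd0 <- delta_degree(psn, psn)
  expect_true(all(dd0$per_node == 0))
  expect_equal(dd0$total, 0)
  ## one extra edge adds +1 at both endpoints, +2 total
  all_pairs <- t(utils::combn(g$nodes, 2))
  have <- paste(pmin(g$edges[, 1], g$edges[, 2]),
                pmax(g$edges[, 1], g$edges[, 2]))
  free <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), ,
                    drop = FALSE]
  extra <- rbind(g$edges, free[1, ])
  psn2 <- psn_from_edges(extra, g$nodes)
  dd <- delta_degree(psn2, psn)
  expect_equal(dd$total, 2)
  expect_equal(sort(names(dd$per_node[dd$per_node == 1])),
               sort(extra[nrow(extra), ]))
  ## totals match a brute-force recount on a planted rewiring
  g2 <- random_test_graph(8, 0.5, seed = 33)
  psn3 <- psn_from_edges(g2$edges, g$nodes)
  dd2 <- delta_degree(psn3, psn)
  brute <- rowSums(as.matrix(igraph::as_adjacency_matrix(psn3$graph))[g$nodes, g$nodes]) -
    rowSums(as.matrix(igraph::as_adjacency_matrix(psn$graph))[g$nodes, g$nodes])
  expect_equal(dd2$per_node[g$nodes], brute[g$nodes])
  ## missing node treated as degree zero, with a notice
  keep_e <- g$edges[g$edges[, 1] != "r8" & g$edges[, 2] != "r8", ,
                    drop = FALSE]
  psn_small <- psn_from_edges(keep_e, g$nodes[-8])
  expect_message(ddm <- delta_degree(psn, psn_small, node_set = g$nodes),
                 "degree 0")
  expect_equal(unname(ddm$per_node["r8"]),
               unname(hubs(psn)$degrees["r8"]))
})

test_that("shortest-path structure matches hand-checked cases", {
  ## adjacent nodes
  adj <- psn_from_edges(cbind("x", "y"), c("x", "y"))
  sp <- shortest_paths_psn(adj, "x", "y")
  expect_equal(sp$l, 1L)
  expect_equal(sp$n, 1L)
  ## 4-cycle opposite corners: two length-2 routes
  cyc <- psn_from_edges(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")),
                        letters[1:4], pt = 0.3)
  sp2 <- shortest_paths_psn(cyc, "a", "c")
  expect_equal(sp2$l, 2L)
  expect_equal(sp2$n, 2L)
  expect_setequal(vapply(sp2$paths, paste, character(1), collapse = "-"),
                  c("a-b-c", "a-d-c"))
  ## disconnected pair
  dis <- psn_from_edges(cbind("x", "y"), c("x", "y", "z"))
  spd <- shortest_paths_psn(dis, "x", "z")
  expect_equal(spd$l, Inf)
  expect_equal(spd$n, 0L)
  expect_error(shortest_paths_psn(adj, "x", "nope"), "unknown node")
  expect_error(shortest_paths_psn(adj, "x", "x"), "distinct")
})

test_that("communication robustness evaluates both index forms", {
  ## single path of length 3 at pT = 0.2
  chain <- psn_from_edges(cbind(c("X", "m1", "m2"), c("m1", "m2", "Y")),
                          c("X", "m1", "m2", "Y"), pt = 0.2)
  expect_equal(cr_index(chain, "X", "Y"), 0.2 / 3)
  expect_equal(cr_index(chain, "X", "Y", form = "n_pt_pow_l"), 0.2^3)
  ## 4-cycle opposite corners at pT = 0.3: default form 2 * 0.3 / 2
  cyc <- psn_from_edges(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")),
                        letters[1:4], pt = 0.3)
  expect_equal(cr_index(cyc, "a", "c"), 0.3)
  ## disconnected: zero
  dis <- psn_from_edges(cbind("x", "y"), c("x", "y", "z"))
  expect_equal(cr_index(dis, "x", "z"), 0)
  expect_error(cr_index(cyc, "a", "a"), "distinct")
})

test_that("EF-hand CR matrix is symmetric with correct robustness flags", {
  cr <- run_ef_discrimination("wt", seed = 41)
  expect_equal(cr$cr, t(cr$cr))
  expect_true(all(diag(cr$cr) == 0))
  expect_true(all(cr$cr >= 0))
  expect_true(cr$robust["EF3", "EF4"])
  expect_true(cr$robust["EF1", "EF3"])
  crm <- run_ef_discrimination("mutant", seed = 41)
  expect_equal(crm$cr["EF1", "EF3"], 0)          # route broken: no path
  expect_false(crm$robust["EF1", "EF3"])
  expect_true(crm$robust["EF3", "EF4"])
  ## missing representative residue is an explicit error
  g <- random_test_graph(5, 0.5, seed = 42)
  psn <- psn_from_edges(g$edges, g$nodes)
  expect_error(ef_hand_cr(psn), "missing from the network")
})
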