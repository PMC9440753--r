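render_mask <- function(truth, volume, radius = 1.5, seed = 1) {
  cfg <- clean_config(volume, seed = seed, neurite_radius_um = radius)
  binarize(render_stack(truth, cfg), "neurite", "fixed", threshold = 0.5)
}

test_that("skeletonization recovers a 50 um tube within 5%", {
  g <- line_graph(c(5, 8, 8), c(55, 8, 8))
  m <- render_mask(manual_truth(g), c(60, 16, 16))
  sk <- skeletonize(m)
  traced <- skeleton_to_graph(sk)
  expect_equal(nrow(traced$edges), 1)
  expect_lt(abs(total_length(traced) - 50) / 50, 0.05)
})

test_that("a solid sphere thins to almost nothing", {
  truth <- manual_truth(somas = data.frame(x = 15, y = 15, z = 15, radius = 6,
                                           hollow = FALSE, node = 1L))
  m <- render_mask(truth, c(30, 30, 30))
  g <- skeleton_to_graph(skeletonize(m))
  expect_lt(total_length(g), 12) # less than the sphere diameter
})

test_that("an empty mask gives an empty skeleton and graph", {
  m <- binary_mask(array(FALSE, c(10, 10, 10)), c(0.33, 0.33, 0.5))
  sk <- skeletonize(m)
  expect_false(any(sk$voxels))
  g <- skeleton_to_graph(sk)
  expect_equal(nrow(g$edges), 0)
  expect_equal(total_length(g), 0)
})

test_that("graph extraction classifies a Y junction correctly", {
  nodes <- data.frame(x = c(30, 10, 50, 30), y = c(30, 12, 12, 50),
                      z = 10, kind = c("branch", "end", "end", "end"))
  arm <- function(b) rbind(c(30, 30, 10), b)
  g <- spatial_graph(nodes, data.frame(from = c(1, 1, 1), to = 2:4),
                     list(arm(c(10, 12, 10)), arm(c(50, 12, 10)),
                          arm(c(30, 50, 10))))
  true_len <- total_length(g)
  m <- render_mask(manual_truth(g), c(60, 60, 20))
  traced <- skeleton_to_graph(skeletonize(m))
  expect_equal(sum(traced$nodes$kind == "branch"), 1)
  expect_equal(sum(traced$nodes$kind == "end"), 3)
  expect_lt(abs(total_length(traced) - true_len) / true_len, 0.05)
})

test_that("disjoint tubes come back as separate components", {
  nodes <- data.frame(x = c(5, 45, 5, 45), y = c(6, 6, 18, 18), z = 8,
                      kind = "end")
  g <- spatial_graph(nodes, data.frame(from = c(1, 3), to = c(2, 4)),
                     list(rbind(c(5, 6, 8), c(45, 6, 8)),
                          rbind(c(5, 18, 8), c(45, 18, 8))))
  m <- render_mask(manual_truth(g), c(50, 24, 16))
  traced <- skeleton_to_graph(skeletonize(m))
  expect_equal(max(traced$node_components), 2)
})

test_that("edge lengths in extracted graphs are recomputable arclengths", {
  cfg <- recovery_config(3)
  tr <- generate_network(cfg)
  m <- binarize(render_stack(tr, cfg), "neurite", "fixed", threshold = 0.5)
  g <- skeleton_to_graph(skeletonize(m))
  recomputed <- vapply(g$polylines, neurotrace3d:::polyline_length, numeric(1))
  expect_equal(g$edges$length, recomputed, tolerance = 1e-9)
})

test_that("spur pruning removes short terminal twigs at branch nodes only", {
  # Y with one 1 um arm
  nodes <- data.frame(x = c(20, 5, 35, 20), y = c(20, 20, 20, 21), z = 5,
                      kind = c("branch", "end", "end", "end"))
  g <- spatial_graph(nodes, data.frame(from = c(1, 1, 1), to = 2:4),
                     list(rbind(c(20, 20, 5), c(5, 20, 5)),
                          rbind(c(20, 20, 5), c(35, 20, 5)),
                          rbind(c(20, 20, 5), c(20, 21, 5))))
  expect_identical(prune_spurs(g, 0), g)
  pg <- prune_spurs(g, 2)
  expect_equal(nrow(pg$edges), 1) # two long arms merged into one through-edge
  expect_equal(sum(pg$nodes$kind == "branch"), 0)
  expect_equal(total_length(pg), 30)

  # a bare chain has no branch nodes: unchanged at any threshold
  chain <- line_graph(c(0, 0, 0), c(1, 0, 0))
  expect_equal(total_length(prune_spurs(chain, 50)), 1)
  expect_equal(nrow(prune_spurs(chain, 50)$edges), 1)
})

test_that("loop removal collapses soma-scale rings and keeps circuits", {
  acyc <- star_graph(3)
  out <- remove_loops(acyc, 40)
  expect_equal(attr(out, "loops_removed"), 0)
  expect_equal(total_length(out), total_length(acyc))

  small <- remove_loops(ring_graph(35), 40)
  expect_equal(attr(small, "loops_removed"), 1)
  expect_equal(nrow(small$edges), 0)

  big <- remove_loops(ring_graph(200), 40)
  expect_equal(attr(big, "loops_removed"), 0)
  expect_equal(nrow(big$edges), 1)

  # multi-edge ring (two half-circles) below threshold also collapses
  th1 <- seq(0, pi, length.out = 21); r <- 35 / (2 * pi)
  p1 <- cbind(50 + r * cos(th1), 50 + r * sin(th1), 10)
  p2 <- cbind(50 + r * cos(th1 + pi), 50 + r * sin(th1 + pi), 10)
  nodes <- data.frame(x = c(50 + r, 50 - r), y = 50, z = 10, kind = "end")
  g2 <- spatial_graph(nodes, data.frame(from = c(1, 2), to = c(2, 1)),
                      list(p1, p2))
  col <- remove_loops(g2, 40)
  expect_equal(attr(col, "loops_removed"), 1)
})

test_that("gap bridging joins collinear fragments within the gap limit", {
  mkfrag <- function(gap) {
    nodes <- data.frame(x = c(0, 20, 20 + gap, 40 + gap), y = 0, z = 0,
                        kind = "end")
    spatial_graph(nodes, data.frame(from = c(1, 3), to = c(2, 4)),
                  list(rbind(c(0, 0, 0), c(20, 0, 0)),
                       rbind(c(20 + gap, 0, 0), c(40 + gap, 0, 0))))
  }
  b3 <- bridge_gaps(mkfrag(3), max_gap_um = 4)
  expect_equal(max(b3$node_components), 1)
  expect_equal(attr(b3, "bridges_added"), 1)
  expect_equal(total_length(b3), 43) # bridge adds exactly the gap length

  b5 <- bridge_gaps(mkfrag(5), max_gap_um = 4)
  expect_equal(max(b5$node_components), 2)

  b0 <- bridge_gaps(mkfrag(3), max_gap_um = 0)
  expect_equal(max(b0$node_components), 2)

  # angle gate: perpendicular terminal directions are not bridged
  nodes <- data.frame(x = c(0, 20, 22, 22), y = c(0, 0, 2, 22), z = 0,
                      kind = "end")
  perp <- spatial_graph(nodes, data.frame(from = c(1, 3), to = c(2, 4)),
                        list(rbind(c(0, 0, 0), c(20, 0, 0)),
                             rbind(c(22, 2, 0), c(22, 22, 0))))
  bp <- bridge_gaps(perp, max_gap_um = 4, max_angle_deg = 30)
  expect_equal(max(bp$node_components), 2)
})

test_that("soma assignment fuses nearby nodes and filters by mode", {
  # skeleton mode with no somas: unchanged topology
  g <- star_graph(3)
  gs <- assign_somas(g, data.frame(x = numeric(0), y = numeric(0),
                                   z = numeric(0), radius = numeric(0)),
                     mode = "skeleton")
  expect_equal(nrow(gs$edges), nrow(g$edges))

  # two components, one soma: soma_rooted keeps 1, reports 1 discarded
  nodes <- data.frame(x = c(5, 45, 5, 45), y = c(6, 6, 30, 30), z = 8,
                      kind = "end")
  g2 <- spatial_graph(nodes, data.frame(from = c(1, 3), to = c(2, 4)),
                      list(rbind(c(5, 6, 8), c(45, 6, 8)),
                           rbind(c(5, 30, 8), c(45, 30, 8))))
  somas <- data.frame(x = 5, y = 6, z = 8, radius = 5)
  gr <- assign_somas(g2, somas, mode = "soma_rooted")
  expect_equal(max(gr$node_components), 1)
  expect_equal(attr(gr, "components_discarded"), 1)
  expect_equal(sum(gr$nodes$kind == "soma"), 1)

  # fusion: a soma centred 2 um from a degree-2 slab node absorbs it and
  # inherits its degree
  nodes3 <- data.frame(x = c(0, 20, 40), y = 0, z = 0,
                       kind = c("end", "slab", "end"))
  g3 <- spatial_graph(nodes3, data.frame(from = c(1, 2), to = c(2, 3)),
                      list(rbind(c(0, 0, 0), c(20, 0, 0)),
                           rbind(c(20, 0, 0), c(40, 0, 0))))
  gf <- assign_somas(g3, data.frame(x = 22, y = 0, z = 0, radius = 6),
                     mode = "skeleton")
  soma_id <- which(gf$nodes$kind == "soma")
  expect_equal(length(soma_id), 1)
  expect_equal(neurotrace3d:::sg_degree(gf)[soma_id], 2)
  expect_error(assign_somas(g3, data.frame(x = 90, y = 0, z = 0, radius = 6),
                            mode = "skeleton", volume_um = c(50, 10, 10)),
               "outside")
})

test_that("cleanup operations never increase length; bridging adds its own", {
  cfg <- recovery_config(5)
  tr <- generate_network(cfg)
  m <- binarize(render_stack(tr, cfg), "neurite", "fixed", threshold = 0.5)
  g <- skeleton_to_graph(skeletonize(m))
  L0 <- total_length(g)
  g1 <- prune_spurs(g, 2)
  expect_lte(total_length(g1), L0 + 1e-9)
  g2 <- remove_loops(g1, 40)
  expect_lte(total_length(g2), total_length(g1) + 1e-9)
  g3 <- bridge_gaps(g2, 4, 60)
  nb <- attr(g3, "bridges_added")
  bridge_len <- total_length(g3) - total_length(g2)
  expect_gte(bridge_len, 0)
  if (nb > 0) expect_lte(bridge_len, nb * 4 + 1e-9)
})

test_that("fragmented stacks show more end points in skeleton mode", {
  cfg <- sim_config(volume_um = c(56, 56, 28), n_neurons = 3,
                    neurites_per_soma = 3, neurite_length_um = 30,
                    neurite_radius_um = 1.2, soma_diameter_um = 9,
                    hollow_soma_fraction = 0, tortuosity = 0.15,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 17)
  tr <- generate_network(cfg)
  dmg <- apply_damage(tr, damage_params(prune_fraction = 0.3,
                                        fragment_rate_per_um = 0.05,
                                        gap_length_um = 5,
                                        detach_prob = 0.5), seed = 18)
  st <- render_stack(dmg, cfg)
  sk <- trace_network(st, mode = "skeleton", threshold = 0.5, detect = FALSE)
  sr <- trace_network(st, mode = "soma_rooted", threshold = 0.5,
                      somas = dmg$somas)
  expect_gte(count_end_points(sk$graph), count_end_points(sr$graph))
  expect_gte(total_length(sk$graph), total_length(sr$graph))
})
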