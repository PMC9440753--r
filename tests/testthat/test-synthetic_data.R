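test_that("a single straight neurite carries exactly its commanded length", {
  cfg <- sim_config(volume_um = c(140, 140, 140), n_neurons = 1,
                    neurites_per_soma = 1, neurite_length_um = 50,
                    neurite_length_sd_um = 0, tortuosity = 0,
                    branch_prob_per_um = 0, connect = FALSE,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 4)
  tr <- generate_network(cfg)
  expect_equal(total_length(tr$graph), 50, tolerance = 1e-9)
  expect_equal(nrow(tr$somas), 1)
  expect_equal(tr$neurite_counts, 1L)
})

test_that("an empty culture yields an empty ground truth", {
  cfg <- clean_config(c(50, 50, 50))
  tr <- generate_network(cfg)
  expect_equal(total_length(tr$graph), 0)
  expect_equal(nrow(tr$somas), 0)
  expect_equal(nrow(tr$graph$edges), 0)
})

test_that("radial neurite count per soma matches the commanded count", {
  cfg <- sim_config(volume_um = c(150, 150, 100), n_neurons = 3,
                    neurites_per_soma = 5, branch_prob_per_um = 0,
                    connect = FALSE, neurite_length_um = 30,
                    neurite_length_sd_um = 0,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 8)
  tr <- generate_network(cfg)
  expect_equal(tr$neurite_counts, rep(5L, 3))
})

test_that("generation is deterministic and lengths are recomputable", {
  cfg <- sim_config(volume_um = c(100, 100, 60), n_neurons = 4, seed = 12,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0)
  t1 <- generate_network(cfg)
  t2 <- generate_network(cfg)
  expect_identical(t1, t2)
  # length invariant: stored edge lengths equal recomputed polyline arclengths
  recomputed <- vapply(t1$graph$polylines, neurotrace3d:::polyline_length,
                       numeric(1))
  expect_equal(t1$graph$edges$length, recomputed, tolerance = 1e-9)
  expect_equal(total_length(t1$graph), sum(recomputed), tolerance = 1e-9)
  # partition consistent with soma nodes: every component holds >= 1 soma
  soma_comps <- t1$graph$node_components[t1$somas$node]
  expect_true(all(t1$graph$components %in% soma_comps))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(volume_um = c(-1, 10, 10)), "volume")
  expect_error(sim_config(hollow_soma_fraction = 1.5), "hollow")
  expect_error(sim_config(neurite_radius_um = 0), "positive")
  expect_error(damage_params(prune_fraction = 2), "prune_fraction")
  expect_error(damage_params(soma_swell_factor = 0.5), "swell")
})

test_that("an overcrowded volume raises a placement failure", {
  cfg <- sim_config(volume_um = c(20, 20, 20), n_neurons = 40,
                    soma_diameter_um = 12, seed = 1)
  expect_error(generate_network(cfg), "placement failure")
})

test_that("all-zero damage parameters are the identity transform", {
  cfg <- sim_config(volume_um = c(100, 100, 60), n_neurons = 3, seed = 5,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0)
  tr <- generate_network(cfg)
  expect_identical(apply_damage(tr, damage_params(), seed = 99), tr)
})

test_that("pruning removes the commanded fraction of total length", {
  cfg <- sim_config(volume_um = c(150, 150, 80), n_neurons = 5,
                    neurites_per_soma = 4, neurite_length_um = 55,
                    connect = FALSE,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 6)
  tr <- generate_network(cfg)
  L0 <- total_length(tr$graph)
  d <- damage_params(prune_fraction = 0.5)
  remaining <- vapply(1:25, function(s)
    total_length(apply_damage(tr, d, seed = s)$graph), numeric(1))
  expect_lt(abs(mean(remaining) - 0.5 * L0) / (0.5 * L0), 0.05)
})

test_that("fragmentation raises the component count by the gap count", {
  cfg <- sim_config(volume_um = c(140, 140, 140), n_neurons = 1,
                    neurites_per_soma = 1, neurite_length_um = 80,
                    neurite_length_sd_um = 0, tortuosity = 0,
                    branch_prob_per_um = 0, connect = FALSE,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 4)
  tr <- generate_network(cfg)
  expect_equal(max(tr$graph$node_components), 1)
  d <- damage_params(fragment_rate_per_um = 0.05, gap_length_um = 2)
  dt <- apply_damage(tr, d, seed = 3)
  k <- dt$damage_report$n_gaps
  expect_gt(k, 0)
  expect_equal(max(dt$graph$node_components), 1 + k)
})

test_that("soma swelling changes radii only", {
  cfg <- sim_config(volume_um = c(100, 100, 60), n_neurons = 3, seed = 5,
                    psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
                    noise_poisson_scale = 0)
  tr <- generate_network(cfg)
  dt <- apply_damage(tr, damage_params(soma_swell_factor = 1.4), seed = 2)
  expect_equal(dt$somas$radius, tr$somas$radius * 1.4)
  expect_equal(total_length(dt$graph), total_length(tr$graph))
  expect_equal(max(dt$graph$node_components), max(tr$graph$node_components))
})

test_that("rendering is deterministic and respects geometry", {
  cfg <- sim_config(volume_um = c(60, 60, 30), n_neurons = 2,
                    neurites_per_soma = 2, neurite_length_um = 25,
                    seed = 10)
  tr <- generate_network(cfg)
  s1 <- render_stack(tr, cfg)
  s2 <- render_stack(tr, cfg)
  expect_identical(s1$channels, s2$channels)

  # empty truth renders an all-zero noiseless stack
  empty <- render_stack(manual_truth(), clean_config(c(30, 30, 20)))
  expect_true(all(vapply(empty$channels, function(a) all(a == 0), logical(1))))
})

test_that("a rendered solid sphere recovers the analytic volume", {
  truth <- manual_truth(
    somas = data.frame(x = 15, y = 15, z = 15, radius = 6, hollow = FALSE,
                       node = 1L))
  st <- render_stack(truth, clean_config(c(30, 30, 30)))
  m <- binarize(st, "neurite", "fixed", threshold = 0.5)
  expect_lt(abs(network_volume(m) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3),
            0.05)
})

test_that("hollow somas render as shells with an enclosed cavity", {
  truth <- manual_truth(
    somas = data.frame(x = 15, y = 15, z = 15, radius = 6, hollow = TRUE,
                       node = 1L))
  st <- render_stack(truth, clean_config(c(30, 30, 30)))
  m <- binarize(st, "neurite", "fixed", threshold = 0.5)
  mf <- fill_holes(m)
  expect_gt(sum(mf$voxels), sum(m$voxels)) # filling changed the mask
  expect_lt(abs(network_volume(mf) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3),
            0.05)
})

test_that("a truth outside the render volume raises an extent error", {
  g <- line_graph(c(0, 0, 0), c(80, 0, 0))
  expect_error(render_stack(manual_truth(g), clean_config(c(40, 20, 20))),
               "extent mismatch")
})
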