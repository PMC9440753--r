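make_stack <- function(chans, spacing = c(0.33, 0.33, 0.5)) {
  image_stack(chans, spacing)
}

test_that("channel merge is a voxelwise maximum with idempotence", {
  d <- c(20, 20, 10)
  a <- array(0, d); a[5, 5, 5] <- 0.8
  b <- array(0, d); b[15, 15, 5] <- 0.6
  st <- make_stack(list(a = a, b = b))

  m1 <- get_channel(merge_channels(st, "a", "a"), "merged")
  expect_equal(m1, a / max(a))

  z <- array(0, d)
  st0 <- make_stack(list(a = z, b = b))
  expect_equal(get_channel(merge_channels(st0, "a", "b"), "merged"), b / max(b))

  # disjoint supports keep both peaks after per-channel rescaling
  mm <- get_channel(merge_channels(st, "a", "b"), "merged")
  expect_equal(mm[5, 5, 5], 1)    # 0.8 peak rescaled to 1
  expect_equal(mm[15, 15, 5], 1)  # 0.6 peak rescaled to 1
  # unscaled peaks preserved when channels share their maximum
  a2 <- a; a2[1, 1, 1] <- 1; b2 <- b; b2[1, 1, 2] <- 1
  st2 <- make_stack(list(a = a2, b = b2))
  mm2 <- get_channel(merge_channels(st2, "a", "b"), "merged")
  expect_equal(mm2[5, 5, 5], 0.8)
  expect_equal(mm2[15, 15, 5], 0.6)

  # commutativity
  expect_equal(get_channel(merge_channels(st, "a", "b"), "merged"),
               get_channel(merge_channels(st, "b", "a"), "merged"))
  expect_error(merge_channels(st, "a", "nope"), "unknown channel")
})

test_that("gaussian smoothing is normalized, anisotropy-aware and identity at 0", {
  d <- c(21, 21, 15)
  imp <- array(0, d); imp[11, 11, 8] <- 3
  st <- make_stack(list(x = imp))

  expect_equal(get_channel(gaussian_smooth(st, "x", 0), "x"), imp)

  cst <- make_stack(list(x = array(0.4, d)))
  sm <- get_channel(gaussian_smooth(cst, "x", 1), "x")
  expect_equal(sm, array(0.4, d), tolerance = 1e-12)

  sm2 <- get_channel(gaussian_smooth(st, "x", 0.33), "x")
  expect_equal(sum(sm2), 3, tolerance = 1e-6)
  expect_error(gaussian_smooth(st, "x", -1), ">= 0")
})

test_that("curvature-driven diffusion suppresses speckle but keeps tubes", {
  set.seed(1)
  d <- c(100, 40, 40)
  a <- array(0, d)
  a[10:100, 20, 20] <- 1
  speck <- sample(which(a == 0), 60)
  a[speck] <- 1
  st <- image_stack(list(x = a), c(0.33, 0.33, 0.33))

  expect_equal(get_channel(cdd_filter(st, "x", n_iter = 0), "x"), a)
  cst <- image_stack(list(x = array(0.7, c(10, 10, 10))), c(1, 1, 1))
  expect_equal(get_channel(cdd_filter(cst, "x", 5), "x"),
               array(0.7, c(10, 10, 10)), tolerance = 1e-12)

  f <- get_channel(cdd_filter(st, "x", n_iter = 10), "x")
  expect_gt(mean(f[10:100, 20, 20]), mean(f[speck]))
  # maximum principle
  expect_lte(max(f), max(a) + 1e-6)
  expect_gte(min(f), min(a) - 1e-6)
  expect_error(cdd_filter(st, "x", n_iter = 5, dt = 0.2), "unstable dt")
})

test_that("binarization thresholds as specified and records provenance", {
  d <- c(2, 1, 1)
  x <- array(c(0.4, 0.6), d)
  st <- make_stack(list(x = x))
  m <- binarize(st, "x", "fixed", threshold = 0.5)
  expect_equal(as.vector(m$voxels), c(FALSE, TRUE))
  expect_equal(m$source_threshold, 0.5)

  m2 <- binarize(st, "x", "fixed", threshold = 0.3)
  expect_true(all(m2$voxels))

  # re-binarization at the recorded threshold is the identity
  m3 <- binarize(st, "x", "fixed", threshold = m$source_threshold)
  expect_identical(m3$voxels, m$voxels)
  expect_error(binarize(st, "x", "fixed"), "threshold")
})

test_that("otsu matches a brute-force between-class-variance sweep", {
  set.seed(2)
  x <- c(rnorm(5e4, 0.2, 0.05), rnorm(5e4, 0.8, 0.05))
  thr <- otsu_threshold(x)
  expect_lt(abs(thr - 0.5), 0.1)

  # oracle: directly sweep candidate thresholds and compare achieved
  # between-class variance
  bcv <- function(t) {
    w0 <- mean(x < t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x < t]) - mean(x[x >= t]))^2
  }
  grid <- seq(min(x) + 1e-3, max(x) - 1e-3, length.out = 400)
  best <- max(vapply(grid, bcv, numeric(1)))
  expect_gte(bcv(thr), 0.999 * best)

  expect_error(otsu_threshold(rep(0.5, 100)), "constant")
})

test_that("hole filling fills enclosed cavities only and is idempotent", {
  # solid sphere: unchanged
  solid <- manual_truth(somas = data.frame(x = 15, y = 15, z = 15, radius = 6,
                                           hollow = FALSE, node = 1L))
  ms <- binarize(render_stack(solid, clean_config(c(30, 30, 30))),
                 "neurite", "fixed", threshold = 0.5)
  expect_identical(fill_holes(ms)$voxels, ms$voxels)

  # hollow shell: cavity filled to the analytic sphere volume
  shell <- manual_truth(somas = data.frame(x = 15, y = 15, z = 15, radius = 6,
                                           hollow = TRUE, node = 1L))
  mh <- binarize(render_stack(shell, clean_config(c(30, 30, 30))),
                 "neurite", "fixed", threshold = 0.5)
  mf <- fill_holes(mh)
  v <- 4 / 3 * pi * 6^3
  expect_lt(abs(network_volume(mf) - v) / v, 0.05)
  expect_identical(fill_holes(mf)$voxels, mf$voxels)

  # open half-shell: cavity connects to boundary background, unchanged
  half <- mh
  half$voxels[, , dim(half$voxels)[3] %/% 2 + seq_len(dim(half$voxels)[3] %/% 2)] <- FALSE
  mo <- binary_mask(half$voxels, half$spacing_um)
  expect_identical(fill_holes(mo)$voxels, mo$voxels)
})

test_that("NeuN masking keeps only NeuN-positive nuclei", {
  d <- c(30, 30, 10)
  dapi <- array(0, d)
  neun <- array(0, d)
  dapi[5, 5, 5] <- 1; dapi[15, 15, 5] <- 1; dapi[25, 25, 5] <- 1
  neun[5, 5, 5] <- 1; neun[15, 15, 5] <- 1
  st <- make_stack(list(DAPI = dapi, NeuN = neun))

  all_pass <- get_channel(mask_nuclear_channel(st, neun_threshold = 0), "DAPI_masked")
  expect_equal(all_pass, dapi)

  st0 <- make_stack(list(DAPI = dapi, NeuN = array(0, d)))
  none <- get_channel(mask_nuclear_channel(st0, neun_threshold = 0.5), "DAPI_masked")
  expect_true(all(none == 0))

  masked <- get_channel(mask_nuclear_channel(st, neun_threshold = 0.5), "DAPI_masked")
  expect_equal(sum(masked > 0), 2)
  expect_error(mask_nuclear_channel(st, dapi = "nope"), "unknown channel")
})

test_that("every preprocessing step appends a provenance entry", {
  d <- c(10, 10, 5)
  st <- make_stack(list(a = array(runif(prod(d)), d),
                        b = array(runif(prod(d)), d)))
  n0 <- length(st$log)
  st <- merge_channels(st, "a", "b")
  st <- gaussian_smooth(st, "merged", 0.33)
  st <- cdd_filter(st, "merged", n_iter = 1)
  st <- mask_nuclear_channel(st, dapi = "a", neun = "b", neun_threshold = 0.2)
  expect_equal(length(st$log), n0 + 4)
  expect_equal(vapply(st$log, function(e) e$op, character(1)),
               c("merge_channels", "gaussian_smooth", "cdd_filter",
                 "mask_nuclear_channel"))
})
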