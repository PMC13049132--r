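test_that("depth-dose kernel has Bragg-peak shape", {
  rg <- 120
  expect_equal(depth_dose_kernel(rg, rg), 1.0)
  expect_lt(depth_dose_kernel(rg + 5 * 5, rg, bragg_width = 5), 0.01)
  ratio <- depth_dose_kernel(0, rg) / depth_dose_kernel(rg, rg)
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 0.5)
  z <- seq(0, 200, by = 0.5)
  expect_true(all(depth_dose_kernel(z, rg) >= 0))
  expect_equal(which.max(depth_dose_kernel(z, rg)), which(z == rg))
})

test_that("depth-LET kernel is monotone with an exact entrance value and distal max", {
  z <- seq(0, 200, by = 0.25)
  l <- depth_let_kernel(z, range = 120, let_plateau = 2, let_peak = 12)
  expect_equal(l[1], 2)
  expect_true(all(diff(l) >= -1e-12))
  expect_gte(z[which.max(l)], 120)
  expect_lte(max(l), 12)
  expect_error(depth_let_kernel(-1, 100))
})

test_that("influence assembly satisfies its definitional identities", {
  infl <- small_influence()
  expect_gt(infl$m, 50)
  expect_true(all(infl$D@x >= 0))
  expect_true(all(infl$L@x > 0))
  # M = L o D wherever D is stored
  expect_lt(max(abs(infl$M@x - infl$D@x * infl$L@x)), 1e-12)
  # C = beta1 D + beta2 M, entrywise on a random 10-column sample
  set.seed(1)
  cols <- sample(infl$m, 10)
  Cref <- infl$beta1 * infl$D[, cols] + infl$beta2 * infl$M[, cols]
  expect_lt(max(abs(infl$C[, cols] - Cref)), 1e-14)
  # sparsity sanity: stored nonzeros per column <= 20% of n
  nnz_col <- diff(infl$D@p)
  expect_lt(max(nnz_col) / nrow(infl$D), 0.20)
  # every PTV voxel has beamlet support
  ptv <- which(as.vector(get_mask(small_phantom(), "PTV")))
  expect_true(all(Matrix::rowSums(infl$D[ptv, ] > 0) >= 1))
})

test_that("a lone beamlet deposits a laterally Gaussian Bragg column", {
  cfg <- small_config()
  # single-voxel target centered exactly on a voxel center, no jitter
  cfg$gtv_radius <- 2; cfg$ctv_margin <- 0; cfg$ptv_margin <- 0
  cfg$gtv_center <- c(26, 2, 2); cfg$jitter <- 0; cfg$require_overlap <- FALSE
  ph <- suppressWarnings(make_phantom(cfg))
  expect_equal(sum(get_mask(ph, "PTV")), 1)
  beam <- beam_spec(couch_angle = 0, spot_spacing = 200, layer_spacing = 200)
  infl <- suppressWarnings(build_influence(ph, beams = list(beam)))
  expect_equal(infl$m, 1L)
  col <- array(as.vector(infl$D[, 1]), dim = ph$grid$dims)
  tgt <- which(get_mask(ph, "GTV"), arr.ind = TRUE)
  # the spot axis runs along +x through the target voxel: peak dose 1 there
  expect_equal(max(col), 1, tolerance = 1e-12)
  expect_equal(col[tgt], 1, tolerance = 1e-12)
  # reconstruct the whole column: kernel along depth times Gaussian lateral
  xy <- voxel_coordinates(ph$grid)
  ext <- as.vector(get_mask(ph, "External"))
  # per-column entry: min x over External voxels of that (y, z) column
  df <- data.frame(x = xy[, 1], key = paste(xy[, 2], xy[, 3]), ext = ext)
  entry_map <- tapply(ifelse(df$ext, df$x, Inf), df$key, min)
  depth <- df$x - as.vector(entry_map[df$key])
  tvox <- which(get_mask(ph, "GTV"))
  rg <- depth[tvox]
  r2 <- (xy[, 2] - xy[tvox, 2])^2 + (xy[, 3] - xy[tvox, 3])^2
  expected <- ifelse(ext & depth >= 0 & r2 <= (3 * beam$lateral_sigma)^2,
                     depth_dose_kernel(pmax(depth, 0), rg, beam$bragg_width) *
                       exp(-r2 / (2 * beam$lateral_sigma^2)), 0)
  sup <- which(as.vector(infl$D[, 1]) > 0)
  expect_equal(as.vector(infl$D[sup, 1]), expected[sup], tolerance = 1e-10)
  # single-beamlet LET collapses to that beamlet's L column on its support
  ld <- let_d(infl, 1, dose_floor = 1e-9)
  expect_equal(ld[sup], as.vector(infl$L[sup, 1]), tolerance = 1e-12)
})

test_that("fluence-to-dose projection is linear and columnwise exact", {
  infl <- small_influence()
  m <- infl$m
  expect_equal(dose_from_fluence(infl, rep(0, m)), rep(0, nrow(infl$D)))
  ej <- rep(0, m); ej[17] <- 1
  expect_equal(dose_from_fluence(infl, ej), as.vector(infl$D[, 17]))
  set.seed(2)
  p1 <- stats::runif(m); p2 <- stats::runif(m)
  d12 <- dose_from_fluence(infl, p1 + p2)
  d1 <- dose_from_fluence(infl, p1); d2 <- dose_from_fluence(infl, p2)
  expect_lt(max(abs(d12 - (d1 + d2))) / max(d12), 1e-12)
})

test_that("dose-LET product matches the brute-force dose-weighted average", {
  infl <- small_influence()
  Dd <- as.matrix(infl$D); Ld <- as.matrix(infl$L)
  set.seed(3)
  for (rep_i in 1:50) {
    phi <- stats::runif(infl$m)
    dld <- dose_let_product(infl, phi)
    d <- dose_from_fluence(infl, phi)
    num <- as.vector((Ld * Dd) %*% phi)
    sup <- d > 1e-12
    ref <- d[sup] * (num[sup] / d[sup])
    expect_lt(max(abs(dld[sup] - ref) / pmax(abs(ref), 1e-300)), 1e-10)
  }
  expect_equal(dose_let_product(infl, rep(0, infl$m)), rep(0, nrow(infl$D)))
})

test_that("dose-averaged LET is a convex combination of beamlet LET values", {
  infl <- small_influence()
  set.seed(4)
  phi <- stats::runif(infl$m)
  ld <- let_d(infl, phi, dose_floor = 1e-3)
  d <- dose_from_fluence(infl, phi)
  sup <- d >= 1e-3
  expect_true(all(ld[!sup] == 0))
  expect_true(all(ld[sup] >= min(infl$L@x) - 1e-9))
  expect_true(all(ld[sup] <= max(infl$L@x) + 1e-9))
})

test_that("influence assembly is deterministic", {
  ph <- small_phantom()
  a <- build_influence(ph, beams = default_beams(spot_spacing = 12, layer_spacing = 12))
  b <- build_influence(ph, beams = default_beams(spot_spacing = 12, layer_spacing = 12))
  expect_identical(a$D, b$D)
  expect_identical(a$L, b$L)
})
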