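test_that("linear predictor reproduces the printed coefficient arithmetic", {
  pp <- polo_params()
  expect_equal(linear_predictor(0, 0, 0, pp), -26.3)
  expect_equal(linear_predictor(0, 0, 1, pp), -26.3 + 1.19)
  expect_equal(linear_predictor(100, 100 * 10, 0, pp), -26.3 + 19 + 18)
  d <- c(10, 20); dld <- c(30, 40); b <- c(0, 1)
  expect_equal(linear_predictor(d, dld, b, pp),
               -26.3 + 0.19 * d + 0.018 * dld + 1.19 * b)
  expect_true(all(linear_predictor(d, dld, b, pp) >= pp$intercept))
  expect_error(linear_predictor(-1, 0, 0, pp))
})

test_that("sigmoid probability is stable and point-symmetric", {
  expect_equal(sigmoid_probability(0), 0.5)
  # closed form at the intercept, evaluated without overflow
  expect_equal(sigmoid_probability(-26.3), 1 / (1 + exp(26.3)), tolerance = 1e-12)
  expect_lt(sigmoid_probability(-26.3), 4e-12)
  expect_true(is.finite(sigmoid_probability(-750)))
  expect_true(is.finite(sigmoid_probability(750)))
  set.seed(5)
  eta <- stats::rnorm(1000, sd = 10)
  expect_lt(max(abs(sigmoid_probability(eta) + sigmoid_probability(-eta) - 1)), 1e-15)
})

test_that("volume-corrected probability follows the counter-probability power law", {
  eta01 <- stats::qlogis(0.1)
  expect_equal(volume_corrected_probability(eta01, k = 2), 0.19, tolerance = 1e-15)
  set.seed(6)
  eta <- stats::rnorm(200, sd = 8)
  expect_lt(max(abs(volume_corrected_probability(eta, 1) - sigmoid_probability(eta))),
            1e-15)
  # composing corrections on the counter-probability scale multiplies factors
  p12 <- 1 - (1 - volume_corrected_probability(eta, 3))^4
  expect_equal(p12, volume_corrected_probability(eta, 12), tolerance = 1e-12)
  # strictly increasing in eta and in k (away from float saturation)
  eta_m <- seq(-15, 0, length.out = 100)
  expect_true(all(diff(volume_corrected_probability(eta_m, 25)) > 0))
  expect_true(all(volume_corrected_probability(eta, 2) >
                    volume_corrected_probability(eta, 1)))
})

test_that("the analytic derivative of the corrected sigmoid is exact", {
  # FD comparison where the corrected probability is numerically resolvable:
  # choose eta so p(eta, k) sweeps (0.001, 0.95) for each k
  for (k in c(1, 2, 25)) {
    p_target <- seq(0.001, 0.95, length.out = 12)
    eta <- stats::qlogis(1 - (1 - p_target)^(1 / k))
    h <- 1e-6
    fd <- (volume_corrected_probability(eta + h, k) -
             volume_corrected_probability(eta - h, k)) / (2 * h)
    an <- poloplan:::volume_corrected_dprob_deta(eta, k)
    expect_lt(max(abs(fd - an) / abs(an)), 1e-7)
  }
  # extreme predictors: finite, nonnegative, vanishing in both tails
  ext <- poloplan:::volume_corrected_dprob_deta(c(-700, -26.3, 300), 25)
  expect_true(all(is.finite(ext) & ext >= 0))
  expect_lt(ext[3], 1e-300)
  # k = 1 reduction: sigma'(eta) = sigma(1 - sigma)
  s <- sigmoid_probability(eta)
  expect_equal(poloplan:::volume_corrected_dprob_deta(eta, 1), s * (1 - s),
               tolerance = 1e-14)
})

test_that("decision values are the identity and order-preserving", {
  eta <- c(-26.3, -3, 0, 7)
  expect_identical(decision_values(eta), eta)
  set.seed(7)
  # keep the probabilities away from float saturation so ranks are tie-free
  eta <- stats::runif(500, -12, -2)
  p <- volume_corrected_probability(eta, 25)
  expect_equal(cor(rank(decision_values(eta)), rank(p)), 1)
  expect_equal(linear_predictor(0, 0, 0, polo_params()), -26.3) # domain minimum
})

test_that("dose index filter is inclusive and region-gated", {
  region <- c(TRUE, TRUE, TRUE, FALSE)
  d <- c(2.0, 1.99, 100, 100)
  expect_equal(dose_index_filter(d, region, 2.0), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("ntcp matches the direct product and its probability bounds", {
  expect_equal(ntcp(0.3), 0.3)
  expect_equal(ntcp(c(0.1, 0.2)), 0.28, tolerance = 1e-15)
  expect_equal(ntcp(numeric(0)), 0)
  expect_equal(ntcp(rep(0, 5)), 0)
  expect_error(ntcp(c(0.2, 1)), "\\[0, 1\\)")
  set.seed(8)
  for (i in 1:25) {
    p <- stats::runif(sample(100, 1), 0, 0.9)
    expect_lt(abs(ntcp(p) - (1 - prod(1 - p))), 1e-12)
    expect_gte(ntcp(p) + 1e-15, max(p))
    expect_lte(ntcp(p), min(1, sum(p)))
  }
  # strictly increasing in any single voxel probability
  p <- c(0.1, 0.05, 0.2)
  p2 <- p; p2[2] <- p[2] + 1e-6
  expect_gt(ntcp(p2), ntcp(p))
})

test_that("forward pass equals the step-by-step manual composition", {
  pr <- small_problem()
  infl <- small_influence()
  phi <- small_fluence() * 0.9
  st <- polo_forward(phi, infl, pr$region, pr$b, pr$polo)
  d <- as.vector(infl$D %*% phi)
  dld <- as.vector(infl$M %*% phi)
  act <- pr$region & d >= pr$polo$dose_filter_threshold
  expect_identical(st$active, act)
  idx <- which(act)
  eta <- pr$polo$intercept + pr$polo$beta1 * d[idx] + pr$polo$beta2 * dld[idx] +
    pr$polo$b_coeff * pr$b[idx]
  expect_equal(st$eta, eta, tolerance = 1e-14)
  expect_equal(st$p, volume_corrected_probability(eta, pr$polo$k), tolerance = 1e-14)
  expect_identical(st$p_tilde, st$eta)
  expect_equal(st$ntcp, ntcp(st$p))
  # monotone in the fluence scale: every active eta increases
  st10 <- polo_forward(phi * 1.2, infl, pr$region, pr$b, pr$polo)
  shared <- which(st$active & st10$active)
  expect_true(all(st10$eta[match(shared, which(st10$active))] >
                    st$eta[match(shared, which(st$active))]))
  # zero fluence: no voxel passes the dose filter, empty-product NTCP = 0
  st0 <- polo_forward(rep(0, infl$m), infl, pr$region, pr$b, pr$polo)
  expect_equal(sum(st0$active), 0)
  expect_equal(st0$ntcp, 0)
})
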