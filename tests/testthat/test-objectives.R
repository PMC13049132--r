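fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

expect_fd_match <- function(obj_fun, x, tol = 1e-6, h = 1e-5) {
  r <- obj_fun(x)
  fd <- fd_gradient(function(z) obj_fun(z)$value, x, h)
  # components far below the gradient scale are dominated by FD roundoff;
  # check them against the gradient magnitude instead
  scale <- pmax(abs(fd), abs(r$gradient), 1e-3 * max(abs(r$gradient)), 1e-12)
  expect_lt(max(abs(fd - r$gradient) / scale), tol)
}

test_that("NTCP objective: products, leave-one-out gradient, FD oracle", {
  r <- obj_ntcp(c(0.1, 0.2))
  expect_equal(r$value, 0.28, tolerance = 1e-15)
  expect_equal(r$gradient, c(0.8, 0.9), tolerance = 1e-15)
  r0 <- obj_ntcp(rep(0, 4))
  expect_equal(r0$value, 0)
  expect_equal(r0$gradient, rep(1, 4))
  expect_equal(obj_ntcp(numeric(0))$value, 0)
  set.seed(10)
  for (i in 1:20) {
    # keep the total complication probability away from 1 so the FD quotient
    # of the product form stays resolvable
    p <- stats::runif(sample(12, 1), 0, 0.6)
    expect_fd_match(obj_ntcp, p)
    expect_equal(obj_ntcp(p)$value, ntcp(p), tolerance = 1e-14)
    expect_true(all(obj_ntcp(p)$gradient >= 0))
  }
})

test_that("log-sum-exp objective: closed forms, softmax gradient, stability", {
  n <- 7; cval <- 2.5
  r <- obj_lse(rep(cval, n))
  expect_equal(r$value, cval + log(n), tolerance = 1e-12)
  r1 <- obj_lse(3.3)
  expect_equal(r1$value, 3.3)
  expect_equal(r1$gradient, 1)
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(sample(40, 1), sd = 5)
    r <- obj_lse(x)
    expect_lt(abs(sum(r$gradient) - 1), 1e-12)
    expect_gte(r$value, max(x))
    expect_lte(r$value, max(x) + log(length(x)) + 1e-12)
    expect_fd_match(obj_lse, x, tol = 1e-6, h = 1e-5)
  }
  # the max-shift makes huge decision values safe
  expect_equal(obj_lse(c(700, 710))$value, 710 + log1p(exp(-10)))
})

test_that("log-sum-exp is numerically convex", {
  set.seed(12)
  for (i in 1:50) {
    x <- stats::rnorm(10, sd = 4); y <- stats::rnorm(10, sd = 4)
    lam <- stats::runif(1)
    expect_lte(obj_lse(lam * x + (1 - lam) * y)$value,
               lam * obj_lse(x)$value + (1 - lam) * obj_lse(y)$value + 1e-10)
  }
})

test_that("Hellinger-type objective sums with unit gradient on both scales", {
  r <- obj_hellinger(c(0.1, 0.2, 0.3), "probability")
  expect_equal(r$value, 0.6)
  expect_equal(r$gradient, rep(1, 3))
  expect_equal(obj_hellinger(rep(0, 4), "probability")$value, 0)
  p <- stats::runif(50, 0, 0.99)
  expect_gt(obj_hellinger(p, "probability")$value, 0)
  expect_lt(obj_hellinger(p, "probability")$value, 50)
  expect_error(obj_hellinger(c(0.2, 1.2), "probability"), "\\[0, 1\\)")
  expect_equal(obj_hellinger(c(-20, -10), "decision")$value, -30)
})

test_that("dosimetric penalties reproduce their defining arithmetic", {
  r <- dose_objective("squared_deviation", rep(54, 10), list(d_ref = 54))
  expect_equal(r$value, 0)
  expect_equal(r$gradient, rep(0, 10))
  r <- dose_objective("squared_underdosing", c(50, 54), list(d_min = 52))
  expect_equal(r$value, 2)
  expect_equal(r$gradient, c(-2, 0))
  r <- dose_objective("squared_overdosing", c(50, 58), list(d_max = 54))
  expect_equal(r$value, 8)
  expect_equal(r$gradient, c(0, 4))
  r <- dose_objective("dose_uniformity", c(1, 3), list())
  expect_equal(r$value, 2 * 1 / 2) # variance around the mean 2
  expect_equal(r$gradient, c(-1, 1))
  expect_error(dose_objective("nope", 1, list()), "unknown")
  expect_error(objective_spec("PTV", "min_dvh", 1, d_ref = 50, volume = 150),
               "volume")
})

test_that("DVH penalties gate on the current volume quantile", {
  dose <- c(40, 45, 50, 55, 60)
  # min DVH: 60% of volume should reach 52; pivot = 3rd highest = 50;
  # penalized: voxels below 52 but at/above 50
  r <- dose_objective("min_dvh", dose, list(d_ref = 52, volume = 60))
  expect_equal(r$value, (52 - 50)^2 / 5)
  expect_equal(which(r$gradient != 0), 3L)
  # max DVH at 0% volume degenerates to a pure max-dose penalty
  r <- dose_objective("max_dvh", dose, list(d_ref = 52, volume = 0))
  expect_equal(r$value, ((55 - 52)^2 + (60 - 52)^2) / 5)
  expect_true(all(r$gradient[dose > 52] > 0))
  # FD agreement away from quantile ties
  set.seed(13)
  for (i in 1:10) {
    d <- stats::runif(30, 30, 70)
    for (fid in c("min_dvh", "max_dvh"))
      expect_fd_match(function(x)
        dose_objective(fid, x, list(d_ref = 52, volume = 40)), d,
        tol = 1e-5, h = 1e-7)
  }
})

test_that("constraint residuals flag exactly the violating voxels", {
  spec <- constraint_spec("PTV", lower = 10, upper = 56)
  ok <- dose_constraints(c(10, 30, 56), spec)
  expect_true(ok$feasible)
  bad <- dose_constraints(c(9, 30, 57), spec)
  expect_false(bad$feasible)
  expect_equal(sum(bad$upper < 0), 1)
  expect_equal(sum(bad$lower < 0), 1)
  expect_error(constraint_spec("PTV", 10, 5))
})

test_that("objective values are invariant under voxel permutation", {
  set.seed(14)
  d <- stats::runif(40, 30, 70)
  perm <- sample(40)
  for (fid in c("squared_deviation", "dose_uniformity", "squared_underdosing",
                "squared_overdosing", "min_dvh", "max_dvh")) {
    pars <- list(d_ref = 52, d_min = 52, d_max = 54, volume = 30)
    expect_equal(dose_objective(fid, d, pars)$value,
                 dose_objective(fid, d[perm], pars)$value, tolerance = 1e-12)
  }
  p <- stats::runif(40, 0, 0.5)
  expect_equal(obj_ntcp(p)$value, obj_ntcp(p[perm])$value, tolerance = 1e-14)
  expect_equal(obj_lse(p)$value, obj_lse(p[perm])$value, tolerance = 1e-12)
})

test_that("weighted-sum objective assembles values and chain-rule gradients", {
  pr <- small_problem()
  phi <- small_fluence()
  # all weights zero
  pr0 <- pr
  pr0$objectives <- lapply(pr$objectives, function(o) { o$weight <- 0; o })
  r0 <- total_objective(phi, pr0)
  expect_equal(r0$value, 0)
  expect_equal(r0$gradient, rep(0, length(phi)))
  # single dosimetric term: gradient = w * rbe * D_r^T grad_d
  pr1 <- pr
  pr1$objectives <- list(objective_spec("PTV", "squared_deviation", 7, d_ref = 54))
  r1 <- total_objective(phi, pr1)
  si <- pr$struct_idx$PTV
  g_d <- dose_objective("squared_deviation", 1.1 * as.vector(pr$influence$D[si, ] %*% phi),
                        list(d_ref = 54))$gradient
  ref <- 7 * 1.1 * as.vector(Matrix::crossprod(pr$influence$D[si, ], g_d))
  expect_equal(r1$gradient, ref, tolerance = 1e-12)
  expect_error(plan_problem(small_phantom(), small_influence(),
                            objectives = list(objective_spec("Nope", "max_dvh", 1,
                                                             d_ref = 5, volume = 0)),
                            constraints = list()),
               "unknown structure")
})
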