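test_that("ground-truth model construction places coefficients as specified", {
  sp0 <- coupling_spec(2, self_coef = 0.5, block_scale = 1)
  m0 <- make_var_model(sp0)
  expect_equal(m0$coeffs[1, , ], diag(0.5, 2))
  expect_equal(companion_radius(m0), 0.5)

  sp1 <- coupling_spec(2, data.frame(source = 1, target = 2, strength = 0.7),
                       self_coef = c(0.5, 0.2), block_scale = 1)
  expect_equal(make_var_model(sp1)$coeffs[1, , ],
               matrix(c(0.5, 0.7, 0, 0.2), 2))

  # block scaling lands on the (target, source) entry
  sp2 <- coupling_spec(2, data.frame(source = 1, target = 2, strength = 0.7),
                       self_coef = 0.2, block_scale = c(1, 0.5))
  expect_equal(make_var_model(sp2, block = 2)$coeffs[1, 2, 1], 0.35)
})

test_that("unstable specifications are shrunk to spectral radius <= 0.95", {
  set.seed(1)
  edges <- data.frame(source = rep(1:5, 2), target = rep(6:10, 2),
                      strength = 0.9)
  sp <- coupling_spec(10, edges, self_coef = 0.99, block_scale = 1)
  m <- make_var_model(sp)
  expect_lte(companion_radius(m), 0.95 + 1e-12)
  expect_true(is_stable(m))
  # shrinkage is uniform: topology (zero pattern) preserved
  naive <- diag(0.99, 10); naive[cbind(edges$target, edges$source)] <- 0.9
  expect_equal(m$coeffs[1, , ] != 0, naive != 0)
})

test_that("invalid coupling specifications are rejected", {
  expect_error(coupling_spec(2, data.frame(source = 1, target = 2,
                                           strength = NaN)), "non-finite")
  expect_error(coupling_spec(2, data.frame(source = 1, target = 1,
                                           strength = 0.5)), "self-loops")
  expect_error(coupling_spec(2, self_coef = 1.2), "self_coef")
  expect_error(make_var_model(coupling_spec(2, block_scale = 1), block = 3),
               "block")
})

test_that("simulated processes match closed-form stationary variances", {
  m_white <- var_model(array(0, c(1, 1, 1)), noise_cov = diag(1, 1))
  x <- simulate_var(m_white, 1e5, seed = 11)
  expect_lt(abs(var(drop(x)) - 1), 0.05)

  m_ar <- var_model(array(0.5, c(1, 1, 1)), noise_cov = diag(1, 1))
  y <- simulate_var(m_ar, 1e5, seed = 12)
  expect_lt(abs(var(drop(y)) - 1 / (1 - 0.25)), 0.05 * 4 / 3)
})

test_that("simulation is deterministic under a seed and refuses unstable models", {
  m <- rand_stable_model(3, 2)
  expect_identical(simulate_var(m, 500, seed = 5),
                   simulate_var(m, 500, seed = 5))
  bad <- structure(list(coeffs = array(1.1, c(1, 1, 1)),
                        noise_cov = diag(1, 1), order = 1L),
                   class = "var_model")
  expect_error(simulate_var(bad, 100), "unstable")
})

test_that("lag-1 cross-covariance of a long VAR(1) simulation recovers A(1)", {
  set.seed(21)
  sp <- default_coupling_spec(4, seed = 21, block_scale = 1)
  mod <- make_var_model(sp, noise_sd = 1)
  x <- simulate_var(mod, 1e5, seed = 22)
  n <- ncol(x)
  C0 <- tcrossprod(x) / n
  C1 <- x[, 2:n] %*% t(x[, 1:(n - 1)]) / (n - 1)
  expect_lt(max(abs(C1 %*% solve(C0) - mod$coeffs[1, , ])), 0.05)
})

test_that("session structure follows the block design", {
  sp <- coupling_spec(1, self_coef = 0.3)
  s <- simulate_session("vigilance", sp, fs = 500, seed = 3)
  expect_equal(unname(s$block_bounds[1, 2] - s$block_bounds[1, 1] + 1L),
               600000L)  # 20 min at 500 Hz
  expect_equal(nrow(s$block_bounds), 3L)
  per_block <- vapply(1:3, function(b)
    sum(s$events >= s$block_bounds[b, 1] & s$events <= s$block_bounds[b, 2]),
    integer(1))
  expect_true(all(per_block >= 400))
  expect_true(all(diff(s$events) > 0))
  L <- round(1.2 * 500)
  expect_true(all(s$events + L - 1 <= ncol(s$signal)))
})

test_that("block scales encode the vigilance decrement and enhancement maintenance", {
  sp <- default_coupling_spec(3, seed = 1)
  sv <- simulate_session("vigilance", sp, fs = 100, seed = 2,
                         block_minutes = 0.1, epochs_per_block = 1)
  expect_equal(sv$truth$block_scale, c(1.0, 0.7, 0.4))
  expect_equal(sv$truth$models[[3]]$coeffs[1, 2, 1],
               0.4 * sv$truth$models[[1]]$coeffs[1, 2, 1])
  se <- simulate_session("enhancement", sp, fs = 100, seed = 2,
                         block_minutes = 0.1, epochs_per_block = 1)
  expect_equal(se$truth$block_scale, c(1.0, 1.0, 0.95))
  expect_true(all(diff(se$truth$block_scale) >= -0.05 - 1e-12))
  expect_error(simulate_session("vigilance", sp, fs = -1), "fs")
})

test_that("behavioural series have the designed time-on-task trends", {
  bv <- simulate_behavior("vigilance", n_bins = 20, seed = 1, rt_noise = 0,
                          acc_noise = 0)
  expect_true(all(diff(bv$reaction_time) > 0))
  expect_true(all(diff(bv$accuracy) < 0))
  expect_equal(diff(bv$bin_time)[1], 3)   # twenty 3-min bins over 60 min
  expect_equal(nrow(bv), 20L)
  be <- simulate_behavior("enhancement", n_bins = 20, seed = 1, rt_noise = 0)
  expect_true(all(diff(be$reaction_time) < 0))
  expect_true(all(bv$accuracy >= 0 & bv$accuracy <= 1))
  expect_true(all(bv$reaction_time > 0))
  expect_error(simulate_behavior("vigilance", n_bins = 1), "n_bins")
})

test_that("every generated model is stationary and jitter only rescales strengths", {
  set.seed(31)
  for (k in 1:20) {
    sp <- default_coupling_spec(sample(2:10, 1), seed = k)
    for (b in 1:3) {
      sp$block_scale <- if (k %% 2) c(1.0, 0.7, 0.4) else c(1.0, 1.0, 0.95)
      expect_lt(companion_radius(make_var_model(sp, b)), 1)
    }
  }
  sp <- default_coupling_spec(5, seed = 1)
  spj <- jitter_spec(sp, 0.1, seed = 2)
  expect_equal(spj$edges[, c("source", "target")],
               sp$edges[, c("source", "target")])
  expect_true(all(abs(spj$edges$strength / sp$edges$strength - 1) <= 0.1))
})
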