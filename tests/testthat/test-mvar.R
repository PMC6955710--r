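true_2ch_model <- function() {
  var_model(array(c(0.5, 0.7, 0, 0.2), c(1, 2, 2)), noise_cov = diag(2))
}

test_that("least squares recovers known VAR coefficients", {
  mod <- true_2ch_model()
  x <- simulate_var(mod, 1e4, seed = 1)
  fit <- fit_mvar(x, p = 1)
  expect_lt(max(abs(fit$coeffs[1, , ] - mod$coeffs[1, , ])), 0.05)

  # white noise: all coefficients near zero at any order
  set.seed(2)
  w <- matrix(rnorm(3 * 1e4), 3)
  fitw <- fit_mvar(w, p = 3)
  expect_lt(max(abs(fitw$coeffs)), 0.05)
  expect_equal(fitw$order, 3L)
  expect_equal(dim(fitw$coeffs), c(3L, 3L, 3L))
})

test_that("rank-deficient regressors produce an error advising ridge", {
  set.seed(3)
  x <- matrix(rnorm(2 * 500), 2)
  dup <- rbind(x, colSums(x) * -1)   # third channel = -(ch1 + ch2)
  dup <- sweep(dup, 2, colMeans(dup))  # CAR-like exact dependence
  expect_error(fit_mvar(dup, p = 2), "ridge")
  expect_silent(fit_mvar(dup, p = 2, ridge = 1e-6))
  expect_error(fit_mvar(x[, 1:10], p = 7), "too few samples")
})

test_that("AIC order selection returns an audit curve and penalises overfit", {
  set.seed(4)
  hits <- replicate(30, {
    w <- matrix(rnorm(2 * 500), 2)
    sel <- select_order_aic(w, p_max = 5)
    expect_length(sel$aic, 5)
    sel$order
  })
  expect_gte(mean(hits == 1), 0.6)   # white noise: smallest order wins
  expect_error(select_order_aic(matrix(rnorm(40), 4), p_max = 10), "p_max")
})

test_that("AIC finds the neighbourhood of a true order-3 model", {
  set.seed(5)
  A <- array(0, c(3, 4, 4))
  A[1, , ] <- diag(0.25, 4)
  A[3, , ] <- diag(0.25, 4); A[3, 2, 1] <- 0.3; A[3, 4, 3] <- 0.3
  mod <- var_model(A, diag(4))
  hits <- replicate(20, {
    x <- simulate_var(mod, 5000)
    select_order_aic(x, p_max = 6)$order
  })
  expect_gte(mean(hits %in% 2:4), 0.9)
})

test_that("PDC has the closed-form value and column normalisation", {
  mod <- true_2ch_model()
  sp <- pdc_spectrum(mod, freqs = 1e-4, fs = 500)  # effectively f = 0
  expect_equal(sp$values[1, 2, 1], 0.7 / sqrt(0.5^2 + 0.7^2),
               tolerance = 1e-6)
  expect_equal(sp$values[1, 1, 2], 0)  # no 2 -> 1 flow in the model

  # diagonal (uncoupled) model: identity PDC at every frequency
  dm <- var_model(array(diag(c(0.3, 0.6)), c(1, 2, 2)), diag(2))
  spd <- pdc_spectrum(dm)
  expect_true(all(abs(spd$values[, 1, 2]) == 0))
  expect_true(all(abs(spd$values[, 2, 1]) == 0))
  expect_true(all(abs(spd$values[, 1, 1] - 1) < 1e-12))

  expect_error(pdc_spectrum(mod, freqs = c(10, 400), fs = 500), "fs/2")
})

test_that("column normalisation holds for random stable models", {
  set.seed(6)
  for (k in 1:50) {
    mod <- rand_stable_model(sample(2:8, 1), sample(1:5, 1))
    sp <- pdc_spectrum(mod, freqs = seq(0.5, 30, by = 2.5), fs = 500)
    norms <- apply(sp$values^2, c(1, 3), sum)
    expect_lt(max(abs(norms - 1)), 1e-8)
    expect_true(all(sp$values >= 0 & sp$values <= 1))
  }
})

test_that("band averaging uses the inclusive bin grid", {
  mod <- true_2ch_model()
  sp <- pdc_spectrum(mod, freqs = seq(0.5, 30, by = 0.5), fs = 500)
  expect_equal(sum(sp$freqs >= 0.5 & sp$freqs <= 30), 60L)
  cm <- band_average(sp, 0.5, 30)
  expect_equal(cm$W[2, 1], mean(sp$values[, 2, 1]))
  # constant-in-f spectrum: band average equals the constant
  dm <- var_model(array(0, c(1, 2, 2)), diag(2))  # white noise: PDC = I
  cmd <- band_average(pdc_spectrum(dm), 0.5, 30)
  expect_equal(cmd$W, diag(2), ignore_attr = TRUE)
  expect_error(band_average(sp, 40, 50), "empty band")
})

test_that("block connectivity averages epochs and zeroes the diagonal", {
  set.seed(7)
  sp <- default_coupling_spec(4, seed = 7)
  s <- simulate_session("vigilance", sp, fs = 250, seed = 8,
                        block_minutes = 0.5, epochs_per_block = 6)
  ep <- epoch_and_baseline(s)
  cm <- block_connectivity(ep, 1, p = 2)
  expect_equal(dim(cm$W), c(4L, 4L))
  expect_equal(unname(diag(cm$W)), rep(0, 4))
  expect_equal(cm$n_epochs_averaged, 6L)
  expect_true(all(cm$W >= 0 & cm$W <= 1))

  # a single-epoch block equals that epoch's matrix
  one <- ep; keep <- which(ep$block_labels == 2)[1]
  one$kept_mask <- seq_along(ep$kept_mask) == keep
  cm1 <- block_connectivity(one, 2, p = 2)
  fit <- fit_mvar(ep$data[keep, , ], p = 2)
  direct <- band_average(pdc_spectrum(fit, fs = ep$fs))$W
  diag(direct) <- 0
  expect_equal(cm1$W, direct, ignore_attr = TRUE)
  expect_error(block_connectivity(one, 3, p = 2), "no kept epochs")
})

test_that("PDC is invariant to a uniform gain change up to estimation noise", {
  # units cancel exactly only for a gain common to all channels (classical
  # PDC is not invariant to per-channel rescaling)
  mod <- true_2ch_model()
  x <- simulate_var(mod, 1e4, seed = 9)
  base <- band_average(pdc_spectrum(fit_mvar(x, 1), fs = 500))$W
  resc <- band_average(pdc_spectrum(fit_mvar(x * 1e3, 1), fs = 500))$W
  expect_lt(max(abs(base - resc)), 1e-10)
})

test_that("directed flow is specific: 1 -> 2 coupling dominates the reverse", {
  mod <- true_2ch_model()
  set.seed(10)
  wins <- replicate(100, {
    x <- simulate_var(mod, 600)
    W <- band_average(pdc_spectrum(fit_mvar(x, 1), fs = 500))$W
    W[2, 1] > W[1, 2]
  })
  expect_gte(mean(wins), 0.95)
})
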