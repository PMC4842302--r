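test_that("the reference size grid yields 4950 unordered distinct-size pairs", {
  cfg <- background_config()
  expect_equal(nrow(background_size_pairs(cfg)), 4950)
  tiny <- background_config(size_min = 10, size_max = 20, size_step = 10,
                            repetitions = 1)
  expect_equal(nrow(background_size_pairs(tiny)), 1)
})

test_that("background sampling is deterministic and needs a big enough universe", {
  cfg <- synthetic_config(n_bits = 256, n_background = 80,
                          bit_density = 0.06, seed = 5)
  uni <- generate_null_universe(cfg)
  bc <- background_config(size_min = 10, size_max = 30, size_step = 10,
                          repetitions = 3, seed = 11)
  s1 <- generate_background_pairs(uni, bc)
  s2 <- generate_background_pairs(uni, bc)
  expect_identical(s1$rs, s2$rs)
  expect_identical(s1$sizes, s2$sizes)
  expect_equal(nrow(s1$rs), 3 * 3)      # C(3,2)=3 pairs x 3 reps
  expect_equal(s1$sizes$s, s1$sizes$n_A * s1$sizes$n_B)
  big <- background_config(size_min = 100, size_max = 200, size_step = 100,
                           repetitions = 1)
  expect_error(generate_background_pairs(uni, big), "universe")
})

test_that("raw scores are non-increasing in the TS threshold", {
  cfg <- synthetic_config(n_bits = 256, n_background = 100,
                          bit_density = 0.08, seed = 2)
  uni <- generate_null_universe(cfg)
  bc <- background_config(size_min = 10, size_max = 40, size_step = 10,
                          repetitions = 2, seed = 4)
  samp <- generate_background_pairs(uni, bc)
  diffs <- t(apply(samp$rs, 1, diff))
  expect_true(all(diffs <= 1e-12))
  # and the TS=0 column equals the full Tanimoto sum (nothing excluded)
  expect_true(all(samp$rs[, 1] >= samp$rs[, ncol(samp$rs)]))
})

test_that("mean/sd law fitting recovers known parameters", {
  set.seed(17)
  mu <- 0.002; phi <- 0.5; eta <- 0.7
  # size products of the reference grid, one draw per pair and repetition
  sprod <- background_size_pairs(background_config())
  s <- rep(sprod[, 1] * sprod[, 2], 100)
  rs <- mu * s + rnorm(length(s), 0, phi * s^eta)
  samp <- fake_samples(s, matrix(rs, ncol = 1), ts_grid = 0.3)
  fit <- fit_mean_sd(samp, 0.3)
  expect_true(fit$usable)
  expect_lt(abs(fit$mu - mu) / mu, 0.05)
  expect_lt(abs(fit$eta - eta) / eta, 0.10)
  expect_lt(abs(fit$phi - phi) / phi, 0.15)
})

test_that("a two-group sd law is interpolated exactly", {
  s <- rep(c(100, 400), each = 3)
  # group sds 2 and 8: eta = log(4)/log(4) = 1, phi = 2/100^1
  rs <- c(0, 2, 4, 0, 8, 16) + 5 * s
  samp <- fake_samples(s, matrix(rs, ncol = 1), ts_grid = 0.1)
  fit <- fit_mean_sd(samp, 0.1)
  sd1 <- sd(c(0, 2, 4)); sd2 <- sd(c(0, 8, 16))
  eta_exp <- log(sd2 / sd1) / log(4)
  expect_equal(fit$eta, eta_exp, tolerance = 1e-10)
  expect_equal(fit$phi, sd1 / 100^eta_exp, tolerance = 1e-10)
})

test_that("degenerate raw scores flag the TS as unusable", {
  s <- rep(c(100, 200, 400), each = 4)
  rs <- 0.01 * s                      # exactly mu*s, zero spread
  samp <- fake_samples(s, matrix(rs, ncol = 1), ts_grid = 0.5)
  fit <- fit_mean_sd(samp, 0.5)
  expect_false(fit$usable)
  expect_equal(fit$mu, 0.01, tolerance = 1e-12)
  expect_error(select_ts(samp), "no usable TS")
})

test_that("TS selection finds the threshold whose Z-scores are Gumbel", {
  set.seed(23)
  s <- rep(round(seq(500, 20000, length.out = 40)), each = 25)
  n <- length(s)
  mu <- 0.001; phi <- 0.3; eta <- 0.75
  sdv <- phi * s^eta
  rs_gumbel <- mu * s + sdv * rgumbel_std(n)
  rs_normal <- mu * s + sdv * rnorm(n)
  rs_skewed <- mu * s + sdv * (rexp(n) - 1) * 2
  samp <- fake_samples(s, cbind(rs_skewed, rs_gumbel, rs_normal),
                       ts_grid = c(0.10, 0.20, 0.30))
  fit <- select_ts(samp)
  expect_equal(fit$ts, 0.20)
  expect_equal(nrow(fit$diagnostics), 3)
  expect_true(all(fit$diagnostics$usable))
})

test_that("chi-square ties break toward the lowest TS", {
  set.seed(31)
  s <- rep(c(1000, 4000, 9000, 16000), each = 30)
  rs <- 0.002 * s + 0.4 * s^0.7 * rgumbel_std(length(s))
  samp <- fake_samples(s, cbind(rs, rs), ts_grid = c(0.15, 0.25))
  fit <- select_ts(samp)
  expect_equal(fit$ts, 0.15)
})

test_that("fitted models round-trip through JSON", {
  cfg <- synthetic_config(n_bits = 256, n_background = 150,
                          bit_density = 0.08, seed = 9)
  uni <- generate_null_universe(cfg)
  bc <- background_config(size_min = 10, size_max = 50, size_step = 10,
                          repetitions = 5, seed = 6,
                          ts_grid = seq(0, 0.5, by = 0.05))
  model <- fit_background(uni, bc)
  expect_s3_class(model, "sea_model")
  expect_gt(model$fit$phi, 0)
  expect_gte(model$fit$mu, 0)
  path <- tempfile(fileext = ".json")
  write_sea_model(model, path)
  back <- read_sea_model(path)
  expect_equal(back$fit$ts, model$fit$ts)
  expect_equal(back$fit$mu, model$fit$mu)
  expect_equal(back$fit$phi, model$fit$phi)
  expect_equal(back$fit$eta, model$fit$eta)
  expect_equal(back$provider_id, model$provider_id)
})
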