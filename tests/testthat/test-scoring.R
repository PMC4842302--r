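test_that("raw score sums exactly the qualifying cross-pair similarities", {
  # one qualifying pair with TC 0.8 above ts 0.57, everything else below
  A <- list(sea_fp(1:4, "x"), sea_fp(100:105, "x"))
  B <- list(sea_fp(1:5, "x"), sea_fp(200:205, "x"))
  expect_equal(tanimoto(A[[1]], B[[1]]), 0.8)
  expect_equal(raw_score(A, B, 0.57), 0.8)
  # all pairs below ts contribute nothing
  expect_equal(raw_score(A, B, 0.81), 0)
})

test_that("raw score equals the brute-force double-loop oracle", {
  set.seed(101)
  for (i in 1:10) {
    A <- random_fp_list(20, n_bits = 128, density = 0.08)
    B <- random_fp_list(30, n_bits = 128, density = 0.08)
    ts <- runif(1, 0, 0.5)
    rs <- raw_score(A, B, ts)
    expect_equal(rs, oracle_raw_score(A, B, ts), tolerance = 1e-9)
  }
})

test_that("z-score standardizes with the fitted background laws", {
  fit <- structure(list(ts = 0.3, mu = 0.001, phi = 0.2, eta = 0.8,
                        s_range = c(100, 1e6)), class = "background_fit")
  s <- 100 * 100
  expect_equal(z_score(fit$mu * s, 100, 100, fit), 0)
  expect_equal(z_score(fit$mu * s + fit$phi * s^fit$eta, 100, 100, fit), 1)
  expect_equal(z_score(40, 100, 100, fit), (40 - 10) / (0.2 * 10000^0.8))
  expect_equal(z_score(40, 100, 100, fit), 0.0946, tolerance = 1e-3)
  bad <- fit; bad$phi <- 0
  expect_error(z_score(1, 10, 10, bad), "phi")
})

test_that("the EVD tail gives the closed-form P at z = 0 and 1 in the limit", {
  expect_equal(p_value(0), 1 - exp(-exp(-0.577215665)))
  expect_equal(p_value(0), 0.4296, tolerance = 1e-4)
  expect_equal(p_value(-50), 1)
  expect_true(all(p_value(c(-3, 0, 5, 30, 200)) >= 0))
  expect_true(all(p_value(c(-3, 0, 5, 30, 200)) <= 1))
})

test_that("the Taylor branch is continuous at z = 28", {
  below <- p_value(28)
  x <- -exp(-(28 * pi / sqrt(6) + 0.577215665))
  above <- -x - x^2 / 2 - x^3 / 6
  expect_lt(abs(below - above) / above, 1e-6)
  # and immediately across the switch
  expect_lt(abs(p_value(28 - 1e-9) - p_value(28 + 1e-9)) / p_value(28), 1e-6)
})

test_that("P-values decrease strictly in z and log10 P tracks the tail", {
  # below z ~ -2.5 the P-value saturates to 1 in double precision, so
  # strictness is asserted where the tail is representable
  z <- seq(-2, 100, by = 0.5)
  p <- p_value(z)
  expect_true(all(diff(p) < 0))
  lp <- p_value_log10(z)
  expect_true(all(diff(lp) < 0))
  mid <- z > -2 & z < 20
  expect_equal(lp[mid], log10(p[mid]), tolerance = 1e-9)
  # far tail stays finite and meaningful where p underflows
  expect_lt(p_value_log10(200), -100)
  expect_true(is.finite(p_value_log10(2000)))
})

make_null_model <- function() {
  cfg <- synthetic_config(n_bits = 256, n_background = 200,
                          bit_density = 0.06, seed = 19)
  uni <- generate_null_universe(cfg)
  bc <- background_config(size_min = 10, size_max = 60, size_step = 10,
                          repetitions = 5, seed = 21,
                          ts_grid = seq(0, 0.6, by = 0.02))
  list(model = fit_background(uni, bc), uni = uni)
}

test_that("set comparison is symmetric and self-comparison is significant", {
  mm <- make_null_model()
  uni <- mm$uni
  A <- uni[1:20]; B <- uni[30:49]
  ab <- compare_sets(A, B, mm$model)
  ba <- compare_sets(B, A, mm$model)
  expect_equal(ab$raw_score, ba$raw_score)
  expect_equal(ab$z_score, ba$z_score)
  expect_equal(ab$p_value, ba$p_value)
  # a homogeneous set against itself scores far off the null
  self <- compare_sets(A, A, mm$model)
  expect_lt(self$p_value, 1e-6)
  expect_gt(self$z_score, ab$z_score)
})

test_that("target prediction ranks the true set first and nests in alpha", {
  mm <- make_null_model()
  uni <- mm$uni
  targets <- list(T1 = uni[1:15], T2 = uni[16:30], T3 = uni[31:45])
  # query identical to every member of a planted degenerate target
  clone <- sea_fp(uni[[1]]$bits, "synthetic")
  targets$Tclone <- rep(list(clone), 10)
  hits <- predict_targets(clone, mm$model, targets, alpha = 1)
  expect_equal(nrow(hits), 4)           # alpha = 1 keeps everything
  expect_equal(hits$target_id[1], "Tclone")
  h05 <- predict_targets(clone, mm$model, targets, alpha = 0.05)
  h01 <- predict_targets(clone, mm$model, targets, alpha = 0.01)
  expect_true(all(h01$target_id %in% h05$target_id))
  expect_warning(predict_targets(clone, mm$model, list()), "empty")
})

test_that("the target network keeps only significant edges, monotonically", {
  mm <- make_null_model()
  uni <- mm$uni
  dup <- uni[1:12]
  targets <- list(A = dup, B = dup, C = uni[100:111], D = uni[120:131])
  expect_equal(nrow(target_network(targets, mm$model, 0)), 0)
  tiny <- target_network(targets, mm$model, 1e-12)
  expect_true(any(tiny$target_a == "A" & tiny$target_b == "B"))
  counts <- vapply(c(1e-12, 1e-4, 0.05, 1),
                   function(p) nrow(target_network(targets, mm$model, p)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})
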