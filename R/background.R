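## Random background statistical model.
##
## Pairs of random ligand sets spanning a size grid are compared at every
## candidate Tanimoto threshold (TS); the raw-score mean and standard
## deviation are fitted as functions of the set-size product s = nA * nB
## (mean linear through the origin, sd a power law), and the working TS is
## the one whose standardized raw scores best fit an extreme value
## (Gumbel) distribution by a chi-square statistic.

.euler_gamma <- 0.577215665

## Standard Gumbel scaled to zero mean and unit variance: location
## -gamma*sqrt(6)/pi, scale sqrt(6)/pi. Quantiles feed the equal-probability
## chi-square binning.
.gumbel_scale <- sqrt(6) / pi
.gumbel_loc <- -.euler_gamma * sqrt(6) / pi

qgumbel_std <- function(p) .gumbel_loc - .gumbel_scale * log(-log(p))

#' Background model configuration
#'
#' Defaults follow the reference protocol: ligand-set sizes 10 to 1000 in
#' steps of 10 (4950 unordered distinct-size pairs), 100 repetitions, and
#' a TS grid from 0.00 to 0.99 in steps of 0.01.
#'
#' @param size_min,size_max,size_step integer set-size grid.
#' @param repetitions how many times the whole pair grid is redrawn.
#' @param ts_grid increasing vector of candidate Tanimoto thresholds in
#'   \[0, 1).
#' @param seed integer seed for the random subset draws.
#' @return a `background_config` object.
#' @export
background_config <- function(size_min = 10L, size_max = 1000L,
                              size_step = 10L, repetitions = 100L,
                              ts_grid = seq(0, 0.99, by = 0.01),
                              seed = 1L) {
  sizes <- seq(size_min, size_max, by = size_step)
  assert_that(length(sizes) >= 2, "the size grid needs at least two sizes")
  assert_that(!is.unsorted(ts_grid, strictly = TRUE) &&
                all(ts_grid >= 0) && all(ts_grid < 1),
              "ts_grid must be strictly increasing within [0, 1)")
  structure(list(size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 size_step = as.integer(size_step),
                 sizes = as.integer(sizes),
                 repetitions = as.integer(repetitions),
                 ts_grid = as.numeric(ts_grid),
                 seed = as.integer(seed)),
            class = "background_config")
}

#' Unordered distinct-size pairs of the background grid
#'
#' @param config a [background_config()].
#' @return two-column matrix of (n_A, n_B) with n_A < n_B; for the default
#'   grid this has 4950 rows.
#' @export
background_size_pairs <- function(config) {
  t(utils::combn(config$sizes, 2))
}

#' Draw background set pairs and score them across the TS grid
#'
#' For every repetition and every unordered pair of distinct grid sizes,
#' two disjoint random subsets of the fingerprint universe are drawn and
#' their raw score is recorded at every TS of the grid in a single pass
#' over the pairwise Tanimoto values.
#'
#' @param universe named list of `sea_fp` (the background molecule pool).
#' @param config a [background_config()].
#' @return a `background_samples` object: `sizes` data.frame
#'   (`rep`, `n_A`, `n_B`, `s`) and matrix `rs` (samples x TS grid).
#' @export
generate_background_pairs <- function(universe, config) {
  pairs <- background_size_pairs(config)
  need <- max(pairs[, 1] + pairs[, 2])
  if (length(universe) < config$size_max)
    stop(sprintf("universe has %d molecules but the size grid needs %d",
                 length(universe), config$size_max))
  if (length(universe) < need)
    stop(sprintf(
      "universe has %d molecules; disjoint pair draws need at least %d",
      length(universe), need))
  bits_universe <- sort(unique(unlist(lapply(universe, `[[`, "bits"))))
  M <- fp_bit_matrix(universe, bits_universe)
  sizes <- Matrix::colSums(M)
  nts <- length(config$ts_grid)
  nsamp <- nrow(pairs) * config$repetitions
  rs <- matrix(0, nrow = nsamp, ncol = nts)
  tab <- data.frame(rep = integer(nsamp), n_A = integer(nsamp),
                    n_B = integer(nsamp), s = numeric(nsamp))
  row <- 0L
  with_seed(config$seed, {
    for (r in seq_len(config$repetitions)) {
      for (p in seq_len(nrow(pairs))) {
        na <- pairs[p, 1]; nb <- pairs[p, 2]
        idx <- sample.int(length(universe), na + nb)
        ia <- idx[seq_len(na)]
        ib <- idx[(na + 1):(na + nb)]
        common <- Matrix::crossprod(M[, ia, drop = FALSE],
                                    M[, ib, drop = FALSE])
        v <- rs_curve(common, sizes[ia], sizes[ib], config$ts_grid)
        row <- row + 1L
        rs[row, ] <- v
        tab$rep[row] <- r; tab$n_A[row] <- na; tab$n_B[row] <- nb
        tab$s[row] <- as.numeric(na) * nb
      }
    }
  })
  structure(list(sizes = tab, rs = rs, ts_grid = config$ts_grid,
                 config = config),
            class = "background_samples")
}

## Raw score at every TS from the sparse common-bit count matrix of one set
## pair: only nonzero Tanimoto values can contribute to any sum.
rs_curve <- function(common, sizes_a, sizes_b, ts_grid) {
  cm <- as(common, "TsparseMatrix")
  if (!length(cm@x)) return(numeric(length(ts_grid)))
  denom <- sizes_a[cm@i + 1L] + sizes_b[cm@j + 1L] - cm@x
  tc <- cm@x / denom
  o <- order(tc)
  tc <- tc[o]
  csum <- cumsum(tc[length(tc):1])[length(tc):1]  # suffix sums, ascending tc
  ## raw score at ts = sum of tc values >= ts
  pos <- findInterval(ts_grid, tc, left.open = TRUE) + 1L
  ifelse(pos > length(tc), 0, csum[pmax(pos, 1L)])
}

#' Fit the raw-score mean and sd laws at one TS
#'
#' Groups background raw scores by the set-size product `s`; the mean law
#' `mu * s` is fitted by least squares through the origin on group means,
#' and the sd law `phi * s^eta` by ordinary least squares of log group sd
#' on log s (zero-sd groups excluded). A TS where fewer than two groups
#' have positive spread is flagged unusable.
#'
#' @param samples a `background_samples` object.
#' @param ts one TS value present in the sampled grid.
#' @return list with `mu`, `phi`, `eta`, `usable`, `n_groups`.
#' @export
fit_mean_sd <- function(samples, ts) {
  col <- match(TRUE, abs(samples$ts_grid - ts) < 1e-9)
  assert_that(!is.na(col), sprintf("TS %.3f not in the sampled grid", ts))
  rs <- samples$rs[, col]
  s <- samples$sizes$s
  gm <- tapply(rs, s, mean)
  gsd <- tapply(rs, s, stats::sd)
  gn <- tapply(rs, s, length)
  sv <- as.numeric(names(gm))
  assert_that(length(sv) >= 2, "need at least two distinct size products")
  mu <- sum(sv * gm) / sum(sv^2)
  ok <- is.finite(gsd) & gsd > 0 & gn >= 2
  if (sum(ok) < 2)
    return(list(mu = mu, phi = NA_real_, eta = NA_real_, usable = FALSE,
                n_groups = length(sv)))
  fit <- stats::lm.fit(cbind(1, log(sv[ok])), log(gsd[ok]))
  phi <- exp(fit$coefficients[[1]])
  eta <- fit$coefficients[[2]]
  list(mu = mu, phi = phi, eta = eta, usable = TRUE, n_groups = length(sv))
}

#' Select the working TS by extreme-value goodness of fit
#'
#' For every usable TS the background raw scores are standardized with the
#' fitted mean/sd laws and binned into equal-probability bins of the
#' zero-mean unit-variance Gumbel distribution; the TS minimizing the
#' chi-square statistic wins (ties: the lowest TS). Diagnostics for all TS
#' are retained.
#'
#' @param samples a `background_samples` object.
#' @param n_bins number of equal-probability bins before enforcing an
#'   expected count of at least 5 per bin (default 20).
#' @return a `background_fit`: `ts`, `mu`, `phi`, `eta`, `chisq`, the
#'   per-TS `diagnostics` data.frame, and the fitted size-product range.
#' @export
select_ts <- function(samples, n_bins = 20L) {
  ts_grid <- samples$ts_grid
  n <- nrow(samples$rs)
  k <- max(3L, min(as.integer(n_bins), floor(n / 5)))
  edges <- qgumbel_std(seq(0, 1, length.out = k + 1))
  edges[1] <- -Inf; edges[k + 1] <- Inf
  diag_tab <- data.frame(ts = ts_grid, mu = NA_real_, phi = NA_real_,
                         eta = NA_real_, chisq = NA_real_, usable = FALSE)
  for (i in seq_along(ts_grid)) {
    f <- fit_mean_sd(samples, ts_grid[i])
    diag_tab$mu[i] <- f$mu
    if (!f$usable) next
    diag_tab$phi[i] <- f$phi; diag_tab$eta[i] <- f$eta
    z <- (samples$rs[, i] - f$mu * samples$sizes$s) /
      (f$phi * samples$sizes$s^f$eta)
    obs <- tabulate(findInterval(z, edges, left.open = TRUE), nbins = k)
    expd <- n / k
    diag_tab$chisq[i] <- sum((obs - expd)^2 / expd)
    diag_tab$usable[i] <- TRUE
  }
  if (!any(diag_tab$usable))
    stop("no usable TS: background raw scores are degenerate at every threshold")
  best <- which.min(ifelse(diag_tab$usable, diag_tab$chisq, Inf))
  structure(list(ts = ts_grid[best], mu = diag_tab$mu[best],
                 phi = diag_tab$phi[best], eta = diag_tab$eta[best],
                 chisq = diag_tab$chisq[best], diagnostics = diag_tab,
                 s_range = range(samples$sizes$s)),
            class = "background_fit")
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf(
    "<background_fit ts=%.2f mu=%.4g phi=%.4g eta=%.4g chisq=%.3g>\n",
    x$ts, x$mu, x$phi, x$eta, x$chisq))
  invisible(x)
}

#' Fit a complete SEA model on a fingerprint universe
#'
#' Convenience wrapper: draws the background pairs, fits the mean/sd laws
#' and selects TS, returning a model ready for [compare_sets()].
#'
#' @param universe named list of `sea_fp`.
#' @param config a [background_config()].
#' @param provider_id provider tag recorded in the model (defaults to the
#'   universe's provider).
#' @return a `sea_model`: `provider_id`, `fit`, `config`.
#' @export
fit_background <- function(universe, config = background_config(),
                           provider_id = NULL) {
  provider_id <- provider_id %||% fp_provider(universe)
  samples <- generate_background_pairs(universe, config)
  fit <- select_ts(samples)
  structure(list(provider_id = provider_id, fit = fit, config = config),
            class = "sea_model")
}

#' @export
print.sea_model <- function(x, ...) {
  cat(sprintf("<sea_model provider=%s ts=%.2f mu=%.4g phi=%.4g eta=%.4g>\n",
              x$provider_id, x$fit$ts, x$fit$mu, x$fit$phi, x$fit$eta))
  invisible(x)
}

#' Write / read a fitted SEA model as JSON
#'
#' The file stores the provider, the selected TS with its fitted
#' parameters, the grid definition and seed, and the per-TS chi-square
#' diagnostics table.
#'
#' @param model a `sea_model`.
#' @param path JSON file path.
#' @return `write_sea_model` returns `path` invisibly; `read_sea_model`
#'   returns the `sea_model`.
#' @export
write_sea_model <- function(model, path) {
  obj <- list(provider_id = model$provider_id,
              fit = list(ts = model$fit$ts, mu = model$fit$mu,
                         phi = model$fit$phi, eta = model$fit$eta,
                         chisq = model$fit$chisq,
                         s_range = model$fit$s_range),
              diagnostics = model$fit$diagnostics,
              config = model$config[c("size_min", "size_max", "size_step",
                                      "repetitions", "ts_grid", "seed")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_sea_model
#' @export
read_sea_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- background_config(size_min = obj$config$size_min,
                           size_max = obj$config$size_max,
                           size_step = obj$config$size_step,
                           repetitions = obj$config$repetitions,
                           ts_grid = obj$config$ts_grid,
                           seed = obj$config$seed)
  fit <- structure(list(ts = obj$fit$ts, mu = obj$fit$mu, phi = obj$fit$phi,
                        eta = obj$fit$eta, chisq = obj$fit$chisq,
                        diagnostics = as.data.frame(obj$diagnostics),
                        s_range = obj$fit$s_range),
                   class = "background_fit")
  structure(list(provider_id = obj$provider_id, fit = fit, config = cfg),
            class = "sea_model")
}
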