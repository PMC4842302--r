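## Core SEA comparison.
##
## The raw score of two ligand sets is the sum of all cross-pair Tanimoto
## coefficients at or above the model's TS; it is standardized with the
## background mean/sd laws into a Z-score, whose extreme-value tail gives
## the P-value. For z above 28 the closed form 1 - exp(x) underflows, so a
## three-term Taylor expansion of the tail is used instead; the tail is
## additionally evaluated in log space so that extremely significant
## comparisons (P ~ 1e-80 and below) keep a meaningful log10 P.

#' Raw score of two fingerprinted ligand sets
#'
#' Sum over all cross pairs of the Tanimoto coefficients that reach the
#' threshold `ts`; pairs below `ts` contribute zero. Semantics are those of
#' the quadratic reference double loop regardless of the sparse kernel
#' used internally.
#'
#' @param A,B lists of `sea_fp` under one provider.
#' @param ts Tanimoto threshold in \[0, 1\).
#' @return non-negative raw score.
#' @export
raw_score <- function(A, B, ts) {
  assert_that(length(A) >= 1 && length(B) >= 1,
              "raw_score needs non-empty sets")
  tc <- tanimoto_matrix(A, B)
  sum(tc[tc >= ts])
}

#' Z-score of a raw score
#'
#' Standardizes a raw score with the fitted background laws evaluated at
#' the size product `s = n_A * n_B`: `(rs - mu*s) / (phi * s^eta)`.
#'
#' @param rs raw score.
#' @param n_A,n_B ligand-set sizes.
#' @param fit a `background_fit` (or `sea_model`).
#' @return the Z-score.
#' @export
z_score <- function(rs, n_A, n_B, fit) {
  if (inherits(fit, "sea_model")) fit <- fit$fit
  assert_that(is.finite(fit$phi) && fit$phi > 0,
              "invalid background model: phi must be positive")
  s <- as.numeric(n_A) * as.numeric(n_B)
  assert_that(s > 0, "set sizes must be positive")
  (rs - fit$mu * s) / (fit$phi * s^fit$eta)
}

## Gumbel tail exponent: x(z) = -exp(-(z*pi/sqrt(6) + gamma)). Always in
## (-exp(-gamma), 0) for z >= 0; its log is computed directly to survive
## very large z.
.tail_log_negx <- function(z) -(z * pi / sqrt(6) + .euler_gamma)

#' Extreme-value P-value of a Z-score
#'
#' With `x(z) = -exp(-(z*pi/sqrt(6) + 0.577215665))`, returns
#' `1 - exp(x)` for `z <= 28` and the Taylor expansion
#' `-x - x^2/2 - x^3/6` beyond, where the closed form would be swamped by
#' floating-point cancellation. Vectorized; results are clamped to \[0, 1\].
#'
#' @param z finite Z-score(s).
#' @return P-value(s) in \[0, 1\].
#' @export
p_value <- function(z) {
  assert_that(all(is.finite(z)), "z must be finite")
  x <- -exp(.tail_log_negx(z))
  small <- z <= 28
  p <- numeric(length(z))
  p[small] <- -expm1(x[small])
  xb <- x[!small]
  p[!small] <- -xb - xb^2 / 2 - xb^3 / 6
  pmin(pmax(p, 0), 1)
}

#' Log10 P-value computed in log space
#'
#' For very significant comparisons `p_value()` underflows to 0; this
#' companion evaluates the tail's logarithm directly, so P-values around
#' 1e-80 and far beyond remain comparable.
#'
#' @param z finite Z-score(s).
#' @return log10 of the P-value.
#' @export
p_value_log10 <- function(z) {
  assert_that(all(is.finite(z)), "z must be finite")
  lx <- .tail_log_negx(z)          # log(-x)
  out <- numeric(length(z))
  small <- z <= 28
  if (any(small)) out[small] <- log10(p_value(z[small]))
  if (any(!small)) {
    x <- -exp(lx[!small])
    ## p = (-x) * (1 + x/2 + x^2/6)
    out[!small] <- (lx[!small] + log1p(x / 2 + x^2 / 6)) / log(10)
  }
  out
}

#' Compare two ligand sets under a fitted model
#'
#' Composes raw score, Z-score and P-value; symmetric in its arguments.
#' When the size product falls below the background grid actually fitted,
#' the extrapolation is flagged via a message-level log (not an error).
#'
#' @param A,B lists of `sea_fp` under the model's provider.
#' @param model a `sea_model`.
#' @param quiet suppress the extrapolation message.
#' @return a `sea_score`: `raw_score`, `z_score`, `p_value`, `log10_p`,
#'   `n_A`, `n_B`, `ts_used`.
#' @export
compare_sets <- function(A, B, model, quiet = TRUE) {
  fit <- model$fit
  rs <- raw_score(A, B, fit$ts)
  nA <- length(A); nB <- length(B)
  s <- as.numeric(nA) * nB
  if (!quiet && !is.null(fit$s_range) && s < fit$s_range[1])
    message(sprintf(
      "size product %g below fitted background range [%g, %g]: extrapolating",
      s, fit$s_range[1], fit$s_range[2]))
  z <- z_score(rs, nA, nB, fit)
  structure(list(raw_score = rs, z_score = z, p_value = p_value(z),
                 log10_p = p_value_log10(z), n_A = nA, n_B = nB,
                 ts_used = fit$ts),
            class = "sea_score")
}

#' @export
print.sea_score <- function(x, ...) {
  cat(sprintf("<sea_score rs=%.4g z=%.4g p=%.4g (log10p=%.4g) %dx%d>\n",
              x$raw_score, x$z_score, x$p_value, x$log10_p, x$n_A, x$n_B))
  invisible(x)
}

#' Predict targets for one query molecule
#'
#' The query is treated as a singleton ligand set and compared against
#' every target set; targets meeting the significance cutoff are returned
#' sorted by ascending P-value (ties by log10 P, then target id).
#'
#' @param query a single `sea_fp`.
#' @param model a `sea_model`.
#' @param targets named list of fingerprint lists (one per target).
#' @param alpha per-comparison significance cutoff in (0, 1\].
#' @return data.frame with `target_id`, `raw_score`, `z_score`, `p_value`,
#'   `log10_p`.
#' @export
predict_targets <- function(query, model, targets, alpha = 0.05) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  if (!length(targets)) {
    warning("empty target list: no predictions")
    return(data.frame(target_id = character(0), raw_score = numeric(0),
                      z_score = numeric(0), p_value = numeric(0),
                      log10_p = numeric(0)))
  }
  rows <- lapply(names(targets), function(t) {
    sc <- compare_sets(list(query), targets[[t]], model)
    data.frame(target_id = t, raw_score = sc$raw_score,
               z_score = sc$z_score, p_value = sc$p_value,
               log10_p = sc$log10_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$log10_p, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance-thresholded target-target network
#'
#' Compares every unordered pair of target ligand sets and keeps the edges
#' at or below the P-value cutoff; the edge list can be consumed by
#' standard graph tools.
#'
#' @param targets named list (length >= 2) of fingerprint lists.
#' @param model a `sea_model`.
#' @param p_cutoff edge significance cutoff.
#' @return data.frame with `target_a`, `target_b`, `raw_score`, `z_score`,
#'   `p_value`, `log10_p`.
#' @export
target_network <- function(targets, model, p_cutoff) {
  assert_that(length(targets) >= 2, "a network needs at least two targets")
  ids <- names(targets)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq(i + 1, length(ids))) {
      sc <- compare_sets(targets[[i]], targets[[j]], model)
      if (sc$p_value <= p_cutoff)
        rows[[length(rows) + 1]] <- data.frame(
          target_a = ids[i], target_b = ids[j], raw_score = sc$raw_score,
          z_score = sc$z_score, p_value = sc$p_value, log10_p = sc$log10_p,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(target_a = character(0), target_b = character(0),
                      raw_score = numeric(0), z_score = numeric(0),
                      p_value = numeric(0), log10_p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
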