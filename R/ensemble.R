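## Multi-voting ensemble over per-fingerprint SEA models.
##
## Each single-fingerprint model contributes one vote per ligand-target
## pair: its P-value at or below the cutoff. A k-vote scheme declares a
## pair significant when at least k models vote for it, so prediction sets
## are nested in k (k = 1 is the union of single-model positives, k equal
## to the number of models their intersection).

#' Define a k-vote election scheme
#'
#' @param k votes required for significance (1 to the number of models).
#' @param alpha per-model P-value cutoff in (0, 1\].
#' @param models character vector of model identifiers taking part.
#' @return a `vote_scheme` object.
#' @export
vote_scheme <- function(k, alpha = 0.05, models) {
  models <- as.character(models)
  assert_that(length(models) >= 1, "a vote scheme needs at least one model")
  assert_that(k >= 1 && k <= length(models),
              "k must lie between 1 and the number of models")
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  structure(list(k = as.integer(k), alpha = alpha, models = models),
            class = "vote_scheme")
}

#' Cast the votes of the single models for one pair
#'
#' A model votes when its P-value is at or below the scheme's alpha
#' (ties at alpha count, matching the P <= cutoff convention); a missing
#' P-value is a non-vote. Invariant to model ordering.
#'
#' @param p_values named numeric vector of per-model P-values.
#' @param scheme a [vote_scheme()].
#' @return list with `significant` (flag) and `votes` (integer count).
#' @export
vote <- function(p_values, scheme) {
  assert_that(inherits(scheme, "vote_scheme"), "scheme must be a vote_scheme")
  p <- p_values[scheme$models]
  votes <- sum(!is.na(p) & p <= scheme$alpha)
  list(significant = votes >= scheme$k, votes = as.integer(votes))
}

#' Per-scheme ensemble predictions over a pair table
#'
#' Takes a merged table of per-model P-values keyed by
#' (`molecule_id`, `target_id`) and returns, for every requested k, the
#' set of pairs voted significant. Missing P-values count as non-votes.
#'
#' @param pairs data.frame with columns `molecule_id`, `target_id` and one
#'   numeric P-value column per model.
#' @param models character vector naming the model columns (defaults to
#'   every column beyond the two keys).
#' @param k integer vector of vote quorums (default `1:length(models)`).
#' @param alpha per-model P-value cutoff.
#' @return list with `votes` (the pair table plus a `votes` column) and
#'   `predictions`, a named list (`k1`, `k2`, ...) of pair data.frames.
#' @export
ensemble_predict <- function(pairs, models = NULL, k = NULL, alpha = 0.05) {
  keys <- c("molecule_id", "target_id")
  assert_that(all(keys %in% names(pairs)),
              "pair table needs molecule_id and target_id columns")
  models <- models %||% setdiff(names(pairs), keys)
  assert_that(length(models) >= 1, "no model columns found")
  k <- k %||% seq_along(models)
  pm <- as.matrix(pairs[models])
  votes <- rowSums(!is.na(pm) & pm <= alpha)
  out <- pairs[keys]
  out$votes <- as.integer(votes)
  preds <- lapply(k, function(kk) {
    sel <- out[out$votes >= kk, keys, drop = FALSE]
    rownames(sel) <- NULL
    sel
  })
  names(preds) <- paste0("k", k)
  list(votes = out, predictions = preds)
}
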