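## Synthetic fingerprint universes with planted target families.
##
## Background molecules get independent Bernoulli bits; each planted
## family shares a fixed random core bit pattern plus per-molecule noise
## bits, so the expected within-family Tanimoto is roughly
## core / (core + 2 * noise). The generator emits the same containers the
## real pipeline consumes (fingerprints, an activity table, a labeled test
## pair list), so every statistical module is testable without chemical
## structures or downloads.

#' Synthetic universe configuration
#'
#' @param n_bits size of the bit space (default 2048).
#' @param n_background number of pure-background molecules.
#' @param families data.frame with `target_id`, `n_members`, `core_bits`,
#'   `noise_bits` (one planted family per row); may be empty.
#' @param bit_density background probability that any bit is on, in (0, 1).
#' @param seed integer seed; generation is fully deterministic under it.
#' @param pchembl_range range the members' activities are drawn from
#'   (uniform), on the pChEMBL scale.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_bits = 2048L, n_background = 1000L,
                             families = data.frame(), bit_density = 0.02,
                             seed = 1L, pchembl_range = c(6, 9)) {
  assert_that(bit_density > 0 && bit_density < 1,
              "bit_density must be in (0, 1)")
  if (nrow(families)) {
    need <- c("target_id", "n_members", "core_bits", "noise_bits")
    assert_that(all(need %in% names(families)),
                "families needs target_id, n_members, core_bits, noise_bits")
    assert_that(all(families$core_bits + families$noise_bits <= n_bits),
                "core_bits + noise_bits cannot exceed n_bits")
    assert_that(all(families$n_members >= 1),
                "every family needs at least one member")
  }
  structure(list(n_bits = as.integer(n_bits),
                 n_background = as.integer(n_background),
                 families = families, bit_density = bit_density,
                 seed = as.integer(seed),
                 pchembl_range = as.numeric(pchembl_range)),
            class = "synthetic_config")
}

random_fp <- function(n_bits, density) {
  k <- stats::rbinom(1, n_bits, density)
  sea_fp(sample.int(n_bits, k), "synthetic")
}

#' Generate a synthetic universe with planted families
#'
#' @param config a [synthetic_config()].
#' @return list with `fingerprints` (named `sea_fp` list: background plus
#'   family members), `activity` (data.frame `molecule_id`, `target_id`,
#'   `pchembl` for the members), `truth` (labeled test pairs: each member
#'   against its own target as `"active"` and against one other family's
#'   target as `"inactive"`), and `cores` (the family core bit sets).
#' @export
generate_universe <- function(config) {
  with_seed(config$seed, {
    fps <- list()
    for (i in seq_len(config$n_background)) {
      fps[[paste0("bg", i)]] <- random_fp(config$n_bits, config$bit_density)
    }
    activity <- data.frame(molecule_id = character(0),
                           target_id = character(0), pchembl = numeric(0),
                           stringsAsFactors = FALSE)
    truth <- activity[c("molecule_id", "target_id")]
    truth$label <- character(0)
    cores <- list()
    fam <- config$families
    for (f in seq_len(nrow(fam))) {
      tid <- fam$target_id[f]
      core <- sample.int(config$n_bits, fam$core_bits[f])
      cores[[tid]] <- core
      rest <- setdiff(seq_len(config$n_bits), core)
      for (m in seq_len(fam$n_members[f])) {
        mid <- sprintf("%s_m%d", tid, m)
        noise <- if (fam$noise_bits[f] > 0)
          sample(rest, fam$noise_bits[f]) else integer(0)
        fps[[mid]] <- sea_fp(c(core, noise), "synthetic")
        activity <- rbind(activity, data.frame(
          molecule_id = mid, target_id = tid,
          pchembl = stats::runif(1, config$pchembl_range[1],
                                 config$pchembl_range[2]),
          stringsAsFactors = FALSE))
        other <- setdiff(fam$target_id, tid)
        decoy <- if (length(other)) sample(other, 1) else NA_character_
        truth <- rbind(truth,
                       data.frame(molecule_id = mid, target_id = tid,
                                  label = "active", stringsAsFactors = FALSE))
        if (!is.na(decoy))
          truth <- rbind(truth,
                         data.frame(molecule_id = mid, target_id = decoy,
                                    label = "inactive",
                                    stringsAsFactors = FALSE))
      }
    }
    attr(fps, "provider_id") <- "synthetic"
    list(fingerprints = fps, activity = activity, truth = truth,
         cores = cores)
  })
}

#' Generate a pure-background (null) universe
#'
#' Background molecules only, for background fitting and P-value
#' calibration studies. For independent Bernoulli bit vectors the expected
#' pairwise Tanimoto is about `d / (2 - d)` at bit density `d`.
#'
#' @param config a [synthetic_config()] (families are ignored).
#' @return named list of `sea_fp`.
#' @export
generate_null_universe <- function(config) {
  with_seed(config$seed, {
    fps <- list()
    for (i in seq_len(config$n_background)) {
      fps[[paste0("bg", i)]] <- random_fp(config$n_bits, config$bit_density)
    }
    attr(fps, "provider_id") <- "synthetic"
    fps
  })
}
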