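## Fingerprint containers and pairwise similarity.
##
## A binary fingerprint is stored as its set of on-bit indices (sparse,
## unfolded), so Tanimoto counts are exact. SHED descriptors are dense
## 10-vectors compared by normalised Euclidean distance.

#' Construct a binary fingerprint
#'
#' A fingerprint is the set of on-bit indices of a binary feature vector,
#' tagged with the provider that produced it. Bits are stored sparse and
#' unfolded: two fingerprints are comparable only under the same provider.
#'
#' @param bits numeric vector of non-negative on-bit indices (duplicates
#'   are collapsed).
#' @param provider_id character scalar naming the representation.
#' @return an object of class `sea_fp`.
#' @examples
#' tanimoto(sea_fp(c(1, 2, 3), "demo"), sea_fp(c(2, 3, 4), "demo"))
#' @export
sea_fp <- function(bits, provider_id) {
  bits <- sort(unique(as.numeric(bits)))
  if (length(bits) && any(bits < 0)) stop("on-bit indices must be non-negative")
  structure(list(bits = bits, provider_id = as.character(provider_id)),
            class = "sea_fp")
}

#' @export
print.sea_fp <- function(x, ...) {
  cat(sprintf("<sea_fp %s: %d on bits>\n", x$provider_id, length(x$bits)))
  invisible(x)
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' Computes `c / (a + b + c)` where `c` is the number of on bits shared by
#' both fingerprints and `a`, `b` count bits unique to each. Two empty
#' fingerprints have similarity 0 (featureless molecules are not treated
#' as maximally similar).
#'
#' @param A,B `sea_fp` objects from the same provider.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(A, B) {
  assert_that(inherits(A, "sea_fp") && inherits(B, "sea_fp"),
              "tanimoto() expects sea_fp objects")
  assert_that(identical(A$provider_id, B$provider_id),
              sprintf("incomparable representations: '%s' vs '%s'",
                      A$provider_id, B$provider_id))
  n_common <- length(intersect(A$bits, B$bits))
  denom <- length(A$bits) + length(B$bits) - n_common
  if (denom == 0) return(0)
  n_common / denom
}

#' Construct a SHED descriptor
#'
#' A SHED descriptor is a 10-dimensional vector of entropy-derived
#' pharmacophore feature-pair values, each in \[0, 20\].
#'
#' @param values numeric vector of length 10 with components in \[0, 20\].
#' @return an object of class `shed_descriptor`.
#' @export
shed_descriptor <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 10) stop("a SHED descriptor has exactly 10 components")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 20))
    stop("SHED components must be finite and within [0, 20]")
  structure(list(values = values, provider_id = "shed"),
            class = "shed_descriptor")
}

#' Similarity of two SHED descriptors
#'
#' One minus the Euclidean distance between the descriptors divided by its
#' maximum attainable value `20 * sqrt(10)`.
#'
#' @param A,B `shed_descriptor` objects.
#' @return similarity in \[0, 1\].
#' @export
shed_similarity <- function(A, B) {
  if (!inherits(A, "shed_descriptor")) A <- shed_descriptor(A)
  if (!inherits(B, "shed_descriptor")) B <- shed_descriptor(B)
  d <- sqrt(sum((A$values - B$values)^2))
  1 - d / (20 * sqrt(10))
}

## ---- collections ----------------------------------------------------------

#' Provider of a fingerprint collection
#' @param fps list of `sea_fp` objects.
#' @return provider_id shared by the collection.
#' @keywords internal
fp_provider <- function(fps) {
  ids <- unique(vapply(fps, function(f) f$provider_id, character(1)))
  assert_that(length(ids) == 1, "mixed providers in one fingerprint collection")
  ids
}

## Sparse pattern matrix (bits x molecules) over the union bit space of one
## or two collections; used by the fast cross-similarity kernel.
fp_bit_matrix <- function(fps, universe_bits) {
  j <- rep.int(seq_along(fps), vapply(fps, function(f) length(f$bits), integer(1)))
  i <- match(unlist(lapply(fps, function(f) f$bits)), universe_bits)
  Matrix::sparseMatrix(i = i, j = j,
                       dims = c(length(universe_bits), length(fps)),
                       x = 1)
}

#' Pairwise Tanimoto matrix between two fingerprint collections
#'
#' Computes all cross-pair Tanimoto coefficients with one sparse
#' cross-product; semantics identical to calling [tanimoto()] on every
#' pair.
#'
#' @param A,B lists of `sea_fp` objects from a common provider.
#' @return a `length(A)` by `length(B)` numeric matrix.
#' @export
tanimoto_matrix <- function(A, B) {
  pa <- fp_provider(A)
  pb <- fp_provider(B)
  assert_that(identical(pa, pb),
              sprintf("incomparable representations: '%s' vs '%s'", pa, pb))
  universe <- sort(unique(c(unlist(lapply(A, `[[`, "bits")),
                            unlist(lapply(B, `[[`, "bits")))))
  if (!length(universe))
    return(matrix(0, nrow = length(A), ncol = length(B)))
  Ma <- fp_bit_matrix(A, universe)
  Mb <- fp_bit_matrix(B, universe)
  common <- as.matrix(Matrix::crossprod(Ma, Mb))
  na <- Matrix::colSums(Ma)
  nb <- Matrix::colSums(Mb)
  denom <- outer(na, nb, `+`) - common
  tc <- common / denom
  tc[denom == 0] <- 0
  tc
}
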