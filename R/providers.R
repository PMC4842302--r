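## Fingerprint providers.
##
## Six 2D molecular representations share one interface: a provider turns
## standardized SMILES into sparse on-bit sets (or SHED 10-vectors). The
## Morgan-style circular, atom-pair, topological-torsion, pharmacophore and
## SHED providers are computed on the internal molecular graph; MACCS keys
## come from OpenBabel.

.providers <- c("morgan", "atom_pair", "topological_torsion", "maccs",
                "pharmacophore_2d", "shed")

#' Configure a fingerprint provider
#'
#' @param provider_id one of `"morgan"`, `"atom_pair"`,
#'   `"topological_torsion"`, `"maccs"`, `"pharmacophore_2d"`, `"shed"`.
#' @param radius circular-fingerprint radius (morgan only; default 2, the
#'   ECFP4-like convention).
#' @param points pharmacophore point counts, either `2` or `c(2, 3)`.
#' @param bins list of `c(lo, hi)` topological-distance bins for the
#'   pharmacophore provider; half-open `[lo, hi)`, ordered, non-overlapping.
#' @return a `provider_config` object.
#' @examples
#' provider_config("morgan", radius = 2)
#' provider_config("pharmacophore_2d", points = c(2, 3),
#'                 bins = list(c(0, 2), c(2, 5), c(5, 8)))
#' @export
provider_config <- function(provider_id,
                            radius = 2L,
                            points = c(2L, 3L),
                            bins = list(c(2, 3), c(3, 4), c(4, 5),
                                        c(5, 6), c(6, 7), c(7, 20))) {
  if (!provider_id %in% .providers)
    stop(sprintf("unknown provider '%s' (available: %s)", provider_id,
                 paste(.providers, collapse = ", ")))
  points <- sort(unique(as.integer(points)))
  if (provider_id == "pharmacophore_2d") {
    if (!identical(points, 2L) && !identical(points, c(2L, 3L)))
      stop("pharmacophore point counts must be {2} or {2,3}")
    lo <- vapply(bins, `[`, numeric(1), 1)
    hi <- vapply(bins, `[`, numeric(1), 2)
    if (any(hi <= lo) || is.unsorted(lo, strictly = TRUE) ||
        any(lo[-1] < hi[-length(hi)]))
      stop("pharmacophore bins must be an ordered, non-overlapping edge list")
  }
  structure(list(provider_id = provider_id, radius = as.integer(radius),
                 points = points, bins = bins),
            class = "provider_config")
}

#' Compute fingerprints for a set of molecules
#'
#' Applies one provider to a named vector of SMILES, returning one
#' representation per molecule. Results are deterministic: identical
#' structures under one provider give identical fingerprints.
#'
#' @param smiles named character vector of (preferably standardized) SMILES.
#' @param config a [provider_config()].
#' @return named list of `sea_fp` (binary providers) or `shed_descriptor`
#'   objects, with attribute `provider_id`. Molecules that fail to parse are
#'   dropped with a warning.
#' @export
compute_fingerprints <- function(smiles, config) {
  if (is.character(config)) config <- provider_config(config)
  assert_that(inherits(config, "provider_config"),
              "config must be a provider_config")
  ids <- names(smiles) %||% paste0("mol", seq_along(smiles))
  if (config$provider_id == "maccs") {
    fps <- maccs_fingerprints(smiles, ids)
  } else {
    graphs <- parse_molgraphs(stats::setNames(smiles, ids))
    ok <- !vapply(graphs, is.null, logical(1))
    if (any(!ok))
      warning(sprintf("%d structure(s) failed to parse and were dropped",
                      sum(!ok)))
    graphs <- graphs[ok]
    fn <- switch(config$provider_id,
                 morgan = function(g) fp_morgan(g, config$radius),
                 atom_pair = fp_atom_pair,
                 topological_torsion = fp_torsion,
                 pharmacophore_2d = function(g)
                   fp_pharmacophore(g, config$points, config$bins),
                 shed = fp_shed)
    fps <- lapply(graphs, fn)
  }
  attr(fps, "provider_id") <- config$provider_id
  fps
}

## ---- morgan ---------------------------------------------------------------

## Circular fingerprint in the ECFP spirit: iteratively hashed atom
## neighbourhoods up to `radius` bonds, seeded from an invariant of
## (element, degree, H count, ring flag, aromatic flag).
fp_morgan <- function(g, radius = 2L) {
  z <- .atomic_number[g$elem]
  z[is.na(z)] <- 0
  h <- mapply(function(a, d, hc, r, ar) hash_tuple(1, a, d, hc, r, ar),
              z, g$deg, g$hcount, as.numeric(g$ring), as.numeric(g$aromatic))
  bits <- h
  if (radius > 0 && g$n > 0) {
    for (r in seq_len(radius)) {
      hnew <- numeric(g$n)
      for (i in seq_len(g$n)) {
        nb <- g$adj[[i]]
        acc <- hash_tuple(2, r, h[i])
        if (!is.null(nb)) {
          key <- nb[, 2] * .hash_mod + h[nb[, 1]]
          ord <- order(key)
          for (k in ord) acc <- hash_mix(hash_mix(acc, nb[k, 2]), h[nb[k, 1]])
        }
        hnew[i] <- acc
      }
      h <- hnew
      bits <- c(bits, h)
    }
  }
  sea_fp(bits, "morgan")
}

## ---- atom pair ------------------------------------------------------------

## Carhart-style atom pairs: (atom type, atom type, topological distance),
## atom type = (element, heavy degree, pi-bond count).
fp_atom_pair <- function(g) {
  z <- .atomic_number[g$elem]
  z[is.na(z)] <- 0
  typ <- mapply(function(a, d, p) hash_tuple(3, a, d, p), z, g$deg, g$pisum)
  bits <- numeric(0)
  if (g$n >= 2) {
    idx <- which(upper.tri(g$dist) & is.finite(g$dist) & g$dist >= 1,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      t1 <- pmin(typ[idx[, 1]], typ[idx[, 2]])
      t2 <- pmax(typ[idx[, 1]], typ[idx[, 2]])
      d <- g$dist[idx]
      bits <- hash_mix(hash_mix(hash_mix(hash_mix(17, 4), t1), t2), d)
    }
  }
  sea_fp(bits, "atom_pair")
}

## ---- topological torsion --------------------------------------------------

## Linear paths of four bonded atoms; atom type = (element, pi count,
## heavy degree); a path and its reverse hash identically.
fp_torsion <- function(g) {
  z <- .atomic_number[g$elem]
  z[is.na(z)] <- 0
  typ <- mapply(function(a, p, d) hash_tuple(5, a, p, d), z, g$pisum, g$deg)
  bits <- numeric(0)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      j <- g$bonds[k, 1]; l <- g$bonds[k, 2]
      nj <- g$adj[[j]][, 1]; nl <- g$adj[[l]][, 1]
      for (i in setdiff(nj, l)) {
        for (m in setdiff(nl, c(j, i))) {
          fwd <- c(typ[i], typ[j], typ[l], typ[m])
          rev <- base::rev(fwd)
          key <- if (paste(fwd, collapse = ",") <= paste(rev, collapse = ","))
            fwd else rev
          bits <- c(bits, hash_tuple(6, key[1], key[2], key[3], key[4]))
        }
      }
    }
  }
  sea_fp(bits, "topological_torsion")
}

## ---- MACCS ----------------------------------------------------------------

maccs_fingerprints <- function(smiles, ids) {
  block <- paste(paste(smiles, ids), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", block, identity)
  bits <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  out <- lapply(seq_len(nrow(bits)), function(i)
    sea_fp(which(bits[i, ] != 0), "maccs"))
  names(out) <- ids[seq_len(nrow(bits))]
  if (nrow(bits) < length(ids))
    warning(sprintf("%d structure(s) failed to parse and were dropped",
                    length(ids) - nrow(bits)))
  out
}

## ---- 2D pharmacophore -----------------------------------------------------

## Feature pairs (and optionally triplets) with binned topological
## distances; bins are half-open [lo, hi).
.bin_index <- function(d, bins) {
  for (b in seq_along(bins)) {
    if (d >= bins[[b]][1] && d < bins[[b]][2]) return(b)
  }
  NA_integer_
}

fp_pharmacophore <- function(g, points = c(2L, 3L), bins) {
  feats <- molgraph_features(g)
  cls <- rep(seq_along(feats), lengths(feats))
  atom <- unlist(feats, use.names = FALSE)
  bits <- numeric(0)
  nf <- length(atom)
  if (nf >= 2 && 2L %in% points) {
    for (i in seq_len(nf - 1)) {
      for (j in seq((i + 1), nf)) {
        if (atom[i] == atom[j]) next
        d <- g$dist[atom[i], atom[j]]
        if (!is.finite(d)) next
        b <- .bin_index(d, bins)
        if (is.na(b)) next
        c1 <- min(cls[i], cls[j]); c2 <- max(cls[i], cls[j])
        bits <- c(bits, hash_tuple(8, c1, c2, b))
      }
    }
  }
  if (nf >= 3 && 3L %in% points) {
    trip <- utils::combn(nf, 3)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (t in seq_len(ncol(trip))) {
      v <- trip[, t]
      a <- atom[v]
      if (anyDuplicated(a)) next
      d12 <- g$dist[a[1], a[2]]; d23 <- g$dist[a[2], a[3]]
      d13 <- g$dist[a[1], a[3]]
      if (!all(is.finite(c(d12, d23, d13)))) next
      b12 <- .bin_index(d12, bins); b23 <- .bin_index(d23, bins)
      b13 <- .bin_index(d13, bins)
      if (anyNA(c(b12, b23, b13))) next
      cc <- cls[v]
      bmat <- matrix(c(0, b12, b13, b12, 0, b23, b13, b23, 0), 3, 3)
      best <- NULL
      for (p in perms) {
        tup <- c(cc[p[1]], cc[p[2]], cc[p[3]],
                 bmat[p[1], p[2]], bmat[p[2], p[3]], bmat[p[1], p[3]])
        if (is.null(best) ||
            paste(tup, collapse = ",") < paste(best, collapse = ","))
          best <- tup
      }
      bits <- c(bits, hash_tuple(9, best[1], best[2], best[3],
                                 best[4], best[5], best[6]))
    }
  }
  sea_fp(bits, "pharmacophore_2d")
}

## ---- SHED -----------------------------------------------------------------

## Shannon-entropy descriptors over the 10 unordered pairs of the four
## pharmacophore families (acceptor, donor, hydrophobe, aromatic): the
## topological distances of each feature pair are histogrammed into 20 bins
## and the descriptor component is 2^H (H in bits), giving values in
## [0, 20]; 0 when the molecule has no such feature pair.
fp_shed <- function(g) {
  feats <- molgraph_features(g)[c("HA", "HD", "HY", "AR")]
  fam <- names(feats)
  vals <- numeric(10)
  k <- 0
  for (i in seq_along(fam)) {
    for (j in seq(i, length(fam))) {
      k <- k + 1
      ai <- feats[[i]]; aj <- feats[[j]]
      dists <- numeric(0)
      if (length(ai) && length(aj)) {
        dd <- g$dist[ai, aj, drop = FALSE]
        if (i == j) {
          dd <- dd[upper.tri(dd)]
        } else {
          dd <- as.vector(dd)
          same <- outer(ai, aj, `==`)
          dd <- dd[!as.vector(same)]
        }
        dists <- dd[is.finite(dd) & dd >= 1]
      }
      if (length(dists)) {
        bin <- pmin(ceiling(dists), 20)
        p <- tabulate(bin, nbins = 20)
        p <- p / sum(p)
        p <- p[p > 0]
        H <- -sum(p * log2(p))
        vals[k] <- 2^H
      }
    }
  }
  shed_descriptor(pmin(vals, 20))
}
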