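## Internal molecular graph model.
##
## Structures are parsed with ChemmineR/OpenBabel into a light graph
## (elements, bonds with orders, topological distances) from which the
## graph-based fingerprints and pharmacophore features are derived.
## Hydrogens are implicit and counted from a standard valence model;
## formal charges are not modelled (see the methods vignette).

.valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
              I = 1, B = 3, Si = 4)

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

## Average atomic masses for the molecular-weight fallback used when a
## structure has no OpenBabel-computed properties attached.
.atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                  Cl = 35.45, Br = 79.904, I = 126.904)

#' Parse SMILES into internal molecular graphs
#'
#' @param smiles character vector of SMILES (names become molecule ids).
#' @return named list of molgraph objects; unparseable entries are `NULL`.
#' @keywords internal
parse_molgraphs <- function(smiles) {
  out <- vector("list", length(smiles))
  names(out) <- names(smiles) %||% paste0("mol", seq_along(smiles))
  for (i in seq_along(smiles)) {
    out[[i]] <- tryCatch(molgraph_from_smiles(smiles[[i]]),
                         error = function(e) NULL)
  }
  out
}

molgraph_from_smiles <- function(smi) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  molgraph_from_sdf(sdf[[1]])
}

molgraph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(numeric(0), ncol = 3)
  } else {
    bonds <- cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]),
                   pmin(as.numeric(bb[, 3]), 3))
  }
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  ordsum <- numeric(n)
  pisum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      ordsum[a] <- ordsum[a] + o
      ordsum[b] <- ordsum[b] + o
      pisum[a] <- pisum[a] + (o - 1)
      pisum[b] <- pisum[b] + (o - 1)
    }
  }
  val <- .valence[elem]
  val[is.na(val)] <- 0
  hcount <- pmax(0, val - ordsum)

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, t(bonds[, 1:2]))
  dist <- igraph::distances(g)

  ## Ring membership: atoms inside a biconnected component of >= 3 vertices.
  ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      v <- as.integer(comp)
      if (length(v) >= 3) ring[v] <- TRUE
    }
    ## Aromatic-like flag: every atom of the ring system is sp2-capable
    ## (carries a double bond or is a ring heteroatom). This recovers the
    ## common aromatics from kekulised structures without full Hueckel
    ## perception.
    aromatic <- rep(FALSE, n)
    for (comp in bc$components) {
      v <- as.integer(comp)
      if (length(v) < 5) next
      sp2 <- pisum[v] > 0 | elem[v] %in% c("N", "O", "S")
      if (all(sp2)) aromatic[v] <- TRUE
    }
  } else {
    aromatic <- rep(FALSE, n)
  }

  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }

  structure(list(elem = elem, n = n, bonds = bonds, adj = adj, deg = deg,
                 pisum = pisum, hcount = hcount, dist = dist, ring = ring,
                 aromatic = aromatic),
            class = "molgraph")
}

molgraph_mw <- function(g) {
  m <- .atomic_mass[g$elem]
  m[is.na(m)] <- 0
  sum(m) + sum(g$hcount) * .atomic_mass[["H"]]
}

## Pharmacophore feature typing (Gobbi-style family definitions applied to
## the neutral graph model): returns atom index vectors per family.
##   HD donor      N/O carrying at least one hydrogen
##   HA acceptor   O, or N that is not a pyrrole-like NH inside an aromatic ring
##   AR aromatic   member of an aromatic-like ring system
##   HY hydrophobe carbon with only carbon neighbours, or heavy halogen
molgraph_features <- function(g) {
  is_N <- g$elem == "N"
  is_O <- g$elem == "O"
  donor <- which((is_N | is_O) & g$hcount >= 1)
  acceptor <- which(is_O | (is_N & !(g$aromatic & g$hcount >= 1)))
  aromatic <- which(g$aromatic)
  only_c_nbrs <- vapply(seq_len(g$n), function(i) {
    nb <- g$adj[[i]]
    is.null(nb) || all(g$elem[nb[, 1]] == "C")
  }, logical(1))
  hydrophobic <- which((g$elem == "C" & only_c_nbrs) |
                         g$elem %in% c("Cl", "Br", "I"))
  list(HD = donor, HA = acceptor, AR = aromatic, HY = hydrophobic)
}
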