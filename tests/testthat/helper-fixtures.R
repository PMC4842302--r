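# Shared fixtures and independent oracles for the suite.

# Small drug-like SMILES set used by curation/provider tests.
fixture_smiles <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  benzylamine = "NCc1ccccc1",
  toluene = "Cc1ccccc1",
  ethanol = "CCO",
  salicylic = "OC(=O)c1ccccc1O",
  phenol = "Oc1ccccc1",
  aniline = "Nc1ccccc1"
)

# Random sparse fingerprints under a fixed provider tag.
random_fp_list <- function(n, n_bits = 256, density = 0.05,
                           provider = "synthetic") {
  fps <- lapply(seq_len(n), function(i) {
    k <- stats::rbinom(1, n_bits, density)
    sea_fp(sample.int(n_bits, k), provider)
  })
  names(fps) <- paste0("m", seq_len(n))
  fps
}

# Independent brute-force raw-score oracle: nested loops over explicit
# bit-set intersections, no shared code with the sparse kernel.
oracle_raw_score <- function(A, B, ts) {
  total <- 0
  for (a in A) {
    for (b in B) {
      common <- length(intersect(a$bits, b$bits))
      denom <- length(a$bits) + length(b$bits) - common
      tc <- if (denom == 0) 0 else common / denom
      if (tc >= ts) total <- total + tc
    }
  }
  total
}

# Zero-mean unit-variance Gumbel deviates (inverse CDF).
rgumbel_std <- function(n) {
  -0.577215665 * sqrt(6) / pi - sqrt(6) / pi * log(-log(stats::runif(n)))
}

# Assemble a background_samples object directly from simulated raw scores
# (used to test the fitting layer in isolation).
fake_samples <- function(s, rs_matrix, ts_grid) {
  structure(list(sizes = data.frame(s = s), rs = rs_matrix,
                 ts_grid = ts_grid, config = NULL),
            class = "background_samples")
}
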