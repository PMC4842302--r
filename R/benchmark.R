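## Access to the bundled published-benchmark reference figures.

#' Published ChEMBL benchmark reference figures
#'
#' Returns the bundled reference figures for five fingerprint SEA models
#' and their multi-voting ensemble on a ChEMBL-derived ligand-target test
#' set (37,138 active and 42,928 inactive pairs): printed classification
#' rates per model, true-positive counts, and the voting-scheme positive
#' counts. These are inputs for metric-arithmetic cross-checks, not
#' quantities the package recomputes from structures.
#'
#' @return nested list mirroring `inst/extdata/chembl_benchmark.json`.
#' @export
chembl_benchmark <- function() {
  path <- system.file("extdata", "chembl_benchmark.json",
                      package = "multisea", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
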