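test_that("standardization keeps the largest organic fragment under the MW cap", {
  std <- standardize_molecule("CCO.Cl")
  expect_equal(std$smiles, "CCO")
  # canonical: identical inputs give identical outputs
  expect_identical(standardize_molecule("OCC")$smiles,
                   standardize_molecule("CCO")$smiles)
  # a 72-carbon alkane exceeds 1000 Da, a 71-carbon one does not
  expect_null(standardize_molecule(strrep("C", 72)))
  expect_false(is.null(standardize_molecule(strrep("C", 71))))
  expect_null(standardize_molecule("CCO", mw_max = 40))
  expect_null(suppressWarnings(standardize_molecule("][not-a-molecule")))
})

test_that("activity aggregation is the geometric mean in concentration space", {
  expect_equal(aggregate_activity(c(7, 6)), 6.5)
  expect_equal(aggregate_activity(5), 5)
  expect_equal(aggregate_activity(c(5, 5, 8)), 6)
  # 100 nM and 1000 nM average to ~316.2 nM
  expect_equal(10^-aggregate_activity(c(7, 6)) * 1e9, 316.2278,
               tolerance = 1e-6)
  expect_error(aggregate_activity(numeric(0)), "empty")
})

make_records <- function() {
  data.frame(
    molecule_id = c("m1", "m2", "m3", "m4", "m5", "m6", "m1"),
    smiles = unname(fixture_smiles[c(1:6, 1)]),
    target_id = c(rep("T1", 5), "T2", "T1"),
    pchembl = c(6, 7, 5.2, 8, 6.5, 7, 5),
    stringsAsFactors = FALSE
  )
}

test_that("ligand sets respect threshold, size floor, and replicate merging", {
  std <- standardize_activities(make_records(), curation_config())
  # replicate (m1, T1) rows merged by their mean
  expect_equal(std$report$replicates_merged, 1)
  m1 <- std$records[std$records$molecule_id == "m1", ]
  expect_equal(m1$pchembl, 5.5)

  built <- build_ligand_sets(std$records, curation_config())
  # T2 has a single ligand and is dropped; T1 keeps its 5 members
  expect_named(built$sets, "T1")
  expect_equal(built$sets$T1$n, 5)
  expect_equal(built$report$targets_too_small, 1)

  # all rows below threshold -> explicit empty-model error
  low <- std$records
  low$pchembl <- 4.9
  expect_error(build_ligand_sets(low, curation_config()), "empty model")
})

test_that("pchembl filtering is monotone in the threshold", {
  std <- standardize_activities(make_records(), curation_config())
  surviving <- function(thr) {
    r <- std$records[std$records$pchembl >= thr, ]
    paste(r$molecule_id, r$target_id)
  }
  expect_true(all(surviving(7) %in% surviving(6)))
  expect_true(all(surviving(6) %in% surviving(5)))
})

test_that("oversized targets are capped to an exactly-sized diverse subset", {
  set.seed(3)
  fps <- random_fp_list(40, n_bits = 128, density = 0.1)
  records <- data.frame(molecule_id = names(fps), smiles = NA,
                        target_id = "T", pchembl = 7,
                        stringsAsFactors = FALSE)
  records$smiles <- NULL
  cfg <- curation_config(min_ligands_per_target = 5,
                         max_ligands_per_target = 12, diversity_seed = 9)
  built <- build_ligand_sets(records, cfg, fps)
  expect_equal(built$sets$T$n, 12)
  expect_equal(built$report$targets_capped, 1)
  # deterministic under the same seed
  built2 <- build_ligand_sets(records, cfg, fps)
  expect_identical(built$sets$T$members, built2$sets$T$members)
  # capping requires fingerprints
  expect_error(build_ligand_sets(records, cfg), "fingerprints")
})

test_that("max-min picking spreads picks further apart than random", {
  set.seed(5)
  fps <- random_fp_list(60, n_bits = 96, density = 0.12)
  picked <- diverse_pick(fps, 10, seed = 2)
  expect_length(picked, 10)
  expect_false(anyDuplicated(picked) > 0)
  min_pair_dist <- function(ids) {
    tm <- tanimoto_matrix(fps[ids], fps[ids])
    min(1 - tm[upper.tri(tm)])
  }
  set.seed(2)
  rand_ids <- sample(names(fps), 10)
  expect_gte(min_pair_dist(picked), min_pair_dist(rand_ids))
})

test_that("curated duplicate structures collapse within a target", {
  records <- data.frame(
    molecule_id = c("a", "b", "c", "d", "e", "dup"),
    smiles = c(fixture_smiles[1:5], fixture_smiles[[1]]),
    target_id = "T1", pchembl = 7, stringsAsFactors = FALSE)
  built <- build_ligand_sets(records, curation_config())
  expect_equal(built$sets$T1$n, 5)
  expect_equal(built$report$duplicate_structures_dropped, 1)
})

test_that("activity tables round-trip with schema validation", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(molecule_id = "m1", smiles = "CCO", target_id = "T1",
                   pchembl = 6.2, target_type = "SINGLE PROTEIN")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- read_activity_table(path, target_type_filter = "SINGLE PROTEIN")
  expect_equal(nrow(rd), 1)
  bad <- tempfile(fileext = ".tsv")
  write.table(df[-2], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_activity_table(bad), "smiles")
})
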