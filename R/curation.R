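## Curation of raw activity tables into per-target ligand sets.
##
## Workflow: standardize structures (largest organic fragment, molecular
## weight cap), aggregate replicate activities by their geometric mean in
## concentration space, apply the pChEMBL activity threshold, drop
## under-populated targets, and cap oversized targets with max-min
## diversity picking. Every filtering step is counted in a curation report.

#' Curation configuration
#'
#' @param mw_max molecular weight cap in Daltons (default 1000).
#' @param pchembl_min activity threshold on the pChEMBL scale (negative
#'   log10 molar activity; 5 means 10 uM). Conventional choices are 5, 6
#'   or 7; default 5.
#' @param min_ligands_per_target smallest ligand set kept (default 5).
#' @param max_ligands_per_target cap above which a diverse subset is picked
#'   (default 3000).
#' @param diversity_seed seed for the seeded start of max-min picking.
#' @return a `curation_config` object.
#' @export
curation_config <- function(mw_max = 1000,
                            pchembl_min = 5,
                            min_ligands_per_target = 5L,
                            max_ligands_per_target = 3000L,
                            diversity_seed = 1L) {
  assert_that(mw_max > 0, "mw_max must be positive")
  assert_that(min_ligands_per_target >= 1,
              "min_ligands_per_target must be at least 1")
  assert_that(max_ligands_per_target >= min_ligands_per_target,
              "max_ligands_per_target must be >= min_ligands_per_target")
  structure(list(mw_max = mw_max, pchembl_min = pchembl_min,
                 min_ligands_per_target = as.integer(min_ligands_per_target),
                 max_ligands_per_target = as.integer(max_ligands_per_target),
                 diversity_seed = as.integer(diversity_seed)),
            class = "curation_config")
}

#' Read a delimited activity table
#'
#' Expects headered columns `molecule_id`, `smiles`, `target_id`,
#' `pchembl`; the delimiter is inferred from the file extension (`.csv`
#' comma, otherwise tab). An optional `target_type` column can be used to
#' restrict to single-protein targets upstream via `target_type_filter`.
#'
#' @param path file path.
#' @param target_type_filter optional string; when given and the table has
#'   a `target_type` column, only matching rows are kept.
#' @return data.frame of activity records.
#' @export
read_activity_table <- function(path, target_type_filter = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("molecule_id", "smiles", "target_id", "pchembl")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("activity table lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!is.null(target_type_filter) && "target_type" %in% names(df))
    df <- df[df$target_type == target_type_filter, , drop = FALSE]
  df$pchembl <- as.numeric(df$pchembl)
  bad <- !is.finite(df$pchembl) | !nzchar(df$smiles)
  if (any(bad)) df <- df[!bad, , drop = FALSE]
  df[need]
}

#' Standardize one structure
#'
#' Keeps the largest organic fragment of a (possibly multi-component)
#' SMILES, canonicalized with OpenBabel, and rejects it when its molecular
#' weight exceeds `mw_max`. Identical inputs always give identical outputs.
#'
#' @param smiles a single SMILES string.
#' @param mw_max molecular weight cap in Daltons.
#' @return `list(smiles =, mw =)` for the kept fragment, or `NULL` when the
#'   structure is unparseable or too heavy.
#' @export
standardize_molecule <- function(smiles, mw_max = 1000) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return(NULL)
  props <- tryCatch({
    block <- paste(paste(frags, seq_along(frags)), collapse = "\n")
    mols <- ChemmineOB::forEachMol("SMILES", block, identity)
    ChemmineOB::prop_OB(mols)
  }, error = function(e) NULL)
  if (is.null(props) || nrow(props) != length(frags)) return(NULL)
  if (any(props$MW <= 0)) return(NULL)
  organic <- grepl("C(?![a-z])", props$formula, perl = TRUE)
  keep <- if (any(organic)) which(organic) else seq_len(nrow(props))
  ## largest fragment by weight; ties broken by canonical SMILES
  keep <- keep[order(-props$MW[keep], props$cansmi[keep])]
  best <- keep[1]
  if (props$MW[best] > mw_max) return(NULL)
  list(smiles = props$cansmi[best], mw = props$MW[best])
}

#' Geometric-mean aggregation of replicate activities
#'
#' pChEMBL values are negative log10 molar activities, so the geometric
#' mean in concentration space is the arithmetic mean on the pChEMBL
#' scale.
#'
#' @param values numeric vector of pChEMBL values.
#' @return the aggregated pChEMBL value.
#' @export
aggregate_activity <- function(values) {
  if (!length(values)) stop("cannot aggregate an empty activity group")
  if (any(!is.finite(values))) stop("activity values must be finite")
  mean(values)
}

#' Standardize and aggregate an activity table
#'
#' Applies [standardize_molecule()] to every distinct structure, drops
#' unparseable or overweight molecules (counted, never fatal), replaces
#' structures by their canonical form, and collapses replicate
#' (molecule, target) activities with [aggregate_activity()].
#'
#' @param records activity data.frame with `molecule_id`, `smiles`,
#'   `target_id`, `pchembl`.
#' @param config a [curation_config()].
#' @return `list(records =, report =)`: one row per (molecule, target) with
#'   standardized SMILES, plus step counts.
#' @export
standardize_activities <- function(records, config = curation_config()) {
  report <- list(input_rows = nrow(records))
  usm <- unique(records$smiles)
  std <- lapply(usm, standardize_molecule, mw_max = config$mw_max)
  ok <- !vapply(std, is.null, logical(1))
  map <- stats::setNames(vapply(std[ok], `[[`, character(1), "smiles"),
                         usm[ok])
  dropped_structures <- usm[!ok]
  keep <- records$smiles %in% names(map)
  report$rows_dropped_structure <- sum(!keep)
  report$structures_dropped <- length(dropped_structures)
  records <- records[keep, , drop = FALSE]
  records$smiles <- unname(map[records$smiles])
  if (!nrow(records)) {
    report$aggregated_rows <- 0L
    return(list(records = records, report = report))
  }
  key <- paste(records$molecule_id, records$target_id, sep = "\r")
  agg <- tapply(records$pchembl, key, aggregate_activity)
  first <- !duplicated(key)
  out <- records[first, c("molecule_id", "smiles", "target_id")]
  out$pchembl <- as.numeric(agg[key[first]])
  report$replicates_merged <- nrow(records) - nrow(out)
  report$aggregated_rows <- nrow(out)
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' Max-min (farthest point) diverse subset selection
#'
#' Greedy picking on Tanimoto distance: the first pick is random under
#' `seed`, each further pick maximizes the minimum distance to the picks
#' so far (ties broken by input order).
#'
#' @param fps named list of `sea_fp` for the candidate molecules.
#' @param k number of molecules to pick.
#' @param seed integer seed for the starting pick.
#' @return character vector of `k` picked molecule ids.
#' @export
diverse_pick <- function(fps, k, seed = 1L) {
  n <- length(fps)
  if (k >= n) return(names(fps))
  universe <- sort(unique(unlist(lapply(fps, `[[`, "bits"))))
  M <- fp_bit_matrix(fps, universe)
  sizes <- Matrix::colSums(M)
  sim_to <- function(j) {
    common <- as.vector(Matrix::crossprod(M, M[, j]))
    denom <- sizes + sizes[j] - common
    s <- common / denom
    s[denom == 0] <- 0
    s
  }
  start <- with_seed(seed, sample.int(n, 1))
  picked <- integer(k)
  picked[1] <- start
  mindist <- 1 - sim_to(start)
  mindist[start] <- -Inf
  for (i in seq_len(k - 1)) {
    nxt <- which.max(mindist)
    picked[i + 1] <- nxt
    mindist <- pmin(mindist, 1 - sim_to(nxt))
    mindist[nxt] <- -Inf
  }
  names(fps)[picked]
}

#' Build per-target ligand sets
#'
#' From standardized, aggregated records: keeps rows at or above the
#' activity threshold, deduplicates identical structures within a target,
#' drops targets below the minimum set size and caps oversized targets by
#' [diverse_pick()] on the supplied fingerprints.
#'
#' @param records standardized activity data.frame (one row per
#'   molecule-target), as produced by [standardize_activities()].
#' @param config a [curation_config()].
#' @param fingerprints named list of `sea_fp` keyed by molecule_id; required
#'   only when some target exceeds the size cap.
#' @return `list(sets =, report =)` where `sets` is a named list of
#'   `ligand_set` objects (`target_id`, `members`, `n`).
#' @export
build_ligand_sets <- function(records, config = curation_config(),
                              fingerprints = NULL) {
  report <- list(input_rows = nrow(records))
  keep <- records$pchembl >= config$pchembl_min
  report$rows_below_threshold <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records))
    stop("no activity rows at or above the pChEMBL threshold; empty model")

  ## deduplicate identical structures listed under different ids per target
  if ("smiles" %in% names(records)) {
    dup <- duplicated(paste(records$target_id, records$smiles, sep = "\r"))
    report$duplicate_structures_dropped <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  dup2 <- duplicated(paste(records$target_id, records$molecule_id, sep = "\r"))
  records <- records[!dup2, , drop = FALSE]

  members <- split(records$molecule_id, records$target_id)
  small <- vapply(members, length, integer(1)) < config$min_ligands_per_target
  report$targets_too_small <- sum(small)
  members <- members[!small]
  if (!length(members))
    stop("no targets with enough ligands survive curation; empty model")

  report$targets_capped <- 0L
  sets <- vector("list", length(members))
  names(sets) <- names(members)
  for (t in names(members)) {
    ids <- members[[t]]
    if (length(ids) > config$max_ligands_per_target) {
      assert_that(!is.null(fingerprints),
                  "fingerprints are required to diversity-cap oversized targets")
      fps <- fingerprints[ids]
      assert_that(!anyNA(names(fps)),
                  sprintf("missing fingerprints for target %s", t))
      ids <- diverse_pick(fps, config$max_ligands_per_target,
                          seed = config$diversity_seed)
      report$targets_capped <- report$targets_capped + 1L
    }
    sets[[t]] <- ligand_set(t, ids)
  }
  report$targets_kept <- length(sets)
  report$rows_kept <- sum(vapply(sets, function(s) s$n, integer(1)))
  list(sets = sets, report = report)
}

#' Ligand set container
#'
#' @param target_id target identifier.
#' @param members character vector of molecule ids (deduplicated).
#' @return a `ligand_set` with fields `target_id`, `members`, `n`.
#' @export
ligand_set <- function(target_id, members) {
  members <- unique(as.character(members))
  assert_that(length(members) >= 1, "a ligand set needs at least one member")
  structure(list(target_id = as.character(target_id), members = members,
                 n = length(members)),
            class = "ligand_set")
}

#' Write / read ligand sets as a two-column TSV
#'
#' @param sets named list of `ligand_set`.
#' @param path file path for the (target_id, molecule_id) TSV.
#' @return `write_ligand_sets` returns `path` invisibly; `read_ligand_sets`
#'   returns a named list of `ligand_set`.
#' @export
write_ligand_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(target_id = s$target_id, molecule_id = s$members,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ligand_sets
#' @export
read_ligand_sets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  members <- split(df$molecule_id, df$target_id)
  sets <- lapply(names(members), function(t) ligand_set(t, members[[t]]))
  stats::setNames(sets, names(members))
}
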