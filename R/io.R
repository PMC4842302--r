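## Plain-text sidecar formats shared by the command-line workflow.

#' Write / read a fingerprint sidecar TSV
#'
#' One row per molecule: `molecule_id`, `provider_id`, and the
#' space-separated on-bit indices (or, for SHED, the 10 descriptor
#' values).
#'
#' @param fps named list of `sea_fp` or `shed_descriptor`.
#' @param path TSV path.
#' @return `write_fingerprints` returns `path` invisibly;
#'   `read_fingerprints` the named fingerprint list with attribute
#'   `provider_id`.
#' @export
write_fingerprints <- function(fps, path) {
  provider <- attr(fps, "provider_id") %||%
    unique(vapply(fps, `[[`, character(1), "provider_id"))
  assert_that(length(provider) == 1, "mixed providers in sidecar")
  payload <- vapply(fps, function(f) {
    vals <- if (inherits(f, "shed_descriptor")) f$values else f$bits
    paste(format(vals, trim = TRUE, scientific = FALSE), collapse = " ")
  }, character(1))
  df <- data.frame(molecule_id = names(fps), provider_id = provider,
                   bits = unname(payload), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character"))
  provider <- unique(df$provider_id)
  assert_that(length(provider) == 1, "mixed providers in sidecar")
  parse_one <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  fps <- lapply(df$bits, function(s) {
    vals <- if (nzchar(trimws(s))) parse_one(s) else numeric(0)
    if (provider == "shed") shed_descriptor(vals) else sea_fp(vals, provider)
  })
  names(fps) <- df$molecule_id
  attr(fps, "provider_id") <- provider
  fps
}
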