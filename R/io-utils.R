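#' Read a list of essential nodes
#'
#' Plain-text format: one node name per line, `#` comments and blank lines
#' ignored.
#'
#' @param path file path.
#' @return character vector of node names.
#' @export
readEssentialNodes <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  bad <- !grepl(.NODE_NAME_RE, lines)
  if (any(bad))
    stop("invalid node name(s): ", paste(lines[bad], collapse = ", "))
  lines
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a stochastic run bit-for-bit: a
#' configuration snapshot, the master seed and any derived seeds, the
#' package version, and MD5 digests of the input files.
#'
#' @param config named list (configuration snapshot).
#' @param masterSeed integer master seed.
#' @param derivedSeeds integer vector of per-run seeds (possibly empty).
#' @param inputFiles character vector of input file paths to digest.
#' @return a named list ready for JSON serialization.
#' @export
runManifest <- function(config = list(), masterSeed = NA_integer_,
                        derivedSeeds = integer(), inputFiles = character()) {
  digests <- if (length(inputFiles)) as.list(tools::md5sum(inputFiles))
  else list()
  list(tool = "BoolContext",
       version = as.character(utils::packageVersion("BoolContext")),
       masterSeed = masterSeed,
       derivedSeeds = as.list(derivedSeeds),
       config = config,
       inputDigests = digests)
}

#' @rdname runManifest
#' @param manifest a list from `runManifest`.
#' @param path output file path.
#' @export
writeRunManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a GA trace as TSV
#'
#' One row per iteration: iteration number, cumulative evaluations and the
#' best-ever fitness components, reproducing the per-run optimization trace.
#'
#' @param run a [GARun-class].
#' @param path output file path.
#' @export
writeGATrace <- function(run, path) {
  stopifnot(is(run, "GARun"))
  utils::write.table(run@trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a transition table as TSV
#'
#' Flattens the matrix columns of [buildTransitionTable()] into
#' `before_<node>` / `after_<node>` columns.
#'
#' @param table a transition table.
#' @param path output file path.
#' @export
writeTransitionTable <- function(table, path) {
  flat <- data.frame(perturbedNode = table$perturbedNode,
                     direction = table$direction, stringsAsFactors = FALSE)
  b <- as.data.frame(table$before); names(b) <- paste0("before_", names(b))
  a <- as.data.frame(table$after); names(a) <- paste0("after_", names(a))
  utils::write.table(cbind(flat, b, a), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
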