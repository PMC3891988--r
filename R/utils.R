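#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals (printed enrichment tables
# use half-up rounding, unlike base round()'s round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write a table as TSV with provenance comment header
#'
#' All toolkit outputs are plain TSV preceded by `#`-prefixed comment lines
#' recording the package version and the resolved parameters of the run, so
#' any file can be traced back to the settings that produced it. The file is
#' written to a temporary path and atomically renamed, so a failed run never
#' leaves a partial output behind.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param params named list recorded in the header (may be empty).
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, params = list()) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, "w")
  ok <- FALSE
  tryCatch({
    writeLines(sprintf("# duoprobe %s",
                       as.character(utils::packageVersion("duoprobe"))), con)
    writeLines(sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d")), con)
    for (nm in names(params)) {
      writeLines(sprintf("# param %s: %s", nm,
                         paste(format(params[[nm]]), collapse = ",")), con)
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    ok <- TRUE
  }, finally = close(con))
  if (!ok) { unlink(tmp); stop("failed writing ", path) }
  if (!file.rename(tmp, path)) { unlink(tmp); stop("failed writing ", path) }
  invisible(path)
}

#' Read a TSV written by the toolkit (skipping `#` comment lines)
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}
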