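# Attractor output records and run manifests.

#' Write attractors as JSON lines or a CSV summary
#'
#' JSON lines: one object per attractor with `period`, `transient`,
#' `canonical` and `cycle` (states as bit strings in node order).  CSV: one
#' row per attractor (`period`, `transient`, `states` joined by `|`).
#'
#' @param attractors list of `bn_attractor`s.
#' @param file output path.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_attractors <- function(attractors, file, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- if (length(attractors) == 0L)
      data.frame(period = integer(0), transient = integer(0),
                 states = character(0)) else
      do.call(rbind, lapply(attractors, as.data.frame))
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(file))
  }
  lines <- vapply(attractors, function(a) {
    jsonlite::toJSON(list(
      period = a$period,
      transient = if (is.null(a$transient)) NA_integer_ else a$transient,
      canonical = isTRUE(a$canonical),
      cycle = vapply(a$cycle, state_key, "")), auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

#' Read attractors from a JSON-lines file
#'
#' @param file path written by [write_attractors()] (jsonl format).
#' @return list of `bn_attractor`s.
#' @export
read_attractors <- function(file) {
  lapply(readLines(file, warn = FALSE), function(ln) {
    o <- jsonlite::fromJSON(ln)
    cycle <- lapply(strsplit(o$cycle, ""), as.integer)
    structure(list(cycle = cycle, period = as.integer(o$period),
                   canonical = isTRUE(o$canonical),
                   transient = if (is.null(o$transient) || is.na(o$transient))
                     NULL else as.integer(o$transient)),
              class = "bn_attractor")
  })
}

# Run manifest: enough to rerun a CLI invocation byte-for-byte.
write_manifest <- function(dir, subcommand, config, seed, inputs) {
  digests <- if (length(inputs) > 0L)
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    input_digests = digests,
    version = as.character(utils::packageVersion("attapriori")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
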