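#' Write a table as TSV with a JSON metadata header
#'
#' The interchange format used throughout the package: a single
#' \code{#}-prefixed JSON line holding metadata, followed by a plain
#' tab-separated table with a header row.
#'
#' @param df data frame to write.
#' @param path output file.
#' @param meta named list serialized to the JSON header line.
#' @return \code{path}, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV file with a JSON metadata header
#'
#' @param path file written by [write_tsv_meta()].
#' @return list with \code{data} (data frame) and \code{meta} (list).
#' @export
read_tsv_meta <- function(path) {
  first <- readLines(path, n = 1)
  meta <- if (startsWith(first, "#"))
    jsonlite::fromJSON(substring(first, 2)) else list()
  data <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
  list(data = data, meta = meta)
}

#' Serialize a frontier state to TSV
#'
#' One row per wall (angular position plus the strain labels to its left and
#' right); the JSON header carries \code{R0}, \code{R}, \code{L}, \code{t},
#' geometry and strain count.
#'
#' @param st a [frontier_state()].
#' @param path output file.
#' @param extra further metadata merged into the header.
#' @return \code{path}, invisibly.
#' @export
write_frontier_tsv <- function(st, path, extra = list()) {
  n <- length(st$phi)
  left <- if (n) st$labels[c(n, seq_len(n - 1))] else integer()
  df <- data.frame(phi = st$phi, left_label = left, right_label = st$labels)
  meta <- modifyList(list(R0 = st$R0, R = st$R, L = st$L, t = st$t,
                          geometry = st$geometry, q = st$q,
                          mono = if (n == 0) st$mono else NULL), extra)
  write_tsv_meta(df, path, meta)
}

#' Read a frontier state from TSV
#'
#' @param path file written by [write_frontier_tsv()].
#' @return a [frontier_state()].
#' @export
read_frontier_tsv <- function(path) {
  r <- read_tsv_meta(path)
  m <- r$meta
  frontier_state(r$data$phi, r$data$right_label, q = m$q, R0 = m$R0,
                 R = m$R, L = m$L, t = m$t, geometry = m$geometry,
                 mono = if (!is.null(m$mono)) m$mono else NA_integer_)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, seed, timestamp and
#' an inventory of output files with MD5 content hashes, so a deterministic
#' run can be verified to reproduce byte-identical outputs.
#'
#' @param path manifest file (JSON).
#' @param config configuration list.
#' @param seed seed used.
#' @param files character vector of produced files.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, config, seed, files) {
  manifest <- list(
    package = "rangewalk",
    version = as.character(packageVersion("rangewalk")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize simulation parameters to a flat JSON config
#'
#' @param p a [sim_params()] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_params_json <- function(p, path) {
  validate_params(p)
  cfg <- p[c("n0", "q", "init_fractions", "a", "d", "geometry", "seed",
             "snapshot_lengths", "init_mode", "max_steps")]
  cfg$bias <- as.vector(p$bias)   # column-major, reshaped on read
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read simulation parameters from a JSON config
#'
#' @param path file written by [write_params_json()].
#' @return a validated [sim_params()] object.
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  sim_params(n0 = cfg$n0, q = cfg$q, init_fractions = cfg$init_fractions,
             bias = matrix(cfg$bias, cfg$q, cfg$q), a = cfg$a, d = cfg$d,
             geometry = cfg$geometry, seed = cfg$seed,
             snapshot_lengths = if (is.null(cfg$snapshot_lengths)) numeric()
                                else cfg$snapshot_lengths,
             init_mode = cfg$init_mode,
             max_steps = cfg$max_steps)
}
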