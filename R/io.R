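# Plain-text I/O: spike rasters, voltage traces, feedforward trains, flat
# key = value configuration files, and run manifests.

#' Write / read a spike raster
#'
#' Two whitespace-separated columns (`time_ms`, `neuron`), sorted by time,
#' with a `# time_ms neuron` header line.
#'
#' @param spikes a spike data frame (`time`, `neuron`) or an `hh_sim`.
#' @param path file path.
#' @return `read_raster` returns the spike data frame.
#' @export
write_raster <- function(spikes, path) {
  if (inherits(spikes, "hh_sim")) spikes <- spikes$spikes
  spikes <- spikes[order(spikes$time, spikes$neuron), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ms neuron", con)
  if (nrow(spikes))
    writeLines(sprintf("%.17g %d", spikes$time, spikes$neuron), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.table(path, col.names = c("time", "neuron"), comment.char = "#",
                   colClasses = c("numeric", "integer"))
  if (!nrow(df)) df <- data.frame(time = numeric(0), neuron = integer(0))
  df
}

#' Write / read a feedforward spike train
#'
#' One event per line, columns (`neuron`, `time_ms`), header
#' `# neuron time_ms`.
#'
#' @param train a `feedforward_train` object.
#' @param path file path.
#' @param N,T neuron count and duration when reading (duration defaults to
#'   the latest event time).
#' @return `read_train` returns a `feedforward_train`.
#' @export
write_train <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# neuron time_ms",
               sprintf("# N %d T %.17g", train$N, train$T)), con)
  for (i in seq_len(train$N)) {
    tt <- train$times[[i]]
    if (length(tt)) writeLines(sprintf("%d %.17g", i, tt), con)
  }
  invisible(path)
}

#' @rdname write_train
#' @export
read_train <- function(path, N = NULL, T = NULL) {
  hdr <- readLines(path, n = 2)
  meta <- regmatches(hdr[2], regexec("^# N (\\d+) T ([0-9.eE+-]+)", hdr[2]))[[1]]
  if (is.null(N)) N <- if (length(meta) == 3) as.integer(meta[2]) else NULL
  if (is.null(T) && length(meta) == 3) T <- as.numeric(meta[3])
  df <- read.table(path, col.names = c("neuron", "time"), comment.char = "#",
                   colClasses = c("integer", "numeric"))
  if (is.null(N)) N <- max(df$neuron)
  if (is.null(T)) T <- if (nrow(df)) max(df$time) else 0
  times <- lapply(seq_len(N), function(i) sort(df$time[df$neuron == i]))
  structure(list(times = times, N = N, T = T), class = "feedforward_train")
}

#' Write / read sampled voltage traces
#'
#' Whitespace-delimited text: a time column `t` (ms) plus one column per
#' recorded neuron (mV), with a header naming the columns.
#'
#' @param sim an `hh_sim` with recorded traces, or the trace data frame.
#' @param path file path.
#' @return `read_traces` returns the trace data frame.
#' @export
write_traces <- function(sim, path) {
  tr <- if (inherits(sim, "hh_sim")) sim$trace else sim
  if (is.null(tr)) stop("no traces recorded (set 'record' in the config)")
  write.table(format(tr, digits = 17, trim = TRUE), path,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  read.table(path, header = TRUE)
}

.config_keys <- c("N", "N_E", "N_I", "topology", "p", "S", "f", "nu", "dt",
                  "T", "method", "model", "stiff_duration",
                  "stiff_slope_threshold", "seed", "include_self", "V0",
                  "V0_jitter", "record", "record_every")

#' Read / write a flat configuration file
#'
#' One `key = value` pair per line (`#` comments allowed); keys mirror the
#' [network_config()] arguments. `record` is a comma-separated list of neuron
#' indices.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file's values (used for
#'   command-line flag overrides).
#' @param config a `network_config` to serialize.
#' @return `read_config` returns a [network_config()].
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(sub("=.*", "", lines))
  vals <- stats::setNames(as.list(trimws(sub("^[^=]*=", "", lines))), keys)
  unknown <- setdiff(names(vals), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals[names(overrides)] <- overrides
  parse_val <- function(key, v) {
    switch(key,
      topology = , method = , model = as.character(v),
      include_self = as.logical(v),
      record = if (nzchar(v)) as.integer(strsplit(as.character(v), ",")[[1]])
               else integer(0),
      N = , N_E = , N_I = , seed = , record_every = as.integer(v),
      as.numeric(v))
  }
  args <- lapply(names(vals), function(k) parse_val(k, vals[[k]]))
  names(args) <- names(vals)
  do.call(network_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  fmt <- function(k) {
    v <- config[[k]]
    if (k == "record") paste(v, collapse = ",") else as.character(v)
  }
  writeLines(paste(.config_keys, "=", vapply(.config_keys, fmt, "")), path)
  invisible(path)
}

#' Run manifest
#'
#' A small record of a completed run: the full configuration echo, the seed,
#' the package version, the output file paths and the final status. Reruns
#' with an identical manifest reproduce the outputs exactly.
#'
#' @param config the [network_config()] used.
#' @param files named character vector of output paths.
#' @param status `"ok"` or an error note.
#' @param path file to write (`key = value` lines).
#' @return The manifest as a named list (invisibly for `write_manifest`).
#' @export
run_manifest <- function(config, files = character(), status = "ok") {
  c(list(package = "etdhh",
         version = as.character(utils::packageVersion("etdhh")),
         status = status),
    stats::setNames(as.list(files), paste0("file_", names(files))),
    lapply(stats::setNames(.config_keys, .config_keys), function(k) {
      v <- config[[k]]
      if (k == "record") paste(v, collapse = ",") else v
    }))
}

#' @rdname run_manifest
#' @export
write_manifest <- function(config, files = character(), status = "ok", path) {
  m <- run_manifest(config, files, status)
  writeLines(paste(names(m), "=", vapply(m, as.character, "")), path)
  invisible(m)
}
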