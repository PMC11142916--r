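# Plain-text file formats: traces and kymographs as tab-delimited text
# with '#'-prefixed key=value header lines; fits and manifests as JSON.

parse_header <- function(path, n_max = 100L) {
  lines <- readLines(path, n = n_max, warn = FALSE)
  hdr_lines <- lines[startsWith(lines, "#")]
  kv <- list()
  for (i in seq_along(hdr_lines)) {
    s <- sub("^#\\s*", "", hdr_lines[i])
    if (!nzchar(s)) next
    if (!grepl("=", s, fixed = TRUE)) {
      abort(sprintf("malformed header line %d in %s: `%s` (expected key=value).",
                    i, path, s))
    }
    key <- sub("=.*$", "", s)
    val <- sub("^[^=]*=", "", s)
    num <- suppressWarnings(as.numeric(val))
    kv[[trimws(key)]] <- if (!is.na(num)) num else trimws(val)
  }
  kv
}

write_header <- function(con, kv) {
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.null(v) || length(v) != 1L) next
    writeLines(sprintf("# %s=%s", k, format(v, digits = 15)), con)
  }
}

#' Write a trace to delimited text
#'
#' Tab-delimited columns with a '#'-prefixed key=value header recording
#' the trace kind, sampling rate and provenance metadata. Angular traces
#' carry `(time_s, angle_rad[, angle_filt_rad])`; kinetic traces
#' `(time_s, signal)`; anisotropy channel pairs `(time_s, ivv, ivh)`.
#'
#' @param trace An [angular_trace()] or kinetic-trace tibble.
#' @param path Output file.
#' @param kind Override the trace kind (`"angular"`, `"fluorescence"`,
#'   `"phosphate"`, `"anisotropy"`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (inherits(trace, "angular_trace") || "angle_rad" %in% names(trace)) {
      "angular"
    } else if (all(c("ivv", "ivh") %in% names(trace))) {
      "anisotropy"
    } else {
      ch <- attr(trace, "channel")
      if (is.null(ch)) "fluorescence" else ch
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  kv <- list(kind = kind)
  sr <- attr(trace, "sample_rate_hz")
  if (!is.null(sr)) kv$sample_rate_hz <- sr
  md <- attr(trace, "metadata")
  if (!is.null(md)) {
    for (k in names(md)) if (length(md[[k]]) == 1L && is.atomic(md[[k]])) {
      kv[[k]] <- md[[k]]
    }
  }
  write_header(con, kv)
  cols <- as.data.frame(trace)
  utils::write.table(cols, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Dispatches on the `kind` header: `angular` returns an
#' [angular_trace()]; kinetic kinds return a `kinetic_trace` tibble with
#' the channel recorded. Non-monotone time stamps are an error.
#'
#' @param path File path.
#' @return A trace tibble with header metadata attached.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  kv <- parse_header(path)
  if (is.null(kv$kind)) {
    abort(sprintf("missing `kind` header in %s (first line must declare kind=...).",
                  path))
  }
  d <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         check.names = FALSE)
  if (!"time_s" %in% names(d)) abort(sprintf("no `time_s` column in %s.", path))
  if (any(diff(d$time_s) <= 0)) {
    abort(sprintf("time stamps in %s are not strictly increasing (first at row %d).",
                  path, which(diff(d$time_s) <= 0)[1L] + 1L))
  }
  kind <- kv$kind
  if (kind == "angular") {
    if (!"angle_rad" %in% names(d)) {
      abort(sprintf("angular trace %s lacks an `angle_rad` column.", path))
    }
    sr <- kv$sample_rate_hz
    if (is.null(sr)) sr <- 1 / median(diff(d$time_s))
    out <- angular_trace(d$angle_rad, sr, time_s = d$time_s,
                         metadata = kv[setdiff(names(kv),
                                               c("kind", "sample_rate_hz"))])
    if ("angle_filt_rad" %in% names(d)) out$angle_filt_rad <- d$angle_filt_rad
    if ("label" %in% names(d)) out$label <- d$label
    return(out)
  }
  if (kind %in% c("fluorescence", "phosphate", "anisotropy", "ivv", "ivh")) {
    out <- as_tibble(d)
    attr(out, "channel") <- kind
    attr(out, "header") <- kv
    class(out) <- c("kinetic_trace", class(out))
    return(out)
  }
  abort(sprintf("unknown trace kind `%s` in %s.", kind, path))
}

#' Write / read a kymograph as a delimited integer matrix
#'
#' One scan line per row; the '#' header records `line_time_s` and
#' `pixel_size_nm`.
#'
#' @param kymo Integer matrix.
#' @param path File path.
#' @param line_time,pixel_size Acquisition metadata.
#' @return `path` / list with `kymo`, `line_time_s`, `pixel_size_nm`.
#' @export
write_kymograph <- function(kymo, path, line_time = 0.028, pixel_size = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(kind = "kymograph", line_time_s = line_time,
                         pixel_size_nm = pixel_size))
  utils::write.table(kymo, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  kv <- parse_header(path)
  if (is.null(kv$kind) || kv$kind != "kymograph") {
    abort(sprintf("%s does not declare kind=kymograph.", path))
  }
  m <- as.matrix(utils::read.delim(path, comment.char = "#", sep = "\t",
                                   header = FALSE))
  dimnames(m) <- NULL
  list(kymo = m, line_time_s = kv$line_time_s, pixel_size_nm = kv$pixel_size_nm)
}

#' Write an event table with its detection parameters
#'
#' Tab-delimited event rows; all detection thresholds travel in the '#'
#' header so a table is self-describing.
#'
#' @param events A `translocation_events` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pars <- attr(events, "params")
  kv <- c(list(kind = "translocation_events"),
          pars[vapply(pars, function(p) length(p) == 1L && is.atomic(p),
                      logical(1))])
  write_header(con, kv)
  utils::write.table(as.data.frame(events), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  kv <- parse_header(path)
  d <- as_tibble(utils::read.delim(path, comment.char = "#", sep = "\t"))
  attr(d, "params") <- kv[setdiff(names(kv), "kind")]
  class(d) <- c("translocation_events", class(d))
  d
}

#' Build a run manifest
#'
#' Records the package version, input digests, all effective parameters
#' and seeds, and a timestamp, so that a results bundle is traceable to
#' exactly one configuration. Deterministic reruns with an identical
#' manifest reproduce the outputs bit for bit.
#'
#' @param inputs Character vector of input file paths (digested), or
#'   `NULL` for fully synthetic runs.
#' @param params Named list of effective parameters.
#' @param seed Master seed of the run.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(inputs = NULL, params = list(), seed = NULL) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  structure(
    list(pipeline = "nanorotor",
         version = as.character(utils::packageVersion("nanorotor")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input_digests = digests, params = params, seed = seed),
    class = "run_manifest"
  )
}

#' Write a manifest (or any fit object) as JSON
#'
#' @param x List-like object; fit objects are tidied first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  if (inherits(x, c("gauss_mix_fit", "exp_mix_fit"))) {
    x <- list(components = tidy(x), summary = glance(x))
  }
  x <- rapply(unclass(x), function(e) if (is.language(e) || is.function(e)) NULL else e,
              how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
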