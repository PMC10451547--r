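#' Read / write potential traces
#'
#' Traces are stored as comma-separated files with `#`-prefixed metadata
#' lines (`t_add_s`, `temperature_K`, `seed`, ...) followed by a
#' `t_s,E_V` header.  All numbers are written with 15 significant digits
#' so a write/read round trip is lossless at working precision.
#'
#' @param path File path.
#' @return [read_trace()] returns a `kp_trace`; [write_trace()] returns
#'   `path` invisibly.
#' @name trace_io
NULL

.read_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  meta
}

.write_csv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm,
                       if (is.numeric(meta[[nm]]))
                         format(meta[[nm]], digits = 15)
                       else as.character(meta[[nm]])), con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- apply(vapply(df, function(col) format(col, digits = 15,
                                                scientific = NA,
                                                trim = TRUE),
                       character(nrow(df))), 1L, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

.read_csv_meta <- function(path, expected_cols) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  meta <- .read_meta(lines)
  data_lines <- grep("^#", lines, invert = TRUE)
  if (length(data_lines) < 2L) abort("no data rows.")
  hdr_i <- data_lines[1L]
  hdr <- strsplit(lines[hdr_i], ",")[[1]]
  if (!all(expected_cols %in% hdr))
    abort(paste0("expected columns ", paste(expected_cols, collapse = ", "),
                 " in ", path))
  rows <- lines[data_lines[-1L]]
  vals <- strsplit(rows, ",")
  bad <- which(lengths(vals) != length(hdr))
  if (length(bad))
    abort(paste0("malformed row at line ", data_lines[-1L][bad[1L]],
                 " of ", path))
  m <- matrix(as.numeric(unlist(vals)), ncol = length(hdr), byrow = TRUE)
  df <- as_tibble(as.data.frame(m))
  names(df) <- hdr
  list(df = df, meta = meta, line_of_row = data_lines[-1L])
}

#' @rdname trace_io
#' @param trace A `kp_trace`.
#' @export
write_trace <- function(trace, path) {
  meta <- list(format = "kinpot-trace-v1",
               t_add_s = attr(trace, "t_add") %||% NA_real_)
  el <- attr(trace, "electrode")
  if (!is.null(el)) meta$temperature_K <- el$temperature
  truth <- attr(trace, "truth")
  if (inherits(truth, "kp_config")) meta$seed <- truth$seed
  .write_csv_meta(tibble(t_s = trace$t, E_V = trace$e), path, meta)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  parsed <- .read_csv_meta(path, c("t_s", "E_V"))
  t_add <- parsed$meta$t_add_s
  if (is.null(t_add) || !is.finite(t_add))
    abort("trace file lacks the t_add_s metadata line.")
  dup <- which(diff(parsed$df$t_s) <= 0)
  if (length(dup))
    abort(paste0("non-monotone time at line ",
                 parsed$line_of_row[dup[1L] + 1L], " of ", path))
  new_trace(parsed$df$t_s, parsed$df$E_V, t_add = t_add)
}

#' Read / write residual-concentration series
#'
#' CSV with columns `t_s`, `c_M` and metadata lines `c0_M` and `name`.
#'
#' @param path File path.
#' @param series A [concentration_series()].
#' @return [read_series()] returns a `kp_series`.
#' @name series_io
NULL

#' @rdname series_io
#' @export
write_series <- function(series, path) {
  .write_csv_meta(tibble(t_s = series$t, c_M = series$c), path,
                  list(format = "kinpot-series-v1",
                       c0_M = attr(series, "c0"),
                       name = attr(series, "name") %||% "antioxidant"))
}

#' @rdname series_io
#' @export
read_series <- function(path) {
  parsed <- .read_csv_meta(path, c("t_s", "c_M"))
  c0 <- parsed$meta$c0_M
  if (is.null(c0)) abort("series file lacks the c0_M metadata line.")
  concentration_series(parsed$df$t_s, parsed$df$c_M, c0 = c0,
                       name = as.character(parsed$meta$name %||% NA))
}

#' Read / write experiment configurations (YAML)
#'
#' @param path YAML file path.
#' @param config An [experiment_config()].
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "kp_config"))
  x <- list(
    kinetics = config$params[c("ki", "two_k2", "initiator_c0",
                               "temperature", "efficiency")],
    antioxidants = purrr::transpose(as.list(config$antioxidants)),
    electrode = unclass(config$electrode),
    cell = unclass(config$cell),
    experiment = config[c("t_add", "duration", "sampling_hz",
                          "noise_sigma", "drift_sigma",
                          "noise_sigma_mediator", "aliquot_every",
                          "mode", "seed")]
  )
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- yaml::read_yaml(path)
  params <- do.call(rate_params, x$kinetics %||% list())
  ao <- if (length(x$antioxidants))
    purrr::map_dfr(x$antioxidants, function(a) do.call(antioxidant, a))
  else no_antioxidant()
  el <- do.call(electrode_model, x$electrode %||% list())
  cell <- do.call(ferro_cell, x$cell %||% list())
  do.call(experiment_config,
          c(list(params = params, antioxidants = ao,
                 electrode = el, cell = cell),
            x$experiment %||% list()))
}

# run manifest: provenance for CLI artefacts
run_manifest <- function(inputs = character(), seed = NA_integer_,
                         config = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "kinpot",
       version = as.character(utils::packageVersion("kinpot")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config_hash = if (!is.null(config))
         digest_config(config) else NA_character_,
       input_digests = digests)
}

digest_config <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
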