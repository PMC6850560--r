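#' Read a binary activity matrix
#'
#' Reads either headerless delimited text (rows = neurons, columns = frames)
#' or a MatrixMarket coordinate file (1-based indices) into a dense 0/1
#' integer matrix.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension: .mtx is MatrixMarket, anything
#'   else delimited), \code{"delim"} or \code{"mtx"}.
#' @param sep field separator for delimited input (default any whitespace).
#' @return N x M integer 0/1 matrix.
#' @export
read_activity_matrix <- function(path, format = c("auto", "delim", "mtx"),
                                 sep = "") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delim"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "integer"
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
  }
  check_binary_matrix(m)
}

#' Write a binary activity matrix
#'
#' @param s N x M 0/1 matrix.
#' @param path output file path.
#' @param format \code{"delim"} (headerless, tab-separated) or \code{"mtx"}
#'   (MatrixMarket coordinate, sparse).
#' @return The path, invisibly.
#' @export
write_activity_matrix <- function(s, path, format = c("delim", "mtx")) {
  format <- match.arg(format)
  s <- check_binary_matrix(s)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(s, sparse = TRUE), "TsparseMatrix"),
                    path)
  } else {
    utils::write.table(s, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read per-neuron traces
#'
#' Reads a CSV/TSV with one column per neuron; if the first column is named
#' \code{time} (case-insensitive) it supplies the sampling interval,
#' otherwise \code{dt} must be given.
#'
#' @param path file path.
#' @param dt sampling interval in seconds (required when no time column).
#' @param sep field separator (default auto: comma or tab by extension).
#' @return A list with the trace matrix \code{x} (rows = frames, columns =
#'   neurons) and \code{dt}.
#' @export
read_traces <- function(path, dt = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (tolower(names(d)[1]) == "time") {
    tt <- d[[1]]
    dt <- stats::median(diff(tt))
    d <- d[-1L]
  }
  if (is.null(dt)) stop("'dt' required when the file has no time column")
  list(x = as.matrix(d), dt = dt)
}

#' Read neuron coordinates
#'
#' CSV with columns id, x, y and optionally z.
#'
#' @param path file path.
#' @return Data frame with columns \code{id}, \code{x}, \code{y} (and
#'   \code{z} if present).
#' @export
read_coordinates <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("id", "x", "y") %in% names(d)))
  d
}

#' Read a flat key = value configuration file
#'
#' INI-style configuration mirroring the hyperparameters and simulation
#' parameters: one \code{key = value} pair per line, \code{#} comments,
#' values parsed as numbers where possible.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key = value configuration file
#'
#' @param config named list of scalar values.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Hyperparameters from a configuration list
#'
#' Builds an \code{\link{assembly_hyper}} from a configuration list, using
#' defaults for absent keys.
#'
#' @param config named list, e.g. from \code{\link{read_config}}.
#' @return An \code{assembly_hyper}.
#' @export
hyper_from_config <- function(config) {
  def <- assembly_hyper()
  args <- lapply(names(unclass(def)), function(k)
    if (!is.null(config[[k]])) config[[k]] else def[[k]])
  names(args) <- names(unclass(def))
  do.call(assembly_hyper, args)
}
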