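#' Read an XAS spectrum from a text file
#'
#' Supported dialects:
#' \describe{
#'   \item{`two_column`}{whitespace-delimited `energy intensity` rows; lines
#'     starting with `#` are comments.}
#'   \item{`xdi_like`}{`# key: value` header lines followed by two-column
#'     data; header keys are stored in `meta`.}
#'   \item{`csv`}{comma-separated with a header line `energy,intensity`.}
#' }
#' Rows are sorted to ascending energy if needed (recorded in history) and
#' duplicate energies are collapsed by averaging their intensities, the
#' conventional treatment for repeat scans at identical points.
#'
#' @param path Path to an existing file.
#' @param dialect One of `"two_column"`, `"xdi_like"`, `"csv"`.
#' @param edge Edge label passed to [xas_spectrum()].
#' @return An [xas_spectrum()].
#' @seealso [write_spectrum()], [read_sticks()]
#' @export
read_spectrum <- function(path, dialect = c("two_column", "xdi_like", "csv"),
                          edge = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  meta <- list(source_file = path, dialect = dialect)

  if (dialect == "xdi_like") {
    hdr <- grep("^\\s*#", lines, value = TRUE)
    kv <- regmatches(hdr, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*)$", hdr))
    for (m in kv) if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (dialect == "csv") {
    if (!length(body)) stop("format error: '", path, "' has no data rows")
    header <- tolower(gsub("\\s", "", body[1L]))
    if (!grepl("^energy,intensity", header))
      stop("format error: csv header must be 'energy,intensity'")
    body <- body[-1L]
    fields <- strsplit(body, ",", fixed = TRUE)
  } else {
    fields <- strsplit(trimws(body), "\\s+")
  }
  ncols <- vapply(fields, length, integer(1))
  if (length(fields) == 0L || any(ncols < 2L))
    stop("format error: '", path, "' needs at least 2 numeric columns per row")
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  i <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(e) || anyNA(i)) {
    bad <- which(is.na(e) | is.na(i))[1L]
    stop("validation error: non-numeric value at data row ", bad,
         " of '", path, "'")
  }
  if (any(!is.finite(e) | !is.finite(i))) {
    bad <- which(!is.finite(e) | !is.finite(i))[1L]
    stop("validation error: non-finite value at data row ", bad,
         " of '", path, "'")
  }

  history <- character(0)
  if (is.unsorted(e, strictly = FALSE)) {
    ord <- order(e)
    e <- e[ord]; i <- i[ord]
    history <- c(history, "reordered rows to ascending energy")
  }
  if (anyDuplicated(e)) {
    ndup <- length(e) - length(unique(e))
    i <- as.numeric(tapply(i, e, mean))
    e <- sort(unique(e))
    history <- c(history,
                 sprintf("averaged %d duplicate-energy row(s)", ndup))
  }
  meta$history <- c(sprintf("read %d points from '%s' (%s)",
                            length(e), path, dialect), history)
  xas_spectrum(e, i, edge = edge, meta = meta)
}

#' Write an XAS spectrum to a text file
#'
#' Writes full double precision so that read -> write -> read round-trips
#' bit-identically for the native dialects.
#'
#' @param s An [xas_spectrum()].
#' @param path Output path.
#' @param dialect One of `"two_column"`, `"xdi_like"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path,
                           dialect = c("two_column", "xdi_like", "csv")) {
  dialect <- match.arg(dialect)
  assert_spectrum(s)
  e <- formatC(s$energy, format = "g", digits = 17)
  i <- formatC(s$intensity, format = "g", digits = 17)
  lines <- switch(dialect,
    two_column = paste(e, i),
    xdi_like = {
      hdr <- c(sprintf("# edge: %s", s$edge),
               sprintf("# normalized: %s", s$normalized))
      c(hdr, paste(e, i))
    },
    csv = c("energy,intensity", paste(e, i, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a stick spectrum (excitation energy, oscillator strength)
#'
#' Two whitespace-delimited numeric columns; `#` comments allowed; an empty
#' file yields an empty (valid) stick spectrum. Negative strengths are
#' rejected.
#'
#' @param path Path to an existing file.
#' @return A [stick_spectrum()].
#' @export
read_sticks <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) return(stick_spectrum())
  fields <- strsplit(trimws(body), "\\s+")
  if (any(vapply(fields, length, integer(1)) < 2L))
    stop("format error: '", path, "' needs 2 numeric columns per row")
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  f <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(e) || anyNA(f))
    stop("validation error: non-numeric value in '", path, "'")
  stick_spectrum(e, f)
}

#' Interpolate a spectrum onto a target energy grid
#'
#' Linear interpolation, the default because it never overshoots near sharp
#' edge features; it is exact on linear data and idempotent on its own
#' output grid. Extrapolation is refused.
#'
#' @param s An [xas_spectrum()].
#' @param grid Strictly increasing target energies, all inside
#'   `range(s$energy)`.
#' @return An [xas_spectrum()] on `grid`.
#' @export
interpolate_to_grid <- function(s, grid) {
  assert_spectrum(s)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < min(s$energy) || max(grid) > max(s$energy))
    stop(sprintf(
      "range error: grid [%.4f, %.4f] extends beyond spectrum [%.4f, %.4f]; extrapolation refused",
      min(grid), max(grid), min(s$energy), max(s$energy)))
  yi <- stats::approx(s$energy, s$intensity, xout = grid, method = "linear",
                      ties = "ordered")$y
  out <- xas_spectrum(grid, yi, edge = s$edge, normalized = s$normalized,
                      meta = s$meta)
  add_history(out, sprintf("interpolated onto %d-point grid [%.4g, %.4g] eV",
                           length(grid), min(grid), max(grid)))
}
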