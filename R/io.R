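# On-disk formats. Window TSVs use '#'-prefixed headers and whitespace
# separated numeric lines; readers reject malformed input with the offending
# line/field named rather than repairing it silently. Unicode minus signs
# (as printed in typesetting) are normalized to ASCII on read.

normalize_minus <- function(x) gsub("−", "-", x)

parse_num <- function(tok, path, lineno) {
  v <- suppressWarnings(as.numeric(normalize_minus(tok)))
  if (any(is.na(v)))
    stop(sprintf("%s: non-numeric value on line %d", path, lineno))
  v
}

#' Write an umbrella window to a TSV file
#'
#' Format: header lines `# center <A>`, `# force_constant <kcal/mol/A^2>`,
#' `# temperature <K>`, then one sample per line — a single xi value, or
#' `xi d_nuc d_lg` when per-frame distance pairs are stored.
#'
#' @param window an [umbrella_window()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# center %.10g", window$center),
    sprintf("# force_constant %.10g", window$force_constant),
    sprintf("# temperature %.10g", window$temperature)), con)
  if (is.null(window$d_nuc)) {
    writeLines(sprintf("%.10g", window$samples), con)
  } else {
    writeLines(sprintf("%.10g\t%.10g\t%.10g",
                       window$samples, window$d_nuc, window$d_lg), con)
  }
  invisible(path)
}

#' Read an umbrella window from a TSV file
#'
#' @param path file written by [write_window()] (or hand-built in the same
#'   dialect). A missing `# temperature` header defaults to 300 K with a
#'   warning; a missing `# center` or `# force_constant` is an error naming
#'   the missing key.
#' @return An [umbrella_window()].
#' @export
read_window <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  data_start <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      tok <- strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]
      if (length(tok) != 2L)
        stop(sprintf("%s: malformed header on line %d", path, i))
      hdr[[tok[1L]]] <- parse_num(tok[2L], path, i)
    } else {
      data_start <- i
      break
    }
  }
  for (key in c("center", "force_constant")) {
    if (is.null(hdr[[key]]))
      stop(sprintf("%s: missing required header key '%s'", path, key))
  }
  if (is.null(hdr$temperature)) {
    warning(sprintf("%s: missing '# temperature' header, assuming 300 K", path))
    hdr$temperature <- 300
  }
  if (is.null(data_start)) stop(sprintf("%s: empty sample block", path))
  xi <- c(); dn <- c(); dl <- c()
  ncol_seen <- NULL
  for (i in data_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!is.null(ncol_seen) && length(tok) != ncol_seen)
      stop(sprintf("%s: inconsistent column count on line %d", path, i))
    ncol_seen <- length(tok)
    if (!(ncol_seen %in% c(1L, 3L)))
      stop(sprintf("%s: expected 1 or 3 columns on line %d", path, i))
    v <- parse_num(tok, path, i)
    xi <- c(xi, v[1L])
    if (ncol_seen == 3L) { dn <- c(dn, v[2L]); dl <- c(dl, v[3L]) }
  }
  if (!length(xi)) stop(sprintf("%s: empty sample block", path))
  umbrella_window(hdr$center, hdr$force_constant, xi, hdr$temperature,
                  d_nuc = if (length(dn)) dn else NULL,
                  d_lg = if (length(dl)) dl else NULL)
}

#' Write / read a window manifest
#'
#' The manifest is a JSON file listing the per-window TSV files of one
#' umbrella-sampling campaign together with their restraint metadata.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param dir directory receiving the manifest and one TSV per window.
#' @param name manifest file name.
#' @return Path of the manifest file.
#' @export
write_manifest <- function(windows, dir, name = "windows.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    fn <- sprintf("window_%02d.tsv", i)
    write_window(w, file.path(dir, fn))
    entries[[i]] <- list(file = fn, center = w$center,
                         force_constant = w$force_constant,
                         temperature = w$temperature,
                         n_samples = length(w$samples))
  }
  path <- file.path(dir, name)
  jsonlite::write_json(list(windows = entries), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname write_manifest
#' @param path manifest JSON path.
#' @return For `read_manifest`, the list of windows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- jsonlite::read_json(path)
  if (is.null(m$windows)) stop(sprintf("%s: manifest has no 'windows' field", path))
  lapply(m$windows, function(e) read_window(file.path(dirname(path), e$file)))
}

#' Write a free-energy profile as a two-column TSV
#'
#' Format: `# reference <label>`, `# estimator <label>`, then tab-separated
#' `xi  A` lines (Angstrom, kcal/mol). Non-finite values (uncovered bins)
#' are written as `inf`/`nan` and restored on read.
#'
#' @param profile an `fe_profile` (see [wham()], [umbrella_integration()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference %s", profile$reference),
               sprintf("# estimator %s", profile$estimator)), con)
  writeLines(sprintf("%.10g\t%.10g", profile$grid, profile$values), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  reference <- "unknown"; estimator <- "unknown"
  grid <- c(); vals <- c()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      tok <- strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]
      if (length(tok) == 2L && tok[1L] == "reference") reference <- tok[2L]
      if (length(tok) == 2L && tok[1L] == "estimator") estimator <- tok[2L]
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 2L)
      stop(sprintf("%s: expected 2 columns on line %d", path, i))
    v <- suppressWarnings(as.numeric(normalize_minus(tok)))
    if (is.na(v[1L]))
      stop(sprintf("%s: non-numeric grid value on line %d", path, i))
    grid <- c(grid, v[1L]); vals <- c(vals, v[2L])
  }
  if (!length(grid)) stop(sprintf("%s: no profile data", path))
  if (any(diff(grid) <= 0))
    stop(sprintf("%s: profile grid is not strictly increasing", path))
  fe_profile(grid, vals, reference = reference, estimator = estimator)
}
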