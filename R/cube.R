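# Gaussian cube format. Standard layout: two comment lines; a line with
# natoms and the grid origin; three axis lines (count + step vector); natoms
# atom records (Z, charge, x, y, z); then values six per line with the last
# (z) index varying fastest. Geometry in Bohr, values in atomic units.
# The negative-natoms orbital-cube dialect is rejected explicitly.

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return A [scalar_field3d()] in Bohr / atomic units.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop(sprintf("%s: truncated cube header", path))
  toks <- function(i) strsplit(trimws(normalize_minus(lines[i])), "\\s+")[[1]]
  l3 <- suppressWarnings(as.numeric(toks(3L)))
  if (length(l3) < 4L || any(is.na(l3[1:4])))
    stop(sprintf("%s: malformed natoms/origin line (line 3)", path))
  natoms <- l3[1L]
  if (natoms < 0)
    stop(sprintf("%s: negative natoms (orbital-cube dialect) is unsupported", path))
  natoms <- as.integer(natoms)
  origin <- l3[2:4]
  counts <- integer(3L)
  axes <- matrix(0, 3L, 3L)
  for (a in 1:3) {
    la <- suppressWarnings(as.numeric(toks(3L + a)))
    if (length(la) < 4L || any(is.na(la)))
      stop(sprintf("%s: malformed axis line %d", path, 3L + a))
    counts[a] <- as.integer(la[1L])
    axes[a, ] <- la[2:4]
  }
  if (any(counts < 2L)) stop(sprintf("%s: fewer than 2 points along an axis", path))
  atoms <- NULL
  if (natoms > 0L) {
    if (length(lines) < 6L + natoms)
      stop(sprintf("%s: truncated atom block", path))
    rec <- t(vapply(seq_len(natoms), function(i) {
      v <- suppressWarnings(as.numeric(toks(6L + i)))
      if (length(v) < 5L || any(is.na(v)))
        stop(sprintf("%s: malformed atom record on line %d", path, 6L + i))
      v[1:5]
    }, numeric(5L)))
    atoms <- data.frame(Z = as.integer(rec[, 1L]), x = rec[, 3L],
                        y = rec[, 4L], z = rec[, 5L])
  }
  # value block begins after 6 header lines + natoms atom records
  body <- lines[seq.int(7L + natoms, length.out = max(0L, length(lines) - 6L - natoms))]
  tok <- unlist(strsplit(trimws(normalize_minus(body)), "\\s+"))
  tok <- tok[nzchar(tok)]
  vals <- suppressWarnings(as.numeric(tok))
  if (any(is.na(vals))) stop(sprintf("%s: non-numeric value in cube body", path))
  nexp <- prod(counts)
  if (length(vals) != nexp)
    stop(sprintf("%s: value block has %d values, expected %d (truncated or natoms mismatch)",
                 path, length(vals), nexp))
  # file order is z-fastest: values[ix][iy][iz] with iz innermost
  arr <- aperm(array(vals, dim = rev(counts)), 3:1)
  scalar_field3d(origin, axes, arr, atoms = atoms)
}

#' Write a Gaussian cube file
#'
#' @param field a [scalar_field3d()] (Bohr / atomic units).
#' @param path output path.
#' @param comment up to two comment lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path, comment = c("pmftools scalar field", "")) {
  stopifnot(inherits(field, "scalar_field3d"))
  comment <- rep_len(as.character(comment), 2L)
  atoms <- field$atoms
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", natoms,
                     field$origin[1], field$origin[2], field$origin[3]), con)
  for (a in 1:3)
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f", field$counts[a],
                       field$axes[a, 1], field$axes[a, 2], field$axes[a, 3]), con)
  if (natoms > 0L)
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f",
                       atoms$Z, as.numeric(atoms$Z), atoms$x, atoms$y, atoms$z),
               con)
  # z-fastest ordering: one pencil of nz values per (x, y), six per line
  nz <- field$counts[3L]
  breaks <- ceiling(seq_len(nz) / 6)
  lines <- character(0)
  for (ix in seq_len(field$counts[1L]))
    for (iy in seq_len(field$counts[2L])) {
      pencil <- sprintf("%13.5E", field$values[ix, iy, ])
      lines <- c(lines, vapply(split(pencil, breaks), paste,
                               character(1L), collapse = " "))
    }
  writeLines(lines, con)
  invisible(path)
}
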