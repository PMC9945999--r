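#' Read or write a per-frame energy table
#'
#' Energy tables are plain CSV with header `frame,E_GS_eV,E_CS_eV,E_ES_eV`,
#' one row per trajectory frame, all energies in eV.
#'
#' @param table A `data.frame` as returned by [generate_cs_trajectory()].
#' @param path File path.
#' @return `read_energy_table()` returns the validated `data.frame`;
#'   `write_energy_table()` returns `path` invisibly.
#' @seealso [validate_energy_table()]
#' @export
write_energy_table <- function(table, path) {
  table <- validate_energy_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_energy_table(utils::read.csv(path))
}

#' Validate an energy table against the expected schema
#'
#' Checks that the required columns are present, all energies are finite, and
#' frame indices are strictly increasing with no duplicates.
#'
#' @param table A `data.frame` (or a path to a CSV file).
#' @return The validated `data.frame` (invisibly usable downstream).
#' @export
validate_energy_table <- function(table) {
  if (is.character(table) && length(table) == 1L) table <- utils::read.csv(table)
  if (!is.data.frame(table)) stop("energy table must be a data.frame", call. = FALSE)
  required <- c("frame", "E_GS_eV", "E_CS_eV", "E_ES_eV")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop(sprintf("energy table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(table) == 0L) stop("energy table has no frames", call. = FALSE)
  for (col in required[-1L]) {
    bad <- which(!is.finite(table[[col]]))
    if (length(bad))
      stop(sprintf("non-finite value in column %s at row %d", col, bad[1L]),
           call. = FALSE)
  }
  if (anyDuplicated(table$frame))
    stop("duplicate frame indices in energy table", call. = FALSE)
  if (is.unsorted(table$frame, strictly = TRUE))
    stop("frame indices must be strictly increasing", call. = FALSE)
  table[required]
}

#' Write point placements as extended XYZ
#'
#' Element labels are a placeholder (`X`) since the points represent whole
#' molecules, not atoms.  An optional per-point charge column is appended,
#' which is the convention used for transition-charge site files.
#'
#' @param points `data.frame` with columns `x`, `y`, `z` (and optionally
#'   `charge`).
#' @param path Output path.
#' @param comment Comment line (second line of the XYZ file).
#' @param element Element label to write for each point.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(points, path, comment = "", element = "X") {
  stopifnot(is.data.frame(points), all(c("x", "y", "z") %in% names(points)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(points)), comment), con)
  if ("charge" %in% names(points)) {
    writeLines(sprintf("%s %.8f %.8f %.8f %.8f", element,
                       points$x, points$y, points$z, points$charge), con)
  } else {
    writeLines(sprintf("%s %.8f %.8f %.8f", element,
                       points$x, points$y, points$z), con)
  }
  invisible(path)
}

#' Read an (extended) XYZ file
#'
#' @param path File path.
#' @return A list with `comment` (the second line) and `points`, a
#'   `data.frame` with `element`, `x`, `y`, `z` and, when a fifth numeric
#'   column is present, `charge`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("first line of an XYZ file must be the atom count", call. = FALSE)
  if (length(lines) < n + 2L) stop("truncated XYZ file", call. = FALSE)
  body <- strsplit(trimws(lines[2L + seq_len(n)]), "\\s+")
  ncol <- unique(lengths(body))
  if (length(ncol) != 1L || !(ncol %in% c(4L, 5L)))
    stop("XYZ rows must have 4 or 5 whitespace-separated fields", call. = FALSE)
  m <- do.call(rbind, body)
  pts <- data.frame(element = m[, 1L],
                    x = as.numeric(m[, 2L]),
                    y = as.numeric(m[, 3L]),
                    z = as.numeric(m[, 4L]))
  if (ncol == 5L) pts$charge <- as.numeric(m[, 5L])
  list(comment = lines[2L], points = pts)
}
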