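## XYZ structure I/O and interatomic-distance reports.
##
## Standard chemical XYZ dialect: an atom-count line, a free-form comment
## line, then one "element x y z" row per atom (angstrom). Atom indices are
## 1-based at the user surface; a label-map sidecar (CSV with columns
## label,index) lets distances be requested by the atom labels used in
## mechanism narratives (O21, C6, ...) instead of raw indices.

#' Read a structure from an XYZ file or text
#'
#' @param con path to an XYZ file, or a character vector of its lines
#' @return object of class \code{xyz_structure}: list with \code{name}
#'   (the comment line) and \code{atoms} (data frame: element, x, y, z)
#' @export
read_xyz <- function(con) {
  lines <- if (length(con) == 1L && file.exists(con)) readLines(con) else con
  if (length(lines) < 2L) stop("XYZ parse error: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: invalid atom count")
  if (length(lines) < 2L + n)
    stop(sprintf("XYZ parse error: %d atoms declared but only %d atom lines",
                 n, max(0L, length(lines) - 2L)))
  atoms <- data.frame(element = character(n), x = numeric(n),
                      y = numeric(n), z = numeric(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)) || any(!is.finite(xyz)))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    atoms$element[i] <- tok[1]
    atoms[i, c("x", "y", "z")] <- xyz
  }
  structure(list(name = lines[2], atoms = atoms), class = "xyz_structure")
}

#' Write a structure to an XYZ file
#'
#' @param structure an \code{xyz_structure}
#' @param path output file path (or \code{NULL} to return the lines)
#' @param digits coordinate decimals (default 6)
#' @return invisibly, the lines written
#' @export
write_xyz <- function(structure, path = NULL, digits = 6) {
  stopifnot(inherits(structure, "xyz_structure"))
  a <- structure$atoms
  lines <- c(as.character(nrow(a)), structure$name,
             sprintf(paste0("%-3s %.", digits, "f %.", digits, "f %.",
                            digits, "f"),
                     a$element, a$x, a$y, a$z))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("XYZ structure \"%s\": %d atoms\n", x$name, nrow(x$atoms)))
  invisible(x)
}

.coords <- function(structure) as.matrix(structure$atoms[, c("x", "y", "z")])

#' Interatomic distance
#'
#' @param structure an \code{xyz_structure}
#' @param a,b 1-based atom indices (distinct)
#' @return Euclidean distance in angstrom
#' @export
atom_distance <- function(structure, a, b) {
  stopifnot(inherits(structure, "xyz_structure"))
  n <- nrow(structure$atoms)
  a <- as.integer(a); b <- as.integer(b)
  if (any(c(a, b) < 1L) || any(c(a, b) > n))
    stop("atom index out of range")
  if (a == b) stop("distance requires two distinct atoms")
  xyz <- .coords(structure)
  sqrt(sum((xyz[a, ] - xyz[b, ])^2))
}

#' Read a label-to-index sidecar map
#'
#' @param path CSV file with columns \code{label,index}
#' @return named integer vector mapping labels to 1-based indices
#' @export
read_label_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "index") %in% names(m)))
  stats::setNames(as.integer(m$index), m$label)
}

#' Distance report over atom pairs
#'
#' @param structure an \code{xyz_structure}
#' @param pairs two-column matrix or data frame of atom indices, or of atom
#'   labels when \code{label_map} is given; duplicated pairs are reported
#'   as requested, without deduplication
#' @param label_map optional named index vector from
#'   \code{\link{read_label_map}}
#' @return data frame with columns \code{label}, \code{a}, \code{b},
#'   \code{distance} (angstrom, rounded to 2 decimals to match narrative
#'   precision) and \code{distance_exact}
#' @export
geometry_report <- function(structure, pairs, label_map = NULL) {
  stopifnot(inherits(structure, "xyz_structure"))
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L)
    return(data.frame(label = character(0), a = integer(0), b = integer(0),
                      distance = numeric(0), distance_exact = numeric(0)))
  if (ncol(pairs) < 2L) stop("pairs must have two columns")
  la <- as.character(pairs[[1]]); lb <- as.character(pairs[[2]])
  if (!is.null(label_map)) {
    bad <- setdiff(c(la, lb), names(label_map))
    if (length(bad))
      stop("labels not in map: ", paste(unique(bad), collapse = ", "))
    ia <- label_map[la]; ib <- label_map[lb]
  } else {
    ia <- as.integer(la); ib <- as.integer(lb)
    if (any(is.na(ia)) || any(is.na(ib)))
      stop("pairs must be atom indices, or labels with a label_map")
  }
  d <- mapply(function(a, b) atom_distance(structure, a, b), ia, ib)
  data.frame(label = paste0("d(", la, "-", lb, ")"),
             a = unname(ia), b = unname(ib),
             distance = round(d, 2), distance_exact = unname(d),
             stringsAsFactors = FALSE)
}
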