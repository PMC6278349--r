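# Molecular coordinate container and readers (XYZ, PDB) for the ASA engine.

# Element symbols accepted by the readers. Covers main-group and common
# heteroatoms; extend via the radius table if ever needed.
.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Fe", "Zn", "Se", "Br", "Kr", "I", "Xe"
)

.normalize_element <- function(sym) {
  sym <- trimws(sym)
  ifelse(nchar(sym) == 0L, sym,
         paste0(toupper(substr(sym, 1L, 1L)),
                tolower(substr(sym, 2L, nchar(sym)))))
}

#' Construct a molecule
#'
#' A molecule is a named list with a `name` label and an `atoms` data frame
#' holding one row per atom: `element`, Cartesian `x`, `y`, `z` in Angstrom,
#' and a `radius` column (van der Waals radius, Angstrom) that is `NA` until
#' [assign_radii()] is called.
#'
#' @param name character label.
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinate vectors, Angstrom.
#' @param radius optional numeric vector of van der Waals radii, Angstrom.
#' @return An object of class `molecule`.
#' @examples
#' molecule("dimer", c("C", "C"), x = c(0, 5), y = c(0, 0), z = c(0, 0))
#' @export
molecule <- function(name, element, x, y, z, radius = NA_real_) {
  element <- .normalize_element(as.character(element))
  n <- length(element)
  if (n < 1L) stop("a molecule needs at least one atom", call. = FALSE)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (!all(is.finite(c(x, y, z)))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  bad <- setdiff(unique(element), .known_elements)
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cbind(x, y, z))) {
    stop("two atoms occupy identical positions", call. = FALSE)
  }
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      radius = rep_len(as.numeric(radius), n),
                      stringsAsFactors = FALSE)
  structure(list(name = as.character(name), atoms = atoms),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%s)\n", x$name, nrow(x$atoms),
              paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                    sort(table(x$atoms$element), decreasing = TRUE),
                    sep = "", collapse = " ")))
  invisible(x)
}

#' Read molecular coordinates from XYZ or PDB
#'
#' XYZ files follow the count/comment/records dialect: an integer atom count,
#' a free-text comment, then one `element x y z` record per atom. PDB files
#' are parsed with [bio3d::read.pdb()]; only the ATOM/HETATM coordinate fields
#' are used. Element symbols are normalized to standard capitalization and
#' validated; van der Waals radii are NOT read from the file (use
#' [assign_radii()]).
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guesses from the file extension.
#' @return A [molecule()].
#' @examples
#' xyz <- system.file("extdata", "geometries", "benzene.xyz",
#'                    package = "hydrodecomp")
#' mol <- read_coordinates(xyz)
#' table(mol$atoms$element)
#' @export
read_coordinates <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  switch(format, xyz = .read_xyz(path), pdb = .read_pdb(path))
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("XYZ header is not a positive atom count: '", lines[1L], "'",
         call. = FALSE)
  }
  body <- lines[-c(1L, 2L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("XYZ declares %d atoms but has %d record lines", n,
                 length(body)), call. = FALSE)
  }
  fields <- strsplit(trimws(body), "\\s+")
  bad_len <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad_len) > 0L) {
    stop("malformed XYZ record at body line ", bad_len[1L], call. = FALSE)
  }
  el <- .normalize_element(vapply(fields, `[`, "", 1L))
  unknown <- which(!(el %in% .known_elements))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol '%s' at body line %d",
                 el[unknown[1L]], unknown[1L]), call. = FALSE)
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
    if (anyNA(v)) {
      stop("non-numeric coordinate at body line ", which(is.na(v))[1L],
           call. = FALSE)
    }
    v
  }
  molecule(name = tools::file_path_sans_ext(basename(path)),
           element = el, x = num(2L), y = num(3L), z = num(4L))
}

.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) < 1L) stop("PDB has no ATOM/HETATM records: ", path,
                          call. = FALSE)
  el <- at$elesy
  # fall back to the first letter(s) of the atom name when the element
  # column is blank (common in minimal files)
  miss <- is.na(el) | !nzchar(trimws(el))
  el[miss] <- gsub("[^A-Za-z].*$", "", trimws(at$elety[miss]))
  molecule(name = tools::file_path_sans_ext(basename(path)),
           element = el, x = at$x, y = at$y, z = at$z)
}

#' Bondi van der Waals radii
#'
#' Default radius set (Angstrom) used by [assign_radii()]: the Bondi
#' compilation values for the elements this package commonly meets
#' (C 1.70, H 1.20, N 1.55, O 1.52, F 1.47, P 1.80, S 1.80, Cl 1.75,
#' Br 1.85, I 1.98, plus noble gases and Si).
#'
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @examples
#' bondi_radii()[c("C", "H")]
#' @export
bondi_radii <- function() {
  c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
    Br = 1.85, Kr = 2.02, Se = 1.90, I = 1.98, Xe = 2.16)
}

#' Assign van der Waals radii to a molecule
#'
#' @param mol a [molecule()].
#' @param radii named numeric vector mapping element symbol to radius
#'   (Angstrom); defaults to [bondi_radii()]. Every element present in the
#'   molecule must appear in the table.
#' @return The molecule with its `radius` column filled; atom order preserved.
#' @examples
#' mol <- make_fixture_geometry("benzene")
#' mol <- assign_radii(mol)
#' unique(mol$atoms[, c("element", "radius")])
#' @export
assign_radii <- function(mol, radii = bondi_radii()) {
  stopifnot(inherits(mol, "molecule"))
  if (length(radii) == 0L) stop("radius table is empty", call. = FALSE)
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
    stop("radius table must be a named vector (element -> Angstrom)",
         call. = FALSE)
  }
  radii <- setNames(as.numeric(radii), .normalize_element(names(radii)))
  missing <- setdiff(unique(mol$atoms$element), names(radii))
  if (length(missing) > 0L) {
    stop("no radius for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("radii must be finite and positive", call. = FALSE)
  }
  mol$atoms$radius <- unname(radii[mol$atoms$element])
  mol
}

#' Read a two-column radius table
#'
#' Plain-text table with two whitespace- or comma-separated columns
#' (element symbol, radius in Angstrom); `#` lines are comments.
#'
#' @param path file path.
#' @return Named numeric vector usable as the `radii` argument of
#'   [assign_radii()].
#' @export
read_radius_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("radius table is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "[,\\s]+")
  if (any(vapply(parts, length, 1L) < 2L)) {
    stop("radius table rows need two columns: element, Angstrom",
         call. = FALSE)
  }
  el <- .normalize_element(vapply(parts, `[`, "", 1L))
  r <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(r)) stop("non-numeric radius in table: ", path, call. = FALSE)
  setNames(r, el)
}
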