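## Shared domain types and I/O: molecular geometries (XYZ), scalar-field
## grids (Gaussian cube), solvent media with radical-cycle reference
## enthalpies, and the delimited summary-table ingestion format.

# symbol -> atomic number, H through Ar (covers every element the
# analyses touch; extend here if heavier atoms are ever needed)
.element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
  Cl = 17, Ar = 18
)

#' Construct a molecular geometry
#'
#' A light container for an ordered list of atoms with optional named
#' fragment annotations (used by the IGM intra/inter interaction split).
#'
#' @param elements character vector of chemical symbols (H, C, N, O, ...).
#' @param coords numeric matrix, n x 3, Cartesian coordinates in Angstrom.
#' @param name molecule label.
#' @param fragments optional named list of integer vectors of 1-based atom
#'   indices; fragments must not overlap.
#' @return an object of class `molecule_geometry` with components
#'   `name`, `elements`, `coords` (Angstrom) and `fragments`.
#' @export
molecule_geometry <- function(elements, coords, name = "molecule",
                              fragments = NULL) {
  coords <- as.matrix(coords)
  if (length(elements) == 0L && nrow(coords) == 0L) {
    coords <- matrix(numeric(0), 0L, 3L)
  }
  if (ncol(coords) != 3L || nrow(coords) != length(elements))
    stop("coords must be an n x 3 matrix matching length(elements)")
  elements <- as.character(elements)
  bad <- setdiff(unique(elements), names(.element_numbers))
  if (length(bad))
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  if (!is.null(fragments)) {
    fragments <- lapply(fragments, as.integer)
    idx <- unlist(fragments, use.names = FALSE)
    if (anyDuplicated(idx))
      stop("fragments overlap: atom indices must partition disjoint sets")
    if (length(idx) && (min(idx) < 1L || max(idx) > length(elements)))
      stop("fragment atom index out of range")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(name = name, elements = elements, coords = coords,
                 fragments = fragments),
            class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat(sprintf("molecule_geometry '%s': %d atoms (%s)\n", x$name,
              length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = " ")))
  if (!is.null(x$fragments))
    cat("  fragments:", paste(sprintf("%s[%d]", names(x$fragments),
                                      lengths(x$fragments)),
                              collapse = " "), "\n")
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ convention: an atom-count line, a comment line, then one
#' `element x y z` row per atom in Angstrom. Atom indices are assigned in
#' file order starting at 1.
#'
#' @param path file path.
#' @return a [molecule_geometry()]; the comment line becomes the name when
#'   non-empty.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ format error: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L)
    stop("XYZ format error: first line must be the atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop(sprintf("XYZ format error: declared %d atoms but found %d rows",
                 n, length(body)))
  body <- body[seq_len(n)]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop(sprintf("XYZ format error at atom line %d: need 'El x y z'", i))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ format error at atom line %d: unparseable coordinate",
                   i))
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  nm <- trimws(lines[2L])
  molecule_geometry(elements, coords,
                    name = if (nzchar(nm)) nm else "molecule")
}

#' Write an XYZ geometry file
#'
#' @param geometry a [molecule_geometry()].
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return invisibly, `path`.
#' @export
write_xyz <- function(geometry, path, digits = 8) {
  n <- length(geometry$elements)
  rows <- sprintf(paste0("%-2s %", digits + 6, ".", digits, "f %",
                         digits + 6, ".", digits, "f %",
                         digits + 6, ".", digits, "f"),
                  geometry$elements, geometry$coords[, 1L],
                  geometry$coords[, 2L], geometry$coords[, 3L])
  writeLines(c(as.character(n), geometry$name, rows), path)
  invisible(path)
}

#' Construct a regular 3-D scalar field
#'
#' @param origin numeric 3-vector, Bohr.
#' @param spacing numeric 3-vector of positive voxel steps, Bohr.
#' @param dims integer 3-vector of grid dimensions.
#' @param values numeric vector or array of `prod(dims)` scalar values,
#'   stored z-fastest (the cube-file ordering).
#' @param quantity label for the stored quantity.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(origin, spacing, dims, values, quantity = "rho") {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  if (length(origin) != 3L || length(spacing) != 3L || length(dims) != 3L)
    stop("origin, spacing and dims must have length 3")
  if (any(spacing <= 0)) stop("spacing components must be positive")
  if (any(dims < 1L)) stop("dims must be positive")
  values <- as.numeric(values)
  if (length(values) != prod(dims))
    stop(sprintf("grid_field contract error: %d values for dims %s (need %d)",
                 length(values), paste(dims, collapse = "x"), prod(dims)))
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values, quantity = quantity),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field '%s': %s voxels, spacing (%s) Bohr\n", x$quantity,
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Grid point coordinates of a field (z-fastest order, Bohr)
#'
#' @param field a [grid_field()] or a list with `origin`, `spacing`, `dims`.
#' @return numeric matrix `prod(dims)` x 3.
#' @export
grid_points <- function(field) {
  d <- field$dims
  ix <- rep(seq_len(d[1L]) - 1L, each = d[2L] * d[3L])
  iy <- rep(rep(seq_len(d[2L]) - 1L, each = d[3L]), times = d[1L])
  iz <- rep(seq_len(d[3L]) - 1L, times = d[1L] * d[2L])
  cbind(x = field$origin[1L] + ix * field$spacing[1L],
        y = field$origin[2L] + iy * field$spacing[2L],
        z = field$origin[3L] + iz * field$spacing[3L])
}

#' Write a scalar field as a Gaussian cube file
#'
#' Follows the cube convention: two comment lines; atom count + origin;
#' three voxel-vector lines; one line per atom (atomic number, charge,
#' position in Bohr); values in z-fastest order, six per line, scientific
#' notation. Geometry coordinates (Angstrom) are converted to Bohr.
#'
#' @param field a [grid_field()].
#' @param geometry a [molecule_geometry()]; may be empty.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cube <- function(field, geometry, path) {
  stopifnot(inherits(field, "grid_field"))
  n_at <- length(geometry$elements)
  hdr <- c(sprintf("reactikit cube: %s", field$quantity),
           "generated by write_cube",
           sprintf("%5d %11.6f %11.6f %11.6f", n_at,
                   field$origin[1L], field$origin[2L], field$origin[3L]),
           sprintf("%5d %11.6f %11.6f %11.6f", field$dims[1L],
                   field$spacing[1L], 0, 0),
           sprintf("%5d %11.6f %11.6f %11.6f", field$dims[2L],
                   0, field$spacing[2L], 0),
           sprintf("%5d %11.6f %11.6f %11.6f", field$dims[3L],
                   0, 0, field$spacing[3L]))
  at_lines <- character(0)
  if (n_at > 0L) {
    z <- .element_numbers[geometry$elements]
    pos <- convert_length(geometry$coords, "angstrom", "bohr")
    at_lines <- sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                        z, z, pos[, 1L], pos[, 2L], pos[, 3L])
  }
  v <- field$values
  v[!is.finite(v)] <- 0  # masked voxels serialize as 0
  padded <- c(v, rep(0, (6 - length(v) %% 6) %% 6))
  mat <- matrix(sprintf("%13.5E", padded), ncol = 6L, byrow = TRUE)
  val_lines <- apply(mat, 1L, paste, collapse = " ")
  # drop padding on the final line
  extra <- (6 - length(v) %% 6) %% 6
  if (extra > 0L) {
    last <- sprintf("%13.5E", v[(length(v) - (6 - extra) + 1L):length(v)])
    val_lines[length(val_lines)] <- paste(last, collapse = " ")
  }
  writeLines(c(hdr, at_lines, val_lines), path)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Counterpart of [write_cube()], used for round-trip verification.
#'
#' @param path cube file path.
#' @return list with `field` (a [grid_field()]) and `geometry`
#'   (a [molecule_geometry()], coordinates back-converted to Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1L]])
  l3 <- num(lines[3L]); n_at <- as.integer(l3[1L]); origin <- l3[2:4]
  vx <- num(lines[4L]); vy <- num(lines[5L]); vz <- num(lines[6L])
  dims <- as.integer(c(vx[1L], vy[1L], vz[1L]))
  spacing <- c(vx[2L], vy[3L], vz[4L])
  elements <- character(0); coords <- matrix(numeric(0), 0L, 3L)
  if (n_at > 0L) {
    at <- t(vapply(lines[7:(6 + n_at)], num, numeric(5)))
    sym <- names(.element_numbers)[match(as.integer(at[, 1L]),
                                         .element_numbers)]
    elements <- sym
    coords <- convert_length(at[, 3:5, drop = FALSE], "bohr", "angstrom")
  }
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(7L + n_at):length(lines)]), "[[:space:]]+")))
  vals <- vals[seq_len(prod(dims))]
  list(field = grid_field(origin, spacing, dims, vals,
                          quantity = sub("^reactikit cube: ", "", lines[1L])),
       geometry = molecule_geometry(elements, coords, name = "from_cube"))
}

## ---- media ------------------------------------------------------------

#' Define a solvent medium with radical-cycle reference enthalpies
#'
#' A medium carries a dielectric constant and the reference enthalpies of
#' the hydrogen atom, electron and proton in that medium (kcal/mol), which
#' close the HAT/SET-PT/SPLET thermodynamic cycle.
#'
#' @param name medium label; matched case-insensitively after trimming.
#' @param dielectric relative permittivity (> 0).
#' @param H_hydrogen,H_electron,H_proton reference enthalpies of H., e-
#'   and H+ in kcal/mol; all three `NA` is allowed (cycle identities that
#'   need no references remain checkable).
#' @return an object of class `rk_medium`.
#' @export
medium <- function(name, dielectric, H_hydrogen = NA_real_,
                   H_electron = NA_real_, H_proton = NA_real_) {
  if (!is.finite(dielectric) || dielectric <= 0)
    stop("dielectric must be positive")
  structure(list(name = trimws(name), dielectric = dielectric,
                 H_hydrogen = H_hydrogen, H_electron = H_electron,
                 H_proton = H_proton),
            class = "rk_medium")
}

#' Built-in media table
#'
#' The seven media of the study with their dielectric constants. Gas-phase
#' reference enthalpies are the commonly accepted values H(H.) = -312.30,
#' H(e-) = 0.75 and H(H+) = 1.48 kcal/mol; solvent references come from the
#' literature and must be supplied by the user (they are `NA` here).
#'
#' @return named list of [medium()] objects keyed by lower-case name.
#' @export
default_media <- function() {
  m <- list(
    medium("gas",         1.00, -312.30, 0.75, 1.48),
    medium("benzene",     2.27),
    medium("acetic acid", 6.25),
    medium("lactic acid", 22.00),
    medium("ethanol",     24.85),
    medium("formic acid", 51.1),
    medium("water",       78.35)
  )
  stats::setNames(m, vapply(m, function(x) tolower(x$name), ""))
}

#' Resolve a medium by name
#'
#' @param name medium label (case-insensitive, trimmed).
#' @param media named list of [medium()] objects; defaults to
#'   [default_media()].
#' @param require_refs error unless all three reference enthalpies are set.
#' @return the matching `rk_medium`.
#' @export
resolve_medium <- function(name, media = default_media(),
                           require_refs = FALSE) {
  if (inherits(name, "rk_medium")) {
    m <- name
  } else {
    key <- tolower(trimws(name))
    if (!key %in% names(media))
      stop(sprintf("unknown medium '%s'; supply it via `media` with its %s",
                   name, "dielectric and reference enthalpies"))
    m <- media[[key]]
  }
  if (require_refs &&
      !all(is.finite(c(m$H_hydrogen, m$H_electron, m$H_proton))))
    stop(sprintf(
      "medium '%s' has no reference enthalpies configured (H(H.), H(e-), H(H+))",
      m$name))
  m
}

## ---- summary tables ---------------------------------------------------

#' Read a typed electronic-structure summary table
#'
#' The supported ingestion format is delimited text (tab or comma) with a
#' small key-value header of `#!` directives declaring the table kind and
#' its unit, followed by a column header line and data rows, e.g.
#' \preformatted{
#' #! table: orbitals
#' #! unit: eV
#' molecule  medium  homo  lumo
#' Neu5Gc    gas     -8.900  0.753
#' }
#' Recognized kinds and their required columns:
#' \describe{
#'   \item{orbitals}{`molecule, medium, homo, lumo` (unit eV)}
#'   \item{charges}{`molecule, medium, atom, q_n, q_nm1, q_np1` (unit e)}
#'   \item{enthalpies}{`molecule, medium, site, h_parent, h_cation,
#'     h_radical, h_anion` (unit kcal/mol)}
#'   \item{bcp}{`molecule, medium, bond, rho, lap, v, g` (unit a.u.)}
#' }
#'
#' @param path file path.
#' @param media named list of [medium()] objects used to validate medium
#'   labels; unknown media are rejected.
#' @return a data.frame of typed records with attributes `table_kind` and
#'   `unit`.
#' @export
read_summary_tables <- function(path, media = default_media()) {
  lines <- readLines(path, warn = FALSE)
  is_directive <- grepl("^#!", lines)
  kv <- list()
  for (d in lines[is_directive]) {
    m <- regmatches(d, regexec("^#!\\s*([^:]+):\\s*(.*)$", d))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  if (is.null(kv$table))
    stop("summary table error: missing '#! table:' directive")
  if (is.null(kv$unit))
    stop("unit error: missing '#! unit:' directive")
  kind <- tolower(kv$table)
  expected_unit <- c(orbitals = "ev", charges = "e",
                     enthalpies = "kcal/mol", bcp = "a.u.")
  if (!kind %in% names(expected_unit))
    stop("summary table error: unknown table kind '", kind, "'")
  if (tolower(kv$unit) != expected_unit[[kind]])
    stop(sprintf("unit error: table kind '%s' requires unit '%s', got '%s'",
                 kind, expected_unit[[kind]], kv$unit))
  body <- lines[!is_directive]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE,
                          strip.white = TRUE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  required <- switch(kind,
    orbitals   = c("molecule", "medium", "homo", "lumo"),
    charges    = c("molecule", "medium", "atom", "q_n", "q_nm1", "q_np1"),
    enthalpies = c("molecule", "medium", "site", "h_parent", "h_cation",
                   "h_radical", "h_anion"),
    bcp        = c("molecule", "medium", "bond", "rho", "lap", "v", "g"))
  missing_col <- setdiff(required, names(df))
  if (length(missing_col))
    stop("schema error: missing required column(s): ",
         paste(missing_col, collapse = ", "))
  if (nrow(df) > 0L) {
    for (med in unique(df$medium)) resolve_medium(med, media)
    if (kind == "enthalpies")
      for (med in unique(df$medium))
        resolve_medium(med, media, require_refs = TRUE)
  }
  attr(df, "table_kind") <- kind
  attr(df, "unit") <- kv$unit
  df
}
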