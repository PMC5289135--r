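#' Conformer structures and datasets
#'
#' A *conformer* is one molecular configuration: an ordered vector of element
#' symbols, an `n x 3` matrix of Cartesian coordinates in Angstrom, and an
#' optional named list of scalar properties (for example `energy`, in eV).
#' A *conformer set* is an ordered list of conformers; the order is stable
#' and defines the row/column indices of every matrix computed from it.
#'
#' Atom indexing is 1-based throughout the package, following R convention.
#'
#' @param id Character label, unique within a dataset.
#' @param species Character vector of element symbols.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param properties Named list of scalar properties.
#' @return `conformer()` returns an object of class `"conformer"`;
#'   `conformer_set()` an object of class `"conformer_set"`.
#' @examples
#' s <- conformer("water", c("O", "H", "H"),
#'                rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' ds <- conformer_set(list(s))
#' @export
conformer <- function(id, species, coords, properties = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!is.character(species) || length(species) == 0) {
    abort("`species` must be a non-empty character vector.")
  }
  if (ncol(coords) != 3 || nrow(coords) != length(species)) {
    abort("`coords` must be an n x 3 matrix matching length(species).")
  }
  if (any(!is.finite(coords))) {
    abort("all coordinates must be finite.")
  }
  structure(
    list(id = as.character(id), species = species, coords = coords,
         properties = as.list(properties)),
    class = "conformer"
  )
}

#' @param structures List of `conformer` objects.
#' @param name Dataset label.
#' @rdname conformer
#' @export
conformer_set <- function(structures, name = "dataset") {
  if (!length(structures) || !all(vapply(structures, inherits, logical(1), "conformer"))) {
    abort("`structures` must be a non-empty list of conformer objects.")
  }
  ids <- vapply(structures, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate structure id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(structures = structures, name = as.character(name)),
            class = "conformer_set")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms (%s)\n", x$id, length(x$species),
              paste(unique(x$species), collapse = ", ")))
  if (length(x$properties)) {
    cat("  properties:",
        paste(sprintf("%s=%g", names(x$properties), unlist(x$properties)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> '%s': %d structures\n", x$name, length(x$structures)))
  invisible(x)
}

#' @export
length.conformer_set <- function(x) length(x$structures)

#' Structure ids of a conformer set
#' @param dataset A `conformer_set`.
#' @return Character vector of ids in dataset order.
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$structures, function(s) s$id, character(1))
}

#' Per-structure properties as a tibble
#'
#' @param dataset A `conformer_set`.
#' @return A tibble with one row per structure: `id` plus one column per
#'   property key present anywhere in the set (NA where absent).
#' @export
dataset_properties <- function(dataset) {
  keys <- unique(unlist(lapply(dataset$structures, function(s) names(s$properties))))
  out <- tibble(id = dataset_ids(dataset))
  for (k in keys) {
    out[[k]] <- vapply(dataset$structures, function(s) {
      v <- s$properties[[k]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  out
}

# ---------------------------------------------------------------------------
# Extended-XYZ I/O.
#
# Dialect: the comment line carries whitespace-separated key=value pairs.
# Values that parse as floats become scalar properties; any other pair is
# preserved verbatim and re-emitted on write.

parse_comment <- function(line) {
  tokens <- strsplit(trimws(line), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  kv <- grepl("=", tokens, fixed = TRUE)
  props <- list()
  extras <- character(0)
  for (tok in tokens[kv]) {
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) props[[key]] <- num else extras[key] <- val
  }
  list(props = props, extras = extras, free = tokens[!kv])
}

#' Read an extended-XYZ file
#'
#' Reads concatenated extended-XYZ frames: an atom-count line, a comment line
#' holding optional whitespace-separated `key=value` pairs, then one line per
#' atom (`symbol x y z`). Scalar float values on the comment line are parsed
#' as per-structure properties; non-numeric pairs are kept and round-tripped
#' by [write_xyz()].
#'
#' @param path Path to the file.
#' @param property_keys Character vector of property keys to require-parse
#'   when present (any numeric `key=value` pair is parsed regardless).
#' @param name Dataset name; defaults to the file name.
#' @return A [conformer_set()].
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path, property_keys = "energy", name = NULL) {
  lines <- readLines(path)
  structures <- list()
  pos <- 1L
  frame <- 0L
  n_lines <- length(lines)
  while (pos <= n_lines && nzchar(trimws(lines[pos]))) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0) {
      abort(sprintf("frame %d: invalid atom-count line '%s'.", frame, lines[pos]))
    }
    if (pos + 1L + nat > n_lines) {
      abort(sprintf("frame %d: file truncated (%d atom lines expected).", frame, nat))
    }
    parsed <- parse_comment(lines[pos + 1L])
    atoms <- lines[(pos + 2L):(pos + 1L + nat)]
    fields <- strsplit(trimws(atoms), "\\s+")
    if (any(lengths(fields) < 4L)) {
      abort(sprintf("frame %d: atom line with fewer than 4 fields.", frame))
    }
    species <- vapply(fields, `[`, character(1), 1L)
    xyz <- t(vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(v)) abort(sprintf("frame %d: unparsable coordinate.", frame))
      v
    }, numeric(3)))
    id <- if (!is.null(parsed$extras["id"]) && !is.na(parsed$extras["id"])) {
      unname(parsed$extras["id"])
    } else if (!is.null(parsed$props[["id"]])) {
      as.character(parsed$props[["id"]])
    } else {
      sprintf("frame_%04d", frame)
    }
    parsed$props[["id"]] <- NULL
    s <- conformer(id, species, xyz, parsed$props)
    extras <- parsed$extras[names(parsed$extras) != "id"]
    if (length(extras)) attr(s, "extras") <- extras
    structures[[frame]] <- s
    pos <- pos + 2L + nat
    while (pos <= n_lines && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(structures)) abort("no frames found in file.")
  missing_req <- setdiff(property_keys, Reduce(union, lapply(structures, function(s) names(s$properties))))
  if (length(missing_req) && length(property_keys)) {
    # requested keys absent everywhere is allowed; properties stay absent
  }
  conformer_set(structures, name = name %||% basename(path))
}

#' Write an extended-XYZ file
#'
#' Inverse of [read_xyz()]: one frame per structure, numeric properties and
#' preserved non-numeric `key=value` pairs on the comment line, coordinates
#' printed with enough digits to round-trip within 1e-8 Angstrom.
#'
#' @param dataset A [conformer_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in dataset$structures) {
    cat(length(s$species), "\n", sep = "", file = con)
    kv <- c(sprintf("id=%s", s$id),
            if (length(s$properties)) {
              sprintf("%s=%.10g", names(s$properties), unlist(s$properties))
            },
            if (!is.null(attr(s, "extras"))) {
              sprintf("%s=%s", names(attr(s, "extras")), attr(s, "extras"))
            })
    cat(paste(kv, collapse = " "), "\n", sep = "", file = con)
    for (a in seq_along(s$species)) {
      cat(sprintf("%s %.10f %.10f %.10f\n", s$species[a],
                  s$coords[a, 1], s$coords[a, 2], s$coords[a, 3]), file = con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Geometric order parameters.

#' Signed dihedral angle
#'
#' Torsion of atoms `i-j-k-l` about the `j-k` axis, IUPAC sign convention
#' (looking from j towards k, a clockwise rotation of the far bond is
#' positive). Used for backbone angles such as phi, psi, omega1, omega2 once
#' the user supplies the defining atom quadruple.
#'
#' @param s A [conformer()].
#' @param i,j,k,l Distinct 1-based atom indices.
#' @return Angle in degrees, in (-180, 180].
#' @export
dihedral <- function(s, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) abort("dihedral indices must be distinct.")
  if (any(idx < 1L) || any(idx > nrow(s$coords))) abort("atom index out of range.")
  r <- s$coords[idx, , drop = FALSE]
  b1 <- r[2, ] - r[1, ]
  b2 <- r[3, ] - r[2, ]
  b3 <- r[4, ] - r[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    abort("torsion undefined: collinear atoms.")
  }
  u2 <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * u2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Minimum distance between two atom groups
#'
#' The minimum over all cross pairs of the Euclidean distance, e.g. the
#' D_ON, D_H and D_CN contact parameters used to interpret conformer maps.
#'
#' @param s A [conformer()].
#' @param groupA,groupB Non-empty, disjoint vectors of 1-based atom indices.
#' @return Minimum distance in Angstrom.
#' @export
min_group_distance <- function(s, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) abort("groups must be non-empty.")
  if (length(intersect(groupA, groupB))) abort("groups must be disjoint.")
  n <- nrow(s$coords)
  if (any(c(groupA, groupB) < 1L) || any(c(groupA, groupB) > n)) {
    abort("atom index out of range.")
  }
  a <- s$coords[groupA, , drop = FALSE]
  b <- s$coords[groupB, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}
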