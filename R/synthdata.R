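# Synthetic torsional-basin conformer generator.
#
# Emulates the statistical structure of real conformer databases: a small
# chain molecule whose two rotatable torsions sit in well-separated basins
# (the cis/trans-like bimodality that dominates peptide landscapes), plus a
# smooth torsional energy model, rare planted outliers, and an optional
# energy-inconsistent subset for exercising the consistency screen.

default_chain_template <- function() {
  # internal-coordinate (z-matrix) rows; bond in Angstrom, angles/torsions
  # in degrees; torsion NA marks the rotatable basin torsions, in order
  data.frame(
    species = c("C", "C", "N", "C", "C", "O", "H", "H"),
    ref_i = c(NA, 1, 2, 3, 4, 5, 1, 6),
    ref_j = c(NA, NA, 1, 2, 3, 4, 2, 5),
    ref_k = c(NA, NA, NA, 1, 2, 3, 3, 4),
    bond = c(NA, 1.52, 1.45, 1.40, 1.52, 1.43, 1.09, 0.96),
    angle = c(NA, NA, 112, 112, 112, 109, 109.5, 107),
    torsion = c(NA, NA, NA, NA, NA, 180, 60, 180),
    rotatable = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Specification for the synthetic conformer generator
#'
#' The defaults define a 200-structure, two-basin dataset: basin torsion
#' centers (180, 180) and (0, 180) degrees (a trans/trans versus cis/trans
#' pair), Gaussian torsional noise of 5 degrees, an 8-atom C/C/N/C/C/O+2H
#' chain template, and the energy model
#' `E = basin_offset + sum_t k (1 - cos(theta_t - theta0_t)) + N(0, noise)`
#' with `k = 0.3` eV, basin offsets `(0, 0.1)` eV and 0.02 eV noise.
#' `outlier_fraction` plants conformers whose torsions are far from every
#' basin center; `inconsistent_fraction` adds a constant energy offset
#' (default 1.0 eV) to a random subset, mimicking data generated at a
#' different level of theory slipping into a database.
#'
#' @param n_structures Number of conformers.
#' @param n_basins Number of torsional basins (>= 1).
#' @param torsion_centers List of length-2 numeric vectors (degrees), one
#'   per basin.
#' @param torsion_noise Gaussian torsional noise SD in degrees (> 0).
#' @param chain_template Z-matrix data frame (see source) defining the
#'   molecule; rows marked `rotatable` carry the basin torsions.
#' @param basin_offsets Energy offset per basin, eV.
#' @param torsion_k Harmonic-cosine stiffness, eV.
#' @param energy_noise Energy noise SD, eV.
#' @param outlier_fraction Fraction of planted outliers in `[0, 1)`.
#' @param inconsistent_fraction Fraction given the constant energy offset.
#' @param inconsistent_offset The constant offset, eV.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_structures = 200L,
                           n_basins = 2L,
                           torsion_centers = list(c(180, 180), c(0, 180)),
                           torsion_noise = 5,
                           chain_template = default_chain_template(),
                           basin_offsets = c(0, 0.1),
                           torsion_k = 0.3,
                           energy_noise = 0.02,
                           outlier_fraction = 0,
                           inconsistent_fraction = 0,
                           inconsistent_offset = 1.0,
                           seed = 1L) {
  if (n_basins < 1) abort("`n_basins` must be >= 1.")
  if (torsion_noise <= 0) abort("`torsion_noise` must be > 0.")
  if (outlier_fraction < 0 || outlier_fraction >= 1 ||
      inconsistent_fraction < 0 || inconsistent_fraction >= 1) {
    abort("fractions must lie in [0, 1).")
  }
  if (length(torsion_centers) < n_basins) {
    abort("`torsion_centers` must supply one center per basin.")
  }
  if (length(basin_offsets) < n_basins) {
    basin_offsets <- rep_len(basin_offsets, n_basins)
  }
  structure(
    list(n_structures = as.integer(n_structures), n_basins = as.integer(n_basins),
         torsion_centers = torsion_centers[seq_len(n_basins)],
         torsion_noise = torsion_noise, chain_template = chain_template,
         basin_offsets = basin_offsets[seq_len(n_basins)],
         torsion_k = torsion_k, energy_noise = energy_noise,
         outlier_fraction = outlier_fraction,
         inconsistent_fraction = inconsistent_fraction,
         inconsistent_offset = inconsistent_offset, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(
    "<generator_spec> %d structures, %d basins, noise %g deg, seed %d\n",
    x$n_structures, x$n_basins, x$torsion_noise, x$seed))
  invisible(x)
}

# Place one atom X given bonded ref A, angle ref B, torsion ref C such that
# |X-A| = bond, angle X-A-B = ang, dihedral X-A-B-C = tor (degrees).
place_atom <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  ab <- A - B
  ab <- ab / sqrt(sum(ab^2))
  cb <- B - C
  n <- cross3(cb, ab)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) abort("degenerate z-matrix reference (collinear atoms).")
  n <- n / nn
  m <- cross3(n, ab)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  A + d[1] * ab + d[2] * m + d[3] * n
}

build_chain <- function(template, rot_torsions) {
  n <- nrow(template)
  coords <- matrix(0, n, 3)
  tors <- template$torsion
  tors[template$rotatable] <- rot_torsions
  for (a in seq_len(n)) {
    if (a == 1) {
      coords[a, ] <- c(0, 0, 0)
    } else if (a == 2) {
      coords[a, ] <- c(template$bond[a], 0, 0)
    } else if (a == 3) {
      # first three atoms span the xy-plane
      th <- template$angle[a] * pi / 180
      A <- coords[template$ref_i[a], ]
      u <- coords[template$ref_j[a], ] - A
      u <- u / sqrt(sum(u^2))
      coords[a, ] <- A + template$bond[a] * (cos(th) * u + sin(th) * c(0, 1, 0))
    } else {
      coords[a, ] <- place_atom(coords[template$ref_i[a], ],
                                coords[template$ref_j[a], ],
                                coords[template$ref_k[a], ],
                                template$bond[a], template$angle[a], tors[a])
    }
  }
  coords
}

# circular distance in degrees
circ_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# torsion tuple maximizing the minimum circular distance to all centers
far_torsions <- function(centers) {
  grid <- seq(-175, 180, by = 5)
  vapply(seq_along(centers[[1]]), function(t) {
    scores <- vapply(grid, function(g) {
      min(vapply(centers, function(ct) circ_dist(g, ct[t]), numeric(1)))
    }, numeric(1))
    grid[which.max(scores)]
  }, numeric(1))
}

torsional_energy <- function(theta, theta0, k) {
  sum(k * (1 - cos((theta - theta0) * pi / 180)))
}

#' Generate a labeled synthetic conformer dataset
#'
#' Builds each conformer by placing the chain template with its rotatable
#' torsions at the assigned basin center plus Gaussian noise; computes
#' energies from the torsional energy model; plants outliers (torsions far
#' from every center) and an energy-inconsistent subset.  Geometries with
#' any interatomic distance below 0.5 Angstrom are resampled (error after
#' 100 attempts).  Fully reproducible from `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A list with `dataset` (a [conformer_set()], energies attached as
#'   the `energy` property) and `truth`, a tibble
#'   `id, basin, is_outlier, is_inconsistent, energy, tau1, tau2`
#'   (`basin` is `NA` for outliers).
#' @export
generate_conformers <- function(spec) {
  template <- spec$chain_template
  n_rot <- sum(template$rotatable)
  centers <- lapply(spec$torsion_centers, function(x) rep_len(x, n_rot))
  with_local_seed(spec$seed, {
    n <- spec$n_structures
    n_out <- round(spec$outlier_fraction * n)
    basin <- sample(rep_len(seq_len(spec$n_basins), n))
    out_idx <- if (n_out > 0) sample(n, n_out) else integer(0)
    basin[out_idx] <- NA_integer_
    inconsistent <- runif(n) < spec$inconsistent_fraction
    far <- if (n_out > 0) far_torsions(centers) else NULL
    structures <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      center <- if (is.na(basin[i])) far else centers[[basin[i]]]
      for (try in seq_len(100)) {
        tors <- center + rnorm(n_rot, sd = spec$torsion_noise)
        coords <- build_chain(template, tors)
        dmin <- min(stats::dist(coords))
        if (dmin >= 0.5) break
        if (try == 100) abort("could not generate a clash-free geometry.")
      }
      e_tors <- if (is.na(basin[i])) {
        min(vapply(seq_len(spec$n_basins), function(b) {
          spec$basin_offsets[b] + torsional_energy(tors, centers[[b]], spec$torsion_k)
        }, numeric(1)))
      } else {
        spec$basin_offsets[basin[i]] +
          torsional_energy(tors, centers[[basin[i]]], spec$torsion_k)
      }
      energy <- e_tors + rnorm(1, sd = spec$energy_noise) +
        if (inconsistent[i]) spec$inconsistent_offset else 0
      id <- sprintf("conf_%04d", i)
      structures[[i]] <- conformer(id, template$species, coords,
                                   list(energy = energy))
      truth_rows[[i]] <- tibble(
        id = id, basin = basin[i], is_outlier = i %in% out_idx,
        is_inconsistent = inconsistent[i], energy = energy,
        tau1 = tors[1], tau2 = if (n_rot > 1) tors[2] else NA_real_
      )
    }
    list(dataset = conformer_set(structures, name = "synthetic_basins"),
         truth = dplyr::bind_rows(truth_rows))
  })
}

#' Write a synthetic dataset and its ground-truth sidecar
#'
#' @param gen Output of [generate_conformers()].
#' @param xyz_path Extended-XYZ output path (energies in the comment line).
#' @param truth_path TSV path for the truth labels/flags.
#' @return `xyz_path`, invisibly.
#' @export
write_synthetic <- function(gen, xyz_path, truth_path) {
  write_xyz(gen$dataset, xyz_path)
  write.table(gen$truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(xyz_path)
}
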