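#' SOAP descriptor parameters
#'
#' Hyperparameters of the smooth-overlap atomic-environment descriptor.
#' The atom-centered neighbor density is a sum of Gaussians of width
#' `atom_sigma` at the positions of all atoms within `cutoff` (including the
#' central atom), partitioned by neighbor species and taken smoothly to zero
#' at the cutoff by a cosine switching function.  The density is expanded in
#' `n_max` orthonormal radial basis functions times real spherical harmonics
#' to `l_max`, and the rotation-invariant power spectrum over species pairs
#' is returned, unit-normalized.  `zeta` is the exponent of the environment
#' kernel built from descriptor dot products.
#'
#' `species_mask` lists element symbols to exclude entirely from the density
#' (they are neither centers nor neighbors) — used to measure the impact of
#' a perturbation, e.g. an added cation, without letting it dominate the
#' metric.
#'
#' @param cutoff Radial cutoff r_c in Angstrom (> 0).
#' @param atom_sigma Gaussian smearing width in Angstrom (> 0).
#' @param n_max Number of radial basis functions (>= 1).
#' @param l_max Angular band limit (>= 0).
#' @param zeta Kernel exponent (>= 1).
#' @param species_mask Character vector of element symbols to exclude.
#' @return An object of class `"soap_params"`.
#' @export
soap_params <- function(cutoff = 4.0, atom_sigma = 0.3, n_max = 8L,
                        l_max = 6L, zeta = 2, species_mask = character()) {
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  if (atom_sigma <= 0) abort("`atom_sigma` must be > 0.")
  if (n_max < 1) abort("`n_max` must be >= 1.")
  if (l_max < 0) abort("`l_max` must be >= 0.")
  if (zeta < 1) abort("`zeta` must be >= 1.")
  structure(
    list(cutoff = cutoff, atom_sigma = atom_sigma, n_max = as.integer(n_max),
         l_max = as.integer(l_max), zeta = zeta,
         species_mask = as.character(species_mask)),
    class = "soap_params"
  )
}

#' @export
print.soap_params <- function(x, ...) {
  cat(sprintf(
    "<soap_params> cutoff=%.2f A, sigma=%.2f A, n_max=%d, l_max=%d, zeta=%g%s\n",
    x$cutoff, x$atom_sigma, x$n_max, x$l_max, x$zeta,
    if (length(x$species_mask)) paste0(", mask={", paste(x$species_mask, collapse = ","), "}")
    else ""
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Real spherical harmonics Y_lm for l = 0..l_max at unit vectors (rows of U).
# Returns an n x (l_max+1)^2 matrix; columns ordered l-major, m = -l..l.
# Associated Legendre values via the standard stable recurrences (no
# Condon-Shortley phase; irrelevant for the power spectrum).
real_sph_harm <- function(l_max, U) {
  n <- nrow(U)
  ct <- U[, 3]
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(U[, 2], U[, 1])
  # P[[l+1]] is an n x (l+1) matrix of P_l^m, m = 0..l
  P <- vector("list", l_max + 1)
  P[[1]] <- matrix(1, n, 1)
  if (l_max >= 1) {
    for (l in 1:l_max) {
      Pl <- matrix(0, n, l + 1)
      # m = l: P_l^l = (2l-1)!! st^l
      Pl[, l + 1] <- prod(seq(1, 2 * l - 1, by = 2)) * st^l
      # m = l-1: P_l^{l-1} = (2l-1) ct P_{l-1}^{l-1}
      Pl[, l] <- (2 * l - 1) * ct * P[[l]][, l]
      if (l >= 2) {
        for (m in (l - 2):0) {
          Pl[, m + 1] <- ((2 * l - 1) * ct * P[[l]][, m + 1] -
                            (l + m - 1) * P[[l - 1]][, m + 1]) / (l - m)
        }
      }
      P[[l + 1]] <- Pl
    }
  }
  Y <- matrix(0, n, (l_max + 1)^2)
  for (l in 0:l_max) {
    base <- l^2
    for (m in 0:l) {
      nl <- sqrt((2 * l + 1) / (4 * pi) *
                   exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      Plm <- P[[l + 1]][, m + 1]
      if (m == 0) {
        Y[, base + l + 1] <- nl * Plm
      } else {
        Y[, base + l + 1 + m] <- sqrt(2) * nl * Plm * cos(m * phi)
        Y[, base + l + 1 - m] <- sqrt(2) * nl * Plm * sin(m * phi)
      }
    }
  }
  Y
}

# Quadrature + radial basis tables, reused across centers and structures.
# Radial basis: shifted Legendre polynomials, orthonormal under unit weight
# on [0, r_c]; the r^2 Jacobian of the projection integral is folded into
# the quadrature weights.
soap_tables <- function(p, n_quad = 64L) {
  gl <- pracma::gaussLegendre(n_quad, 0, p$cutoff)
  r <- gl$x
  w <- gl$w
  u <- 2 * r / p$cutoff - 1
  P <- matrix(0, n_quad, p$n_max)
  for (k in seq_len(p$n_max)) {
    deg <- k - 1L
    P[, k] <- if (deg == 0L) 1 else if (deg == 1L) u else {
      ((2 * deg - 1) * u * P[, k - 1] - (deg - 1) * P[, k - 2]) / deg
    }
  }
  G <- sweep(P, 2, sqrt((2 * (seq_len(p$n_max) - 1) + 1) / p$cutoff), "*")
  list(r = r, wG = G * (w * r^2), n_quad = n_quad)
}

# Radial projection factors psi_l(r_q; R) for one neighbor distance R:
# 4*pi * i_l(r R / sigma^2) e^{-x} * exp(-(r-R)^2 / (2 sigma^2)) computed
# overflow-free with exponentially scaled Bessel functions.
radial_factors <- function(r, R, sigma, l_max) {
  x <- r * R / sigma^2
  gauss <- exp(-(r - R)^2 / (2 * sigma^2))
  Psi <- matrix(0, length(r), l_max + 1)
  small <- x < 1e-8
  for (l in 0:l_max) {
    il_scaled <- numeric(length(r))
    if (any(!small)) {
      xs <- x[!small]
      il_scaled[!small] <- sqrt(pi / (2 * xs)) *
        besselI(xs, l + 0.5, expon.scaled = TRUE)
    }
    if (any(small)) {
      # i_l(x) ~ x^l / (2l+1)!!, e^{-x} ~ 1
      dfact <- prod(seq(1, 2 * l + 1, by = 2))
      il_scaled[small] <- x[small]^l / dfact
    }
    Psi[, l + 1] <- 4 * pi * il_scaled * gauss
  }
  Psi
}

#' Compute SOAP descriptors for one structure
#'
#' Returns one rotation-invariant, unit-normalized power-spectrum vector per
#' non-masked atom.  The flattening order is fixed: species pairs `(a, b)`
#' with `a <= b` in alphabet order; within a pair, `l = 0..l_max`; within a
#' block, radial pairs `(n <= n')` for `a == b` and all `(n, n')` for
#' `a < b`, with off-diagonal terms weighted by `sqrt(2)` so the vector norm
#' equals the norm of the full redundant tensor.
#'
#' @param s A [conformer()].
#' @param p A [soap_params()].
#' @param species_alphabet Optional character vector fixing the species
#'   alphabet (must cover all non-masked species of `s`).  Fix it to the
#'   union over a whole dataset so descriptors are comparable across
#'   structures; defaults to the species present in `s`.
#' @return An object of class `"soap_descriptors"`: a list with `vectors`
#'   (matrix, one row per center), `center_species`, `alphabet`, `params`.
#' @export
compute_descriptors <- function(s, p, species_alphabet = NULL) {
  keep <- !(s$species %in% p$species_mask)
  if (!any(keep)) abort("all atoms masked; structure empty.")
  species <- s$species[keep]
  coords <- s$coords[keep, , drop = FALSE]
  if (any(!is.finite(coords))) abort("non-finite coordinates.")
  alphabet <- sort(unique(c(species, species_alphabet)))
  if (!is.null(species_alphabet)) {
    extra <- setdiff(species, species_alphabet)
    if (length(extra)) {
      abort(sprintf("species %s not in the supplied alphabet.",
                    paste(extra, collapse = ", ")))
    }
    alphabet <- sort(unique(species_alphabet))
  }
  tabs <- soap_tables(p)
  n_at <- nrow(coords)
  n_lm <- (p$l_max + 1)^2
  S <- length(alphabet)
  dim_out <- soap_dim(S, p$n_max, p$l_max)
  out <- matrix(0, n_at, dim_out)
  l_cols <- lapply(0:p$l_max, function(l) (l^2 + 1):((l + 1)^2))

  for (ci in seq_len(n_at)) {
    rel <- sweep(coords, 2, coords[ci, ])
    R <- sqrt(rowSums(rel^2))
    nb <- which(R <= p$cutoff)
    # coefficient arrays per species: n_max x n_lm
    C <- lapply(seq_len(S), function(i) matrix(0, p$n_max, n_lm))
    names(C) <- alphabet
    for (j in nb) {
      a <- species[j]
      fc <- 0.5 * (cos(pi * R[j] / p$cutoff) + 1)
      if (R[j] < 1e-10) {
        # central atom: only l = 0 survives; Y_00 integral = sqrt(4*pi)
        I0 <- crossprod(tabs$wG, exp(-tabs$r^2 / (2 * p$atom_sigma^2)))
        C[[a]][, 1] <- C[[a]][, 1] + fc * sqrt(4 * pi) * I0
      } else {
        u <- rel[j, , drop = FALSE] / R[j]
        Y <- real_sph_harm(p$l_max, u)
        Psi <- radial_factors(tabs$r, R[j], p$atom_sigma, p$l_max)
        I <- crossprod(tabs$wG, Psi)          # n_max x (l_max+1)
        for (l in 0:p$l_max) {
          cols <- l_cols[[l + 1]]
          C[[a]][, cols] <- C[[a]][, cols] +
            fc * (I[, l + 1] %o% Y[1, cols])
        }
      }
    }
    out[ci, ] <- flatten_power_spectrum(C, alphabet, p, l_cols)
  }
  norms <- sqrt(rowSums(out^2))
  if (any(norms <= 0)) abort("zero-norm descriptor (empty environment).")
  structure(
    list(vectors = out / norms, center_species = species,
         alphabet = alphabet, params = p),
    class = "soap_descriptors"
  )
}

soap_dim <- function(S, n_max, l_max) {
  diag_blocks <- S * (n_max * (n_max + 1) / 2)
  off_blocks <- S * (S - 1) / 2 * n_max^2
  as.integer((diag_blocks + off_blocks) * (l_max + 1))
}

flatten_power_spectrum <- function(C, alphabet, p, l_cols) {
  n_max <- p$n_max
  ut <- upper.tri(diag(n_max), diag = TRUE)
  w_diag <- ifelse(upper.tri(diag(n_max)), sqrt(2), 1)[ut]
  parts <- list()
  k <- 0L
  for (ai in seq_along(alphabet)) {
    for (bi in ai:length(alphabet)) {
      for (l in 0:p$l_max) {
        cols <- l_cols[[l + 1]]
        block <- C[[ai]][, cols, drop = FALSE] %*% t(C[[bi]][, cols, drop = FALSE])
        k <- k + 1L
        parts[[k]] <- if (ai == bi) block[ut] * w_diag else sqrt(2) * as.vector(block)
      }
    }
  }
  unlist(parts, use.names = FALSE)
}

#' @export
print.soap_descriptors <- function(x, ...) {
  cat(sprintf("<soap_descriptors> %d centers, dim %d, alphabet {%s}\n",
              nrow(x$vectors), ncol(x$vectors), paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

#' Environment kernel between two descriptors
#'
#' Similarity of two atom-centered environments: the descriptor dot product,
#' clamped to `[0, 1]`, raised to the power `zeta`.
#'
#' @param a,b Unit-normalized descriptor vectors of equal length (rows of
#'   [compute_descriptors()] output).
#' @param zeta Kernel exponent (>= 1).
#' @return Similarity in `[0, 1]`.
#' @export
environment_kernel <- function(a, b, zeta = 2) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("descriptor length mismatch.")
  min(max(sum(a * b), 0), 1)^zeta
}

#' Descriptors for every structure of a dataset
#'
#' Fixes the species alphabet to the union over the dataset (minus masked
#' species) so that all descriptors live in one comparable space.
#'
#' @param dataset A [conformer_set()].
#' @param p A [soap_params()].
#' @return A list of `"soap_descriptors"`, one per structure, plus the
#'   common alphabet as attribute `"alphabet"`.
#' @export
dataset_descriptors <- function(dataset, p) {
  alphabet <- sort(setdiff(
    unique(unlist(lapply(dataset$structures, function(s) s$species))),
    p$species_mask
  ))
  if (!length(alphabet)) abort("all species masked; dataset empty.")
  out <- lapply(dataset$structures, compute_descriptors, p = p,
                species_alphabet = alphabet)
  names(out) <- dataset_ids(dataset)
  attr(out, "alphabet") <- alphabet
  out
}

#' Export descriptors to a JSON container
#'
#' One array per structure plus a parameter block recording the
#' [soap_params()] and species alphabet.
#'
#' @param descs Output of [dataset_descriptors()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descs, path) {
  payload <- list(
    params = unclass(attr(descs[[1]], "params") %||% descs[[1]]$params),
    alphabet = attr(descs, "alphabet") %||% descs[[1]]$alphabet,
    structures = lapply(descs, function(d) {
      list(center_species = d$center_species, vectors = d$vectors)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
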