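# Solvent accessibility (Shrake-Rupley), surface classification, and a
# screened-Coulomb potential sampler for qualitative electrostatic maps.

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' Golden-angle spiral; near-uniform point distribution used both as the
#' Shrake-Rupley quadrature and as the scaffold for synthetic shell
#' structures.
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)   # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `n_points` quadrature points on each atom's expanded sphere
#' (radius + probe) using a Fibonacci lattice and counts points not buried
#' inside any neighbouring atom's expanded sphere.  Per-residue SASA is the
#' sum over the residue's atoms.  Deterministic for fixed arguments.
#'
#' @param s A `charged_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4,
#'   water).
#' @param n_points Quadrature points per atom (default 960; must be >= 32).
#' @return Object of class `surface_annotation`: data.frame with
#'   `res_index`, `res_key`, `resid`, `sasa` plus (after
#'   [classify_surface]) `rel_sasa` and `is_surface`.  Attributes
#'   `probe_radius`, `n_points`, `atom_area` (per-atom areas).
#' @export
compute_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "charged_structure"))
  if (n_points < 32)
    stop("n_points must be >= 32 (quadrature too coarse)")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  rad <- s$atoms$radius + probe_radius
  n <- nrow(xyz)
  u <- fibonacci_sphere(n_points)
  # neighbour lists from the full distance matrix (structures here are
  # small; ~3000 atoms is a 70 MB temporary at worst)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2)
    nb <- nb[nb != i]
    p <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= rad[j]^2
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rad[i]^2
  }
  res_sasa <- rowsum(area, s$atoms$res_index)
  ann <- data.frame(res_index = s$residues$res_index,
                    res_key = s$residues$res_key,
                    resid = s$residues$resid,
                    sasa = as.numeric(res_sasa[
                      as.character(s$residues$res_index), 1]),
                    stringsAsFactors = FALSE)
  attr(ann, "probe_radius") <- probe_radius
  attr(ann, "n_points") <- n_points
  attr(ann, "atom_area") <- area
  class(ann) <- c("surface_annotation", "data.frame")
  ann
}

#' Classify residues as surface or buried by relative SASA
#'
#' Relative SASA is `sasa / maxASA(residue type)`; residues at or above
#' `threshold` are called surface.  The default normalisation is the
#' theoretical maximum-ASA table of Tien et al. ([max_asa_tien]); for
#' single-sphere pseudo-residue fixtures use [max_asa_sphere].
#'
#' @param ann A `surface_annotation` from [compute_sasa].
#' @param max_asa_table Named numeric vector, three-letter residue code ->
#'   maximum ASA in Angstrom^2.
#' @param threshold Relative-SASA cutoff for the surface call (default
#'   0.20).
#' @return `ann` with `rel_sasa` and `is_surface` columns and a
#'   `threshold` attribute.
#' @export
classify_surface <- function(ann, max_asa_table = max_asa_tien(),
                             threshold = 0.20) {
  stopifnot(inherits(ann, "surface_annotation"), threshold > 0)
  mx <- max_asa_table[ann$resid]
  if (anyNA(mx))
    stop("residue type(s) missing from max-ASA table: ",
         paste(unique(ann$resid[is.na(mx)]), collapse = ", "))
  ann$rel_sasa <- ann$sasa / unname(mx)
  ann$is_surface <- ann$rel_sasa >= threshold
  attr(ann, "threshold") <- threshold
  ann
}

#' Inverse Debye length from ionic strength
#'
#' kappa = sqrt(I) / 3.04 per Angstrom for aqueous solution at 25 C, with
#' I in mol/L.  The default culture-medium condition of 0.15 M gives
#' kappa ~ 0.127 1/A (Debye length ~ 7.9 A).
#'
#' @param ionic_strength mol/L.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength = 0.15) {
  stopifnot(ionic_strength >= 0)
  sqrt(ionic_strength) / 3.04
}

# Preferred side-chain charge-center atom per charged residue type.
charge_center_atoms <- list(ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD",
                            HIS = c("ND1", "NE2"))

# One charge position per charged residue: named atom(s), else side-chain
# centroid, else CA.
charge_centers <- function(s) {
  res <- s$residues[!is.na(s$residues$charge) & s$residues$charge != 0, ,
                    drop = FALSE]
  if (nrow(res) == 0)
    return(list(xyz = matrix(numeric(0), 0, 3), q = numeric(0),
                res_key = character(0)))
  backbone <- c("N", "CA", "C", "O", "OXT")
  xyz <- t(vapply(seq_len(nrow(res)), function(i) {
    a <- s$atoms[s$atoms$res_index == res$res_index[i], , drop = FALSE]
    want <- charge_center_atoms[[res$resid[i]]]
    hit <- a[a$elety %in% want, , drop = FALSE]
    if (!is.null(want) && nrow(hit) == length(want))
      return(colMeans(as.matrix(hit[, c("x", "y", "z")])))
    sc <- a[!a$elety %in% backbone, , drop = FALSE]
    if (nrow(sc) > 0)
      return(colMeans(as.matrix(sc[, c("x", "y", "z")])))
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(ca) > 0)
      return(as.numeric(ca[1, c("x", "y", "z")]))
    colMeans(as.matrix(a[, c("x", "y", "z")]))
  }, numeric(3)))
  list(xyz = xyz, q = res$charge, res_key = res$res_key)
}

#' Screened-Coulomb electrostatic potential at sample points
#'
#' Evaluates phi(x) = sum_i q_i exp(-kappa r_i) / (dielectric * r_i) with
#' point charges at side-chain charge centers (ARG CZ, LYS NZ, ASP CG,
#' GLU CD, HIS midpoint of ND1/NE2; side-chain centroid then CA as
#' fallbacks).  This uniform-dielectric Debye-Hueckel field is a
#' qualitative map of the molecule's electrostatic environment; it is
#' deliberately not a Poisson-Boltzmann solution and is never used in
#' patch detection or the PCP score.
#'
#' @param s A `charged_structure` with charges assigned.
#' @param points m x 3 matrix of sample positions (Angstrom).
#' @param dielectric Relative dielectric constant (default 80, water).
#' @param kappa Inverse Debye length in 1/Angstrom (default
#'   `debye_kappa(0.15)`).
#' @param scale `"reduced"` returns charge/(dielectric*Angstrom) units;
#'   `"kT_e"` multiplies by 560.74 (the vacuum Bjerrum length in Angstrom
#'   at 298 K) to express the potential in kT/e.
#' @return Object of class `potential_sample`: list with `points`,
#'   `potential`, `dielectric`, `kappa`, `scale`.
#' @export
coulomb_potential <- function(s, points, dielectric = 80,
                              kappa = debye_kappa(0.15),
                              scale = c("reduced", "kT_e")) {
  scale <- match.arg(scale)
  stopifnot(inherits(s, "charged_structure"), dielectric > 0, kappa >= 0)
  if (all(is.na(s$residues$charge)))
    stop("charges not assigned; call assign_charges() first")
  points <- rbind(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  cc <- charge_centers(s)
  phi <- numeric(nrow(points))
  if (length(cc$q) > 0) {
    too_close <- character(0)
    for (k in seq_len(nrow(points))) {
      d <- sqrt(colSums((t(cc$xyz) - points[k, ])^2))
      off <- d < 0.5
      if (any(off))
        too_close <- c(too_close,
                       sprintf("point %d ~ %s (%.2f A)", k,
                               cc$res_key[off], d[off]))
      phi[k] <- sum(cc$q * exp(-kappa * d) / (dielectric * d))
    }
    if (length(too_close))
      stop("sample point(s) closer than 0.5 A to a charge center:\n  ",
           paste(too_close, collapse = "\n  "))
  }
  if (scale == "kT_e") phi <- phi * 560.74
  structure(list(points = points, potential = phi,
                 dielectric = dielectric, kappa = kappa, scale = scale),
            class = "potential_sample")
}

#' @export
print.potential_sample <- function(x, ...) {
  cat(sprintf(
    "<potential_sample> %d points, eps=%g kappa=%.4g 1/A [%s]\n",
    nrow(x$points), x$dielectric, x$kappa, x$scale))
  cat(sprintf("  potential range [%.4g, %.4g]\n",
              min(x$potential), max(x$potential)))
  invisible(x)
}
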