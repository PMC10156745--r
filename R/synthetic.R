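# Synthetic fixtures: pseudo-structures with planted charged surface
# patches of known size, and assay cohorts with known correlation
# structure.  Every downstream module is testable against these without
# any external data.

# run code under a temporary RNG state; never touches the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a planted-patch shell structure
#'
#' @param sizes Planted positive-patch sizes (residue counts), any order;
#'   stored descending.
#' @param min_separation Minimum inter-patch distance in Angstrom; must
#'   exceed the adjacency cutoff intended for testing so planted patches
#'   can never merge.
#' @param shell_radius Sphere radius in Angstrom carrying the
#'   pseudo-residues (default 25, roughly an scFv-sized globule).
#' @param n_buried Interior glycines packed into a dense central ball so
#'   the surface classifier sees genuinely buried residues; 0, or at
#'   least 15 (smaller balls cannot guarantee burial).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param lattice_spacing Target nearest-neighbour spacing on the shell
#'   (default 4.2 A: below the 5 A contact cutoff, so neighbouring planted
#'   residues are contiguous, and above the 4 A floor so distinct patches
#'   stay resolvable).
#' @param cutoff Adjacency cutoff (A) the fixture is designed for.
#' @return Object of class `patch_spec`.
#' @export
patch_spec <- function(sizes = c(12, 9, 5), min_separation = 8,
                       shell_radius = 25, n_buried = 30, seed = 1,
                       lattice_spacing = 4.2, cutoff = 5.0) {
  stopifnot(all(sizes >= 1), min_separation > cutoff, shell_radius > 0,
            n_buried == 0 || n_buried >= 15,
            lattice_spacing >= 4.0, cutoff > 0)
  structure(list(sizes = sort(as.integer(sizes), decreasing = TRUE),
                 min_separation = min_separation,
                 shell_radius = shell_radius,
                 n_buried = as.integer(n_buried),
                 seed = as.integer(seed),
                 lattice_spacing = lattice_spacing, cutoff = cutoff),
            class = "patch_spec")
}

# flood fill over an adjacency cutoff; used only for generator sanity
.connected_under <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n <= 1) return(TRUE)
  adj <- as.matrix(stats::dist(xyz)) <= cutoff
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate a pseudo-structure with planted charged surface patches
#'
#' Places single-atom (CA-like, carbon-sized) pseudo-residues on a
#' Fibonacci lattice over a sphere.  Each planted patch is a contiguous
#' geodesic cap of lysines grown around a well-separated anchor; all other
#' shell residues are glycine.  `n_buried` additional glycines form a
#' dense central ball whose members are solvent-inaccessible.  The whole
#' construction is deterministic for a fixed seed (the lattice is randomly
#' rotated and the first anchor randomly chosen; remaining anchors by
#' greedy farthest-point).
#'
#' Because every pseudo-residue is a single sphere, ground truth is exact:
#' patch sizes, surface/buried labels, and the PCP score are known by
#' construction.  When scoring the emitted file use
#' `max_asa_table = max_asa_sphere()` (see the manifest's `params`).
#'
#' @param spec A [patch_spec()].
#' @return List with `pdb_text` (character vector of PDB lines),
#'   `manifest` (data.frame: `resno`, `res_key`, `type`, `charge`,
#'   `surface`, `patch` -- 0 for unplanted), `expected_pcp_score`, and
#'   `params` (the scoring parameters the fixture is designed for).
#' @export
generate_shell_structure <- function(spec = patch_spec()) {
  stopifnot(inherits(spec, "patch_spec"))
  R <- spec$shell_radius
  # hexagonal-packing estimate of the lattice size for the target spacing
  n_shell <- max(sum(spec$sizes) + 10,
                 round(4 * pi * R^2 / (spec$lattice_spacing^2 * sqrt(3) / 2)))
  pts <- fibonacci_sphere(n_shell) * R

  with_seed(spec$seed, {
    # random rotation (QR of a Gaussian matrix, det +1)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    pts <- pts %*% rot
    first_anchor <- sample.int(n_shell, 1)
  })

  k <- length(spec$sizes)
  anchors <- first_anchor
  if (k > 1) {
    d2a <- colSums((t(pts) - pts[first_anchor, ])^2)
    for (j in 2:k) {
      anchors <- c(anchors, which.max(d2a))
      d2new <- colSums((t(pts) - pts[anchors[j], ])^2)
      d2a <- pmin(d2a, d2new)
    }
  }

  patch_id <- integer(n_shell)
  for (j in seq_len(k)) {
    d <- colSums((t(pts) - pts[anchors[j], ])^2)
    d[patch_id != 0] <- Inf
    members <- order(d)[seq_len(spec$sizes[j])]
    patch_id[members] <- j
  }

  # planted patches must be internally contiguous and mutually separated
  for (j in seq_len(k))
    if (!.connected_under(pts[patch_id == j, , drop = FALSE], spec$cutoff))
      stop("infeasible packing: planted patch ", j, " is not contiguous ",
           "at cutoff ", spec$cutoff,
           " A; increase shell_radius or reduce sizes")
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      da <- pts[patch_id == a, , drop = FALSE]
      db <- pts[patch_id == b, , drop = FALSE]
      mind <- min(sqrt(outer(rowSums(da^2), rowSums(db^2), `+`) -
                         2 * da %*% t(db)))
      if (mind <= spec$min_separation)
        stop("infeasible packing: patches ", a, " and ", b, " are only ",
             sprintf("%.2f", mind), " A apart; increase shell_radius")
    }
  }

  # buried ball: volume-filling Fibonacci spiral, ~1.5 A spacing, so the
  # outermost layer is still occluded by its neighbours
  buried <- NULL
  if (spec$n_buried > 0) {
    nb <- spec$n_buried
    s_pack <- 1.5
    r_max <- s_pack * (3 * nb / (4 * pi))^(1 / 3)
    dirs <- fibonacci_sphere(nb)
    rr <- r_max * ((seq_len(nb) - 0.5) / nb)^(1 / 3)
    buried <- dirs * rr
  }

  coords <- rbind(pts, buried)
  n_total <- nrow(coords)
  type <- c(ifelse(patch_id > 0, "LYS", "GLY"), rep("GLY", n_total - n_shell))
  surface <- c(rep(TRUE, n_shell), rep(FALSE, n_total - n_shell))
  patch <- c(patch_id, rep(0L, n_total - n_shell))
  resno <- seq_len(n_total)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(pdb = NULL, file = tmp,
                   xyz = as.vector(t(coords)),
                   resno = resno, resid = type,
                   eleno = resno, elety = rep("CA", n_total),
                   chain = rep("A", n_total),
                   o = rep(1, n_total), b = rep(0, n_total),
                   elesy = rep("C", n_total), verbose = FALSE)
  pdb_text <- readLines(tmp)

  scheme <- charge_scheme()
  manifest <- data.frame(resno = resno,
                         res_key = paste0("A:", resno),
                         type = type,
                         charge = unname(scheme$charges[type]),
                         surface = surface,
                         patch = as.integer(patch),
                         stringsAsFactors = FALSE)
  list(pdb_text = pdb_text,
       manifest = manifest,
       expected_pcp_score =
         as.integer(sum(head(spec$sizes, 3L))),
       params = list(cutoff = spec$cutoff, rel_sasa_threshold = 0.20,
                     probe_radius = 1.4, max_asa = "sphere",
                     sizes = spec$sizes, seed = spec$seed,
                     shell_radius = spec$shell_radius))
}

#' Write a generated fixture to disk
#'
#' @param fix Result of [generate_shell_structure].
#' @param pdb_path Output PDB path.
#' @param manifest_path Optional JSON manifest path.
#' @return `pdb_path`, invisibly.
#' @export
write_fixture <- function(fix, pdb_path, manifest_path = NULL) {
  writeLines(fix$pdb_text, pdb_path)
  if (!is.null(manifest_path))
    jsonlite::write_json(
      list(manifest = fix$manifest,
           expected_pcp_score = fix$expected_pcp_score,
           params = fix$params),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(pdb_path)
}

#' Generate a synthetic assay cohort with known correlation structure
#'
#' Draws latent (patch score, tonic index) pairs from a bivariate normal
#' with correlation `true_r` (patch score: mean 30, sd 10, spanning the
#' observed range of scFv PCP scores; tonic index: mean 2.0, sd 0.5),
#' then converts the tonic index into positive marker MFIs with
#' multiplicative lognormal measurement noise of coefficient of variation
#' `noise_cv`: GFP ~ `mfi_scale`, CD69 = tonic x GFP, and the exhaustion
#' markers PD1/LAG3/TIM3 likewise proportional to the tonic latent.  With
#' `noise_cv = 0` the assay-derived tonic index reproduces the latent
#' value exactly.
#'
#' @param n Cohort size (>= 3).
#' @param true_r Target latent correlation, in \[-1, 1\].
#' @param mfi_scale Median GFP MFI (arbitrary units).
#' @param noise_cv Lognormal measurement noise CV (0 = noise-free).
#' @param seed Integer seed.
#' @return List with `assay` (wide data.frame: `sample_id`, `group`,
#'   `GFP`, `CD69`, `PD1`, `LAG3`, `TIM3`) and `truth` (`sample_id`,
#'   `pcp_score`, `tonic_true`).
#' @export
generate_assay_cohort <- function(n, true_r, mfi_scale = 1000,
                                  noise_cv = 0.1, seed = 1) {
  if (!is.finite(true_r) || abs(true_r) > 1)
    stop("true_r must lie in [-1, 1]")
  stopifnot(n >= 3, mfi_scale > 0, noise_cv >= 0)
  sdlog <- sqrt(log1p(noise_cv^2))
  ln <- function(z) exp(z * sdlog - sdlog^2 / 2)
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- true_r * z1 + sqrt(1 - true_r^2) * rnorm(n)
    pcp <- 30 + 10 * z1
    tonic <- 2.0 + 0.5 * z2
    gfp <- mfi_scale * ln(rnorm(n))
    assay <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = "cohort",
      GFP = gfp,
      CD69 = pmax(tonic, 0) * gfp * ln(rnorm(n)),
      PD1 = pmax(1.2 * tonic, 0) * gfp * ln(rnorm(n)),
      LAG3 = pmax(0.8 * tonic, 0) * gfp * ln(rnorm(n)),
      TIM3 = pmax(1.0 * tonic, 0) * gfp * ln(rnorm(n)),
      stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = assay$sample_id,
                        pcp_score = pcp, tonic_true = tonic,
                        stringsAsFactors = FALSE)
    list(assay = assay, truth = truth)
  })
}
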