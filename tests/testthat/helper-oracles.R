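# Independent oracles and tiny fixture builders shared across tests.
# These deliberately re-derive results by the most direct route possible
# (per-pair distance scans, breadth-first flood fill, closed-form sphere
# geometry) so they stay independent of the package implementation.

# O(n^2) residue-pair minimum-atom-distance scan -> edge list (i < j),
# restricted to residues flagged as surface.  Distances come from the
# explicit all-against-all expansion |a|^2 + |b|^2 - 2 a.b (not dist()),
# aggregated to per-residue-pair minima, so the route is independent of
# build_contact_graph().
oracle_contact_edges <- function(s, surface_keys, cutoff) {
  surf_idx <- s$residues$res_index[s$residues$res_key %in% surface_keys]
  keep <- s$atoms$res_index %in% surf_idx
  X <- as.matrix(s$atoms[keep, c("x", "y", "z")])
  rid <- match(s$atoms$res_index[keep], surf_idx)
  n <- length(surf_idx)
  if (n < 2) return(matrix(integer(0), 0, 2))
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * X %*% t(X)
  rows_of <- split(seq_len(nrow(X)), rid)
  # min over atom rows per residue, then over atom columns per residue
  byrow <- t(vapply(rows_of, function(rr)
    do.call(pmin, lapply(rr, function(r) D2[r, ])), numeric(nrow(X))))
  M <- vapply(rows_of, function(cc)
    do.call(pmin, lapply(cc, function(c_) byrow[, c_])), numeric(n))
  hit <- which(M <= cutoff^2 + 1e-9, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0) matrix(integer(0), 0, 2) else unname(hit)
}

# breadth-first flood fill over an edge list -> component label per node
oracle_components <- function(n_nodes, edges) {
  adj <- vector("list", n_nodes)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n_nodes)
  cur <- 0L
  for (v in seq_len(n_nodes)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# accessible area of sphere 1 (radius r1, centre distance d from sphere 2
# of radius r2), both probe-expanded: full area minus the buried cap
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)   # buried cap height on sphere 1
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# canonical sorted edge matrix for comparison
canon_edges <- function(e) {
  if (nrow(e) == 0) return(matrix(integer(0), 0, 2))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# component partitions as comparable canonical forms (sets of sorted
# member vectors, order-independent)
canon_partition <- function(labels) {
  parts <- split(seq_along(labels), labels)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, integer(1), 1))])
}

# hand-rolled minimal PDB writer for tiny ad-hoc test structures
write_mini_pdb <- function(path, resno, resid, x, y, z,
                           elety = "CA", chain = "A", elesy = "C",
                           record = "ATOM", occ = 1, alt = "") {
  n <- length(resno)
  elety <- rep_len(elety, n); chain <- rep_len(chain, n)
  elesy <- rep_len(elesy, n); record <- rep_len(record, n)
  occ <- rep_len(occ, n); alt <- rep_len(alt, n)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, seq_len(n), paste0(" ", elety), alt, resid, chain, resno,
    x, y, z, occ, 0, elesy)
  writeLines(c(lines, "END"), path)
  path
}

# rotation matrix from axis-angle (unit axis)
rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# apply a rigid transform to every atom of a charged_structure
transform_structure <- function(s, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# fixture -> parsed/charged structure + truth-based annotation (bypasses
# SASA so graph/patch logic can be exercised at scale)
fixture_pipeline <- function(fix, run_sasa = FALSE, cutoff = 5) {
  pdb <- tempfile(fileext = ".pdb")
  write_fixture(fix, pdb)
  s <- assign_charges(parse_structure(pdb))
  unlink(pdb)
  if (run_sasa) {
    ann <- compute_sasa(s)
    ann <- classify_surface(ann, max_asa_table = max_asa_sphere(),
                            threshold = 0.2)
  } else {
    ann <- data.frame(res_index = s$residues$res_index,
                      res_key = s$residues$res_key,
                      resid = s$residues$resid,
                      sasa = NA_real_, rel_sasa = NA_real_,
                      is_surface = fix$manifest$surface,
                      stringsAsFactors = FALSE)
    class(ann) <- c("surface_annotation", "data.frame")
  }
  list(s = s, ann = ann,
       g = build_contact_graph(s, ann, cutoff = cutoff))
}
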