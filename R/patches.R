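# Contact graph over surface residues, charged-patch detection, the PCP
# score, and the in-silico charge-mutation scanner.

#' Build the surface-residue contact graph
#'
#' Nodes are residues classified as surface; an edge joins two residues
#' when their minimum heavy-atom distance (any atoms, side chain or
#' backbone) is at most `cutoff`.  5 A is the standard residue-contact
#' convention used to approximate surface contiguity.
#'
#' @param s A `charged_structure`.
#' @param ann A `surface_annotation` with `is_surface` (from
#'   [classify_surface]).
#' @param cutoff Contact distance cutoff in Angstrom (default 5.0).
#' @return Object of class `contact_graph`: list with `nodes` (res_key of
#'   surface residues, in residue order), `node_index` (their res_index),
#'   `edges` (m x 2 integer matrix indexing `nodes`, each pair once with
#'   i < j), `cutoff`.
#' @export
build_contact_graph <- function(s, ann, cutoff = 5.0) {
  stopifnot(inherits(s, "charged_structure"),
            inherits(ann, "surface_annotation"))
  if (is.null(ann$is_surface))
    stop("surface not classified; call classify_surface() first")
  if (cutoff <= 0) stop("cutoff must be > 0")
  surf_idx <- ann$res_index[ann$is_surface]
  keep <- s$atoms$res_index %in% surf_idx
  xyz <- as.matrix(s$atoms[keep, c("x", "y", "z")])
  arid <- match(s$atoms$res_index[keep], surf_idx)   # node id per atom
  n <- length(surf_idx)
  edges <- matrix(integer(0), 0, 2)
  if (n >= 2 && nrow(xyz) >= 2) {
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    ri <- arid[hit[, 1]]
    rj <- arid[hit[, 2]]
    ok <- ri != rj
    if (any(ok)) {
      e <- cbind(pmin(ri[ok], rj[ok]), pmax(ri[ok], rj[ok]))
      edges <- unique(e)
      edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    }
  }
  structure(list(nodes = s$residues$res_key[match(surf_idx,
                                                  s$residues$res_index)],
                 node_index = surf_idx, edges = edges, cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d surface residues, %d contacts (<= %g A)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Detect contiguous same-sign charged surface patches
#'
#' Patches are the connected components of the contact-graph subgraph
#' induced by surface residues whose assigned charge has the requested
#' sign.  Components are ranked by size (descending), ties broken by the
#' smallest (chain, residue number) among members, so the ranking is fully
#' deterministic.
#'
#' @param g A `contact_graph`.
#' @param s The `charged_structure` (with charges assigned) the graph was
#'   built from.
#' @param sign `+1` for positively charged patches (the PCP convention) or
#'   `-1` for negative patches.
#' @return Object of class `patch_set`: list with `patches` (each a list
#'   `members` (res_key, residue order), `size`, `rank`), `sizes`,
#'   `pcp_score` (sum of the top `min(3, n)` sizes), `sign`.
#' @export
find_patches <- function(g, s, sign = +1) {
  stopifnot(inherits(g, "contact_graph"),
            inherits(s, "charged_structure"), sign %in% c(-1, 1))
  if (all(is.na(s$residues$charge)))
    stop("charges not assigned; call assign_charges() first")
  q <- s$residues$charge[match(g$node_index, s$residues$res_index)]
  sel <- which(q * sign > 0)
  patches <- list()
  if (length(sel) > 0) {
    sub_edges <- g$edges[g$edges[, 1] %in% sel & g$edges[, 2] %in% sel, ,
                         drop = FALSE]
    ig <- igraph::make_graph(
      edges = as.vector(t(cbind(match(sub_edges[, 1], sel),
                                match(sub_edges[, 2], sel)))),
      n = length(sel), directed = FALSE)
    comp <- igraph::components(ig)$membership
    groups <- split(sel, comp)
    # rank: size desc, then smallest member residue index asc
    sizes <- lengths(groups)
    firsts <- vapply(groups, function(m) min(g$node_index[m]), numeric(1))
    ord <- order(-sizes, firsts)
    patches <- lapply(seq_along(ord), function(r) {
      m <- sort(g$node_index[groups[[ord[r]]]])
      list(members = s$residues$res_key[match(m, s$residues$res_index)],
           size = length(m), rank = r)
    })
  }
  sizes <- vapply(patches, function(p) p$size, numeric(1))
  structure(list(patches = patches, sizes = as.integer(sizes),
                 pcp_score = as.integer(sum(head(sizes, 3L))),
                 sign = sign),
            class = "patch_set")
}

#' The PCP score of a patch set
#'
#' Total number of residues in the top three largest patches (fewer than
#' three patches: sum whatever exists; none: 0).
#'
#' @param ps A `patch_set` from [find_patches].
#' @return Integer score.
#' @export
pcp_score <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  as.integer(sum(head(sort(ps$sizes, decreasing = TRUE), 3L)))
}

#' @export
print.patch_set <- function(x, ...) {
  lab <- if (x$sign > 0) "positive" else "negative"
  cat(sprintf("<patch_set> %d %s patch(es); PCP score %d\n",
              length(x$patches), lab, x$pcp_score))
  for (p in head(x$patches, 10))
    cat(sprintf("  #%d size %2d: %s%s\n", p$rank, p$size,
                paste(head(p$members, 8), collapse = " "),
                if (p$size > 8) " ..." else ""))
  if (length(x$patches) > 10) cat("  ...\n")
  invisible(x)
}

#' Parse a mutation specification
#'
#' Mutations are written `chain:resnum:newtype`, e.g. `"A:42:S"` (one- or
#' three-letter new type).
#'
#' @param lines Character vector of specs.
#' @return data.frame with `res_key`, `new_type` (three-letter).
#' @export
parse_mutations <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed mutation line ", bad[1], ": '", lines[bad[1]],
         "' (expected chain:resnum:newtype)")
  new_type <- toupper(vapply(parts, `[`, "", 3))
  one <- nchar(new_type) == 1
  new_type[one] <- aa1_to_3(new_type[one])
  if (anyNA(new_type) || !all(new_type %in% AA3))
    stop("unknown residue type in mutation spec")
  data.frame(res_key = paste(vapply(parts, `[`, "", 1),
                             vapply(parts, `[`, "", 2), sep = ":"),
             new_type = new_type, stringsAsFactors = FALSE)
}

apply_mutations <- function(s, muts, scheme) {
  idx <- match(muts$res_key, s$residues$res_key)
  if (anyNA(idx))
    stop("unknown position(s): ",
         paste(muts$res_key[is.na(idx)], collapse = ", "))
  s$residues$resid[idx] <- muts$new_type
  q <- if (!is.null(muts$new_charge)) muts$new_charge
       else unname(scheme$charges[muts$new_type])
  s$residues$charge[idx] <- q
  s
}

#' Scan charge mutations for their effect on the PCP score
#'
#' Each candidate mutation is applied as a residue-type and charge
#' reassignment on the fixed backbone: coordinates, SASA and the contact
#' graph are retained, only patch detection and the score are recomputed.
#' This mirrors framework-region charge engineering -- neutralising
#' lysines to damp tonic signaling (`direction = "down"`) or introducing
#' lysines to strengthen it (`direction = "up"`) -- where the fold is
#' assumed unchanged.
#'
#' @param s `charged_structure` with charges assigned.
#' @param ann Classified `surface_annotation`.
#' @param candidates data.frame from [parse_mutations] (columns `res_key`,
#'   `new_type`, optional `new_charge`).
#' @param direction `"down"` or `"up"` (recorded in the result; both
#'   directions use the same machinery).
#' @param graph Optional precomputed `contact_graph`; built at `cutoff`
#'   otherwise.
#' @param cutoff Contact cutoff if `graph` is NULL.
#' @param cdr_mask Optional character vector of res_keys that must not be
#'   mutated (CDR positions); a candidate inside the mask is an error.
#' @param combinatorial If TRUE the whole candidate set is applied jointly
#'   as one variant (emulating multi-mutation constructs); otherwise each
#'   candidate is evaluated singly.
#' @param scheme Charge scheme for the mutated types (default: the scheme
#'   stored on `s`).
#' @return Object of class `scan_result`: data.frame with `res_key`,
#'   `new_type`, `delta_pcp`, `pcp_score`, `patch_sizes` (comma-joined),
#'   ranked by |delta| descending, ties by residue order ascending.
#'   Attribute `base_score` carries the unmutated score.
#' @export
mutation_scan <- function(s, ann, candidates, direction = c("down", "up"),
                          graph = NULL, cutoff = 5.0, cdr_mask = NULL,
                          combinatorial = FALSE, scheme = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(s, "charged_structure"))
  if (is.null(scheme)) scheme <- s$scheme
  if (is.null(scheme)) scheme <- charge_scheme()
  if (is.null(graph)) graph <- build_contact_graph(s, ann, cutoff)
  if (!all(candidates$res_key %in% s$residues$res_key))
    stop("unknown position(s): ",
         paste(setdiff(candidates$res_key, s$residues$res_key),
               collapse = ", "))
  if (!is.null(cdr_mask)) {
    inside <- candidates$res_key %in% cdr_mask
    if (any(inside))
      stop("mutation(s) rejected, position inside CDR mask: ",
           paste(candidates$res_key[inside], collapse = ", "))
  }
  base <- find_patches(graph, s, sign = +1)
  score_of <- function(muts) {
    ps <- find_patches(graph, apply_mutations(s, muts, scheme), sign = +1)
    list(score = ps$pcp_score, sizes = ps$sizes)
  }
  if (combinatorial) {
    r <- score_of(candidates)
    out <- data.frame(res_key = paste(candidates$res_key, collapse = "+"),
                      new_type = paste(candidates$new_type, collapse = "+"),
                      delta_pcp = r$score - base$pcp_score,
                      pcp_score = r$score,
                      patch_sizes = paste(r$sizes, collapse = ","),
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(candidates)), function(i) {
      r <- score_of(candidates[i, , drop = FALSE])
      data.frame(res_key = candidates$res_key[i],
                 new_type = candidates$new_type[i],
                 delta_pcp = r$score - base$pcp_score,
                 pcp_score = r$score,
                 patch_sizes = paste(r$sizes, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    pos <- match(out$res_key, s$residues$res_key)
    out <- out[order(-abs(out$delta_pcp), pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "base_score") <- base$pcp_score
  attr(out, "direction") <- direction
  class(out) <- c("scan_result", "data.frame")
  out
}

# ---- patch-set exporters ---------------------------------------------------

#' Serialize a patch set
#'
#' @param ps A `patch_set`.
#' @return JSON string (members, sizes, score); stable key order, so
#'   identical inputs serialize byte-identically.
#' @export
patchset_json <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  jsonlite::toJSON(list(
    sign = ps$sign,
    pcp_score = ps$pcp_score,
    patches = lapply(ps$patches, function(p)
      list(rank = p$rank, size = p$size, members = p$members))),
    auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname patchset_json
#' @return `patchset_table` returns a data.frame (rank, size, members).
#' @export
patchset_table <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  if (length(ps$patches) == 0)
    return(data.frame(rank = integer(0), size = integer(0),
                      members = character(0)))
  data.frame(rank = vapply(ps$patches, `[[`, 1L, "rank"),
             size = vapply(ps$patches, `[[`, 1L, "size"),
             members = vapply(ps$patches, function(p)
               paste(p$members, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' Residue-colouring files for molecular viewers
#'
#' `write_defattr` writes a UCSF Chimera attribute file assigning each
#' residue its patch rank; `write_pymol` writes a PyMOL selection script
#' with one named selection per patch rank.
#'
#' @param ps A `patch_set`.
#' @param path Output file.
#' @param attribute Chimera attribute name.
#' @export
write_defattr <- function(ps, path, attribute = "pcpRank") {
  lines <- c(sprintf("attribute: %s", attribute),
             "match mode: 1-to-1", "recipient: residues")
  for (p in ps$patches)
    for (m in p$members) {
      ch <- sub(":.*$", "", m)
      rn <- sub("^[^:]*:", "", m)
      lines <- c(lines, sprintf("\t:%s.%s\t%d", rn, ch, p$rank))
    }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_defattr
#' @export
write_pymol <- function(ps, path) {
  lines <- character(0)
  for (p in ps$patches) {
    sel <- paste(vapply(p$members, function(m) {
      ch <- sub(":.*$", "", m)
      rn <- sub("^[^:]*:", "", m)
      sprintf("(chain %s and resi %s)", ch, rn)
    }, ""), collapse = " or ")
    lines <- c(lines, sprintf("select patch_rank%d, %s", p$rank, sel))
  }
  writeLines(lines, path)
  invisible(path)
}
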