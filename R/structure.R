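# Structure parsing and per-residue charge assignment.

#' Parse a protein structure into a charged-structure object
#'
#' Reads a PDB or mmCIF file (via bio3d), keeps standard amino-acid ATOM
#' records only (HETATM, water and hydrogens are dropped), resolves
#' alternate locations to the highest-occupancy copy (ties keep the first
#' encountered), and orders residues by chain, then author residue number,
#' then insertion code.  Multi-chain structures are treated as one molecule,
#' since scFv models may carry VH and VL as separate chains.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are read as mmCIF, everything else as PDB).
#' @return An object of class `charged_structure`: a list with
#'   \describe{
#'     \item{atoms}{data.frame: `res_index`, `chain`, `resno`, `insert`,
#'       `resid`, `elety`, `element`, `x`, `y`, `z`, `radius`, `occupancy`}
#'     \item{residues}{data.frame: `res_index`, `res_key` (chain:number),
#'       `chain`, `resno`, `insert`, `resid`, `charge` (NA until
#'       [assign_charges] is called)}
#'     \item{sequence}{named character vector, one-letter sequence per chain}
#'   }
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      bio3d::read.cif(path, verbose = FALSE)
    else
      bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e)
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0)
    stop("empty structure: no standard amino-acid ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  element <- toupper(at$elesy)
  bad <- is.na(element) | element == "" | !element %in% names(c(vdw_radii()))
  if (any(bad)) {
    # derive from the atom name: strip leading digits, take leading letters
    guess <- sub("^[0-9]*", "", at$elety[bad])
    two <- toupper(substr(guess, 1, 2))
    one <- toupper(substr(guess, 1, 1))
    element[bad] <- ifelse(two %in% c("SE"), two, one)
  }
  at <- at[element != "H", , drop = FALSE]
  element <- element[element != "H"]
  if (nrow(at) == 0)
    stop("empty structure: only hydrogens present in ", path)

  # altloc resolution: per (chain, resno, insert, atom name) keep the
  # highest occupancy, first-encountered on ties
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(factor(akey, levels = unique(akey)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  element <- element[ord]
  keep <- !duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                            sep = "|"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]

  rad <- vdw_radii()[element]
  rad[is.na(rad)] <- 1.70
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = at$insert, resid = at$resid,
                      elety = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z,
                      radius = unname(rad), occupancy = at$o,
                      stringsAsFactors = FALSE)
  stopifnot(all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
            all(atoms$radius > 0))
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), ,
                 drop = FALSE]
  rkey <- paste(atoms$chain, paste0(atoms$resno, atoms$insert), sep = ":")
  atoms$res_index <- match(rkey, unique(rkey))
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(res_index = atoms$res_index[first],
                         res_key = rkey[first],
                         chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resid = atoms$resid[first],
                         charge = NA_real_,
                         stringsAsFactors = FALSE)
  seqs <- vapply(split(residues, residues$chain),
                 function(d) paste(aa3_to_1(d$resid), collapse = ""), "")
  structure(list(atoms = atoms, residues = residues, sequence = seqs,
                 source = path),
            class = "charged_structure")
}

#' @export
print.charged_structure <- function(x, ...) {
  cat(sprintf("<charged_structure> %d residues, %d atoms, %d chain(s)\n",
              nrow(x$residues), nrow(x$atoms), length(x$sequence)))
  if (!all(is.na(x$residues$charge)))
    cat(sprintf("  net charge %+0.3g e (%d positive, %d negative residues)\n",
                sum(x$residues$charge),
                sum(x$residues$charge > 0), sum(x$residues$charge < 0)))
  invisible(x)
}

#' Assign per-residue formal charges
#'
#' Stamps every residue with the charge its type carries under `scheme`.
#' Residue types outside the scheme's table (none, for structures produced
#' by [parse_structure]) receive charge 0 with a warning.
#'
#' @param s A `charged_structure` from [parse_structure].
#' @param scheme A [charge_scheme()].
#' @return `s` with `residues$charge` filled in.
#' @export
assign_charges <- function(s, scheme = charge_scheme()) {
  stopifnot(inherits(s, "charged_structure"),
            inherits(scheme, "charge_scheme"))
  q <- scheme$charges[s$residues$resid]
  unknown <- is.na(q)
  if (any(unknown)) {
    warning("unknown residue type(s) assigned charge 0: ",
            paste(unique(s$residues$resid[unknown]), collapse = ", "))
    q[unknown] <- 0
  }
  s$residues$charge <- unname(q)
  s$scheme <- scheme
  s
}

#' Sequence-level charge density
#'
#' Counts positive and negative charge in a one-letter sequence under a
#' charge scheme and normalises by length, reproducing the
#' "charge per amino acid" summary used to relate scFv net charge to tonic
#' signaling.
#'
#' @param seq One-letter amino-acid sequence (single string).
#' @param scheme A [charge_scheme()].
#' @return An object of class `charge_density`: list with `net_charge`
#'   (e), `n_residues`, `net_per_residue`, `positive_per_residue`,
#'   `negative_per_residue`.
#' @examples
#' charge_density("KKDD")$net_per_residue   # 0
#' @export
charge_density <- function(seq, scheme = charge_scheme()) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  letters1 <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!letters1 %in% AA1)
  if (length(bad))
    stop("non-standard letter '", letters1[bad[1]], "' at position ", bad[1])
  q <- scheme$charges1[letters1]
  n <- length(q)
  out <- list(net_charge = sum(q),
              n_residues = n,
              net_per_residue = sum(q) / n,
              positive_per_residue = sum(q[q > 0]) / n,
              negative_per_residue = sum(q[q < 0]) / n)
  class(out) <- "charge_density"
  out
}

#' @export
print.charge_density <- function(x, ...) {
  cat(sprintf(paste0("<charge_density> n=%d net=%+0.4g e ",
                     "net/res=%+0.4g pos/res=%0.4g neg/res=%0.4g\n"),
              x$n_residues, x$net_charge, x$net_per_residue,
              x$positive_per_residue, x$negative_per_residue))
  invisible(x)
}

#' Read one-letter sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  vapply(seq_len(nrow(fa$ali)), function(i)
    paste(fa$ali[i, fa$ali[i, ] != "-"], collapse = ""), "") |>
    setNames(fa$id)
}
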