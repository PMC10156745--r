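# Reference tables: amino-acid codes, van der Waals radii, maximum ASA,
# side-chain pKa values.  All tables are exported so users can inspect or
# override them; CSV copies ship in inst/extdata for provenance.

#' Standard amino-acid three-letter codes
#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa3_to_1 <- function(x) {
  m <- setNames(AA1, AA3)
  out <- m[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1_to_3 <- function(x) {
  m <- setNames(AA3, AA1)
  out <- m[toupper(x)]
  unname(out)
}

#' Van der Waals radii by element
#'
#' Bondi-style van der Waals radii (Angstrom) for the heavy elements found
#' in protein structures.  Elements absent from the table fall back to
#' 1.70 A (carbon).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90, H = 1.20)
}

#' Theoretical maximum accessible surface area per residue type
#'
#' Theoretical maximum ASA values (Angstrom^2) for Gly-X-Gly tripeptides
#' (Tien et al. 2013), used to convert absolute SASA into relative SASA.
#'
#' @return Named numeric vector, names are three-letter residue codes.
#' @export
max_asa_tien <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' Maximum ASA table for single-sphere pseudo-residues
#'
#' Synthetic fixture structures represent each residue as one carbon-sized
#' sphere, so the appropriate normalisation is the isolated-sphere area
#' 4*pi*(r + probe)^2, identical for every residue type.  Use this table
#' when classifying surface residues of structures written by
#' [generate_shell_structure].
#'
#' @param radius Sphere radius in Angstrom (default carbon, 1.70).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @return Named numeric vector covering the 20 standard residue types.
#' @export
max_asa_sphere <- function(radius = 1.70, probe_radius = 1.4) {
  a <- 4 * pi * (radius + probe_radius)^2
  setNames(rep(a, length(AA3)), AA3)
}

# Standard side-chain pKa values (Thurlkill-style consensus table).
sidechain_pka <- function() {
  c(ASP = 3.65, GLU = 4.25, HIS = 6.00, CYS = 8.30,
    TYR = 10.07, LYS = 10.53, ARG = 12.48)
}

#' Construct a per-residue formal charge scheme
#'
#' Defines the charge each residue type carries when patches are detected.
#' The default is the integer convention at pH 7.5: ARG and LYS +1, ASP and
#' GLU -1, HIS 0, everything else 0.  Integer charges make patch membership
#' binary and therefore exactly testable.  A Henderson-Hasselbalch
#' fractional mode is available for charge-density summaries
#' (q = 1/(1 + 10^(pH - pKa)) for bases, -1/(1 + 10^(pKa - pH)) for acids,
#' covering Asp, Glu, His, Cys, Tyr, Lys, Arg).
#'
#' @param mode `"integer"` (default) or `"fractional"`.
#' @param pH Solution pH; default 7.5 (physiological-chemical convention
#'   used throughout, matching 0.15 M ionic strength).
#' @param histidine_mode How histidine is charged: `"neutral"` (default at
#'   pH 7.5), `"positive"` (+1), or `"fractional"`
#'   (Henderson-Hasselbalch at `pH`).
#' @return An object of class `charge_scheme` with elements `charges`
#'   (named by three-letter code), `charges1` (named by one-letter code),
#'   `mode`, `pH`, `histidine_mode`.
#' @examples
#' sc <- charge_scheme()
#' sc$charges[c("LYS", "ARG", "ASP", "HIS", "GLY")]
#' @export
charge_scheme <- function(mode = c("integer", "fractional"), pH = 7.5,
                          histidine_mode = c("neutral", "positive",
                                             "fractional")) {
  mode <- match.arg(mode)
  histidine_mode <- match.arg(histidine_mode)
  stopifnot(is.numeric(pH), length(pH) == 1, is.finite(pH))
  pka <- sidechain_pka()
  hh_base <- function(pk)  1 / (1 + 10^(pH - pk))
  hh_acid <- function(pk) -1 / (1 + 10^(pk - pH))
  q <- setNames(rep(0, length(AA3)), AA3)
  if (mode == "integer") {
    q[c("ARG", "LYS")] <- 1
    q[c("ASP", "GLU")] <- -1
  } else {
    q["ARG"] <- hh_base(pka["ARG"])
    q["LYS"] <- hh_base(pka["LYS"])
    q["ASP"] <- hh_acid(pka["ASP"])
    q["GLU"] <- hh_acid(pka["GLU"])
    q["CYS"] <- hh_acid(pka["CYS"])
    q["TYR"] <- hh_acid(pka["TYR"])
  }
  q["HIS"] <- switch(histidine_mode,
                     neutral = 0,
                     positive = 1,
                     fractional = hh_base(pka["HIS"]))
  stopifnot(all(q >= -1 & q <= 1))
  structure(list(charges = q,
                 charges1 = setNames(unname(q[AA3]), AA1),
                 mode = mode, pH = pH,
                 histidine_mode = histidine_mode),
            class = "charge_scheme")
}

#' @export
print.charge_scheme <- function(x, ...) {
  cat(sprintf("<charge_scheme> mode=%s pH=%.2f his=%s\n",
              x$mode, x$pH, x$histidine_mode))
  nz <- x$charges[x$charges != 0]
  if (length(nz))
    cat(paste(sprintf("  %s %+0.3g", names(nz), nz), collapse = "\n"), "\n")
  invisible(x)
}
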