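# Residue-level constant tables used throughout the scoring function.
# All tables are keyed by one-letter amino acid code.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

# Maximum side-chain rotamer count R and Wimley-White hydrophobicity index H.
ROTAMER_COUNT <- c(A = 1, C = 3, D = 18, E = 54, F = 18, G = 1, H = 36,
                   I = 9, K = 81, L = 9, M = 27, N = 36, P = 2, Q = 108,
                   R = 81, S = 3, T = 3, V = 3, W = 36, Y = 18)

HYDROPHOBICITY <- c(A = 0.2, C = -0.2, D = 1.2, E = 1.01, F = -1.1, G = 0,
                    H = 0.57, I = -0.3, K = 1, L = -0.6, M = -0.2, N = 0.4,
                    P = 0.5, Q = 0.6, R = 0.8, S = 0.1, T = 0.1, V = 0.1,
                    W = -1.9, Y = -0.9)

# Dielectric classes: charged / polar / other, with default per-class
# dielectric constants 9 / 8 / 7 used for the polar solvation energy; the
# Coulomb (EE) component uses the lowest value, 7, uniformly.
CHARGED_AA <- c("D", "E", "K", "R", "H")
POLAR_AA   <- c("S", "T", "N", "Q", "Y")

#' Dielectric class of each amino acid
#'
#' Charged (Asp, Glu, Lys, Arg, His), polar (Ser, Thr, Asn, Gln, Tyr) and
#' other residues are modeled with distinct dielectric constants (default
#' 9, 8 and 7) to mimic conformational flexibility in a rigid-body protocol.
#'
#' @param aa character vector of one-letter amino acid codes.
#' @return character vector with values `"charged"`, `"polar"` or `"other"`.
#' @export
#' @examples
#' dielectric_class(c("D", "S", "L"))
dielectric_class <- function(aa) {
  stopifnot(all(aa %in% AA1))
  out <- rep("other", length(aa))
  out[aa %in% CHARGED_AA] <- "charged"
  out[aa %in% POLAR_AA] <- "polar"
  out
}

# NACCESS/Chothia-style heavy-atom van der Waals radii by element (Angstrom).
DEFAULT_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80)

# Theoretical maximum accessible surface area per residue type (Angstrom^2),
# Tien et al. style reference for a fully exposed residue ("residue in
# water"); rSASA = SASA / reference.
MAX_ASA <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
             I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
             R = 274, S = 155, T = 172, V = 174, W = 285, Y = 263)

# Coulomb constant in kcal*Angstrom/(mol*e^2).
COULOMB_K <- 332.0636

#' Van der Waals radii table for surface calculations
#'
#' @param radii named numeric vector, element symbol -> radius (Angstrom).
#' @param probe_radius solvent probe radius (Angstrom, default 1.4).
#' @param n_sphere_points quadrature points per atom (default 960).
#' @return an object of class `radii_table`.
#' @export
radii_table <- function(radii = DEFAULT_RADII, probe_radius = 1.4,
                        n_sphere_points = 960) {
  stopifnot(is.numeric(radii), length(radii) > 0, !is.null(names(radii)))
  if (any(radii <= 0.5 | radii >= 3.0))
    stop("van der Waals radii must lie in (0.5, 3.0) Angstrom")
  if (n_sphere_points < 60)
    stop("n_sphere_points must be >= 60")
  structure(list(radii = radii, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "radii_table")
}

aa3to1 <- function(resid) {
  m <- match(toupper(resid), AA3)
  out <- names(AA3)[m]
  out
}

aa1to3 <- function(aa) {
  stopifnot(all(aa %in% AA1))
  unname(AA3[aa])
}
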