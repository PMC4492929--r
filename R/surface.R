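# Solvent accessible surface area (Shrake-Rupley quadrature over a
# deterministic generalized-spiral point set), relative SASA, interface
# areas, and the five-way residue location classification.

#' Deterministic generalized-spiral points on the unit sphere
#'
#' Saff-Kuijlaars spiral: near-uniform, fully deterministic quadrature nodes,
#' so SASA values are reproducible to the bit for a given point count.
#'
#' @param n number of points (>= 2).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(1, pmax(-1, h)))
  phi <- numeric(n)
  for (i in 2:(n - 1))
    phi[i] <- (phi[i - 1] + 3.6 / sqrt(n * (1 - h[i]^2))) %% (2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

atom_radii <- function(atoms, radii) {
  r <- radii$radii[atoms$element]
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1]
    stop(sprintf("no van der Waals radius for element '%s' (atom %s %s %s%d)",
                 atoms$element[bad], atoms$elety[bad], atoms$resid[bad],
                 atoms$chain[bad], atoms$resno[bad]), call. = FALSE)
  }
  unname(r)
}

#' Solvent accessible surface area of a structure
#'
#' Shrake-Rupley quadrature on the heavy atoms (hydrogens are ignored): each
#' atom is inflated by the probe radius, sampled with a deterministic spiral
#' point set, and a point counts as accessible when it lies outside every
#' neighboring inflated sphere.
#'
#' @param model a `structure_model`.
#' @param radii a [radii_table()].
#' @return list with `atom` (data.frame of heavy atoms with `sasa`, Angstrom^2)
#'   and `residue` (per-residue data.frame with summed `sasa`).
#' @export
compute_sasa <- function(model, radii = radii_table()) {
  a <- model$atoms[!model$atoms$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms in model", call. = FALSE)
  rads <- atom_radii(a, radii) + radii$probe_radius
  pts <- sphere_points(radii$n_sphere_points)
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(a)
  sasa <- numeric(n)
  # neighbor candidates via pairwise distances (fixtures are small; the
  # dominant cost is the per-atom point test, vectorized below)
  d2 <- as.matrix(stats::dist(xyz))^2
  maxr <- max(rads)
  for (i in seq_len(n)) {
    cutoff <- (rads[i] + maxr)^2
    nb <- which(d2[i, ] < cutoff & seq_len(n) != i)
    nb <- nb[d2[i, nb] < (rads[i] + rads[nb])^2]
    p <- pts * rads[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      acc <- nrow(p)
    } else {
      buried <- rep(FALSE, nrow(p))
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < rads[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    sasa[i] <- 4 * pi * rads[i]^2 * acc / radii$n_sphere_points
  }
  a$sasa <- sasa
  key <- residue_key(a$chain, a$resno, a$insert)
  res <- residue_table(new_structure_model(a))
  res$sasa <- as.numeric(tapply(sasa, key, sum)[res$key])
  list(atom = a, residue = res)
}

#' Relative solvent accessibility
#'
#' rSASA is the ratio between the SASA of a residue in the protein and its
#' reference SASA fully exposed in water (rSASA = 1 for a totally exposed
#' residue).  Values are not clipped and may mildly exceed 1.
#'
#' @param sasa residue SASA (Angstrom^2), vectorized.
#' @param aa one-letter residue type(s).
#' @param reference named reference table (defaults to the bundled
#'   theoretical maximum ASA values).
#' @return numeric rSASA fraction(s).
#' @export
relative_sasa <- function(sasa, aa, reference = MAX_ASA) {
  ref <- reference[aa]
  if (any(is.na(ref)))
    stop("no reference SASA for residue type(s): ",
         paste(unique(aa[is.na(ref)]), collapse = ","), call. = FALSE)
  unname(sasa / ref)
}

#' Per-residue SASA profile of a partnered complex
#'
#' Computes each residue's SASA in the complex and in its own unbound
#' monomer (rigid-body), the corresponding relative accessibilities and
#' their difference, and the location class.
#'
#' @param model complex `structure_model`.
#' @param chains_a,chains_b partner chain groupings.
#' @param radii a [radii_table()].
#' @return data.frame with columns `chain`, `resno`, `insert`, `aa`,
#'   `sasa_c`, `sasa_m`, `rsasa_c`, `rsasa_m`, `delta_rsasa`, `location`.
#' @export
sasa_profile <- function(model, chains_a, chains_b, radii = radii_table()) {
  sc <- compute_sasa(model, radii)$residue
  sm_a <- compute_sasa(subset_chains(model, chains_a), radii)$residue
  sm_b <- compute_sasa(subset_chains(model, chains_b), radii)$residue
  sm <- rbind(sm_a, sm_b)
  m <- match(sc$key, sm$key)
  out <- sc[, c("chain", "resno", "insert", "aa", "key")]
  out$sasa_c <- sc$sasa
  out$sasa_m <- sm$sasa[m]
  out$rsasa_c <- relative_sasa(out$sasa_c, out$aa)
  out$rsasa_m <- relative_sasa(out$sasa_m, out$aa)
  out$delta_rsasa <- out$rsasa_m - out$rsasa_c
  out$location <- classify_location(out$rsasa_m, out$rsasa_c)
  out
}

#' Classify a residue's interface location
#'
#' Five classes from relative accessibility in the monomer (rSASAm) and
#' complex (rSASAc) states: COR (interface core), SUP (interface support),
#' RIM (interface rim), INT (non-interface interior), SUR (non-interface
#' surface).  The 25% thresholds are applied with values exactly at 0.25
#' assigned to the "exposed" (> 25%) branch; "no change" means
#' |rSASAm - rSASAc| <= 1e-6.  Any residual combination (only reachable with
#' rSASAm < rSASAc, which rigid-body splitting cannot produce) is returned
#' as `"unclassifiable"` rather than silently defaulted.
#'
#' @param rsasa_m,rsasa_c relative SASA in the monomer and complex state.
#' @return character vector of class labels.
#' @export
classify_location <- function(rsasa_m, rsasa_c) {
  stopifnot(length(rsasa_m) == length(rsasa_c))
  delta <- rsasa_m - rsasa_c
  out <- rep("unclassifiable", length(delta))
  zero <- abs(delta) <= 1e-6
  pos <- delta > 1e-6
  out[pos & rsasa_c >= 0.25] <- "RIM"
  out[pos & rsasa_c < 0.25 & rsasa_m >= 0.25] <- "COR"
  out[pos & rsasa_c < 0.25 & rsasa_m < 0.25] <- "SUP"
  out[zero & rsasa_c >= 0.25] <- "SUR"
  out[zero & rsasa_c < 0.25] <- "INT"
  out
}

total_sasa <- function(model, radii) sum(compute_sasa(model, radii)$residue$sasa)

#' Interface areas and SASA-derived features of a case
#'
#' The interface area is reported with the positive buried-area convention,
#' `SASA(A) + SASA(B) - SASA(AB)`; `dd_sasa` is the WT-to-MT double
#' difference of total SASA (complex minus monomers, MT minus WT), and
#' `dd_sasa_over_interface_mt` normalizes it by the MT interface (defined as
#' 0, with a warning, for non-touching partners).
#'
#' @param case a [complex_case()].
#' @param radii a [radii_table()].
#' @return list with `interface_wt`, `interface_mt`, `dd_sasa`,
#'   `dd_sasa_over_interface_mt` (areas in Angstrom^2).
#' @export
surface_features <- function(case, radii = radii_table()) {
  f <- function(which) {
    parts <- split_partners(case, which)
    ab <- total_sasa(parts$complex, radii)
    a <- total_sasa(parts$monomer_a, radii)
    b <- total_sasa(parts$monomer_b, radii)
    c(ab = ab, a = a, b = b, interface = a + b - ab)
  }
  wt <- f("WT"); mt <- f("MT")
  dd_sasa <- (mt[["ab"]] - mt[["a"]] - mt[["b"]]) -
    (wt[["ab"]] - wt[["a"]] - wt[["b"]])
  interface_mt <- mt[["interface"]]
  if (interface_mt <= 0) {
    warning("MT interface area is zero (non-touching partners); normalized term set to 0")
    ratio <- 0
  } else {
    ratio <- dd_sasa / interface_mt
  }
  list(interface_wt = wt[["interface"]], interface_mt = interface_mt,
       dd_sasa = unname(dd_sasa), dd_sasa_over_interface_mt = unname(ratio))
}
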