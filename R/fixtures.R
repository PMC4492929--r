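# Deterministic toy two-chain complexes and simulated feature/ddG datasets.
# The toy geometry is deliberately schematic (extended chains with stylized
# side chains), built so that every downstream stage - SASA, interface
# classification, hydrogen-bond counting, feature assembly - is exercised
# without any external structure.

# Side-chain heavy-atom (and polar hydrogen) templates as offsets from CA:
# (dx along the chain, dy toward the binding partner, dz).  Hydrogens are
# appended only when requested.
SIDE_CHAIN_TEMPLATES <- list(
  G = list(),
  A = list(),
  S = list(OG = c(0.2, 2.9, 0)),
  C = list(SG = c(0.2, 2.9, 0)),
  T = list(OG1 = c(0.4, 2.8, 0.2), CG2 = c(-0.6, 2.4, -0.6)),
  V = list(CG1 = c(0.5, 2.6, 0.5), CG2 = c(-0.5, 2.6, -0.5)),
  L = list(CG = c(0, 2.9, 0), CD1 = c(0.7, 3.9, 0.5), CD2 = c(-0.7, 3.9, -0.5)),
  I = list(CG1 = c(0.4, 2.8, 0.3), CG2 = c(-0.8, 2.2, -0.6), CD1 = c(0.5, 4.1, 0.4)),
  M = list(CG = c(0, 2.9, 0), SD = c(0.3, 4.3, 0.2), CE = c(1.2, 5.3, 0.4)),
  P = list(CG = c(0.4, 2.7, 0.4), CD = c(-0.8, 1.8, 0.6)),
  F = list(CG = c(0, 2.9, 0), CZ = c(0, 5.2, 0)),
  W = list(CG = c(0, 2.9, 0), CD1 = c(0.9, 3.8, 0.3), NE1 = c(0.8, 5.0, 0.3)),
  Y = list(CG = c(0, 2.9, 0), CZ = c(0, 5.2, 0), OH = c(0, 6.5, 0)),
  D = list(CG = c(0, 2.9, 0), OD1 = c(0.9, 3.8, 0), OD2 = c(-0.9, 3.8, 0)),
  E = list(CG = c(0, 2.9, 0), CD = c(0, 4.2, 0), OE1 = c(0.9, 5.1, 0), OE2 = c(-0.9, 5.1, 0)),
  N = list(CG = c(0, 2.9, 0), OD1 = c(0.9, 3.8, 0), ND2 = c(-0.9, 3.8, 0)),
  Q = list(CG = c(0, 2.9, 0), CD = c(0, 4.2, 0), OE1 = c(0.9, 5.1, 0), NE2 = c(-0.9, 5.1, 0)),
  K = list(CG = c(0, 2.9, 0), CD = c(0, 4.2, 0), CE = c(0, 5.5, 0), NZ = c(0, 6.8, 0)),
  R = list(CG = c(0, 2.9, 0), CD = c(0, 4.2, 0), NE = c(0, 5.4, 0), CZ = c(0, 6.6, 0),
           NH1 = c(0.9, 7.4, 0), NH2 = c(-0.9, 7.4, 0)),
  H = list(CG = c(0, 2.9, 0), ND1 = c(0.9, 3.8, 0), CE1 = c(0.5, 5.0, 0),
           NE2 = c(-0.7, 4.9, 0))
)

SIDE_CHAIN_HYDROGENS <- list(
  S = list(HG = c(0.3, 3.85, 0)),
  T = list(HG1 = c(0.5, 3.75, 0.2)),
  Y = list(HH = c(0, 7.45, 0)),
  N = list(HD21 = c(-1.0, 4.75, 0), HD22 = c(-1.7, 3.4, 0)),
  Q = list(HE21 = c(-1.0, 6.05, 0), HE22 = c(-1.7, 4.7, 0)),
  K = list(HZ1 = c(0.5, 7.6, 0.3)),
  R = list(HE = c(0.6, 5.9, 0.5), HH11 = c(1.0, 8.35, 0)),
  H = list(HD1 = c(1.6, 3.6, 0.6))
)

build_toy_chain <- function(seq1, chain_id, y0, s, hydrogens, jitter_fun) {
  rows <- list()
  add <- function(name, pos, resno, resid, is_h) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", eleno = 0L, elety = name, resid = resid,
      chain = chain_id, resno = resno, insert = "",
      x = pos[1], y = pos[2], z = pos[3], occ = 1,
      element = if (is_h) "H" else derive_element(name),
      is_hydrogen = is_h, stringsAsFactors = FALSE)
  }
  aas <- strsplit(seq1, "")[[1]]
  stopifnot(all(aas %in% AA1))
  for (i in seq_along(aas)) {
    aa <- aas[i]
    resid3 <- aa1to3(aa)
    ca <- c((i - 1) * 3.8, y0, 0) + jitter_fun()
    loc <- function(off) ca + c(off[1], s * off[2], off[3])
    add("N", loc(c(-1.2, -0.5, 0.4)), i, resid3, FALSE)
    add("CA", ca, i, resid3, FALSE)
    add("C", loc(c(1.2, -0.5, 0.4)), i, resid3, FALSE)
    add("O", loc(c(1.4, -1.5, 1.0)), i, resid3, FALSE)
    if (hydrogens) add("H", loc(c(-1.8, -1.0, 1.0)), i, resid3, TRUE)
    if (aa != "G") add("CB", loc(c(0, 1.5, 0.3)), i, resid3, FALSE)
    for (nm in names(SIDE_CHAIN_TEMPLATES[[aa]]))
      add(nm, loc(SIDE_CHAIN_TEMPLATES[[aa]][[nm]]), i, resid3, FALSE)
    if (hydrogens && !is.null(SIDE_CHAIN_HYDROGENS[[aa]]))
      for (nm in names(SIDE_CHAIN_HYDROGENS[[aa]]))
        add(nm, loc(SIDE_CHAIN_HYDROGENS[[aa]][[nm]]), i, resid3, TRUE)
  }
  do.call(rbind, rows)
}

#' Build a deterministic toy two-chain complex
#'
#' Two extended chains facing each other across a gap along y, with
#' stylized side chains pointing into the interface.  Optionally plants a
#' Ser(A)-Asp(B) hydrogen bond at an exact H...O distance across the
#' interface, adds polar hydrogens, and derives the mutant complex by
#' naive side-chain relabeling at the declared site.  Fully deterministic
#' given `seed`.
#'
#' @param seq_a,seq_b one-letter sequences of chains A and B.
#' @param gap distance between the chain axes (Angstrom).
#' @param hydrogens add amide and polar side-chain hydrogens.
#' @param hbond optional list `(site_a, site_b, dist)` planting an
#'   H-bond between the Ser at `site_a` of chain A (donor HG) and the Asp
#'   at `site_b` of chain B (acceptor OD1); requires `hydrogens = TRUE`.
#' @param mutation optional [mutation_descriptor()]; the MT complex is the
#'   WT after [naive_mutate()] (self-mutations leave it identical).
#' @param seed RNG seed for the small coordinate jitter.
#' @param jitter jitter half-width (Angstrom).
#' @return list with `wt`, `mt` (`structure_model`s) and `mutation`.
#' @export
make_toy_complex <- function(seq_a, seq_b, gap = 12, hydrogens = FALSE,
                             hbond = NULL, mutation = NULL, seed = 1,
                             jitter = 0.02) {
  atoms <- with_seed(seed, {
    jf <- function() runif(3, -jitter, jitter)
    rbind(build_toy_chain(seq_a, "A", 0, +1, hydrogens, jf),
          build_toy_chain(seq_b, "B", gap, -1, hydrogens, jf))
  })
  if (!is.null(hbond)) {
    if (!hydrogens) stop("planting an H-bond requires hydrogens = TRUE", call. = FALSE)
    aas_a <- strsplit(seq_a, "")[[1]]; aas_b <- strsplit(seq_b, "")[[1]]
    if (aas_a[hbond$site_a] != "S" || aas_b[hbond$site_b] != "D")
      stop("hbond planting needs Ser at site_a (chain A) and Asp at site_b (chain B)",
           call. = FALSE)
    hg <- atoms$chain == "A" & atoms$resno == hbond$site_a & atoms$elety == "HG"
    target <- c(atoms$x[hg], atoms$y[hg] + hbond$dist, atoms$z[hg])
    sc <- atoms$chain == "B" & atoms$resno == hbond$site_b &
      atoms$elety %in% c("CB", "CG", "OD1", "OD2")
    od1 <- atoms$chain == "B" & atoms$resno == hbond$site_b & atoms$elety == "OD1"
    shift <- target - c(atoms$x[od1], atoms$y[od1], atoms$z[od1])
    atoms$x[sc] <- atoms$x[sc] + shift[1]
    atoms$y[sc] <- atoms$y[sc] + shift[2]
    atoms$z[sc] <- atoms$z[sc] + shift[3]
  }
  atoms$eleno <- seq_len(nrow(atoms))
  wt <- new_structure_model(atoms, "toy_wt")
  heavy <- wt$atoms[!wt$atoms$is_hydrogen, ]
  d <- as.matrix(stats::dist(cbind(heavy$x, heavy$y, heavy$z)))
  # clashes only count between non-bonded residues (same chain neighbors
  # are covalently linked through the peptide bond)
  sep <- outer(heavy$resno, heavy$resno, function(a, b) abs(a - b))
  same_chain <- outer(heavy$chain, heavy$chain, "==")
  nonbonded <- ifelse(same_chain, sep > 1, TRUE)
  if (any(d[nonbonded] < 1.5))
    stop("toy geometry produced an inter-residue heavy-atom clash (< 1.5 Angstrom)",
         call. = FALSE)
  mt <- if (is.null(mutation) || mutation$wt_aa == mutation$mt_aa) {
    new_structure_model(wt$atoms, "toy_mt")
  } else {
    naive_mutate(wt, mutation)
  }
  list(wt = wt, mt = mt, mutation = mutation)
}

#' Convenience: toy complex case
#'
#' Wraps [make_toy_complex()] output into a [complex_case()] (chain A is
#' partner a, chain B partner b).
#'
#' @inheritParams make_toy_complex
#' @return a [complex_case()].
#' @export
make_toy_case <- function(seq_a, seq_b, mutation, gap = 12,
                          hydrogens = FALSE, hbond = NULL, seed = 1) {
  toy <- make_toy_complex(seq_a, seq_b, gap = gap, hydrogens = hydrogens,
                          hbond = hbond, mutation = mutation, seed = seed)
  complex_case(toy$wt, toy$mt, "A", "B", mutation)
}

# Default simulated-feature distributions: spreads chosen once to roughly
# match the magnitudes the published weights act on (energies of a few
# kcal/mol, interface areas of order 10^3 Angstrom^2, a dimensionless
# normalized-area ratio of order 0.05).
DEFAULT_FEATURE_MEANS <- c(d_ie = 0, dd_ee = 0, dd_ve = 0, dd_sp = 0,
                           dd_sn = 0, dd_s = 0, dd_hydr = 0, d_hb = 0,
                           interface_mt = 1600, dd_sasa_over_interface = 0)
DEFAULT_FEATURE_SDS <- c(d_ie = 8, dd_ee = 2, dd_ve = 2, dd_sp = 2,
                         dd_sn = 40, dd_s = 1.5, dd_hydr = 1, d_hb = 1,
                         interface_mt = 400, dd_sasa_over_interface = 0.05)

#' Simulate a feature/ddG dataset from known weights
#'
#' Draws independent Gaussian features and generates
#' `ddg = w0 + sum_k w_k x_k + N(0, noise_sd)`, so regression-based stages
#' can be tested against a known ground truth.  Seed-reproducible; the
#' generating configuration is returned alongside the data.
#'
#' @param n_cases number of simulated cases.
#' @param true_weights a `weight_set` (default: the bundled full-dataset
#'   set).
#' @param feature_means,feature_sds named per-term Gaussian parameters.
#' @param noise_sd residual noise SD (kcal/mol).
#' @param seed RNG seed.
#' @return list with `features` (data.frame over `TERM_NAMES`), `ddg`,
#'   and `config`.
#' @export
simulate_dataset <- function(n_cases, true_weights = saambe_weights("tdb"),
                             feature_means = DEFAULT_FEATURE_MEANS,
                             feature_sds = DEFAULT_FEATURE_SDS,
                             noise_sd = 0.5, seed = 1) {
  stopifnot(n_cases > 0, noise_sd >= 0)
  out <- with_seed(seed, {
    features <- as.data.frame(lapply(setNames(TERM_NAMES, TERM_NAMES), function(t)
      rnorm(n_cases, feature_means[[t]], feature_sds[[t]])))
    noise <- rnorm(n_cases, 0, noise_sd)
    list(features = features, noise = noise)
  })
  signal <- as.numeric(as.matrix(out$features) %*% true_weights$weights[TERM_NAMES])
  ddg <- true_weights$w0 + signal + out$noise
  list(features = out$features, ddg = ddg,
       config = list(n_cases = n_cases, noise_sd = noise_sd, seed = seed,
                     w0 = true_weights$w0,
                     true_weights = true_weights$weights,
                     feature_means = feature_means,
                     feature_sds = feature_sds))
}

#' Simulated dataset with a planted dielectric optimum
#'
#' Each case carries latent per-group (charged/polar/other) energy
#' contributions.  At dielectric constants `(e1, e2, e3)` the Coulomb
#' feature is the `1/eps`-weighted mixture of its group contributions, the
#' polar-solvation feature follows a Born-like `1/eps - 1/eps_solvent`
#' dependence (solvent fixed at 80), and the van der Waals feature is
#' dielectric-independent.  ddG is generated from the features evaluated
#' at `true_eps`, so refitting across the grid peaks at the planted
#' combination: the solvation term's fixed solvent reference breaks the
#' overall-scale degeneracy a pure `1/eps` mixture would have.
#'
#' @param n_cases number of cases.
#' @param true_eps planted `(charged, polar, other)` dielectric constants.
#' @param weights generating weights for `dd_ee`, `dd_ve`, `dd_sp`.
#' @param latent_sd SD of the latent group contributions.
#' @param noise_sd residual noise SD (kcal/mol).
#' @param eps_solvent external (solvent) dielectric constant.
#' @param seed RNG seed.
#' @return list with `provider` (function of three dielectric constants
#'   returning the feature data.frame) and `ddg`.
#' @export
make_dielectric_scan_data <- function(n_cases = 800, true_eps = c(9, 8, 7),
                                      weights = c(dd_ee = 0.39, dd_ve = 0.19,
                                                  dd_sp = 0.43),
                                      latent_sd = 10, noise_sd = 0.1,
                                      eps_solvent = 80, seed = 1) {
  lat <- with_seed(seed, {
    list(ee = matrix(rnorm(n_cases * 3, 0, latent_sd), n_cases, 3),
         sp = matrix(rnorm(n_cases * 3, 0, latent_sd), n_cases, 3),
         # reaction-field part set by the fixed solvent dielectric: does not
         # rescale with the interior eps, anchoring the overall scale
         sp0 = rnorm(n_cases, 0, latent_sd / 10),
         ve = rnorm(n_cases, 0, latent_sd / 4),
         noise = rnorm(n_cases, 0, noise_sd))
  })
  provider <- function(eps_charged, eps_polar, eps_other) {
    eps <- c(eps_charged, eps_polar, eps_other)
    data.frame(dd_ee = as.numeric(lat$ee %*% (1 / eps)),
               dd_ve = lat$ve,
               dd_sp = as.numeric(lat$sp %*% (1 / eps - 1 / eps_solvent)) +
                 lat$sp0)
  }
  feats0 <- provider(true_eps[1], true_eps[2], true_eps[3])
  ddg <- as.numeric(as.matrix(feats0) %*% weights[c("dd_ee", "dd_ve", "dd_sp")]) +
    lat$noise
  list(provider = provider, ddg = ddg, true_eps = true_eps)
}
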