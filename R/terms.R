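# The ten features of the scoring formula:
#   d_ie      change of complex internal energy (imported)
#   dd_ee     double difference of Coulomb energy (imported, or internal
#             uniform-dielectric fallback)
#   dd_ve     double difference of van der Waals energy (imported)
#   dd_sp     double difference of polar solvation energy (imported)
#   dd_sn     double difference of nonpolar solvation; linear in SASA with
#             the slope absorbed into the weight, so the feature is the
#             double difference of total SASA
#   dd_s      double difference of rotamer entropy
#   dd_hydr   double difference of Wimley-White hydrophobicity
#   d_hb      hydrogen-bond balance change
#   interface_mt             MT interface area
#   dd_sasa_over_interface   dd_sasa normalized by the MT interface

TERM_NAMES <- c("d_ie", "dd_ee", "dd_ve", "dd_sp", "dd_sn", "dd_s",
                "dd_hydr", "d_hb", "interface_mt", "dd_sasa_over_interface")

#' Double difference of an energy-like quantity
#'
#' `(E_AB^MT - E_A^MT - E_B^MT) - (E_AB^WT - E_A^WT - E_B^WT)`: the change,
#' caused by the mutation, of a term's contribution to binding.
#'
#' @param ab_mt,a_mt,b_mt MT complex and monomer values.
#' @param ab_wt,a_wt,b_wt WT complex and monomer values.
#' @return the double difference.
#' @export
#' @examples
#' delta_delta(-10, -4, -3, -8, -4, -3)  # -2
delta_delta <- function(ab_mt, a_mt, b_mt, ab_wt, a_wt, b_wt) {
  vals <- list(ab_mt = ab_mt, a_mt = a_mt, b_mt = b_mt,
               ab_wt = ab_wt, a_wt = a_wt, b_wt = b_wt)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !is.finite(v))
      stop(sprintf("delta_delta: input '%s' is missing or non-finite", nm),
           call. = FALSE)
  }
  (ab_mt - a_mt - b_mt) - (ab_wt - a_wt - b_wt)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Rotamer entropy of a structure
#'
#' Per residue `S = ln[rSASA * (R - 1) + 1]`, where R is the maximum
#' side-chain rotamer count of the residue type: a fully exposed residue
#' samples all R rotamers, a fully buried one is frozen in a single rotamer.
#' rSASA is clipped to `[0, 1]` so the logarithm's argument stays >= 1.
#'
#' @param aa one-letter residue types.
#' @param rsasa matching relative accessibilities (state-appropriate:
#'   monomer rSASA when scoring a monomer, complex rSASA for the complex).
#' @return total entropy (dimensionless), summed over residues.
#' @export
#' @examples
#' rotamer_entropy("K", 1)    # log(81)
#' rotamer_entropy("A", 0.7)  # 0
rotamer_entropy <- function(aa, rsasa) {
  stopifnot(length(aa) == length(rsasa), all(aa %in% AA1))
  sum(log(clip01(rsasa) * (ROTAMER_COUNT[aa] - 1) + 1))
}

#' Hydrophobicity of a structure
#'
#' `HYDR = sum_j H_j * rSASA_j` over residues, with H the Wimley-White
#' hydrophobicity index: an exposed residue contributes its full index, a
#' buried one nothing.  rSASA is clipped to `[0, 1]`.
#'
#' @inheritParams rotamer_entropy
#' @return total hydrophobicity (dimensionless).
#' @export
#' @examples
#' hydrophobicity("W", 1)  # -1.9
hydrophobicity <- function(aa, rsasa) {
  stopifnot(length(aa) == length(rsasa), all(aa %in% AA1))
  sum(HYDROPHOBICITY[aa] * clip01(rsasa))
}

state_entropy <- function(model, radii) {
  res <- compute_sasa(model, radii)$residue
  rotamer_entropy(res$aa, relative_sasa(res$sasa, res$aa))
}

state_hydrophobicity <- function(model, radii) {
  res <- compute_sasa(model, radii)$residue
  hydrophobicity(res$aa, relative_sasa(res$sasa, res$aa))
}

HB_ELIGIBLE_AA <- c(POLAR_AA, CHARGED_AA)

#' Count hydrogen bonds in one state of a complex
#'
#' A hydrogen bond is an (H, O) atom pair closer than `cutoff` (default
#' 2.4 Angstrom) where the hydrogen is not an alpha/beta carbon hydrogen
#' (names HA*/HB*), both residues belong to the polar (S, T, N, Q, Y) or
#' charged (R, H, K, D, E) set, the pair is not intra-residue, and the
#' hydrogen is not covalently bound to that oxygen (< 1.2 Angstrom).
#' Nitrogen acceptors and bond geometry are deliberately ignored.  Any
#' oxygen of an eligible residue (including the backbone carbonyl) counts
#' as an acceptor.
#'
#' With `heavy_proxy = TRUE` (a documented deviation for hydrogen-free
#' inputs) donor N/O heavy atoms within 3.4 Angstrom of an acceptor O are
#' counted instead.
#'
#' @param model complex `structure_model` (hydrogens required unless
#'   `heavy_proxy`).
#' @param chains_a,chains_b partner chain groupings.
#' @param cutoff H...O distance cutoff (Angstrom).
#' @param heavy_proxy count donor-heavy-atom/acceptor pairs < 3.4 Angstrom.
#' @return list of integer counts `inter_ab`, `intra_aa`, `intra_bb`.
#' @export
count_hbonds <- function(model, chains_a, chains_b, cutoff = 2.4,
                         heavy_proxy = FALSE) {
  a <- model$atoms
  aa <- aa3to1(a$resid)
  eligible <- !is.na(aa) & aa %in% HB_ELIGIBLE_AA
  if (heavy_proxy) {
    don <- which(eligible & !a$is_hydrogen & a$element %in% c("N", "O"))
    cutoff <- 3.4
  } else {
    if (!any(a$is_hydrogen))
      stop("hydrogens required for hydrogen-bond counting (or set heavy_proxy = TRUE)",
           call. = FALSE)
    nm <- sub("^[0-9]+", "", a$elety)
    don <- which(eligible & a$is_hydrogen &
                   !(substr(nm, 1, 2) %in% c("HA", "HB")))
  }
  acc <- which(eligible & a$element == "O")
  counts <- c(inter_ab = 0L, intra_aa = 0L, intra_bb = 0L)
  if (length(don) == 0L || length(acc) == 0L)
    return(as.list(counts))
  keys <- residue_key(a$chain, a$resno, a$insert)
  seen <- character()
  for (d in don) {
    dx <- a$x[acc] - a$x[d]; dy <- a$y[acc] - a$y[d]; dz <- a$z[acc] - a$z[d]
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hits <- acc[dist < cutoff & dist >= 1.2 & keys[acc] != keys[d]]
    if (length(hits) == 0L) next
    d_in_a <- a$chain[d] %in% chains_a
    for (o in hits) {
      pair <- paste(sort(c(d, o)), collapse = "-")  # proxy mode: O can be on both sides
      if (pair %in% seen) next
      seen <- c(seen, pair)
      o_in_a <- a$chain[o] %in% chains_a
      slot <- if (d_in_a != o_in_a) "inter_ab" else if (d_in_a) "intra_aa" else "intra_bb"
      counts[slot] <- counts[slot] + 1L
    }
  }
  as.list(counts)
}

#' Hydrogen-bond balance change between mutant and wild type
#'
#' `(HB_AB^MT - HB_AA^MT - HB_BB^MT) - (HB_AB^WT - HB_AA^WT - HB_BB^WT)`:
#' extra inter-partner bonds in the mutant strengthen binding while extra
#' intra-monomer bonds stabilize the unbound monomers, hence the signs.
#'
#' @param wt_counts,mt_counts outputs of [count_hbonds()] computed with
#'   identical settings.
#' @return integer Delta-HB.
#' @export
hbond_delta <- function(wt_counts, mt_counts) {
  (mt_counts$inter_ab - mt_counts$intra_aa - mt_counts$intra_bb) -
    (wt_counts$inter_ab - wt_counts$intra_aa - wt_counts$intra_bb)
}

# Formal charge sites: Asp/Glu -1 at the carboxylate-oxygen midpoint,
# Lys +1 at NZ, Arg +1 at CZ, His +1 at the ND1/NE2 midpoint.
charge_sites <- function(model) {
  a <- model$atoms
  aa <- aa3to1(a$resid)
  keys <- residue_key(a$chain, a$resno, a$insert)
  out <- list()
  for (k in unique(keys[!is.na(aa) & aa %in% CHARGED_AA])) {
    sel <- a[keys == k, , drop = FALSE]
    type <- aa3to1(sel$resid[1])
    pick <- switch(type,
                   D = c("OD1", "OD2"), E = c("OE1", "OE2"),
                   K = "NZ", R = "CZ", H = c("ND1", "NE2"))
    at <- sel[sel$elety %in% pick, , drop = FALSE]
    if (nrow(at) == 0L) next  # truncated side chain: no charge site
    q <- if (type %in% c("D", "E")) -1 else 1
    out[[k]] <- c(mean(at$x), mean(at$y), mean(at$z), q)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(), q = numeric()))
  m <- do.call(rbind, out)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], q = m[, 4])
}

#' Coarse Coulomb electrostatic energy (internal fallback)
#'
#' Pairwise Coulomb energy over residue formal charges at a uniform
#' dielectric, `EE = sum_{i<j} 332.0636 q_i q_j / (eps * r_ij)` kcal/mol,
#' with inter-site distances clamped below at 1 Angstrom and same-residue
#' pairs excluded.  This is a deliberately coarse continuum stand-in for a
#' Poisson-Boltzmann Coulombic calculation; imported EE values always take
#' precedence when available.
#'
#' @param model a `structure_model`.
#' @param epsilon uniform dielectric constant (> 0, default 7).
#' @return EE in kcal/mol.
#' @export
coulomb_ee <- function(model, epsilon = 7) {
  if (epsilon <= 0) stop("dielectric constant must be positive", call. = FALSE)
  cs <- charge_sites(model)
  n <- nrow(cs)
  if (n < 2L) return(0)
  e <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    r <- pmax(1, sqrt((cs$x[j] - cs$x[i])^2 + (cs$y[j] - cs$y[i])^2 +
                        (cs$z[j] - cs$z[i])^2))
    e <- e + sum(COULOMB_K * cs$q[i] * cs$q[j] / (epsilon * r))
  }
  e
}

#' Load per-case imported energy components
#'
#' Reads a TSV with header `case_id, state, part, IE, EE, VE, SP` (states
#' WT/MT, parts AB/A/B, energies in kcal/mol; empty cells mean absent).
#'
#' @param path TSV file path.
#' @return named list by case_id; each element is
#'   `components[[state]][[part]]` with entries `IE`, `EE`, `VE`, `SP`
#'   (`NA` when absent), of class `energy_components`.
#' @export
load_energy_components <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("case_id", "state", "part")
  if (!all(need %in% names(df)))
    stop("energy components file must have columns case_id, state, part",
         call. = FALSE)
  comps <- c("IE", "EE", "VE", "SP")
  missing_cols <- setdiff(comps, names(df))
  if (length(missing_cols) > 0L) {
    warning("energy component column(s) absent: ",
            paste(missing_cols, collapse = ", "))
    for (m in missing_cols) df[[m]] <- ""
  }
  key <- paste(df$case_id, df$state, df$part)
  if (anyDuplicated(key))
    stop("duplicate energy rows for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (!all(df$state %in% c("WT", "MT")))
    stop("state must be WT or MT", call. = FALSE)
  if (!all(df$part %in% c("AB", "A", "B")))
    stop("part must be AB, A or B", call. = FALSE)
  parse_num <- function(x, row, col) {
    x <- trimws(x)
    if (x == "" || is.na(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop(sprintf("malformed number '%s' in column %s, row %d", x, col, row),
           call. = FALSE)
    v
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$case_id[i]
    if (is.null(out[[id]]))
      out[[id]] <- structure(list(WT = list(), MT = list()),
                             class = "energy_components",
                             provenance = "imported")
    out[[id]][[df$state[i]]][[df$part[i]]] <-
      lapply(setNames(comps, comps), function(cc) parse_num(df[[cc]][i], i, cc))
  }
  out
}

energy_of <- function(energies, state, part, comp) {
  if (is.null(energies)) return(NA_real_)
  v <- energies[[state]][[part]][[comp]]
  if (is.null(v)) NA_real_ else v
}

dd_from_energies <- function(energies, comp) {
  vals <- c(energy_of(energies, "MT", "AB", comp),
            energy_of(energies, "MT", "A", comp),
            energy_of(energies, "MT", "B", comp),
            energy_of(energies, "WT", "AB", comp),
            energy_of(energies, "WT", "A", comp),
            energy_of(energies, "WT", "B", comp))
  if (any(is.na(vals))) return(NA_real_)
  delta_delta(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
}

#' Assemble the full feature vector of a case
#'
#' Structure-derived terms (entropy, hydrophobicity, hydrogen bonds,
#' nonpolar solvation proxy, interface areas) are computed from the
#' coordinates; molecular-mechanics terms (`d_ie`, `dd_ve`, `dd_sp`, and
#' normally `dd_ee`) come from imported energy components.  `d_ie` uses the
#' complexes only (the rigid-body double difference of internal energy is
#' identically zero).  When `ee_fallback = TRUE` and no imported EE is
#' available, the internal uniform-dielectric Coulomb stand-in is used.
#' Terms that cannot be obtained are `NA` with provenance `"absent"`.
#'
#' @param case a [complex_case()].
#' @param energies one case's `energy_components` (or `NULL`).
#' @param radii a [radii_table()].
#' @param hb_cutoff hydrogen-bond distance cutoff (Angstrom).
#' @param hb_heavy_proxy heavy-atom proxy for hydrogen-free inputs.
#' @param ee_fallback allow the internal Coulomb fallback for `dd_ee`.
#' @param ee_epsilon dielectric for the fallback (default 7).
#' @return named numeric `term_vector` (see `TERM_NAMES`) with a
#'   `provenance` attribute.
#' @export
assemble_terms <- function(case, energies = NULL, radii = radii_table(),
                           hb_cutoff = 2.4, hb_heavy_proxy = FALSE,
                           ee_fallback = FALSE, ee_epsilon = 7) {
  wt <- split_partners(case, "WT")
  mt <- split_partners(case, "MT")

  terms <- setNames(rep(NA_real_, length(TERM_NAMES)), TERM_NAMES)
  prov <- setNames(rep("absent", length(TERM_NAMES)), TERM_NAMES)

  sf <- surface_features(case, radii)
  terms["interface_mt"] <- sf$interface_mt
  terms["dd_sasa_over_interface"] <- sf$dd_sasa_over_interface_mt
  terms["dd_sn"] <- sf$dd_sasa
  prov[c("interface_mt", "dd_sasa_over_interface", "dd_sn")] <- "structure"

  terms["dd_s"] <- delta_delta(
    state_entropy(mt$complex, radii), state_entropy(mt$monomer_a, radii),
    state_entropy(mt$monomer_b, radii),
    state_entropy(wt$complex, radii), state_entropy(wt$monomer_a, radii),
    state_entropy(wt$monomer_b, radii))
  terms["dd_hydr"] <- delta_delta(
    state_hydrophobicity(mt$complex, radii),
    state_hydrophobicity(mt$monomer_a, radii),
    state_hydrophobicity(mt$monomer_b, radii),
    state_hydrophobicity(wt$complex, radii),
    state_hydrophobicity(wt$monomer_a, radii),
    state_hydrophobicity(wt$monomer_b, radii))
  prov[c("dd_s", "dd_hydr")] <- "structure"

  hb_wt <- count_hbonds(wt$complex, case$chains_a, case$chains_b,
                        cutoff = hb_cutoff, heavy_proxy = hb_heavy_proxy)
  hb_mt <- count_hbonds(mt$complex, case$chains_a, case$chains_b,
                        cutoff = hb_cutoff, heavy_proxy = hb_heavy_proxy)
  terms["d_hb"] <- hbond_delta(hb_wt, hb_mt)
  prov["d_hb"] <- "structure"

  ie_mt <- energy_of(energies, "MT", "AB", "IE")
  ie_wt <- energy_of(energies, "WT", "AB", "IE")
  if (!is.na(ie_mt) && !is.na(ie_wt)) {
    terms["d_ie"] <- ie_mt - ie_wt
    prov["d_ie"] <- "imported"
  }
  for (comp in c("EE", "VE", "SP")) {
    nm <- c(EE = "dd_ee", VE = "dd_ve", SP = "dd_sp")[[comp]]
    v <- dd_from_energies(energies, comp)
    if (!is.na(v)) {
      terms[nm] <- v
      prov[nm] <- "imported"
    }
  }
  if (is.na(terms["dd_ee"]) && ee_fallback) {
    terms["dd_ee"] <- delta_delta(
      coulomb_ee(mt$complex, ee_epsilon), coulomb_ee(mt$monomer_a, ee_epsilon),
      coulomb_ee(mt$monomer_b, ee_epsilon),
      coulomb_ee(wt$complex, ee_epsilon), coulomb_ee(wt$monomer_a, ee_epsilon),
      coulomb_ee(wt$monomer_b, ee_epsilon))
    prov["dd_ee"] <- "internal"
  }
  structure(terms, provenance = prov, class = c("term_vector", "numeric"))
}
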