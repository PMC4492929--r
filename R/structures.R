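# Structure handling: PDB parsing (via bio3d), the two-partner complex model,
# rigid-body splitting, and mutation descriptors.
#
# A structure_model carries an atom table in bio3d column convention:
# type, eleno, elety, alt, resid, chain, resno, insert, x, y, z, occ,
# element, is_hydrogen.  Residues keep PDB author numbering (with insertion
# codes) verbatim; no renumbering is ever performed.

WATER_RESIDS <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SOL")

residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, insert)
}

derive_element <- function(elety) {
  nm <- sub("^[0-9]+", "", trimws(elety))
  el <- ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
  # two-letter elements that occur in practice (ions when heteroatoms kept)
  two <- toupper(nm) %in% c("ZN", "MG", "FE", "CA2", "NA", "CL", "MN", "CU", "SE")
  el[two] <- toupper(nm[two])
  el
}

new_structure_model <- function(atoms, source_label = "", n_waters = 0L) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_label = source_label,
                 n_waters = as.integer(n_waters)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues, chains [%s], %d waters removed\n",
              x$source_label, nrow(x$atoms), nrow(residue_table(x)),
              paste(sort(unique(x$atoms$chain)), collapse = ","), x$n_waters))
  invisible(x)
}

chain_ids <- function(model) sort(unique(model$atoms$chain))

# Pre-scan raw PDB text so malformed coordinate records are reported with
# their line number (bio3d's own error does not carry one).
check_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(coords))
    if (any(is.na(vals)) || any(!is.finite(vals)))
      stop(sprintf("PDB format error at line %d: cannot parse coordinates from '%s'",
                   i, lines[i]), call. = FALSE)
  }
  invisible(TRUE)
}

# Keep, within each (chain, resno, insert, elety) group, the altloc with the
# highest occupancy; ties go to the alphabetically first altloc identifier.
resolve_altloc <- function(atoms) {
  alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  if (all(alt == "")) return(atoms)
  key <- paste(residue_key(atoms$chain, atoms$resno, atoms$insert), atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    if (length(ii) == 1L) return(ii)
    occ <- atoms$occ[ii]
    cand <- ii[occ == max(occ)]
    cand[order(alt[cand])][1L]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a PDB file or PDB-format text into a structure model
#'
#' Fixed-column ATOM/HETATM records are parsed (through [bio3d::read.pdb()]).
#' Crystallographic waters are always removed from the working model (their
#' count is retained in the `n_waters` field); other HETATM records are
#' removed when `drop_heteroatoms = TRUE`.  Alternate locations are resolved
#' to the highest-occupancy conformer (ties alphabetically).  Non-canonical
#' ATOM residues are rejected because the residue-level constant tables only
#' cover the 20 canonical amino acids.
#'
#' @param source path to a PDB file, or a character vector / single string of
#'   PDB-format text.
#' @param drop_heteroatoms drop HETATM records (default `TRUE`).
#' @param source_label label stored on the model (defaults to the file name).
#' @return a `structure_model`.
#' @export
read_pdb <- function(source, drop_heteroatoms = TRUE, source_label = NULL) {
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  if (is_path) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(source_label)) source_label <- basename(source)
  } else {
    lines <- if (length(source) == 1L) strsplit(source, "\n", fixed = TRUE)[[1]] else source
    if (is.null(source_label)) source_label <- "<text>"
  }
  check_pdb_lines(lines)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE))
  atoms <- pdb$atom
  names(atoms)[names(atoms) == "o"] <- "occ"
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms$chain <- ifelse(is.na(atoms$chain), "", atoms$chain)

  is_water <- atoms$resid %in% WATER_RESIDS
  n_waters <- sum(is_water)
  atoms <- atoms[!is_water, , drop = FALSE]
  if (drop_heteroatoms) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms remain after filtering", call. = FALSE)

  bad <- atoms$type == "ATOM" & !(toupper(atoms$resid) %in% AA3)
  if (any(bad))
    stop(sprintf("non-canonical residue(s) in ATOM records: %s",
                 paste(unique(atoms$resid[bad]), collapse = ", ")), call. = FALSE)

  atoms <- resolve_altloc(atoms)
  element <- atoms$elesy
  miss <- is.na(element) | element == ""
  element[miss] <- derive_element(atoms$elety[miss])
  atoms$element <- toupper(element)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")

  keep <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "occ", "element", "is_hydrogen")
  atoms <- atoms[, keep]
  new_structure_model(atoms, source_label, n_waters)
}

#' Write a structure model as fixed-column PDB text
#'
#' @param model a `structure_model`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return character vector of PDB lines (invisibly when writing to a file).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  name4 <- ifelse(nchar(a$elety) <= 3 & nchar(a$element) == 1,
                  paste0(" ", a$elety), a$elety)
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$type, a$eleno %% 100000L, name4, "", a$resid, a$chain,
                   a$resno, ifelse(a$insert == "", " ", a$insert),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Per-residue summary table of a structure model
#'
#' One row per residue in file order: chain, author number, insertion code,
#' three- and one-letter type, heavy-atom count.
#'
#' @param model a `structure_model`.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`, `aa`,
#'   `key`, `n_heavy`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    aa = aa3to1(a$resid[first]), key = key[first],
                    stringsAsFactors = FALSE)
  out$n_heavy <- as.integer(tapply(!a$is_hydrogen, key, sum)[out$key])
  rownames(out) <- NULL
  out
}

subset_chains <- function(model, chains, label = NULL) {
  atoms <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  new_structure_model(atoms, label %||% paste0(model$source_label, "[",
                                               paste(chains, collapse = ""), "]"),
                      0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mutation descriptor
#'
#' @param chain chain identifier of the mutated residue.
#' @param site author residue number (PDB numbering, used verbatim).
#' @param wt_aa,mt_aa one-letter wild-type and mutant amino acids
#'   (`wt_aa == mt_aa` is allowed as a self-mutation control).
#' @param insert insertion code (default none).
#' @return a `mutation_descriptor`.
#' @export
mutation_descriptor <- function(chain, site, wt_aa, mt_aa, insert = "") {
  stopifnot(wt_aa %in% AA1, mt_aa %in% AA1, length(chain) == 1L)
  structure(list(chain = as.character(chain), site = as.integer(site),
                 insert = insert, wt_aa = wt_aa, mt_aa = mt_aa),
            class = "mutation_descriptor")
}

#' Parse a mutation string
#'
#' Accepts the CLI form `"A:123:Q>P"` (chain:site:wt>mt) and the SKEMPI form
#' `"QA123P"` (wt, chain, site with optional insertion code, mt).
#'
#' @param x mutation string.
#' @return a [mutation_descriptor()].
#' @export
parse_mutation <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([A-Za-z0-9]):(-?[0-9]+)([A-Za-z]?):([A-Z])>([A-Z])$", x))[[1]]
  if (length(m) == 6L)
    return(mutation_descriptor(m[2], as.integer(m[3]), m[5], m[6], insert = toupper(m[4])))
  m <- regmatches(x, regexec("^([A-Z])([A-Za-z0-9])(-?[0-9]+)([a-z]?)([A-Z])$", x))[[1]]
  if (length(m) == 6L)
    return(mutation_descriptor(m[3], as.integer(m[4]), m[2], m[6], insert = toupper(m[5])))
  stop(sprintf("cannot parse mutation string '%s'", x), call. = FALSE)
}

#' Paired wild-type / mutant complex case
#'
#' The unit of prediction: WT and MT complex structures plus the rigid-body
#' grouping of chains into the two binding partners and the mutation
#' descriptor.  Partner chain sets must be disjoint, non-empty and jointly
#' cover every chain of the complex; the mutated chain must belong to exactly
#' one partner.
#'
#' @param wt,mt `structure_model`s of the wild-type and mutant complex.
#' @param chains_a,chains_b character vectors of chain ids of the partners.
#' @param mutation a [mutation_descriptor()].
#' @return a `complex_case`.
#' @export
complex_case <- function(wt, mt, chains_a, chains_b, mutation) {
  stopifnot(inherits(wt, "structure_model"), inherits(mt, "structure_model"),
            inherits(mutation, "mutation_descriptor"))
  chains_a <- as.character(chains_a); chains_b <- as.character(chains_b)
  if (length(chains_a) == 0L || length(chains_b) == 0L)
    stop("both partners need at least one chain", call. = FALSE)
  if (length(intersect(chains_a, chains_b)) > 0L)
    stop("partner chain sets overlap: ",
         paste(intersect(chains_a, chains_b), collapse = ","), call. = FALSE)
  all_chains <- union(chain_ids(wt), chain_ids(mt))
  uncovered <- setdiff(all_chains, union(chains_a, chains_b))
  if (length(uncovered) > 0L)
    stop("chain grouping does not cover chain(s): ",
         paste(uncovered, collapse = ","), call. = FALSE)
  if (!(mutation$chain %in% union(chains_a, chains_b)))
    stop("mutation chain '", mutation$chain, "' not in either partner", call. = FALSE)
  structure(list(wt = wt, mt = mt, chains_a = chains_a, chains_b = chains_b,
                 mutation = mutation),
            class = "complex_case")
}

#' Rigid-body split of a complex into its two binding partners
#'
#' Unbound monomer structures are taken from the complex unchanged: monomer
#' coordinates are bit-identical to their coordinates in the complex, and the
#' two monomers partition the complex atoms.
#'
#' @param case a [complex_case()].
#' @param which `"WT"` or `"MT"`.
#' @return list with `complex`, `monomer_a`, `monomer_b` structure models.
#' @export
split_partners <- function(case, which = c("WT", "MT")) {
  which <- match.arg(which)
  model <- if (which == "WT") case$wt else case$mt
  list(complex = model,
       monomer_a = subset_chains(model, case$chains_a),
       monomer_b = subset_chains(model, case$chains_b))
}

residue_atoms <- function(model, chain, resno, insert = "") {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$insert == insert, , drop = FALSE]
}

#' Validate a complex case against its mutation descriptor
#'
#' Checks that the WT complex carries the declared wild-type residue at the
#' mutation site and the MT complex the mutant residue, and that WT and MT
#' differ only in side-chain atoms at that site.  Report-based: nothing is
#' thrown.
#'
#' @param case a [complex_case()].
#' @return list with character vectors `violations` and `warnings`.
#' @export
validate_case <- function(case) {
  violations <- character(); warnings <- character()
  mut <- case$mutation
  wt_res <- residue_atoms(case$wt, mut$chain, mut$site, mut$insert)
  mt_res <- residue_atoms(case$mt, mut$chain, mut$site, mut$insert)
  if (nrow(wt_res) == 0L) {
    violations <- c(violations, sprintf("site %s:%d%s absent from WT complex",
                                        mut$chain, mut$site, mut$insert))
  } else if (aa3to1(wt_res$resid[1]) != mut$wt_aa) {
    violations <- c(violations, sprintf(
      "WT residue mismatch at %s:%d%s: model has %s, descriptor says %s",
      mut$chain, mut$site, mut$insert, aa3to1(wt_res$resid[1]), mut$wt_aa))
  }
  if (nrow(mt_res) == 0L) {
    violations <- c(violations, sprintf("site %s:%d%s absent from MT complex",
                                        mut$chain, mut$site, mut$insert))
  } else if (aa3to1(mt_res$resid[1]) != mut$mt_aa) {
    violations <- c(violations, sprintf(
      "MT residue mismatch at %s:%d%s: model has %s, descriptor says %s",
      mut$chain, mut$site, mut$insert, aa3to1(mt_res$resid[1]), mut$mt_aa))
  }

  rt_wt <- residue_table(case$wt); rt_mt <- residue_table(case$mt)
  site_key <- residue_key(mut$chain, mut$site, mut$insert)
  if (!identical(rt_wt$key[rt_wt$key != site_key], rt_mt$key[rt_mt$key != site_key])) {
    violations <- c(violations, "WT and MT complexes differ outside the mutation site (residue inventory)")
  } else {
    for (k in rt_wt$key[rt_wt$key != site_key]) {
      aw <- case$wt$atoms[residue_key(case$wt$atoms$chain, case$wt$atoms$resno, case$wt$atoms$insert) == k, ]
      am <- case$mt$atoms[residue_key(case$mt$atoms$chain, case$mt$atoms$resno, case$mt$atoms$insert) == k, ]
      if (!identical(sort(aw$elety[!aw$is_hydrogen]), sort(am$elety[!am$is_hydrogen]))) {
        violations <- c(violations, sprintf("heavy-atom inventory differs outside the mutation site at %s", k))
        break
      }
    }
  }
  if (sum(case$wt$atoms$is_hydrogen) != sum(case$mt$atoms$is_hydrogen))
    warnings <- c(warnings, "hydrogen inventory differs between WT and MT")
  list(violations = violations, warnings = warnings)
}

#' Naive side-chain relabeling mutation (fixtures only)
#'
#' Relabels the residue at the mutation site to the mutant type and strips
#' side-chain atoms beyond C-beta (and side-chain hydrogens).  This is a
#' deliberately non-physical convenience for building test fixtures; real
#' mutant structures should be prepared with a side-chain modeling and
#' minimization pipeline and supplied as inputs.
#'
#' @param model a `structure_model`.
#' @param mutation a [mutation_descriptor()].
#' @return mutated `structure_model`.
#' @export
naive_mutate <- function(model, mutation) {
  a <- model$atoms
  at_site <- a$chain == mutation$chain & a$resno == mutation$site &
    a$insert == mutation$insert
  if (!any(at_site))
    stop("mutation site not found in model", call. = FALSE)
  if (aa3to1(a$resid[at_site][1]) != mutation$wt_aa)
    stop("model residue at site is not the declared wild type", call. = FALSE)
  keep_names <- c("N", "CA", "C", "O", "OXT", "H", "HA")
  if (mutation$mt_aa != "G") keep_names <- c(keep_names, "CB")
  drop <- at_site & !(a$elety %in% keep_names)
  a <- a[!drop, , drop = FALSE]
  at_site <- a$chain == mutation$chain & a$resno == mutation$site &
    a$insert == mutation$insert
  a$resid[at_site] <- aa1to3(mutation$mt_aa)
  new_structure_model(a, paste0(model$source_label, ">", mutation$mt_aa),
                      model$n_waters)
}
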