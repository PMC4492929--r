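# Shared fixture builders and independent oracles.

# Compact structure builder: rows of (name, resid3, chain, resno, x, y, z).
make_model <- function(..., label = "fixture") {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r) {
    nm <- r[[1]]
    data.frame(type = "ATOM", eleno = 0L, elety = nm, resid = r[[2]],
               chain = r[[3]], resno = as.integer(r[[4]]), insert = "",
               x = as.numeric(r[[5]]), y = as.numeric(r[[6]]),
               z = as.numeric(r[[7]]), occ = 1,
               element = saambe:::derive_element(nm),
               is_hydrogen = saambe:::derive_element(nm) == "H",
               stringsAsFactors = FALSE)
  }))
  atoms$eleno <- seq_len(nrow(atoms))
  saambe:::new_structure_model(atoms, label)
}

# Independent SASA oracle: golden-angle Fibonacci sphere (a different point
# generator from the implementation's Saff-Kuijlaars spiral) and a direct
# all-atoms burial test per point.
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

sasa_oracle <- function(model, n_points = 10000, probe = 1.4,
                        radii = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85,
                                  P = 1.80)) {
  a <- model$atoms[!model$atoms$is_hydrogen, , drop = FALSE]
  rads <- unname(radii[a$element]) + probe
  pts <- fib_sphere(n_points)
  vapply(seq_len(nrow(a)), function(i) {
    p <- sweep(pts * rads[i], 2, c(a$x[i], a$y[i], a$z[i]), "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      d2 <- (p[, 1] - a$x[j])^2 + (p[, 2] - a$y[j])^2 + (p[, 3] - a$z[j])^2
      exposed <- exposed & d2 >= rads[j]^2
    }
    4 * pi * rads[i]^2 * sum(exposed) / n_points
  }, 0)
}

# Brute-force all-pairs hydrogen-bond oracle, re-stating the counting rule
# independently of the implementation.
hbond_oracle <- function(model, chains_a, chains_b, cutoff = 2.4) {
  a <- model$atoms
  aa1 <- saambe:::aa3to1(a$resid)
  elig <- !is.na(aa1) & aa1 %in% c("S", "T", "N", "Q", "Y", "R", "H", "K", "D", "E")
  key <- paste(a$chain, a$resno, a$insert)
  counts <- c(inter_ab = 0L, intra_aa = 0L, intra_bb = 0L)
  for (h in seq_len(nrow(a))) {
    if (!a$is_hydrogen[h] || !elig[h]) next
    base <- sub("^[0-9]+", "", a$elety[h])
    if (substr(base, 1, 2) %in% c("HA", "HB")) next
    for (o in seq_len(nrow(a))) {
      if (a$element[o] != "O" || !elig[o] || key[h] == key[o]) next
      d <- sqrt((a$x[h] - a$x[o])^2 + (a$y[h] - a$y[o])^2 + (a$z[h] - a$z[o])^2)
      if (d >= cutoff || d < 1.2) next
      ha <- a$chain[h] %in% chains_a
      oa <- a$chain[o] %in% chains_a
      slot <- if (ha != oa) "inter_ab" else if (ha) "intra_aa" else "intra_bb"
      counts[slot] <- counts[slot] + 1L
    }
  }
  as.list(counts)
}

# Toy PDB text: two chains, 10 ATOM records, 2 ion HETATM, 1 water.
toy_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000  -0.800  -1.200  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.500  -1.900  -1.400  1.00  0.00           O",
    "ATOM      6  N   SER B   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  SER B   1      11.458   0.000   0.000  1.00  0.00           C",
    "ATOM      8  CB  SER B   1      12.000   1.400   0.000  1.00  0.00           C",
    "ATOM      9  OG  SER B   1      13.300   1.500   0.500  1.00  0.00           O",
    "ATOM     10  C   SER B   1      12.000  -0.800  -1.200  1.00  0.00           C",
    "HETATM   11 ZN    ZN A  90       5.000   5.000   5.000  1.00  0.00          ZN",
    "HETATM   12 MG    MG B  91       6.000   6.000   6.000  1.00  0.00          MG",
    "HETATM   13  O   HOH A  92       7.000   7.000   7.000  1.00  0.00           O")
}
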