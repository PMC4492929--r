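test_that("the double-difference operator does exact arithmetic and flags gaps", {
  expect_equal(delta_delta(-10, -4, -3, -8, -4, -3), -2)
  expect_equal(delta_delta(5, 2, 1, 5, 2, 1), 0)
  expect_equal(delta_delta(0, 0, 0, 0, 0, 0), 0)
  expect_error(delta_delta(NA, 0, 0, 0, 0, 0), "ab_mt")
  expect_error(delta_delta(1, 2, 3, 4, 5, NULL), "b_wt")
})

test_that("rotamer entropy follows the log-rotamer form with clipping", {
  expect_equal(rotamer_entropy("K", 1), log(81))
  expect_equal(rotamer_entropy("A", 0.3), 0)
  expect_equal(rotamer_entropy("A", 1), 0)
  expect_equal(rotamer_entropy("D", 0.5), log(0.5 * 17 + 1))
  expect_equal(rotamer_entropy("K", 1.2), log(81))  # rSASA clipped at 1
  # additive over disjoint residue sets
  expect_equal(rotamer_entropy(c("K", "D"), c(1, 0.5)),
               rotamer_entropy("K", 1) + rotamer_entropy("D", 0.5))
})

test_that("hydrophobicity is the rSASA-weighted Wimley-White sum", {
  expect_equal(hydrophobicity("W", 1), -1.9)
  expect_equal(hydrophobicity(c("A", "K", "W"), c(0, 0, 0)), 0)
  expect_equal(hydrophobicity(c("D", "K"), c(0.5, 1.0)), 1.2 * 0.5 + 1.0)
})

test_that("hydrogen bonds obey the distance, name and residue-class rules", {
  base <- list(list("CB", "SER", "A", 1, -1.4, 0, -0.5),
               list("OG", "SER", "A", 1, 0, 0, 0),
               list("HG", "SER", "A", 1, 0, 0, 0.96),
               list("CG", "ASP", "B", 1, 1.0, 0, 4.0),
               list("OD1", "ASP", "B", 1, 0, 0, 3.26),
               list("OD2", "ASP", "B", 1, 2.0, 0, 4.6))
  m <- do.call(make_model, base)  # HG...OD1 = 2.30
  expect_equal(count_hbonds(m, "A", "B")$inter_ab, 1)

  far <- base; far[[5]][[7]] <- 3.46  # 2.50 away
  expect_equal(count_hbonds(do.call(make_model, far), "A", "B")$inter_ab, 0)

  # alpha hydrogens never donate
  ha <- base; ha[[3]][[1]] <- "HA"
  expect_equal(count_hbonds(do.call(make_model, ha), "A", "B")$inter_ab, 0)

  # both partners must be polar/charged: Ala backbone O is no acceptor
  ala <- list(list("OG", "SER", "A", 1, 0, 0, 0),
              list("CB", "SER", "A", 1, -1.4, 0, -0.5),
              list("HG", "SER", "A", 1, 0, 0, 0.96),
              list("CA", "ALA", "B", 1, 1.5, 0, 3.8),
              list("O", "ALA", "B", 1, 0, 0, 3.1))
  expect_equal(count_hbonds(do.call(make_model, ala), "A", "B")$inter_ab, 0)

  # own covalent OG-HG pair and intra-residue pairs never count
  solo <- do.call(make_model, base[1:3])
  expect_equal(unlist(count_hbonds(solo, "A", "B")), c(inter_ab = 0, intra_aa = 0, intra_bb = 0))

  # hydrogens are mandatory unless the heavy proxy is requested
  heavy <- do.call(make_model, base[-3])
  expect_error(count_hbonds(heavy, "A", "B"), "hydrogens required")
  expect_equal(count_hbonds(heavy, "A", "B", heavy_proxy = TRUE)$inter_ab, 1)
})

test_that("hydrogen-bond counting matches the all-pairs oracle", {
  # crowded hand-placed network: inter- and intra-partner bonds plus decoys
  crowd <- make_model(
    list("OG", "SER", "A", 1, 0, 0, 0), list("HG", "SER", "A", 1, 0, 0, 0.96),
    list("CB", "SER", "A", 1, -1.4, 0, -0.5),
    list("OG", "SER", "A", 2, 0.5, 0, 2.9),   # intra-A acceptor 1.95 from HG
    list("CB", "SER", "A", 2, 1.9, 0, 2.9),
    list("HG", "SER", "A", 2, 0.5, 0.95, 2.9),
    list("OD1", "ASP", "B", 1, 0, 0, 3.2),    # inter at 2.24 from A1 HG
    list("OD2", "ASP", "B", 1, 1.8, 0, 3.4),
    list("CG", "ASP", "B", 1, 0.9, 0, 4.0),
    list("ND2", "ASN", "B", 2, 0.5, 2.2, 3.0),
    list("HD21", "ASN", "B", 2, 0.5, 1.25, 3.0),  # 2.26 from B1 OD1... decoys
    list("CG", "ASN", "B", 2, 0.5, 3.3, 3.6),
    list("OD1", "ASN", "B", 2, 1.5, 3.9, 3.6),
    list("O", "ALA", "A", 3, 0.5, -0.5, 1.9))  # ineligible residue oxygen
  got <- count_hbonds(crowd, "A", "B")
  expect_identical(got, hbond_oracle(crowd, "A", "B"))
  expect_gt(got$inter_ab + got$intra_aa + got$intra_bb, 1)

  # planted inter-partner bonds across the cutoff boundary
  for (d in c(1.9, 2.39, 2.41, 3.0)) {
    toy <- make_toy_complex("GGSGG", "GGDGG", gap = 12, hydrogens = TRUE,
                            hbond = list(site_a = 3, site_b = 3, dist = d))
    expect_lt(nrow(toy$wt$atoms), 500)
    expect_equal(count_hbonds(toy$wt, "A", "B")$inter_ab, as.integer(d < 2.4))
    expect_identical(count_hbonds(toy$wt, "A", "B"),
                     hbond_oracle(toy$wt, "A", "B"))
  }
})

test_that("hbond_delta applies the inter-minus-intra balance", {
  wt <- list(inter_ab = 3, intra_aa = 2, intra_bb = 1)
  mt <- list(inter_ab = 4, intra_aa = 2, intra_bb = 1)
  expect_equal(hbond_delta(wt, mt), 1)
  expect_equal(hbond_delta(wt, wt), 0)
  expect_equal(hbond_delta(list(inter_ab = 0, intra_aa = 0, intra_bb = 0),
                           list(inter_ab = 0, intra_aa = 1, intra_bb = 0)), -1)
})

test_that("the Coulomb fallback uses formal charges at a uniform dielectric", {
  two <- make_model(list("NZ", "LYS", "A", 1, 0, 0, 0),
                    list("OD1", "ASP", "B", 2, 7, 1, 0),
                    list("OD2", "ASP", "B", 2, 7, -1, 0))
  expect_equal(coulomb_ee(two, 7), 332.0636 * (-1) / (7 * 7), tolerance = 1e-12)
  same <- make_model(list("NZ", "LYS", "A", 1, 0, 0, 0),
                     list("NZ", "LYS", "A", 2, 7, 0, 0))
  expect_equal(coulomb_ee(same, 7), 332.0636 / (7 * 7))
  one <- make_model(list("NZ", "LYS", "A", 1, 0, 0, 0))
  expect_equal(coulomb_ee(one, 7), 0)
  # sub-Angstrom separations are clamped to 1
  close <- make_model(list("NZ", "LYS", "A", 1, 0, 0, 0),
                      list("OD1", "ASP", "B", 2, 0.5, 0.2, 0),
                      list("OD2", "ASP", "B", 2, 0.5, -0.2, 0))
  expect_equal(coulomb_ee(close, 7), -332.0636 / 7)
  expect_error(coulomb_ee(two, 0), "positive")
})

test_that("energy component files load, warn and fail as specified", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tstate\tpart\tIE\tEE\tVE\tSP",
               "c1\tWT\tAB\t-100\t-50\t-20\t-10",
               "c1\tWT\tA\t\t-30\t-12\t-6",
               "c1\tWT\tB\t\t-15\t-6\t-3",
               "c1\tMT\tAB\t-98\t-48\t-19\t-9",
               "c1\tMT\tA\t\t-30\t-12\t-6",
               "c1\tMT\tB\t\t-15\t-6\t-3"), path)
  e <- load_energy_components(path)
  expect_named(e, "c1")
  expect_equal(e$c1$WT$AB$IE, -100)
  expect_true(is.na(e$c1$WT$A$IE))  # empty cell = absent

  nosp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tstate\tpart\tIE\tEE\tVE",
               "c1\tWT\tAB\t-100\t-50\t-20"), nosp)
  expect_warning(e2 <- load_energy_components(nosp), "SP")
  expect_true(is.na(e2$c1$WT$AB$SP))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tstate\tpart\tIE\tEE\tVE\tSP",
               "c1\tWT\tAB\t-100\t-50\t-20\t-10",
               "c1\tWT\tAB\t-99\t-50\t-20\t-10"), dup)
  expect_error(load_energy_components(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tstate\tpart\tIE\tEE\tVE\tSP",
               "c1\tWT\tAB\toops\t-50\t-20\t-10"), bad)
  expect_error(load_energy_components(bad), "malformed number")
})

test_that("a self-mutation yields the zero feature vector with interface intact", {
  case <- make_toy_case("ASDKG", "GSETA", mutation_descriptor("A", 3, "D", "D"),
                        gap = 13, hydrogens = TRUE)
  tv <- assemble_terms(case)
  for (t in c("dd_sn", "dd_s", "dd_hydr", "d_hb", "dd_sasa_over_interface"))
    expect_equal(unname(tv[t]), 0, info = t)
  expect_gt(tv[["interface_mt"]], 0)
  expect_true(is.na(tv[["d_ie"]]))  # no imported energies
})

test_that("swapping WT and MT negates every difference term", {
  mut <- mutation_descriptor("A", 3, "D", "A")
  case <- make_toy_case("ASDKG", "GSETA", mut, gap = 13, hydrogens = TRUE)
  fwd <- assemble_terms(case, ee_fallback = TRUE)
  swapped <- complex_case(case$mt, case$wt, "A", "B",
                          mutation_descriptor("A", 3, "A", "D"))
  rev <- assemble_terms(swapped, ee_fallback = TRUE)
  for (t in c("dd_ee", "dd_sn", "dd_s", "dd_hydr", "d_hb"))
    expect_equal(unname(rev[t]), -unname(fwd[t]), tolerance = 1e-9, info = t)
  # interface_mt now refers to the new mutant, i.e. the original WT complex
  expect_equal(unname(rev[["interface_mt"]]),
               surface_features(swapped)$interface_mt)
})

test_that("an H-bond gained in the mutant shows up as d_hb = +1", {
  wt <- make_toy_complex("GGSGG", "GGDGG", gap = 12, hydrogens = TRUE, seed = 5)
  mt <- make_toy_complex("GGSGG", "GGDGG", gap = 12, hydrogens = TRUE, seed = 5,
                         hbond = list(site_a = 3, site_b = 3, dist = 2.2))
  case <- complex_case(wt$wt, mt$wt, "A", "B",
                       mutation_descriptor("B", 3, "D", "D"))
  tv <- assemble_terms(case)
  expect_equal(unname(tv[["d_hb"]]), 1)
})

test_that("imported energies populate the MM/PBSA terms per the double difference", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tstate\tpart\tIE\tEE\tVE\tSP",
               "c1\tWT\tAB\t-100\t-8\t-20\t-10",
               "c1\tWT\tA\t\t-4\t-12\t-6",
               "c1\tWT\tB\t\t-3\t-6\t-3",
               "c1\tMT\tAB\t-98\t-10\t-19\t-9",
               "c1\tMT\tA\t\t-4\t-12\t-6",
               "c1\tMT\tB\t\t-3\t-6\t-3"), path)
  energies <- load_energy_components(path)$c1
  case <- make_toy_case("ASDKG", "GSETA", mutation_descriptor("A", 3, "D", "A"),
                        gap = 13, hydrogens = TRUE)
  tv <- assemble_terms(case, energies)
  expect_equal(unname(tv[["d_ie"]]), 2)      # complexes only
  expect_equal(unname(tv[["dd_ee"]]), -2)    # (-10+4+3) - (-8+4+3)
  expect_equal(unname(tv[["dd_ve"]]), 1)
  expect_equal(unname(tv[["dd_sp"]]), 1)
  expect_equal(attr(tv, "provenance")[["dd_ee"]], "imported")
})
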