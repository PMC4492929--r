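rec <- function(wt, mt, lw, lm, ddg) {
  data.frame(wt_aa = wt, mt_aa = mt, loc_wt = lw, loc_mt = lm, ddg_exp = ddg,
             stringsAsFactors = FALSE)
}

test_that("probability tables are exact empirical fractions of the 1 kcal/mol split", {
  one <- rec("G", "A", "COR", "COR", 2.0)
  t1 <- build_probability_tables(one)
  expect_equal(t1$wt_residue[t1$wt_residue$key == "G", c("p_small", "p_large")],
               data.frame(p_small = 0, p_large = 1),
               ignore_attr = TRUE)

  two <- rbind(rec("A", "G", "COR", "COR", 0.5), rec("A", "S", "RIM", "RIM", 1.5))
  t2 <- build_probability_tables(two)
  a <- t2$wt_residue[t2$wt_residue$key == "A", ]
  expect_equal(c(a$p_small, a$p_large), c(0.5, 0.5))

  # |ddG| exactly 1 counts as large
  t3 <- build_probability_tables(rec("A", "G", "COR", "COR", -1.0))
  expect_equal(t3$wt_residue$p_large, 1)

  expect_error(build_probability_tables(rec("A", "G", "COR", "COR", 1)[0, ]),
               "empty")
})

test_that("probabilities reproduce a brute-force recount on random datasets", {
  set.seed(42)
  n <- 60
  recs <- rec(sample(c("A", "G", "K"), n, TRUE), sample(c("P", "S"), n, TRUE),
              sample(c("COR", "RIM", "SUR"), n, TRUE),
              sample(c("COR", "SUP"), n, TRUE),
              round(rnorm(n, 1, 1.2), 3))
  tabs <- build_probability_tables(recs)
  for (aa in unique(recs$wt_aa)) {
    sel <- abs(recs$ddg_exp[recs$wt_aa == aa])
    expect_equal(tabs$wt_residue$p_large[tabs$wt_residue$key == aa],
                 sum(sel >= 1) / length(sel))
  }
  for (lc in unique(recs$loc_mt)) {
    sel <- abs(recs$ddg_exp[recs$loc_mt == lc])
    expect_equal(tabs$mt_location$p_large[tabs$mt_location$key == lc],
                 sum(sel >= 1) / length(sel))
  }
})

test_that("the magnitude alteration follows the two-branch flag formula", {
  expect_equal(alter_ddg(10, 1, c(0.2, 0.86, 0.68, 0.56)), 6.0)
  # neutral probabilities leave any magnitude unchanged
  for (v in c(0.2, 0.9999, 1, 3.7))
    expect_equal(alter_ddg(v, 2, rep(0.5, 4)), v)
  expect_equal(alter_ddg(0.5, 4, c(0.6, 0.6, 0.6, 0.1)), (2 / 3) * 1.8 * 0.5)
  # linear in |ddG| within each branch
  p <- c(0.3, 0.7, 0.4, 0.6)
  expect_equal(alter_ddg(0.8, 1, p), 4 * alter_ddg(0.2, 1, p))
  expect_equal(alter_ddg(8, 1, p), 4 * alter_ddg(2, 1, p))
})

test_that("reweighting is a fixed point for all-neutral tables", {
  neutral <- rbind(rec("A", "G", "COR", "RIM", 0.5),
                   rec("A", "G", "COR", "RIM", 1.5))
  t0 <- build_probability_tables(neutral)
  expect_true(all(t0$wt_residue$p_large == 0.5))
  t1 <- reweight_tables(neutral, t0)
  for (dm in c("wt_residue", "mt_residue", "wt_location", "mt_location"))
    expect_equal(t1[[dm]], t0[[dm]])
})

test_that("reweighting matches a hand-computed two-record alteration", {
  recs <- rbind(rec("A", "P", "COR", "COR", 2.0),
                rec("G", "P", "RIM", "COR", 0.4))
  t0 <- build_probability_tables(recs)
  # initial: P(A->any)=1, P(G->any)=0, P(any->P)=0.5, P(COR,WT)=1, P(RIM,WT)=0,
  # P(COR,MT)=0.5
  t1 <- reweight_tables(recs, t0)
  # wt_residue dimension (i = 1):
  # record 1 (|ddG|=2, large): (2/3)*((1-0.5)+(1-1)+(1-0.5))*2 = 4/3 -> large
  # record 2 (0.4, small): (2/3)*(0.5+0+0.5)*0.4 = 0.2667 -> small
  expect_equal(t1$wt_residue$p_large[t1$wt_residue$key == "A"], 1)
  expect_equal(t1$wt_residue$p_large[t1$wt_residue$key == "G"], 0)
  # mt_location dimension (i = 4), both records are COR in MT:
  # record 1: (2/3)*((1-1)+(1-0.5)+(1-1))*2 = 2/3 < 1 -> small now
  # record 2: (2/3)*(0+0.5+0)*0.4 = 0.1333 -> small
  expect_equal(t1$mt_location$p_large[t1$mt_location$key == "COR"], 0)

  # a single-record dataset keeps its probabilities in {0, 1}
  t2 <- reweight_tables(recs[1, ], build_probability_tables(recs[1, ]))
  expect_true(all(unlist(lapply(t2, function(d) d$p_large)) %in% c(0, 1)))
})

test_that("records with unknown flags are excluded from reweighting with a warning", {
  known <- rbind(rec("A", "P", "COR", "COR", 2.0),
                 rec("A", "P", "COR", "COR", 0.4))
  t0 <- build_probability_tables(known)
  mixed <- rbind(known, rec("W", "P", "COR", "COR", 1.0))
  expect_warning(t1 <- reweight_tables(mixed, t0), "undefined flag")
  expect_false("W" %in% t1$wt_residue$key)
})

test_that("consensus routing reproduces the bundled-table examples", {
  qp <- consensus_probability(mutation_annotation("Q", "P", "COR", "SUP"))
  expect_equal(qp$p, (0.19 + 0.81 + 0.66 + 0.56) / 4)
  expect_equal(qp$subset, "large")

  aa <- consensus_probability(mutation_annotation("A", "A", "SUR", "SUR"))
  expect_equal(aa$p, (0.42 + 0.36 + 0.08 + 0.10) / 4)
  expect_equal(aa$subset, "small")

  # boundary P = 0.5 is inclusive on the large side
  half <- saambe:::new_probability_tables(
    data.frame(key = "A", n = 2, p_small = 0.5, p_large = 0.5),
    data.frame(key = "A", n = 2, p_small = 0.5, p_large = 0.5),
    data.frame(key = "SUR", n = 2, p_small = 0.5, p_large = 0.5),
    data.frame(key = "SUR", n = 2, p_small = 0.5, p_large = 0.5))
  at_half <- consensus_probability(mutation_annotation("A", "A", "SUR", "SUR"),
                                   half)
  expect_equal(at_half$p, 0.5)
  expect_equal(at_half$subset, "large")

  expect_error(consensus_probability(mutation_annotation("W", "A", "SUR", "SUR"),
                                     half), "wt_residue")
})

test_that("the consensus is the plain mean of its four flag probabilities", {
  tabs <- bundled_probability_tables()
  cons <- consensus_probability(mutation_annotation("K", "G", "RIM", "COR"), tabs)
  expect_equal(cons$p, mean(cons$flags))
  expect_equal(cons$p, mean(sample(cons$flags)))  # order irrelevant
})

test_that("bundled printed tables sum to one within printed rounding", {
  tabs <- bundled_probability_tables()
  for (dm in c("wt_residue", "mt_residue", "wt_location", "mt_location")) {
    sums <- tabs[[dm]]$p_small + tabs[[dm]]$p_large
    expect_true(all(sums >= 0.99 & sums <= 1.01), info = dm)
  }
  expect_equal(nrow(tabs$wt_residue), 20)
  expect_equal(nrow(tabs$wt_location), 5)
})
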