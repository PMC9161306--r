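test_that("condition deviations follow the fixed 12-pair enumeration", {
  cp <- condition_pairs()
  expect_equal(nrow(cp), 12L)
  expect_equal(paste0(cp$j, "|", cp$i)[1:3], c("DS|DR", "NR|DR", "NS|DR"))
  expect_equal(paste0(cp$j, "|", cp$i)[10:12], c("DR|NS", "DS|NS", "NR|NS"))

  # all means equal -> 12 zeros
  s0 <- make_summary_row(rep(2, 4), rep(1, 4))
  expect_equal(unname(condition_deviations(s0)$d), rep(0, 12))

  # hand-arithmetic oracle over all 12 entries
  s <- make_summary_row(c(0, 1, 2, 3), c(1, 2, 1, 1))
  d <- condition_deviations(s)$d
  expect_equal(unname(d),
               c(1, 2, 3,            # (DS|DR, NR|DR, NS|DR) / sd(DR)=1
                 -0.5, 0.5, 1,       # (DR|DS, NR|DS, NS|DS) / sd(DS)=2
                 -2, -1, 1,          # (DR|NR, DS|NR, NS|NR) / sd(NR)=1
                 -3, -2, -1))        # (DR|NS, DS|NS, NR|NS) / sd(NS)=1
  expect_equal(d[["DS|DR"]], 1)
  expect_equal(d[["DR|DS"]], -0.5)
  expect_equal(d[["NS|NR"]], 1)

  # zero sd with a real mean difference lands in the outermost class
  sz <- make_summary_row(c(0, 1, 0, 0), c(0, 1, 1, 1))
  dz <- condition_deviations(sz)
  expect_equal(dz$d[["DS|DR"]], Inf)
  expect_equal(discretize_deviation(dz$d[["DS|DR"]]), 2)

  # absent condition invalidates its pairs
  sa <- make_summary_row(c(0, 1, 2, NA), c(1, 1, 1, NA))
  da <- condition_deviations(sa)
  expect_false(any(da$valid[grepl("NS", names(da$valid))]))
  expect_equal(sum(da$valid), 6L)
})

test_that("combined deviations take the signed minimum magnitude", {
  mk <- function(d) list(d = rep(d, 12), valid = rep(TRUE, 12))
  expect_equal(unname(combine_deviations(mk(3.8), mk(2.5))), rep(2.5, 12))
  expect_equal(unname(combine_deviations(mk(3.8), mk(-2.5))), rep(-2.5, 12))
  expect_equal(unname(combine_deviations(mk(0), mk(7))), rep(0, 12))
  # invalid components contribute 0
  a <- mk(3)
  a$valid[4] <- FALSE
  z <- combine_deviations(a, mk(2))
  expect_equal(unname(z[4]), 0)
  expect_equal(unname(z[1]), 2)
})

test_that("deviation-class discretization matches the boundary table", {
  z <- c(0, 0.5, 0.99, 1, 1.5, 1.99, 2, 2.99, 3, 3.8, 4.99, 5, 9.99, 10, 50,
         Inf)
  want <- c(0, 0, 0, 0.25, 0.25, 0.25, 1, 1, 1.5, 1.5, 1.5, 1.75, 1.75, 2, 2,
            2)
  expect_equal(discretize_deviation(z), want)
  expect_equal(discretize_deviation(-z), -want)  # negative mirror
  # odd and non-decreasing
  grid <- seq(-12, 12, by = 0.01)
  comp <- discretize_deviation(grid)
  expect_equal(discretize_deviation(-grid), -comp)
  expect_true(all(diff(comp) >= 0))
})

test_that("concordance index sums negative and positive components", {
  big <- list(d = rep(c(10, -10), 6), valid = rep(TRUE, 12))
  res <- concordance_index(big, big)
  expect_equal(res$ic, 24)
  expect_equal(res$ic_neg, 0)
  expect_equal(res$ic_pos, 24)

  mixed <- list(d = c(3.8, -3.8, 0.5, 7, rep(0, 8)), valid = rep(TRUE, 12))
  other <- list(d = c(2.5, 2.5, 2, -20, rep(0, 8)), valid = rep(TRUE, 12))
  res2 <- concordance_index(mixed, other)
  # components: +1 (2.5 in [2,3)), -1 (-2.5), 0 (0.5), -1.75 (-7)
  expect_equal(res2$ic_pos, 1)
  expect_equal(res2$ic_neg, -2.75)
  expect_equal(res2$ic, res2$ic_neg + res2$ic_pos)
})

test_that("pairwise concordance properties hold on random pairs", {
  set.seed(11)
  for (i in 1:1000) {
    sA <- random_summary("a")
    sB <- random_summary("b")
    dA <- condition_deviations(sA)
    dB <- condition_deviations(sB)
    ab <- concordance_index(dA, dB)
    ba <- concordance_index(dB, dA)
    expect_identical(ab$ic, ba$ic)                  # symmetry
    expect_true(ab$ic >= -24 && ab$ic <= 24)        # bounds
    expect_gte(ab$ic_pos, 0)
    expect_lte(ab$ic_neg, 0)
    expect_equal(ab$ic, ab$ic_neg + ab$ic_pos)
  }
})

test_that("concordance is affine invariant and reflection antisymmetric", {
  set.seed(13)
  lv <- condition_levels()
  for (i in 1:200) {
    means <- rnorm(4)
    sds <- abs(rnorm(4)) + 0.1
    a <- runif(1, 0.2, 5)
    b <- rnorm(1)
    sA <- make_summary_row(means, sds)
    sB <- random_summary("b")
    # x -> a x + b scales means and sds coherently
    sA2 <- make_summary_row(a * means + b, a * sds)
    dB <- condition_deviations(sB)
    ic0 <- concordance_index(condition_deviations(sA), dB)
    ic1 <- concordance_index(condition_deviations(sA2), dB)
    expect_equal(ic1$ic, ic0$ic, tolerance = 1e-9)
    expect_equal(ic1$components, ic0$components, tolerance = 1e-9)
    # x -> -x + b reflects the deviations and negates the index
    sA3 <- make_summary_row(-means + b, sds)
    ic2 <- concordance_index(condition_deviations(sA3), dB)
    expect_equal(ic2$ic, -ic0$ic, tolerance = 1e-9)
    # self-concordance
    dA <- condition_deviations(sA)
    dA2 <- condition_deviations(sA2)
    self0 <- concordance_index(dA, dA)
    expect_gte(self0$ic, 0)
    expect_equal(concordance_index(dA, dA2)$ic, self0$ic, tolerance = 1e-9)
  }
})

test_that("a flat partner suppresses the index to zero", {
  set.seed(17)
  flat <- make_summary_row(rep(1.3, 4), c(0.5, 1, 2, 0.2))
  dF <- condition_deviations(flat)
  for (i in 1:50) {
    dB <- condition_deviations(random_summary("b"))
    expect_identical(concordance_index(dF, dB)$ic, 0)
  }
})

test_that("spearman pairing matches the closed-form rank formula", {
  vals <- list(DR = 1:3, DS = 4:6, NR = 7:9, NS = 10:12)
  m <- make_series(vals)
  set.seed(23)
  perm <- sample(12)
  p <- make_series(list(DR = perm[1:3], DS = perm[4:6], NR = perm[7:9],
                        NS = perm[10:12]), molecule_id = "p1",
                  molecule_class = "phosphopeptide")
  res <- spearman_pair(m, p)
  dsq <- sum((1:12 - perm)^2)
  expect_equal(res$rho, 1 - 6 * dsq / (12 * (12^2 - 1)), tolerance = 1e-12)
  expect_equal(res$n_rho, 12L)

  ident <- spearman_pair(m, m)
  expect_equal(ident$rho, 1)
  expect_lt(ident$rho_p, 0.05)

  neg <- m
  neg$value <- -neg$value
  expect_equal(spearman_pair(m, neg)$rho, -1)

  # replicate truncation: 3 vs 2 replicates pair only the first two slots
  p2 <- make_series(list(DR = 1:2, DS = 2:3, NR = 3:4, NS = 4:5),
                    molecule_id = "p2")
  res2 <- spearman_pair(m, p2)
  expect_equal(res2$n_rho, 8L)

  # too few paired points: p forced to 1 with a warning
  short <- make_series(list(DR = 1:2), molecule_id = "s")
  expect_warning(res3 <- spearman_pair(short, short), "fewer than 4")
  expect_equal(res3$rho_p, 1)
})

test_that("the pair table enumerates all pairs and matches scalar recomputation", {
  set.seed(31)
  ds <- generate_dataset(n_metabolites = 3, n_phospho = 5, genotypes = 1,
                         seed = 5)
  s <- summarize_conditions(ds$data)
  pt <- concordance_table(ds$data, s, genotype = "gt1")
  expect_equal(nrow(pt), 15L)

  # independent per-pair recomputation through the scalar API
  for (r in seq_len(nrow(pt))) {
    sm <- s[s$molecule_id == pt$metabolite_id[r], ]
    sp <- s[s$molecule_id == pt$phosphopeptide_id[r], ]
    ora <- concordance_index(condition_deviations(sm),
                             condition_deviations(sp))
    expect_equal(pt$ic[r], ora$ic)
    expect_equal(pt$ic_neg[r], ora$ic_neg)
    dm <- ds$data[ds$data$molecule_id == pt$metabolite_id[r], ]
    dp <- ds$data[ds$data$molecule_id == pt$phosphopeptide_id[r], ]
    osp <- spearman_pair(dm, dp)
    expect_equal(pt$rho[r], osp$rho, tolerance = 1e-12)
    expect_equal(pt$rho_p[r], osp$rho_p, tolerance = 1e-12)
  }

  # 1 x 1
  one <- concordance_table(
    ds$data[ds$data$molecule_id %in% c("met_001", "pep_0001"), ],
    s[s$molecule_id %in% c("met_001", "pep_0001"), ], genotype = "gt1")
  expect_equal(nrow(one), 1L)

  # duplicate ids rejected
  sdup <- dplyr::bind_rows(s, s[s$molecule_class == "metabolite", ][1, ])
  expect_error(concordance_table(ds$data, sdup, genotype = "gt1"),
               "duplicate")
})
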