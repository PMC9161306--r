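make_pair_rows <- function(ic, rho_p = 0.01, flat_m = FALSE, flat_p = FALSE,
                           genotype = "wt") {
  n <- length(ic)
  tibble::tibble(
    metabolite_id = sprintf("met_%03d", seq_len(n)),
    phosphopeptide_id = sprintf("pep_%03d", seq_len(n)),
    genotype = genotype, ic_neg = pmin(ic, 0), ic_pos = pmax(ic, 0),
    ic = ic, rho = 0.8, rho_p = rho_p, n_rho = 16L,
    flat_m = flat_m, flat_p = flat_p, n_valid_components = 12L
  )
}

test_that("connection filtering applies inclusive threshold and co-filters", {
  pt <- make_pair_rows(c(6.75, 7, 8, 10), rho_p = c(0.01, 0.01, 0.2, 0.01))
  pt$flat_p[4] <- TRUE
  out <- filter_connections(pt, ic_min = 7)
  # 6.75 below threshold; 8 fails the Spearman filter; 10 has a flat partner
  expect_equal(out$ic, 7)

  # discordant direction
  ptn <- make_pair_rows(c(-8, -6, 5))
  expect_equal(filter_connections(ptn, ic_min = 7,
                                  direction = "negative")$ic, -8)

  # planted passing rows among thousands survive exactly
  set.seed(61)
  n <- 10000
  ic <- round(runif(n, -5, 5) * 4) / 4
  pass <- sample(n, 100)
  ic[pass] <- runif(100, 7, 20)
  big <- make_pair_rows(ic)
  big$metabolite_id <- sprintf("met_%05d", 1:n)
  big$phosphopeptide_id <- sprintf("pep_%05d", 1:n)
  got <- filter_connections(big, ic_min = 7)
  expect_setequal(got$metabolite_id, big$metabolite_id[pass])

  # monotonicity: edges at ic_min = 7 are a subset of edges at 6
  at7 <- filter_connections(big, ic_min = 7)
  at6 <- filter_connections(big, ic_min = 6)
  expect_true(all(at7$metabolite_id %in% at6$metabolite_id))
  expect_equal(nrow(filter_connections(make_pair_rows(numeric(0)))), 0L)
})

test_that("bin aggregation averages member connections", {
  conn <- tibble::tibble(
    metabolite_id = c("glc", "glc", "glc"),
    phosphopeptide_id = c("p1", "p2", "p3"),
    genotype = "wt", ic = c(9, 7, 11), rho = 0.9, rho_p = 0.01,
    flat_m = FALSE, flat_p = FALSE
  )
  ann <- tibble::tibble(molecule_id = c("p1", "p2", "p3"),
                        bin_code = c("30.2", "34.19", "34.19.1"),
                        bin_name = NA_character_)
  edges <- aggregate_bins(conn, ann, bin_depth = 2)
  e1 <- edges[edges$bin_code == "30.2", ]
  expect_equal(e1$mean_ic, 9)
  expect_equal(e1$n_connections, 1L)
  e2 <- edges[edges$bin_code == "34.19", ]
  expect_equal(e2$mean_ic, 9)  # mean of 7 and 11
  expect_equal(e2$n_connections, 2L)
  # conservation of connection counts
  expect_equal(sum(edges$n_connections), nrow(conn))

  # unannotated phosphopeptides fall into "unknown"
  expect_message(
    edges2 <- aggregate_bins(conn, ann[1:2, ], bin_depth = 2),
    "unknown")
  expect_true("unknown" %in% edges2$bin_code)

  # multi-bin phosphopeptides contribute to each mapped bin
  ann3 <- dplyr::bind_rows(ann,
                           tibble::tibble(molecule_id = "p1",
                                          bin_code = "4.1",
                                          bin_name = NA_character_))
  edges3 <- aggregate_bins(conn, ann3, bin_depth = 2)
  expect_equal(sum(edges3$n_connections), nrow(conn) + 1L)

  # random grouping equals a brute-force group-by
  set.seed(63)
  connr <- tibble::tibble(
    metabolite_id = sample(c("m1", "m2"), 40, TRUE),
    phosphopeptide_id = sprintf("p%02d", sample(10, 40, TRUE)),
    genotype = sample(c("wt", "mut"), 40, TRUE),
    ic = round(runif(40, 7, 20) * 4) / 4
  )
  annr <- tibble::tibble(molecule_id = sprintf("p%02d", 1:10),
                         bin_code = sample(c("1.1", "30.2", "34.19"), 10,
                                           TRUE),
                         bin_name = NA_character_)
  er <- aggregate_bins(connr, annr, bin_depth = 2)
  for (r in seq_len(nrow(er))) {
    sub <- connr[connr$metabolite_id == er$metabolite_id[r] &
                   connr$genotype == er$genotype[r] &
                   connr$phosphopeptide_id %in%
                     annr$molecule_id[annr$bin_code == er$bin_code[r]], ]
    expect_equal(er$mean_ic[r], mean(sub$ic))
    expect_equal(er$n_connections[r], nrow(sub))
  }
})

test_that("the bipartite network carries genotype-attributed parallel edges", {
  edges <- tibble::tibble(
    metabolite_id = rep("suc", 3), bin_code = rep("34.19", 3),
    genotype = c("wt", "pgm", "sweet"), mean_ic = c(8, 9, 10),
    n_connections = c(2L, 1L, 3L)
  )
  g <- build_network(edges)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::E(g)$genotype, c("wt", "pgm", "sweet"))
  expect_equal(sort(igraph::V(g)$type), c("bin", "metabolite"))

  single <- build_network(edges[1, ])
  expect_equal(unique(igraph::E(single)$genotype), "wt")

  # planted hub has the highest degree
  hub_edges <- tibble::tibble(
    metabolite_id = c(rep("hub", 8), "other"),
    bin_code = c(sprintf("b%d", 1:8), "b1"),
    genotype = "wt", mean_ic = 8, n_connections = 1L
  )
  gh <- build_network(hub_edges)
  deg <- igraph::degree(gh)
  expect_equal(names(which.max(deg)), "hub")
})

test_that("genotype comparison recounts degrees and flags specificity", {
  edges <- tibble::tibble(
    metabolite_id = c("m1", "m1", "m2"), bin_code = c("b1", "b1", "b2"),
    genotype = c("wt", "mut", "wt"), mean_ic = c(8, 8, 9),
    n_connections = 1L
  )
  cmp <- compare_genotypes(edges)
  m1 <- cmp[cmp$node == "m1", ]
  expect_equal(m1$degree_diff, 0L)
  expect_equal(m1$present_in, "mut,wt")
  m2 <- cmp[cmp$node == "m2", ]
  expect_equal(m2$degree_wt, 1L)
  expect_equal(m2$degree_mut, 0L)
  expect_equal(m2$present_in, "wt")

  # identical networks in both genotypes -> all differences zero
  same <- dplyr::bind_rows(
    tibble::tibble(metabolite_id = "m1", bin_code = "b1", genotype = "wt",
                   mean_ic = 8, n_connections = 1L),
    tibble::tibble(metabolite_id = "m1", bin_code = "b1", genotype = "mut",
                   mean_ic = 8, n_connections = 1L))
  cmps <- compare_genotypes(same)
  expect_true(all(cmps$degree_diff == 0))
  expect_true(all(cmps$sum_ic_diff == 0))

  # a genotype dropping half its edges shows up in the recount
  set.seed(67)
  full <- tibble::tibble(metabolite_id = "m1",
                         bin_code = sprintf("b%d", 1:8),
                         genotype = "wt", mean_ic = 8, n_connections = 1L)
  half <- full[1:4, ]
  half$genotype <- "mut"
  cmp2 <- compare_genotypes(dplyr::bind_rows(full, half))
  expect_equal(cmp2$degree_diff[cmp2$node == "m1"], 4L)
  expect_error(compare_genotypes(full), ">= 2 genotypes")
})

test_that("networks export to GraphML, GML and TSV", {
  edges <- tibble::tibble(metabolite_id = "m1", bin_code = "b1",
                          genotype = "wt", mean_ic = 8.25,
                          n_connections = 2L)
  g <- build_network(edges)
  tmp <- withr::local_tempdir()
  gml_path <- export_network(g, file.path(tmp, "net.graphml"), "graphml")
  expect_true(file.exists(gml_path))
  expect_true(any(grepl("graphml", readLines(gml_path, n = 5))))
  tsv_path <- export_network(g, file.path(tmp, "net.tsv"), "tsv")
  back <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  expect_equal(back$mean_ic, 8.25)
  expect_true(file.exists(export_network(g, file.path(tmp, "net.gml"),
                                         "gml")))
})
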