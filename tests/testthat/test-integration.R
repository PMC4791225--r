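test_that("top-N overlap matrix is symmetric with a 100 diagonal", {
  set.seed(13)
  regs <- sprintf("R%03d", 1:150)
  rks <- list(a = random_ranking(regs, "a"), b = random_ranking(regs, "b"))
  m <- topn_overlap_matrix(rks, n = 100)
  expect_equal(diag(unclass(m)), c(a = 100, b = 100))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m >= 0 & m <= 100))
  expect_error(topn_overlap_matrix(rks, n = 0), "positive")
})

test_that("overlap percentages equal the constructed intersection", {
  regs_shared <- sprintf("S%03d", 1:37)
  a <- random_ranking(c(regs_shared, sprintf("A%03d", 1:63)), "a")
  b <- random_ranking(c(regs_shared, sprintf("B%03d", 1:63)), "b")
  m <- topn_overlap_matrix(list(a = a, b = b), n = 100)
  expect_equal(unclass(m)["a", "b"], 37)

  disjoint <- topn_overlap_matrix(
    list(x = random_ranking(sprintf("X%02d", 1:10), "x"),
         y = random_ranking(sprintf("Y%02d", 1:10), "y")),
    n = 10
  )
  expect_equal(unclass(disjoint)["x", "y"], 0)
})

test_that("overlap matrix permutes consistently under condition reordering", {
  set.seed(14)
  regs <- sprintf("R%03d", 1:60)
  rks <- list(a = random_ranking(regs[1:50], "a"),
              b = random_ranking(regs[5:54], "b"),
              c = random_ranking(regs[11:60], "c"))
  m1 <- unclass(topn_overlap_matrix(rks, n = 20))
  m2 <- unclass(topn_overlap_matrix(rev(rks), n = 20))
  expect_equal(m2[rownames(m1), colnames(m1)], m1)
})

test_that("common_core finds regulators in enough top lists", {
  regs <- sprintf("R%02d", 1:20)
  rk <- random_ranking(regs, "a")
  core <- common_core(list(a = rk, b = rk, c = rk), n = 5, min_conditions = 3)
  expect_setequal(core$regulators, rk$regulator[1:5])

  # only R07 shared across all three top-10 lists
  mk <- function(extra, cond) random_ranking(c("R07", extra), cond)
  shared_one <- list(
    mk(sprintf("A%02d", 1:9), "a"),
    mk(sprintf("B%02d", 1:9), "b"),
    mk(sprintf("C%02d", 1:9), "c")
  )
  core1 <- common_core(shared_one, n = 10, min_conditions = 3)
  expect_equal(core1$regulators, "R07")
  expect_equal(core1$membership$n_conditions, 3L)
})

test_that("common_core matches brute-force membership counting", {
  set.seed(15)
  for (rep in 1:10) {
    pool <- sprintf("R%03d", 1:40)
    rks <- lapply(1:4, function(i) random_ranking(sample(pool, 25), paste0("c", i)))
    names(rks) <- paste0("c", 1:4)
    n <- 10
    minc <- sample(2:4, 1)
    core <- common_core(rks, n = n, min_conditions = minc)
    counts <- table(unlist(lapply(rks, function(r) r$regulator[1:n])))
    expected <- sort(names(counts)[counts >= minc])
    expect_equal(sort(core$regulators), expected)
  }
})

test_that("core_network induces the right subgraph with component summary", {
  graph <- interaction_graph(tibble::tibble(
    node_a = c("A", "B", "C", "X"),
    node_b = c("B", "C", "A", "Y")
  ))
  # 3 isolated core nodes
  cn0 <- core_network(c("P", "Q", "R"), graph)
  expect_equal(cn0$summary$n_edges, 0)
  expect_equal(cn0$summary$largest_component, 1)
  expect_equal(cn0$summary$fraction_isolated, 1)

  # complete triangle
  cn1 <- core_network(c("A", "B", "C"), graph)
  expect_equal(cn1$summary$n_edges, 3)
  expect_equal(cn1$summary$largest_component, 3)
  expect_equal(cn1$summary$fraction_isolated, 0)

  # type filtering drops chemicals
  cn2 <- core_network(c("A", "B", "C"), graph,
                      types = c(A = "gene", B = "chemical", C = "gene"),
                      exclude_types = "chemical")
  expect_equal(sort(cn2$nodes), c("A", "C"))
})

test_that("core_network component sizes match a union-find oracle", {
  set.seed(16)
  for (rep in 1:5) {
    nodes <- sprintf("N%02d", 1:30)
    raw <- tibble::tibble(
      node_a = sample(nodes, 40, replace = TRUE),
      node_b = sample(nodes, 40, replace = TRUE)
    )
    suppressWarnings(graph <- interaction_graph(raw))
    cn <- core_network(nodes, graph)
    comps <- igraph::components(cn$graph)
    expect_equal(sort(as.integer(comps$csize), decreasing = TRUE),
                 component_sizes_oracle(nodes, cn$edges))
    expect_equal(cn$summary$largest_component, max(comps$csize))
  }
})

test_that("pathway enrichment matches enumeration and handles degenerate cases", {
  universe <- sprintf("G%02d", 1:20)
  sets <- list(P1 = universe[1:6], P2 = universe[7:12], P3 = c("Z1", "Z2"))
  node_set <- universe[c(1:4, 13)]
  expect_warning(res <- pathway_enrichment(node_set, sets, universe), "P3")
  p1 <- res$p[res$pathway == "P1"]
  expect_equal(p1, hyper_upper_oracle(6, 5, 20, 4), tolerance = 1e-12)
  p2 <- res$p[res$pathway == "P2"]
  expect_equal(p2, hyper_upper_oracle(6, 5, 20, 0), tolerance = 1e-12)
  expect_equal(res$fdr, stats::p.adjust(res$p, "BH")[order(res$p)])

  # saturated draw: node_set = pathway = universe -> p = 1
  res_sat <- pathway_enrichment(universe, list(ALL = universe), universe)
  expect_equal(res_sat$p, 1)
  # no overlap -> p = 1
  res0 <- pathway_enrichment(universe[1:2], list(P = universe[11:14]), universe)
  expect_equal(res0$p, 1)
})

test_that("pathway enrichment equals the enumeration oracle on random small universes", {
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(10:25, 1)
    universe <- sprintf("U%02d", 1:N)
    pw <- sample(universe, sample(2:N, 1))
    ns <- sample(universe, sample(1:N, 1))
    res <- pathway_enrichment(ns, list(PW = pw), universe)
    k <- length(intersect(pw, ns))
    expect_equal(res$p, hyper_upper_oracle(length(pw), length(ns), N, k),
                 tolerance = 1e-12)
  }
})

test_that("z_profiles pivot losslessly and preserve missing conditions", {
  set.seed(18)
  rka <- random_ranking(sprintf("R%02d", 1:10), "a")
  rkb <- random_ranking(sprintf("R%02d", 3:12), "b")
  prof <- z_profiles(list(rka, rkb), regulators = c("R01", "R05", "R12"))
  expect_false("a" %in% prof$condition[prof$regulator == "R12"])
  expect_true(all(c("a", "b") %in% prof$condition[prof$regulator == "R05"]))
  # single condition / single regulator -> verbatim call values
  one <- z_profiles(list(rka), regulators = "R01")
  expect_equal(one$z, rka$z[rka$regulator == "R01"])
  expect_equal(one$p_overlap, rka$p_overlap[rka$regulator == "R01"])
  # pivot round trip: per-condition subsets recover the source values
  wide <- tidyr::pivot_wider(z_profiles(list(rka, rkb)),
                             id_cols = "regulator",
                             names_from = "condition", values_from = "z")
  back <- wide$a[match(rka$regulator, wide$regulator)]
  expect_equal(back, rka$z)
})
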