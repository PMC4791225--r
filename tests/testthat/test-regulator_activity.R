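test_that("overlap_pvalue matches enumeration and handles edge cases", {
  expect_equal(overlap_pvalue(5, 3, 10, 0), 1)
  expect_equal(overlap_pvalue(5, 5, 10, 5), 1 / choose(10, 5))
  expect_equal(overlap_pvalue(3, 4, 8, 2), hyper_upper_oracle(3, 4, 8, 2))
  set.seed(5)
  for (i in 1:50) {
    N <- sample(5:25, 1)
    m <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(m, n), 1)
    expect_equal(overlap_pvalue(m, n, N, k), hyper_upper_oracle(m, n, N, k),
                 tolerance = 1e-12)
  }
  expect_error(overlap_pvalue(3, 4, 8, 5), "Inconsistent")
  expect_error(overlap_pvalue(9, 4, 8, 2), "Inconsistent")
})

test_that("activation_z agrees with brute force over all direction assignments", {
  # closed-form checks
  edges <- tibble::tibble(target = c("A", "B", "C", "D"),
                          sign = "activates", weight = 1)
  dirs <- stats::setNames(rep(1, 4), c("A", "B", "C", "D"))
  expect_equal(activation_z(edges, dirs), 2)

  edges2 <- tibble::tibble(target = c("A", "B", "C", "D"),
                           sign = c("activates", "activates",
                                    "represses", "represses"),
                           weight = 1)
  dirs2 <- c(A = 1, B = 1, C = 1, D = 1)  # 2 consistent, 2 inconsistent
  expect_equal(activation_z(edges2, dirs2), 0)

  # exhaustive: every direction assignment on <= 6 signed edges, random signs
  # and weights
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    genes <- sprintf("T%d", 1:n)
    edges <- tibble::tibble(
      target = genes,
      sign = sample(c("activates", "represses"), n, replace = TRUE),
      weight = if (rep %% 2 == 0) runif(n, 0.5, 2) else rep(1, n)
    )
    grid <- expand.grid(rep(list(c(-1, 1)), n))
    for (row in seq_len(nrow(grid))) {
      dirs <- stats::setNames(as.numeric(grid[row, ]), genes)
      expect_equal(activation_z(edges, dirs),
                   activation_z_oracle(edges, dirs),
                   tolerance = 1e-12)
    }
  }
})

test_that("activation_z is undefined without signed overlapping edges", {
  edges <- tibble::tibble(target = c("A", "B"), sign = "unknown", weight = 1)
  expect_true(is.na(activation_z(edges, c(A = 1, B = -1))))
  edges2 <- tibble::tibble(target = "A", sign = "activates", weight = 1)
  expect_true(is.na(activation_z(edges2, c(Z = 1))))
  expect_error(activation_z(edges2, c(A = 0.5)), "\\+1 or -1")
})

test_that("call_state applies inclusive thresholds", {
  expect_equal(call_state(2.5, 2), "activated")
  expect_equal(call_state(-2.0, 2), "inhibited")
  expect_equal(call_state(2.0, 2), "activated")
  expect_equal(call_state(1.9, 2), "indeterminate")
  expect_equal(call_state(NA_real_, 2), "indeterminate")
})

test_that("infer_itrs reproduces the hand-computed toy example", {
  net <- prior_network(tibble::tibble(
    regulator = c("R1", "R1", "R2"),
    target = c("A", "B", "C"),
    sign = "+", weight = 1
  ))
  ev <- evidence_set(c("A", "B"), c("A", "B", "C", "D"),
                     directions = c(A = 1, B = 1))
  rk <- infer_itrs(net, ev, z_threshold = 2)
  expect_equal(rk$regulator[1], "R1")
  expect_equal(rk$z[1], sqrt(2))
  expect_equal(rk$state[1], "indeterminate")
  expect_equal(rk$n_overlap, c(2L, 0L))
  expect_equal(rk$p_overlap[1],
               hyper_upper_oracle(2, 2, 4, 2))
  # n_consistent + n_inconsistent never exceeds n_overlap
  expect_true(all(rk$n_consistent + rk$n_inconsistent <= rk$n_overlap))
})

test_that("non-directional evidence yields undefined z and p-only ranking", {
  net <- toy_network()
  ev <- gene_set_evidence(c("A", "C", "F"), c(LETTERS[1:6], "X", "Y"),
                          kind = "bound")
  rk <- infer_itrs(net, ev)
  expect_true(all(is.na(rk$z)))
  expect_true(all(rk$state == "indeterminate"))
  expect_equal(rk$p_overlap, sort(rk$p_overlap))
})

test_that("negating all directions negates z and preserves p and ranking", {
  set.seed(31)
  cfg <- scenario_config(seed = 31, n_genes = 300, n_regulators = 25,
                         mean_out_degree = 8)
  net <- generate_prior_network(cfg)
  gen <- generate_contrasts(net, list(c1 = c(R001 = 1)), cfg)
  ev <- significant_set(gen$contrasts$c1)
  ev_neg <- evidence_set(ev$genes, ev$universe, ev$condition,
                         directions = -ev$directions, kind = "de")
  rk <- infer_itrs(net, ev)
  rk_neg <- infer_itrs(net, ev_neg)
  m <- match(rk$regulator, rk_neg$regulator)
  expect_equal(rk_neg$z[m], -rk$z)
  expect_equal(rk_neg$p_overlap[m], rk$p_overlap)
  expect_equal(rk_neg$n_overlap[m], rk$n_overlap)
})

test_that("BH fdr is non-decreasing in rank order and ranking ties are deterministic", {
  set.seed(77)
  cfg <- scenario_config(seed = 77, n_genes = 200, n_regulators = 30,
                         mean_out_degree = 6)
  net <- generate_prior_network(cfg)
  gen <- generate_contrasts(net, list(c1 = c(R001 = 1)), cfg)
  rk <- infer_itrs(net, significant_set(gen$contrasts$c1))
  ord <- order(rk$p_overlap)
  expect_true(all(diff(rk$fdr_overlap[ord]) >= -1e-12))
  expect_equal(rk$fdr_overlap,
               stats::p.adjust(rk$p_overlap, "BH"))
  # re-running is bit-identical
  rk2 <- infer_itrs(net, significant_set(gen$contrasts$c1))
  expect_identical(as.data.frame(rk), as.data.frame(rk2))
})

test_that("equal overlap p-values break ties by |z| then regulator name", {
  # RB/RA overlap one target each of two evidence genes in a 4-gene
  # universe: identical counts, hence identical p; RB consistent (|z| = 1),
  # RA inconsistent (also |z| = 1) -> falls to lexicographic order; RC has
  # no overlapping signed direction (undefined z) and identical p -> last.
  net <- prior_network(tibble::tibble(
    regulator = c("RB", "RA", "RC"),
    target = c("A", "B", "C"),
    sign = c("+", "+", "?"),
    weight = 1
  ))
  ev <- evidence_set(c("A", "B", "C"), c("A", "B", "C", "D"),
                     directions = c(A = 1, B = -1))
  rk <- infer_itrs(net, ev)
  expect_equal(length(unique(rk$p_overlap)), 1L)
  expect_equal(rk$regulator, c("RA", "RB", "RC"))
  expect_true(is.na(rk$z[3]))
})

test_that("itr_contributions returns overlapping targets with observed directions", {
  net <- toy_network()
  ev <- evidence_set(c("A", "C", "E"), LETTERS[1:8],
                     directions = c(A = 1, C = -1, E = -1), condition = "c1")
  contrib <- itr_contributions(net, ev, "R1")
  expect_setequal(contrib$gene, c("A", "C"))
  expect_equal(contrib$direction[contrib$gene == "C"], -1)
  contrib2 <- itr_contributions(net, ev, "R2")
  expect_setequal(contrib2$gene, c("C", "E"))
})

test_that("top_regulators truncates, warns when short, and filters by type", {
  r <- random_ranking(sprintf("R%02d", 1:30), "c")
  expect_length(top_regulators(r, 10), 10)
  expect_warning(top <- top_regulators(r, 50), "only 30")
  expect_length(top, 30)
  types <- stats::setNames(rep(c("gene", "chemical"), 15), r$regulator)
  top_g <- top_regulators(r, 5, types = types, keep = "gene")
  expect_true(all(types[top_g] == "gene"))
})
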