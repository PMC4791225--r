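contrib_row <- function(cond, gene, dir) {
  tibble::tibble(condition = cond, gene = gene, direction = dir)
}

test_that("build_signature applies the min-conditions and conflict rules", {
  contributions <- dplyr::bind_rows(
    contrib_row("c1", "A", 1), contrib_row("c2", "A", 1),          # kept +1
    contrib_row("c1", "B", 1), contrib_row("c2", "B", -1),         # conflict
    contrib_row("c1", "C", -1),                                    # 1 condition
    contrib_row("c1", "D", -1), contrib_row("c2", "D", -1),
    contrib_row("c3", "D", -1)                                     # kept -1
  )
  suppressMessages(sig <- build_signature("ESTRADIOL", contributions,
                                          min_conditions = 2))
  expect_setequal(sig$gene, c("A", "D"))
  expect_equal(sig$direction[sig$gene == "A"], 1)
  expect_equal(sig$direction[sig$gene == "D"], -1)
  expect_equal(sig$n_conditions[sig$gene == "D"], 3L)
  expect_equal(attr(sig, "dropped"), "B")

  expect_error(
    suppressMessages(build_signature("X", contrib_row("c1", "A", 1),
                                     min_conditions = 2)),
    "Empty signature"
  )
})

test_that("build_signature matches brute-force counting on random contributions", {
  set.seed(23)
  for (rep in 1:20) {
    genes <- sprintf("G%02d", 1:30)
    conds <- paste0("c", 1:4)
    contributions <- dplyr::bind_rows(lapply(conds, function(cc) {
      g <- sample(genes, sample(5:20, 1))
      contrib_row(cc, g, sample(c(-1, 1), length(g), replace = TRUE))
    }))
    minc <- sample(2:3, 1)
    expected <- character()
    for (g in genes) {
      sub <- contributions[contributions$gene == g, ]
      if (nrow(sub) >= minc && length(unique(sub$direction)) == 1) {
        expected <- c(expected, g)
      }
    }
    if (length(expected) == 0) {
      expect_error(
        suppressMessages(build_signature("R", contributions, minc)),
        "Empty signature"
      )
    } else {
      suppressMessages(sig <- build_signature("R", contributions, minc))
      expect_setequal(sig$gene, expected)
    }
  }
})

make_cohort <- function(expr, time = NULL, event = NULL) {
  n <- ncol(expr)
  cohort_data(expr, tibble::tibble(
    patient = colnames(expr),
    time = time %||% seq_len(n) * 10,
    event = event %||% rep(1L, n)
  ))
}

test_that("score_cohort standardizes rows and averages direction-weighted z", {
  set.seed(24)
  expr <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(sprintf("G%d", 1:5), sprintf("P%02d", 1:40)))
  sig <- tibble::tibble(gene = sprintf("G%d", 1:5),
                        direction = c(1, 1, -1, -1, 1))
  cohort <- make_cohort(expr)
  scores <- score_cohort(sig, cohort)
  # independent two-pass reimplementation
  manual <- rep(0, 40)
  for (i in 1:5) {
    row <- expr[i, ]
    z <- (row - mean(row)) / sd(row)
    manual <- manual + sig$direction[i] * z
  }
  manual <- manual / 5
  expect_equal(unname(scores), unname(manual), tolerance = 1e-12)

  # patient at the cohort mean scores 0 (single-gene signature)
  expr1 <- matrix(c(1, 2, 3), 1, 3,
                  dimnames = list("G1", c("P1", "P2", "P3")))
  s1 <- score_cohort(tibble::tibble(gene = "G1", direction = 1),
                     make_cohort(expr1))
  expect_equal(unname(s1["P2"]), 0)

  # opposite directions on identical rows cancel
  expr2 <- rbind(G1 = c(1, 5, 9), G2 = c(1, 5, 9))
  colnames(expr2) <- c("P1", "P2", "P3")
  s2 <- score_cohort(tibble::tibble(gene = c("G1", "G2"),
                                    direction = c(1, -1)),
                     make_cohort(expr2))
  expect_equal(unname(s2), c(0, 0, 0))
})

test_that("score_cohort skips absent and degenerate genes, errors with none usable", {
  expr <- rbind(G1 = c(1, 2, 3), G2 = c(5, 5, 5))
  colnames(expr) <- c("P1", "P2", "P3")
  cohort <- make_cohort(expr)
  sig <- tibble::tibble(gene = c("G1", "G2", "G9"), direction = c(1, 1, 1))
  expect_warning(expect_warning(s <- score_cohort(sig, cohort),
                                "absent"), "zero-variance")
  expect_length(s, 3)
  sig_bad <- tibble::tibble(gene = "G2", direction = 1)
  expect_warning(expect_error(score_cohort(sig_bad, cohort), "usable"))
})

test_that("scoring is invariant to per-gene affine rescaling", {
  set.seed(25)
  expr <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(sprintf("G%d", 1:4), sprintf("P%02d", 1:30)))
  sig <- tibble::tibble(gene = sprintf("G%d", 1:4), direction = c(1, -1, 1, -1))
  s1 <- score_cohort(sig, make_cohort(expr))
  expr2 <- expr * c(3, 0.5, 10, 2) + c(100, -5, 0, 7)
  s2 <- score_cohort(sig, make_cohort(expr2))
  expect_equal(s1, s2, tolerance = 1e-12)
  # flipping all directions negates scores
  sig_flip <- dplyr::mutate(sig, direction = -direction)
  s3 <- score_cohort(sig_flip, make_cohort(expr))
  expect_equal(s3, -s1, tolerance = 1e-12)
})

test_that("stratify_and_test splits at the median with ties to low", {
  scores <- stats::setNames(c(1, 2, 3, 3, 5, 6), sprintf("P%d", 1:6))
  expr <- matrix(rnorm(6), 1, 6, dimnames = list("G1", names(scores)))
  cohort <- make_cohort(expr)
  res <- stratify_and_test(scores, cohort)
  # median is 3: the two patients at 3 go low
  expect_equal(res$groups$group[res$groups$patient %in% c("P3", "P4")],
               c("low", "low"))
  expect_equal(sum(res$groups$group == "high"), 2)
  # KM curves start at 1 and are non-increasing
  for (g in unique(res$km$group)) {
    s <- res$km$surv[res$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s <= 1))
  }
})

test_that("identical survival in both groups gives a null log-rank test", {
  n <- 20
  scores <- stats::setNames(c(rep(-1, n / 2), rep(1, n / 2)),
                            sprintf("P%02d", 1:n))
  times <- rep(c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50), 2)
  expr <- matrix(rnorm(n), 1, n, dimnames = list("G1", names(scores)))
  cohort <- make_cohort(expr, time = times, event = rep(1L, n))
  res <- stratify_and_test(scores, cohort)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p, 0.999)
  # flipping all scores leaves the median-split p unchanged
  res_flip <- stratify_and_test(-scores, cohort)
  expect_equal(res_flip$p, res$p, tolerance = 1e-9)
})

test_that("planted hazard separates survival groups; glance/tidy expose results", {
  sig <- tibble::tibble(gene = sprintf("SG%02d", 1:10),
                        direction = rep(c(1, -1), 5))
  gen <- generate_cohort(sig, scenario_config(seed = 42))
  scores <- score_cohort(sig, gen$cohort)
  res <- stratify_and_test(scores, gen$cohort)
  expect_lt(res$p, 0.001)
  g <- glance(res)
  expect_equal(g$p.value, res$p)
  expect_equal(g$n, 300)
  expect_true(all(c("group", "time", "surv") %in% names(tidy(res))))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  # scores recover the planted latent factor
  expect_gt(cor(scores[gen$truth$patient], gen$truth$latent), 0.8)
})

test_that("stratification refuses degenerate groups", {
  scores <- stats::setNames(c(1, 1, 1, 2), sprintf("P%d", 1:4))
  expr <- matrix(rnorm(4), 1, 4, dimnames = list("G1", names(scores)))
  expect_error(stratify_and_test(scores, make_cohort(expr)),
               "at least 2 patients")
})
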