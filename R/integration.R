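# Half-up rounding: 0.5 always rounds away from zero (base round() is
# banker's rounding, which would print 74.5 as 74).
round_half_up <- function(x) floor(x + 0.5)

ranking_condition <- function(ranking, default) {
  attr(ranking, "condition") %||% default
}

#' Pairwise top-N overlap matrix across conditions
#'
#' For each pair of conditions, the percentage of shared regulators among
#' their top-N ITRs: `100 * |topN(A) intersect topN(B)| / n`, rounded
#' half-up to an integer. Diagonal entries are 100 by construction.
#'
#' @param rankings List of `itr_ranking` objects (named, or carrying
#'   `condition` attributes).
#' @param n Top-list size (default 100).
#' @return A symmetric integer matrix of class `overlap_matrix` with
#'   condition dimnames.
#' @export
topn_overlap_matrix <- function(rankings, n = 100) {
  if (n <= 0) abort("n must be positive.")
  conds <- unname(purrr::imap_chr(rankings, function(r, i) {
    ranking_condition(r, if (is.character(i)) i else paste0("condition_", i))
  }))
  tops <- purrr::map(rankings, top_regulators, n = n)
  k <- length(tops)
  values <- matrix(0, k, k, dimnames = list(conds, conds))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      values[i, j] <- round_half_up(
        100 * length(intersect(tops[[i]], tops[[j]])) / n
      )
    }
  }
  structure(values, class = c("overlap_matrix", "matrix"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> top-N ITR overlap (%)\n")
  print(unclass(x))
  invisible(x)
}

#' Write an overlap matrix as TSV with condition header row/column
#'
#' @param matrix An `overlap_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(matrix, path) {
  tab <- as_tibble(unclass(matrix), rownames = "condition")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Heatmap of a top-N overlap matrix
#'
#' @param object An `overlap_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  tab <- as_tibble(unclass(object), rownames = "a") %>%
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "overlap")
  lev <- rownames(unclass(object))
  tab$a <- factor(tab$a, levels = lev)
  tab$b <- factor(tab$b, levels = lev)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$b, y = .data$a,
                                    fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$overlap)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% overlap") +
    ggplot2::theme_minimal()
}

#' Common core of regulators across conditions
#'
#' Regulators present in the top-N of at least `min_conditions` rankings,
#' with a membership map recording which conditions contributed.
#'
#' @param rankings List of `itr_ranking` objects.
#' @param n Top-list size.
#' @param min_conditions Minimum number of rankings whose top-N must contain
#'   a regulator (default: all of them).
#' @return An object of class `core_set`: list with `regulators` (character)
#'   and `membership` (tibble `regulator`, `n_conditions`, `conditions`
#'   list-column).
#' @export
common_core <- function(rankings, n = 100, min_conditions = length(rankings)) {
  if (min_conditions > length(rankings)) {
    abort("min_conditions exceeds the number of rankings.")
  }
  conds <- purrr::imap_chr(rankings, function(r, i) {
    ranking_condition(r, if (is.character(i)) i else paste0("condition_", i))
  })
  tops <- purrr::map(rankings, top_regulators, n = n)
  long <- tibble(
    condition = rep(conds, lengths(tops)),
    regulator = unlist(tops, use.names = FALSE)
  )
  membership <- long %>%
    dplyr::group_by(.data$regulator) %>%
    dplyr::summarise(
      n_conditions = dplyr::n(),
      conditions = list(sort(.data$condition)),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_conditions >= min_conditions) %>%
    dplyr::arrange(dplyr::desc(.data$n_conditions), .data$regulator)
  structure(
    list(regulators = membership$regulator, membership = membership,
         n = n, min_conditions = min_conditions),
    class = "core_set"
  )
}

#' @export
print.core_set <- function(x, ...) {
  cat("<core_set> ", length(x$regulators), " regulators in the top-", x$n,
      " of >= ", x$min_conditions, " conditions\n", sep = "")
  invisible(x)
}

#' Induced interaction subnetwork on a core regulator set
#'
#' Builds the subgraph of previously known protein-protein interactions
#' among core regulators. Chemical/drug regulators can be excluded via a
#' type tag (they appear in ITR lists but are not proteins); they are kept
#' in overlap matrices.
#'
#' @param core A [common_core()] result or a character vector of regulators.
#' @param graph An [interaction_graph()].
#' @param types Optional named character vector regulator -> type.
#' @param exclude_types Types to drop before induction (e.g. `"chemical"`).
#' @return List of class `core_network` with `graph` (igraph induced
#'   subgraph including isolated core nodes), `edges` (tibble) and `summary`
#'   (tibble: `n_nodes`, `n_edges`, `largest_component`,
#'   `fraction_isolated`).
#' @export
core_network <- function(core, graph, types = NULL, exclude_types = NULL) {
  regs <- if (inherits(core, "core_set")) core$regulators else canon_id(core)
  if (!is.null(types) && !is.null(exclude_types)) {
    regs <- regs[!(types[regs] %in% exclude_types)]
  }
  tab <- as_tibble(graph)
  edges <- tab[tab$node_a %in% regs & tab$node_b %in% regs, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = regs)
  )
  comps <- igraph::components(g)
  summary <- tibble(
    n_nodes = length(regs),
    n_edges = nrow(edges),
    largest_component = if (length(regs) > 0) max(comps$csize) else 0L,
    fraction_isolated = if (length(regs) > 0) {
      mean(igraph::degree(g) == 0)
    } else NA_real_
  )
  structure(list(graph = g, edges = edges, nodes = regs, summary = summary),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  s <- x$summary
  cat("<core_network> ", s$n_nodes, " nodes, ", s$n_edges,
      " edges; largest component ", s$largest_component, "; ",
      round(100 * s$fraction_isolated, 1), "% isolated\n", sep = "")
  invisible(x)
}

#' Hypergeometric pathway over-representation of a node set
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the seen intersection between the pathway (restricted to the
#' universe) and the node set, with Benjamini-Hochberg adjustment across
#' pathways. Pathways with no member in the universe are skipped with a
#' warning.
#'
#' @param node_set Character vector of nodes (must lie inside `universe`).
#' @param pathways Named list of gene sets ([read_gene_sets()]).
#' @param universe Background gene universe.
#' @return Tibble sorted by `p`: `pathway`, `k_in`, `k_set`, `n_set`, `p`,
#'   `fdr`.
#' @export
pathway_enrichment <- function(node_set, pathways, universe) {
  node_set <- unique(canon_id(node_set))
  universe <- unique(canon_id(universe))
  outside <- setdiff(node_set, universe)
  if (length(outside) > 0) {
    abort(paste0("Node(s) outside the enrichment universe: ",
                 paste(utils::head(outside, 5), collapse = ", ")))
  }
  sets <- purrr::map(as.list(pathways), ~ intersect(unique(canon_id(.x)), universe))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    warn(paste0(length(empty), " pathway(s) with no member in the universe skipped: ",
                paste(utils::head(empty, 5), collapse = ", ")))
    sets <- sets[lengths(sets) > 0]
  }
  if (length(sets) == 0) abort("No pathway overlaps the universe.")
  n_universe <- length(universe)
  n_set <- length(node_set)
  rows <- purrr::imap(sets, function(members, nm) {
    k_in <- length(intersect(members, node_set))
    tibble(
      pathway = nm,
      k_in = k_in,
      k_set = length(members),
      n_set = n_set,
      p = overlap_pvalue(length(members), n_set, n_universe, k_in)
    )
  })
  dplyr::bind_rows(rows) %>%
    dplyr::mutate(fdr = stats::p.adjust(.data$p, method = "BH")) %>%
    dplyr::arrange(.data$p, .data$pathway)
}

#' Cross-condition activation z profiles
#'
#' Long-format table of each requested regulator's activation z and overlap
#' p-value per condition; a regulator absent from a condition's calls has no
#' row for that condition, and an undefined z is preserved as `NA`.
#'
#' @param rankings List of `itr_ranking` objects.
#' @param regulators Regulators to profile (default: union of all).
#' @return Tibble `regulator`, `condition`, `z`, `p_overlap`.
#' @export
z_profiles <- function(rankings, regulators = NULL) {
  conds <- purrr::imap_chr(rankings, function(r, i) {
    ranking_condition(r, if (is.character(i)) i else paste0("condition_", i))
  })
  long <- purrr::map2(rankings, conds, function(r, cond) {
    tab <- as_tibble(r)
    tibble(regulator = tab$regulator, condition = cond,
           z = tab$z, p_overlap = tab$p_overlap)
  }) %>%
    dplyr::bind_rows()
  if (!is.null(regulators)) {
    long <- long[long$regulator %in% canon_id(regulators), , drop = FALSE]
  }
  dplyr::arrange(long, .data$regulator, .data$condition)
}

#' Plot cross-condition z profiles
#'
#' @param profiles Output of [z_profiles()].
#' @return A ggplot object (grouped bar chart of z per condition).
#' @export
plot_z_profiles <- function(profiles) {
  ggplot2::ggplot(
    profiles[!is.na(profiles$z), , drop = FALSE],
    ggplot2::aes(x = .data$condition, y = .data$z, fill = .data$regulator)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "activation z-score") +
    ggplot2::theme_minimal()
}
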