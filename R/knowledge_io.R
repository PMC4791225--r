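#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr %>%
#' @import tibble
NULL

# Canonical identifier folding used across all omic layers: gene symbols,
# miRNA names and regulator labels join case-insensitively.
canon_id <- function(x) toupper(trimws(as.character(x)))

canon_sign <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    x,
    c("+", "activates", "activate", "activation", "1") ~ "activates",
    c("-", "represses", "repress", "repression", "-1") ~ "represses",
    c("?", "unknown", "na", "") ~ "unknown",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort(paste0(
      "Unrecognised edge sign value(s): ",
      paste(unique(x[is.na(out)]), collapse = ", "),
      ". Expected one of +, -, ? or activates/represses/unknown."
    ))
  }
  out
}

#' Construct a prior regulatory network
#'
#' A prior network is the stand-in for a curated regulatory knowledge base:
#' signed regulator -> target edges, each carrying a positive weight
#' (unit weights by default). Duplicate (regulator, target) pairs are
#' collapsed: agreeing signs are kept, conflicting signs become `"unknown"`,
#' and the maximum weight is retained.
#'
#' @param edges Data frame with columns `regulator`, `target`, `sign`
#'   (one of `+`/`-`/`?` or `activates`/`represses`/`unknown`) and an
#'   optional `weight` (positive; defaults to 1).
#' @return An object of class `prior_network`: a list with `edges` (tibble
#'   of canonicalized, deduplicated edges), `regulators` and `targets`
#'   (character vectors).
#' @export
prior_network <- function(edges) {
  edges <- as_tibble(edges)
  required <- c("regulator", "target", "sign")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("Prior network is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(edges) == 0) {
    abort("Prior network has no edges.")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$weight[is.na(edges$weight)] <- 1
  if (!is.numeric(edges$weight) || any(edges$weight <= 0)) {
    abort("Edge weights must be positive numbers.")
  }

  edges <- edges %>%
    dplyr::transmute(
      regulator = canon_id(.data$regulator),
      target = canon_id(.data$target),
      sign = canon_sign(.data$sign),
      weight = as.numeric(.data$weight)
    )

  n_self <- sum(edges$regulator == edges$target)
  if (n_self > 0) {
    warn(paste0(n_self, " self-edge(s) (regulator == target) present; kept but flagged."))
  }

  edges <- edges %>%
    dplyr::group_by(.data$regulator, .data$target) %>%
    dplyr::summarise(
      sign = if (dplyr::n_distinct(.data$sign) == 1L) .data$sign[1] else "unknown",
      weight = max(.data$weight),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$regulator, .data$target)

  structure(
    list(
      edges = edges,
      regulators = sort(unique(edges$regulator)),
      targets = sort(unique(edges$target))
    ),
    class = "prior_network"
  )
}

#' @export
print.prior_network <- function(x, ...) {
  cat("<prior_network> ", length(x$regulators), " regulators, ",
      length(x$targets), " targets, ", nrow(x$edges), " edges\n", sep = "")
  sign_tab <- table(x$edges$sign)
  cat("  signs: ", paste(names(sign_tab), sign_tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a prior regulatory network from TSV
#'
#' Expects a header with columns `regulator`, `target`, `sign` and an
#' optional `weight`. Sign dialects `{+, -, ?}` and
#' `{activates, represses, unknown}` are both accepted.
#'
#' @param path Path to a tab-separated edge list.
#' @return A [prior_network()] object.
#' @export
read_prior_network <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) abort(paste0("Empty prior network file: ", path))
  if ("weight" %in% names(tab)) tab$weight <- as.numeric(tab$weight)
  prior_network(tab)
}

#' Write a prior regulatory network to TSV
#'
#' Canonical form: columns `regulator`, `target`, `sign`, `weight`, sorted
#' by regulator then target, so read -> write -> read is the identity.
#'
#' @param network A [prior_network()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prior_network <- function(network, path) {
  stopifnot(inherits(network, "prior_network"))
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard Broad GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' canonicalized (upper case) and deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `pathway_sets`).
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("Empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0) {
    abort(paste0("Malformed GMT line (fewer than 3 fields) at line ", bad[1], "."))
  }
  nms <- vapply(fields, function(f) trimws(f[1]), character(1))
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene-set name(s) in GMT: ",
                 paste(unique(dup), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) {
    members <- unique(canon_id(f[-c(1, 2)]))
    members[nzchar(members)]
  })
  names(sets) <- nms
  empty <- nms[vapply(sets, length, integer(1)) == 0L]
  if (length(empty) > 0) {
    abort(paste0("Gene set(s) with no members: ", paste(empty, collapse = ", ")))
  }
  structure(sets, class = c("pathway_sets", "list"))
}

#' Write gene sets to a canonical GMT file
#'
#' Members are written sorted so that a read -> write -> read round trip is
#' byte-identical on canonical files.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- purrr::imap_chr(as.list(sets), function(members, nm) {
    paste(c(nm, descriptions[[match(nm, names(sets))]], sort(unique(canon_id(members)))),
          collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Construct a protein-protein interaction graph
#'
#' Undirected edges over protein identifiers with an optional confidence
#' score in \[0, 1\]. `(a, b)` and `(b, a)` duplicates are merged keeping
#' the maximum score; self-edges are dropped with a warning.
#'
#' @param edges Data frame with columns `node_a`, `node_b` and optional
#'   `score`.
#' @return An `interaction_graph`: a tibble of canonical undirected edges
#'   (`node_a < node_b` lexicographically) with a `score` column.
#' @export
interaction_graph <- function(edges) {
  edges <- as_tibble(edges)
  required <- c("node_a", "node_b")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("Interaction edge list is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  edges$score <- as.numeric(edges$score)
  if (any(!is.na(edges$score) & (edges$score < 0 | edges$score > 1))) {
    abort("Interaction scores must lie in [0, 1].")
  }
  a <- canon_id(edges$node_a)
  b <- canon_id(edges$node_b)
  self <- a == b
  if (any(self)) {
    warn(paste0(sum(self), " self-interaction(s) dropped."))
    edges <- edges[!self, , drop = FALSE]
    a <- a[!self]; b <- b[!self]
  }
  out <- tibble(
    node_a = pmin(a, b),
    node_b = pmax(a, b),
    score = edges$score
  ) %>%
    dplyr::group_by(.data$node_a, .data$node_b) %>%
    dplyr::summarise(
      score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$node_a, .data$node_b)
  class(out) <- c("interaction_graph", class(tibble()))
  out
}

#' Read a protein-interaction edge list from TSV
#'
#' @param path Path to a TSV with header `node_a`, `node_b` and optional
#'   `score` in \[0, 1\].
#' @return An [interaction_graph()] tibble.
#' @export
read_interactions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  interaction_graph(tab)
}

#' Write a protein-interaction edge list to TSV
#'
#' @param graph An [interaction_graph()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(graph, path) {
  readr::write_tsv(as_tibble(graph), path, progress = FALSE)
  invisible(path)
}

#' Convert an interaction graph to igraph
#'
#' @param graph An [interaction_graph()] tibble.
#' @return An undirected [igraph::graph] with a `score` edge attribute.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(as.data.frame(graph), directed = FALSE)
}
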