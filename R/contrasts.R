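#' Construct a differential-expression contrast table
#'
#' One row per gene with its log2 fold change and significance for a single
#' condition/contrast. The measured-gene universe is the full set of rows:
#' overlap p-values downstream are computed against it.
#'
#' @param records Data frame with columns `gene`, `log2fc`, `p`, `fdr`.
#' @param condition Label for the contrast (e.g. a cell line or time point).
#' @return A tibble of class `contrast_tbl` with a `condition` attribute.
#' @export
contrast_table <- function(records, condition) {
  records <- as_tibble(records)
  required <- c("gene", "log2fc", "p", "fdr")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Contrast table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records <- records %>%
    dplyr::transmute(
      gene = canon_id(.data$gene),
      log2fc = as.numeric(.data$log2fc),
      p = as.numeric(.data$p),
      fdr = as.numeric(.data$fdr)
    )
  if (any(!is.finite(records$log2fc))) abort("Non-finite log2fc values.")
  if (any(is.na(records$p)) || any(records$p < 0 | records$p > 1)) {
    abort("p values must lie in [0, 1].")
  }
  if (any(is.na(records$fdr)) || any(records$fdr < 0 | records$fdr > 1)) {
    abort("fdr values must lie in [0, 1].")
  }
  dup <- records$gene[duplicated(records$gene)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene row(s) in contrast: ",
                 paste(unique(dup), collapse = ", ")))
  }
  out <- records
  attr(out, "condition") <- as.character(condition)
  class(out) <- c("contrast_tbl", class(tibble()))
  out
}

#' Load a contrast table from TSV
#'
#' @param path TSV file with header `gene`, `log2fc`, `p`, `fdr`.
#' @param condition Label for the contrast.
#' @return A [contrast_table()].
#' @export
load_contrast <- function(path, condition) {
  tab <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      log2fc = readr::col_double(),
      p = readr::col_double(),
      fdr = readr::col_double()
    )
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0("Non-numeric or malformed field(s) in ", path,
                 " (first at line ", probs$row[1] + 1L, ")."))
  }
  contrast_table(tab, condition)
}

#' Write a contrast table to TSV
#'
#' @param table A [contrast_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Construct an evidence set
#'
#' The uniform evidence object consumed by regulator inference: a gene set,
#' optionally with observed regulation directions, inside a measured-gene
#' universe. Directional sets come from DE tables; non-directional sets from
#' ChIP-bound genes, co-precipitated interactors or screen hits.
#'
#' @param genes Character vector of evidence genes.
#' @param universe Character vector of all measured/annotated genes; must
#'   contain `genes`.
#' @param condition Label.
#' @param directions Optional named numeric vector (values +1/-1, names a
#'   subset of `genes`).
#' @param kind One of `"de"`, `"bound"`, `"interactor"`, `"screen_hit"`.
#' @return An object of class `evidence_set`.
#' @export
evidence_set <- function(genes, universe, condition = "evidence",
                         directions = NULL,
                         kind = c("de", "bound", "interactor", "screen_hit")) {
  kind <- match.arg(kind)
  genes <- unique(canon_id(genes))
  universe <- unique(canon_id(universe))
  if (length(universe) == 0) abort("Evidence universe is empty.")
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    abort(paste0("Evidence gene(s) outside the universe: ",
                 paste(utils::head(outside, 5), collapse = ", "),
                 if (length(outside) > 5) ", ..." else ""))
  }
  if (!is.null(directions)) {
    if (is.null(names(directions))) abort("directions must be a named vector.")
    names(directions) <- canon_id(names(directions))
    if (!all(directions %in% c(-1, 1))) {
      abort("Direction values must be +1 or -1.")
    }
    extra <- setdiff(names(directions), genes)
    if (length(extra) > 0) {
      abort("directions may only cover evidence genes.")
    }
  }
  structure(
    list(condition = as.character(condition), genes = genes,
         directions = directions, universe = universe, kind = kind),
    class = "evidence_set"
  )
}

#' @export
print.evidence_set <- function(x, ...) {
  cat("<evidence_set> ", x$condition, " [", x$kind, "]: ",
      length(x$genes), " genes in a universe of ", length(x$universe),
      if (!is.null(x$directions)) " (directional)" else " (non-directional)",
      "\n", sep = "")
  invisible(x)
}

#' Threshold a contrast table into a directional evidence set
#'
#' Keeps genes with `fdr <= fdr_max` and `|log2fc| >= min_abs_log2fc`;
#' directions are `sign(log2fc)`. The universe is all measured genes of the
#' contrast. The default keeps every significant DE gene with no fold-change
#' cut (significance alone defines DE).
#'
#' @param table A [contrast_table()].
#' @param fdr_max FDR ceiling (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 0).
#' @return A directional [evidence_set()] of kind `"de"`.
#' @export
significant_set <- function(table, fdr_max = 0.05, min_abs_log2fc = 0) {
  stopifnot(fdr_max >= 0, min_abs_log2fc >= 0)
  tab <- as_tibble(table)
  keep <- tab$fdr <= fdr_max & abs(tab$log2fc) >= min_abs_log2fc
  genes <- tab$gene[keep]
  # A direction requires a non-zero fold change; directions may cover a
  # strict subset of the evidence genes.
  signed <- keep & tab$log2fc != 0
  directions <- stats::setNames(sign(tab$log2fc[signed]), tab$gene[signed])
  evidence_set(
    genes = genes,
    universe = tab$gene,
    condition = attr(table, "condition") %||% "contrast",
    directions = if (length(directions) > 0) directions else NULL,
    kind = "de"
  )
}

#' Build a non-directional evidence set from a plain gene list
#'
#' For assays with no measurement-based universe (ChIP-bound genes,
#' interactor sets, screen hits) the universe must be supplied explicitly;
#' overlap p-values are universe-sensitive.
#'
#' @param genes Character vector of evidence genes.
#' @param universe Explicit background gene universe.
#' @inheritParams evidence_set
#' @return A non-directional [evidence_set()].
#' @export
gene_set_evidence <- function(genes, universe, condition = "evidence",
                              kind = c("bound", "interactor", "screen_hit")) {
  kind <- match.arg(kind)
  evidence_set(genes, universe, condition = condition, directions = NULL,
               kind = kind)
}

#' Up/down proportions of a directional evidence set
#'
#' @param evidence A directional [evidence_set()].
#' @return A tibble with columns `condition`, `n`, `pct_up`, `pct_down`
#'   (percentages summing to 100 for non-empty sets).
#' @export
up_down_proportions <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_set"))
  if (is.null(evidence$directions)) {
    abort("Evidence set is non-directional; up/down proportions undefined.")
  }
  d <- evidence$directions
  n <- length(d)
  tibble(
    condition = evidence$condition,
    n = n,
    pct_up = 100 * sum(d > 0) / n,
    pct_down = 100 * sum(d < 0) / n
  )
}
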