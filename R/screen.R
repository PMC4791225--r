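PLATE_ROWS <- 16L
PLATE_COLS <- 24L

#' Default control mask for a 384-well screen plate
#'
#' Controls occupy lines 1-2 and 23-24 along the 24-position axis (a 16-row
#' plate has no line 23, so the mask is taken along the columns); these
#' wells are excluded when fitting the normalization surface so that only
#' the sample fraction of the plate is normalized.
#'
#' @return A 16 x 24 logical matrix, `TRUE` for control wells.
#' @export
default_control_mask <- function() {
  mask <- matrix(FALSE, PLATE_ROWS, PLATE_COLS)
  mask[, c(1, 2, 23, 24)] <- TRUE
  mask
}

well_name <- function(row, col) {
  paste0(LETTERS[row], sprintf("%02d", col))
}

#' Construct a 384-well plate grid
#'
#' @param signal 16 x 24 numeric matrix of raw luminescence readouts.
#' @param plate_id Plate identifier.
#' @param control_mask 16 x 24 logical matrix marking control wells
#'   (default: [default_control_mask()]).
#' @param annotation Optional tibble `well`, `gene`, `role`
#'   (`sample`/`neg_ctrl`/`pos_ctrl`).
#' @return An object of class `plate_grid`.
#' @export
plate_grid <- function(signal, plate_id = "plate1",
                       control_mask = default_control_mask(),
                       annotation = NULL) {
  signal <- as.matrix(signal)
  if (!all(dim(signal) == c(PLATE_ROWS, PLATE_COLS))) {
    abort("Plate signal must be a 16 x 24 matrix.")
  }
  if (!all(dim(control_mask) == c(PLATE_ROWS, PLATE_COLS)) ||
      !is.logical(control_mask)) {
    abort("Control mask must be a 16 x 24 logical matrix.")
  }
  if (any(signal < 0, na.rm = TRUE)) {
    abort("Raw luminescence must be non-negative.")
  }
  structure(
    list(plate_id = as.character(plate_id), signal = signal,
         control_mask = control_mask, annotation = annotation,
         corrected = FALSE),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat("<plate_grid> ", x$plate_id, ": 16 x 24, ",
      sum(x$control_mask), " control wells",
      if (isTRUE(x$corrected)) " (loess-corrected)" else "", "\n", sep = "")
  invisible(x)
}

#' Read a plate from CSV grid + annotation
#'
#' @param plate_path CSV of 16 rows x 24 columns of raw readouts (no
#'   header).
#' @param annotation_path Optional CSV with columns `well` (e.g. `C07`),
#'   `gene`, `role`.
#' @param plate_id Plate identifier.
#' @inheritParams plate_grid
#' @return A [plate_grid()].
#' @export
read_plate <- function(plate_path, annotation_path = NULL,
                       plate_id = "plate1",
                       control_mask = default_control_mask()) {
  mat <- as.matrix(utils::read.csv(plate_path, header = FALSE))
  dimnames(mat) <- NULL
  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- readr::read_csv(annotation_path, show_col_types = FALSE,
                                  progress = FALSE)
  }
  plate_grid(mat, plate_id = plate_id, control_mask = control_mask,
             annotation = annotation)
}

#' Loess surface normalization of a screen plate
#'
#' Fits a locally weighted quadratic surface of `log2(signal)` over the
#' (row, column) well coordinates using only non-control wells with positive
#' signal, then replaces each well's log2 signal by its residual plus the
#' grand median of the fitted sample values. This removes smooth spatial
#' artifacts (edge effects, dispenser gradients) while leaving genuine
#' well-level effects in place; control wells are corrected by evaluating
#' the fitted surface at their coordinates but never influence the fit.
#'
#' @param plate A [plate_grid()].
#' @param span Loess span in (0, 1] (default 0.5).
#' @return The plate with `signal` replaced by corrected (linear-scale)
#'   values, `corrected = TRUE`, and a `wells` tibble (`well`, `row`, `col`,
#'   `is_control`, `raw`, `corrected_log2`) attached.
#' @export
loess_normalize <- function(plate, span = 0.5) {
  stopifnot(inherits(plate, "plate_grid"), span > 0, span <= 1)
  signal <- plate$signal
  mask <- plate$control_mask
  coords <- expand.grid(row = seq_len(PLATE_ROWS), col = seq_len(PLATE_COLS))
  y <- log2(as.vector(signal))
  is_control <- as.vector(mask)
  positive <- is.finite(y)
  n_dropped <- sum(!positive & !is_control)
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " non-positive sample well(s) dropped from the fit."))
  }
  fit_idx <- !is_control & positive
  if (sum(fit_idx) < 30) {
    abort("Need at least 30 positive non-control wells to fit the surface.")
  }
  df <- data.frame(y = y, row = coords$row, col = coords$col)
  fit <- stats::loess(y ~ row + col, data = df[fit_idx, , drop = FALSE],
                      span = span, degree = 2, surface = "direct",
                      family = "gaussian")
  surface <- stats::predict(fit, newdata = df)
  centre <- stats::median(surface[fit_idx])
  corrected_log2 <- y - surface + centre
  out <- plate
  out$signal <- matrix(2^corrected_log2, PLATE_ROWS, PLATE_COLS)
  out$corrected <- TRUE
  out$wells <- tibble(
    well = well_name(coords$row, coords$col),
    row = coords$row,
    col = coords$col,
    is_control = is_control,
    raw = as.vector(signal),
    corrected_log2 = corrected_log2
  )
  out
}

#' Robust z-scores (median / MAD)
#'
#' `z = (x - median) / (1.4826 * MAD)`, the 1.4826 factor making the MAD a
#' consistent estimator of the standard deviation under normality. When the
#' MAD is zero every z is set to 0 and a `degenerate_scale` attribute flags
#' the result.
#'
#' @param values Numeric vector (length >= 2).
#' @return Numeric vector of z-scores (attribute `degenerate_scale` set to
#'   `TRUE` when MAD = 0).
#' @export
robust_z <- function(values) {
  if (length(values) < 2) abort("robust_z needs at least 2 values.")
  med <- stats::median(values)
  scale <- stats::mad(values, constant = 1.4826)
  if (scale == 0) {
    warn("MAD is zero; returning all-zero z-scores (degenerate scale).")
    return(structure(rep(0, length(values)), degenerate_scale = TRUE))
  }
  structure((values - med) / scale, degenerate_scale = FALSE)
}

#' Per-well screen results for a corrected plate
#'
#' log2 fold changes are taken against the median corrected signal of the
#' sample wells; robust z-scores are computed per plate over the corrected
#' sample-well distribution (controls receive values against the same
#' reference).
#'
#' @param plate A loess-corrected [plate_grid()].
#' @return Tibble `well`, `row`, `col`, `is_control`, `gene`, `role`,
#'   `corrected`, `log2fc`, `z`.
#' @export
well_results <- function(plate) {
  stopifnot(inherits(plate, "plate_grid"))
  if (!isTRUE(plate$corrected)) {
    abort("Plate must be loess-corrected first (see loess_normalize()).")
  }
  wells <- plate$wells
  sample_log2 <- wells$corrected_log2[!wells$is_control]
  ref <- stats::median(sample_log2)
  med <- stats::median(sample_log2)
  scale <- stats::mad(sample_log2, constant = 1.4826)
  z <- if (scale == 0) rep(0, nrow(wells)) else (wells$corrected_log2 - med) / scale
  out <- wells %>%
    dplyr::mutate(
      corrected = 2^.data$corrected_log2,
      log2fc = .data$corrected_log2 - ref,
      z = z
    )
  if (!is.null(plate$annotation)) {
    out <- dplyr::left_join(out, plate$annotation, by = "well")
  } else {
    out$gene <- ifelse(out$is_control, NA_character_, out$well)
    out$role <- ifelse(out$is_control, "neg_ctrl", "sample")
  }
  out
}

#' Call viability hits from per-gene log2 fold changes
#'
#' Genes are aggregated as the mean log2FC over their replicate wells (four
#' pooled siRNAs share one well, so replication is across plates/wells, not
#' within); hits are wells that changed viability by at least the threshold,
#' boundary inclusive: `decreased` at `log2fc <= -threshold`, `increased`
#' at `log2fc >= threshold`.
#'
#' @param well_table Tibble with columns `gene` and `log2fc` (e.g. from
#'   [well_results()], sample wells only).
#' @param threshold Positive log2FC hit threshold (default 1).
#' @return Tibble `gene`, `n_wells`, `log2fc`, `hit` of class `hit_table`.
#' @export
call_hits <- function(well_table, threshold = 1) {
  stopifnot(threshold > 0)
  tab <- as_tibble(well_table)
  stopifnot(all(c("gene", "log2fc") %in% names(tab)))
  tab <- tab[!is.na(tab$gene), , drop = FALSE]
  out <- tab %>%
    dplyr::group_by(gene = canon_id(.data$gene)) %>%
    dplyr::summarise(
      n_wells = dplyr::n(),
      log2fc = mean(.data$log2fc),
      .groups = "drop"
    ) %>%
    dplyr::mutate(hit = dplyr::case_when(
      .data$log2fc <= -threshold ~ "decreased",
      .data$log2fc >= threshold ~ "increased",
      TRUE ~ "none"
    )) %>%
    dplyr::arrange(.data$log2fc)
  class(out) <- c("hit_table", class(tibble()))
  attr(out, "threshold") <- threshold
  out
}

#' Convert screen hits to an evidence set
#'
#' Hit genes (default: viability-decreasing) become a non-directional
#' evidence set over the universe of all screened genes, ready for
#' [infer_itrs()].
#'
#' @param hits A [call_hits()] table.
#' @param which Hit classes to keep (default `"decreased"`).
#' @param condition Label.
#' @return An [evidence_set()] of kind `"screen_hit"`.
#' @export
hits_as_evidence <- function(hits, which = "decreased",
                             condition = "rnai_screen") {
  gene_set_evidence(
    genes = hits$gene[hits$hit %in% which],
    universe = hits$gene,
    condition = condition,
    kind = "screen_hit"
  )
}

#' Plate signal heatmap
#'
#' @param plate A [plate_grid()].
#' @param log2 Show log2 signal (default TRUE).
#' @return A ggplot object.
#' @export
plot_plate <- function(plate, log2 = TRUE) {
  tab <- tibble(
    row = rep(seq_len(PLATE_ROWS), PLATE_COLS),
    col = rep(seq_len(PLATE_COLS), each = PLATE_ROWS),
    value = as.vector(if (log2) base::log2(plate$signal) else plate$signal),
    control = as.vector(plate$control_mask)
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tab[tab$control, , drop = FALSE],
                        shape = 4, size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "column", y = "row",
                  fill = if (log2) "log2 signal" else "signal",
                  title = plate$plate_id) +
    ggplot2::theme_minimal()
}

#' Differentiation-ratio statistics with pairwise Welch tests
#'
#' The differentiation ratio of a cell is the length of its longest neurite
#' divided by the cell's width; differentiated neuroblastoma cells grow
#' long neurites on narrow bodies, so higher ratios mean more
#' differentiation. Reports per-group mean and standard error of the mean,
#' plus two-sided Welch two-sample t-tests for all (or requested) group
#' pairs.
#'
#' @param measurements Tibble with columns `group`, `neurite_length`,
#'   `cell_width` (same length unit, e.g. micrometres).
#' @param pairs Optional 2-column matrix / list of group pairs to test
#'   (default: all pairs).
#' @return List with `ratios` (input plus `ratio` column), `groups` (tibble
#'   `group`, `n`, `mean_ratio`, `sem`) and `tests` (tibble `group1`,
#'   `group2`, `t`, `df`, `p`).
#' @export
differentiation_stats <- function(measurements, pairs = NULL) {
  tab <- as_tibble(measurements)
  stopifnot(all(c("group", "neurite_length", "cell_width") %in% names(tab)))
  if (any(tab$cell_width <= 0)) abort("Cell widths must be positive.")
  if (any(tab$neurite_length < 0)) abort("Neurite lengths must be non-negative.")
  tab$ratio <- tab$neurite_length / tab$cell_width
  groups <- tab %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      sem = stats::sd(.data$ratio) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  if (any(groups$n < 2)) abort("Each group needs at least 2 cells.")
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(unique(tab$group)), 2, simplify = FALSE)
  } else if (is.matrix(pairs)) {
    pairs <- asplit(pairs, 1)
  }
  tests <- purrr::map(pairs, function(pr) {
    x <- tab$ratio[tab$group == pr[1]]
    y <- tab$ratio[tab$group == pr[2]]
    tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    tibble(group1 = pr[1], group2 = pr[2],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }) %>%
    dplyr::bind_rows()
  list(ratios = tab, groups = groups, tests = tests)
}
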