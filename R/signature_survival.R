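#' Build a directional gene signature from a regulator's contributing genes
#'
#' Pools the DE genes that supported a regulator's calls across conditions
#' (see [itr_contributions()]) and keeps genes observed with a consistent
#' direction in at least `min_conditions` conditions. Genes seen with
#' conflicting directions in different conditions are dropped (and logged).
#'
#' @param regulator Regulator identifier the signature belongs to.
#' @param contributions Tibble with columns `condition`, `gene`, `direction`
#'   (+1/-1); typically `dplyr::bind_rows()` of per-condition
#'   [itr_contributions()].
#' @param min_conditions Minimum number of supporting conditions
#'   (default 2).
#' @return A tibble of class `itr_signature` with columns `gene`,
#'   `direction`, `n_conditions`, plus `regulator` and `dropped` attributes.
#' @export
build_signature <- function(regulator, contributions, min_conditions = 2) {
  contributions <- as_tibble(contributions)
  stopifnot(all(c("condition", "gene", "direction") %in% names(contributions)))
  if (!all(contributions$direction %in% c(-1, 1))) {
    abort("Contribution directions must be +1 or -1.")
  }
  per_gene <- contributions %>%
    dplyr::distinct(.data$condition, .data$gene, .data$direction) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_conditions = dplyr::n_distinct(.data$condition),
      consistent = dplyr::n_distinct(.data$direction) == 1L,
      direction = .data$direction[1],
      .groups = "drop"
    )
  dropped <- per_gene$gene[!per_gene$consistent]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " gene(s) dropped for conflicting directions: ",
                  paste(utils::head(dropped, 5), collapse = ", "),
                  if (length(dropped) > 5) ", ..." else ""))
  }
  sig <- per_gene %>%
    dplyr::filter(.data$consistent, .data$n_conditions >= min_conditions) %>%
    dplyr::select("gene", "direction", "n_conditions") %>%
    dplyr::arrange(.data$gene)
  if (nrow(sig) == 0) {
    abort(paste0("Empty signature for ", regulator,
                 ": no gene is consistently DE in >= ", min_conditions,
                 " conditions."))
  }
  attr(sig, "regulator") <- canon_id(regulator)
  attr(sig, "dropped") <- dropped
  class(sig) <- c("itr_signature", class(tibble()))
  sig
}

#' Write a signature to TSV
#'
#' @param signature An `itr_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  readr::write_tsv(as_tibble(signature), path, progress = FALSE)
  invisible(path)
}

#' Assemble a patient cohort
#'
#' @param expression Numeric matrix, genes in rows (rownames = gene ids),
#'   patients in columns (colnames = patient ids).
#' @param survival Data frame with columns `patient`, `time` (non-negative),
#'   `event` (0/1).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(expression, survival) {
  survival <- as_tibble(survival)
  stopifnot(all(c("patient", "time", "event") %in% names(survival)))
  expression <- as.matrix(expression)
  rownames(expression) <- canon_id(rownames(expression))
  if (is.null(colnames(expression))) {
    abort("Expression matrix must carry patient column names.")
  }
  if (!setequal(colnames(expression), survival$patient)) {
    abort("Expression columns and survival rows must cover the same patients.")
  }
  if (any(is.na(survival$time)) || any(survival$time < 0)) {
    abort("Survival times must be non-negative and non-missing.")
  }
  if (!all(survival$event %in% c(0, 1))) {
    abort("Events must be 0 (censored) or 1 (event).")
  }
  survival <- survival[match(colnames(expression), survival$patient), , drop = FALSE]
  structure(list(expression = expression, survival = survival),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data> ", ncol(x$expression), " patients x ",
      nrow(x$expression), " genes; ", sum(x$survival$event), " events\n",
      sep = "")
  invisible(x)
}

#' Read a cohort from expression + survival TSVs
#'
#' @param expression_path TSV: first column `gene`, remaining columns one
#'   per patient.
#' @param survival_path TSV with columns `patient`, `time`, `event`.
#' @return A [cohort_data()] object.
#' @export
read_cohort <- function(expression_path, survival_path) {
  expr_tab <- readr::read_tsv(expression_path, show_col_types = FALSE,
                              progress = FALSE)
  genes <- expr_tab[[1]]
  mat <- as.matrix(expr_tab[, -1, drop = FALSE])
  rownames(mat) <- genes
  surv <- readr::read_tsv(survival_path, show_col_types = FALSE,
                          progress = FALSE)
  cohort_data(mat, surv)
}

#' Score a cohort against a directional signature
#'
#' Each signature gene's expression row is standardized to mean 0 / sd 1
#' across patients; a patient's score is the mean over signature genes of
#' `direction * standardized expression`. High scores mean expression moves
#' with the signature's expected directions. Signature genes missing from
#' the matrix or with zero variance are skipped with a warning.
#'
#' @param signature An [build_signature()] result (or tibble with `gene`,
#'   `direction`).
#' @param cohort A [cohort_data()].
#' @return Named numeric vector of per-patient scores.
#' @export
score_cohort <- function(signature, cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  sig <- as_tibble(signature)
  genes <- canon_id(sig$gene)
  present <- genes %in% rownames(cohort$expression)
  if (any(!present)) {
    warn(paste0(sum(!present), " signature gene(s) absent from the cohort ",
                "expression matrix skipped."))
  }
  sig <- sig[present, , drop = FALSE]
  if (nrow(sig) == 0) abort("No signature gene is present in the cohort.")
  rows <- cohort$expression[canon_id(sig$gene), , drop = FALSE]
  sds <- apply(rows, 1, stats::sd)
  degenerate <- sds == 0 | is.na(sds)
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " zero-variance signature gene row(s) skipped."))
    rows <- rows[!degenerate, , drop = FALSE]
    sig <- sig[!degenerate, , drop = FALSE]
    sds <- sds[!degenerate]
  }
  if (nrow(sig) == 0) abort("No usable (non-degenerate) signature gene.")
  z <- (rows - rowMeans(rows)) / sds
  scores <- colMeans(sig$direction * z)
  stats::setNames(scores, colnames(cohort$expression))
}

#' Stratify a cohort by signature score and test survival separation
#'
#' Splits patients into high/low groups at a score quantile (median by
#' default; ties at the cut go to the low group), fits per-group
#' Kaplan-Meier curves and runs a two-sided log-rank test.
#'
#' @param scores Named per-patient score vector ([score_cohort()]).
#' @param cohort A [cohort_data()].
#' @param split Quantile for the cut (default 0.5, the median).
#' @return Object of class `strat_result`: list with `groups` (tibble
#'   `patient`, `score`, `group`), `statistic` (log-rank chi-square), `p`,
#'   `km` (tibble `group`, `time`, `surv`) and `fit` (the survfit object).
#' @export
stratify_and_test <- function(scores, cohort, split = 0.5) {
  stopifnot(inherits(cohort, "cohort_data"), split > 0, split < 1)
  surv <- cohort$survival
  scores <- scores[surv$patient]
  if (any(is.na(scores))) abort("Scores must cover every cohort patient.")
  cut <- stats::quantile(scores, split, names = FALSE, type = 7)
  group <- unname(ifelse(scores > cut, "high", "low"))
  if (min(table(factor(group, levels = c("high", "low")))) < 2) {
    abort("Each score group needs at least 2 patients.")
  }
  df <- data.frame(time = surv$time, event = surv$event,
                   group = factor(group, levels = c("low", "high")))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  statistic <- unname(sd_fit$chisq)
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  km_fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(sub("^group=", "", names(km_fit$strata)), km_fit$strata)
  km <- tibble(group = strata, time = km_fit$time, surv = km_fit$surv)
  structure(
    list(
      groups = tibble(patient = surv$patient, score = unname(scores),
                      group = group),
      statistic = statistic, p = p, km = km, fit = km_fit, split = split
    ),
    class = "strat_result"
  )
}

#' @export
print.strat_result <- function(x, ...) {
  cat("<strat_result> log-rank chi-square = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  print(table(x$groups$group))
  invisible(x)
}

#' @export
tidy.strat_result <- function(x, ...) x$km

#' @export
glance.strat_result <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p.value = x$p,
    n = nrow(x$groups),
    n_high = sum(x$groups$group == "high"),
    n_low = sum(x$groups$group == "low"),
    split = x$split
  )
}

#' Kaplan-Meier plot of a stratification result
#'
#' @param object A `strat_result`.
#' @param ... Unused.
#' @return A ggplot object with per-group step curves.
#' @export
autoplot.strat_result <- function(object, ...) {
  km <- dplyr::bind_rows(
    tibble(group = unique(object$km$group), time = 0, surv = 1),
    object$km
  )
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival fraction",
      subtitle = paste0("log-rank p = ", signif(object$p, 3))
    ) +
    ggplot2::theme_minimal()
}
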