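#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of drawing at least `n_overlap` of a regulator's targets when
#' `n_evidence` genes are sampled without replacement from a universe of
#' `n_universe` genes containing `n_targets_in_universe` targets:
#' `P(X >= n_overlap)`. Equals 1 when `n_overlap` is 0.
#'
#' @param n_targets_in_universe Number of the regulator's known targets that
#'   are in the measured universe.
#' @param n_evidence Number of evidence genes (e.g. significant DE genes).
#' @param n_universe Size of the measured-gene universe.
#' @param n_overlap Observed intersection size.
#' @return Upper-tail probability in (0, 1].
#' @export
overlap_pvalue <- function(n_targets_in_universe, n_evidence, n_universe,
                           n_overlap) {
  if (n_overlap > min(n_targets_in_universe, n_evidence) ||
      max(n_targets_in_universe, n_evidence) > n_universe ||
      any(c(n_targets_in_universe, n_evidence, n_universe, n_overlap) < 0)) {
    abort("Inconsistent overlap counts: need n_overlap <= min(targets, evidence) <= universe.")
  }
  stats::phyper(n_overlap - 1, n_targets_in_universe,
                n_universe - n_targets_in_universe, n_evidence,
                lower.tail = FALSE)
}

#' Signed activation z-score for one regulator
#'
#' Measures whether a regulator's overlapping targets moved the way its
#' edge signs predict: `z = sum(w * m) / sqrt(sum(w^2))` over signed
#' overlapping edges, where `m = +1` when the predicted direction
#' (activates -> up, represses -> down) matches the observed DE direction
#' and `-1` otherwise. Unknown-sign edges are excluded. With unit weights
#' this is `(n_consistent - n_inconsistent) / sqrt(n_signed_overlap)`.
#' Positive z supports activation of the regulator, negative z inhibition.
#'
#' @param edges Tibble of edges for a single regulator (columns `target`,
#'   `sign`, `weight`).
#' @param directions Named numeric vector of observed directions (+1/-1)
#'   keyed by gene.
#' @return The z-score, or `NA_real_` when no signed edge overlaps the
#'   directional evidence.
#' @export
activation_z <- function(edges, directions) {
  if (length(directions) == 0 || is.null(directions)) return(NA_real_)
  if (!all(directions %in% c(-1, 1))) {
    abort("Observed directions must be +1 or -1.")
  }
  if ("regulator" %in% names(edges) &&
      length(unique(edges$regulator)) > 1) {
    abort("activation_z expects the edges of a single regulator.")
  }
  signed <- edges[edges$sign != "unknown" & edges$target %in% names(directions), ,
                  drop = FALSE]
  if (nrow(signed) == 0) return(NA_real_)
  predicted <- ifelse(signed$sign == "activates", 1, -1)
  m <- ifelse(predicted == directions[signed$target], 1, -1)
  w <- signed$weight
  sum(w * m) / sqrt(sum(w^2))
}

#' Dichotomize an activation z-score
#'
#' @param z Activation z-score (may be `NA`).
#' @param z_threshold Positive call threshold (default 2). Boundaries are
#'   inclusive: `z >= threshold` is activated, `z <= -threshold` inhibited.
#' @return `"activated"`, `"inhibited"` or `"indeterminate"`.
#' @export
call_state <- function(z, z_threshold = 2) {
  stopifnot(z_threshold > 0)
  dplyr::case_when(
    is.na(z) ~ "indeterminate",
    z >= z_threshold ~ "activated",
    z <= -z_threshold ~ "inhibited",
    TRUE ~ "indeterminate"
  )
}

#' Infer transcriptional regulators (ITRs) for an evidence set
#'
#' The core inference: every regulator of the prior network with at least
#' one target inside the evidence universe is scored by (i) the upper-tail
#' hypergeometric p-value of its target overlap with the evidence genes
#' (unknown-sign edges count towards overlap) and (ii), when the evidence is
#' directional, the signed activation z-score over its signed overlapping
#' edges. Overlap p-values are Benjamini-Hochberg adjusted across
#' regulators. Regulators are ranked by ascending overlap p-value with a
#' deterministic tie-break: larger `|z|` first (undefined z last), then
#' regulator name.
#'
#' @param network A [prior_network()].
#' @param evidence An [evidence_set()].
#' @param z_threshold Activation-call threshold passed to [call_state()].
#' @return A tibble of class `itr_ranking` with one row per regulator:
#'   `regulator`, `n_targets_in_universe`, `n_overlap`, `n_consistent`,
#'   `n_inconsistent`, `p_overlap`, `fdr_overlap`, `z`, `state`, plus a
#'   `condition` attribute.
#' @export
infer_itrs <- function(network, evidence, z_threshold = 2) {
  stopifnot(inherits(network, "prior_network"), inherits(evidence, "evidence_set"))
  universe <- evidence$universe
  if (length(universe) == 0) abort("Evidence universe is empty.")
  ev_genes <- evidence$genes
  directions <- evidence$directions

  edges <- network$edges[network$edges$target %in% universe, , drop = FALSE]
  if (nrow(edges) == 0) {
    abort("No prior-network target falls inside the evidence universe.")
  }

  n_universe <- length(universe)
  n_evidence <- length(ev_genes)

  calls <- edges %>%
    dplyr::group_by(.data$regulator) %>%
    dplyr::group_map(function(e, key) {
      reg <- key$regulator[[1]]
      in_ev <- e$target %in% ev_genes
      n_overlap <- sum(in_ev)
      signed <- e[in_ev & e$sign != "unknown", , drop = FALSE]
      if (!is.null(directions)) {
        signed <- signed[signed$target %in% names(directions), , drop = FALSE]
        predicted <- ifelse(signed$sign == "activates", 1, -1)
        consistent <- predicted == directions[signed$target]
        n_cons <- sum(consistent)
        n_incons <- sum(!consistent)
        z <- if (nrow(signed) > 0) {
          sum(signed$weight * ifelse(consistent, 1, -1)) / sqrt(sum(signed$weight^2))
        } else NA_real_
      } else {
        n_cons <- 0L
        n_incons <- 0L
        z <- NA_real_
      }
      tibble(
        regulator = reg,
        n_targets_in_universe = nrow(e),
        n_overlap = n_overlap,
        n_consistent = as.integer(n_cons),
        n_inconsistent = as.integer(n_incons),
        p_overlap = overlap_pvalue(nrow(e), n_evidence, n_universe, n_overlap),
        z = z
      )
    }) %>%
    dplyr::bind_rows()

  calls <- calls %>%
    dplyr::mutate(
      fdr_overlap = stats::p.adjust(.data$p_overlap, method = "BH"),
      state = call_state(.data$z, z_threshold)
    ) %>%
    dplyr::arrange(
      .data$p_overlap,
      dplyr::desc(dplyr::coalesce(abs(.data$z), -Inf)),
      .data$regulator
    ) %>%
    dplyr::select(
      "regulator", "n_targets_in_universe", "n_overlap", "n_consistent",
      "n_inconsistent", "p_overlap", "fdr_overlap", "z", "state"
    )

  attr(calls, "condition") <- evidence$condition
  attr(calls, "z_threshold") <- z_threshold
  class(calls) <- c("itr_ranking", class(tibble()))
  calls
}

#' Contributing DE genes of one regulator
#'
#' The overlapping target genes on which a regulator's call rests, with
#' their observed directions: the raw material for a gene signature.
#'
#' @param network A [prior_network()].
#' @param evidence A directional [evidence_set()].
#' @param regulator Regulator identifier.
#' @return Tibble with columns `condition`, `gene`, `direction`.
#' @export
itr_contributions <- function(network, evidence, regulator) {
  stopifnot(inherits(network, "prior_network"), inherits(evidence, "evidence_set"))
  if (is.null(evidence$directions)) {
    abort("Contributions require directional evidence.")
  }
  regulator <- canon_id(regulator)
  targets <- network$edges$target[network$edges$regulator == regulator]
  genes <- intersect(targets, names(evidence$directions))
  tibble(
    condition = evidence$condition,
    gene = genes,
    direction = unname(evidence$directions[genes])
  )
}

#' Truncate a ranking to its top-N regulators
#'
#' @param ranking An `itr_ranking`.
#' @param n Number of top regulators (default 100, the conventional list
#'   size for cross-condition comparisons).
#' @param types Optional regulator-type filter: a named character vector
#'   (regulator -> type) plus `keep`, the types to retain.
#' @param keep Types to retain when `types` is given.
#' @return Character vector of regulator identifiers in rank order.
#' @export
top_regulators <- function(ranking, n = 100, types = NULL, keep = NULL) {
  stopifnot(n > 0)
  regs <- ranking$regulator
  if (!is.null(types) && !is.null(keep)) {
    regs <- regs[types[regs] %in% keep]
  }
  if (length(regs) < n) {
    warn(paste0("Ranking has only ", length(regs),
                " regulators; using all of them."))
    n <- length(regs)
  }
  regs[seq_len(n)]
}

#' Write an ITR ranking to TSV
#'
#' @param ranking An `itr_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itr_ranking <- function(ranking, path) {
  readr::write_tsv(as_tibble(ranking), path, progress = FALSE)
  invisible(path)
}

#' @export
tidy.itr_ranking <- function(x, ...) {
  out <- as_tibble(x)
  out$condition <- attr(x, "condition") %||% NA_character_
  dplyr::relocate(out, "condition")
}

#' @export
glance.itr_ranking <- function(x, ...) {
  tibble(
    condition = attr(x, "condition") %||% NA_character_,
    n_regulators = nrow(x),
    n_significant_fdr05 = sum(x$fdr_overlap <= 0.05),
    n_activated = sum(x$state == "activated"),
    n_inhibited = sum(x$state == "inhibited"),
    min_p_overlap = min(x$p_overlap)
  )
}

#' Plot the top regulators of a ranking
#'
#' Horizontal bar chart of activation z-scores for the top-N regulators by
#' overlap p-value; indeterminate (undefined-z) regulators are omitted.
#'
#' @param object An `itr_ranking`.
#' @param n Number of top regulators to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itr_ranking <- function(object, n = 20, ...) {
  top <- utils::head(as_tibble(object), n)
  top <- top[!is.na(top$z), , drop = FALSE]
  top$regulator <- factor(top$regulator, levels = rev(top$regulator))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$z, y = .data$regulator,
                                    fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "activation z-score", y = NULL,
      title = paste0("Top regulators: ", attr(object, "condition") %||% "")
    ) +
    ggplot2::theme_minimal()
}
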