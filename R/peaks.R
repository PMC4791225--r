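#' Read ChIP peaks from a BED3+ file
#'
#' @param path BED file (0-based, half-open).
#' @return Tibble `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_peaks_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    df <- as.data.frame(rtracklayer::import(path, format = "BED"))
    tab <- tibble(
      chrom = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,  # back to 0-based half-open
      end = as.integer(df$end)
    )
    if (!is.null(df$name)) tab$name <- df$name
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    tab <- tibble(chrom = raw[[1]], start = as.integer(raw[[2]]),
                  end = as.integer(raw[[3]]))
    if (ncol(raw) >= 4) tab$name <- raw[[4]]
  }
  validate_intervals(tab)
  tab
}

validate_intervals <- function(tab) {
  if (any(tab$start < 0) || any(tab$start >= tab$end)) {
    abort("Malformed interval(s): need 0 <= start < end.")
  }
  invisible(tab)
}

#' Read gene models from a GTF (gene/exon features)
#'
#' @param path GTF file with `gene` and `exon` features carrying a
#'   `gene_id` attribute.
#' @return A gene-model tibble: `gene`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, and `exons` (list-column of `start`/`end`
#'   tibbles).
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GTF requires the rtracklayer package.")
  }
  df <- as.data.frame(rtracklayer::import(path, format = "GTF"))
  tab <- tibble(
    type = as.character(df$type),
    gene = canon_id(df$gene_id),
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
  genes <- tab[tab$type == "gene", , drop = FALSE]
  exons <- tab[tab$type == "exon", , drop = FALSE]
  gene_models(
    genes = genes[, c("gene", "chrom", "start", "end", "strand")],
    exons = exons[, c("gene", "start", "end")]
  )
}

#' Assemble gene models from gene and exon tables
#'
#' Exons are merged per gene where they overlap and must fall inside the
#' gene interval.
#'
#' @param genes Tibble `gene`, `chrom`, `start`, `end`, `strand` (0-based
#'   half-open, strand `+`/`-`).
#' @param exons Tibble `gene`, `start`, `end`.
#' @return Gene-model tibble with an `exons` list-column.
#' @export
gene_models <- function(genes, exons) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  validate_intervals(genes)
  if (nrow(exons) > 0) validate_intervals(exons)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("Gene strand must be '+' or '-'.")
  }
  genes$gene <- canon_id(genes$gene)
  exons$gene <- canon_id(exons$gene)
  merged <- purrr::map(genes$gene, function(g) {
    e <- exons[exons$gene == g, c("start", "end"), drop = FALSE]
    if (nrow(e) == 0) return(tibble(start = integer(), end = integer()))
    gi <- genes[genes$gene == g, , drop = FALSE]
    if (any(e$start < gi$start) || any(e$end > gi$end)) {
      abort(paste0("Exon outside gene interval for ", g, "."))
    }
    e <- e[order(e$start), , drop = FALSE]
    out_start <- e$start[1]; out_end <- e$end[1]
    starts <- integer(); ends <- integer()
    for (i in seq_len(nrow(e))[-1]) {
      if (e$start[i] <= out_end) {
        out_end <- max(out_end, e$end[i])
      } else {
        starts <- c(starts, out_start); ends <- c(ends, out_end)
        out_start <- e$start[i]; out_end <- e$end[i]
      }
    }
    tibble(start = c(starts, out_start), end = c(ends, out_end))
  })
  genes$exons <- merged
  genes
}

#' Classify ChIP peaks by genomic context
#'
#' Assigns each peak, by its midpoint, to one of five mutually exclusive
#' categories with precedence promoter > exon > intron > immediate
#' downstream > distal. Windows are strand-aware: the promoter spans
#' `upstream_bp` before to `downstream_of_tss_bp` past the TSS, and the
#' immediate-downstream window spans `downstream_bp` past the TES. Distal
#' peaks overlapping a supplied enhancer interval are sub-labelled
#' `enhancer`.
#'
#' @param peaks Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene-model tibble ([gene_models()]).
#' @param promoter_window Length-2 numeric: bp upstream and downstream of
#'   the TSS (default `c(2000, 500)`).
#' @param downstream_bp Immediate-downstream window past the TES
#'   (default 2000).
#' @param enhancers Optional tibble `chrom`, `start`, `end` of enhancer
#'   intervals.
#' @return List with `peaks` (input plus `label` and `sublabel` columns) and
#'   `summary` (tibble `category`, `n`, `pct`).
#' @export
classify_peaks <- function(peaks, genes, promoter_window = c(2000, 500),
                           downstream_bp = 2000, enhancers = NULL) {
  peaks <- as_tibble(peaks)
  validate_intervals(peaks)
  stopifnot(length(promoter_window) == 2, all(promoter_window >= 0),
            downstream_bp >= 0)
  shared <- intersect(unique(peaks$chrom), unique(genes$chrom))
  orphan <- sum(!peaks$chrom %in% genes$chrom)
  if (orphan > 0) {
    warn(paste0(orphan, " peak(s) on chromosome(s) absent from the gene ",
                "models; they can only be classified distal."))
  }
  mid <- (peaks$start + peaks$end) / 2

  up <- promoter_window[1]
  down_tss <- promoter_window[2]

  label <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    m <- mid[i]
    cat_i <- "distal"
    if (nrow(g) > 0) {
      plus <- g$strand == "+"
      tss <- ifelse(plus, g$start, g$end)
      tes <- ifelse(plus, g$end, g$start)
      in_promoter <- ifelse(
        plus,
        m >= tss - up & m < tss + down_tss,
        m >= tss - down_tss & m < tss + up
      )
      in_gene <- m >= g$start & m < g$end
      in_exon <- purrr::map2_lgl(g$exons, in_gene, function(e, inside) {
        inside && nrow(e) > 0 && any(m >= e$start & m < e$end)
      })
      in_downstream <- ifelse(
        plus,
        m >= tes & m < tes + downstream_bp,
        m >= tes - downstream_bp & m < tes
      )
      cat_i <- if (any(in_promoter)) "promoter"
      else if (any(in_exon)) "exon"
      else if (any(in_gene)) "intron"
      else if (any(in_downstream)) "immediate_downstream"
      else "distal"
    }
    label[i] <- cat_i
  }

  sublabel <- label
  if (!is.null(enhancers) && nrow(enhancers) > 0) {
    for (i in which(label == "distal")) {
      e <- enhancers[enhancers$chrom == peaks$chrom[i], , drop = FALSE]
      if (nrow(e) > 0 && any(mid[i] >= e$start & mid[i] < e$end)) {
        sublabel[i] <- "enhancer"
      }
    }
  }

  categories <- c("promoter", "exon", "intron", "immediate_downstream", "distal")
  counts <- table(factor(label, levels = categories))
  summary <- tibble(
    category = categories,
    n = as.integer(counts),
    pct = if (nrow(peaks) > 0) 100 * as.integer(counts) / nrow(peaks) else 0
  )
  peaks$label <- label
  peaks$sublabel <- sublabel
  list(peaks = peaks, summary = summary)
}

#' Bar chart of peak genomic-context proportions
#'
#' @param summary The `summary` tibble from [classify_peaks()].
#' @return A ggplot object.
#' @export
plot_peak_context <- function(summary) {
  summary$category <- factor(summary$category, levels = summary$category)
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write per-peak labels as BED
#'
#' @param classified Output of [classify_peaks()].
#' @param path Output BED path (label in the name field).
#' @return `path`, invisibly.
#' @export
write_peak_labels <- function(classified, path) {
  tab <- classified$peaks
  readr::write_tsv(
    tibble(chrom = tab$chrom, start = tab$start, end = tab$end,
           name = tab$sublabel),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
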