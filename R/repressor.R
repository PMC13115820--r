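#' Expression contrast between two samples
#'
#' Computes, over the shared gene universe, the log2 fold change
#' `e_g = log2((E_B + pc) / (E_A + pc))` and the binary downregulation
#' indicator `d_g = 1` when `e_g <= -lfc_threshold`. Expression values
#' are taken as linear-scale quantities (TPM-like); the pseudocount
#' guards zeros.
#'
#' @param expr_a,expr_b Expression tibbles (`gene_id`, `expression`) for
#'   the initial (A) and final (B) sample.
#' @param lfc_threshold Downregulation cutoff on the log2 fold change.
#' @param pseudocount Added to both values before the ratio.
#' @return A tibble with `gene_id`, `expr_a`, `expr_b`, `lfc`, `down`;
#'   the number of shared genes is attached as attribute `n_shared`.
#' @export
expression_contrast <- function(expr_a, expr_b, lfc_threshold = 1,
                                pseudocount = 1) {
  shared <- intersect(expr_a$gene_id, expr_b$gene_id)
  if (length(shared) == 0) abort("no shared genes between the two samples")
  a <- expr_a$expression[match(shared, expr_a$gene_id)]
  b <- expr_b$expression[match(shared, expr_b$gene_id)]
  lfc <- log2((b + pseudocount) / (a + pseudocount))
  out <- tibble(gene_id = shared, expr_a = a, expr_b = b, lfc = lfc,
                down = as.integer(lfc <= -lfc_threshold))
  attr(out, "n_shared") <- length(shared)
  out
}

#' Foreground selection for transition-linked motif analysis
#'
#' Given the indicator `x` of union regions undergoing a transition of
#' interest, the region-level promoter matrix `Q`, and the downregulation
#' indicator `d`, computes the association counts `C = x^T Q` and the
#' foreground set: transitioning regions whose promoters include at least
#' one downregulated gene. When the fraction of target-subtype arrays
#' overlapping any promoter does not exceed `promoter_frac_threshold`,
#' the foreground falls back to all arrays of that subtype to preserve
#' statistical power.
#'
#' @param x Tibble with `region_id` and indicator `x` (0/1).
#' @param q_regions Promoter matrix on regions (rows named by region id).
#' @param d Named 0/1 vector of downregulation indicators over genes.
#' @param subtype_arrays Tibble of the target subtype's arrays in the
#'   final sample, with `array_id`, `region_id` (its union region, or NA)
#'   and `overlaps_promoter` (logical).
#' @param promoter_frac_threshold Promoter-overlap fraction above which
#'   the transition-derived foreground is used (default 0.2).
#' @return A list with `C` (named gene counts), `foreground_arrays`,
#'   `promoter_fraction`, and `fallback`.
#' @export
select_foreground <- function(x, q_regions, d, subtype_arrays,
                              promoter_frac_threshold = 0.2) {
  xv <- setNames(as.numeric(x$x), x$region_id)
  xv <- xv[rownames(q_regions)]
  xv[is.na(xv)] <- 0
  cc <- as.vector(xv %*% q_regions)
  names(cc) <- colnames(q_regions)
  dd <- d[colnames(q_regions)]
  dd[is.na(dd)] <- 0
  fg_region_ids <- rownames(q_regions)[
    xv == 1 & as.vector(q_regions %*% dd) > 0]
  promoter_fraction <- mean(subtype_arrays$overlaps_promoter)
  fallback <- !(promoter_fraction > promoter_frac_threshold)
  fg_arrays <- if (fallback) {
    subtype_arrays$array_id
  } else {
    out <- subtype_arrays$array_id[subtype_arrays$region_id %in% fg_region_ids]
    if (length(out) == 0) {
      warn("foreground is empty: no transitioning region has a downregulated promoter gene")
    }
    out
  }
  list(C = cc, foreground_arrays = fg_arrays,
       promoter_fraction = promoter_fraction, fallback = fallback)
}

# mean occupancy signal from nucleosome calls over [s, e): each call
# contributes its signal over its footprint
nucleosome_signal_mean <- function(nucs, chrom, s, e) {
  if (e <= s) return(0)
  nn <- nucs[nucs$chrom == chrom, ]
  if (nrow(nn) == 0) return(0)
  ov <- overlap_bp(nn$start, nn$end, s, e)
  sum(nn$signal * ov) / (e - s)
}

#' Detect the phasing boundary of an array
#'
#' The phasing boundary is the array edge with the steeper decline in
#' nucleosome occupancy: for each edge the decline is the mean signal
#' over the outermost `probe_bp` inside the array minus the mean over the
#' adjacent `probe_bp` outside. Ties break to the left edge.
#'
#' @param arrays Arrays tibble.
#' @param nucleosomes Full nucleosome call tibble providing the occupancy
#'   signal around each array.
#' @param probe_bp Probe window width (default 200).
#' @return The arrays tibble with a `boundary` column (`"left"`/`"right"`).
#' @export
detect_phasing_boundary <- function(arrays, nucleosomes, probe_bp = 200L) {
  boundary <- vapply(seq_len(nrow(arrays)), function(i) {
    ch <- arrays$chrom[i]
    s <- arrays$start[i]
    e <- arrays$end[i]
    dl <- nucleosome_signal_mean(nucleosomes, ch, s, s + probe_bp) -
      nucleosome_signal_mean(nucleosomes, ch, max(0L, s - probe_bp), s)
    dr <- nucleosome_signal_mean(nucleosomes, ch, e - probe_bp, e) -
      nucleosome_signal_mean(nucleosomes, ch, e, e + probe_bp)
    if (dr > dl) "right" else "left"
  }, character(1))
  mutate(arrays, boundary = boundary)
}

#' Extract linker and boundary-window scan regions for an array
#'
#' Linker regions are the inter-nucleosome gaps inside the array
#' (zero-width gaps skipped, label `"linker"`). Boundary windows are
#' `max_dist / window_bp` contiguous windows of `window_bp` stepping
#' outward from the phasing-boundary edge, labeled by their offset range
#' (e.g. `"boundary_0_200"`). Windows are clipped at chromosome bounds
#' and empty windows dropped.
#'
#' @param array_row One row of an arrays tibble (with its `nucleosomes`
#'   list-column and a `boundary` side).
#' @param window_bp Boundary window width.
#' @param max_dist Maximum distance from the boundary.
#' @param chrom_size Optional chromosome length for clipping.
#' @return A tibble with `array_id`, `label`, `chrom`, `start`, `end`.
#' @export
extract_scan_regions <- function(array_row, window_bp = 200L,
                                 max_dist = 1000L, chrom_size = NULL) {
  nucs <- arrange(array_row$nucleosomes[[1]], .data$start)
  gaps_s <- head(nucs$end, -1)
  gaps_e <- nucs$start[-1]
  keep <- gaps_e > gaps_s
  linkers <- tibble(
    array_id = array_row$array_id, label = "linker",
    chrom = array_row$chrom, start = gaps_s[keep], end = gaps_e[keep]
  )
  side <- array_row$boundary %||% "left"
  n_win <- max_dist %/% window_bp
  offs <- (seq_len(n_win) - 1L) * window_bp
  if (identical(side, "right")) {
    ws <- array_row$end + offs
    we <- ws + window_bp
  } else {
    we <- array_row$start - offs
    ws <- we - window_bp
  }
  windows <- tibble(
    array_id = array_row$array_id,
    label = sprintf("boundary_%d_%d", offs, offs + window_bp),
    chrom = array_row$chrom,
    start = pmax(0L, as.integer(ws)),
    end = as.integer(we)
  )
  if (!is.null(chrom_size)) windows$end <- pmin(windows$end, as.integer(chrom_size))
  windows <- filter(windows, .data$end > .data$start)
  out <- bind_rows(linkers, windows)
  mutate(out, region_id = sprintf("%s_%s_%d", .data$array_id, .data$label,
                                  dplyr::row_number()))
}

#' Subtype-level Repressive Efficacy (RE)
#'
#' For each subtype c, genes are split into those whose promoters contain
#' only subtype-c arrays and those whose promoters contain no well-phased
#' arrays at all. The effect size is the difference of median expression
#' (exclusive minus absent); significance is a one-sided Wilcoxon
#' rank-sum test (exclusive group lower). `RE = |delta| * (-log10 p)`
#' when delta is negative and 0 otherwise; RE is undefined (NA) when
#' either group is empty.
#'
#' @param expr Expression tibble (`gene_id`, `expression`) for the sample.
#' @param q_arrays Binary promoter matrix on arrays (rows = array ids,
#'   columns = gene ids) from [build_promoter_matrix()].
#' @param subtype_labels Tibble with `array_id`, `subtype`.
#' @return A tibble with one row per subtype: `subtype`, `delta`,
#'   `p_expr`, `re`, `n_only`, `n_absent`.
#' @export
repressive_efficacy <- function(expr, q_arrays, subtype_labels) {
  subtypes <- sort(unique(subtype_labels$subtype))
  genes <- intersect(colnames(q_arrays), expr$gene_id)
  q <- q_arrays[, genes, drop = FALSE]
  e_val <- setNames(expr$expression, expr$gene_id)[genes]
  lab <- setNames(subtype_labels$subtype, subtype_labels$array_id)
  lab <- lab[rownames(q)]
  covered <- colSums(q) > 0
  absent_genes <- genes[!covered]
  rows <- map(subtypes, function(cc) {
    in_c <- colSums(q[lab == cc, , drop = FALSE]) > 0
    in_other <- colSums(q[lab != cc, , drop = FALSE]) > 0
    only_genes <- genes[in_c & !in_other]
    if (length(only_genes) == 0 || length(absent_genes) == 0) {
      inform(sprintf("RE undefined for subtype %s (empty group)", cc))
      return(tibble(subtype = cc, delta = NA_real_, p_expr = NA_real_,
                    re = NA_real_, n_only = length(only_genes),
                    n_absent = length(absent_genes)))
    }
    e_only <- e_val[only_genes]
    e_absent <- e_val[absent_genes]
    delta <- median(e_only) - median(e_absent)
    p <- rank_sum_p_less(e_only, e_absent)
    re <- if (delta < 0) abs(delta) * (-log10(p)) else 0
    tibble(subtype = cc, delta = delta, p_expr = p, re = re,
           n_only = length(only_genes), n_absent = length(absent_genes))
  })
  bind_rows(rows)
}

#' Motif Potential (MP) per TF
#'
#' The maximum `-log10(adjusted p)` across window labels. By default the
#' linker label is pooled with the boundary windows; set
#' `include_linker = FALSE` to restrict the maximum to boundary windows.
#'
#' @param enrichment Enrichment tibble from [motif_enrichment()].
#' @param include_linker Include the linker label in the maximum.
#' @return A tibble with `tf`, `mp`, and `best_label`.
#' @export
motif_potential <- function(enrichment, include_linker = TRUE) {
  keep <- if (include_linker) enrichment else
    filter(enrichment, .data$label != "linker")
  if (nrow(keep) == 0) {
    return(tibble(tf = character(), mp = numeric(), best_label = character()))
  }
  keep |>
    group_by(.data$tf) |>
    arrange(.data$p_adj, .by_group = TRUE) |>
    summarise(mp = -log10(.data$p_adj[1]), best_label = .data$label[1],
              .groups = "drop")
}

#' Combine RE and MP into ranked repressor predictions
#'
#' For every (sample, subtype, TF): `RPS = RE * MP`; the candidate flag
#' requires `RE > 0` and `MP > -log10(alpha)`; the specificity score is
#' the TF's MP in the subtype minus its best MP in any other subtype of
#' the same sample (missing MPs count as 0). Rows are sorted by RPS
#' within subtype.
#'
#' @param re_tbl Tibble with `sample_id`, `subtype`, `re`.
#' @param mp_tbl Tibble with `sample_id`, `subtype`, `tf`, `mp`.
#' @param alpha Significance threshold for the candidate flag.
#' @return A tibble with `sample_id`, `subtype`, `tf`, `re`, `mp`, `rps`,
#'   `s_score`, `candidate`.
#' @export
score_and_rank <- function(re_tbl, mp_tbl, alpha = 0.05) {
  grid <- tidyr::expand_grid(
    dplyr::distinct(re_tbl[, c("sample_id", "subtype")]),
    tf = unique(mp_tbl$tf)
  )
  full <- grid |>
    left_join(mp_tbl, by = c("sample_id", "subtype", "tf")) |>
    mutate(mp = dplyr::coalesce(.data$mp, 0)) |>
    left_join(re_tbl[, c("sample_id", "subtype", "re")],
              by = c("sample_id", "subtype"))
  full <- full |>
    group_by(.data$sample_id, .data$tf) |>
    mutate(s_score = {
      m <- .data$mp
      vapply(seq_along(m), function(i) {
        m[i] - if (length(m) > 1) max(m[-i]) else 0
      }, numeric(1))
    }) |>
    ungroup() |>
    mutate(
      rps = .data$re * .data$mp,
      candidate = !is.na(.data$re) & .data$re > 0 & .data$mp > -log10(alpha)
    ) |>
    arrange(.data$sample_id, .data$subtype, desc(.data$rps)) |>
    select("sample_id", "subtype", "tf", "re", "mp", "rps", "s_score",
           "candidate")
  full
}
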