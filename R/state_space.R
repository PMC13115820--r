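#' Build cross-sample union regions from per-sample arrays
#'
#' Pools arrays from all samples, links two arrays on the same chromosome
#' when their overlap is at least `min_overlap` of the shorter array, and
#' turns connected components into union regions spanning the coordinate
#' union of their members. When a sample contributes more than one array
#' to a component, the array with the greatest overlap with the union
#' interval is kept as that sample's member (ties favor the longer array)
#' and the others are detached into their own regions.
#'
#' @param array_sets Either a named list of arrays tibbles (one per
#'   sample) or a single tibble with a `sample_id` column.
#' @param min_overlap Minimum overlap as a fraction of the shorter array.
#' @return A tibble with `region_id`, `chrom`, `start`, `end` and a
#'   `members` list-column of `(sample_id, array_id)` tibbles.
#' @export
build_union_regions <- function(array_sets, min_overlap = 0.5) {
  if (is.data.frame(array_sets)) {
    stop_missing_cols(array_sets, c("sample_id", "array_id", "chrom", "start", "end"),
                      "pooled array table")
    pooled <- as_tibble(array_sets[, c("sample_id", "array_id", "chrom", "start", "end")])
  } else {
    pooled <- bind_rows(imap(array_sets, function(a, s) {
      tibble(sample_id = s, array_id = a$array_id, chrom = a$chrom,
             start = a$start, end = a$end)
    }))
  }
  pooled <- arrange(pooled, .data$chrom, .data$start, .data$end, .data$sample_id)
  n <- nrow(pooled)
  if (n == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), members = list()))
  }
  # union-find over pooled arrays
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  idx_by_chrom <- split(seq_len(n), pooled$chrom)
  for (idx in idx_by_chrom) {
    starts <- pooled$start[idx]; ends <- pooled$end[idx]
    lens <- ends - starts
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && starts[b] < ends[a]) {
        ov <- min(ends[a], ends[b]) - starts[b] # sorted: starts[b] >= starts[a]
        if (ov > 0 && ov >= min_overlap * min(lens[a], lens[b])) {
          unite(idx[a], idx[b])
        }
        b <- b + 1L
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  regions <- list()
  for (members in split(seq_len(n), comp)) {
    m <- pooled[members, ]
    u_start <- min(m$start); u_end <- max(m$end)
    # one member per sample: keep greatest overlap with the union interval
    keep <- m |>
      mutate(ov = overlap_bp(.data$start, .data$end, u_start, u_end),
             len = .data$end - .data$start) |>
      group_by(.data$sample_id) |>
      arrange(desc(.data$ov), desc(.data$len), .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
    detached <- dplyr::anti_join(m, keep[, c("sample_id", "array_id")],
                                 by = c("sample_id", "array_id"))
    regions[[length(regions) + 1L]] <- tibble(
      chrom = m$chrom[1], start = u_start, end = u_end,
      members = list(keep[, c("sample_id", "array_id")])
    )
    for (i in seq_len(nrow(detached))) {
      regions[[length(regions) + 1L]] <- tibble(
        chrom = detached$chrom[i], start = detached$start[i],
        end = detached$end[i],
        members = list(detached[i, c("sample_id", "array_id")])
      )
    }
  }
  out <- bind_rows(regions) |> arrange(.data$chrom, .data$start, .data$end)
  out$region_id <- sprintf("ur_%04d", seq_len(nrow(out)))
  select(out, "region_id", dplyr::everything())
}

#' Encode per-sample region states
#'
#' The state of a union region in a sample is the accessibility subtype of
#' that sample's member array, or `"None"` when the sample has no member.
#'
#' @param regions Union regions from [build_union_regions()].
#' @param subtype_labels Tibble with `sample_id`, `array_id`, `subtype`.
#' @param samples Character vector of sample ids to encode (defaults to
#'   all samples present in `subtype_labels`).
#' @return A long tibble with `region_id`, `sample_id`, `state`.
#' @export
encode_states <- function(regions, subtype_labels, samples = NULL) {
  stop_missing_cols(subtype_labels, c("sample_id", "array_id", "subtype"),
                    "subtype labels")
  samples <- samples %||% unique(subtype_labels$sample_id)
  membership <- bind_rows(map2(regions$region_id, regions$members,
                               function(rid, m) mutate(m, region_id = rid)))
  labeled <- left_join(membership, subtype_labels,
                       by = c("sample_id", "array_id"))
  missing <- labeled$array_id[is.na(labeled$subtype)]
  if (length(missing) > 0) {
    abort(sprintf("member array without subtype label: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(region_id = regions$region_id,
                             sample_id = samples)
  grid |>
    left_join(labeled[, c("region_id", "sample_id", "subtype")],
              by = c("region_id", "sample_id")) |>
    mutate(state = dplyr::coalesce(.data$subtype, "None")) |>
    select("region_id", "sample_id", "state")
}

#' Cross-sample state transition matrix
#'
#' Counts, over the shared union-region universe, the number of regions
#' in state `i` in sample A and state `j` in sample B. The state order is
#' fixed as `None, C1, ..., Ck`.
#'
#' @param states Long state tibble from [encode_states()] (or a pair of
#'   named vectors via `state_a`/`state_b`).
#' @param sample_a,sample_b The initial (rows) and final (columns) sample.
#' @param levels Optional explicit state levels; derived from the data
#'   when `NULL`.
#' @return A `(k+1) x (k+1)` integer matrix with dimnames.
#' @export
transition_matrix <- function(states, sample_a, sample_b, levels = NULL) {
  a <- filter(states, .data$sample_id == sample_a)
  b <- filter(states, .data$sample_id == sample_b)
  if (!setequal(a$region_id, b$region_id) || nrow(a) != nrow(b)) {
    abort("samples A and B must cover the identical region universe")
  }
  b <- b[match(a$region_id, b$region_id), ]
  if (is.null(levels)) {
    ks <- sort(setdiff(unique(c(a$state, b$state)), "None"))
    levels <- c("None", ks)
  }
  table(
    factor(a$state, levels = levels),
    factor(b$state, levels = levels),
    dnn = c(sample_a, sample_b)
  ) |> unclass()
}

#' Binary promoter annotation matrix Q
#'
#' `Q[i, g] = 1` when item `i` (an array or union region) overlaps the
#' promoter of gene `g` by at least 1 bp.
#'
#' @param items Tibble with an id column (`array_id` or `region_id`) plus
#'   `chrom`, `start`, `end`.
#' @param promoters Promoter tibble from [promoters_from_genes()].
#' @param id_col Name of the id column (auto-detected by default).
#' @return An integer matrix, rows = items, columns = genes.
#' @export
build_promoter_matrix <- function(items, promoters, id_col = NULL) {
  id_col <- id_col %||% intersect(c("array_id", "region_id"), names(items))[1]
  if (is.na(id_col)) abort("no array_id/region_id column in items")
  genes <- unique(promoters$gene_id)
  q <- matrix(0L, nrow = nrow(items), ncol = length(genes),
              dimnames = list(items[[id_col]], genes))
  if (nrow(items) == 0 || nrow(promoters) == 0) return(q)
  hits <- GenomicRanges::findOverlaps(gr_from_tbl(items), gr_from_tbl(promoters))
  if (length(hits) > 0) {
    q[cbind(S4Vectors::queryHits(hits),
            match(promoters$gene_id[S4Vectors::subjectHits(hits)], genes))] <- 1L
  }
  q
}

#' Annotate arrays by genomic context
#'
#' Assigns each array a category with precedence promoter > genic >
#' distal, plus the strand-signed distance from the array midpoint to the
#' nearest TSS (negative = upstream of the gene).
#'
#' @param arrays Arrays tibble.
#' @param genes Gene models from [read_gene_models()].
#' @param promoters Promoters from [promoters_from_genes()].
#' @return The arrays tibble with `annotation` and `tss_distance` added.
#' @export
annotate_arrays <- function(arrays, genes, promoters) {
  if (nrow(arrays) == 0) {
    return(mutate(arrays, annotation = character(0), tss_distance = numeric(0)))
  }
  arr_gr <- gr_from_tbl(arrays)
  in_prom <- rep(FALSE, nrow(arrays))
  if (nrow(promoters) > 0) {
    in_prom <- IRanges::overlapsAny(arr_gr, gr_from_tbl(promoters))
  }
  in_gene <- rep(FALSE, nrow(arrays))
  if (nrow(genes) > 0) {
    in_gene <- IRanges::overlapsAny(arr_gr, gr_from_tbl(genes))
  }
  mid <- midpoint(arrays$start, arrays$end)
  tss_distance <- rep(NA_real_, nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    g <- genes[genes$chrom == arrays$chrom[i], ]
    if (nrow(g) == 0) next
    dd <- mid[i] - g$tss
    j <- which.min(abs(dd))
    tss_distance[i] <- dd[j] * ifelse(g$strand[j] == "-", -1, 1)
  }
  mutate(arrays,
         annotation = dplyr::case_when(in_prom ~ "promoter",
                                       in_gene ~ "genic",
                                       TRUE ~ "distal"),
         tss_distance = tss_distance)
}

#' Relative position of arrays within repressive domains
#'
#' Each array is assigned to the domain it overlaps most; its relative
#' position is the array midpoint scaled to `[0, 1]` between the domain
#' boundaries (clipped for partial overlaps). Arrays overlapping no
#' domain get `NA`.
#'
#' @param arrays Arrays tibble.
#' @param domains Domain interval tibble.
#' @return Numeric vector of relative positions, one per array.
#' @export
relative_domain_position <- function(arrays, domains) {
  if (nrow(arrays) == 0) return(numeric(0))
  out <- rep(NA_real_, nrow(arrays))
  if (nrow(domains) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(gr_from_tbl(arrays), gr_from_tbl(domains))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- overlap_bp(arrays$start[qh], arrays$end[qh],
                   domains$start[sh], domains$end[sh])
  best <- tibble(qh = qh, sh = sh, ov = ov) |>
    group_by(.data$qh) |>
    arrange(desc(.data$ov), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  mid <- midpoint(arrays$start[best$qh], arrays$end[best$qh])
  rel <- (mid - domains$start[best$sh]) /
    (domains$end[best$sh] - domains$start[best$sh])
  out[best$qh] <- pmin(1, pmax(0, rel))
  out
}
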