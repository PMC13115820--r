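#' Phasing criteria for well-phased nucleosome array detection
#'
#' Bundles the filtering thresholds applied to candidate arrays: the
#' admissible inter-nucleosome spacing range and its coefficient of
#' variation, percentile-based occupancy-signal floors and fuzziness
#' ceiling (computed genome-wide by [compute_thresholds()]), the window
#' size, the merge gap for the sliding algorithm, the relaxation factor
#' and failure limit for seed-and-extend, and the minimum repressive-domain
#' overlap fraction.
#'
#' @param spacing_min,spacing_max Admissible summit-to-summit spacing (bp).
#' @param cv_max Maximum coefficient of variation of spacings (population
#'   SD over mean).
#' @param mean_signal_pct,min_signal_pct Genome-wide signal percentiles the
#'   window mean and minimum must exceed.
#' @param fuzziness_pct Genome-wide fuzziness percentile the window maximum
#'   must stay below.
#' @param window_k Number of consecutive nucleosomes per evaluation window.
#' @param merge_gap Maximum gap (bp) between passing window spans merged by
#'   the sliding algorithm.
#' @param relax_factor Relaxation applied to every criterion during
#'   seed-and-extend extension (always in the loosening direction).
#' @param max_fail Consecutive extension failures after which a side closes.
#' @param domain_overlap_frac Minimum fraction of array length overlapping
#'   repressive domains.
#' @param spacing_on_mean If `TRUE`, the spacing range is checked on the
#'   mean spacing instead of each spacing.
#' @return An object of class `phasing_criteria`.
#' @export
phasing_criteria <- function(spacing_min = 160, spacing_max = 220,
                             cv_max = 0.15, mean_signal_pct = 30,
                             min_signal_pct = 20, fuzziness_pct = 20,
                             window_k = 3L, merge_gap = 200L,
                             relax_factor = 1.2, max_fail = 2L,
                             domain_overlap_frac = 0.3,
                             spacing_on_mean = FALSE) {
  stopifnot(
    spacing_min > 0, spacing_min < spacing_max, cv_max > 0,
    mean_signal_pct > 0, mean_signal_pct < 100,
    min_signal_pct > 0, min_signal_pct < 100,
    fuzziness_pct > 0, fuzziness_pct < 100,
    window_k >= 2, merge_gap >= 0, relax_factor >= 1, max_fail >= 1,
    domain_overlap_frac >= 0, domain_overlap_frac <= 1
  )
  structure(
    list(
      spacing_min = spacing_min, spacing_max = spacing_max, cv_max = cv_max,
      mean_signal_pct = mean_signal_pct, min_signal_pct = min_signal_pct,
      fuzziness_pct = fuzziness_pct, window_k = as.integer(window_k),
      merge_gap = as.integer(merge_gap), relax_factor = relax_factor,
      max_fail = as.integer(max_fail),
      domain_overlap_frac = domain_overlap_frac,
      spacing_on_mean = spacing_on_mean
    ),
    class = "phasing_criteria"
  )
}

#' Filter fragments by median-absolute-deviation length thresholds
#'
#' Removes extreme fragment-length outliers: a fragment is kept when its
#' length lies within `n_mads` scaled MADs (constant 1.4826) of the
#' median length. When the MAD is zero (near-constant lengths) all
#' fragments are kept with a warning.
#'
#' @param fragments Fragment tibble from [read_fragments()].
#' @param n_mads Number of scaled MADs defining the keep window.
#' @return The filtered fragment tibble.
#' @export
mad_filter_fragments <- function(fragments, n_mads = 3) {
  if (nrow(fragments) == 0) abort("no fragments to filter")
  med <- median(fragments$length)
  smad <- stats::mad(fragments$length) # 1.4826-scaled by default
  if (smad == 0) {
    warn("fragment-length MAD is zero; keeping all fragments")
    return(fragments)
  }
  fragments[abs(fragments$length - med) <= n_mads * smad, ]
}

#' Genome-wide signal thresholds for phasing criteria
#'
#' Computes the occupancy-signal floors and fuzziness ceiling from the
#' full (genome-wide) nucleosome set using linear-interpolation
#' percentiles. These must be computed once on the complete input, never
#' on a subset.
#'
#' @param nucleosomes The full nucleosome call tibble.
#' @param criteria A [phasing_criteria()] object.
#' @return A list with `mean_signal_floor`, `min_signal_floor`,
#'   `fuzziness_ceiling`.
#' @export
compute_thresholds <- function(nucleosomes, criteria = phasing_criteria()) {
  if (nrow(nucleosomes) < 2) {
    abort("at least 2 nucleosomes are required to compute thresholds")
  }
  list(
    mean_signal_floor = pctl(nucleosomes$signal, criteria$mean_signal_pct),
    min_signal_floor = pctl(nucleosomes$signal, criteria$min_signal_pct),
    fuzziness_ceiling = pctl(nucleosomes$fuzziness, criteria$fuzziness_pct)
  )
}

# scalar evaluator on plain vectors (sorted by summit); returns the full
# verdict list used by both finder algorithms and evaluate_window()
eval_run <- function(summit, signal, fuzziness, criteria, thresholds) {
  spacings <- diff(summit)
  cv <- spacing_cv(spacings)
  spacing_ok <- if (criteria$spacing_on_mean) {
    mean(spacings) >= criteria$spacing_min && mean(spacings) <= criteria$spacing_max
  } else {
    all(spacings >= criteria$spacing_min & spacings <= criteria$spacing_max)
  }
  checks <- c(
    spacing_range = spacing_ok,
    spacing_cv = cv < criteria$cv_max,
    mean_signal = mean(signal) > thresholds$mean_signal_floor,
    min_signal = min(signal) > thresholds$min_signal_floor,
    fuzziness = max(fuzziness) < thresholds$fuzziness_ceiling
  )
  list(
    pass = all(checks), checks = checks,
    spacings = spacings, mean_spacing = mean(spacings), spacing_cv = cv,
    mean_signal = mean(signal), min_signal = min(signal),
    max_fuzziness = max(fuzziness)
  )
}

#' Evaluate a window of consecutive nucleosomes against phasing criteria
#'
#' A window passes when every summit-to-summit spacing lies in the
#' admissible range, the coefficient of variation of spacings (population
#' SD / mean; defined as 0 for a single spacing) is below `cv_max`, the
#' mean and minimum occupancy signals exceed their floors, and the maximum
#' fuzziness stays below its ceiling.
#'
#' @param nucs A tibble of at least 2 nucleosomes sorted by summit.
#' @param criteria A [phasing_criteria()] object.
#' @param thresholds Output of [compute_thresholds()].
#' @return A list with `pass` (logical), per-criterion `checks`, and the
#'   window statistics.
#' @export
evaluate_window <- function(nucs, criteria, thresholds) {
  if (nrow(nucs) < 2) abort("a window needs at least 2 nucleosomes")
  if (is.unsorted(nucs$summit)) nucs <- arrange(nucs, .data$summit)
  eval_run(nucs$summit, nucs$signal, nucs$fuzziness, criteria, thresholds)
}

make_array_row <- function(nucs_sub, method) {
  nucs_sub <- arrange(nucs_sub, .data$summit)
  spacings <- diff(nucs_sub$summit)
  tibble(
    chrom = nucs_sub$chrom[1],
    start = min(nucs_sub$start),
    end = max(nucs_sub$end),
    n_nucleosomes = nrow(nucs_sub),
    mean_spacing = mean(spacings),
    spacing_cv = spacing_cv(spacings),
    mean_signal = mean(nucs_sub$signal),
    min_signal = min(nucs_sub$signal),
    max_fuzziness = max(nucs_sub$fuzziness),
    method = method,
    nucleosomes = list(nucs_sub)
  )
}

finish_arrays <- function(rows) {
  if (length(rows) == 0 || (is.data.frame(rows) && nrow(rows) == 0)) {
    return(tibble(
      array_id = character(), chrom = character(), start = integer(),
      end = integer(), n_nucleosomes = integer(), mean_spacing = numeric(),
      spacing_cv = numeric(), mean_signal = numeric(), min_signal = numeric(),
      max_fuzziness = numeric(), method = character(), nucleosomes = list()
    ))
  }
  out <- if (is.data.frame(rows)) rows else bind_rows(rows)
  out <- arrange(out, .data$chrom, .data$start)
  out$array_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  select(out, "array_id", dplyr::everything())
}

window_pass_vector <- function(summit, signal, fuzziness, k, criteria, thresholds) {
  n <- length(summit)
  n_win <- n - k + 1L
  if (n_win < 1) return(logical(0))
  vapply(seq_len(n_win), function(i) {
    idx <- i:(i + k - 1L)
    eval_run(summit[idx], signal[idx], fuzziness[idx], criteria, thresholds)$pass
  }, logical(1))
}

#' Find well-phased arrays by sliding-window merging
#'
#' Evaluates every window of `window_k` consecutive nucleosomes, merges
#' passing windows whose genomic spans overlap or lie within `merge_gap`
#' of each other into candidate arrays spanning all nucleosomes between
#' the first and last merged window, and re-applies the full criteria to
#' each merged candidate (locally compliant windows need not retain their
#' phasing properties at array scale).
#'
#' @inheritParams compute_thresholds
#' @param thresholds Output of [compute_thresholds()] on the full input.
#' @return An arrays tibble (one row per array, nucleosomes as a
#'   list-column).
#' @export
find_arrays_sliding <- function(nucleosomes, criteria = phasing_criteria(),
                                thresholds = compute_thresholds(nucleosomes, criteria)) {
  nucleosomes <- arrange(nucleosomes, .data$chrom, .data$summit)
  k <- criteria$window_k
  rows <- list()
  for (chr_nucs in split(nucleosomes, nucleosomes$chrom)) {
    n <- nrow(chr_nucs)
    if (n < k) next
    pass <- window_pass_vector(chr_nucs$summit, chr_nucs$signal,
                               chr_nucs$fuzziness, k, criteria, thresholds)
    if (!any(pass)) next
    # blocks of consecutive passing window indices -> nucleosome runs
    p_idx <- which(pass)
    block_id <- cumsum(c(1L, diff(p_idx) != 1L))
    runs <- lapply(split(p_idx, block_id), function(w) {
      c(first = w[1], last = w[length(w)] + k - 1L)
    })
    # merge runs whose genomic spans overlap or fall within merge_gap
    spans <- lapply(runs, function(r) {
      idx <- r[["first"]]:r[["last"]]
      c(min(chr_nucs$start[idx]), max(chr_nucs$end[idx]))
    })
    merged <- list(runs[[1]])
    merged_span <- list(spans[[1]])
    if (length(runs) > 1) {
      for (i in 2:length(runs)) {
        last <- length(merged)
        if (spans[[i]][1] - merged_span[[last]][2] <= criteria$merge_gap) {
          merged[[last]] <- c(first = merged[[last]][["first"]],
                              last = runs[[i]][["last"]])
          merged_span[[last]] <- c(merged_span[[last]][1],
                                   max(merged_span[[last]][2], spans[[i]][2]))
        } else {
          merged[[length(merged) + 1L]] <- runs[[i]]
          merged_span[[length(merged_span) + 1L]] <- spans[[i]]
        }
      }
    }
    for (r in merged) {
      idx <- r[["first"]]:r[["last"]]
      verdict <- eval_run(chr_nucs$summit[idx], chr_nucs$signal[idx],
                          chr_nucs$fuzziness[idx], criteria, thresholds)
      if (verdict$pass) {
        rows[[length(rows) + 1L]] <- make_array_row(chr_nucs[idx, ], "sliding")
      }
    }
  }
  finish_arrays(rows)
}

relax_criteria <- function(criteria) {
  f <- criteria$relax_factor
  mid <- (criteria$spacing_min + criteria$spacing_max) / 2
  half <- (criteria$spacing_max - criteria$spacing_min) / 2
  out <- criteria
  out$spacing_min <- mid - half * f
  out$spacing_max <- mid + half * f
  out$cv_max <- criteria$cv_max * f
  out
}

relax_thresholds <- function(thresholds, factor) {
  list(
    mean_signal_floor = thresholds$mean_signal_floor / factor,
    min_signal_floor = thresholds$min_signal_floor / factor,
    fuzziness_ceiling = thresholds$fuzziness_ceiling * factor
  )
}

#' Find well-phased arrays by seed-and-extend
#'
#' Non-overlapping passing windows of `window_k` nucleosomes (greedy,
#' left-to-right) serve as high-confidence seeds. Each seed is extended by
#' one nucleosome at a time: both flanking candidates are provisionally
#' added, and the side yielding the greater improvement in array quality
#' (lower spacing CV, ties broken by higher mean signal, then left) is
#' accepted provided the extended array passes the relaxed criteria
#' (every criterion loosened by `relax_factor`). A rejected candidate is
#' consumed and counts one consecutive failure; a side closes after
#' `max_fail` consecutive failures. Final arrays are re-checked against
#' the unrelaxed criteria, reverting extensions (most recent first) until
#' the array passes.
#'
#' @inheritParams find_arrays_sliding
#' @return An arrays tibble.
#' @export
find_arrays_seed_extend <- function(nucleosomes, criteria = phasing_criteria(),
                                    thresholds = compute_thresholds(nucleosomes, criteria)) {
  nucleosomes <- arrange(nucleosomes, .data$chrom, .data$summit)
  k <- criteria$window_k
  relaxed_c <- relax_criteria(criteria)
  relaxed_t <- relax_thresholds(thresholds, criteria$relax_factor)
  rows <- list()
  for (chr_nucs in split(nucleosomes, nucleosomes$chrom)) {
    n <- nrow(chr_nucs)
    if (n < k) next
    summit <- chr_nucs$summit
    signal <- chr_nucs$signal
    fuzz <- chr_nucs$fuzziness
    pass <- window_pass_vector(summit, signal, fuzz, k, criteria, thresholds)
    used <- rep(FALSE, n)
    seeds <- list()
    for (i in seq_along(pass)) {
      idx <- i:(i + k - 1L)
      if (pass[i] && !any(used[idx])) {
        seeds[[length(seeds) + 1L]] <- idx
        used[idx] <- TRUE
      }
    }
    for (seed in seeds) {
      members <- seed
      accepted <- integer(0) # extension acceptance order
      lp <- seed[1] - 1L     # next left candidate
      rp <- seed[length(seed)] + 1L
      fail_l <- 0L
      fail_r <- 0L
      open_l <- lp >= 1L
      open_r <- rp <= n
      cur <- eval_run(summit[members], signal[members], fuzz[members],
                      criteria, thresholds)
      quality <- -cur$spacing_cv
      while (open_l || open_r) {
        cand <- list()
        if (open_l) {
          ml <- sort(c(lp, members))
          vl <- eval_run(summit[ml], signal[ml], fuzz[ml], relaxed_c, relaxed_t)
          cand$left <- list(members = ml, verdict = vl, idx = lp)
        }
        if (open_r) {
          mr <- sort(c(members, rp))
          vr <- eval_run(summit[mr], signal[mr], fuzz[mr], relaxed_c, relaxed_t)
          cand$right <- list(members = mr, verdict = vr, idx = rp)
        }
        ok <- names(cand)[vapply(cand, function(c) c$verdict$pass, logical(1))]
        # failures: candidates not passing relaxed criteria are consumed
        for (side in setdiff(names(cand), ok)) {
          if (side == "left") {
            fail_l <- fail_l + 1L
            lp <- lp - 1L
            open_l <- fail_l < criteria$max_fail && lp >= 1L
          } else {
            fail_r <- fail_r + 1L
            rp <- rp + 1L
            open_r <- fail_r < criteria$max_fail && rp <= n
          }
        }
        if (length(ok) == 0) next
        pick <- if (length(ok) == 1) ok else {
          dq <- vapply(cand[ok], function(c) -c$verdict$spacing_cv - quality,
                       numeric(1))
          if (abs(dq[1] - dq[2]) > 1e-12) ok[which.max(dq)] else {
            ms <- vapply(cand[ok], function(c) c$verdict$mean_signal, numeric(1))
            if (abs(ms[1] - ms[2]) > 1e-12) ok[which.max(ms)] else "left"
          }
        }
        chosen <- cand[[pick]]
        members <- chosen$members
        accepted <- c(accepted, chosen$idx)
        quality <- -chosen$verdict$spacing_cv
        if (pick == "left") {
          fail_l <- 0L
          lp <- lp - 1L
          open_l <- lp >= 1L
        } else {
          fail_r <- 0L
          rp <- rp + 1L
          open_r <- rp <= n
        }
      }
      # re-check against unrelaxed criteria; revert extensions until passing
      repeat {
        v <- eval_run(summit[members], signal[members], fuzz[members],
                      criteria, thresholds)
        if (v$pass || length(accepted) == 0) break
        members <- setdiff(members, accepted[length(accepted)])
        accepted <- accepted[-length(accepted)]
      }
      rows[[length(rows) + 1L]] <- make_array_row(chr_nucs[sort(members), ],
                                                  "seed_extend")
    }
  }
  finish_arrays(rows)
}

#' Keep arrays sufficiently covered by repressive domains
#'
#' An array is retained when the total base pairs it shares with the
#' (merged) domain intervals amount to at least `min_frac` of its length.
#'
#' @param arrays Arrays tibble.
#' @param domains Tibble of domain intervals (`chrom`, `start`, `end`).
#' @param min_frac Minimum overlap fraction of the array length.
#' @return The filtered arrays tibble.
#' @export
filter_by_domain_overlap <- function(arrays, domains, min_frac = 0.3) {
  if (nrow(arrays) == 0) return(arrays)
  if (nrow(domains) == 0) return(arrays[0, ])
  dom_gr <- GenomicRanges::reduce(gr_from_tbl(domains))
  arr_gr <- gr_from_tbl(arrays)
  hits <- GenomicRanges::findOverlaps(arr_gr, dom_gr)
  ov_bp <- rep(0, nrow(arrays))
  if (length(hits) > 0) {
    widths <- IRanges::width(IRanges::pintersect(
      arr_gr[S4Vectors::queryHits(hits)], dom_gr[S4Vectors::subjectHits(hits)]
    ))
    ov_bp <- as.numeric(tapply(widths, factor(S4Vectors::queryHits(hits),
                                              levels = seq_len(nrow(arrays))),
                               sum, default = 0))
    ov_bp[is.na(ov_bp)] <- 0
  }
  arrays[ov_bp / (arrays$end - arrays$start) >= min_frac, ]
}

#' Deduplicate and merge arrays by genomic coordinates
#'
#' Arrays with identical coordinates collapse to one; overlapping arrays
#' on the same chromosome merge into a single array containing the union
#' of their nucleosomes, with all statistics recomputed. Every nucleosome
#' appears in at most one final array.
#'
#' @param arrays Arrays tibble (possibly pooled from both algorithms).
#' @return A merged arrays tibble.
#' @export
dedup_merge <- function(arrays) {
  if (nrow(arrays) == 0) return(arrays)
  arrays <- arrange(arrays, .data$chrom, .data$start, .data$end)
  arrays <- distinct(arrays, .data$chrom, .data$start, .data$end,
                     .keep_all = TRUE)
  rows <- list()
  for (chr_arr in split(arrays, arrays$chrom)) {
    n_arr <- nrow(chr_arr)
    group <- if (n_arr == 1) 1L else {
      cm <- cummax(chr_arr$end)
      cumsum(c(1L, chr_arr$start[-1] >= cm[-n_arr]))
    }
    for (g in split(chr_arr, group)) {
      if (nrow(g) == 1) {
        rows[[length(rows) + 1L]] <- select(g, -"array_id")
      } else {
        nucs <- distinct(bind_rows(g$nucleosomes),
                         .data$chrom, .data$summit, .keep_all = TRUE)
        rows[[length(rows) + 1L]] <- make_array_row(nucs, g$method[1])
      }
    }
  }
  finish_arrays(rows)
}

#' Find well-phased nucleosome arrays inside repressive domains
#'
#' End-to-end array detection: sorts the input, computes genome-wide
#' thresholds, runs the selected algorithm (seed-and-extend by default),
#' applies the repressive-domain overlap filter when domains are given,
#' and deduplicates/merges the result.
#'
#' @param nucleosomes Nucleosome call tibble
#'   (see [read_nucleosome_table()]).
#' @param criteria A [phasing_criteria()] object.
#' @param domains Optional tibble of repressive-domain intervals.
#' @param method `"seed_extend"` (default) or `"sliding"`.
#' @param thresholds Optional precomputed [compute_thresholds()] output;
#'   computed from the full input when `NULL`.
#' @return An arrays tibble with one row per well-phased array.
#' @examples
#' nucs <- tibble::tibble(
#'   chrom = "chr1",
#'   summit = as.integer(seq(1000, by = 180, length.out = 6)),
#'   signal = 30, fuzziness = 20
#' )
#' nucs$start <- nucs$summit - 73L
#' nucs$end <- nucs$summit + 74L
#' bg <- tibble::tibble(
#'   chrom = "chr1", summit = as.integer(seq(10000, by = 700, length.out = 40)),
#'   signal = 10, fuzziness = 60
#' )
#' bg$start <- bg$summit - 73L
#' bg$end <- bg$summit + 74L
#' find_arrays(rbind(nucs, bg), method = "sliding")
#' @export
find_arrays <- function(nucleosomes, criteria = phasing_criteria(),
                        domains = NULL,
                        method = c("seed_extend", "sliding"),
                        thresholds = NULL) {
  method <- match.arg(method)
  validate_nucleosomes(nucleosomes)
  thresholds <- thresholds %||% compute_thresholds(nucleosomes, criteria)
  finder <- switch(method, seed_extend = find_arrays_seed_extend,
                   sliding = find_arrays_sliding)
  arrays <- finder(nucleosomes, criteria, thresholds)
  if (!is.null(domains)) {
    arrays <- filter_by_domain_overlap(arrays, domains,
                                       criteria$domain_overlap_frac)
  }
  dedup_merge(arrays)
}
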