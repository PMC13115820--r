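# Shared fixture builders used across the suite.

make_nucs <- function(summits, signal = 10, fuzziness = 20, chrom = "chr1",
                      width = 147L) {
  summits <- as.integer(summits)
  tibble::tibble(
    chrom = chrom,
    start = summits - width %/% 2L,
    end = summits - width %/% 2L + width,
    summit = summits,
    signal = rep_len(signal, length(summits)),
    fuzziness = rep_len(fuzziness, length(summits))
  )
}

# permissive thresholds for toy instances whose signals are all ~10/fuzz ~20
toy_thresholds <- function() {
  list(mean_signal_floor = 5, min_signal_floor = 4, fuzziness_ceiling = 50)
}

make_track <- function(pos, count, chrom = "chr1", library_size = NULL) {
  tbl <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        count = as.numeric(count))
  tbl <- dplyr::arrange(tbl, chrom, pos)
  attr(tbl, "library_size") <- library_size %||% as.integer(sum(count))
  attr(tbl, "normalized") <- is.null(library_size)
  class(tbl) <- unique(c("insertion_track", class(tbl)))
  tbl
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# two-archetype accessibility features: boundary-transition arrays have a
# strongly negative IAE with a wider BPS spread; accessibility-uniform
# arrays sit near the origin. Noise scales mirror what the insertion model
# produces at the default sequencing depth (counting-noise dominated).
archetype_features <- function(n_per = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    array_id = sprintf("a%03d", seq_len(2 * n_per)),
    iae = c(rnorm(n_per, -2.6, 0.4), rnorm(n_per, 0, 0.3)),
    bps = c(rnorm(n_per, 0, 0.5), rnorm(n_per, 0, 0.37)),
    truth = rep(c("C1", "C2"), each = n_per)
  )
}

# reciprocal-overlap matching of detected arrays against planted truth
match_to_truth <- function(arrays, truth, min_frac = 0.5) {
  if (nrow(arrays) == 0) {
    return(list(sensitivity = 0, false_rate = 0, matches = integer(0)))
  }
  matched_truth <- logical(nrow(truth))
  matched_arr <- logical(nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    for (j in seq_len(nrow(truth))) {
      if (arrays$chrom[i] != truth$chrom[j]) next
      ov <- min(arrays$end[i], truth$end[j]) - max(arrays$start[i], truth$start[j])
      if (ov <= 0) next
      if (ov / (arrays$end[i] - arrays$start[i]) >= min_frac &&
          ov / (truth$end[j] - truth$start[j]) >= min_frac) {
        matched_truth[j] <- TRUE
        matched_arr[i] <- TRUE
      }
    }
  }
  list(sensitivity = mean(matched_truth),
       false_rate = mean(!matched_arr),
       matches = which(matched_truth))
}
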