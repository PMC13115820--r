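#' CPM-normalize an insertion track
#'
#' Multiplies every positional count by `1e6 / library_size` so the total
#' normalized mass over all positions equals one million (when no events
#' were dropped at extraction).
#'
#' @param track An insertion track from [extract_insertions()].
#' @return The normalized track (attribute `normalized = TRUE`).
#' @export
cpm_normalize <- function(track) {
  lib <- attr(track, "library_size")
  if (is.null(lib) || lib <= 0) abort("insertion track has zero library size")
  if (isTRUE(attr(track, "normalized"))) {
    warn("track is already CPM-normalized; returning unchanged")
    return(track)
  }
  track$count <- track$count * 1e6 / lib
  attr(track, "normalized") <- TRUE
  track
}

# sum of track counts over [s, e) on one chromosome's (pos, count) vectors
track_window_sum <- function(pos, count, s, e) {
  if (e <= s) return(0)
  i <- findInterval(c(s - 1L, e - 1L), pos)
  lo <- i[1] + 1L
  hi <- i[2]
  # shift hi down if pos[hi] == e - 1 is inside (findInterval gives <=)
  if (hi >= lo) sum(count[lo:hi]) else 0
}

#' Binned accessibility profiles for arrays
#'
#' Divides each array body into `n_bins` near-equal bins (any remainder
#' spread over the leading bins) and computes per-bp mean insertion signal
#' per bin, over the whole body, and over the two flanking windows of
#' `flank_bp` (clipped at chromosome bounds, with the clipped width as
#' denominator; a zero-width flank contributes mean 0 with a warning).
#'
#' @param arrays Arrays tibble from [find_arrays()].
#' @param track An insertion track (typically CPM-normalized).
#' @param n_bins Number of body bins (reduced with a warning for arrays
#'   shorter than `n_bins` bp).
#' @param flank_bp Flank extent in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clip right flanks.
#' @return A tibble with `array_id`, coordinates, `inside_mean`,
#'   `left_flank_mean`, `right_flank_mean`, and a `bins` list-column.
#' @export
profile_arrays <- function(arrays, track, n_bins = 100L, flank_bp = 1000L,
                           chrom_sizes = NULL) {
  by_chrom <- split(track[, c("pos", "count")], track$chrom)
  warned_short <- FALSE
  warned_clip <- FALSE
  res <- pmap(list(arrays$array_id, arrays$chrom, arrays$start, arrays$end),
              function(id, chrom, start, end) {
    tr <- by_chrom[[chrom]]
    pos <- tr$pos %||% integer(0)
    count <- tr$count %||% numeric(0)
    len <- end - start
    nb <- n_bins
    if (len < nb) {
      if (!warned_short) {
        warn(sprintf("array %s shorter than n_bins; bins reduced", id))
        warned_short <<- TRUE
      }
      nb <- len
    }
    base <- len %/% nb
    rem <- len %% nb
    widths <- rep(base, nb) + c(rep(1L, rem), rep(0L, nb - rem))
    bounds <- start + cumsum(c(0L, widths))
    bins <- vapply(seq_len(nb), function(b) {
      track_window_sum(pos, count, bounds[b], bounds[b + 1]) / widths[b]
    }, numeric(1))
    inside_mean <- track_window_sum(pos, count, start, end) / len
    l0 <- max(0L, start - flank_bp)
    lw <- start - l0
    csize <- if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
      chrom_sizes[[chrom]]
    } else {
      Inf
    }
    r1 <- min(csize, end + flank_bp)
    rw <- max(0, r1 - end)
    if ((lw == 0 || rw == 0) && !warned_clip) {
      warn("flank fully clipped at chromosome bound; its mean is set to 0")
      warned_clip <<- TRUE
    }
    left_mean <- if (lw > 0) track_window_sum(pos, count, l0, start) / lw else 0
    right_mean <- if (rw > 0) track_window_sum(pos, count, end, r1) / rw else 0
    tibble(array_id = id, chrom = chrom, start = start, end = end,
           inside_mean = inside_mean, left_flank_mean = left_mean,
           right_flank_mean = right_mean, flank_bp = as.integer(flank_bp),
           bins = list(bins))
  })
  bind_rows(res)
}

#' Internal Accessibility Enrichment (IAE)
#'
#' Log2 ratio of the mean insertion signal inside the array body to the
#' average of the two flank means, with a pseudocount guarding zeros.
#' Negative values indicate an interior more closed than its flanks.
#'
#' @param profile A tibble from [profile_arrays()] (or any data frame with
#'   `inside_mean`, `left_flank_mean`, `right_flank_mean`).
#' @param eps Pseudocount (default 1e-9).
#' @return A numeric vector, one value per profile row.
#' @export
compute_iae <- function(profile, eps = 1e-9) {
  stopifnot(eps > 0)
  log2((profile$inside_mean + eps) /
         ((profile$left_flank_mean + profile$right_flank_mean) / 2 + eps))
}

#' Boundary Polarity Strength (BPS)
#'
#' Log2 ratio of right-flank to left-flank mean insertion signal; values
#' near zero indicate comparable accessibility on both sides of the array.
#'
#' @inheritParams compute_iae
#' @return A numeric vector, one value per profile row.
#' @export
compute_bps <- function(profile, eps = 1e-9) {
  stopifnot(eps > 0)
  log2((profile$right_flank_mean + eps) / (profile$left_flank_mean + eps))
}

#' Accessibility feature table for arrays
#'
#' Convenience wrapper computing IAE and BPS for each profiled array and
#' standardizing both within the sample.
#'
#' @inheritParams compute_iae
#' @return A tibble with `array_id`, `iae`, `bps`, `iae_z`, `bps_z`.
#' @export
array_accessibility <- function(profile, eps = 1e-9) {
  zscore_features(tibble(
    array_id = profile$array_id,
    iae = compute_iae(profile, eps),
    bps = compute_bps(profile, eps)
  ))
}

#' Within-sample z-score standardization of IAE/BPS features
#'
#' Centers and scales each feature using the population standard
#' deviation, so the standardized columns have mean 0 and SD 1 across the
#' clustered set. A constant feature yields all-zero z-scores with a
#' warning.
#'
#' @param features Tibble with `iae` and `bps` columns.
#' @return The input with `iae_z` and `bps_z` columns added.
#' @export
zscore_features <- function(features) {
  stop_missing_cols(features, c("iae", "bps"), "feature table")
  if (nrow(features) < 2) abort("z-scoring needs at least 2 arrays")
  z <- function(x, nm) {
    s <- pop_sd(x)
    if (s == 0) {
      warn(sprintf("feature '%s' is constant; z-scores set to 0", nm))
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  mutate(features, iae_z = z(.data$iae, "iae"), bps_z = z(.data$bps, "bps"))
}
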