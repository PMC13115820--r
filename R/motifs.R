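# Internal motif-enrichment engine: log-odds PWM scanning with an exact
# dynamic-programming score threshold, GC/length-matched background
# sampling, and one-sided hypergeometric enrichment.

pwm_log_odds <- function(pwm, pseudo = 0.0025) {
  p <- (pwm$matrix + pseudo) / (1 + 4 * pseudo)
  log2(sweep(p, 2, pwm$background, "/")) # L x 4
}

#' Exact PWM score threshold for a target p-value
#'
#' Computes, by dynamic programming over the discretized log-odds score
#' distribution under the background model, the smallest score whose
#' upper-tail probability does not exceed `p`. Scores are discretized to
#' `resolution` bits.
#'
#' @param pwm A `pwm` object from [read_pwms()].
#' @param p Target p-value for a single-position match (default 1e-4).
#' @param resolution Score discretization in bits.
#' @return The score threshold (bits).
#' @export
pwm_threshold <- function(pwm, p = 1e-4, resolution = 0.01) {
  lom <- pwm_log_odds(pwm)
  scaled <- round(lom / resolution)
  # dist over integer scores as a named-offset numeric vector
  offset <- 0L
  dist <- 1
  for (i in seq_len(nrow(scaled))) {
    s <- scaled[i, ]
    lo <- offset + min(s)
    hi <- offset + length(dist) - 1L + max(s)
    new <- numeric(hi - lo + 1L)
    for (b in 1:4) {
      sh <- offset + s[b] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * pwm$background[b]
    }
    dist <- new
    offset <- lo
  }
  scores <- (offset + seq_along(dist) - 1L) * resolution
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p)
  if (length(ok) == 0) return(scores[length(scores)] + resolution)
  scores[ok[1]]
}

seq_to_code <- function(seq_char) {
  # A=1 C=2 G=3 T=4, anything else NA
  match(strsplit(toupper(seq_char), "")[[1]], c("A", "C", "G", "T"))
}

score_positions <- function(code, lom) {
  L <- nrow(lom)
  n <- length(code)
  if (n < L) return(numeric(0))
  n_off <- n - L + 1L
  total <- numeric(n_off)
  for (j in seq_len(L)) {
    v <- lom[j, code[j:(j + n_off - 1L)]]
    v[is.na(v)] <- -1e9 # windows covering N can never reach threshold
    total <- total + v
  }
  total
}

revcomp_lom <- function(lom) {
  # scanning the forward strand with the reverse-complement matrix is
  # equivalent to scanning the reverse strand
  lom[rev(seq_len(nrow(lom))), c(4, 3, 2, 1)]
}

#' Scan regions for PWM hits on both strands
#'
#' Scores every PWM at every offset of every region sequence (forward and
#' reverse strand); a region is a hit for a TF when any offset reaches
#' the TF's score threshold (by default the exact-DP threshold at
#' p <= 1e-4 under the background model). Regions with more than 50%
#' ambiguous bases are excluded with a warning.
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param pwms List of `pwm` objects.
#' @param genome A named `Biostrings::DNAStringSet` (or FASTA path).
#' @param p Per-position p-value defining each TF's threshold.
#' @return A tibble with `region_id`, `tf`, `hit` (logical; `NA` for
#'   excluded regions).
#' @export
scan_motifs <- function(regions, pwms, genome, p = 1e-4) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  loms <- map(pwms, pwm_log_odds)
  thresholds <- map_dbl(pwms, pwm_threshold, p = p)
  tfs <- map_chr(pwms, "tf")
  rc_loms <- map(loms, revcomp_lom)
  n_excluded <- 0L
  n_reg <- nrow(regions)
  hit_mat <- matrix(NA, nrow = n_reg, ncol = length(pwms))
  for (i in seq_len(n_reg)) {
    chrom <- regions$chrom[i]
    s <- max(0L, regions$start[i])
    e <- min(length(genome[[chrom]]), regions$end[i])
    if (e <= s) {
      hit_mat[i, ] <- FALSE
      next
    }
    code <- seq_to_code(as.character(Biostrings::subseq(genome[[chrom]],
                                                        s + 1L, e)))
    if (mean(is.na(code)) > 0.5) {
      n_excluded <- n_excluded + 1L
      next
    }
    hit_mat[i, ] <- vapply(seq_along(pwms), function(m) {
      fwd <- score_positions(code, loms[[m]])
      if (length(fwd) > 0 && max(fwd) >= thresholds[m] - 1e-9) return(TRUE)
      rev <- score_positions(code, rc_loms[[m]])
      length(rev) > 0 && max(rev) >= thresholds[m] - 1e-9
    }, logical(1))
  }
  if (n_excluded > 0) {
    warn(sprintf("%d region(s) with > 50%% ambiguous bases excluded", n_excluded))
  }
  tibble(region_id = rep(regions$region_id, each = length(pwms)),
         tf = rep(tfs, n_reg), hit = as.vector(t(hit_mat)))
}

gc_fraction <- function(code) {
  mean(code %in% c(2L, 3L), na.rm = TRUE)
}

#' Sample a GC- and length-matched background region set
#'
#' Draws, for each foreground region, `ratio` background regions of the
#' same length from the genome, excluding the foreground regions padded
#' by `exclude_pad` bp, and matched to the foreground GC content within
#' `gc_bin`-wide bins. If matching fails after `max_tries` draws for a
#' region, the last draw is accepted with a warning. Deterministic for a
#' fixed seed.
#'
#' @param fg_regions Foreground tibble (`region_id`, `label`, `chrom`,
#'   `start`, `end`).
#' @param genome A named `DNAStringSet`.
#' @param ratio Background regions per foreground region.
#' @param seed Integer seed.
#' @param gc_bin GC-matching bin width (default 0.05).
#' @param exclude_pad Padding around foreground excluded from sampling.
#' @param max_tries Draw attempts per background region.
#' @return A background tibble with the same columns as `fg_regions`
#'   (labels inherited from the matched foreground region).
#' @export
sample_background <- function(fg_regions, genome, ratio = 10L, seed = 1L,
                              gc_bin = 0.05, exclude_pad = 1000L,
                              max_tries = 50L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- names(genome)
  chrom_len <- setNames(Biostrings::width(genome), chroms)
  padded <- GenomicRanges::reduce(gr_from_tbl(
    mutate(fg_regions, start = pmax(0L, .data$start - exclude_pad),
           end = .data$end + exclude_pad)
  ))
  # per-chromosome exclusion intervals (0-based half-open) and GC prefix sums
  excl_tbl <- tibble(chrom = as.character(GenomicRanges::seqnames(padded)),
                     start = GenomicRanges::start(padded) - 1L,
                     end = GenomicRanges::end(padded))
  excl_by <- split(excl_tbl, excl_tbl$chrom)
  gc_cum <- lapply(chroms, function(ch) {
    code <- seq_to_code(as.character(genome[[ch]]))
    cumsum(!is.na(code) & (code == 2L | code == 3L))
  })
  names(gc_cum) <- chroms
  window_gc <- function(ch, s, len) {
    (gc_cum[[ch]][s + len] - if (s > 0) gc_cum[[ch]][s] else 0) / len
  }
  overlaps_excl <- function(ch, s, e) {
    ex <- excl_by[[ch]]
    if (is.null(ex) || nrow(ex) == 0) return(FALSE)
    j <- findInterval(s, ex$start) # last exclusion starting at or before s
    (j >= 1 && ex$end[j] > s) || (j < nrow(ex) && ex$start[j + 1] < e)
  }
  set.seed(seed)
  n_forced <- 0L
  acc_id <- character(0)
  acc_lab <- character(0)
  acc_ch <- character(0)
  acc_s <- integer(0)
  acc_e <- integer(0)
  has_lab <- "label" %in% names(fg_regions)
  for (i in seq_len(nrow(fg_regions))) {
    len <- fg_regions$end[i] - fg_regions$start[i]
    fg_gc_bin <- floor(window_gc(fg_regions$chrom[i], fg_regions$start[i],
                                 len) / gc_bin)
    lab <- if (has_lab) fg_regions$label[i] else "all"
    for (r in seq_len(ratio)) {
      best_s <- NA_integer_
      best_ch <- NA_character_
      matched <- FALSE
      for (t in seq_len(max_tries)) {
        ch <- if (length(chroms) == 1) chroms else
          sample(chroms, 1, prob = chrom_len[chroms])
        if (chrom_len[[ch]] <= len) next
        s <- sample.int(chrom_len[[ch]] - len, 1) - 1L
        if (overlaps_excl(ch, s, s + len)) next
        best_s <- s
        best_ch <- ch
        if (floor(window_gc(ch, s, len) / gc_bin) == fg_gc_bin) {
          matched <- TRUE
          break
        }
      }
      if (!is.na(best_s)) {
        if (!matched) n_forced <- n_forced + 1L
        acc_id <- c(acc_id, sprintf("bg_%s_%d", fg_regions$region_id[i], r))
        acc_lab <- c(acc_lab, lab)
        acc_ch <- c(acc_ch, best_ch)
        acc_s <- c(acc_s, best_s)
        acc_e <- c(acc_e, best_s + len)
      }
    }
  }
  if (n_forced > 0) {
    inform(sprintf("%d background region(s) accepted outside the GC bin", n_forced))
  }
  tibble(region_id = acc_id, label = acc_lab, chrom = acc_ch,
         start = acc_s, end = acc_e)
}

#' Distance-resolved motif enrichment
#'
#' One-sided hypergeometric enrichment of foreground hit counts over the
#' pooled foreground + background universe, computed per TF within each
#' window label, with Benjamini-Hochberg adjustment across TFs within
#' each label.
#'
#' @param fg_hits Hit tibble for foreground regions (from
#'   [scan_motifs()]), with a `label` column joined from the regions.
#' @param bg_hits Hit tibble for background regions, likewise labeled.
#' @return A tibble with `label`, `tf`, hit/region counts, `p`, `p_adj`.
#' @export
motif_enrichment <- function(fg_hits, bg_hits) {
  if (nrow(fg_hits) == 0) {
    warn("empty foreground; no enrichment computed")
    return(tibble(label = character(), tf = character(),
                  fg_hits = integer(), fg_n = integer(),
                  bg_hits = integer(), bg_n = integer(),
                  p = numeric(), p_adj = numeric()))
  }
  summarise_hits <- function(h) {
    h |>
      filter(!is.na(.data$hit)) |>
      group_by(.data$label, .data$tf) |>
      summarise(hits = sum(.data$hit), n = n(), .groups = "drop")
  }
  fg <- summarise_hits(fg_hits)
  bg <- summarise_hits(bg_hits)
  joined <- left_join(fg, bg, by = c("label", "tf"),
                      suffix = c("_fg", "_bg")) |>
    mutate(hits_bg = dplyr::coalesce(.data$hits_bg, 0L),
           n_bg = dplyr::coalesce(.data$n_bg, 0L))
  joined |>
    mutate(p = hyper_enrichment_p(.data$hits_fg,
                                  .data$hits_fg + .data$hits_bg,
                                  (.data$n_fg - .data$hits_fg) +
                                    (.data$n_bg - .data$hits_bg),
                                  .data$n_fg)) |>
    group_by(.data$label) |>
    mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    select(label = "label", tf = "tf", fg_hits = "hits_fg", fg_n = "n_fg",
           bg_hits = "hits_bg", bg_n = "n_bg", "p", "p_adj") |>
    arrange(.data$label, .data$p)
}
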