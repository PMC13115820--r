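# Independent brute-force oracles. These deliberately use naive scalar
# loops (no shared code with the package internals) so that agreement is
# a meaningful check.

# -- phasing criteria, scalar re-implementation ---------------------------
oracle_run_passes <- function(nucs, criteria, thresholds) {
  nucs <- nucs[order(nucs$summit), ]
  n <- nrow(nucs)
  sp <- numeric(0)
  for (i in seq_len(n - 1)) sp[i] <- nucs$summit[i + 1] - nucs$summit[i]
  for (s in sp) {
    if (s < criteria$spacing_min || s > criteria$spacing_max) return(FALSE)
  }
  if (length(sp) >= 2) {
    m <- sum(sp) / length(sp)
    v <- 0
    for (s in sp) v <- v + (s - m)^2
    cv <- sqrt(v / length(sp)) / m
    if (cv >= criteria$cv_max) return(FALSE)
  }
  if (!(sum(nucs$signal) / n > thresholds$mean_signal_floor)) return(FALSE)
  if (!(min(nucs$signal) > thresholds$min_signal_floor)) return(FALSE)
  if (!(max(nucs$fuzziness) < thresholds$fuzziness_ceiling)) return(FALSE)
  TRUE
}

# -- sliding-window algorithm, naive re-implementation --------------------
# every k-window tested; blocks of consecutive passing windows become runs;
# runs merged to a fixed point when spans overlap or sit within merge_gap;
# merged runs (all bridged nucleosomes included) re-tested whole.
oracle_sliding <- function(nucs, criteria, thresholds) {
  nucs <- nucs[order(nucs$chrom, nucs$summit), ]
  out <- list()
  for (ch in unique(nucs$chrom)) {
    cn <- nucs[nucs$chrom == ch, ]
    n <- nrow(cn)
    k <- criteria$window_k
    if (n < k) next
    pass <- logical(n - k + 1)
    for (i in seq_len(n - k + 1)) {
      pass[i] <- oracle_run_passes(cn[i:(i + k - 1), ], criteria, thresholds)
    }
    runs <- list()
    i <- 1
    while (i <= length(pass)) {
      if (pass[i]) {
        j <- i
        while (j < length(pass) && pass[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(i, j + k - 1)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    # fixed-point merging on genomic spans
    repeat {
      merged_any <- FALSE
      if (length(runs) >= 2) {
        for (a in seq_len(length(runs) - 1)) {
          span_a <- c(min(cn$start[runs[[a]][1]:runs[[a]][2]]),
                      max(cn$end[runs[[a]][1]:runs[[a]][2]]))
          span_b <- c(min(cn$start[runs[[a + 1]][1]:runs[[a + 1]][2]]),
                      max(cn$end[runs[[a + 1]][1]:runs[[a + 1]][2]]))
          if (span_b[1] - span_a[2] <= criteria$merge_gap) {
            runs[[a]] <- c(min(runs[[a]][1], runs[[a + 1]][1]),
                           max(runs[[a]][2], runs[[a + 1]][2]))
            runs[[a + 1]] <- NULL
            merged_any <- TRUE
            break
          }
        }
      }
      if (!merged_any) break
    }
    for (r in runs) {
      sub <- cn[r[1]:r[2], ]
      if (oracle_run_passes(sub, criteria, thresholds)) {
        out[[length(out) + 1]] <- c(ch = ch, start = min(sub$start),
                                    end = max(sub$end), n = nrow(sub))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ch = character(), start = integer(), end = integer(),
                      n = integer()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$n <- as.integer(df$n)
  df[order(df$ch, df$start), ]
}

# -- silhouette, double-loop oracle ---------------------------------------
oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    own_others <- setdiff(which(labels == own), i)
    if (length(own_others) == 0) {
      s[i] <- 0
      next
    }
    a <- 0
    for (j in own_others) a <- a + d(i, j)
    a <- a / length(own_others)
    b <- Inf
    for (oc in setdiff(unique(labels), own)) {
      bb <- 0
      members <- which(labels == oc)
      for (j in members) bb <- bb + d(i, j)
      bb <- bb / length(members)
      if (bb < b) b <- bb
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# -- one-sided rank-sum p by full enumeration -----------------------------
oracle_ranksum_less <- function(x, y) {
  pooled <- c(x, y)
  # midranks computed from scratch
  r <- numeric(length(pooled))
  for (i in seq_along(pooled)) {
    r[i] <- sum(pooled < pooled[i]) + (sum(pooled == pooled[i]) + 1) / 2
  }
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  count <- 0
  for (c_i in seq_len(ncol(combos))) {
    if (sum(r[combos[, c_i]]) <= w_obs + 1e-9) count <- count + 1
  }
  count / ncol(combos)
}

# -- hypergeometric upper tail by direct summation ------------------------
oracle_hyper_tail <- function(q, m, n, k) {
  total <- 0
  for (i in q:min(m, k)) {
    total <- total + choose(m, i) * choose(n, k - i) / choose(m + n, k)
  }
  total
}
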