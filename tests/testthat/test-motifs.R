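toy_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chr1"
  g
}

test_that("PWM threshold tail probability is honored by construction", {
  set.seed(1)
  cons <- c("T", "G", "C", "A", "T", "A", "C", "G", "G", "A")
  pwm <- nurepress:::sharp_pwm("TF1", cons)
  thr <- pwm_threshold(pwm, p = 1e-4)
  # the exact consensus must reach the threshold
  lom <- nurepress:::pwm_log_odds(pwm)
  cons_score <- sum(lom[cbind(1:10, match(cons, c("A", "C", "G", "T")))])
  expect_gte(cons_score, thr)
  # empirical tail: the chance of a random 10-mer scoring >= thr is <= 1e-4
  # (checked loosely by simulation)
  hits <- 0
  for (i in 1:2000) {
    code <- sample.int(4, 10, replace = TRUE)
    if (sum(lom[cbind(1:10, code)]) >= thr) hits <- hits + 1
  }
  expect_lte(hits / 2000, 5e-3)
})

test_that("motif scanning detects planted consensus on both strands", {
  cons <- c("T", "G", "C", "A", "T", "A", "C", "G", "G", "A")
  pwm <- nurepress:::sharp_pwm("TF1", cons)
  set.seed(2)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  fwd_seq <- paste0(substr(bg, 1, 100), paste(cons, collapse = ""),
                    substr(bg, 111, 300))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(cons, collapse = ""))))
  rc_seq <- paste0(substr(bg, 1, 100), rc, substr(bg, 111, 300))
  regions <- tibble::tibble(region_id = c("fwd", "rc", "short"),
                            chrom = "chr1",
                            start = c(0L, 0L, 0L), end = c(300L, 300L, 6L))
  hits_f <- scan_motifs(regions[1, ], list(pwm), toy_genome(fwd_seq))
  expect_true(hits_f$hit)
  hits_r <- scan_motifs(regions[2, ], list(pwm), toy_genome(rc_seq))
  expect_true(hits_r$hit)
  # region shorter than the motif has no valid offset
  hits_s <- scan_motifs(regions[3, ], list(pwm), toy_genome(bg))
  expect_false(hits_s$hit)
})

test_that("ambiguous-base regions are excluded with a warning", {
  seq <- paste0(strrep("N", 200), strrep("ACGT", 50))
  regions <- tibble::tibble(region_id = c("nn", "ok"), chrom = "chr1",
                            start = c(0L, 200L), end = c(200L, 400L))
  pwm <- nurepress:::sharp_pwm("TF1", rep("A", 6))
  expect_warning(h <- scan_motifs(regions, list(pwm), toy_genome(seq)),
                 "ambiguous")
  expect_true(is.na(h$hit[h$region_id == "nn"]))
  expect_false(is.na(h$hit[h$region_id == "ok"]))
})

test_that("hypergeometric enrichment matches the brute-force tail sum", {
  # worked example: all 10 foreground regions hit, 5 of 100 background
  p <- hyper_enrichment_p(10, 15, 95, 10)
  expect_equal(p, oracle_hyper_tail(10, 15, 95, 10), tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:25) {
    m <- sample(1:200, 1)
    n <- sample(1:200, 1)
    k <- sample(1:min(120, m + n), 1)
    q <- sample(0:min(k, m), 1)
    expect_equal(hyper_enrichment_p(max(q, 1), m, n, k),
                 oracle_hyper_tail(max(q, 1), m, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment table behaves at the null and degenerate ends", {
  fg <- tidyr::expand_grid(region_id = sprintf("f%d", 1:10), tf = "TF1") |>
    dplyr::mutate(hit = c(rep(TRUE, 5), rep(FALSE, 5)), label = "linker")
  bg <- tidyr::expand_grid(region_id = sprintf("b%d", 1:100), tf = "TF1") |>
    dplyr::mutate(hit = c(rep(TRUE, 50), rep(FALSE, 50)), label = "linker")
  res <- motif_enrichment(fg, bg)
  expect_gte(res$p, 0.4) # equal rates: not significant

  fg0 <- dplyr::mutate(fg, hit = FALSE)
  res0 <- motif_enrichment(fg0, bg)
  expect_equal(res0$p, 1)

  expect_warning(empty <- motif_enrichment(fg[0, ], bg), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(4)
  fg <- tidyr::expand_grid(region_id = sprintf("f%d", 1:20),
                           tf = sprintf("TF%d", 1:12)) |>
    dplyr::mutate(hit = runif(dplyr::n()) < 0.3, label = "boundary_0_200")
  bg <- tidyr::expand_grid(region_id = sprintf("b%d", 1:200),
                           tf = sprintf("TF%d", 1:12)) |>
    dplyr::mutate(hit = runif(dplyr::n()) < 0.2, label = "boundary_0_200")
  res <- motif_enrichment(fg, bg)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
})

test_that("background sampling is GC/length matched, seeded, and exclusive", {
  set.seed(6)
  # genome with a GC gradient so matching is non-trivial
  probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(c(sample(c("A", "C", "G", "T"), 50000, TRUE, probs(0.3)),
                 sample(c("A", "C", "G", "T"), 50000, TRUE, probs(0.7))),
               collapse = "")
  genome <- toy_genome(seq)
  fg <- tibble::tibble(region_id = c("r1", "r2"), label = "linker",
                       chrom = "chr1", start = c(10000L, 80000L),
                       end = c(10200L, 80200L))
  bg1 <- sample_background(fg, genome, ratio = 5L, seed = 9L)
  bg2 <- sample_background(fg, genome, ratio = 5L, seed = 9L)
  expect_identical(bg1, bg2)
  expect_equal(unique(bg1$end - bg1$start), 200L)
  # no background region intrudes into the padded foreground
  for (i in seq_len(nrow(bg1))) {
    expect_true(all(bg1$end[i] <= fg$start - 1000 |
                      bg1$start[i] >= fg$end + 1000))
  }
  # GC of matched backgrounds falls in the same 5% bin as its foreground
  gc_of <- function(ch, s, e) {
    code <- nurepress:::seq_to_code(substr(seq, s + 1, e))
    mean(code %in% c(2L, 3L))
  }
  fg_bins <- floor(vapply(seq_len(nrow(fg)), function(i)
    gc_of("chr1", fg$start[i], fg$end[i]), numeric(1)) / 0.05)
  bg_src <- match(sub("^bg_(r[0-9]+)_.*$", "\\1", bg1$region_id),
                  fg$region_id)
  bg_bins <- floor(vapply(seq_len(nrow(bg1)), function(i)
    gc_of("chr1", bg1$start[i], bg1$end[i]), numeric(1)) / 0.05)
  expect_gte(mean(bg_bins == fg_bins[bg_src]), 0.8)
})
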