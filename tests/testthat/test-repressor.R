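test_that("expression contrast flags downregulation at the threshold", {
  ea <- tibble::tibble(gene_id = c("g1", "g2", "g3"), expression = c(8, 4, 4))
  eb <- tibble::tibble(gene_id = c("g1", "g2", "g3"), expression = c(2, 4, 2.5))
  ct <- expression_contrast(ea, eb, lfc_threshold = 1, pseudocount = 0)
  expect_equal(ct$lfc, c(-2, 0, log2(2.5 / 4)))
  expect_equal(ct$down, c(1L, 0L, 0L))

  same <- expression_contrast(ea, ea)
  expect_true(all(same$lfc == 0) && all(same$down == 0L))
  expect_error(expression_contrast(
    ea, tibble::tibble(gene_id = "zz", expression = 1)), "shared")
})

test_that("one-sided rank-sum p equals exact enumeration", {
  # the all-ties toy: only 1 of choose(6,3) arrangements is as extreme
  expect_equal(rank_sum_p_less(c(1, 1, 1), c(5, 5, 5)), 0.05,
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    n <- sample(2:8, 1)
    x <- sample(1:6, m, replace = TRUE) # ties likely
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(rank_sum_p_less(x, y), oracle_ranksum_less(x, y),
                 tolerance = 1e-10)
  }
  # tie-free case agrees with the base-R exact distribution
  x <- c(1.2, 3.4, 0.5, 2.2)
  y <- c(4.1, 5.6, 3.9, 7.2, 6.1)
  expect_equal(rank_sum_p_less(x, y),
               wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("repressive efficacy combines effect size and significance", {
  # arrays a1..a3 are subtype C1 over genes g1..g3; genes g4..g6 absent
  q <- matrix(0L, nrow = 3, ncol = 6,
              dimnames = list(c("a1", "a2", "a3"), sprintf("g%d", 1:6)))
  q[cbind(1:3, 1:3)] <- 1L
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                         expression = c(1, 1, 1, 5, 5, 5))
  labels <- tibble::tibble(array_id = c("a1", "a2", "a3"),
                           subtype = "C1")
  re <- repressive_efficacy(expr, q, labels)
  expect_equal(re$delta, -4)
  expect_equal(re$p_expr, 0.05, tolerance = 1e-12)
  expect_equal(re$re, 4 * -log10(0.05), tolerance = 1e-12)

  # positive delta forces RE to zero regardless of p
  expr_up <- dplyr::mutate(expr,
                           expression = c(9, 9, 9, 5, 5, 5))
  expect_equal(repressive_efficacy(expr_up, q, labels)$re, 0)

  # an empty exclusive group reports RE as absent, not zero
  q_all <- q
  q_all[, 4:6] <- 1L # no absent genes left
  expect_message(re_na <- repressive_efficacy(expr, q_all, labels),
                 "undefined")
  expect_true(is.na(re_na$re))
})

test_that("foreground selection follows the promoter-fraction rule", {
  q <- matrix(0L, nrow = 3, ncol = 2,
              dimnames = list(c("r1", "r2", "r3"), c("g1", "g2")))
  q["r1", "g1"] <- 1L
  q["r3", "g2"] <- 1L
  x <- tibble::tibble(region_id = c("r1", "r2", "r3"), x = c(1L, 1L, 1L))
  d <- c(g1 = 1, g2 = 0)
  sub_arrays <- tibble::tibble(
    array_id = c("b1", "b2", "b3"), region_id = c("r1", "r2", "r3"),
    overlaps_promoter = c(TRUE, FALSE, TRUE)
  )
  # promoter fraction 2/3 > 0.2: transition-derived foreground
  sel <- select_foreground(x, q, d, sub_arrays, 0.2)
  expect_false(sel$fallback)
  expect_equal(sel$foreground_arrays, "b1")
  expect_equal(unname(sel$C), c(1, 1))

  # low promoter fraction: fall back to all subtype arrays
  sub_low <- dplyr::mutate(sub_arrays, overlaps_promoter = c(TRUE, FALSE, FALSE))
  sel2 <- select_foreground(x, q, d, sub_low, 0.5)
  expect_true(sel2$fallback)
  expect_equal(sel2$foreground_arrays, c("b1", "b2", "b3"))

  # nothing downregulated: empty foreground with a warning
  expect_warning(
    sel3 <- select_foreground(x, q, c(g1 = 0, g2 = 0), sub_arrays, 0.2),
    "empty"
  )
  expect_length(sel3$foreground_arrays, 0)
})

test_that("phasing boundary is the edge with the steeper signal decline", {
  # high occupancy inside, nothing beyond the right edge, gradual left
  nucs <- dplyr::bind_rows(
    make_nucs(2000L + 180L * (0:4), signal = 20),
    make_nucs(c(1840L, 1660L), signal = c(12, 6)) # gradual left shoulder
  )
  arrays <- tibble::tibble(array_id = "a", chrom = "chr1",
                           start = min(make_nucs(2000L + 180L * (0:4))$start),
                           end = max(make_nucs(2000L + 180L * (0:4))$end))
  b <- detect_phasing_boundary(arrays, nucs)
  expect_equal(b$boundary, "right")

  # perfectly symmetric profile ties to the left
  sym <- make_nucs(5000L + 180L * (0:4), signal = 20)
  arr_sym <- tibble::tibble(array_id = "s", chrom = "chr1",
                            start = min(sym$start), end = max(sym$end))
  expect_equal(detect_phasing_boundary(arr_sym, sym)$boundary, "left")

  # declines on a step-function track match hand-computed window means
  d_right <- nurepress:::nucleosome_signal_mean(sym, "chr1",
                                                max(sym$end) - 200L,
                                                max(sym$end)) -
    nurepress:::nucleosome_signal_mean(sym, "chr1", max(sym$end),
                                       max(sym$end) + 200L)
  ov <- 200 - (180 - 147) # footprint bp of the last nucleosome's tail window
  expect_gt(d_right, 0)
  expect_equal(nurepress:::nucleosome_signal_mean(sym, "chr1",
                                                  max(sym$end),
                                                  max(sym$end) + 200L), 0)
})

test_that("scan regions cover linkers and five boundary windows", {
  nucs <- make_nucs(c(1073L, 1253L, 1433L)) # 147 bp wide, 180 bp spacing
  arr <- tibble::tibble(
    array_id = "a", chrom = "chr1",
    start = min(nucs$start), end = max(nucs$end),
    nucleosomes = list(nucs), boundary = "right"
  )
  regions <- extract_scan_regions(arr[1, ], window_bp = 200L,
                                  max_dist = 1000L)
  linkers <- dplyr::filter(regions, label == "linker")
  expect_equal(nrow(linkers), 2)
  expect_equal(unique(linkers$end - linkers$start), 33L)
  windows <- dplyr::filter(regions, label != "linker")
  expect_equal(nrow(windows), 5)
  expect_equal(windows$start[1], arr$end)
  expect_equal(windows$label,
               sprintf("boundary_%d_%d", seq(0, 800, 200), seq(200, 1000, 200)))
  # boundary at the chromosome end: windows clipped, empty ones dropped
  clipped <- extract_scan_regions(arr[1, ], window_bp = 200L,
                                  max_dist = 1000L,
                                  chrom_size = arr$end + 300L)
  expect_equal(nrow(dplyr::filter(clipped, label != "linker")), 2)
})

test_that("MP, RPS, S_score and the candidate rule are computed as defined", {
  enr <- tibble::tibble(
    label = rep(c("boundary_0_200", "boundary_200_400", "linker"), 2),
    tf = rep(c("TF1", "TF2"), each = 3),
    fg_hits = 1L, fg_n = 2L, bg_hits = 1L, bg_n = 20L,
    p = c(0.01, 0.001, 0.5, 1, 1, 1),
    p_adj = c(0.01, 0.001, 0.5, 1, 1, 1)
  )
  mp <- motif_potential(enr)
  expect_equal(mp$mp[mp$tf == "TF1"], 3)
  expect_equal(mp$mp[mp$tf == "TF2"], 0)
  # restricting to boundary windows drops the linker label from the max
  enr_link <- dplyr::mutate(enr, p_adj = ifelse(label == "linker", 1e-6, p_adj))
  expect_equal(motif_potential(enr_link)$mp[1], 6)
  expect_equal(motif_potential(enr_link, include_linker = FALSE)$mp[1], 3)
  expect_equal(motif_potential(dplyr::mutate(enr, p_adj = 0.05))$mp[1],
               -log10(0.05), tolerance = 1e-12)

  re_tbl <- tibble::tibble(sample_id = "B", subtype = c("C1", "C2"),
                           re = c(0, 1.6))
  mp_tbl <- tibble::tibble(
    sample_id = "B", subtype = rep(c("C1", "C2"), each = 1),
    tf = "TF1", mp = c(5, 3)
  )
  sc <- score_and_rank(re_tbl, mp_tbl, alpha = 0.05)
  expect_equal(sc$rps[sc$subtype == "C2"], 1.6 * 3)
  expect_equal(sc$rps[sc$subtype == "C1"], 0)
  expect_equal(sc$s_score[sc$subtype == "C1"], 2)
  expect_equal(sc$s_score[sc$subtype == "C2"], -2)
  # candidate needs RE > 0 and MP above -log10(alpha) ~ 1.301
  expect_false(sc$candidate[sc$subtype == "C1"]) # re = 0
  expect_true(sc$candidate[sc$subtype == "C2"])
  weak <- score_and_rank(re_tbl,
                         dplyr::mutate(mp_tbl, mp = c(5, 1.2)), 0.05)
  expect_false(weak$candidate[weak$subtype == "C2"]) # mp below 1.301
})

test_that("RPS is monotone in each factor with the other fixed", {
  set.seed(12)
  re_vals <- sort(runif(5, 0.1, 3))
  mp_vals <- sort(runif(5, 0.1, 6))
  for (mp in mp_vals) {
    rps <- re_vals * mp
    expect_true(all(diff(rps) >= 0))
  }
  for (re in re_vals) {
    rps <- re * mp_vals
    expect_true(all(diff(rps) >= 0))
  }
})
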