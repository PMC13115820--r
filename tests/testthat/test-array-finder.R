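test_that("MAD fragment filter removes length outliers", {
  frags <- tibble::tibble(chrom = "chr1", start = 0L,
                          end = c(140L, 150L, 160L, 170L, 600L),
                          length = c(140L, 150L, 160L, 170L, 600L))
  # median 160, scaled MAD 14.826, 3-MAD window 160 +- 44.478
  kept <- mad_filter_fragments(frags, n_mads = 3)
  expect_equal(sort(kept$length), c(140L, 150L, 160L, 170L))

  same <- tibble::tibble(chrom = "chr1", start = 0L, end = 150L,
                         length = rep(150L, 4))
  expect_warning(kept2 <- mad_filter_fragments(same), "MAD")
  expect_equal(nrow(kept2), 4)

  one <- frags[1, ]
  expect_equal(nrow(suppressWarnings(mad_filter_fragments(one))), 1)
})

test_that("thresholds use linear-interpolation percentiles genome-wide", {
  nucs <- make_nucs(200L * (1:100), signal = 1:100, fuzziness = 1:100)
  th <- compute_thresholds(nucs, phasing_criteria())
  expect_equal(th$mean_signal_floor, 30.7)
  expect_equal(th$min_signal_floor, 20.8)
  expect_equal(th$fuzziness_ceiling, 20.8)

  const <- make_nucs(c(200L, 400L), signal = 5, fuzziness = 5)
  th2 <- compute_thresholds(const, phasing_criteria())
  expect_equal(th2$mean_signal_floor, 5)
  expect_equal(th2$min_signal_floor, 5)

  two <- make_nucs(c(200L, 400L), signal = c(0, 10))
  expect_equal(compute_thresholds(two, phasing_criteria())$min_signal_floor, 2)
  expect_error(compute_thresholds(two[0, ], phasing_criteria()), "2 nucleosomes")
})

test_that("window evaluation applies all five phasing criteria", {
  crit <- phasing_criteria()
  th <- toy_thresholds()

  even <- make_nucs(c(1000L, 1180L, 1360L))
  v <- evaluate_window(even, crit, th)
  expect_true(v$pass)
  expect_equal(v$spacing_cv, 0)

  # each spacing in range but CV = 30/190 > 0.15
  wide <- make_nucs(c(1000L, 1160L, 1380L))
  v2 <- evaluate_window(wide, crit, th)
  expect_false(v2$pass)
  expect_false(v2$checks[["spacing_cv"]])
  expect_true(v2$checks[["spacing_range"]])
  expect_equal(v2$spacing_cv, 30 / 190, tolerance = 1e-12)

  gap <- make_nucs(c(1000L, 1300L, 1480L))
  v3 <- evaluate_window(gap, crit, th)
  expect_false(v3$checks[["spacing_range"]])

  dull <- make_nucs(c(1000L, 1180L, 1360L), signal = c(10, 3, 10))
  expect_false(evaluate_window(dull, crit, th)$checks[["min_signal"]])
  fuzzy <- make_nucs(c(1000L, 1180L, 1360L), fuzziness = c(20, 60, 20))
  expect_false(evaluate_window(fuzzy, crit, th)$checks[["fuzziness"]])
})

test_that("sliding-window merging finds, merges and re-filters arrays", {
  crit <- phasing_criteria()
  th <- toy_thresholds()

  five <- make_nucs(1000L + 180L * (0:4))
  arr <- find_arrays_sliding(five, crit, th)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_nucleosomes, 5L)

  # two qualifying triplets separated by far more than the merge gap
  two_far <- make_nucs(c(1000L + 180L * (0:2), 5000L + 180L * (0:2)))
  arr2 <- find_arrays_sliding(two_far, crit, th)
  expect_equal(nrow(arr2), 2)
  expect_equal(arr2$n_nucleosomes, c(3L, 3L))

  # windows pass individually but the merged union fails the CV check
  bridge <- make_nucs(cumsum(c(1000L, 160L, 160L, 220L, 220L)))
  expect_true(evaluate_window(bridge[1:3, ], crit, th)$pass)
  expect_true(evaluate_window(bridge[3:5, ], crit, th)$pass)
  union_sp <- c(160, 160, 220, 220)
  union_cv <- sqrt(mean((union_sp - mean(union_sp))^2)) / mean(union_sp)
  expect_gte(union_cv, 0.15) # 30/190 = 0.1579: the union must fail
  expect_equal(nrow(find_arrays_sliding(bridge, crit, th)), 0)
})

test_that("seed-and-extend grows seeds and respects the failure limit", {
  crit <- phasing_criteria()
  th <- toy_thresholds()

  seven <- make_nucs(1000L + 180L * (0:6))
  arr <- find_arrays(seven, crit, method = "seed_extend", thresholds = th)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_nucleosomes, 7L)

  # qualifying seed flanked by 400-bp-spaced nucleosomes on both sides:
  # both sides must close after max_fail consecutive rejections
  iso <- make_nucs(c(2000L - c(800L, 400L), 2000L + 180L * (0:2),
                     2360L + c(400L, 800L)))
  arr2 <- find_arrays_seed_extend(iso, crit, th)
  expect_equal(nrow(arr2), 1)
  expect_equal(arr2$n_nucleosomes, 3L)
  expect_equal(arr2$mean_spacing, 180)

  none <- make_nucs(c(1000L, 1500L, 2000L, 2500L))
  expect_equal(nrow(find_arrays_seed_extend(none, crit, th)), 0)
})

test_that("every returned array passes the unrelaxed criteria", {
  crit <- phasing_criteria()
  th <- toy_thresholds()
  set.seed(42)
  for (rep in 1:10) {
    summits <- sort(sample.int(8000, 25)) + 500L
    nucs <- make_nucs(summits, signal = runif(25, 5, 15),
                      fuzziness = runif(25, 10, 60))
    for (finder in list(find_arrays_sliding, find_arrays_seed_extend)) {
      arr <- finder(nucs, crit, th)
      for (i in seq_len(nrow(arr))) {
        expect_true(evaluate_window(arr$nucleosomes[[i]], crit, th)$pass)
      }
    }
  }
})

test_that("domain-overlap filtering uses the fraction of array length", {
  arrays <- tibble::tibble(
    array_id = c("a", "b"), chrom = "chr1",
    start = c(0L, 2000L), end = c(1000L, 3000L),
    n_nucleosomes = 5L, mean_spacing = 180, spacing_cv = 0.01,
    mean_signal = 10, min_signal = 9, max_fuzziness = 20,
    method = "sliding", nucleosomes = list(NULL, NULL)
  )
  doms <- tibble::tibble(chrom = "chr1", start = c(700L, 2701L),
                         end = c(1100L, 3100L))
  # array a overlaps 300/1000 (kept at the >= 0.3 boundary),
  # array b overlaps 299/1000 (dropped)
  kept <- filter_by_domain_overlap(arrays, doms, 0.3)
  expect_equal(kept$array_id, "a")
  expect_equal(nrow(filter_by_domain_overlap(arrays, doms[0, ], 0.3)), 0)
})

test_that("dedup_merge collapses duplicates and merges overlaps", {
  crit <- phasing_criteria()
  th <- toy_thresholds()
  nucs <- make_nucs(1000L + 180L * (0:6))
  a1 <- find_arrays_sliding(nucs, crit, th)
  a2 <- find_arrays_seed_extend(nucs, crit, th)
  both <- dplyr::bind_rows(a1, a2)
  merged <- dedup_merge(both)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_nucleosomes, 7L)

  # overlapping arrays with distinct coordinates merge into the union
  o1 <- find_arrays_sliding(nucs[1:5, ], crit, th)
  o2 <- find_arrays_sliding(nucs[3:7, ], crit, th)
  m2 <- dedup_merge(dplyr::bind_rows(o1, o2))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, min(nucs$start))
  expect_equal(m2$end, max(nucs$end))
  expect_equal(m2$n_nucleosomes, 7L)

  # disjoint arrays pass through unchanged
  far <- make_nucs(9000L + 180L * (0:2))
  d <- dedup_merge(dplyr::bind_rows(o1, find_arrays_sliding(far, crit, th)))
  expect_equal(nrow(d), 2)
})

test_that("finder output is independent of input row order", {
  set.seed(7)
  nucs <- dplyr::bind_rows(
    make_nucs(1000L + 180L * (0:5)),
    make_nucs(sort(sample.int(50000, 30)) + 10000L,
              signal = runif(30, 5, 15), fuzziness = runif(30, 10, 60))
  )
  th <- toy_thresholds()
  shuffled <- nucs[sample.int(nrow(nucs)), ]
  for (finder in list(find_arrays_sliding, find_arrays_seed_extend)) {
    a <- finder(nucs, phasing_criteria(), th)
    b <- finder(shuffled, phasing_criteria(), th)
    expect_equal(a$array_id, b$array_id)
    expect_equal(a$mean_spacing, b$mean_spacing)
  }
})

test_that("tightening criteria never yields more arrays", {
  set.seed(11)
  b <- simulate_landscape(simulation_config(seed = 3L, n_arrays = 10L,
                                            chrom_length = 500000L,
                                            n_decoys = 400L))
  loose <- phasing_criteria()
  tight_cv <- phasing_criteria(cv_max = 0.08)
  tight_sp <- phasing_criteria(spacing_min = 170, spacing_max = 200)
  n_loose <- nrow(find_arrays(b$nucleosomes, loose, method = "sliding"))
  expect_lte(nrow(find_arrays(b$nucleosomes, tight_cv, method = "sliding")),
             n_loose)
  expect_lte(nrow(find_arrays(b$nucleosomes, tight_sp, method = "sliding")),
             n_loose)
})
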