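two_sample_arrays <- function(a_coords, b_coords) {
  mk <- function(coords, s) {
    tibble::tibble(
      sample_id = s,
      array_id = sprintf("%s_%d", s, seq_len(nrow(coords))),
      chrom = "chr1", start = coords[, 1], end = coords[, 2]
    )
  }
  dplyr::bind_rows(mk(a_coords, "A"), mk(b_coords, "B"))
}

test_that("union regions apply the shorter-array overlap rule", {
  # overlap 400 of shorter length 600 (0.67 >= 0.5): one union [100, 900)
  pooled <- two_sample_arrays(cbind(100L, 700L), cbind(300L, 900L))
  r <- build_union_regions(pooled, min_overlap = 0.5)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(100L, 900L))
  expect_equal(nrow(r$members[[1]]), 2)

  # overlap 100 of shorter 600 (0.17): two separate regions
  pooled2 <- two_sample_arrays(cbind(100L, 700L), cbind(600L, 1200L))
  r2 <- build_union_regions(pooled2, min_overlap = 0.5)
  expect_equal(nrow(r2), 2)

  # a single sample yields one region per array
  solo <- two_sample_arrays(rbind(c(100L, 700L), c(5000L, 5600L)),
                            matrix(integer(0), ncol = 2))
  r3 <- build_union_regions(solo, min_overlap = 0.5)
  expect_equal(nrow(r3), 2)
  expect_true(all(vapply(r3$members, nrow, integer(1)) == 1))
})

test_that("union regions are symmetric in sample order", {
  set.seed(13)
  coords <- cbind(sort(sample.int(50000, 12)) * 10L, 0L)
  coords[, 2] <- coords[, 1] + sample(500:1500, 12)
  a <- coords[1:6, , drop = FALSE]
  b <- coords[7:12, , drop = FALSE]
  r_ab <- build_union_regions(two_sample_arrays(a, b))
  r_ba <- build_union_regions(two_sample_arrays(b, a))
  expect_equal(r_ab[, c("chrom", "start", "end")],
               r_ba[, c("chrom", "start", "end")])
})

test_that("state encoding and transition counting match direct counts", {
  pooled <- two_sample_arrays(
    rbind(c(100L, 700L), c(2000L, 2600L), c(5000L, 5700L)),
    rbind(c(120L, 720L), c(5050L, 5750L), c(9000L, 9600L))
  )
  r <- build_union_regions(pooled, 0.5)
  labels <- tibble::tibble(
    sample_id = pooled$sample_id, array_id = pooled$array_id,
    subtype = c("C1", "C2", "C2", "C1", "C2", "C2")
  )
  st <- encode_states(r, labels, samples = c("A", "B"))
  expect_equal(nrow(st), 2 * nrow(r))
  tm <- transition_matrix(st, "A", "B")
  expect_equal(sum(tm), nrow(r))
  # row sums reproduce sample-A state counts, columns sample-B counts
  a_states <- dplyr::filter(st, sample_id == "A")$state
  expect_equal(as.vector(rowSums(tm)),
               as.vector(table(factor(a_states, levels = rownames(tm)))))
  b_states <- dplyr::filter(st, sample_id == "B")$state
  expect_equal(as.vector(colSums(tm)),
               as.vector(table(factor(b_states, levels = colnames(tm)))))
  # identical state vectors put all mass on the diagonal
  tm_id <- transition_matrix(st, "A", "A")
  expect_equal(sum(diag(tm_id)), nrow(r))

  # a member array without a subtype label is a hard error
  expect_error(encode_states(r, labels[-1, ], samples = c("A", "B")),
               "without subtype")
})

test_that("transition counts match brute-force counting on random instances", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 30
    states <- c("None", "C1", "C2")
    sa <- sample(states, n, replace = TRUE)
    sb <- sample(states, n, replace = TRUE)
    st <- tibble::tibble(
      region_id = rep(sprintf("r%02d", 1:n), 2),
      sample_id = rep(c("A", "B"), each = n),
      state = c(sa, sb)
    )
    tm <- transition_matrix(st, "A", "B", levels = states)
    for (i in states) {
      for (j in states) {
        expect_equal(tm[i, j], sum(sa == i & sb == j))
      }
    }
  }
})

test_that("promoter matrix uses half-open one-bp overlap", {
  items <- tibble::tibble(array_id = c("a1", "a2"), chrom = "chr1",
                          start = c(900L, 0L), end = c(1200L, 900L))
  promoters <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                              start = 1000L, end = 3000L,
                              tss = 2000L, strand = "+")
  q <- build_promoter_matrix(items, promoters)
  expect_equal(q["a1", "g1"], 1L)
  expect_equal(q["a2", "g1"], 0L) # end 900 is exclusive
  q0 <- build_promoter_matrix(items, promoters[0, ])
  expect_equal(sum(q0), 0)
})

test_that("annotation precedence is promoter > genic > distal", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000L,
                          end = 20000L, strand = "+", tss = 10000L)
  promoters <- promoters_from_genes(genes)
  arrays <- tibble::tibble(
    array_id = c("p", "g", "d"), chrom = "chr1",
    start = c(9500L, 15000L, 60000L), end = c(10500L, 16000L, 61000L)
  )
  ann <- annotate_arrays(arrays, genes, promoters)
  expect_equal(ann$annotation, c("promoter", "genic", "distal"))
  expect_equal(ann$tss_distance[3], 50500)
  # minus-strand gene flips the distance sign
  genes_m <- dplyr::mutate(genes, strand = "-", tss = 20000L)
  ann_m <- annotate_arrays(arrays[3, ], genes_m, promoters_from_genes(genes_m))
  expect_equal(ann_m$tss_distance, -(60500 - 20000))
})

test_that("relative domain position is the clipped scaled midpoint", {
  domains <- tibble::tibble(chrom = "chr1", start = 1000L, end = 3000L)
  arrays <- tibble::tibble(
    array_id = c("at_start", "center", "past_end", "outside"),
    chrom = "chr1",
    start = c(900L, 1900L, 2900L, 50000L),
    end = c(1100L, 2100L, 3400L, 51000L)
  )
  pos <- relative_domain_position(arrays, domains)
  expect_equal(pos[1], 0)
  expect_equal(pos[2], 0.5)
  expect_equal(pos[3], 1) # midpoint 3150 beyond the end, clipped
  expect_true(is.na(pos[4]))
})
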