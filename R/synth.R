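#' Configuration for the synthetic chromatin landscape generator
#'
#' Defines the toy-scale study conditions every stage of the pipeline is
#' exercised against: a single-chromosome genome carrying repressive
#' domains with planted well-phased arrays of two accessibility
#' archetypes, decoy nucleosomes, an ATAC-like fragment library, gene
#' models with expression for two ordered samples, and a motif library
#' with one TF planted in the boundary windows of repressed-gene arrays.
#'
#' @param seed Master seed; per-component streams are derived from it.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param n_arrays Number of planted arrays.
#' @param array_size Range (min, max) of nucleosomes per planted array.
#' @param spacing_mean,spacing_sd Summit-to-summit spacing distribution
#'   of planted arrays (bp), truncated to stay inside the phasing range.
#' @param nuc_width Nucleosome footprint width (bp).
#' @param signal_fg,signal_bg Occupancy signal levels of planted vs decoy
#'   nucleosomes (foreground defaults to 3x background).
#' @param fuzz_fg,fuzz_bg Fuzziness levels of planted vs decoy
#'   nucleosomes (foreground constructed to sit below the global 20th
#'   percentile).
#' @param n_decoys Number of decoy nucleosomes (each violates at least
#'   one phasing criterion through its fuzziness/signal draw).
#' @param c1_frac Fraction of planted arrays given the boundary-transition
#'   (C1) accessibility archetype; the rest are accessibility-uniform (C2).
#' @param insertion_rate_bg Background Tn5 insertion events per bp.
#' @param c1_flank_boost Extra flank insertion rate for C1 arrays, as a
#'   multiple of the background rate.
#' @param c2_boost Extra uniform insertion rate over C2 arrays and their
#'   flanks, as a multiple of the background rate.
#' @param c1_asym_sd Log-scale SD of the left/right flank asymmetry of C1
#'   arrays (generates the BPS spread).
#' @param frag_len_mean,frag_len_sd ATAC fragment length distribution.
#' @param n_genes Total genes; a fraction get promoters overlapping
#'   planted arrays, the rest sit between domains (the array-absent set).
#' @param promoter_array_frac Fraction of arrays whose boundary hosts a
#'   gene promoter.
#' @param expr_base_meanlog,expr_base_sdlog Log-normal baseline
#'   expression (linear TPM-like scale).
#' @param sub_only_factor Expression factor for genes whose promoters
#'   host an array (both archetypes), relative to baseline.
#' @param repress_fold Fold-reduction applied in sample B to genes whose
#'   promoters host C2 arrays (the planted repression effect).
#' @param expr_noise_sdlog Per-sample multiplicative expression noise.
#' @param planted_tf Name of the planted TF.
#' @param n_decoy_tfs Number of unplanted decoy PWMs.
#' @param motif_length Motif length (bp).
#' @param plant_offsets Distances (bp) beyond each array edge at which
#'   motif copies are planted for repressed-gene arrays.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 17L,
                              chrom = "chrS", chrom_length = 2e6,
                              n_arrays = 40L, array_size = c(5L, 10L),
                              spacing_mean = 185, spacing_sd = 4,
                              nuc_width = 147L,
                              signal_fg = 30, signal_bg = 10,
                              fuzz_fg = 25, fuzz_bg = 60,
                              n_decoys = 1500L, c1_frac = 0.5,
                              insertion_rate_bg = 0.02,
                              c1_flank_boost = 5, c2_boost = 2,
                              c1_asym_sd = 0.08,
                              frag_len_mean = 90, frag_len_sd = 15,
                              n_genes = 200L, promoter_array_frac = 0.4,
                              expr_base_meanlog = log(100),
                              expr_base_sdlog = 0.3,
                              sub_only_factor = 0.85, repress_fold = 8,
                              expr_noise_sdlog = 0.1,
                              planted_tf = "PLANTED1", n_decoy_tfs = 7L,
                              motif_length = 10L,
                              plant_offsets = c(120L, 320L, 520L)) {
  cfg <- as.list(environment())
  stopifnot(
    length(seed) == 1, is.finite(seed),
    chrom_length > 0, n_arrays >= 0, length(array_size) == 2,
    array_size[1] >= 3, array_size[1] <= array_size[2],
    spacing_mean > 0, spacing_sd >= 0,
    c1_frac >= 0, c1_frac <= 1,
    promoter_array_frac >= 0, promoter_array_frac <= 1,
    repress_fold >= 1, insertion_rate_bg > 0
  )
  # layout feasibility: two array slots per 8 kb domain
  n_domains <- max(1L, ceiling(n_arrays / 2))
  if ((n_domains + 1) * 10000 + n_domains * 8000 > chrom_length) {
    abort("chromosome too short for the requested number of arrays")
  }
  structure(cfg, class = "simulation_config")
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

consensus_of <- function(mat) {
  c("A", "C", "G", "T")[apply(mat, 1, which.max)]
}

sharp_pwm <- function(tf, consensus, major = 0.91) {
  L <- length(consensus)
  mat <- matrix((1 - major) / 3, nrow = L, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(seq_len(L), match(consensus, c("A", "C", "G", "T")))] <- major
  new_pwm(tf, mat)
}

#' Generate a synthetic fixture bundle
#'
#' Deterministically (given the config seed) builds the full input set
#' the pipeline consumes — nucleosome calls, repressive domains, ATAC
#' fragments, genome sequence, gene models, two expression tables, and a
#' PWM library — together with truth tables recording the planted arrays,
#' their archetypes, the repressed genes and the planted motif positions.
#' One RNG stream per component is derived from the master seed so that
#' changing one component's parameters leaves the others' draws intact.
#'
#' @param config A [simulation_config()].
#' @return A `fixture_bundle` list with elements `nucleosomes`, `domains`,
#'   `fragments`, `genome`, `genes`, `expression` (list with `A`, `B`),
#'   `pwms`, `truth`, and `config`.
#' @export
simulate_landscape <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  base_seed <- as.integer(cfg$seed) %% 1000000L

  ## --- landscape stream: domains, planted arrays, decoys -----------------
  set.seed(base_seed * 10L + 1L)
  n_domains <- max(1L, ceiling(cfg$n_arrays / 2))
  dom_len <- 8000L
  gap <- (cfg$chrom_length - n_domains * dom_len) %/% (n_domains + 1)
  dom_start <- as.integer(gap + (seq_len(n_domains) - 1L) * (dom_len + gap))
  domains <- tibble(chrom = cfg$chrom, start = dom_start,
                    end = dom_start + dom_len)
  slots <- c(500L, 4500L)
  arr_rows <- list()
  for (i in seq_len(cfg$n_arrays)) {
    d <- ((i - 1L) %/% 2L) + 1L
    slot <- slots[((i - 1L) %% 2L) + 1L]
    n_nuc <- sample(cfg$array_size[1]:cfg$array_size[2], 1)
    spac <- pmin(pmax(rnorm(n_nuc - 1, cfg$spacing_mean, cfg$spacing_sd),
                      cfg$spacing_mean - 20), cfg$spacing_mean + 20)
    summit <- as.integer(dom_start[d] + slot +
                           floor(cfg$nuc_width / 2) + cumsum(c(0, spac)))
    arr_rows[[i]] <- tibble(
      planted_id = sprintf("planted_%02d", i),
      chrom = cfg$chrom, summit = summit,
      start = summit - floor(cfg$nuc_width / 2),
      end = summit - floor(cfg$nuc_width / 2) + cfg$nuc_width,
      signal = cfg$signal_fg * rlnorm(n_nuc, 0, 0.08),
      fuzziness = cfg$fuzz_fg * rlnorm(n_nuc, 0, 0.08)
    )
  }
  planted <- bind_rows(arr_rows)
  truth_arrays <- planted |>
    group_by(.data$planted_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), n_nucleosomes = n(), .groups = "drop")
  archetype <- rep("C2", cfg$n_arrays)
  n_c1 <- round(cfg$c1_frac * cfg$n_arrays)
  if (n_c1 > 0) archetype[sample.int(cfg$n_arrays, n_c1)] <- "C1"
  truth_arrays$archetype <- archetype[match(truth_arrays$planted_id,
                                            sprintf("planted_%02d",
                                                    seq_len(cfg$n_arrays)))]
  # decoys: outside planted arrays +- 400 bp; drawn with low signal and
  # high fuzziness so each violates at least one phasing criterion
  excl <- IRanges::reduce(IRanges::IRanges(truth_arrays$start - 400L,
                                           truth_arrays$end + 400L))
  half <- floor(cfg$nuc_width / 2)
  decoy_summits <- integer(0)
  while (length(decoy_summits) < cfg$n_decoys) {
    cand <- sample.int(cfg$chrom_length - cfg$nuc_width, cfg$n_decoys) + half
    bad <- IRanges::overlapsAny(IRanges::IRanges(cand, cand), excl)
    decoy_summits <- c(decoy_summits, cand[!bad])
  }
  decoy_summits <- sort(decoy_summits[seq_len(cfg$n_decoys)])
  decoys <- tibble(
    chrom = cfg$chrom, summit = decoy_summits,
    start = decoy_summits - half, end = decoy_summits - half + cfg$nuc_width,
    signal = cfg$signal_bg * rlnorm(cfg$n_decoys, 0, 0.3),
    fuzziness = cfg$fuzz_bg * rlnorm(cfg$n_decoys, 0, 0.3)
  )
  nucleosomes <- bind_rows(select(planted, -"planted_id"), decoys) |>
    arrange(.data$chrom, .data$start)

  ## --- accessibility stream: ATAC fragments ------------------------------
  set.seed(base_seed * 10L + 2L)
  frag_from_rate <- function(s, e, rate) {
    if (e <= s || rate <= 0) return(integer(0))
    n <- rpois(1, (e - s) * rate / 2) # each fragment: two insertion events
    if (n == 0) return(integer(0))
    sort(sample.int(e - s, n, replace = TRUE) + s - 1L)
  }
  starts <- frag_from_rate(0L, cfg$chrom_length, cfg$insertion_rate_bg)
  for (i in seq_len(nrow(truth_arrays))) {
    a <- truth_arrays[i, ]
    if (a$archetype == "C1") {
      asym <- exp(rnorm(1, 0, cfg$c1_asym_sd))
      starts <- c(starts,
                  frag_from_rate(max(0L, a$start - 1000L), a$start,
                                 cfg$insertion_rate_bg * cfg$c1_flank_boost * asym),
                  frag_from_rate(a$end, a$end + 1000L,
                                 cfg$insertion_rate_bg * cfg$c1_flank_boost / asym))
    } else {
      starts <- c(starts,
                  frag_from_rate(max(0L, a$start - 1000L), a$end + 1000L,
                                 cfg$insertion_rate_bg * cfg$c2_boost))
    }
  }
  lens <- as.integer(pmin(pmax(round(rnorm(length(starts), cfg$frag_len_mean,
                                           cfg$frag_len_sd)), 40), 160))
  fragments <- tibble(chrom = cfg$chrom, start = as.integer(starts),
                      end = as.integer(starts) + lens) |>
    mutate(length = .data$end - .data$start) |>
    arrange(.data$start)

  ## --- expression stream: genes, promoters, two samples -------------------
  set.seed(base_seed * 10L + 3L)
  n_prom <- round(cfg$promoter_array_frac * cfg$n_arrays)
  prom_arrays <- if (n_prom > 0) {
    # balanced across archetypes so both exclusive gene sets are non-empty
    c1_ids <- truth_arrays$planted_id[truth_arrays$archetype == "C1"]
    c2_ids <- truth_arrays$planted_id[truth_arrays$archetype == "C2"]
    n1 <- min(length(c1_ids), round(n_prom / 2))
    n2 <- min(length(c2_ids), n_prom - n1)
    c(sample(c1_ids, n1), sample(c2_ids, n2))
  } else {
    character(0)
  }
  gene_rows <- list()
  for (j in seq_along(prom_arrays)) {
    a <- truth_arrays[truth_arrays$planted_id == prom_arrays[j], ]
    tss <- a$end + 500L # promoter [tss-1000, tss+1000) overlaps the array
    gene_rows[[j]] <- tibble(
      gene_id = sprintf("gene_prom_%03d", j), chrom = cfg$chrom,
      start = tss, end = tss + 2000L, strand = "+", tss = tss,
      host_array = a$planted_id, host_archetype = a$archetype
    )
  }
  n_absent <- cfg$n_genes - length(prom_arrays)
  # absent genes live midway between domains, > 2 kb from any array
  gap_mids <- as.integer(round((c(0L, dom_start + dom_len) +
                                  c(dom_start, cfg$chrom_length)) / 2))
  slots_abs <- gap_mids[1 + (seq_len(n_absent) %% length(gap_mids))] +
    as.integer(200L * (seq_len(n_absent) %/% length(gap_mids)))
  gene_rows[[length(gene_rows) + 1L]] <- tibble(
    gene_id = sprintf("gene_bg_%03d", seq_len(n_absent)), chrom = cfg$chrom,
    start = slots_abs, end = slots_abs + 2000L, strand = "+",
    tss = slots_abs, host_array = NA_character_,
    host_archetype = NA_character_
  )
  genes <- bind_rows(gene_rows)
  baseline <- rlnorm(cfg$n_genes, cfg$expr_base_meanlog, cfg$expr_base_sdlog)
  factor_a <- ifelse(is.na(genes$host_archetype), 1, cfg$sub_only_factor)
  factor_b <- factor_a / ifelse(!is.na(genes$host_archetype) &
                                  genes$host_archetype == "C2",
                                cfg$repress_fold, 1)
  expr_a <- tibble(gene_id = genes$gene_id,
                   expression = baseline * factor_a *
                     rlnorm(cfg$n_genes, 0, cfg$expr_noise_sdlog))
  expr_b <- tibble(gene_id = genes$gene_id,
                   expression = baseline * factor_b *
                     rlnorm(cfg$n_genes, 0, cfg$expr_noise_sdlog))
  repressed_genes <- genes$gene_id[!is.na(genes$host_archetype) &
                                     genes$host_archetype == "C2"]

  ## --- motif stream: genome sequence, PWM library, planted copies ---------
  set.seed(base_seed * 10L + 4L)
  genome_chars <- rand_dna(cfg$chrom_length)
  consensi <- replicate(cfg$n_decoy_tfs + 1L, rand_dna(cfg$motif_length),
                        simplify = FALSE)
  pwms <- c(
    list(sharp_pwm(cfg$planted_tf, consensi[[1]])),
    map(seq_len(cfg$n_decoy_tfs), function(i) {
      sharp_pwm(sprintf("DECOY%d", i), consensi[[i + 1L]])
    })
  )
  planted_positions <- list()
  target_arrays <- truth_arrays[truth_arrays$planted_id %in%
                                  genes$host_array[genes$host_archetype %in% "C2"], ]
  for (i in seq_len(nrow(target_arrays))) {
    a <- target_arrays[i, ]
    for (off in cfg$plant_offsets) {
      for (pos0 in c(a$end + off, a$start - off - cfg$motif_length)) {
        if (pos0 >= 0 && pos0 + cfg$motif_length <= cfg$chrom_length) {
          genome_chars[(pos0 + 1L):(pos0 + cfg$motif_length)] <- consensi[[1]]
          planted_positions[[length(planted_positions) + 1L]] <- tibble(
            planted_id = a$planted_id, chrom = cfg$chrom, start = pos0,
            end = pos0 + cfg$motif_length
          )
        }
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- cfg$chrom

  structure(
    list(
      nucleosomes = nucleosomes, domains = domains, fragments = fragments,
      genome = genome, genes = genes[, c("gene_id", "chrom", "start", "end",
                                         "strand", "tss")],
      expression = list(A = expr_a, B = expr_b), pwms = pwms,
      truth = list(
        arrays = truth_arrays,
        genes = genes,
        repressed_genes = repressed_genes,
        planted_tf = cfg$planted_tf,
        motif_positions = bind_rows(planted_positions)
      ),
      config = cfg
    ),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> %s (%d bp): %d nucleosomes, %d planted arrays, %d fragments, %d genes, %d PWMs\n",
    x$config$chrom, x$config$chrom_length, nrow(x$nucleosomes),
    nrow(x$truth$arrays), nrow(x$fragments), nrow(x$genes), length(x$pwms)
  ))
  invisible(x)
}

#' Apply a standard perturbation to a fixture bundle
#'
#' Used by invariance tests: `shuffle_rows` permutes the nucleosome table
#' rows (finders must be order-independent), `rescale_depth` duplicates
#' every ATAC fragment (CPM normalization must cancel depth), and
#' `drop_sample` removes sample B's expression (downstream stages must
#' fail loudly).
#'
#' @param bundle A `fixture_bundle`.
#' @param operation One of `"shuffle_rows"`, `"rescale_depth"`,
#'   `"drop_sample"`.
#' @return The perturbed bundle.
#' @export
perturb_bundle <- function(bundle,
                           operation = c("shuffle_rows", "rescale_depth",
                                         "drop_sample")) {
  operation <- match.arg(operation)
  out <- bundle
  if (operation == "shuffle_rows") {
    set.seed(bundle$config$seed + 999L)
    out$nucleosomes <- bundle$nucleosomes[sample.int(nrow(bundle$nucleosomes)), ]
  } else if (operation == "rescale_depth") {
    out$fragments <- bind_rows(bundle$fragments, bundle$fragments)
  } else {
    out$expression$B <- NULL
  }
  out
}

#' Write a fixture bundle to disk in standard formats
#'
#' Emits the DANPOS-dialect nucleosome table (1-based closed), domain and
#' fragment BEDs, genome FASTA, a GTF of gene models, per-sample
#' expression TSVs, the JASPAR-style PWM file, and the truth tables. Every
#' emitted file is read back with the package's own readers and checked
#' against the in-memory bundle.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nucleosomes = file.path(dir, "nucleosomes.tsv"),
    domains = file.path(dir, "domains.bed"),
    fragments = file.path(dir, "fragments.bed"),
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gtf"),
    expression_a = file.path(dir, "expression_A.tsv"),
    expression_b = file.path(dir, "expression_B.tsv"),
    pwms = file.path(dir, "motifs.jaspar"),
    truth_arrays = file.path(dir, "truth_arrays.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  nuc_out <- tibble(
    chr = bundle$nucleosomes$chrom,
    start = bundle$nucleosomes$start + 1L,
    end = bundle$nucleosomes$end,
    smt_pos = bundle$nucleosomes$summit + 1L,
    smt_value = bundle$nucleosomes$signal,
    fuzziness_score = bundle$nucleosomes$fuzziness
  )
  readr::write_tsv(nuc_out, paths[["nucleosomes"]])
  readr::write_tsv(bundle$domains, paths[["domains"]], col_names = FALSE)
  readr::write_tsv(bundle$fragments[, c("chrom", "start", "end")],
                   paths[["fragments"]], col_names = FALSE)
  Biostrings::writeXStringSet(bundle$genome, paths[["genome"]])
  gtf <- sprintf(
    '%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    bundle$genes$chrom, bundle$genes$start + 1L, bundle$genes$end,
    bundle$genes$strand, bundle$genes$gene_id
  )
  writeLines(gtf, paths[["genes"]])
  readr::write_tsv(bundle$expression$A, paths[["expression_a"]])
  readr::write_tsv(bundle$expression$B, paths[["expression_b"]])
  pwm_lines <- unlist(map(bundle$pwms, function(p) {
    counts <- round(t(p$matrix) * 1000)
    c(sprintf(">%s %s", p$tf, p$tf),
      sprintf("%s  [ %s ]", c("A", "C", "G", "T"),
              apply(counts, 1, paste, collapse = " ")))
  }))
  writeLines(pwm_lines, paths[["pwms"]])
  readr::write_tsv(bundle$truth$arrays, paths[["truth_arrays"]])
  readr::write_tsv(bundle$truth$genes, paths[["truth_genes"]])

  # round-trip assertions against the package's own readers
  stopifnot(
    nrow(read_nucleosome_table(paths[["nucleosomes"]])) ==
      nrow(bundle$nucleosomes),
    nrow(read_bed(paths[["domains"]])) == nrow(bundle$domains),
    nrow(read_fragments(paths[["fragments"]])) == nrow(bundle$fragments),
    nrow(read_expression(paths[["expression_a"]])) ==
      nrow(bundle$expression$A),
    length(read_pwms(paths[["pwms"]])) == length(bundle$pwms),
    nrow(read_gene_models(paths[["genes"]])) == nrow(bundle$genes)
  )
  invisible(paths)
}
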