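#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with the
#' package defaults. Unknown names in `...` are rejected so typos fail
#' fast; the validated configuration is serialized verbatim into the run
#' manifest.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    method = "seed_extend",
    criteria = phasing_criteria(),
    shift_plus = 4L, shift_minus = 5L,
    n_bins = 100L, flank_bp = 1000L, eps = 1e-9,
    k_range = 2:6, seed = 17L, n_starts = 10L,
    min_overlap = 0.5,
    promoter_upstream = 1000L, promoter_downstream = 1000L,
    lfc_threshold = 1, pseudocount = 1,
    promoter_frac_threshold = 0.2,
    boundary_window_bp = 200L, boundary_max_dist = 1000L,
    motif_p = 1e-4, bg_ratio = 10L, alpha = 0.05,
    include_linker = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(
    inherits(cfg$criteria, "phasing_criteria"),
    cfg$method %in% c("seed_extend", "sliding"),
    cfg$eps > 0, cfg$alpha > 0, cfg$alpha < 1,
    cfg$min_overlap > 0, cfg$min_overlap <= 1,
    cfg$promoter_frac_threshold >= 0, cfg$promoter_frac_threshold <= 1,
    all(cfg$k_range >= 1), cfg$bg_ratio >= 1
  )
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on a fixture bundle
#'
#' Executes the four stages in order on two ordered samples A and B that
#' share a nucleosome landscape and ATAC library but differ in
#' expression: (1) well-phased array detection inside repressive domains;
#' (2) accessibility profiling and subtype selection; (3) union regions,
#' state encoding and the A-to-B transition matrix; (4) repressive
#' efficacy, boundary-window motif enrichment and repressor scoring for
#' sample B (the final state of the contrast). The foreground for each
#' subtype's motif analysis is the transition-derived set of arrays whose
#' union regions end in that subtype and whose promoter genes are
#' downregulated, falling back to all subtype arrays when the subtype's
#' promoter-overlap fraction does not exceed the configured threshold.
#'
#' @param bundle A `fixture_bundle` from [simulate_landscape()] (or an
#'   equivalent list built from files via the `genome_io` readers).
#' @param config A [run_config()].
#' @return A `nurepress_run` list with each stage's outputs and a
#'   manifest (package version, config, seeds, stage timings).
#' @export
run_all <- function(bundle, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  chrom_sizes <- setNames(Biostrings::width(bundle$genome),
                          names(bundle$genome))

  ## stage 1: arrays (shared landscape -> same arrays in both samples)
  arrays <- find_arrays(bundle$nucleosomes, config$criteria,
                        domains = bundle$domains, method = config$method)
  if (nrow(arrays) < 6) abort("stage find-arrays: too few arrays detected")

  ## stage 2: accessibility subtyping
  track <- cpm_normalize(extract_insertions(bundle$fragments,
                                            config$shift_plus,
                                            config$shift_minus))
  profiles <- profile_arrays(arrays, track, n_bins = config$n_bins,
                             flank_bp = config$flank_bp,
                             chrom_sizes = chrom_sizes)
  features <- array_accessibility(profiles, eps = config$eps)
  subtypes <- select_subtypes(features, k_range = config$k_range,
                              seed = config$seed, n_starts = config$n_starts)
  arrays <- left_join(arrays,
                      subtypes$assignments[, c("array_id", "subtype")],
                      by = "array_id")

  ## stage 3: union regions, states, transition matrix
  samples <- c("A", "B")
  labels <- bind_rows(map(samples, function(s) {
    tibble(sample_id = s, array_id = arrays$array_id,
           subtype = arrays$subtype)
  }))
  regions <- build_union_regions(
    mutate(labels, chrom = rep(arrays$chrom, length(samples)),
           start = rep(arrays$start, length(samples)),
           end = rep(arrays$end, length(samples))),
    min_overlap = config$min_overlap
  )
  states <- encode_states(regions, labels, samples = samples)
  transitions <- transition_matrix(states, "A", "B")

  ## stage 4: repressor scoring on sample B
  if (is.null(bundle$expression$A) || is.null(bundle$expression$B)) {
    abort("stage score: both samples' expression tables are required")
  }
  promoters <- promoters_from_genes(bundle$genes,
                                    upstream = config$promoter_upstream,
                                    downstream = config$promoter_downstream)
  q_arrays <- build_promoter_matrix(arrays, promoters)
  q_regions <- build_promoter_matrix(regions, promoters)
  contrast <- expression_contrast(bundle$expression$A, bundle$expression$B,
                                  lfc_threshold = config$lfc_threshold,
                                  pseudocount = config$pseudocount)
  d <- setNames(contrast$down, contrast$gene_id)
  re_tbl <- repressive_efficacy(bundle$expression$B, q_arrays,
                                arrays[, c("array_id", "subtype")]) |>
    mutate(sample_id = "B", .before = 1)

  arrays <- detect_phasing_boundary(arrays, bundle$nucleosomes)
  region_of_b <- bind_rows(map2(regions$region_id, regions$members,
                                function(rid, m) mutate(m, region_id = rid))) |>
    filter(.data$sample_id == "B")
  state_b <- filter(states, .data$sample_id == "B")
  mp_rows <- list()
  fg_info <- list()
  for (cc in sort(unique(arrays$subtype))) {
    x <- tibble(region_id = state_b$region_id,
                x = as.integer(state_b$state == cc))
    sub_arr <- filter(arrays, .data$subtype == cc) |>
      left_join(region_of_b[, c("array_id", "region_id")], by = "array_id") |>
      mutate(overlaps_promoter = rowSums(
        q_arrays[.data$array_id, , drop = FALSE]) > 0)
    sel <- select_foreground(x, q_regions, d,
                             sub_arr[, c("array_id", "region_id",
                                         "overlaps_promoter")],
                             config$promoter_frac_threshold)
    fg_arrays <- filter(arrays, .data$array_id %in% sel$foreground_arrays)
    fg_info[[cc]] <- sel
    if (nrow(fg_arrays) == 0) next
    fg_regions <- bind_rows(map(seq_len(nrow(fg_arrays)), function(i) {
      extract_scan_regions(fg_arrays[i, ],
                           window_bp = config$boundary_window_bp,
                           max_dist = config$boundary_max_dist,
                           chrom_size = chrom_sizes[[fg_arrays$chrom[i]]])
    }))
    fg_regions$region_id <- sprintf("%s_%d", fg_regions$region_id,
                                    seq_len(nrow(fg_regions)))
    bg_regions <- sample_background(fg_regions, bundle$genome,
                                    ratio = config$bg_ratio,
                                    seed = config$seed + 101L)
    fg_hits <- scan_motifs(fg_regions, bundle$pwms, bundle$genome,
                           p = config$motif_p) |>
      left_join(fg_regions[, c("region_id", "label")], by = "region_id")
    bg_hits <- scan_motifs(bg_regions, bundle$pwms, bundle$genome,
                           p = config$motif_p) |>
      left_join(bg_regions[, c("region_id", "label")], by = "region_id")
    enr <- motif_enrichment(fg_hits, bg_hits)
    mp <- motif_potential(enr, include_linker = config$include_linker)
    if (nrow(mp) > 0) {
      mp_rows[[cc]] <- mutate(mp, sample_id = "B", subtype = cc,
                              .before = 1)
    }
  }
  mp_tbl <- bind_rows(mp_rows)
  scores <- if (nrow(mp_tbl) > 0) {
    score_and_rank(re_tbl, mp_tbl[, c("sample_id", "subtype", "tf", "mp")],
                   alpha = config$alpha)
  } else {
    tibble()
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nurepress")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_arrays = nrow(arrays), k = subtypes$k,
    samples = samples,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(
    list(arrays = arrays, profiles = profiles, features = features,
         subtypes = subtypes, regions = regions, states = states,
         transitions = transitions, contrast = contrast, re = re_tbl,
         foreground = fg_info, mp = mp_tbl, scores = scores,
         config = config, manifest = manifest),
    class = "nurepress_run"
  )
}

#' @export
print.nurepress_run <- function(x, ...) {
  cat(sprintf(
    "<nurepress_run> %d arrays, k = %d subtypes, %d union regions, %d scored TFs\n",
    nrow(x$arrays), x$subtypes$k, nrow(x$regions),
    length(unique(x$scores$tf))
  ))
  invisible(x)
}

#' Write the outputs of a pipeline run to a directory
#'
#' Emits the subtyped arrays BED, the feature and score TSVs, the
#' transition matrix, and the run-metadata JSON manifest.
#'
#' @param run A `nurepress_run` object.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_arrays_bed(run$arrays, file.path(dir, "arrays.bed"))
  write_results(run$features, file.path(dir, "features.tsv"))
  if (nrow(run$scores) > 0) {
    write_results(run$scores, file.path(dir, "scores.tsv"))
  }
  tm <- as_tibble(as.data.frame.matrix(run$transitions), rownames = "state_a")
  write_results(tm, file.path(dir, "transitions.tsv"))
  write_run_metadata(run$manifest, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}
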