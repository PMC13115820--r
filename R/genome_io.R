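#' Read a DANPOS-style nucleosome call table
#'
#' Parses a tab-separated nucleosome table into the package's canonical
#' representation: one row per positioned nucleosome with its occupancy
#' signal and positional fuzziness. DANPOS emits 1-based closed coordinates;
#' these are converted to the 0-based half-open convention used throughout
#' the package (set `one_based = FALSE` for input already in BED-style
#' coordinates).
#'
#' @param path Path to a tab-separated file with a header line.
#' @param col_map Named character vector mapping canonical names
#'   (`chrom`, `start`, `end`, `summit`, `signal`, `fuzziness`) to the
#'   column names used in the file. The default matches the DANPOS dialect.
#' @param one_based Logical; input coordinates are 1-based closed and are
#'   converted on read (default `TRUE`).
#' @return A tibble with columns `chrom`, `start`, `end`, `summit`,
#'   `signal`, `fuzziness`, sorted by `(chrom, start)`.
#' @export
read_nucleosome_table <- function(path,
                                  col_map = c(
                                    chrom = "chr", start = "start",
                                    end = "end", summit = "smt_pos",
                                    signal = "smt_value",
                                    fuzziness = "fuzziness_score"
                                  ),
                                  one_based = TRUE) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stop_missing_cols(raw, unname(col_map), sprintf("nucleosome table '%s'", path))
  out <- tibble(
    chrom = raw[[col_map[["chrom"]]]],
    start = raw[[col_map[["start"]]]],
    end = raw[[col_map[["end"]]]],
    summit = raw[[col_map[["summit"]]]],
    signal = raw[[col_map[["signal"]]]],
    fuzziness = raw[[col_map[["fuzziness"]]]]
  )
  for (col in c("start", "end", "summit", "signal", "fuzziness")) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !is.na(out[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value in column '%s' at line %d of '%s'",
        col_map[[col]], bad[1] + 1L, path
      ))
    }
    out[[col]] <- parsed
  }
  out <- mutate(out,
    start = as.integer(.data$start) - if (one_based) 1L else 0L,
    end = as.integer(.data$end),
    summit = as.integer(.data$summit) - if (one_based) 1L else 0L
  )
  validate_nucleosomes(out)
  arrange(out, .data$chrom, .data$start)
}

validate_nucleosomes <- function(nucs) {
  stop_missing_cols(nucs, c("chrom", "start", "end", "summit", "signal", "fuzziness"),
                    "nucleosome table")
  if (any(nucs$start >= nucs$end)) abort("nucleosome with start >= end")
  if (any(nucs$summit < nucs$start | nucs$summit >= nucs$end)) {
    abort("nucleosome summit outside its interval")
  }
  if (any(nucs$signal < 0) || any(nucs$fuzziness < 0)) {
    abort("negative signal or fuzziness")
  }
  invisible(nucs)
}

#' Read genomic intervals from a BED file
#'
#' @param path Path to a BED3+ file (no header).
#' @return A tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$score <- suppressWarnings(as.numeric(raw[[5]]))
  if (ncol(raw) >= 6) out$strand <- as.character(raw[[6]])
  arrange(out, .data$chrom, .data$start)
}

#' Read sequencing fragments from a BED or BEDPE file
#'
#' Rows with `start >= end` are rejected; the number of rejected rows is
#' attached as the `n_rejected` attribute and reported as a warning. For
#' BEDPE input the fragment spans the outermost coordinates of the two ends
#' (both mates are required to be on the same chromosome).
#'
#' @param path Path to a BED3+ or BEDPE file.
#' @param format `"auto"` (default), `"bed"` or `"bedpe"`.
#' @return A tibble with `chrom`, `start`, `end`, `length`.
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (nrow(raw) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  is_bedpe <- format == "bedpe" ||
    (format == "auto" && ncol(raw) >= 6 &&
       is.character(raw[[4]]) && !anyNA(suppressWarnings(as.integer(raw[[5]]))) &&
       !anyNA(suppressWarnings(as.integer(raw[[6]]))))
  if (is_bedpe) {
    same_chrom <- as.character(raw[[1]]) == as.character(raw[[4]])
    if (!all(same_chrom)) {
      warn(sprintf("%d inter-chromosomal BEDPE rows dropped", sum(!same_chrom)))
      raw <- raw[same_chrom, ]
    }
    out <- tibble(
      chrom = as.character(raw[[1]]),
      start = pmin(as.integer(raw[[2]]), as.integer(raw[[5]])),
      end = pmax(as.integer(raw[[3]]), as.integer(raw[[6]]))
    )
  } else {
    out <- tibble(
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]])
    )
  }
  bad <- out$start >= out$end
  if (any(bad)) {
    warn(sprintf("%d fragment row(s) with start >= end rejected", sum(bad)))
    out <- out[!bad, ]
  }
  out <- mutate(out, length = .data$end - .data$start)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Extract Tn5 insertion events from fragments
#'
#' Each fragment contributes two insertion events, one per end, with the
#' standard ATAC-seq offsets applied (+4 on the plus end, -5 on the minus
#' end by default; use 0/0 for unshifted cut sites). The library size is
#' twice the fragment count, counting events that are subsequently dropped
#' for falling below position zero.
#'
#' @param fragments Tibble from [read_fragments()].
#' @param shift_plus,shift_minus Integer offsets applied to the fragment
#'   start (`start + shift_plus`) and end (`end - shift_minus`).
#' @return An insertion track: a tibble with `chrom`, `pos`, `count` and
#'   attributes `library_size` and `normalized`.
#' @export
extract_insertions <- function(fragments, shift_plus = 4L, shift_minus = 5L) {
  if (nrow(fragments) == 0) abort("no fragments to extract insertions from")
  events <- tibble(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start + as.integer(shift_plus),
            fragments$end - as.integer(shift_minus))
  )
  n_neg <- sum(events$pos < 0)
  if (n_neg > 0) {
    warn(sprintf("%d insertion event(s) below position 0 dropped", n_neg))
    events <- filter(events, .data$pos >= 0)
  }
  track <- events |>
    dplyr::count(.data$chrom, .data$pos, name = "count") |>
    arrange(.data$chrom, .data$pos)
  track$count <- as.numeric(track$count)
  new_insertion_track(track, library_size = 2L * nrow(fragments),
                      normalized = FALSE)
}

new_insertion_track <- function(tbl, library_size, normalized) {
  attr(tbl, "library_size") <- library_size
  attr(tbl, "normalized") <- normalized
  class(tbl) <- unique(c("insertion_track", class(tbl)))
  tbl
}

#' @export
print.insertion_track <- function(x, ...) {
  cat(sprintf(
    "<insertion_track> %d positions, library size %d, %s\n",
    nrow(x), attr(x, "library_size"),
    if (isTRUE(attr(x, "normalized"))) "CPM-normalized" else "raw counts"
  ))
  NextMethod()
}

#' Read gene models from a GTF/GFF file
#'
#' Uses gene features when present, otherwise derives one gene per
#' `gene_id` from the first transcript in file order. Genes without strand
#' are skipped with a warning. The TSS is the strand-aware 5' end in
#' 0-based coordinates.
#'
#' @param path Path to a GTF/GFF3 file.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  types <- tolower(as.character(md$type %||% ""))
  if (any(types == "gene")) gr <- gr[types == "gene"]
  md <- S4Vectors::mcols(gr)
  gene_id <- as.character(md$gene_id %||% md$ID %||% md$Name)
  if (all(is.na(gene_id))) abort("no gene_id attribute found in GTF/GFF")
  tbl <- tibble(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  no_strand <- tbl$strand %in% c("*", ".")
  if (any(no_strand)) {
    warn(sprintf("%d gene(s) without strand skipped", sum(no_strand)))
    tbl <- tbl[!no_strand, ]
  }
  tbl <- distinct(tbl, .data$gene_id, .keep_all = TRUE)
  mutate(tbl, tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
}

#' Derive promoter windows from gene models
#'
#' One promoter per gene id: `[tss - upstream, tss + downstream)` on the
#' plus strand, with up/downstream roles mirrored on the minus strand, and
#' clipped at position 0.
#'
#' @param genes Tibble from [read_gene_models()] (or equivalent with
#'   `gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream,downstream Window extents in bp around the TSS.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `tss`, `strand`.
#' @export
promoters_from_genes <- function(genes, upstream = 1000L, downstream = 1000L) {
  stop_missing_cols(genes, c("gene_id", "chrom", "strand", "tss"), "gene models")
  genes <- distinct(genes, .data$gene_id, .keep_all = TRUE)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(pmax(0L, start)),
    end = as.integer(end),
    tss = as.integer(genes$tss),
    strand = genes$strand
  )
}

#' @rdname promoters_from_genes
#' @param path Path to a GTF/GFF3 file.
#' @export
promoters_from_gtf <- function(path, upstream = 1000L, downstream = 1000L) {
  promoters_from_genes(read_gene_models(path), upstream, downstream)
}

#' Read position weight matrices from a JASPAR-style text file
#'
#' Accepts the JASPAR format (`>id name` header followed by four `A/C/G/T`
#' rows, with or without brackets). Count matrices are normalized
#' position-wise to probabilities.
#'
#' @param path Path to the motif file.
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @return A list of `pwm` objects, each with `tf`, `matrix` (L x 4
#'   probability matrix, columns A/C/G/T) and `background`.
#' @export
read_pwms <- function(path, background = rep(0.25, 4)) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort("no '>' motif headers found")
  bounds <- c(headers, length(lines) + 1L)
  pwms <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[headers[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    tf <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(rows) != 4) {
      abort(sprintf("motif '%s': expected 4 base rows, found %d", tf, length(rows)))
    }
    mat <- t(do.call(rbind, rows)) # L x 4
    colnames(mat) <- c("A", "C", "G", "T")
    mat <- mat / rowSums(mat)
    pwms[[i]] <- new_pwm(tf, mat, background)
  }
  pwms
}

new_pwm <- function(tf, matrix, background = rep(0.25, 4)) {
  stopifnot(ncol(matrix) == 4, all(abs(rowSums(matrix) - 1) < 1e-6))
  structure(list(tf = tf, matrix = matrix, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d\n", x$tf, nrow(x$matrix)))
  invisible(x)
}

#' Read a per-sample expression table
#'
#' @param path Tab-separated file with columns `gene_id` and `expression`
#'   (header required; extra columns ignored).
#' @return A tibble with `gene_id`, `expression`.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  stop_missing_cols(raw, c("gene_id", "expression"),
                    sprintf("expression table '%s'", path))
  dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene id(s) in '%s': %s", path,
                  paste(head(dup, 10), collapse = ", ")))
  }
  if (any(!is.finite(raw$expression))) abort("non-finite expression values")
  select(raw, "gene_id", "expression")
}

#' Write a results table as TSV
#'
#' Numeric columns are serialized at full precision so a write/read
#' round-trip reproduces values to better than 1e-9.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_results <- function(rows, path) {
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Write phased arrays as BED6+
#'
#' Columns: chrom, start, end, array id, mean signal, strand (`.`), then
#' `n_nucleosomes`, `mean_spacing`, `spacing_cv` and (when present)
#' `subtype`.
#'
#' @param arrays Arrays tibble from [find_arrays()].
#' @param path Output path.
#' @export
write_arrays_bed <- function(arrays, path) {
  out <- tibble(
    chrom = arrays$chrom, start = arrays$start, end = arrays$end,
    name = arrays$array_id, score = round(arrays$mean_signal, 4),
    strand = ".",
    n_nucleosomes = arrays$n_nucleosomes,
    mean_spacing = round(arrays$mean_spacing, 4),
    spacing_cv = round(arrays$spacing_cv, 6)
  )
  if ("subtype" %in% names(arrays)) out$subtype <- arrays$subtype
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Parse a HOMER knownResults.txt file
#'
#' Adapter for using precomputed HOMER known-motif enrichment as the motif
#' backend: extracts the TF name and p-value columns.
#'
#' @param path Path to a HOMER `knownResults.txt` file.
#' @return A tibble with `tf`, `p`, and `log_p`.
#' @export
read_homer_known_results <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  name_col <- grep("Motif Name", names(raw), value = TRUE)[1]
  p_col <- grep("^P-value|^p-value", names(raw), value = TRUE)[1]
  logp_col <- grep("Log P-value", names(raw), value = TRUE)[1]
  if (is.na(name_col) || (is.na(p_col) && is.na(logp_col))) {
    abort("not a recognizable HOMER knownResults file")
  }
  tf <- stringr::str_split_fixed(raw[[name_col]], "[/(]", 2)[, 1]
  log_p <- if (!is.na(logp_col)) as.numeric(raw[[logp_col]]) else
    log(as.numeric(raw[[p_col]]))
  tibble(tf = tf, p = exp(pmin(log_p, 0)), log_p = log_p)
}

#' Write run metadata as JSON
#'
#' @param metadata Named list of parameters, seeds and versions.
#' @param path Output path.
#' @export
write_run_metadata <- function(metadata, path) {
  jsonlite::write_json(metadata, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
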