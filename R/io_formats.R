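#' Read a per-read poly(A) tail table (nanopolish-polya dialect)
#'
#' Parses a tab-separated table of per-read poly(A) tail-length estimates as
#' emitted by the nanopolish `polya` pipeline. The mandatory columns are
#' `readname`, `contig`, `polya_length` and `qc_tag`; the full ten-column
#' nanopolish output (with `position`, `leader_start`, `adapter_start`,
#' `polya_start`, `transcript_start`, `read_rate`) is accepted and the extra
#' columns are ignored. Optional `sample_id` and `condition` columns (written
#' by [write_polya_table()]) are carried through when present.
#'
#' QC tags outside the recognised set (`PASS`, `NOREGION`, `SUFFCLIP`,
#' `ADAPTER`, `READ_FAILED_LOAD`) are mapped to `OTHER` and treated as
#' non-PASS, which tolerates tag drift between tool versions.
#'
#' @param path Path to a UTF-8, tab-separated, '.'-decimal table with a
#'   header row.
#' @param require_pass If `TRUE`, only rows whose `qc_tag` is exactly
#'   `"PASS"` are returned; the filter is idempotent and never increases the
#'   row count. Downstream tail profiling assumes PASS-filtered reads.
#' @return A tibble with one row per retained read and columns `read_id`,
#'   `transcript_id`, `sample_id`, `condition`, `polya_length`, `qc_tag`,
#'   preserving the input row order.
#' @seealso [write_polya_table()], [build_tail_profiles()]
#' @export
read_polya_table <- function(path, require_pass = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  mandatory <- c("readname", "contig", "polya_length", "qc_tag")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stopf("poly(A) table '%s' is missing mandatory column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  len <- suppressWarnings(as.numeric(raw$polya_length))
  bad <- which(is.na(len))
  if (length(bad) > 0) {
    # +1 for the header line, so the number matches the file
    stopf("non-numeric polya_length value '%s' at line %d of '%s'",
          raw$polya_length[bad[1]], bad[1] + 1L, path)
  }
  if (any(len < 0)) {
    stopf("negative polya_length at line %d of '%s'",
          which(len < 0)[1] + 1L, path)
  }
  qc <- ifelse(raw$qc_tag %in% QC_TAGS, raw$qc_tag, "OTHER")
  out <- tibble::tibble(
    read_id = raw$readname,
    transcript_id = raw$contig,
    sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else
      NA_character_,
    condition = if ("condition" %in% names(raw)) raw$condition else
      NA_character_,
    polya_length = len,
    qc_tag = qc
  )
  dup <- duplicated(out[, c("read_id", "sample_id")])
  if (any(dup)) {
    stopf("duplicated (read_id, sample_id) pair '%s' in '%s'",
          out$read_id[which(dup)[1]], path)
  }
  if (isTRUE(require_pass)) out <- out[out$qc_tag == "PASS", ]
  out
}

#' Write a per-read poly(A) tail table
#'
#' Writes reads in the tab-separated dialect accepted by
#' [read_polya_table()], including the `sample_id` and `condition` columns so
#' that a round trip reproduces the table field for field.
#'
#' @param reads Tibble of reads as returned by [read_polya_table()] or
#'   [simulate_tail_reads()]. May be empty (a header-only file is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polya_table <- function(reads, path) {
  out <- tibble::tibble(
    readname = as.character(reads$read_id),
    contig = as.character(reads$transcript_id),
    polya_length = as.numeric(reads$polya_length),
    qc_tag = as.character(reads$qc_tag),
    sample_id = as.character(reads$sample_id),
    condition = as.character(reads$condition)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a validated count matrix with sample metadata
#'
#' Container for gene-by-sample integer counts from either RNA-seq or
#' ribosome-footprint (RFP) libraries, with per-sample condition, assay and
#' replicate annotation.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All values must be
#'   non-negative whole numbers.
#' @param sample_meta Data frame with columns `sample_id`, `condition`,
#'   `assay` (one of `"rna"`, `"rfp"`) and `replicate`, covering every
#'   column of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta` (metadata reordered to match the column order).
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  sample_meta <- tibble::as_tibble(sample_meta)
  needed <- c("sample_id", "condition", "assay", "replicate")
  missing_cols <- setdiff(needed, names(sample_meta))
  if (length(missing_cols) > 0) {
    stopf("sample_meta is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(absent) > 0) {
    stopf("sample(s) present in counts but absent from metadata: %s",
          paste(absent, collapse = ", "))
  }
  if (!all(sample_meta$assay %in% c("rna", "rfp"))) {
    stopf("assay must be 'rna' or 'rfp'")
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_meta$assay), collapse = "/")))
  cat("conditions:", paste(unique(x$sample_meta$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param path Counts TSV: first column gene ids, remaining columns one per
#'   sample. Genes with all-zero rows are retained (filtering is a
#'   downstream decision).
#' @param meta_path Metadata TSV with columns `sample_id`, `condition`,
#'   `assay`, `replicate`.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2) stopf("counts table '%s' has no sample columns", path)
  gene_ids <- tab[[1]]
  num <- suppressWarnings(
    vapply(tab[-1], function(x) as.numeric(x), numeric(nrow(tab)))
  )
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(gene_ids, names(tab)[-1]))
  if (any(is.na(num))) stopf("non-numeric count in '%s'", path)
  if (any(num < 0)) stopf("negative count in '%s'", path)
  if (any(num != round(num))) stopf("fractional count in '%s'", path)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(), progress = FALSE)
  count_matrix(num, meta)
}

#' Write a count matrix and its metadata to TSV files
#'
#' @param x A [count_matrix()] object.
#' @param path,meta_path Output paths for the counts and the metadata.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- tibble::as_tibble(x$counts, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(x$sample_meta, meta_path, progress = FALSE)
  invisible(path)
}

#' Construct gene sets for enrichment and filtering
#'
#' Holds the TOP-gene membership over the universe of genes captured in the
#' current dataset, plus an exclusion list (mitochondrial / pseudogene
#' contigs ignored by tail profiling).
#'
#' @param universe Character vector of gene ids captured in the dataset.
#' @param top_genes Character vector of known TOP-motif gene ids; only the
#'   intersection with `universe` is kept and the number of dropped ids is
#'   reported as a message.
#' @param exclusions Character vector of gene ids to exclude from tail
#'   profiling (may overlap the universe).
#' @return An object of class `gene_sets` with elements `universe`,
#'   `top_genes`, `exclusions`, `n_dropped`.
#' @export
gene_sets <- function(universe, top_genes = character(),
                      exclusions = character()) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("gene universe is empty")
  top_genes <- unique(as.character(top_genes))
  kept <- intersect(top_genes, universe)
  n_dropped <- length(top_genes) - length(kept)
  if (n_dropped > 0) {
    message(sprintf("%d TOP gene id(s) not in the universe were dropped",
                    n_dropped))
  }
  structure(list(universe = universe, top_genes = kept,
                 exclusions = unique(as.character(exclusions)),
                 n_dropped = n_dropped),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: universe %d, TOP %d (%d dropped), exclusions %d\n",
              length(x$universe), length(x$top_genes), x$n_dropped,
              length(x$exclusions)))
  invisible(x)
}

#' Read gene sets from plain-text gene lists
#'
#' @param top_list_path Text file with one TOP gene id per line.
#' @param universe Character vector of gene ids captured in the current
#'   dataset (supplied by the caller).
#' @param exclusions_path Optional text file of ids to exclude
#'   (mitochondrial genome, pseudogenes); one id per line.
#' @return A [gene_sets()] object.
#' @export
read_gene_sets <- function(top_list_path, universe, exclusions_path = NULL) {
  read_ids <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x[nzchar(x)]
  }
  top <- read_ids(top_list_path)
  excl <- if (!is.null(exclusions_path)) read_ids(exclusions_path) else
    character()
  gene_sets(universe, top, excl)
}

#' Default pipeline configuration
#'
#' Central record of the tunable analysis parameters: tail-length bin edges
#' (nt), the minimum PASS-read count for a contig to enter tail profiling,
#' significance levels, labeling time points (h), replicate counts, the
#' kinetic-fit acceptance filters and the RNG seed recorded in outputs.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    bin_edges = c(30, 90),
    min_reads_per_contig = 30L,
    alpha_tail = 0.05,
    alpha_q = 0.05,
    te_threshold = 0.5,
    r2_min = 0.6,
    half_life_bounds_min = c(0, 5000),
    timepoints_h = c(0, 3, 6, 9),
    slam_background = 0.001,
    n_replicates = 3L,
    seed = 1L
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$bin_edges) != 2 || diff(cfg$bin_edges) <= 0) {
    stopf("bin_edges must be two strictly increasing values")
  }
  if (cfg$min_reads_per_contig < 1) stopf("min_reads_per_contig must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stopf("seed must be a single integer")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- unclass(default_pipeline_config())
  user <- yaml::read_yaml(path)
  cfg[names(user)] <- user
  validate_pipeline_config(cfg)
}
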