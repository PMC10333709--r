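# Readers and writers for the interchange formats: wide/long TSV tables
# (canonical), MatrixMarket hashtag matrices with barcode/feature sidecars,
# a minimal biallelic SNP panel VCF, and YAML configuration. Every reader
# validates and reports the offending line on malformed input; write(read(x))
# reproduces x record for record.

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

# data line number in the file = row + 1 (header)
abort_lines <- function(rows, path, what) {
  abort(sprintf("%s: %s at line(s) %s.", path, what,
                paste(utils::head(rows + 1L, 5), collapse = ", ")))
}

require_nonneg_int <- function(df, cols, path) {
  for (cl in cols) {
    bad <- which(is.na(df[[cl]]) | df[[cl]] < 0 | df[[cl]] != floor(df[[cl]]))
    if (length(bad) > 0) {
      abort_lines(bad, path, sprintf("`%s` must be a non-negative integer", cl))
    }
  }
  invisible(df)
}

# Hashtag matrices ------------------------------------------------------------

#' Write / read a hashtag count matrix as MatrixMarket
#'
#' `write_hashtag_mtx()` writes `matrix.mtx` (hashtags x cells, the
#' features-by-barcodes orientation of 10x exports) plus `barcodes.tsv` and
#' `features.tsv`; `read_hashtag_mtx()` reads the trio back into a dense
#' cells x hashtags integer matrix.
#'
#' @param counts Cells x hashtags matrix with dimnames.
#' @param dir Directory for the three files (created if needed).
#' @return `write_hashtag_mtx()` the directory, invisibly;
#'   `read_hashtag_mtx()` the counts matrix.
#' @export
write_hashtag_mtx <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have cell rownames and hashtag colnames.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "barcodes.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_hashtag_mtx
#' @export
read_hashtag_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("Missing file(s): %s.", paste(missing, collapse = ", ")))
  }
  m <- Matrix::readMM(paths[1])
  barcodes <- readr::read_lines(paths[2])
  features <- readr::read_lines(paths[3])
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    abort(sprintf(
      "Dimension mismatch: matrix is %d x %d but %d features / %d barcodes.",
      nrow(m), ncol(m), length(features), length(barcodes)
    ))
  }
  if (anyDuplicated(barcodes)) abort("Duplicate cell barcodes.")
  if (anyDuplicated(features)) abort("Duplicate hashtag features.")
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(barcodes, features)
  storage.mode(counts) <- "integer"
  counts
}

#' Write / read a hashtag count matrix as wide TSV
#'
#' One row per cell: a `cell_id` column followed by one count column per
#' hashtag.
#'
#' @param counts Cells x hashtags matrix with dimnames.
#' @param path TSV path.
#' @return `write_hashtag_tsv()` the path, invisibly; `read_hashtag_tsv()`
#'   the counts matrix.
#' @export
write_hashtag_tsv <- function(counts, path) {
  df <- tibble(cell_id = rownames(counts)) %>%
    dplyr::bind_cols(as_tibble(as.data.frame(counts)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_hashtag_tsv
#' @export
read_hashtag_tsv <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(cell_id = readr::col_character(),
                                         .default = readr::col_double()))
  check_columns(df, "cell_id", path)
  if (anyDuplicated(df$cell_id)) abort(sprintf("%s: duplicate cell_id.", path))
  require_nonneg_int(df, setdiff(names(df), "cell_id"), path)
  m <- as.matrix(df[setdiff(names(df), "cell_id")])
  rownames(m) <- df$cell_id
  storage.mode(m) <- "integer"
  m
}

# Long tables ------------------------------------------------------------------

#' Read / write per-cell allele counts (long TSV)
#'
#' Columns `cell_id`, `snp_id`, `ref_count`, `alt_count`; one row per
#' covered (cell, SNP) pair.
#'
#' @param x Allele-count tibble.
#' @param path TSV path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    cell_id = readr::col_character(), snp_id = readr::col_character(),
    ref_count = readr::col_double(), alt_count = readr::col_double()
  ))
  check_columns(df, c("cell_id", "snp_id", "ref_count", "alt_count"), path)
  require_nonneg_int(df, c("ref_count", "alt_count"), path)
  dup <- which(duplicated(df[c("cell_id", "snp_id")]))
  if (length(dup) > 0) abort_lines(dup, path, "duplicate (cell_id, snp_id) pair")
  df %>% dplyr::mutate(ref_count = as.integer(.data$ref_count),
                       alt_count = as.integer(.data$alt_count))
}

#' @rdname read_allele_counts
#' @export
write_allele_counts <- function(x, path) {
  check_columns(x, c("cell_id", "snp_id", "ref_count", "alt_count"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write per-cell QC metrics (TSV)
#'
#' Columns `cell_id`, `umi_count`, `mito_fraction`.
#'
#' @param x QC metrics tibble.
#' @param path TSV path.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
read_cell_qc <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    cell_id = readr::col_character(), umi_count = readr::col_double(),
    mito_fraction = readr::col_double(), .default = readr::col_guess()
  ))
  check_columns(df, c("cell_id", "umi_count", "mito_fraction"), path)
  require_nonneg_int(df, "umi_count", path)
  bad <- which(is.na(df$mito_fraction) | df$mito_fraction < 0 |
                 df$mito_fraction > 1)
  if (length(bad) > 0) abort_lines(bad, path, "`mito_fraction` must be in [0, 1]")
  df %>% dplyr::mutate(umi_count = as.integer(.data$umi_count))
}

#' @rdname read_cell_qc
#' @export
write_cell_qc <- function(x, path) {
  check_columns(x, c("cell_id", "umi_count", "mito_fraction"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a cluster frequency table (TSV)
#'
#' Columns `sample_id`, `donor_id`, `group`, `timepoint`, `cluster_id`,
#' `count`, `total` (and optionally `denominator_kind`).
#'
#' @param x Cluster frequency tibble.
#' @param path TSV path.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
read_cluster_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    count = readr::col_double(), total = readr::col_double(),
    .default = readr::col_character()
  ))
  check_columns(df, c("sample_id", "donor_id", "group", "timepoint",
                      "cluster_id", "count", "total"), path)
  require_nonneg_int(df, c("count", "total"), path)
  bad <- which(df$count > df$total)
  if (length(bad) > 0) abort_lines(bad, path, "`count` exceeds `total`")
  dup <- which(duplicated(df[c("sample_id", "cluster_id")]))
  if (length(dup) > 0) abort_lines(dup, path, "duplicate (sample_id, cluster_id)")
  df %>% dplyr::mutate(count = as.integer(.data$count),
                       total = as.integer(.data$total))
}

#' @rdname read_cluster_table
#' @export
write_cluster_table <- function(x, path) {
  check_columns(x, c("sample_id", "donor_id", "group", "timepoint",
                     "cluster_id", "count", "total"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

# SNP panel VCF ----------------------------------------------------------------

#' Write / read a minimal biallelic SNP panel VCF
#'
#' Sites-only VCFv4.2 with CHROM, POS, ID, REF, ALT (QUAL/FILTER/INFO as
#' `.`). The reader rejects multi-allelic ALT entries (the panel contract is
#' biallelic) and duplicate ids.
#'
#' @param panel Tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path `.vcf` path (plain text).
#' @return The path, invisibly (writer); the panel tibble (reader).
#' @export
write_snp_panel_vcf <- function(panel, path) {
  check_columns(panel, c("snp_id", "chrom", "pos", "ref", "alt"), "panel")
  if (any(grepl(",", panel$alt))) abort("Panel must be biallelic (single ALT).")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=celldemux",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  panel$chrom, as.integer(panel$pos), panel$snp_id,
                  panel$ref, panel$alt)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname write_snp_panel_vcf
#' @export
read_snp_panel_vcf <- function(path) {
  lines <- readr::read_lines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0) {
    return(tibble(snp_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character()))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    abort_lines(which(nf < 5), path, "VCF record with fewer than 5 fields")
    }
  rec <- function(i) vapply(fields, `[[`, character(1), i)
  alt <- rec(5)
  multi <- which(grepl(",", alt))
  if (length(multi) > 0) {
    abort(sprintf("%s: multi-allelic ALT at line(s) %s (biallelic-only).",
                  path, paste(utils::head(body_idx[multi], 5), collapse = ", ")))
  }
  out <- tibble(
    snp_id = rec(3), chrom = rec(1), pos = as.integer(rec(2)),
    ref = rec(4), alt = alt
  )
  if (anyDuplicated(out$snp_id)) abort(sprintf("%s: duplicate SNP ids.", path))
  out
}

# Configuration ----------------------------------------------------------------

#' Read / write a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()] list (writer).
#' @param path YAML path.
#' @return The config list (reader) or the path, invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
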