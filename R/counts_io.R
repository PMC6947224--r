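# Readers and writers for the on-disk formats: HTSeq-count two-column files,
# genes x samples matrices, chromosome maps, and the sex report.

# HTSeq-count appends special summary rows after the genes; they are never
# genes and must not leak into CPM denominators by accident.
HTSEQ_SUMMARY <- c("__no_feature", "__ambiguous", "__too_low_aQual",
                   "__not_aligned", "__alignment_not_unique")

#' Read per-sample HTSeq-count files into a counts table
#'
#' Each file is the two-column tab-separated output of `htseq-count`: a
#' `gene_id` and an integer count per line, with `"__"`-prefixed summary rows
#' (`__no_feature`, `__ambiguous`, ...) at the end. Summary rows are stripped
#' from the gene table but their totals are kept as per-sample metadata,
#' retrievable with [summary_counts()].
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Optional character vector of sample names; defaults to
#'   the file basenames without extension.
#' @return A tibble with a `gene_id` column and one integer column per
#'   sample, columns in the order of `paths`. Gene order follows the first
#'   file.
#' @details All files must contain exactly the same set of gene identifiers;
#'   a mismatch raises a consistency error naming the differing genes.
#' @seealso [read_counts_matrix()] for a single-matrix TSV.
#' @export
read_htseq_counts <- function(paths, sample_ids = NULL) {
  if (length(paths) == 0) abort("no input files given")
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths)) {
    abort("sample_ids must have one entry per path")
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample_id: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }

  parsed <- map(paths, parse_htseq_file)
  ref_genes <- parsed[[1]]$gene_id
  for (i in seq_along(parsed)) {
    genes_i <- parsed[[i]]$gene_id
    if (!setequal(genes_i, ref_genes)) {
      diff <- union(setdiff(ref_genes, genes_i), setdiff(genes_i, ref_genes))
      stop_consistency(
        "gene sets differ between '", paths[1], "' and '", paths[i],
        "'; symmetric difference: ", paste(sort(diff), collapse = ", "))
    }
  }

  counts <- tibble(gene_id = ref_genes)
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    counts[[sample_ids[i]]] <- p$count[match(ref_genes, p$gene_id)]
  }
  summaries <- bind_rows(map(seq_along(parsed), function(i) {
    s <- attr(parsed[[i]], "summary")
    if (nrow(s) == 0) return(s)
    mutate(s, sample_id = sample_ids[i], .before = 1)
  }))
  attr(counts, "summary_counts") <- summaries
  validate_expr_table(counts, "counts", integer_counts = TRUE)
  counts
}

parse_htseq_file <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    bad <- which(nfield != 2)[1]
    stop_parse("malformed line (expected 2 tab-separated columns) at ",
               path, ":", bad)
  }
  gene_id <- map_chr(parts, 1)
  count_chr <- map_chr(parts, 2)
  count <- suppressWarnings(as.integer(count_chr))
  if (anyNA(count) || any(count_chr != as.character(count))) {
    bad <- which(is.na(count) | count_chr != as.character(count))[1]
    stop_parse("non-integer count '", count_chr[bad], "' at ", path, ":", bad)
  }
  if (any(count < 0)) {
    bad <- which(count < 0)[1]
    stop_parse("negative count at ", path, ":", bad)
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    stop_parse("duplicate gene_id in ", path, ": ", paste(dup, collapse = ", "))
  }
  is_summary <- startsWith(gene_id, "__")
  out <- tibble(gene_id = gene_id[!is_summary], count = count[!is_summary])
  attr(out, "summary") <- tibble(category = gene_id[is_summary],
                                 count = count[is_summary])
  out
}

#' Read a genes-by-samples count matrix from TSV
#'
#' Expects a header row whose first field is arbitrary and whose remaining
#' fields are sample identifiers; the first column holds gene identifiers and
#' the remaining cells non-negative integer counts. `"__"`-prefixed rows
#' (HTSeq summary totals) are stripped from the genes and kept as metadata,
#' retrievable with [summary_counts()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene_id` column and one integer column per
#'   sample, preserving the file's row and column order.
#' @export
read_counts_matrix <- function(path) {
  tbl <- read_expr_tsv(path)
  m <- expr_matrix_of(tbl)
  if (any(m != floor(m))) {
    bad <- which(m != floor(m), arr.ind = TRUE)[1, ]
    stop_parse("non-integer count at gene '", rownames(m)[bad[1]],
               "', sample '", colnames(m)[bad[2]], "' in ", path)
  }
  is_summary <- startsWith(tbl$gene_id, "__")
  if (any(is_summary)) {
    s <- tbl[is_summary, ]
    attr(tbl, "summary_counts") <- s |>
      tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                          values_to = "count") |>
      transmute(.data$sample_id,
                category = .data$gene_id, count = as.integer(.data$count))
    tbl <- tbl[!is_summary, ]
  }
  validate_expr_table(tbl, "counts", integer_counts = TRUE)
  tbl
}

# shared TSV reader for counts and CPM matrices; numeric validation only
read_expr_tsv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  # non-numeric cells become NA and are reported as parse errors below;
  # readr's own problem report is redundant here
  tbl <- suppressWarnings(suppressMessages(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE, name_repair = "unique")))
  if (ncol(tbl) < 2) stop_parse("no sample columns in ", path)
  names(tbl)[1] <- "gene_id"
  # readr mangles duplicate headers to name...k; check the raw header instead
  raw_header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  dup_s <- unique(raw_header[duplicated(raw_header)])
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample_id in ", path, ": ",
                 paste(dup_s, collapse = ", ")))
  }
  dup_g <- unique(tbl$gene_id[duplicated(tbl$gene_id)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene_id in ", path, ": ",
                 paste(dup_g, collapse = ", ")))
  }
  if (anyNA(as.matrix(tbl[, -1]))) {
    stop_parse("missing or non-numeric cell in ", path)
  }
  tbl
}

#' Per-sample HTSeq summary totals retained by the readers
#'
#' @param counts A counts table from [read_htseq_counts()] or
#'   [read_counts_matrix()].
#' @return A tibble with columns `sample_id`, `category` (e.g.
#'   `"__no_feature"`), `count`, or an empty tibble if the input carried no
#'   summary rows.
#' @export
summary_counts <- function(counts) {
  s <- attr(counts, "summary_counts")
  if (is.null(s)) {
    return(tibble(sample_id = character(), category = character(),
                  count = integer()))
  }
  as_tibble(s)
}

#' Read a gene-to-chromosome map from a GTF/GFF2 file
#'
#' Only rows with feature type `"gene"` are consulted; the chromosome is
#' column 1 (normalized with [normalize_chrom()]) and the gene identifier is
#' taken from the `gene_id` attribute of column 9.
#'
#' @param path Path to a GTF file (Ensembl dialect).
#' @return A tibble with columns `gene_id` and `chromosome`, one row per gene.
#' @details A `gene_id` listed on two different chromosomes is a consistency
#'   error; a file with no `"gene"` rows is an error.
#' @export
read_chrom_map_gtf <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 9
  if (any(!ok)) {
    stop_parse("malformed GTF line (fewer than 9 columns) at ", path, ":",
               which(!ok)[1])
  }
  feat <- map_chr(fields, 3)
  gene_rows <- fields[feat == "gene"]
  if (length(gene_rows) == 0) {
    stop_parse("no 'gene' feature rows in ", path)
  }
  chrom <- normalize_chrom(map_chr(gene_rows, 1))
  attrs <- map_chr(gene_rows, 9)
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attrs)
  no_id <- !grepl("gene_id", attrs)
  if (any(no_id)) {
    stop_parse("'gene' row without gene_id attribute in ", path)
  }
  map <- distinct(tibble(gene_id = gid, chromosome = chrom))
  validate_chrom_map(map)
  map
}

#' Read a gene-to-chromosome map from a two-column TSV
#'
#' Columns are `gene_id` and `chromosome`; an optional header line is
#' detected (second field non-numeric and equal to a common header word, or
#' first field named `gene`/`gene_id`) and skipped. Chromosome names are
#' normalized with [normalize_chrom()].
#'
#' @inheritParams read_chrom_map_gtf
#' @return A tibble with columns `gene_id` and `chromosome`.
#' @export
read_chrom_map_tsv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_parse("empty chromosome map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop_parse("malformed line (expected 2 tab-separated columns) at ",
               path, ":", which(lengths(parts) != 2)[1])
  }
  first <- parts[[1]]
  if (tolower(first[1]) %in% c("gene", "gene_id", "geneid") ||
      tolower(first[2]) %in% c("chrom", "chromosome", "chr", "seqname")) {
    parts <- parts[-1]
  }
  if (length(parts) == 0) stop_parse("chromosome map has no entries: ", path)
  map <- distinct(tibble(gene_id = map_chr(parts, 1),
                         chromosome = normalize_chrom(map_chr(parts, 2))))
  validate_chrom_map(map)
  map
}

#' Write a sex-call report to TSV
#'
#' Writes columns `sample_id`, `sigma_cpm` (two decimals, ties rounded away
#' from zero), `label`, `n_genes_used`, in the input row order. The file can
#' be read back with [read_sex_report()] to an equal table at two-decimal
#' precision.
#'
#' @param calls A sex-call table from [classify()].
#' @param path Output file path.
#' @return `calls`, invisibly.
#' @export
write_sex_report <- function(calls, path) {
  stopifnot(all(c("sample_id", "sigma_cpm", "label", "n_genes_used")
                %in% names(calls)))
  out <- data.frame(sample_id = calls$sample_id,
                    sigma_cpm = fmt2(calls$sigma_cpm),
                    label = as.character(calls$label),
                    n_genes_used = calls$n_genes_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Read a sex-call report written by [write_sex_report()]
#'
#' @param path Path to the report TSV.
#' @return A tibble with columns `sample_id`, `sigma_cpm`, `label`,
#'   `n_genes_used`.
#' @export
read_sex_report <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cdci", progress = FALSE,
                         show_col_types = FALSE)
  expected <- c("sample_id", "sigma_cpm", "label", "n_genes_used")
  if (!identical(names(tbl), expected)) {
    stop_parse("not a sex report (header mismatch): ", path)
  }
  bad <- setdiff(unique(tbl$label), c("male", "female", "undetermined"))
  if (length(bad) > 0) {
    stop_parse("unknown label in ", path, ": ", paste(bad, collapse = ", "))
  }
  tbl
}
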