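# Counts-per-million normalization and the CPM table contract.
#
# A CPM table is, like a counts table, a tibble with a `gene_id` column and
# one numeric column per sample; it additionally carries the per-sample
# library sizes in the "library_sizes" attribute (used to scale log
# pseudocounts in the MDS distance).

#' Normalize a counts table to counts per million (CPM)
#'
#' For gene g and sample s, `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`
#' where the library size is the column sum over retained genes. Every CPM
#' column therefore sums to one million.
#'
#' @param counts Counts table (tibble with `gene_id` plus one integer column
#'   per sample), e.g. from [read_counts_matrix()].
#' @param include_summary_totals If `TRUE`, HTSeq summary totals carried as
#'   metadata (see [summary_counts()]) are added to the library size, i.e.
#'   the denominator becomes all assigned *and* unassigned reads. Default
#'   `FALSE`: the denominator counts reads assigned to genes only.
#' @return A CPM tibble of the same shape; library sizes are attached as the
#'   `"library_sizes"` attribute and retrievable with [library_sizes()].
#' @details A sample with library size zero cannot be normalized and raises
#'   an error naming the sample.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(3L, 1L))
#' compute_cpm(counts)
compute_cpm <- function(counts, include_summary_totals = FALSE) {
  validate_expr_table(counts, "counts", integer_counts = TRUE)
  m <- expr_matrix_of(counts)
  lib <- colSums(m)
  if (include_summary_totals) {
    s <- summary_counts(counts)
    if (nrow(s) > 0) {
      extra <- s |> group_by(.data$sample_id) |>
        summarise(extra = sum(.data$count))
      add <- setNames(extra$extra, extra$sample_id)[names(lib)]
      add[is.na(add)] <- 0
      lib <- lib + add
    }
  }
  if (any(lib == 0)) {
    abort(paste0("sample(s) with zero library size: ",
                 paste(names(lib)[lib == 0], collapse = ", ")))
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  out <- bind_cols(tibble(gene_id = counts$gene_id), as_tibble(cpm))
  attr(out, "library_sizes") <- lib
  out
}

#' Library sizes attached to a CPM table
#'
#' @param cpm A CPM tibble from [compute_cpm()] or [as_cpm()].
#' @return Named numeric vector of per-sample library sizes, or `NULL` when
#'   the table was built from pre-computed CPM values without known library
#'   sizes.
#' @export
library_sizes <- function(cpm) {
  attr(cpm, "library_sizes")
}

#' Mark a table of pre-computed CPM values as a CPM table
#'
#' Use this when per-gene CPM values come from an external source (e.g. a
#' published table) rather than from counts, so they can flow through
#' [sigma_cpm()], [select_informative_genes()] and
#' [leading_logfc_distance()].
#'
#' @param x Data frame whose first column is `gene_id` and whose remaining
#'   columns are non-negative per-sample CPM values.
#' @param library_sizes Optional named numeric vector of library sizes (used
#'   only to scale log pseudocounts downstream).
#' @return A validated CPM tibble.
#' @export
as_cpm <- function(x, library_sizes = NULL) {
  out <- as_tibble(x)
  names(out)[1] <- "gene_id"
  validate_expr_table(out, "cpm")
  if (!is.null(library_sizes)) {
    if (is.null(names(library_sizes))) {
      names(library_sizes) <- sample_ids_of(out)
    }
    missing <- setdiff(sample_ids_of(out), names(library_sizes))
    if (length(missing) > 0) {
      abort(paste0("library_sizes missing for: ",
                   paste(missing, collapse = ", ")))
    }
    attr(out, "library_sizes") <- library_sizes[sample_ids_of(out)]
  }
  out
}

#' Read a pre-computed CPM matrix from TSV
#'
#' Same layout as [read_counts_matrix()] but with real-valued cells.
#'
#' @param path Path to the TSV file.
#' @param library_sizes Optional named vector of library sizes; see
#'   [as_cpm()].
#' @return A CPM tibble.
#' @export
read_cpm_matrix <- function(path, library_sizes = NULL) {
  as_cpm(read_expr_tsv(path), library_sizes = library_sizes)
}

#' Packaged pig-conceptus Y-gene CPM fixture
#'
#' Per-gene CPM values of ten Y-linked genes (DDX3Y, KDM5D, ZFY, EIF2S3Y,
#' EIF1AY and five uncharacterized LOC genes) across 35 pig conceptus
#' RNA-seq samples: 17 males and 18 females, embryos at 25 days and fetuses
#' at 35 days of gestation. Sample names encode the truth: suffix `-M` male,
#' `-F` female. `conceptus_chrY_map()` returns the matching gene-to-
#' chromosome map, and `conceptus_sigma_published()` the published
#' per-sample score (summed CPM over the ten genes) at two decimals.
#'
#' @return `conceptus_cpm()`: a 10-gene x 35-sample CPM tibble.
#' @export
conceptus_cpm <- function() {
  read_cpm_matrix(system.file("extdata", "conceptus_chrY_cpm.tsv",
                              package = "sexcallr", mustWork = TRUE))
}

#' @rdname conceptus_cpm
#' @return `conceptus_chrY_map()`: a tibble with columns `gene_id`,
#'   `chromosome` (all `"Y"`).
#' @export
conceptus_chrY_map <- function() {
  read_chrom_map_tsv(system.file("extdata", "conceptus_chrY_map.tsv",
                                 package = "sexcallr", mustWork = TRUE))
}

#' @rdname conceptus_cpm
#' @return `conceptus_sigma_published()`: a tibble with columns `sample_id`,
#'   `sigma_cpm`.
#' @export
conceptus_sigma_published <- function() {
  readr::read_tsv(system.file("extdata", "conceptus_sigma_cpm.tsv",
                              package = "sexcallr", mustWork = TRUE),
                  col_types = "cd", progress = FALSE, show_col_types = FALSE)
}

#' Sex of the fixture samples as encoded in their names
#'
#' @param sample_ids Character vector of fixture sample names (suffix `-M`
#'   or `-F`).
#' @return Character vector, `"male"` or `"female"`.
#' @export
conceptus_truth <- function(sample_ids) {
  suffix <- sub(".*-", "", sample_ids)
  if (!all(suffix %in% c("M", "F"))) {
    abort("sample names must end in -M or -F")
  }
  ifelse(suffix == "M", "male", "female")
}
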