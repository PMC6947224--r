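# Shared internal helpers: condition classes, rounding, table validation.

stop_parse <- function(msg, ...) {
  abort(paste0(msg, ...), class = "sexcallr_parse_error")
}

stop_consistency <- function(msg, ...) {
  abort(paste0(msg, ...), class = "sexcallr_consistency_error")
}

stop_usage <- function(msg, ...) {
  abort(paste0(msg, ...), class = "sexcallr_usage_error")
}

#' Round half away from zero
#'
#' Fixed-precision rounding where ties go away from zero (`0.125` at two
#' decimals becomes `0.13`), the convention used for all written reports.
#' Base `round()` rounds half to even, which would make written scores
#' disagree with hand-computed tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.675), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# format at 2 decimals, half-up, for report files
fmt2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix case-insensitively, so UCSC-style
#' (`"chrY"`) and Ensembl-style (`"Y"`) names compare equal. The remainder is
#' left untouched and compared case-sensitively.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("chrY", "Y", "ChR1", "MT"))
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", x)
}

# A counts/CPM table is a tibble whose first column is `gene_id` and whose
# remaining columns are one numeric column per sample.
sample_ids_of <- function(tbl) setdiff(names(tbl), "gene_id")

expr_matrix_of <- function(tbl) {
  m <- as.matrix(tbl[, sample_ids_of(tbl), drop = FALSE])
  rownames(m) <- tbl$gene_id
  m
}

validate_expr_table <- function(tbl, what = "counts", integer_counts = FALSE) {
  if (!is.data.frame(tbl) || names(tbl)[1] != "gene_id") {
    abort(paste0(what, " table must be a data frame whose first column is 'gene_id'"))
  }
  if (ncol(tbl) < 2) abort(paste0(what, " table has no sample columns"))
  dup_g <- unique(tbl$gene_id[duplicated(tbl$gene_id)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene_id in ", what, " table: ",
                 paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(sample_ids_of(tbl)[duplicated(sample_ids_of(tbl))])
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample_id in ", what, " table: ",
                 paste(dup_s, collapse = ", ")))
  }
  m <- expr_matrix_of(tbl)
  if (!is.numeric(m) || anyNA(m)) {
    stop_parse(what, " table contains missing or non-numeric cells")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_parse("negative value in ", what, " table at gene '",
               rownames(m)[bad[1]], "', sample '", colnames(m)[bad[2]], "'")
  }
  if (integer_counts && any(m != floor(m))) {
    bad <- which(m != floor(m), arr.ind = TRUE)[1, ]
    stop_parse("non-integer count at gene '", rownames(m)[bad[1]],
               "', sample '", colnames(m)[bad[2]], "'")
  }
  invisible(tbl)
}

validate_chrom_map <- function(map) {
  if (!is.data.frame(map) || !all(c("gene_id", "chromosome") %in% names(map))) {
    abort("chromosome map must have columns 'gene_id' and 'chromosome'")
  }
  conf <- map |>
    distinct(.data$gene_id, .data$chromosome) |>
    count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(conf) > 0) {
    stop_consistency("gene_id mapped to more than one chromosome: ",
                     paste(conf$gene_id, collapse = ", "))
  }
  invisible(map)
}

#' Look up the chromosome of genes
#'
#' @param map Chromosome map tibble with columns `gene_id`, `chromosome`.
#' @param gene_ids Character vector of gene identifiers.
#' @return Character vector of chromosome names, in the order of `gene_ids`.
#'   Unmapped genes are an error, never a silent `NA`.
#' @export
chrom_of <- function(map, gene_ids) {
  validate_chrom_map(map)
  idx <- match(gene_ids, map$gene_id)
  if (anyNA(idx)) {
    stop_consistency("gene_id not present in chromosome map: ",
                     paste(gene_ids[is.na(idx)], collapse = ", "))
  }
  map$chromosome[idx]
}
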