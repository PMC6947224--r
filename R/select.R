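# Selection of informative (bimodally expressed) Y-linked marker genes.

#' Select Y-linked genes with discrepant (bimodal) CPM across samples
#'
#' A Y-linked gene is informative for sexing when its per-sample CPM values
#' split into a well-separated high group (males, real expression) and low
#' group (females, residual X/Y mismapping artifacts). For each gene on the
#' target chromosome the per-sample CPM values are sorted and cut at the
#' largest consecutive gap; the gene is selected iff
#'
#' 1. both groups contain at least `min_group` samples,
#' 2. the high-group minimum is at least `min_high_cpm`, and
#' 3. the ratio high-group minimum / max(low-group maximum, `epsilon`) is at
#'    least `min_fold` (`epsilon` guards division by the all-zero female
#'    case).
#'
#' The defaults are calibrated on published pig-conceptus data, where true
#' marker genes separate by 67-fold or more and the weakest marker's male
#' CPM stays above 1.2, while artifact-level genes sit near one-fold with
#' CPM well under 1: `min_fold = 20` and `min_high_cpm = 0.3` split those
#' regimes with margin on both sides.
#'
#' @param cpm CPM tibble from [compute_cpm()] or [as_cpm()].
#' @param chrom_map Chromosome map tibble (`gene_id`, `chromosome`).
#' @param target_chrom Chromosome holding the marker genes, normalized with
#'   [normalize_chrom()]; default `"Y"`.
#' @param min_fold Minimum high/low separation ratio.
#' @param min_high_cpm Minimum CPM of the weakest high-group sample.
#' @param min_group Minimum samples per group; the default 2 means a single
#'   outlier sample can never define a group on its own.
#' @param epsilon Floor (in CPM) for the low-group maximum in the ratio.
#' @return A `gene_selection` tibble with one row per target-chromosome gene
#'   present in `cpm`, in input gene order: `gene_id`, `n_low`, `n_high`,
#'   `low_max`, `high_min`, `fold`, `selected`. Extract the selected ids
#'   with [selected_genes()].
#' @details Requires at least `2 * min_group` samples and at least one gene
#'   of `cpm` mapped to `target_chrom`; otherwise an error is raised.
#' @export
select_informative_genes <- function(cpm, chrom_map, target_chrom = "Y",
                                     min_fold = 20, min_high_cpm = 0.3,
                                     min_group = 2, epsilon = 0.01) {
  validate_expr_table(cpm, "cpm")
  validate_chrom_map(chrom_map)
  stopifnot(min_fold > 0, min_high_cpm >= 0, min_group >= 1, epsilon > 0)

  target <- normalize_chrom(target_chrom)
  map_norm <- mutate(chrom_map, chromosome = normalize_chrom(.data$chromosome))
  on_target <- map_norm$gene_id[map_norm$chromosome == target]
  genes <- intersect(cpm$gene_id, on_target)   # input gene order
  if (length(genes) == 0) {
    abort(paste0("no genes on chromosome '", target,
                 "' present in the CPM table"))
  }
  n_samples <- length(sample_ids_of(cpm))
  if (n_samples < 2 * min_group) {
    abort(paste0("need at least ", 2 * min_group, " samples, got ", n_samples))
  }

  m <- expr_matrix_of(cpm)[genes, , drop = FALSE]
  diag <- map(genes, function(g) {
    v <- sort(m[g, ])
    gaps <- diff(v)
    cut <- which.max(gaps)            # first largest gap -> stable
    if (length(gaps) == 0 || max(gaps) == 0) cut <- length(v)  # no split
    low <- v[seq_len(cut)]
    high <- v[-seq_len(cut)]
    tibble(gene_id = g,
           n_low = length(low), n_high = length(high),
           low_max = max(low),
           high_min = if (length(high) > 0) min(high) else NA_real_,
           fold = if (length(high) > 0) min(high) / max(max(low), epsilon)
                  else NA_real_)
  })
  out <- bind_rows(diag) |>
    mutate(selected = !is.na(.data$fold) &
             .data$n_low >= min_group & .data$n_high >= min_group &
             .data$high_min >= min_high_cpm & .data$fold >= min_fold)
  attr(out, "params") <- list(target_chrom = target, min_fold = min_fold,
                              min_high_cpm = min_high_cpm,
                              min_group = min_group, epsilon = epsilon)
  class(out) <- c("gene_selection", class(out))
  out
}

#' Gene ids selected by [select_informative_genes()]
#'
#' @param selection A `gene_selection` tibble.
#' @return Character vector of selected gene ids, in input gene order.
#' @export
selected_genes <- function(selection) {
  stopifnot(inherits(selection, "gene_selection"))
  selection$gene_id[selection$selected]
}

#' Write a gene-selection table with diagnostics to TSV
#'
#' @param selection A `gene_selection` tibble.
#' @param path Output file path.
#' @return `selection`, invisibly.
#' @export
write_gene_selection <- function(selection, path) {
  out <- as.data.frame(selection)
  for (col in c("low_max", "high_min")) out[[col]] <- fmt2(out[[col]])
  out$fold <- formatC(round_half_up(out$fold, 2), format = "f", digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(selection)
}
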