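# The per-sample score (summed CPM over marker genes), threshold
# classification, and group summaries.

#' Per-sample summed CPM over a set of marker genes
#'
#' The sexing score of a sample is the sum of its CPM values over the
#' selected Y-linked marker genes. Male samples score in the hundreds;
#' female samples score near zero (residual mismapping only).
#'
#' @param cpm CPM tibble from [compute_cpm()] or [as_cpm()].
#' @param genes Character vector of marker gene ids, all present in `cpm`.
#'   An empty vector yields a score of 0 for every sample.
#' @return A tibble with columns `sample_id`, `sigma_cpm`, `n_genes_used`,
#'   one row per sample in column order.
#' @export
#' @examples
#' cpm <- conceptus_cpm()
#' sigma_cpm(cpm, cpm$gene_id) |> head(3)
sigma_cpm <- function(cpm, genes) {
  validate_expr_table(cpm, "cpm")
  unknown <- setdiff(genes, cpm$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("gene id(s) not in CPM table: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- expr_matrix_of(cpm)
  sums <- if (length(genes) == 0) {
    rep(0, ncol(m))
  } else {
    colSums(m[genes, , drop = FALSE])
  }
  tibble(sample_id = colnames(m), sigma_cpm = unname(sums),
         n_genes_used = length(genes))
}

#' Classify samples as male or female from their summed-CPM score
#'
#' Labels are a pure function of the score and two thresholds: `male` iff
#' `sigma_cpm > male_threshold`, `female` iff `sigma_cpm < female_threshold`,
#' otherwise `undetermined`. Both inequalities are strict; the open interval
#' between the thresholds is deliberately left uncalled rather than forced
#' to a side.
#'
#' @param sigma A tibble with columns `sample_id` and `sigma_cpm` (and
#'   optionally `n_genes_used`), as returned by [sigma_cpm()].
#' @param male_threshold Score above which a sample is called male
#'   (default 400).
#' @param female_threshold Score below which a sample is called female
#'   (default 2). Must be less than `male_threshold`.
#' @return A `sex_calls` tibble: `sample_id`, `sigma_cpm`, `label`,
#'   `n_genes_used`, in input row order. The thresholds are attached as
#'   attributes and surface in [glance()].
#' @export
#' @examples
#' sigma <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                         sigma_cpm = c(486.84, 1.75, 200))
#' classify(sigma)
classify <- function(sigma, male_threshold = 400, female_threshold = 2) {
  if (!is.data.frame(sigma) ||
      !all(c("sample_id", "sigma_cpm") %in% names(sigma))) {
    abort("sigma must be a data frame with columns sample_id, sigma_cpm")
  }
  if (!(female_threshold < male_threshold)) {
    abort("female_threshold must be less than male_threshold")
  }
  if (any(sigma$sigma_cpm < 0)) abort("sigma_cpm values must be >= 0")

  out <- sigma |>
    mutate(label = case_when(
      .data$sigma_cpm > male_threshold ~ "male",
      .data$sigma_cpm < female_threshold ~ "female",
      TRUE ~ "undetermined"))
  if (!"n_genes_used" %in% names(out)) out$n_genes_used <- NA_integer_
  out <- select(out, "sample_id", "sigma_cpm", "label", "n_genes_used")
  attr(out, "male_threshold") <- male_threshold
  attr(out, "female_threshold") <- female_threshold
  class(out) <- c("sex_calls", class(out))
  out
}

#' Per-label summary statistics of the sexing score
#'
#' @param calls A `sex_calls` tibble from [classify()].
#' @return A tibble with one row per label present in `calls`: `label`, `n`,
#'   `mean`, `sd`, `min`, `max` of `sigma_cpm`, each rounded to two decimals
#'   (ties away from zero). `sd` uses the n-1 (sample) denominator and is
#'   `NA` for single-member groups.
#' @export
summarize_groups <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("label", "sigma_cpm") %in% names(calls)))
  calls |>
    as_tibble() |>
    group_by(label = as.character(.data$label)) |>
    summarise(n = dplyr::n(),
              mean = round_half_up(mean(.data$sigma_cpm), 2),
              sd = round_half_up(sd(.data$sigma_cpm), 2),
              min = round_half_up(min(.data$sigma_cpm), 2),
              max = round_half_up(max(.data$sigma_cpm), 2)) |>
    arrange(factor(.data$label, levels = c("male", "female", "undetermined")))
}

#' Run the whole sexing pipeline on a CPM table
#'
#' Convenience wrapper: select marker genes (unless a fixed gene set is
#' given), score every sample, and classify.
#'
#' @param cpm CPM tibble.
#' @param chrom_map Chromosome map; required when `genes` is `NULL`.
#' @param genes Optional fixed marker gene set; when `NULL`, genes are
#'   chosen by [select_informative_genes()].
#' @param target_chrom,min_fold,min_high_cpm,min_group Passed to
#'   [select_informative_genes()].
#' @param male_threshold,female_threshold Passed to [classify()].
#' @return A `sex_calls` tibble; the gene selection (when computed) is
#'   attached as the `"selection"` attribute.
#' @export
call_sex <- function(cpm, chrom_map = NULL, genes = NULL, target_chrom = "Y",
                     min_fold = 20, min_high_cpm = 0.3, min_group = 2,
                     male_threshold = 400, female_threshold = 2) {
  selection <- NULL
  if (is.null(genes)) {
    if (is.null(chrom_map)) {
      stop_usage("either a fixed gene set or a chromosome map is required")
    }
    selection <- select_informative_genes(
      cpm, chrom_map, target_chrom = target_chrom, min_fold = min_fold,
      min_high_cpm = min_high_cpm, min_group = min_group)
    genes <- selected_genes(selection)
  }
  calls <- classify(sigma_cpm(cpm, genes),
                    male_threshold = male_threshold,
                    female_threshold = female_threshold)
  attr(calls, "selection") <- selection
  calls
}

#' @describeIn classify `tidy()` returns the calls as a plain tibble.
#' @param x A `sex_calls` object.
#' @param ... Unused.
#' @export
tidy.sex_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "sex_calls")
  out
}

#' @describeIn classify `glance()` returns a one-row summary: sample counts
#'   per label and the thresholds used.
#' @export
glance.sex_calls <- function(x, ...) {
  tibble(n = nrow(x),
         n_male = sum(x$label == "male"),
         n_female = sum(x$label == "female"),
         n_undetermined = sum(x$label == "undetermined"),
         male_threshold = attr(x, "male_threshold"),
         female_threshold = attr(x, "female_threshold"))
}

#' Plot per-sample sexing scores with classification thresholds
#'
#' Scores are drawn on a log10(sigma + 1) axis so the male cluster (hundreds
#' of CPM) and the female cluster (< 2 CPM) are both visible; dashed lines
#' mark the two thresholds.
#'
#' @param object A `sex_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_calls <- function(object, ...) {
  df <- tidy(object) |>
    mutate(sample_id = factor(.data$sample_id, levels = .data$sample_id))
  thr <- c(attr(object, "male_threshold"), attr(object, "female_threshold"))
  ggplot(df, aes(x = .data$sample_id, y = .data$sigma_cpm + 1,
                 colour = .data$label)) +
    geom_point(size = 2) +
    geom_hline(yintercept = thr + 1, linetype = "dashed", colour = "grey40") +
    scale_y_log10() +
    labs(x = NULL, y = expression(Sigma * "CPM (chrY) + 1"),
         colour = "call") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
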