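# Builders and independent oracles shared by the tests. Everything is
# generated in code; no binary fixtures.

tiny_counts <- function() {
  tibble::tibble(gene_id = c("geneA", "geneB", "geneC"),
                 s1 = c(3L, 1L, 0L),
                 s2 = c(10L, 10L, 20L))
}

random_counts <- function(n_genes, n_samples, seed, max_count = 1000L) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1L, n_genes * n_samples,
                         replace = TRUE) - 1L,
              n_genes, n_samples)
  out <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)))
  for (j in seq_len(n_samples)) out[[sprintf("s%02d", j)]] <- m[, j]
  out
}

write_htseq_file <- function(path, genes, counts, summary = NULL) {
  lines <- paste(genes, counts, sep = "\t")
  if (!is.null(summary)) {
    lines <- c(lines, paste(names(summary), summary, sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Independent re-evaluation of the discrepancy criterion: for one vector of
# per-sample CPM values, enumerate every cut position of the sorted values,
# find the cut with the widest gap (first such cut), and apply the three
# conditions literally. Written from the definition, not from the package
# implementation.
oracle_discrepant <- function(v, min_fold = 20, min_high_cpm = 0.3,
                              min_group = 2, epsilon = 0.01) {
  v <- sort(v)
  n <- length(v)
  best_cut <- 0L
  best_gap <- -Inf
  for (cut in seq_len(n - 1)) {
    gap <- v[cut + 1] - v[cut]
    if (gap > best_gap) {
      best_gap <- gap
      best_cut <- cut
    }
  }
  if (best_gap <= 0) return(FALSE)
  low <- v[1:best_cut]
  high <- v[(best_cut + 1):n]
  length(low) >= min_group && length(high) >= min_group &&
    min(high) >= min_high_cpm &&
    min(high) / max(max(low), epsilon) >= min_fold
}

# Independent pairwise leading-logFC distance: full sort, mean of the top
# squared differences, straight from the definition.
oracle_pair_distance <- function(la, lb, top) {
  sq <- sort((la - lb)^2, decreasing = TRUE)
  sqrt(mean(sq[seq_len(min(top, length(sq)))]))
}

# fast small config for simulator unit tests (the autosomal background only
# has to provide a denominator)
small_config <- function(seed, n_male = 5, n_female = 5, ...) {
  sim_config(n_male = n_male, n_female = n_female,
             n_autosomal_genes = 2000, seed = seed, ...)
}

run_pipeline <- function(dataset, ...) {
  cpm <- compute_cpm(dataset$counts)
  sel <- select_informative_genes(cpm, dataset$chrom_map, ...)
  calls <- classify(sigma_cpm(cpm, selected_genes(sel)))
  list(cpm = cpm, selection = sel, calls = calls)
}
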