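# Synthetic sexed RNA-seq count matrices with known truth.
#
# The generator reproduces the statistical structure the sexing analysis
# relies on: an autosomal background of overdispersed (negative-binomial)
# counts that fixes a realistic CPM denominator, a small set of Y-linked
# "informative" genes expressed in males inside per-gene CPM bands, and a
# sparse Poisson "mismapping artifact" channel that puts a trickle of
# Y-gene counts into females (X/Y homology makes short reads mismap).

#' Configuration for the synthetic sexed-count generator
#'
#' @param n_male,n_female Number of male / female samples.
#' @param n_autosomal_genes Autosomal background genes (default 20000).
#' @param n_chrY_genes Total Y-linked genes (default 79).
#' @param n_informative Y-linked genes carrying real male expression
#'   (default 10); must not exceed `n_chrY_genes`.
#' @param library_size_mean Mean counted reads per sample (default 1.3e7,
#'   the order of a typical bulk mRNA-seq library).
#' @param library_size_cv Coefficient of variation of library sizes
#'   (default 0.1).
#' @param male_cpm_bands Tibble with columns `gene_id`, `low`, `high`: the
#'   per-gene CPM band male expression is drawn from (uniformly). Default:
#'   the per-gene male min-max bands of the packaged conceptus fixture,
#'   recycled to `n_informative` genes.
#' @param female_artifact_cpm Per-informative-gene mean artifact CPM in
#'   females (Poisson rate in CPM units). Default: the per-gene female
#'   means of the packaged fixture (0-0.09 CPM; ten-gene total ~0.38 CPM).
#' @param noise_cpm_range Range of per-gene artifact rates (CPM) for the
#'   non-informative Y genes, applied to all samples (default 0.02-0.5).
#' @param autosomal_dispersion Negative-binomial dispersion of the
#'   autosomal background (default 0.1, typical bulk RNA-seq).
#' @param min_separation Feasibility margin: every male band's lower bound
#'   must exceed `min_separation *` that gene's artifact rate (floored at
#'   0.01 CPM), otherwise the config is rejected before any sampling.
#' @param seed Integer seed; the same config generates byte-identical data.
#' @return A `sim_config` object (validated list).
#' @seealso [study_config()] for the published study layout,
#'   [generate_dataset()] to draw data.
#' @export
sim_config <- function(n_male, n_female,
                       n_autosomal_genes = 20000,
                       n_chrY_genes = 79,
                       n_informative = 10,
                       library_size_mean = 1.3e7,
                       library_size_cv = 0.1,
                       male_cpm_bands = NULL,
                       female_artifact_cpm = NULL,
                       noise_cpm_range = c(0.02, 0.5),
                       autosomal_dispersion = 0.1,
                       min_separation = 5,
                       seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female >= 1,
            n_autosomal_genes >= 1, n_chrY_genes >= 1,
            n_informative >= 1, library_size_mean > 0,
            library_size_cv >= 0, autosomal_dispersion > 0,
            min_separation > 0, length(noise_cpm_range) == 2,
            all(noise_cpm_range > 0))
  if (n_informative > n_chrY_genes) {
    abort("n_informative must not exceed n_chrY_genes")
  }

  ref <- fixture_band_defaults()
  if (is.null(male_cpm_bands)) {
    idx <- rep_len(seq_len(nrow(ref$bands)), n_informative)
    male_cpm_bands <- ref$bands[idx, ]
    if (n_informative != nrow(ref$bands)) {
      male_cpm_bands$gene_id <- sprintf("chrY_inf_%03d",
                                        seq_len(n_informative))
    }
  }
  male_cpm_bands <- as_tibble(male_cpm_bands)
  stopifnot(all(c("gene_id", "low", "high") %in% names(male_cpm_bands)),
            nrow(male_cpm_bands) == n_informative,
            all(male_cpm_bands$low > 0),
            all(male_cpm_bands$high >= male_cpm_bands$low))
  if (is.null(female_artifact_cpm)) {
    female_artifact_cpm <- rep_len(ref$artifact, n_informative)
  }
  stopifnot(length(female_artifact_cpm) == n_informative,
            all(female_artifact_cpm >= 0))

  # feasibility: male signal must clear the artifact channel with margin,
  # otherwise the simulated truth would not be recoverable even in principle
  floor_rate <- pmax(female_artifact_cpm, 0.01)
  bad <- male_cpm_bands$low < min_separation * floor_rate
  if (any(bad)) {
    abort(paste0(
      "infeasible config: male CPM band overlaps the female artifact rate ",
      "(within the min_separation margin) for gene(s): ",
      paste(male_cpm_bands$gene_id[bad], collapse = ", ")))
  }

  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_chrY_genes = as.integer(n_chrY_genes),
    n_informative = as.integer(n_informative),
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    male_cpm_bands = male_cpm_bands,
    female_artifact_cpm = female_artifact_cpm,
    noise_cpm_range = noise_cpm_range,
    autosomal_dispersion = autosomal_dispersion,
    min_separation = min_separation,
    seed = as.integer(seed)), class = "sim_config")
}

# per-gene male CPM bands (min-max) and female artifact means from the
# packaged conceptus fixture; computed once per session
fixture_band_defaults <- function() {
  if (is.null(the$band_defaults)) {
    cpm <- conceptus_cpm()
    sex <- conceptus_truth(sample_ids_of(cpm))
    m <- expr_matrix_of(cpm)
    males <- m[, sex == "male", drop = FALSE]
    females <- m[, sex == "female", drop = FALSE]
    the$band_defaults <- list(
      bands = tibble(gene_id = rownames(m),
                     low = unname(apply(males, 1, min)),
                     high = unname(apply(males, 1, max))),
      artifact = unname(rowMeans(females)))
  }
  the$band_defaults
}
the <- new.env(parent = emptyenv())

#' Study-layout configuration: 35 conceptuses, 79 Y genes, 10 markers
#'
#' Returns a [sim_config()] mirroring the published pig-conceptus study:
#' 17 male and 18 female samples, 79 Y-linked genes of which 10 are
#' informative, male CPM bands equal to the per-gene min-max of the
#' packaged fixture's male samples, female artifact rates equal to the
#' fixture's per-gene female means, and ~13 million counted reads per
#' sample.
#'
#' @param seed Integer seed forwarded to the config.
#' @return A `sim_config` object.
#' @export
study_config <- function(seed = 1L) {
  sim_config(n_male = 17, n_female = 18, seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_male, " male + ", x$n_female, " female samples\n",
      "  genes: ", x$n_autosomal_genes, " autosomal + ", x$n_chrY_genes,
      " chrY (", x$n_informative, " informative)\n",
      "  library size ~ ", format(x$library_size_mean, big.mark = ","),
      " (cv ", x$library_size_cv, "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a sexed synthetic count dataset with known truth
#'
#' Draws library sizes log-normally around `library_size_mean`; autosomal
#' counts negative-binomially around log-normal gene-specific means;
#' informative Y-gene counts in males as Poisson around a CPM drawn
#' uniformly in the gene's band; and all remaining Y-gene counts (females,
#' and every sample for non-informative Y genes) as low-rate Poisson
#' mismapping artifacts. Gene-level parameters are drawn from the seed
#' first, then each sample from its own derived substream, so adding
#' samples never perturbs existing ones.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_dataset` list: `counts` (tibble, genes x samples),
#'   `chrom_map` (autosomes `"1"`-`"18"` plus `"Y"`), `truth` (tibble
#'   `sample_id`, `sex`), `informative_genes` (character vector), and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_noise <- config$n_chrY_genes - config$n_informative
  inf_genes <- config$male_cpm_bands$gene_id
  noise_genes <- if (n_noise > 0) sprintf("chrY_noise_%03d", seq_len(n_noise))
                 else character()
  auto_genes <- sprintf("AUTO%05d", seq_len(config$n_autosomal_genes))
  gene_ids <- c(inf_genes, noise_genes, auto_genes)
  stopifnot(!anyDuplicated(gene_ids))

  samples <- c(sprintf("M%02d", seq_len(config$n_male)),
               sprintf("F%02d", seq_len(config$n_female)))
  sex <- rep(c("male", "female"), c(config$n_male, config$n_female))

  # gene-level stream: autosomal expression weights, noise-gene artifact
  # rates, per-sample substream seeds
  set.seed(config$seed)
  w <- rlnorm(config$n_autosomal_genes, meanlog = 0, sdlog = 1.5)
  w <- w / sum(w)
  noise_rate <- runif(n_noise, config$noise_cpm_range[1],
                      config$noise_cpm_range[2])
  sample_seeds <- sample.int(.Machine$integer.max - 1L, length(samples))

  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  cols <- vector("list", length(samples))
  lib_true <- numeric(length(samples))
  for (s in seq_along(samples)) {
    set.seed(sample_seeds[s])
    L <- round(rlnorm(1, log(config$library_size_mean) - sdlog^2 / 2, sdlog))
    lib_true[s] <- L
    inf <- if (sex[s] == "male") {
      target_cpm <- runif(config$n_informative,
                          config$male_cpm_bands$low,
                          config$male_cpm_bands$high)
      rpois(config$n_informative, target_cpm * L / 1e6)
    } else {
      rpois(config$n_informative, config$female_artifact_cpm * L / 1e6)
    }
    noise <- rpois(n_noise, noise_rate * L / 1e6)
    auto <- rnbinom(config$n_autosomal_genes, mu = w * L,
                    size = 1 / config$autosomal_dispersion)
    cols[[s]] <- as.integer(c(inf, noise, auto))
  }

  counts <- bind_cols(tibble(gene_id = gene_ids),
                      as_tibble(setNames(cols, samples)))
  chrom_map <- tibble(
    gene_id = gene_ids,
    chromosome = c(rep("Y", config$n_chrY_genes),
                   rep_len(as.character(1:18), config$n_autosomal_genes)))
  structure(list(counts = counts, chrom_map = chrom_map,
                 truth = tibble(sample_id = samples, sex = sex),
                 informative_genes = inf_genes,
                 library_sizes_drawn = setNames(lib_true, samples),
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$counts), " genes x ",
      nrow(x$truth), " samples (", sum(x$truth$sex == "male"), " male, ",
      sum(x$truth$sex == "female"), " female), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to an output directory
#'
#' Writes `counts.tsv` (genes x samples), `chrom_map.tsv` and `truth.tsv`,
#' the formats the readers in this package consume.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "chrom_map.tsv", "truth.tsv"))
  utils::write.table(as.data.frame(dataset$counts), paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dataset$chrom_map), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dataset$truth), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(setNames(paths, c("counts", "chrom_map", "truth")))
}
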