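# Sample embedding: pairwise leading-logFC distances + classical
# (Torgerson) multidimensional scaling, used to verify that samples
# segregate into two sex groups.

#' Pairwise leading log-fold-change distance between samples
#'
#' Log-expression is `log2(cpm + pseudocount)` with a per-sample pseudocount
#' of `prior / library_size * 1e6` CPM (i.e. `prior` counts scaled to CPM
#' units; when library sizes are unknown the pseudocount is `prior` CPM).
#' The distance between two samples is the root-mean-square of the `top`
#' largest absolute log-expression differences across genes, the gene set
#' being chosen independently for every pair ("pairwise" gene selection, the
#' default behavior of edgeR/limma's plotMDS). If fewer than `top` genes
#' exist, all are used.
#'
#' @param cpm CPM tibble with at least two samples.
#' @param top Number of top genes per pair (default 500).
#' @param prior Prior count for the log pseudocount (default 2).
#' @return A symmetric sample-by-sample matrix of distances with zero
#'   diagonal.
#' @export
leading_logfc_distance <- function(cpm, top = 500, prior = 2) {
  validate_expr_table(cpm, "cpm")
  stopifnot(top >= 1, prior > 0)
  samples <- sample_ids_of(cpm)
  n <- length(samples)
  if (n < 2) abort("need at least 2 samples to compute distances")

  m <- expr_matrix_of(cpm)
  lib <- library_sizes(cpm)
  pseudo <- if (is.null(lib)) rep(prior, n) else prior / lib * 1e6
  lg <- log2(sweep(m, 2, pseudo, "+"))

  ntop <- min(top, nrow(lg))
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sq <- (lg[, i] - lg[, j])^2
      topsq <- sort(sq, decreasing = TRUE)[seq_len(ntop)]
      d[i, j] <- d[j, i] <- sqrt(mean(topsq))
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns the top-`k` eigenvectors scaled by the square root of their
#' (non-negative) eigenvalues. Axis signs are arbitrary. Negative
#' eigenvalues — which arise when the distances are not exactly Euclidean —
#' are clamped to zero coordinates with a warning rather than an error.
#'
#' @param d Symmetric distance matrix (e.g. from
#'   [leading_logfc_distance()]), a `dist` object, or anything `as.dist()`
#'   accepts.
#' @param k Number of embedding dimensions; must satisfy
#'   `1 <= k < n_samples`.
#' @return A `sex_mds` object: list with `sample_ids`, `points` (an
#'   `n x k` matrix, each column centered on zero), and `eig` (all
#'   eigenvalues, non-increasing). Use [tidy()] for a tibble of coordinates
#'   and [write_mds_coords()] to export.
#' @export
classical_mds <- function(d, k = 2) {
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k < 1 || k >= n) {
    abort(paste0("k must be in [1, ", n - 1, "], got ", k))
  }
  fit <- suppressWarnings(cmdscale(dd, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    warn("distance matrix is not Euclidean in k dimensions; padding clamped axes with zeros")
    pad <- matrix(0, n, k - ncol(pts))
    pts <- cbind(pts, pad)
  } else if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warn("negative eigenvalues clamped to zero (non-Euclidean distances)")
  }
  ids <- attr(dd, "Labels")
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  rownames(pts) <- ids
  colnames(pts) <- paste0("dim", seq_len(k))
  structure(list(sample_ids = ids, points = pts,
                 eig = sort(fit$eig, decreasing = TRUE)),
            class = "sex_mds")
}

#' @export
print.sex_mds <- function(x, ...) {
  cat("Classical MDS embedding: ", length(x$sample_ids), " samples, ",
      ncol(x$points), " dimensions\n", sep = "")
  pos <- pmax(x$eig, 0)
  ve <- pos[seq_len(ncol(x$points))] / sum(pos)
  cat("variance explained:", paste0(sprintf("%.1f%%", 100 * ve),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn classical_mds `tidy()` returns a tibble with `sample_id` and
#'   one `dim<i>` column per embedding axis.
#' @param x A `sex_mds` object.
#' @param ... Unused.
#' @export
tidy.sex_mds <- function(x, ...) {
  bind_cols(tibble(sample_id = x$sample_ids), as_tibble(x$points))
}

#' @describeIn classical_mds `glance()` returns a one-row summary with the
#'   sample count, dimensions, and fraction of (clamped) eigenvalue mass
#'   captured.
#' @export
glance.sex_mds <- function(x, ...) {
  pos <- pmax(x$eig, 0)
  tibble(n_samples = length(x$sample_ids),
         k = ncol(x$points),
         prop_variance = sum(pos[seq_len(ncol(x$points))]) / sum(pos),
         n_negative_eig = sum(x$eig < 0))
}

#' Scatter plot of an MDS embedding
#'
#' @param object A `sex_mds` object (needs at least two dimensions).
#' @param labels Optional vector (named by sample or in sample order) used
#'   to color points, e.g. sex calls.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_mds <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  if (ncol(object$points) < 2) abort("need a 2-D embedding to plot")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[df$sample_id]
    df$label <- labels
    p <- ggplot(df, aes(x = .data$dim1, y = .data$dim2,
                        colour = .data$label))
  } else {
    p <- ggplot(df, aes(x = .data$dim1, y = .data$dim2))
  }
  p + geom_point(size = 2) +
    labs(x = "MDS dimension 1", y = "MDS dimension 2", colour = NULL) +
    theme_minimal()
}

#' Write MDS coordinates to TSV
#'
#' Eigenvalues are written first as `#`-prefixed comment lines, followed by
#' a header (`sample_id`, `dim1`, ...) and one row per sample.
#'
#' @param mds A `sex_mds` object.
#' @param path Output file path.
#' @return `mds`, invisibly.
#' @export
write_mds_coords <- function(mds, path) {
  stopifnot(inherits(mds, "sex_mds"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eigenvalue %d\t%.10g", seq_along(mds$eig), mds$eig),
             con)
  utils::write.table(as.data.frame(tidy(mds)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(mds)
}
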