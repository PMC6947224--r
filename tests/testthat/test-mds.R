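# Leading-logFC distances and the classical MDS embedding.

test_that("identical samples are at distance zero and distance axioms hold", {
  cpm <- as_cpm(tibble::tibble(gene_id = c("g1", "g2", "g3"),
                               a = c(1, 10, 100), b = c(1, 10, 100),
                               c = c(5, 50, 500)))
  d <- leading_logfc_distance(cpm, top = 3)
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  expect_error(leading_logfc_distance(as_cpm(cpm[, 1:2])), "2 samples")
})

test_that("pair distances equal the brute-force top-gene RMS, with per-sample pseudocounts", {
  # hand case: 3 genes, 2 samples, known library sizes
  cpm <- as_cpm(tibble::tibble(gene_id = c("g1", "g2", "g3"),
                               a = c(100, 10, 1), b = c(1, 10, 100)),
                library_sizes = c(a = 1e6, b = 2e6))
  d <- leading_logfc_distance(cpm, top = 3, prior = 2)
  la <- log2(c(100, 10, 1) + 2)           # pseudo = 2/1e6*1e6
  lb <- log2(c(1, 10, 100) + 1)           # pseudo = 2/2e6*1e6
  expect_equal(d["a", "b"], sqrt(mean((la - lb)^2)))

  # random case vs the independent oracle, top smaller than the gene count
  set.seed(9)
  n <- 120
  m <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                      s1 = runif(n, 0, 300), s2 = runif(n, 0, 300),
                      s3 = runif(n, 0, 300))
  d2 <- leading_logfc_distance(as_cpm(m), top = 25)
  lg <- log2(as.matrix(m[, -1]) + 2)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(d2[pair[1], pair[2]],
                 oracle_pair_distance(lg[, pair[1]], lg[, pair[2]], top = 25))
  }
})

test_that("distance plus embedding reproduces limma's pairwise plotMDS", {
  skip_if_not_installed("limma")
  set.seed(31)
  n <- 300
  vals <- matrix(runif(n * 6, 0, 100), n, 6,
                 dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:6)))
  cpm <- as_cpm(dplyr::bind_cols(tibble::tibble(gene_id = rownames(vals)),
                                 tibble::as_tibble(vals)))
  emb <- classical_mds(leading_logfc_distance(cpm, top = 80), k = 2)
  ref <- limma::plotMDS(log2(vals + 2), top = 80,
                        gene.selection = "pairwise", plot = FALSE)
  lam <- pmax(ref$eigen.values, 0)
  pts <- ref$eigen.vectors[, 1:2] %*% diag(sqrt(lam[1:2]))
  for (j in 1:2) {                         # axis signs are arbitrary
    if (sum(pts[, j] * emb$points[, j]) < 0) pts[, j] <- -pts[, j]
  }
  expect_equal(unname(emb$points), unname(pts), tolerance = 1e-10)
  expect_equal(head(emb$eig, 4),
               head(sort(ref$eigen.values, decreasing = TRUE), 4))
})

test_that("classical MDS recovers exact Euclidean configurations", {
  # collinear points with distances 1, 1, 2 embed exactly in 1-D
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  emb <- classical_mds(d, k = 1)
  expect_equal(unname(as.matrix(dist(emb$points))), unname(d),
               tolerance = 1e-9)
  expect_equal(mean(emb$points[, 1]), 0, tolerance = 1e-9)

  # random planar configurations round-trip through their distance matrix
  for (seed in 1:5) {
    set.seed(seed)
    xy <- matrix(rnorm(16), 8, 2)
    emb2 <- classical_mds(as.matrix(dist(xy)), k = 2)
    expect_equal(as.matrix(dist(emb2$points)), as.matrix(dist(xy)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(colMeans(emb2$points)), c(0, 0), tolerance = 1e-9)
    expect_true(all(diff(emb2$eig) <= 1e-9))
  }
  expect_error(classical_mds(d, k = 3), "k must be")
  expect_error(classical_mds(d, k = 0), "k must be")
})

test_that("on the conceptus fixture every between-sex distance exceeds every within-sex distance and dimension 1 splits the sexes", {
  cpm <- conceptus_cpm()
  d <- leading_logfc_distance(cpm)
  sex <- conceptus_truth(colnames(d))
  between <- d[sex == "male", sex == "female"]
  within_m <- d[sex == "male", sex == "male"]
  within_f <- d[sex == "female", sex == "female"]
  expect_gt(min(between),
            max(within_m[upper.tri(within_m)], within_f[upper.tri(within_f)]))

  emb <- classical_mds(d, k = 2)
  km <- kmeans(emb$points[, 1], centers = 2, nstart = 10)
  tab <- table(km$cluster, sex)
  expect_true(all(rowSums(tab == 0) == 1))   # each cluster is single-sex
  expect_setequal(as.vector(tab[tab > 0]), c(17, 18))
})

test_that("coordinates export with eigenvalue comments and re-read coherently", {
  emb <- classical_mds(leading_logfc_distance(conceptus_cpm()), k = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mds_coords(emb, f)
  lines <- readLines(f)
  n_eig <- sum(startsWith(lines, "#"))
  expect_identical(n_eig, length(emb$eig))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  expect_identical(names(body), c("sample_id", "dim1", "dim2"))
  expect_equal(body$dim1, unname(emb$points[, 1]), tolerance = 1e-6)

  td <- tidy(emb)
  expect_identical(names(td), c("sample_id", "dim1", "dim2"))
  p <- autoplot(emb, labels = conceptus_truth(emb$sample_ids))
  expect_s3_class(p, "ggplot")
})
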