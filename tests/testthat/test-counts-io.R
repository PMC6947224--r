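# Readers and writers: HTSeq files, count matrices, chromosome maps,
# sex reports.

test_that("read_htseq_counts parses the two-column dialect and keeps summary totals as metadata", {
  f1 <- write_htseq_file(withr::local_tempfile(fileext = ".counts"),
                         c("geneA", "geneB"), c(5L, 0L),
                         summary = c("__no_feature" = 3L))
  counts <- read_htseq_counts(f1)
  expect_identical(counts$gene_id, c("geneA", "geneB"))
  expect_identical(counts[[2]], c(5L, 0L))
  s <- summary_counts(counts)
  expect_identical(s$category, "__no_feature")
  expect_identical(s$count, 3L)
  # summary rows never leak into the gene table
  expect_false(any(startsWith(counts$gene_id, "__")))
  # sample id defaults to the basename without extension
  expect_identical(names(counts)[2],
                   sub("\\.counts$", "", basename(f1)))
})

test_that("read_htseq_counts binds multiple files in input order and enforces a shared gene set", {
  d <- withr::local_tempdir()
  f1 <- write_htseq_file(file.path(d, "a.txt"),
                         c("g1", "g2", "g3"), c(1L, 2L, 3L))
  f2 <- write_htseq_file(file.path(d, "b.txt"),
                         c("g1", "g2", "g3"), c(4L, 5L, 6L))
  counts <- read_htseq_counts(c(f1, f2))
  expect_identical(names(counts), c("gene_id", "a", "b"))
  expect_identical(counts$b, c(4L, 5L, 6L))

  f3 <- write_htseq_file(file.path(d, "c.txt"), c("g1", "g2"), c(1L, 2L))
  expect_error(read_htseq_counts(c(f1, f3)),
               class = "sexcallr_consistency_error", regexp = "g3")
})

test_that("malformed HTSeq lines fail with file and line context", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.txt")
  writeLines(c("g1\t5", "g2\tnotanumber"), f)
  expect_error(read_htseq_counts(f), class = "sexcallr_parse_error",
               regexp = "bad.txt:2")
  writeLines(c("g1\t5", "g2 6"), f)
  expect_error(read_htseq_counts(f), class = "sexcallr_parse_error",
               regexp = "2 tab-separated")
})

test_that("read_counts_matrix preserves layout, strips __ rows, rejects duplicates and bad cells", {
  d <- withr::local_tempdir()
  f <- file.path(d, "m.tsv")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2", "g2\t3\t4", "__ambiguous\t9\t9"), f)
  counts <- read_counts_matrix(f)
  expect_identical(counts$gene_id, c("g1", "g2"))
  expect_identical(names(counts), c("gene_id", "S1", "S2"))
  expect_identical(counts$S2, c(2, 4))
  expect_identical(sort(unique(summary_counts(counts)$category)),
                   "__ambiguous")

  writeLines(c("gene\tS1\tS1", "g1\t1\t2"), f)
  expect_error(read_counts_matrix(f), "S1")
  writeLines(c("gene\tS1", "g1\t1", "g1\t2"), f)
  expect_error(read_counts_matrix(f), "g1")
  writeLines(c("gene\tS1\tS2", "g1\t1\t2.5"), f)
  expect_error(read_counts_matrix(f), class = "sexcallr_parse_error",
               regexp = "g1.*S2")
  writeLines(c("gene\tS1\tS2", "g1\t1\t-2"), f)
  expect_error(read_counts_matrix(f), class = "sexcallr_parse_error")
})

test_that("reading k single-sample HTSeq files equals reading their column-bound matrix", {
  d <- withr::local_tempdir()
  set.seed(11)
  genes <- sprintf("g%03d", 1:40)
  paths <- character(3)
  mat_lines <- paste0("gene\tsA\tsB\tsC")
  cols <- list()
  for (i in 1:3) {
    cnt <- sample.int(500L, 40, replace = TRUE)
    cols[[i]] <- cnt
    paths[i] <- write_htseq_file(file.path(d, paste0("s", LETTERS[i], ".txt")),
                                 genes, cnt)
  }
  writeLines(c("gene\tsA\tsB\tsC",
               paste(genes, cols[[1]], cols[[2]], cols[[3]], sep = "\t")),
             file.path(d, "matrix.tsv"))
  from_files <- read_htseq_counts(paths)
  from_matrix <- read_counts_matrix(file.path(d, "matrix.tsv"))
  expect_equal(as.data.frame(from_files),
               as.data.frame(lapply(from_matrix, function(x)
                 if (is.numeric(x)) as.integer(x) else x)),
               ignore_attr = TRUE)
})

test_that("chromosome maps load from GTF and TSV with normalized names", {
  d <- withr::local_tempdir()
  gtf <- file.path(d, "ann.gtf")
  writeLines(c(
    "#!genome-build Sscrofa11.1",
    "Y\tensembl\tgene\t1\t100\t.\t+\t.\tgene_id \"DDX3Y\"; gene_name \"DDX3Y\";",
    "Y\tensembl\ttranscript\t1\t100\t.\t+\t.\tgene_id \"DDX3Y\";",
    "chr1\tensembl\tgene\t1\t100\t.\t-\t.\tgene_id \"GAPDH\";"), gtf)
  map <- read_chrom_map_gtf(gtf)
  expect_identical(chrom_of(map, c("DDX3Y", "GAPDH")), c("Y", "1"))

  # only 'gene' rows are consulted
  expect_identical(nrow(map), 2L)

  # same gene on two chromosomes is an error
  writeLines(c(
    "1\tensembl\tgene\t1\t9\t.\t+\t.\tgene_id \"X1\";",
    "Y\tensembl\tgene\t1\t9\t.\t+\t.\tgene_id \"X1\";"), gtf)
  expect_error(read_chrom_map_gtf(gtf),
               class = "sexcallr_consistency_error", regexp = "X1")
  writeLines("1\tensembl\ttranscript\t1\t9\t.\t+\t.\tgene_id \"X1\";", gtf)
  expect_error(read_chrom_map_gtf(gtf), class = "sexcallr_parse_error")

  tsv <- file.path(d, "map.tsv")
  writeLines(c("gene\tchrom", "DDX3Y\tchrY", "GAPDH\t1"), tsv)
  map2 <- read_chrom_map_tsv(tsv)
  expect_identical(chrom_of(map2, "DDX3Y"), "Y")   # header skipped, chr stripped
  writeLines(c("A\t1", "A\tY"), tsv)
  expect_error(read_chrom_map_tsv(tsv), class = "sexcallr_consistency_error")

  # unmapped lookups are loud, not NA
  expect_error(chrom_of(map2, "NOPE"), class = "sexcallr_consistency_error",
               regexp = "NOPE")
})

test_that("sex reports round-trip at two-decimal precision with half-up rounding", {
  calls <- classify(tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    sigma_cpm = c(486.84, 0.125, 200),
    n_genes_used = 10L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sex_report(calls, f)
  lines <- readLines(f)
  expect_identical(lines[1], "sample_id\tsigma_cpm\tlabel\tn_genes_used")
  expect_identical(lines[2], "S1\t486.84\tmale\t10")
  expect_identical(lines[3], "S2\t0.13\tfemale\t10")    # half rounds up

  back <- read_sex_report(f)
  expect_identical(back$label, calls$label)
  expect_equal(back$sigma_cpm, round_half_up(calls$sigma_cpm, 2))

  # writing the re-read table reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sex_report(classify(back), f2)
  expect_identical(readLines(f2), lines)

  # empty table -> header-only file
  empty <- classify(tibble::tibble(sample_id = character(),
                                   sigma_cpm = numeric()))
  write_sex_report(empty, f)
  expect_identical(readLines(f), lines[1])
})
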