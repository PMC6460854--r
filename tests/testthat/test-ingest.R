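test_that("counts_to_tpm matches hand-derived values and normalizes columns", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- counts_to_tpm(counts, lengths = c(100, 200))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)

  # single gene: normalization forces 1e6 whatever the count
  expect_equal(unname(counts_to_tpm(matrix(7, 1, 1,
    dimnames = list("g", "s")), 500)[1, 1]), 1e6)

  # columns sum to 1e6 and per-sample rescaling is a no-op, random inputs
  set.seed(11)
  for (i in 1:5) {
    cm <- matrix(rpois(60, 50), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    len <- runif(10, 200, 5000)
    tpm <- counts_to_tpm(cm, len)
    expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)
    scaled <- sweep(cm, 2, c(2, 3, 0.5, 10, 1, 7), "*")
    expect_equal(counts_to_tpm(scaled, len), tpm, tolerance = 1e-9)
  }
})

test_that("counts_to_tpm rejects degenerate input", {
  cm <- matrix(c(1, 1, 0, 0), 2, 2,
               dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(counts_to_tpm(cm, c(100, 100)), "all-zero sample.*empty")
  expect_error(counts_to_tpm(cm[, 1, drop = FALSE], c(100, -1)), "length")
})

test_that("average_replicates averages on the linear scale", {
  tpm <- matrix(c(4, 8, 5, 5), 1, 4,
                dimnames = list("g", paste0("s", 1:4)))
  map <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  em <- average_replicates(tpm, map)
  # (4 + 8)/2 = 6, not 2^((2+3)/2)
  expect_equal(unname(em$values["g", "A"]), 6)
  expect_equal(ncol(em$values), 2)
  expect_identical(colnames(em$values), c("A", "B"))

  # single replicate passes through; output bounded by replicate range
  set.seed(3)
  tpm2 <- matrix(runif(30, 0, 100), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  map2 <- setNames(c("x", "x", "x", "y", "y", "z"), colnames(tpm2))
  em2 <- average_replicates(tpm2, map2)
  expect_equal(em2$values[, "z"], tpm2[, "s6"])
  for (cond in c("x", "y")) {
    cols <- names(map2)[map2 == cond]
    expect_true(all(em2$values[, cond] >=
                      apply(tpm2[, cols, drop = FALSE], 1, min) - 1e-12))
    expect_true(all(em2$values[, cond] <=
                      apply(tpm2[, cols, drop = FALSE], 1, max) + 1e-12))
  }
  expect_error(average_replicates(tpm2, map2[-1]), "unmapped.*s1")
})

test_that("expression TSV round-trips and rejects bad files", {
  set.seed(7)
  m <- matrix(round(runif(6, 0, 1000), 4), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("condA", "condB")))
  em <- expression_matrix(m)
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(em, path)
  back <- read_expression_tsv(path)
  expect_identical(rownames(back$values), rownames(m))
  expect_identical(colnames(back$values), colnames(m))
  expect_equal(back$values, m, tolerance = 1e-9)

  dup <- tempfile(); writeLines(c("gene\tA\tB", "g1\t1\t2", "g1\t3\t4"), dup)
  expect_error(read_expression_tsv(dup), "duplicate gene id.*g1")

  nafile <- tempfile(); writeLines(c("gene\tA\tB", "g1\t1\tNA"), nafile)
  expect_error(read_expression_tsv(nafile), "row 1.*'B'")

  ragged <- tempfile(); writeLines(c("gene\tA\tB", "g1\t1\t2", "g2\t3"), ragged)
  expect_error(read_expression_tsv(ragged), "ragged.*row 3")
})

test_that("fastq filter applies the N and low-quality rules at the boundary", {
  recs <- list(
    make_read("has_N", len = 50, with_N = TRUE),        # dropped_N
    make_read("ten_low", n_low = 10),                   # kept (10 is allowed)
    make_read("eleven_low", n_low = 11),                # dropped_quality
    make_read("clean"),                                 # kept
    make_read("q19_boundary", n_low = 11, q_low = 20)   # Q20 not < 20: kept
  )
  path <- write_test_fastq(recs)
  out <- tempfile(fileext = ".fastq")
  counts <- filter_fastq(path, output = out)
  expect_equal(counts, list(kept = 3, dropped_N = 1, dropped_quality = 1,
                            total = 5))
  kept_names <- sub("^@", "", readLines(out)[c(TRUE, FALSE, FALSE, FALSE)])
  expect_identical(kept_names, c("ten_low", "clean", "q19_boundary"))
})

test_that("fastq filter handles gzip, phred64 and paired mode", {
  recs <- list(make_read("a"), make_read("b", n_low = 11))
  gz <- tempfile(fileext = ".fastq.gz")
  lines <- unlist(lapply(recs, function(r)
    c(paste0("@", r$name), r$seq, "+", intToUtf8(r$quals + 33))))
  con <- gzfile(gz, "wt"); writeLines(lines, con); close(con)
  expect_equal(filter_fastq(gz)$kept, 1)

  p64 <- write_test_fastq(list(make_read("x", n_low = 11)), offset = 64)
  expect_equal(filter_fastq(p64, phred_offset = 64)$dropped_quality, 1)
  expect_error(filter_fastq(p64, phred_offset = 30), "33 or 64")

  # paired: pair dropped when either mate fails; counts are pairs
  r1 <- write_test_fastq(list(make_read("p1"), make_read("p2"),
                              make_read("p3", with_N = TRUE)))
  r2 <- write_test_fastq(list(make_read("p1"), make_read("p2", n_low = 11),
                              make_read("p3")))
  o1 <- tempfile(); o2 <- tempfile()
  counts <- filter_fastq(r1, o1, input2 = r2, output2 = o2)
  expect_equal(counts, list(kept = 1, dropped_N = 1, dropped_quality = 1,
                            total = 3))
  expect_equal(length(readLines(o1)), 4)
  expect_equal(length(readLines(o2)), 4)
})

test_that("fastq filter errors name the malformed record", {
  bad <- tempfile()
  writeLines(c("@ok", "ACGT", "+", "IIII", "notheader", "ACGT", "+", "IIII"),
             bad)
  expect_error(filter_fastq(bad), "record 2.*'@'")
  mismatch <- tempfile()
  writeLines(c("@r", "ACGT", "+", "III"), mismatch)
  expect_error(filter_fastq(mismatch), "record 1.*lengths differ")
  truncated <- tempfile()
  writeLines(c("@r", "ACGT", "+"), truncated)
  expect_error(filter_fastq(truncated), "multiple of 4")
})

test_that("filter counts partition any generated input", {
  for (seed in 1:3) {
    g <- gen_fastq(n_reads = 200, read_len = 40, fraction_with_N = 0.2,
                   fraction_low_quality = 0.15, fraction_boundary = 0.1,
                   seed = seed)
    counts <- filter_fastq(g$path)
    expect_equal(counts$kept + counts$dropped_N + counts$dropped_quality,
                 counts$total)
    expect_equal(counts$total, 200)
  }
})
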