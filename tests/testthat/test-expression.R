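toy_call <- function(chrom = "chr1", start = 1000L, end = 2000L,
                     strand = "+", id = "NTR1", exonic = end - start) {
  tibble::tibble(ntr_id = id, chrom = chrom, start = start, end = end,
                 strand = strand, exonic_length = as.integer(exonic),
                 cov_starts = list(start), cov_ends = list(end))
}

test_that("read counting is span overlap on the same strand", {
  call <- toy_call()
  reads <- make_reads(
    make_read("chr1", 990, 1040, "+"),
    make_read("chr1", 1500, 1550, "+"),
    make_read("chr1", 1990, 2040, "+"),
    make_read("chr1", 1500, 1550, "-"),
    make_read("chr1", 1400, 1450, "-"),
    make_read("chr1", 2000, 2050, "+")   # bookended: zero overlap
  )
  expect_equal(count_reads(call, reads)$count, 3L)
  expect_equal(count_reads(call, reads[0, ])$count, 0L)

  # a spliced read whose intron spans the call counts by span, not blocks
  jumper <- make_read("chr1", NULL, NULL, "+", id = "j",
                      blocks = list(starts = c(500, 2500),
                                    ends = c(550, 2550)))
  expect_equal(count_reads(call, jumper)$count, 1L)
  expect_equal(count_reads(call, jumper, by = "blocks")$count, 0L)
})

test_that("read counting matches a per-read scan on random fixtures", {
  set.seed(31)
  reads <- random_reads(300)
  calls <- purrr::map(1:10, function(i) {
    s <- sample.int(15000, 1)
    toy_call(sample(c("chr1", "chr2"), 1), s, s + sample(500:3000, 1),
             sample(c("+", "-"), 1), id = paste0("NTR", i))
  }) |> purrr::list_rbind()
  got <- count_reads(calls, reads)$count
  expected <- vapply(seq_len(nrow(calls)),
                     function(i) oracle_count(calls[i, ], reads), numeric(1))
  expect_equal(got, as.integer(expected))
})

test_that("FPKM implements its definition with scale symmetries", {
  expect_equal(fpkm(1000, 2000, 1e7), 50)
  expect_equal(fpkm(0, 2000, 1e7), 0)
  expect_error(fpkm(10, 0, 1e7), "exonic_length")
  expect_error(fpkm(10, 2000, 0), "library_size")
  set.seed(32)
  for (rep in 1:20) {
    count <- sample.int(5000, 1); len <- sample.int(10000, 1)
    lib <- sample.int(1e8, 1)
    base <- fpkm(count, len, lib)
    expect_equal(fpkm(3 * count, len, lib), 3 * base)
    expect_equal(fpkm(count, 2 * len, lib), base / 2)
    expect_equal(fpkm(count, len, 2 * lib), base / 2)
  }
})

test_that("fold change uses the baseline stage and flags zero baselines", {
  mat <- tibble::tibble(
    ntr_id = c("NTR1", "NTR2", "NTR133"),
    `1-cell` = c(2, 5, 0), `16-cell` = c(4, 5, 1),
    `512-cell` = c(6, 10, 2), epiboly50 = c(8, 2.5, 3)
  )
  fc <- fold_change(mat, "1-cell")
  expect_equal(fc$`1-cell`[1:2], c(1, 1))           # baseline vs itself
  expect_equal(fc$`16-cell`[1], 2)
  expect_equal(fc$epiboly50[2], 0.5)
  # zero baseline: flagged undefined, never numeric/infinite
  expect_true(fc$baseline_undefined[3])
  expect_true(all(is.na(fc$`512-cell`[3])))
  expect_false(any(is.infinite(unlist(fc[sapply(fc, is.numeric)]))))
  expect_error(fold_change(mat, "8-cell"), "baseline")
})

test_that("row scaling centres and standardises each NTR profile", {
  mat <- tibble::tibble(ntr_id = c("a", "b"),
                        s1 = c(1, 3), s2 = c(2, 3), s3 = c(3, 3),
                        s4 = c(4, 3))
  sc <- scale_rows(mat)
  row <- as.numeric(sc[1, -1])
  expect_equal(mean(row), 0)
  expect_equal(sd(row), 1)
  expect_equal(as.numeric(sc[2, -1]), rep(0, 4))    # constant row -> zeros
  set.seed(33)
  for (rep in 1:10) {
    m <- tibble::as_tibble(matrix(runif(40, 0, 100), nrow = 10,
                                  dimnames = list(NULL, paste0("s", 1:4))))
    m <- dplyr::bind_cols(tibble::tibble(ntr_id = paste0("n", 1:10)), m)
    sc <- scale_rows(m)
    expect_true(all(abs(rowMeans(as.matrix(sc[-1]))) <= 1e-9))
  }
})

test_that("profile classification follows the documented rule order", {
  expect_equal(classify_profile(c(5, 3, 1, 0.5)), "maternal_decay")
  expect_equal(classify_profile(c(0.1, 0.2, 5, 1)), "mbt_peak")
  expect_equal(classify_profile(c(0.1, 0.1, 0.5, 2)), "post_mbt_up")
  expect_equal(classify_profile(c(0.5, 0.5, 0.5, 0.5)), "low_flat")
  expect_equal(classify_profile(c(8, 2, 6, 1)), "other")
  expect_error(classify_profile(c(1, 2, 3)), "4 stages")
  # totality: every non-negative 4-vector maps to exactly one class
  set.seed(34)
  classes <- c("maternal_decay", "post_mbt_up", "mbt_peak", "low_flat",
               "other")
  for (rep in 1:200) {
    x <- runif(4, 0, 20) * sample(c(0, 1), 4, replace = TRUE)
    expect_true(classify_profile(x) %in% classes)
  }
})

test_that("the FPKM matrix wires counting, lengths, and library sizes together", {
  sim <- simulate_reads(sim_config(seed = 4, n_genes = 2, n_ntrs = 3,
                                   decoy_singletons = 0))
  res <- run_discovery(sim$reads, sim$genes)
  stages <- list(`1-cell` = sim$reads,
                 `16-cell` = sim$reads[1:2000, ])
  mat <- fpkm_matrix(tidy(res), stages)
  expect_equal(names(mat), c("ntr_id", "1-cell", "16-cell"))
  expect_true(all(as.matrix(mat[-1]) >= 0))
  # spot-check one cell against the scalar definition
  counts <- count_reads(tidy(res), stages[["16-cell"]])$count
  expect_equal(mat$`16-cell`[1],
               fpkm(counts[1], tidy(res)$exonic_length[1], 2000))
  expect_error(fpkm_matrix(tidy(res), unname(stages)), "named")
})
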