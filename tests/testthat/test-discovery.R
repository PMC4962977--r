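ann_single <- function(start, end, strand = "+", chrom = "chr1") {
  make_transcript("t1", chrom, start, end, strand)
}

test_that("distance to annotation is the half-open gap, 0 on overlap, Inf off-strand", {
  frag <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L,
                         strand = "+")
  expect_equal(distance_to_annotation(frag, ann_single(0, 1000)), 1000)
  expect_equal(distance_to_annotation(frag, ann_single(2400, 3000)), 0)
  expect_equal(distance_to_annotation(frag, ann_single(0, 1000, "-")), Inf)
  expect_equal(distance_to_annotation(frag, ann_single(0, 1000, "-"),
                                      same_strand = FALSE), 1000)
  # downstream side and nearest-of-both-sides
  both <- dplyr::bind_rows(ann_single(0, 1000), ann_single(2600, 3000))
  expect_equal(distance_to_annotation(frag, both), 100)
})

test_that("distance agrees with an O(n*m) scan on random fixtures", {
  set.seed(21)
  frags <- build_fragments(random_reads(150))
  ann <- purrr::map(1:15, function(i) {
    s <- sample.int(20000, 1)
    make_transcript(paste0("t", i), sample(c("chr1", "chr2"), 1), s,
                    s + sample(200:3000, 1), sample(c("+", "-"), 1))
  }) |> purrr::list_rbind()
  for (same in c(TRUE, FALSE)) {
    expect_equal(distance_to_annotation(frags, ann, same_strand = same),
                 oracle_distance(frags, ann, same_strand = same))
  }
})

test_that("D1 exclusion boundary is inclusive: gap == D1 removed, D1+1 kept", {
  p <- discovery_params(d1 = 1000)
  mk <- function(gap) {
    frag <- build_fragments(make_read("chr1", 1000 + gap, 1200 + gap, "+"))
    filter_fragments(frag, ann_single(0, 1000), p)$status
  }
  expect_equal(mk(1000), "proximal")
  expect_equal(mk(1001), "kept")
  expect_equal(mk(0), "in_annotation")     # overlap impossible at gap 0; bookended counts as distance 0
  expect_equal(mk(-100), "in_annotation")  # true overlap
})

test_that("fragment filtering partitions the input; empty annotation keeps all", {
  set.seed(22)
  frags <- build_fragments(random_reads(300))
  ann <- purrr::map(1:10, function(i) {
    s <- sample.int(20000, 1)
    make_transcript(paste0("t", i), sample(c("chr1", "chr2"), 1), s,
                    s + 2000L, sample(c("+", "-"), 1))
  }) |> purrr::list_rbind()
  out <- filter_fragments(frags, ann)
  expect_equal(sum(out$status == "kept") + sum(out$status == "in_annotation") +
                 sum(out$status == "proximal"), nrow(frags))
  none <- filter_fragments(frags, ann[0, ])
  expect_true(all(none$status == "kept"))
})

test_that("clustering links fragments at gap <= D2 (with a strict switch)", {
  reads <- make_reads(
    make_read("chr1", 0, 100, "+"),
    make_read("chr1", 3000, 3100, "+"),
    make_read("chr1", 9000, 9100, "+")
  )
  frags <- build_fragments(reads)
  cl <- cluster_fragments(frags, discovery_params(d2 = 5000))
  expect_equal(cl$n_fragments, c(2L, 1L))       # gaps 2900 and 5900
  expect_equal(cl$start, c(0L, 9000L))

  one <- cluster_fragments(frags[1, ], discovery_params())
  expect_equal(one$n_fragments, 1L)

  # boundary: gap exactly D2 links by default, not under strict linkage
  b <- build_fragments(make_reads(make_read("chr1", 0, 100, "+"),
                                  make_read("chr1", 5100, 5200, "+")))
  expect_equal(nrow(cluster_fragments(b, discovery_params(d2 = 5000))), 1L)
  expect_equal(nrow(cluster_fragments(b, discovery_params(d2 = 5000,
                                                          strict_d2 = TRUE))),
               2L)
})

test_that("clustering matches a transitive-closure oracle on random fixtures", {
  set.seed(23)
  for (rep in 1:5) {
    frags <- build_fragments(random_reads(200, span = 100000L))
    d2 <- sample(c(500, 2000, 5000), 1)
    got <- cluster_fragments(frags, discovery_params(d2 = d2))
    oracle <- oracle_clusters(frags, d2)
    expect_equal(got[c("chrom", "start", "end", "strand", "n_fragments")],
                 oracle[c("chrom", "start", "end", "strand", "n_fragments")])
  }
})

test_that("junction and singleton rules classify clusters", {
  p <- discovery_params()
  base <- function(n_junc, n_frag, len) {
    tibble::tibble(
      chrom = "chr1", start = 0L, end = as.integer(len), strand = "+",
      n_fragments = as.integer(n_frag), read_count = 5L,
      n_junctions = as.integer(n_junc),
      junctions = list(tibble::tibble(intron_start = integer(),
                                      intron_end = integer(),
                                      support = integer())),
      frag_starts = list(0L), frag_ends = list(as.integer(len)),
      cov_starts = list(0L), cov_ends = list(as.integer(len))
    )
  }
  expect_equal(filter_clusters(base(2, 3, 500), p)$status, "candidate")
  expect_equal(filter_clusters(base(1, 3, 500), p)$status,
               "rejected_few_junctions")
  expect_equal(filter_clusters(base(0, 1, 60), p)$status, "singleton")
  expect_equal(filter_clusters(base(0, 1, 40), p)$status,
               "rejected_few_junctions")
  # boundary: exactly 50 bp is NOT over 50 bp
  expect_equal(filter_clusters(base(0, 1, 50), p)$status,
               "rejected_few_junctions")
})

test_that("secondary subtraction removes same-strand overlap only", {
  cand <- filter_clusters(cluster_fragments(build_fragments(make_reads(
    make_read("chr1", NULL, NULL, "+", id = "a",
              blocks = list(starts = c(1000, 1500), ends = c(1100, 1600))),
    make_read("chr1", NULL, NULL, "+", id = "b",
              blocks = list(starts = c(1550, 2000), ends = c(1650, 2100)))
  ))))
  expect_equal(cand$status, "candidate")

  no_sec <- subtract_known(cand, NULL)
  expect_equal(no_sec$calls$ntr_id, "NTR1")

  inside <- subtract_known(cand, ann_single(500, 3000, "+"))
  expect_equal(nrow(inside$calls), 0L)
  expect_equal(inside$clusters$status, "annotated_secondary")

  antisense <- subtract_known(cand, ann_single(500, 3000, "-"))
  expect_equal(nrow(antisense$calls), 1L)
})

test_that("NTR ids follow natural chromosome order then start", {
  mk <- function(chrom, start) {
    make_read(chrom, NULL, NULL, "+", id = paste0(chrom, start),
              blocks = list(starts = c(start, start + 600, start + 1200),
                            ends = c(start + 100, start + 700, start + 1300)))
  }
  reads <- make_reads(mk("chr10", 100), mk("chr2", 100), mk("chr2", 50000))
  res <- run_discovery(reads, NULL)
  expect_equal(res$calls$ntr_id, c("NTR1", "NTR2", "NTR3"))
  expect_equal(res$calls$chrom, c("chr2", "chr2", "chr10"))
})

test_that("empty input produces zero calls and an all-zero ledger", {
  res <- run_discovery(make_read("chr1", 0, 50, "+")[0, ], NULL)
  expect_equal(nrow(res$calls), 0L)
  expect_true(all(unlist(res$report) == 0L))
})

test_that("discovery recovers planted transcripts and respects the annotation", {
  sim <- simulate_reads(sim_config(seed = 1))
  res <- run_discovery(sim$reads, sim$genes)
  ev <- evaluate_calls(res$calls, sim$ntr_models)
  expect_true(all(ev$matches$reciprocal_overlap >= 0.5))
  expect_equal(ev$recall, 1)
  # no call overlaps an annotated gene
  expect_equal(sum(GenomicRanges::countOverlaps(
    ntrscout:::intervals_to_granges(res$calls),
    ntrscout:::intervals_to_granges(sim$genes),
    ignore.strand = TRUE)), 0L)
})

test_that("report ledger is conserved and D1/D2 act monotonically", {
  sim <- simulate_reads(sim_config(seed = 2))
  r5 <- run_discovery(sim$reads, sim$genes, params = discovery_params(d2 = 5000))
  r10 <- run_discovery(sim$reads, sim$genes, params = discovery_params(d2 = 10000))
  g5 <- glance(r5); g10 <- glance(r10)
  expect_equal(g5$n_fragments_total,
               g5$n_fragments_in_annotation + g5$n_fragments_proximal_d1 +
                 g5$n_fragments_clustered)
  expect_lte(g10$n_clusters, g5$n_clusters)
  kept <- sapply(c(0, 500, 1000, 2000), function(d1) {
    glance(run_discovery(sim$reads, sim$genes,
                         params = discovery_params(d1 = d1)))$n_fragments_clustered
  })
  expect_true(all(diff(kept) <= 0))
})

test_that("every emitted call satisfies the calling contract", {
  sim <- simulate_reads(sim_config(seed = 3))
  sec <- sim$ntr_models[1, ]   # pretend one planted NTR got annotated later
  p <- discovery_params()
  res <- run_discovery(sim$reads, sim$genes, secondary = sec, params = p)
  calls <- tidy(res)
  expect_true(all(calls$n_junctions >= p$min_junctions))
  expect_true(all(distance_to_annotation(calls, sim$genes) > p$d1))
  expect_equal(sum(GenomicRanges::countOverlaps(
    ntrscout:::intervals_to_granges(calls),
    ntrscout:::intervals_to_granges(sec),
    ignore.strand = FALSE)), 0L)
  expect_equal(glance(res)$n_removed_secondary, 1L)
})
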