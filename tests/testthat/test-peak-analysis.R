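poisson_track <- function(values, window_width = 20L) {
  n <- length(values)
  spikenorm:::new_signal_track(
    tibble::tibble(chrom = "chr1",
                   start = (seq_len(n) - 1L) * window_width,
                   end = seq_len(n) * window_width,
                   score = values),
    window_width = window_width,
    chrom_lengths = c(chr1 = n * window_width),
    scale = "raw", count_rule = "start"
  )
}

test_that("an isolated hot window yields exactly one peak containing it", {
  v <- numeric(5000)
  v[c(100, 900, 2500)] <- 1 # near-zero background
  v[3000] <- 1000
  trk <- poisson_track(v)
  pk <- call_peaks(trk, peak_width = 200, fold_min = 4, p_max = 1e-4)
  expect_identical(nrow(pk), 1L)
  expect_true(pk$start <= 2999 * 20 && pk$end >= 3000 * 20)
  expect_true(pk$summit >= 2999 * 20 && pk$summit < 3000 * 20)
  expect_lt(pk$p_value, 1e-10)
})

test_that("degenerate tracks are handled explicitly", {
  empty <- poisson_track(numeric(0))
  expect_identical(nrow(call_peaks(empty)), 0L)
  flatzero <- poisson_track(numeric(100))
  expect_error(call_peaks(flatzero),
               class = "spikenorm_degenerate_background_error")
  cpm_trk <- apply_cpm(poisson_track(rep(1, 100)), 1e6)
  expect_error(call_peaks(cpm_trk), class = "spikenorm_parameter_error")
})

test_that("peak calls are monotone in the thresholds and contig-order invariant", {
  set.seed(99)
  sim <- simulate_experiment(small_sim_config(seed = 5))
  a <- sim$alignments$s2
  a <- a[!startsWith(a$chrom, "spikein_") & !a$is_duplicate, ]
  lens <- sim$chrom_lengths[c("chr1", "chr2")]
  trk <- windowed_coverage(a, lens, count_rule = "start")

  n_loose <- nrow(call_peaks(trk, fold_min = 2, p_max = 1e-3))
  n_mid <- nrow(call_peaks(trk, fold_min = 4, p_max = 1e-3))
  n_tight <- nrow(call_peaks(trk, fold_min = 4, p_max = 1e-8))
  expect_gte(n_loose, n_mid)
  expect_gte(n_mid, n_tight)
  expect_gt(n_tight, 0)

  trk_rev <- windowed_coverage(a, lens[c("chr2", "chr1")],
                               count_rule = "start")
  pk1 <- call_peaks(trk, fold_min = 4, p_max = 1e-4)
  pk2 <- call_peaks(trk_rev, fold_min = 4, p_max = 1e-4)
  key <- function(p) sort(paste(p$chrom, p$start, p$end))
  expect_identical(key(pk1), key(pk2))
})

test_that("peak files round-trip in narrowPeak and BED form", {
  pk <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100L, 40L),
                       end = c(300L, 140L), summit = c(180L, 90L),
                       score = c(12.5, 6.25), p_value = c(1e-9, 1e-5))
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(pk, np)
  back <- read_peaks(np)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$score, pk$score, tolerance = 1e-5)
  expect_equal(back$p_value, pk$p_value, tolerance = 1e-4)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, bed, format = "bed")
  back2 <- read_peaks(bed)
  expect_equal(back2$end, pk$end)
  expect_identical(ncol(back2), 4L)
})

test_that("overlap partitions resolve the toy cases", {
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  b <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  part <- overlap_partition(list(A = a, B = b))
  expect_identical(nrow(part$regions), 1L)
  expect_identical(part$regions$membership, "A+B")
  expect_identical(venn_as_vector(part), c(`A+B` = 1L))

  disjoint <- overlap_partition(list(
    A = tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
    B = tibble::tibble(chrom = "chr1", start = 100L, end = 110L),
    C = tibble::tibble(chrom = "chr2", start = 0L, end = 10L)
  ))
  expect_identical(nrow(disjoint$regions), 3L)
  expect_true(all(disjoint$regions$n_samples == 1))
  expect_identical(unname(exclusive_counts(disjoint)), c(1L, 1L, 1L))

  # consensus of the overlapping toy is that single region; of the
  # disjoint toy, empty
  expect_identical(nrow(consensus_peaks(part)), 1L)
  expect_identical(nrow(consensus_peaks(disjoint)), 0L)
})

test_that("a peak inside an existing region joins it without adding regions", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))
  b <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  before <- overlap_partition(list(A = a, B = b))
  b2 <- dplyr::bind_rows(b, tibble::tibble(chrom = "chr1", start = 20L,
                                           end = 80L))
  after <- overlap_partition(list(A = a, B = b2))
  expect_identical(nrow(after$regions), nrow(before$regions))
  expect_identical(venn_as_vector(after), venn_as_vector(before))
})

test_that("partition is invariant to sample order up to relabeling", {
  set.seed(31)
  sets <- lapply(1:3, function(i) {
    start <- sort(sample.int(5000, 30)) * 10L
    tibble::tibble(chrom = "chr1", start = start, end = start + 200L)
  })
  names(sets) <- c("A", "B", "C")
  p1 <- overlap_partition(sets)
  p2 <- overlap_partition(sets[c("C", "A", "B")])
  expect_identical(venn_as_vector(p1), venn_as_vector(p2))
  expect_identical(glance(p1)$n_consensus, glance(p2)$n_consensus)
})

test_that("random partitions match the brute-force union-find oracle", {
  set.seed(77)
  for (case in 1:25) {
    sets <- lapply(1:3, function(i) {
      n <- sample(5:40, 1)
      start <- sample.int(3000, n) * 10L
      tibble::tibble(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = start,
                     end = start + sample(c(50L, 150L, 400L), n,
                                          replace = TRUE))
    })
    names(sets) <- c("A", "B", "C")
    expect_identical(venn_as_vector(overlap_partition(sets)),
                     brute_force_venn(sets))
  }
})

test_that("method consensus comparison mirrors the replicate machinery", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                          end = c(200L, 1200L))
  same <- method_consensus_comparison(list(m1 = peaks, m2 = peaks,
                                           m3 = peaks))
  expect_true(all(same$regions$n_samples == 3))

  extra <- dplyr::bind_rows(peaks, tibble::tibble(chrom = "chr1",
                                                  start = 5000L, end = 5200L))
  one_off <- method_consensus_comparison(list(m1 = peaks, m2 = extra))
  expect_identical(sum(one_off$regions$n_samples == 1), 1L)
  expect_identical(glance(one_off)$n_exclusive, 1L)

  path <- withr::local_tempfile(fileext = ".json")
  write_venn_counts(one_off, path)
  venn <- jsonlite::fromJSON(path)
  expect_identical(venn$venn_counts$`m1+m2`, 2L)
})
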