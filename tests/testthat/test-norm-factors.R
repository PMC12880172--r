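test_that("equal-read factors bring every sample to the minimum depth", {
  nfs <- equal_read_factors(bench_metadata())
  expect_equal(nfs$factor, c(1, 0.176584790846, 0.182247160310),
               tolerance = 1e-9)
  expect_identical(attr(nfs, "reference_sample"), "rep1")
  # X_i * f_i is the same constant min(X), exactly
  expect_equal(nfs$expected_retained_reads, rep(4190041, 3))

  two <- sample_stats(data.frame(sample_id = c("a", "b"),
                                 unique_sample_reads = c(100, 100),
                                 unique_spikein_reads = c(1, 1)))
  expect_equal(equal_read_factors(two)$factor, c(1, 1))

  three <- sample_stats(data.frame(sample_id = c("a", "b", "c"),
                                   unique_sample_reads = c(10, 20, 40),
                                   unique_spikein_reads = 1))
  expect_equal(equal_read_factors(three)$factor, c(1, 0.5, 0.25))
})

test_that("spike-in factors equalize spike-in read counts", {
  nfs <- spikein_factors(bench_metadata())
  expect_equal(nfs$factor, c(1, 0.530045063865, 0.444333949395),
               tolerance = 1e-9)
  expect_equal(nfs$expected_retained_reads,
               c(4190041, 12577020.5849, 10215673.3882), tolerance = 1e-6)
  s <- bench_metadata()$unique_spikein_reads
  expect_equal(s * nfs$factor, rep(min(s), 3))

  equal_s <- sample_stats(data.frame(sample_id = c("a", "b", "c"),
                                     unique_sample_reads = c(5, 6, 7),
                                     unique_spikein_reads = c(7, 7, 7)))
  expect_equal(spikein_factors(equal_s)$factor, c(1, 1, 1))
})

test_that("input-adjusted factors rescale so the reference retains all reads", {
  nfs <- input_adjusted_factors(bench_metadata())
  expect_equal(nfs$raw_factor,
               c(0.3211993849225, 0.0625416878896, 0.1584470891433),
               tolerance = 1e-9)
  expect_equal(nfs$factor, c(1, 0.194712975259, 0.493298233375),
               tolerance = 1e-9)
  expect_equal(nfs$expected_retained_reads,
               c(4190041, 4620190.36667, 11341410.31085), tolerance = 1e-6)
  expect_identical(attr(nfs, "reference_sample"), "rep1")
  expect_true(all(nfs$factor > 0 & nfs$factor <= 1))
  expect_identical(sum(nfs$factor == 1), 1L)
})

test_that("input-adjusted factors satisfy the cross-ratio identity", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    st <- sample_stats(data.frame(
      sample_id = paste0("s", seq_len(n)),
      unique_sample_reads = round(runif(n, 1e4, 1e7)),
      unique_spikein_reads = round(runif(n, 1e2, 1e5)),
      input_dna_mass_ng = runif(n, 50, 900),
      spikein_mass_ng = runif(n, 10, 100)
    ))
    nfs <- input_adjusted_factors(st)
    f <- nfs$factor
    x <- st$unique_sample_reads
    s <- st$unique_spikein_reads
    cm <- st$input_dna_mass_ng
    cd <- st$spikein_mass_ng
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        lhs <- (x[i] * f[i]) * s[j] * cm[j] * cd[i]
        rhs <- (x[j] * f[j]) * s[i] * cm[i] * cd[j]
        expect_equal(lhs, rhs, tolerance = 1e-9)
      }
    }
    # after applying factors, X'_i / S_i is proportional to C_m,i / C_d,i
    ratio <- (x * f / s) / (cm / cd)
    expect_equal(ratio / ratio[1], rep(1, n), tolerance = 1e-9)
  }
})

test_that("input-adjusted reduces to spike-in ranking when masses are constant", {
  set.seed(7)
  st <- sample_stats(data.frame(
    sample_id = paste0("s", 1:4),
    unique_sample_reads = 5e6,
    unique_spikein_reads = round(runif(4, 1e3, 1e5)),
    input_dna_mass_ng = 500,
    spikein_mass_ng = 62.5
  ))
  ia <- input_adjusted_factors(st)
  sp <- spikein_factors(st)
  # with constant X and masses, the input-adjusted factor is proportional to
  # S_i (preserving X'_i/S_i ∝ C_m/C_d), i.e. it ranks samples exactly
  # opposite to the spike-in factor min(S)/S_i
  expect_identical(order(ia$factor), rev(order(sp$factor)))
  expect_equal(ia$factor, st$unique_spikein_reads /
                 max(st$unique_spikein_reads))

  sym <- sample_stats(data.frame(
    sample_id = c("a", "b", "c"),
    unique_sample_reads = 1e6, unique_spikein_reads = 1e4,
    input_dna_mass_ng = 400, spikein_mass_ng = 62.5
  ))
  expect_equal(input_adjusted_factors(sym)$factor, rep(1, 3))
})

test_that("factors are invariant to mass units and common rescaling", {
  base <- bench_metadata()
  scaled <- base
  scaled$input_dna_mass_ng <- scaled$input_dna_mass_ng * 1000
  scaled$spikein_mass_ng <- scaled$spikein_mass_ng * 1000
  expect_equal(input_adjusted_factors(base)$factor,
               input_adjusted_factors(scaled)$factor)

  # concentration x volume equals a directly supplied mass
  direct <- sample_stats(data.frame(
    sample_id = c("rep1", "rep2", "rep3"),
    unique_sample_reads = c(4190041, 23728210, 22990981),
    unique_spikein_reads = c(142086, 268064, 319773),
    input_dna_mass_ng = c(29.6, 17.3, 35.6) * 20,
    spikein_mass_ng = 62.5
  ))
  expect_equal(input_adjusted_factors(base)$factor,
               input_adjusted_factors(direct)$factor)
})

test_that("cpm is a display scaling, not a downsampling", {
  nfs <- norm_factors(bench_metadata(), "cpm")
  expect_true(isTRUE(attr(nfs, "scale_only")))
  expect_equal(nfs$factor, rep(1, 3))

  expect_equal(cpm_scale_factor(1e6), 1)
  expect_equal(cpm_scale_factor(4190041), 0.238661149139, tolerance = 1e-9)
  expect_equal(5 * cpm_scale_factor(2e6), 2.5)
  expect_error(cpm_scale_factor(0), class = "spikenorm_degenerate_input_error")
})

test_that("degenerate inputs raise classed errors naming the offender", {
  one <- sample_stats(data.frame(sample_id = "a", unique_sample_reads = 10,
                                 unique_spikein_reads = 1))
  expect_error(equal_read_factors(one), class = "spikenorm_group_size_error")

  zero_x <- sample_stats(data.frame(sample_id = c("a", "b"),
                                    unique_sample_reads = c(0, 10),
                                    unique_spikein_reads = c(1, 1)))
  expect_error(equal_read_factors(zero_x),
               class = "spikenorm_degenerate_input_error")

  zero_s <- sample_stats(data.frame(sample_id = c("a", "bad_sample"),
                                    unique_sample_reads = c(10, 10),
                                    unique_spikein_reads = c(5, 0)))
  err <- tryCatch(spikein_factors(zero_s), error = identity)
  expect_s3_class(err, "spikenorm_degenerate_input_error")
  expect_match(conditionMessage(err), "bad_sample")

  no_mass <- sample_stats(data.frame(sample_id = c("a", "b"),
                                     unique_sample_reads = c(10, 10),
                                     unique_spikein_reads = c(5, 5)))
  expect_error(input_adjusted_factors(no_mass),
               class = "spikenorm_degenerate_input_error")
})

test_that("tidiers and the JSON report expose the factor set faithfully", {
  nfs <- spikein_factors(bench_metadata())
  td <- tidy(nfs)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$method, rep("spikein", 3))
  expect_identical(td$is_reference, c(TRUE, FALSE, FALSE))
  g <- glance(nfs)
  expect_identical(g$reference_sample, "rep1")
  expect_identical(g$n_samples, 3L)

  path <- withr::local_tempfile(fileext = ".json")
  write_norm_report(nfs, path)
  rep <- jsonlite::fromJSON(path)
  expect_identical(rep$method, "spikein")
  expect_equal(rep$factors$rep2, 0.530045063865, tolerance = 1e-9)
  expect_identical(rep$reference_sample, "rep1")
})
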