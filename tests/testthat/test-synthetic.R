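test_that("the generator is deterministic given a seed", {
  a <- generate_dataset(synthetic_config(n_loci = 12L,
                                         n_background_probes = 400L,
                                         seed = 99))
  b <- generate_dataset(synthetic_config(n_loci = 12L,
                                         n_background_probes = 400L,
                                         seed = 99))
  expect_identical(a$probes, b$probes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotations, b$annotations)

  c2 <- generate_dataset(synthetic_config(n_loci = 12L,
                                          n_background_probes = 400L,
                                          seed = 100))
  expect_false(identical(a$probes$ratio_fwd, c2$probes$ratio_fwd))
})

test_that("invalid configurations are rejected with named fields", {
  expect_error(synthetic_config(n_loci = -1, seed = 1), "n_loci")
  expect_error(synthetic_config(tata_fraction = 1.5, seed = 1),
               "tata_fraction")
  expect_error(synthetic_config(time_grid = c(5, 10), seed = 1),
               "time_grid")
  expect_error(synthetic_config(n_loci = 10), "seed")
})

test_that("probe values are positive and signal sits in the left tail at t = 0", {
  ds <- generate_dataset(synthetic_config(n_loci = 30L,
                                          n_background_probes = 2000L,
                                          seed = 17))
  expect_true(all(ds$probes$ratio_fwd > 0 & ds$probes$ratio_rev > 0))

  p0 <- ds$probes[ds$probes$time_min == 0, ]
  is_sig <- grepl("^p_", p0$probe_id)
  l2 <- log2(geometric_average_dyeswap(p0$ratio_fwd, p0$ratio_rev))
  bg_mu <- mean(l2[!is_sig]); bg_sd <- sd(l2[!is_sig])
  # essentially every signal probe is depleted below the background bulk
  expect_gte(mean(l2[is_sig] < bg_mu - 2 * bg_sd), 0.99)
})

test_that("the annotation model hits its correlation target", {
  ds <- generate_dataset(synthetic_config(n_loci = 3000L,
                                          n_background_probes = 400L,
                                          seed = 23))
  rho <- spearman_corr(ds$annotations$tr, ds$truth$t_half)
  # target -0.11; +/-0.04 covers the rank-correlation sampling error at n=3000
  expect_lt(abs(rho - (-0.11)), 0.04)
})

test_that("noise -> 0 makes the pipeline estimates converge to truth", {
  curve <- study_curve()
  tt <- default_time_grid()
  tab <- cached_bias_table()
  med_err <- vapply(c(0.2, 0.05, 0), function(sg) {
    set.seed(400)
    errs <- vapply(c(4, 10, 25), function(th) {
      y <- simulate_occupancy(kinetic_model(0.01, log(2) / th), curve, tt)
      y <- y * 2^rnorm(length(y), 0, sg)
      res <- fit_residence_time(list(times = tt, values = y), curve,
                                bias_table = tab)
      abs(res$t_half - th) / th
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 1e-4)
})

test_that("null annotations are independent of locus values", {
  ids <- sprintf("l%03d", 1:60)
  nul <- generate_null_annotations(ids, seed = 5, n_tf = 10L)
  expect_identical(nul, generate_null_annotations(ids, seed = 5, n_tf = 10L))

  # KS p-values for PolII-vs-PolIII splits of independent values show no
  # excess of small values (the asymptotic two-sample KS p is discrete and
  # conservative at these group sizes, so exact uniformity is not expected)
  set.seed(6)
  pvals <- vapply(1:200, function(i) {
    nu <- generate_null_annotations(ids, seed = 1000 + i, n_tf = 2L)
    vals <- rlnorm(60, log(5), 0.7)
    grp <- nu$annotations$pol_class == "PolII"
    if (sum(grp) < 3 || sum(!grp) < 3) return(NA_real_)
    ks_compare(vals[grp], vals[!grp])$p_value
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05, na.rm = TRUE), 0.08)
  expect_gte(mean(pvals, na.rm = TRUE), 0.45)
})

test_that("datasets round-trip through their on-disk formats", {
  ds <- generate_dataset(synthetic_config(n_loci = 8L,
                                          n_background_probes = 300L,
                                          seed = 44))
  dir <- tempfile("synth")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))

  probes <- read_probe_table(paths[["probes"]])
  expect_equal(nrow(probes), nrow(ds$probes))
  expect_equal(sort(unique(probes$time_min)), default_time_grid())

  peaks <- read_peaks_bed(paths[["peaks"]])
  expect_equal(peaks$start, ds$peaks$start)
  expect_equal(peaks$name, ds$peaks$name)

  ann <- read_annotation_table(paths[["annotations"]])
  expect_equal(ann$tr, ds$annotations$tr, tolerance = 1e-10)
  tf <- read_tf_table(paths[["tf"]])
  expect_identical(nrow(tf), nrow(ds$tf))
})
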