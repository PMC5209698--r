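test_that("dye-swap geometric averaging has the required algebra", {
  expect_identical(geometric_average_dyeswap(4, 1), 2)

  set.seed(3)
  r <- runif(50, 0.01, 100)
  expect_equal(geometric_average_dyeswap(r, r), r, tolerance = 1e-12)

  # log-mean oracle and symmetry / scale equivariance
  a <- runif(100, 0.01, 50); b <- runif(100, 0.01, 50); c0 <- runif(1, 0.1, 10)
  g <- geometric_average_dyeswap(a, b)
  expect_equal(g, exp((log(a) + log(b)) / 2), tolerance = 1e-12)
  expect_equal(g, geometric_average_dyeswap(b, a), tolerance = 1e-15)
  expect_equal(geometric_average_dyeswap(a * c0, b * c0), c0 * g,
               tolerance = 1e-12)

  expect_error(geometric_average_dyeswap(-1, 2), "positive")
  expect_error(geometric_average_dyeswap(1, 0), "positive")
})

test_that("background fit recovers a pure normal within 2%", {
  set.seed(42)
  bg <- fit_background_normal(rnorm(1e5, 0.1, 0.3))
  expect_equal(bg$mu_log2, 0.1, tolerance = 0.02)
  expect_equal(bg$sigma_log2, 0.3, tolerance = 0.02)
})

test_that("background fit ignores an enriched left tail", {
  set.seed(7)
  x <- c(rnorm(9500, 0, 0.25), rnorm(500, -3, 0.25))
  bg <- fit_background_normal(x)
  expect_lt(abs(bg$mu_log2 - 0), 0.02)
  expect_equal(bg$sigma_log2, 0.25, tolerance = 0.05)
})

test_that("background fit rejects degenerate input", {
  expect_error(fit_background_normal(rep(1, 200)), "degenerate")
  expect_error(fit_background_normal(rnorm(50)), "at least 100")
})

test_that("probe selection is near-empty under a pure background", {
  set.seed(8)
  x <- rnorm(1e4, 0.1, 0.25)
  bg <- fit_background_normal(x)
  sel <- select_signal_probes(x, bg, fdr = 0.05)
  expect_lte(length(sel) / length(x), 0.01)
})

test_that("probe selection attains the self-consistent BH power with FDR control", {
  # signal shifted -4 background SDs; the BH threshold at ~5% signal makes
  # the per-probe power pnorm(4 + qnorm(p*)) ~= 0.875 (self-consistent)
  n_sig <- 500; n_bg <- 9500; sigma <- 0.25
  res <- vapply(1:10, function(i) {
    set.seed(100 + i)
    x <- c(rnorm(n_sig, -4 * sigma, sigma), rnorm(n_bg, 0, sigma))
    bg <- fit_background_normal(x)
    sel <- select_signal_probes(x, bg, fdr = 0.05)
    c(recall = mean(seq_len(n_sig) %in% sel),
      fdr = if (length(sel)) mean(sel > n_sig) else 0)
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.84)
  expect_lte(mean(res["fdr", ]), 0.10)
})

test_that("normalisation maps the background mean to unity", {
  bg <- structure(list(mu_log2 = 0.3, sigma_log2 = 0.2, time_min = 0,
                       side = "right", n_used = 1000L),
                  class = "background_model")
  expect_equal(normalize_to_background(2^0.3, bg), 1, tolerance = 1e-12)
  bg0 <- structure(list(mu_log2 = 0, sigma_log2 = 0.2, time_min = 0,
                        side = "right", n_used = 1000L),
                   class = "background_model")
  expect_identical(normalize_to_background(2, bg0), 2)

  # seeded background-only batch: post-normalisation geometric mean ~ 1
  set.seed(12)
  x <- 2^rnorm(5000, 0.2, 0.25)
  bgf <- fit_background_normal(log2(x))
  z <- normalize_to_background(x, bgf)
  expect_equal(exp(mean(log(z))), 1, tolerance = 0.01)
})

test_that("locus aggregation averages probes within peaks", {
  probes <- data.frame(
    probe_id = rep(c("p1", "p2"), each = 3),
    chrom = "chr1",
    start = rep(c(100L, 200L), each = 3),
    end = rep(c(160L, 260L), each = 3),
    time_min = rep(c(0, 10, 20), 2),
    value = c(1, 2, 3, 5, 6, 7))
  one <- aggregate_to_locus(probes[probes$probe_id == "p1", ],
                            data.frame(chrom = "chr1", start = 50L,
                                       end = 300L, name = "A"))
  expect_equal(one$A$values, c(1, 2, 3))
  both <- aggregate_to_locus(probes,
                             data.frame(chrom = "chr1", start = 50L,
                                        end = 300L, name = "A"))
  expect_equal(both$A$values, c(3, 4, 5))
})

test_that("peak membership matches a brute-force overlap scan", {
  set.seed(77)
  n_probe <- 150
  starts <- sample.int(1000, n_probe, replace = TRUE)
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(n_probe)),
                       chrom = "toy", start = starts, end = starts + 20L,
                       time_min = 0, value = runif(n_probe))
  pk_starts <- sample.int(950, 12)
  peaks <- data.frame(chrom = "toy", start = pk_starts,
                      end = pk_starts + 60L,
                      name = sprintf("pk%02d", seq_len(12)))
  got <- suppressWarnings(aggregate_to_locus(probes, peaks))
  for (j in seq_len(nrow(peaks))) {
    member <- probes$start < peaks$end[j] & probes$end > peaks$start[j]
    if (!any(member)) {
      expect_false(peaks$name[j] %in% names(got))
    } else {
      expect_equal(got[[peaks$name[j]]]$values,
                   mean(probes$value[member]), tolerance = 1e-12)
    }
  }
})

test_that("a peak with no probes is skipped with a warning", {
  probes <- data.frame(probe_id = "p1", chrom = "chr1", start = 10L,
                       end = 20L, time_min = 0, value = 1)
  peaks <- data.frame(chrom = "chr1", start = c(0L, 500L),
                      end = c(50L, 600L), name = c("hit", "miss"))
  expect_warning(out <- aggregate_to_locus(probes, peaks), "miss")
  expect_named(out, "hit")
})

test_that("per-time-point normalisation is invariant to time order", {
  set.seed(21)
  ds <- generate_dataset(synthetic_config(n_loci = 10L,
                                          n_background_probes = 500L,
                                          seed = 21))
  probes <- ds$probes
  shuffled <- probes[sample.int(nrow(probes)), ]
  a <- preprocess_probes(probes, ds$peaks)
  b <- preprocess_probes(shuffled, ds$peaks)
  for (id in names(a$series)) {
    expect_equal(a$series[[id]]$values, b$series[[id]]$values,
                 tolerance = 1e-12)
  }
})
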