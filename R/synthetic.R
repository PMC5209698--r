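# Synthetic competition ChIP datasets with known ground truth.  The
# generator inverts the analysis pipeline: exact ODE occupancy ratios per
# locus -> divide by the locus antibody-scale alpha and add the locus
# background B -> multiply by the background level -> apply multiplicative
# log-normal probe noise and antisymmetric dye-swap jitter -> add a
# population of pure-background probes.

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the experimental design the package models: induction
#' truth (rho_inf 2.23, t_ind 22 min, Hill n 4), an 11-point 0-70 min
#' sampling grid, residence times log-normal around a few minutes (most
#' loci turn over in under 5 min, with a tail to tens of minutes),
#' locus backgrounds near 0.08, antibody scale factors near 2.2, and 10%
#' multiplicative (log2) measurement noise.
#'
#' @param n_loci Number of signal loci (peaks).
#' @param n_background_probes Number of pure-background probes per array.
#' @param probes_per_locus Probes tiling each peak.
#' @param time_grid Sampling times in minutes (must start at 0).
#' @param rho_inf,t_ind,hill_n True induction parameters.
#' @param t_half_median,t_half_log_sd Log-normal residence-time
#'   distribution (minutes; natural-log sd).
#' @param B_mean,B_sd Locus background distribution (truncated > 0.005).
#' @param alpha_median,alpha_log_sd Antibody-scale distribution.
#' @param sigma_log2 Log2 SD of multiplicative probe noise on the
#'   dye-averaged value.
#' @param sigma_dye_log2 Log2 SD of the antisymmetric dye-swap jitter
#'   (cancels exactly in the geometric average).
#' @param bg_mu_log2,bg_sigma_log2 Background log2-ratio distribution.
#' @param k_a Nuisance association rate used in the generating ODE, 1/min.
#' @param polII_fraction,tata_fraction,rp_fraction Annotation mix.
#' @param tr_median,tr_log_sd Transcription-rate distribution
#'   (molecules/min).
#' @param tr_spearman_thalf Target Spearman correlation between TR and
#'   residence time (generator target, induced via a Gaussian copula).
#' @param n_tf,tf_presence_rate Factor-presence panel dimensions.
#' @param seed Mandatory RNG seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_loci = 200L,
                             n_background_probes = 5000L,
                             probes_per_locus = 3L,
                             time_grid = default_time_grid(),
                             rho_inf = 2.23, t_ind = 22, hill_n = 4L,
                             t_half_median = 4, t_half_log_sd = 0.8,
                             B_mean = 0.08, B_sd = 0.03,
                             alpha_median = 2.2, alpha_log_sd = 0.2,
                             sigma_log2 = 0.1, sigma_dye_log2 = 0.1,
                             bg_mu_log2 = 0.1, bg_sigma_log2 = 0.25,
                             k_a = 0.01,
                             polII_fraction = 0.8, tata_fraction = 0.2,
                             rp_fraction = 0.1,
                             tr_median = 0.04, tr_log_sd = 1.0,
                             tr_spearman_thalf = -0.11,
                             n_tf = 20L, tf_presence_rate = 0.3,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- list(n_loci = as.integer(n_loci),
              n_background_probes = as.integer(n_background_probes),
              probes_per_locus = as.integer(probes_per_locus),
              time_grid = as.numeric(time_grid),
              rho_inf = rho_inf, t_ind = t_ind, hill_n = as.integer(hill_n),
              t_half_median = t_half_median, t_half_log_sd = t_half_log_sd,
              B_mean = B_mean, B_sd = B_sd,
              alpha_median = alpha_median, alpha_log_sd = alpha_log_sd,
              sigma_log2 = sigma_log2, sigma_dye_log2 = sigma_dye_log2,
              bg_mu_log2 = bg_mu_log2, bg_sigma_log2 = bg_sigma_log2,
              k_a = k_a,
              polII_fraction = polII_fraction,
              tata_fraction = tata_fraction, rp_fraction = rp_fraction,
              tr_median = tr_median, tr_log_sd = tr_log_sd,
              tr_spearman_thalf = tr_spearman_thalf,
              n_tf = as.integer(n_tf),
              tf_presence_rate = tf_presence_rate,
              seed = as.integer(seed))
  bad <- character()
  for (f in c("n_loci", "n_background_probes", "probes_per_locus",
              "rho_inf", "t_ind", "hill_n", "t_half_median",
              "alpha_median", "bg_sigma_log2", "k_a", "tr_median",
              "n_tf")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0) bad <- c(bad, f)
  }
  for (f in c("t_half_log_sd", "B_sd", "alpha_log_sd", "sigma_log2",
              "sigma_dye_log2")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  }
  if (cfg$time_grid[1] != 0 || is.unsorted(cfg$time_grid, strictly = TRUE)) {
    bad <- c(bad, "time_grid")
  }
  for (f in c("polII_fraction", "tata_fraction", "rp_fraction",
              "tf_presence_rate")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) bad <- c(bad, f)
  }
  if (abs(cfg$tr_spearman_thalf) >= 1) bad <- c(bad, "tr_spearman_thalf")
  if (length(bad)) {
    stop(sprintf("invalid synthetic_config fields: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a complete synthetic competition ChIP dataset
#'
#' Produces every input the pipeline consumes, plus the generating ground
#' truth: a dye-swapped probe table, an induction-measurement table, BED-
#' style peak definitions, gene annotations with a factor-presence panel,
#' and a per-locus truth table.  Identical seeds give identical output.
#'
#' @param config A [synthetic_config()].
#' @return List with data frames `probes`, `induction`, `peaks`,
#'   `annotations`, `tf`, `truth`, and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_loci
    times <- cfg$time_grid
    curve <- induction_curve(cfg$rho_inf, cfg$t_ind, cfg$hill_n)

    t_half <- rlnorm(n, log(cfg$t_half_median), cfg$t_half_log_sd)
    k_d <- log(2) / t_half
    B <- pmax(rnorm(n, cfg$B_mean, cfg$B_sd), 0.005)
    alpha <- rlnorm(n, log(cfg$alpha_median), cfg$alpha_log_sd)
    locus_id <- sprintf("locus_%03d", seq_len(n))

    # peaks laid on one synthetic chromosome, 500 bp every 2 kb
    peaks <- data.frame(chrom = "chrSim",
                        start = seq_len(n) * 2000L,
                        end = seq_len(n) * 2000L + 500L,
                        name = locus_id)

    # exact ODE ratio per locus
    ratio <- vapply(k_d, function(kd) {
      simulate_occupancy(kinetic_model(cfg$k_a, kd), curve, times)
    }, numeric(length(times)))          # [time, locus]

    ppl <- cfg$probes_per_locus
    sig <- expand.grid(p = seq_len(ppl), locus = seq_len(n),
                       ti = seq_along(times))
    offs <- round(seq(50, 450, length.out = ppl))
    sig_true_norm <- B[sig$locus] +
      ratio[cbind(sig$ti, sig$locus)] / alpha[sig$locus]
    sig_raw_log2 <- cfg$bg_mu_log2 + log2(sig_true_norm) +
      rnorm(nrow(sig), 0, cfg$sigma_log2)
    dye <- rnorm(nrow(sig), 0, cfg$sigma_dye_log2)
    probes_sig <- data.frame(
      probe_id = sprintf("p_%s_%d", locus_id[sig$locus], sig$p),
      chrom = "chrSim",
      start = peaks$start[sig$locus] + offs[sig$p],
      end = peaks$start[sig$locus] + offs[sig$p] + 60L,
      time_min = times[sig$ti],
      ratio_fwd = 2^(sig_raw_log2 + dye),
      ratio_rev = 2^(sig_raw_log2 - dye))

    nb <- cfg$n_background_probes
    bgg <- expand.grid(b = seq_len(nb), ti = seq_along(times))
    bg_log2 <- rnorm(nrow(bgg), cfg$bg_mu_log2, cfg$bg_sigma_log2)
    bg_dye <- rnorm(nrow(bgg), 0, cfg$sigma_dye_log2)
    bg_start <- (n + 2L) * 2000L + bgg$b * 200L  # beyond all peaks
    probes_bg <- data.frame(
      probe_id = sprintf("bg_%05d", bgg$b),
      chrom = "chrSim",
      start = bg_start, end = bg_start + 60L,
      time_min = times[bgg$ti],
      ratio_fwd = 2^(bg_log2 + bg_dye),
      ratio_rev = 2^(bg_log2 - bg_dye))
    probes <- rbind(probes_sig, probes_bg)
    probes <- probes[order(probes$time_min, probes$probe_id), ]
    rownames(probes) <- NULL

    # induction measurements: true curve with mild multiplicative noise
    ind_t <- times
    ind_true <- eval_induction(curve, ind_t)
    ind_ratio <- ind_true * exp(rnorm(length(ind_t), 0, 0.05 * log(2)))
    ind_ratio[ind_t == 0] <- 0
    induction <- data.frame(time_min = ind_t, ratio = ind_ratio)

    annotations <- make_annotations(locus_id, t_half, cfg)
    tf <- make_tf_panel(locus_id, cfg)

    truth <- data.frame(locus_id = locus_id, k_d = k_d, t_half = t_half,
                        B = B, alpha = alpha)

    list(probes = probes, induction = induction, peaks = peaks,
         annotations = annotations, tf = tf, truth = truth, config = cfg)
  })
}

# Annotation table with a Gaussian-copula-induced weak negative Spearman
# correlation between transcription rate and residence time.
make_annotations <- function(locus_id, t_half, cfg) {
  n <- length(locus_id)
  # normal scores of the t_half ranks
  z_t <- qnorm((rank(t_half, ties.method = "first") - 0.5) / n)
  # bivariate-normal correlation giving the target Spearman value
  r <- 2 * sin(pi * cfg$tr_spearman_thalf / 6)
  z_tr <- r * z_t + sqrt(1 - r^2) * rnorm(n)
  tr <- exp(log(cfg$tr_median) + cfg$tr_log_sd * z_tr)
  # extrinsic noise: weak negative association with t_half as well
  z_ne <- -0.15 * z_t + sqrt(1 - 0.15^2) * rnorm(n)
  data.frame(
    locus_id = locus_id,
    pol_class = ifelse(runif(n) < cfg$polII_fraction, "PolII", "PolIII"),
    tata = ifelse(runif(n) < cfg$tata_fraction, "TATA", "TATA-less"),
    rp = ifelse(runif(n) < cfg$rp_fraction, "RP", "non-RP"),
    tr = tr,
    noise_ext = z_ne)
}

tf_classes <- c("transcription", "initiation", "elongation", "access",
                "orchestration")

make_tf_panel <- function(locus_id, cfg) {
  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tf))
  cls <- sample(tf_classes, cfg$n_tf, replace = TRUE)
  long <- expand.grid(locus_id = locus_id, tf_name = tf_names,
                      stringsAsFactors = FALSE)
  long$tf_class <- cls[match(long$tf_name, tf_names)]
  long$present <- runif(nrow(long)) < cfg$tf_presence_rate
  long[c("locus_id", "tf_name", "tf_class", "present")]
}

#' Null annotations: no association with any locus property
#'
#' Generates an annotation table and factor-presence panel whose flags and
#' numeric columns are drawn independently of everything else — the null
#' fixture for type-I-error calibration of the comparative statistics.
#'
#' @param locus_ids Character vector of locus ids.
#' @param seed RNG seed.
#' @param n_tf Number of presence factors.
#' @return List with `annotations` and `tf` data frames.
#' @export
generate_null_annotations <- function(locus_ids, seed, n_tf = 20L) {
  n <- length(locus_ids)
  if (!n) stop("no loci supplied", call. = FALSE)
  with_seed(seed, {
    annotations <- data.frame(
      locus_id = locus_ids,
      pol_class = sample(c("PolII", "PolIII"), n, replace = TRUE),
      tata = sample(c("TATA", "TATA-less"), n, replace = TRUE),
      rp = sample(c("RP", "non-RP"), n, replace = TRUE),
      tr = rlnorm(n, log(0.04), 1),
      noise_ext = rnorm(n))
    tf_names <- sprintf("nullTF%03d", seq_len(n_tf))
    long <- expand.grid(locus_id = locus_ids, tf_name = tf_names,
                        stringsAsFactors = FALSE)
    long$tf_class <- sample(tf_classes, nrow(long), replace = TRUE)
    long$present <- runif(nrow(long)) < 0.5
    list(annotations = annotations,
         tf = long[c("locus_id", "tf_name", "tf_class", "present")])
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits exactly the file formats the pipeline stages consume
#' (`probes.tsv`, `induction.tsv`, `peaks.bed`, `annotations.tsv`,
#' `tf_presence.tsv`), the ground truth (`truth.tsv`) and a manifest
#' recording the configuration and seed.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$config
  hdr <- provenance_header(unclass(cfg), cfg$seed)
  paths <- c(
    probes = file.path(dir, "probes.tsv"),
    induction = file.path(dir, "induction.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    annotations = file.path(dir, "annotations.tsv"),
    tf = file.path(dir, "tf_presence.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.yaml"))
  write_tsv(dataset$probes, paths[["probes"]], hdr)
  write_tsv(dataset$induction, paths[["induction"]], hdr)
  write_peaks_bed(dataset$peaks, paths[["peaks"]])
  write_tsv(dataset$annotations, paths[["annotations"]], hdr)
  write_tsv(dataset$tf, paths[["tf"]], hdr)
  write_tsv(dataset$truth, paths[["truth"]], hdr)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   truth_file = "truth.tsv",
                   config_md5 = unname(config_hash(unclass(cfg))))
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}
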