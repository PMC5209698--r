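# Pipeline orchestration: configuration, staged execution and file I/O.
# Each stage reads the previous stage's tab-delimited outputs from
# `outdir`, so stages can be run separately or chained with "all".
# Every output table carries a provenance header (package version,
# config hash, seed).

#' Build / read a pipeline configuration
#'
#' A pipeline configuration is a named list; [pipeline_config()] fills
#' defaults and validates, [read_pipeline_config()] loads one from a YAML
#' file.  Induction parameters can be given directly
#' (`induction = list(rho_inf, t_ind)`) or fitted from measurements by
#' setting `induction_file`.
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Integer seed used by every stochastic step.
#' @param sim Named list of [synthetic_config()] overrides for the
#'   `simulate` stage (`NULL` to use its defaults).
#' @param probe_file,peaks_file,induction_file,annotation_file,tf_file
#'   Input paths; default to the files the `simulate` stage writes under
#'   `outdir/sim`.
#' @param induction Fixed induction parameters (used when
#'   `induction_file` is `NULL`).
#' @param hill_n Hill exponent for induction and locus sigmoids.
#' @param fdr Signal-probe selection FDR.
#' @param t0_min,max_relative_rss,max_pct_err [reliability_filter()]
#'   settings.
#' @param k_a Nuisance association rate, 1/min.
#' @param lookup Bias-table settings: `n` grid points and `t_half_range`.
#' @param refine_scaling If `TRUE` (default), follow the three-stage
#'   kinetic fit with [profile_rescale_fit()] on the unscaled series,
#'   removing the sigmoid-asymptote approximation error from `B`, `alpha`
#'   and `k_d`.
#' @param n_perm Permutations for the factor screen.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            sim = NULL,
                            probe_file = NULL, peaks_file = NULL,
                            induction_file = NULL,
                            annotation_file = NULL, tf_file = NULL,
                            induction = list(rho_inf = 2.23, t_ind = 22),
                            hill_n = 4L,
                            fdr = 0.05,
                            t0_min = 24.5,
                            max_relative_rss = 0.001,
                            max_pct_err = 50,
                            k_a = 0.01,
                            lookup = list(n = 60L,
                                          t_half_range = c(0.5, 120)),
                            refine_scaling = TRUE,
                            n_perm = 10000L) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              probe_file = probe_file, peaks_file = peaks_file,
              induction_file = induction_file,
              annotation_file = annotation_file, tf_file = tf_file,
              induction = induction, hill_n = as.integer(hill_n),
              fdr = fdr, t0_min = t0_min,
              max_relative_rss = max_relative_rss,
              max_pct_err = max_pct_err, k_a = k_a, lookup = lookup,
              refine_scaling = isTRUE(refine_scaling),
              n_perm = as.integer(n_perm))
  stopifnot(is.character(outdir), length(outdir) == 1L,
            fdr > 0, fdr < 1, t0_min > 0, k_a > 0, n_perm >= 1000L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with pipeline settings.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

sim_dir <- function(cfg) file.path(cfg$outdir, "sim")

resolve_input <- function(cfg, field, default_name) {
  p <- cfg[[field]]
  if (is.null(p)) p <- file.path(sim_dir(cfg), default_name)
  if (!file.exists(p)) {
    stop(sprintf("input file for `%s` not found: %s (run the simulate stage or point the config at real data)",
                 field, p), call. = FALSE)
  }
  p
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (write a synthetic dataset under `outdir/sim`),
#' `preprocess` (probe table + peaks -> locus series), `scale` (locus
#' sigmoid fits, reliability screen, boundary-condition scaling), `fit`
#' (induction curve, bias table, three-stage kinetic fit per passing
#' locus), `stats` (group contrasts, correlations, factor permutation
#' screen), or `all` to chain every stage.  Filter counts are logged at
#' each step; outputs are deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"simulate"`, `"preprocess"`, `"scale"`, `"fit"`,
#'   `"stats"`, `"all"`.
#' @return Named list of artifact paths written by the stage(s),
#'   invisibly.
#' @export
run_pipeline <- function(config,
                         stage = c("all", "simulate", "preprocess",
                                   "scale", "fit", "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "preprocess", "scale", "fit", "stats")
  } else stage
  out <- list()
  for (s in stages) {
    out <- c(out, switch(s,
      simulate = stage_simulate(config),
      preprocess = stage_preprocess(config),
      scale = stage_scale(config),
      fit = stage_fit(config),
      stats = stage_stats(config)))
  }
  invisible(out)
}

stage_simulate <- function(cfg) {
  args <- cfg$sim %||% list()
  args$seed <- args$seed %||% cfg$seed
  sc <- do.call(synthetic_config, args)
  ds <- generate_dataset(sc)
  paths <- write_dataset(ds, sim_dir(cfg))
  log_msg("simulate: %d loci, %d background probes -> %s",
          sc$n_loci, sc$n_background_probes, sim_dir(cfg))
  as.list(paths)
}

stage_preprocess <- function(cfg) {
  probes <- read_probe_table(resolve_input(cfg, "probe_file", "probes.tsv"))
  peaks <- read_peaks_bed(resolve_input(cfg, "peaks_file", "peaks.bed"))
  res <- preprocess_probes(probes, peaks, fdr = cfg$fdr)
  log_msg("preprocess: %d/%d signal probes, %d/%d loci with coverage",
          res$n_signal_probes, res$n_probes, length(res$series), nrow(peaks))
  df <- do.call(rbind, lapply(res$series, function(s) {
    data.frame(locus_id = s$locus_id, time_min = s$times, value = s$values)
  }))
  path <- file.path(cfg$outdir, "locus_series.tsv")
  write_tsv(df, path, provenance_header(unclass(cfg), cfg$seed))
  list(locus_series = path)
}

read_locus_series <- function(path) {
  df <- read_tsv(path)
  lapply(split(df, df$locus_id), function(d) {
    d <- d[order(d$time_min), ]
    list(locus_id = d$locus_id[1], times = d$time_min, values = d$value)
  })
}

get_induction <- function(cfg) {
  if (!is.null(cfg$induction_file)) {
    fit_induction(read_induction_table(cfg$induction_file),
                  hill_n = cfg$hill_n)
  } else {
    induction_curve(cfg$induction$rho_inf, cfg$induction$t_ind, cfg$hill_n)
  }
}

stage_scale <- function(cfg) {
  series <- read_locus_series(file.path(cfg$outdir, "locus_series.tsv"))
  curve <- get_induction(cfg)
  fits <- lapply(series, fit_locus_sigmoid, hill_n = cfg$hill_n,
                 rho_inf = curve$rho_inf)
  rows <- list(); scaled_rows <- list()
  n_pass <- 0L
  for (id in names(fits)) {
    f <- fits[[id]]
    flt <- reliability_filter(f, t0_min = cfg$t0_min,
                              max_relative_rss = cfg$max_relative_rss,
                              max_pct_err = cfg$max_pct_err,
                              rho_inf = curve$rho_inf)
    pct <- if (isTRUE(f$usable)) t0_percent_error(f) else NA_real_
    rows[[id]] <- data.frame(
      locus_id = id, B = f$B, amplitude = f$amplitude,
      alpha = if (isTRUE(f$usable)) curve$rho_inf / f$amplitude else NA_real_,
      t0 = f$t0, t0_se = f$t0_se, t0_pct_err = pct, rss = f$rss,
      pass = flt$pass,
      reasons = paste(flt$reasons, collapse = "; "))
    if (flt$pass) {
      n_pass <- n_pass + 1L
      sc <- scale_series(series[[id]], f, rho_inf = curve$rho_inf)
      scaled_rows[[id]] <- data.frame(locus_id = id, time_min = sc$times,
                                      value = sc$values)
    }
  }
  log_msg("scale: %d/%d loci pass the reliability screen", n_pass,
          length(fits))
  hdr <- provenance_header(unclass(cfg), cfg$seed)
  fits_path <- file.path(cfg$outdir, "locus_fits.tsv")
  scaled_path <- file.path(cfg$outdir, "scaled_series.tsv")
  write_tsv(do.call(rbind, rows), fits_path, hdr)
  write_tsv(do.call(rbind, scaled_rows), scaled_path, hdr)
  list(locus_fits = fits_path, scaled_series = scaled_path)
}

stage_fit <- function(cfg) {
  scaled <- read_locus_series(file.path(cfg$outdir, "scaled_series.tsv"))
  curve <- get_induction(cfg)
  times <- scaled[[1]]$times

  bias_path <- file.path(cfg$outdir, "bias_table.tsv")
  if (file.exists(bias_path)) {
    table <- read_bias_table(bias_path)
    log_msg("fit: reusing cached bias table %s", bias_path)
  } else {
    rng <- cfg$lookup$t_half_range
    grid <- log(2) / exp(seq(log(rng[2]), log(rng[1]),
                             length.out = cfg$lookup$n))
    table <- build_bias_table(curve, k_d_grid = grid, times = times,
                              k_a = cfg$k_a)
    write_bias_table(table, bias_path)
    log_msg("fit: built and cached bias table (%d grid points) -> %s",
            cfg$lookup$n, bias_path)
  }

  unscaled <- read_locus_series(file.path(cfg$outdir, "locus_series.tsv"))
  rows <- lapply(scaled, function(s) {
    res <- tryCatch(
      fit_residence_time(s, curve, bias_table = table, k_a = cfg$k_a),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(cfg$refine_scaling) &&
        !is.null(unscaled[[s$locus_id]]) && is.finite(res$k_d)) {
      ref <- tryCatch(
        profile_rescale_fit(unscaled[[s$locus_id]], curve,
                            center = res$k_d, k_a = cfg$k_a),
        error = function(e) NULL)
      if (!is.null(ref) && isTRUE(ref$converged)) {
        ref$k_d_ideal <- res$k_d_ideal
        ref$method_trace <- c(res$method_trace, ref$method_trace)
        res <- ref
      }
    }
    if (is.null(res)) {
      return(data.frame(locus_id = s$locus_id, k_d = NA_real_,
                        t_half = NA_real_, k_d_ideal = NA_real_,
                        rss = NA_real_, n_iter = 0L, converged = FALSE,
                        pass = FALSE))
    }
    data.frame(locus_id = s$locus_id, k_d = res$k_d, t_half = res$t_half,
               k_d_ideal = res$k_d_ideal, rss = res$rss,
               n_iter = res$n_iter, converged = res$converged,
               pass = res$converged)
  })
  df <- do.call(rbind, rows)
  log_msg("fit: %d/%d kinetic fits converged", sum(df$converged), nrow(df))
  path <- file.path(cfg$outdir, "residence_times.tsv")
  write_tsv(df, path, provenance_header(unclass(cfg), cfg$seed))
  list(residence_times = path, bias_table = bias_path)
}

stage_stats <- function(cfg) {
  fits <- read_tsv(file.path(cfg$outdir, "residence_times.tsv"))
  fits <- fits[fits$pass %in% c(TRUE, "TRUE"), ]
  ann <- read_annotation_table(
    resolve_input(cfg, "annotation_file", "annotations.tsv"))
  tf <- read_tf_table(resolve_input(cfg, "tf_file", "tf_presence.tsv"))

  m <- merge(fits, ann, by = "locus_id")
  m$t_half <- as.numeric(m$t_half)
  m$tr <- as.numeric(m$tr)
  m$efficiency <- transcription_efficiency(m$tr, m$t_half)
  log_msg("stats: %d loci with residence time + annotation", nrow(m))

  comp_row <- function(label, r) {
    data.frame(comparison = label, statistic = r$statistic, p = r$p_value,
               fdr = NA_real_, n1 = r$n_per_group[1], n2 = r$n_per_group[2])
  }
  rows <- list()
  grp <- function(col, a, b, value_col = "t_half") {
    x <- m[[value_col]][m[[col]] == a]; y <- m[[value_col]][m[[col]] == b]
    if (length(x) >= 3 && length(y) >= 3) {
      comp_row(sprintf("%s %s_vs_%s (%s)", col, a, b, value_col),
               ks_compare(x, y))
    }
  }
  rows$pol <- grp("pol_class", "PolII", "PolIII")
  rows$tata <- grp("tata", "TATA", "TATA-less")
  rows$rp <- grp("rp", "RP", "non-RP")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  contrasts <- do.call(rbind, rows)

  summary_df <- data.frame(
    quantity = c("median_t_half_min", "median_efficiency_molecules",
                 "median_events_per_rna", "spearman_tr_vs_t_half",
                 "median_t0_pct_err"),
    value = c(median(m$t_half),
              median(m$efficiency),
              median(binding_events_per_rna(m$efficiency)),
              spearman_corr(m$tr, m$t_half),
              median_t0_pct_err(cfg)))

  vals <- setNames(m$t_half, m$locus_id)
  screen <- tf_permutation_screen(vals, tf[tf$locus_id %in% m$locus_id, ],
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "tf-screen"))

  hdr <- provenance_header(unclass(cfg), cfg$seed)
  p1 <- file.path(cfg$outdir, "group_contrasts.tsv")
  p2 <- file.path(cfg$outdir, "summary_stats.tsv")
  p3 <- file.path(cfg$outdir, "tf_screen.tsv")
  write_tsv(contrasts, p1, hdr)
  write_tsv(summary_df, p2, hdr)
  write_tsv(screen, p3, hdr)
  list(group_contrasts = p1, summary_stats = p2, tf_screen = p3)
}

median_t0_pct_err <- function(cfg) {
  path <- file.path(cfg$outdir, "locus_fits.tsv")
  if (!file.exists(path)) return(NA_real_)
  lf <- read_tsv(path)
  lf <- lf[lf$pass %in% c(TRUE, "TRUE"), ]
  median(as.numeric(lf$t0_pct_err), na.rm = TRUE)
}
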