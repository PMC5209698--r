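# Probe-level preprocessing of two-color competition ChIP arrays:
# dye-swap averaging, background estimation on the log2 scale, signal-probe
# selection at a controlled FDR, per-time-point normalisation, and
# aggregation of probes into locus (peak) series.

#' Geometric average of dye-swapped ratio pairs
#'
#' Dye-specific intensity bias multiplies one orientation and divides the
#' other, so the geometric mean of the two re-oriented ratios cancels it.
#'
#' @param ratio_fwd,ratio_rev Positive competitor/endogenous ratios from
#'   the two dye orientations (both already oriented identically);
#'   vectorised.
#' @return `sqrt(ratio_fwd * ratio_rev)`.
#' @export
geometric_average_dyeswap <- function(ratio_fwd, ratio_rev) {
  check_positive(ratio_fwd)
  check_positive(ratio_rev)
  sqrt(ratio_fwd * ratio_rev)
}

#' Estimate the non-specific background distribution at t = 0
#'
#' At the start of induction, probes inside binding sites are depleted of
#' competitor signal and therefore sit in one tail of the log2 ratio
#' distribution (the left tail for a competitor/endogenous orientation),
#' while non-specific probes form an approximately normal bulk.  The
#' background (mu, sigma) is estimated from the unenriched side only:
#' the mode is located by kernel density, the unenriched half is reflected
#' about it for starting moments, and the estimate is refined by maximum
#' likelihood on the sample truncated one initial-SD below (above) the
#' mode, which the enriched tail cannot reach.
#'
#' @param log2_ratios Log2 geometric-average ratios at `t = 0`
#'   (length >= 100).
#' @param time_min Time point the model applies to (annotation only).
#' @param side Which side of the distribution is unenriched: `"right"`
#'   (default; signal depletes the left tail) or `"left"`.
#' @param trunc_sd Truncation offset in initial-SD units (default 1).
#' @return Object of class `background_model`: list with `mu_log2`,
#'   `sigma_log2`, `time_min`, `side`, `n_used`.
#' @export
fit_background_normal <- function(log2_ratios, time_min = 0,
                                  side = c("right", "left"), trunc_sd = 1) {
  side <- match.arg(side)
  x <- as.numeric(log2_ratios)
  if (length(x) < 100L) {
    stop("need at least 100 probes to estimate the background", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("log2 ratios must be finite", call. = FALSE)
  if (sd(x) < 1e-12) {
    stop("degenerate (constant) input: background scale not estimable",
         call. = FALSE)
  }
  # work on the orientation where the unenriched side is the right half
  flip <- side == "left"
  if (flip) x <- -x

  d <- density(x, n = 2048)
  mode0 <- d$x[which.max(d$y)]
  right <- x[x >= mode0]
  if (length(right) < 30L) {
    stop("too few probes on the unenriched side of the mode", call. = FALSE)
  }
  sigma0 <- sqrt(mean((right - mode0)^2))

  # truncated-normal ML on x >= cut; the enriched tail lies below cut
  cut <- mode0 - trunc_sd * sigma0
  xt <- x[x >= cut]
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -sum(dnorm(xt, mu, s, log = TRUE) -
           pnorm(cut, mu, s, lower.tail = FALSE, log.p = TRUE))
  }
  opt <- optim(c(mode0, log(sigma0)), nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  mu <- opt$par[1]
  sigma <- exp(opt$par[2])
  if (flip) mu <- -mu
  structure(
    list(mu_log2 = mu, sigma_log2 = sigma, time_min = time_min,
         side = side, n_used = length(xt)),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background (t = %s min): log2 ratio ~ N(%.4g, %.4g^2), %s side, n = %d\n",
    format(x$time_min), x$mu_log2, x$sigma_log2, x$side, x$n_used))
  invisible(x)
}

#' Select signal probes against the fitted background
#'
#' One-sided tail p-values toward the signal side under the fitted normal
#' background, Benjamini-Hochberg adjusted; probes with adjusted p at or
#' below `fdr` are called signal.
#'
#' @param log2_ratios Log2 geometric-average ratios at `t = 0`.
#' @param bg A [fit_background_normal()] result; its `side` determines the
#'   signal tail (signal is opposite the unenriched side).
#' @param fdr Target false discovery rate (default 0.05).
#' @return Integer indices of the selected probes.
#' @export
select_signal_probes <- function(log2_ratios, bg, fdr = 0.05) {
  stopifnot(inherits(bg, "background_model"))
  if (!length(log2_ratios)) stop("empty input", call. = FALSE)
  if (fdr <= 0 || fdr >= 1) stop("`fdr` must be in (0, 1)", call. = FALSE)
  p <- if (bg$side == "right") {
    pnorm(log2_ratios, bg$mu_log2, bg$sigma_log2)            # signal in left tail
  } else {
    pnorm(log2_ratios, bg$mu_log2, bg$sigma_log2, lower.tail = FALSE)
  }
  which(p.adjust(p, method = "BH") <= fdr)
}

#' Normalise a ratio to the background mean
#'
#' Divides by `2^mu_log2`, the (geometric-mean) background level implied by
#' the log2-normal fit, so a probe at the background mean maps to 1.
#' Applied independently per time point.
#'
#' @param ratio Positive ratio(s).
#' @param bg The [fit_background_normal()] result for the matching time
#'   point.
#' @return Normalised ratio(s).
#' @export
normalize_to_background <- function(ratio, bg) {
  stopifnot(inherits(bg, "background_model"))
  check_positive(ratio)
  ratio / 2^bg$mu_log2
}

#' Aggregate normalised probes into locus series
#'
#' Assigns probes to peaks by genomic-interval overlap (>= 1 bp; both on
#' 0-based half-open coordinates) and averages the normalised probe ratios
#' within each peak at each time point.
#'
#' @param probes Data frame with columns `probe_id`, `chrom`, `start`,
#'   `end`, `time_min`, `value` (normalised ratio).
#' @param peaks Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, or a `GRanges`.
#' @param fun Summary over probes within a peak: `"mean"` (default) or
#'   `"median"`.
#' @return Named list of locus series (each: `locus_id`, `times`,
#'   `values`).  Peaks with no overlapping probe are skipped with a
#'   warning.
#' @export
aggregate_to_locus <- function(probes, peaks, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  agg <- if (fun == "mean") mean else median
  stopifnot(all(c("probe_id", "chrom", "start", "end", "time_min", "value")
                %in% names(probes)))
  if (inherits(peaks, "GRanges")) {
    peak_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(peaks)),
      start = GenomicRanges::start(peaks) - 1L,  # back to 0-based
      end = GenomicRanges::end(peaks),
      name = if (!is.null(peaks$name)) as.character(peaks$name)
             else NA_character_)
  } else {
    peak_df <- as.data.frame(peaks)
  }
  if (is.null(peak_df$name) || all(is.na(peak_df$name))) {
    peak_df$name <- sprintf("%s:%d-%d", peak_df$chrom, peak_df$start,
                            peak_df$end)
  }

  coords <- unique(probes[c("probe_id", "chrom", "start", "end")])
  # 0-based half-open -> 1-based closed for IRanges
  probe_gr <- GenomicRanges::GRanges(
    coords$chrom, IRanges::IRanges(coords$start + 1L, coords$end))
  peak_gr <- GenomicRanges::GRanges(
    peak_df$chrom, IRanges::IRanges(peak_df$start + 1L, peak_df$end))
  hits <- GenomicRanges::findOverlaps(probe_gr, peak_gr, minoverlap = 1L)

  out <- list()
  for (j in seq_len(nrow(peak_df))) {
    ids <- coords$probe_id[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == j]]
    if (!length(ids)) {
      warning(sprintf("peak %s has no overlapping probes; skipped",
                      peak_df$name[j]))
      next
    }
    sub <- probes[probes$probe_id %in% ids, ]
    times <- sort(unique(sub$time_min))
    values <- vapply(times, function(tt) agg(sub$value[sub$time_min == tt]),
                     numeric(1))
    out[[peak_df$name[j]]] <- list(locus_id = peak_df$name[j],
                                   times = times, values = values)
  }
  out
}

#' Read a probe table from a tab-delimited file
#'
#' Expects header
#' `probe_id chrom start end time_min ratio_fwd ratio_rev` (0-based
#' half-open intervals; both ratios oriented competitor/endogenous).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_probe_table <- function(path) {
  df <- read_tsv(path)
  need <- c("probe_id", "chrom", "start", "end", "time_min",
            "ratio_fwd", "ratio_rev")
  if (!all(need %in% names(df))) {
    stop(sprintf("probe table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read / write BED3 peak definitions
#'
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end` and `name`
#'   (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)))
}

#' @rdname read_peaks_bed
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  if (!is.null(peaks$name)) gr$name <- peaks$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Full probe-level preprocessing: dye-swap average, per-time background
# fit (anchored at t = 0 for probe selection), normalisation, aggregation.
# Returns the locus series plus the t = 0 background model and counts.
preprocess_probes <- function(probes, peaks, fdr = 0.05,
                              side = "right", fun = "mean") {
  probes$value_raw <- geometric_average_dyeswap(probes$ratio_fwd,
                                                probes$ratio_rev)
  times <- sort(unique(probes$time_min))
  if (!0 %in% times) stop("probe table must include t = 0", call. = FALSE)

  bg_models <- lapply(times, function(tt) {
    fit_background_normal(log2(probes$value_raw[probes$time_min == tt]),
                          time_min = tt, side = side)
  })
  names(bg_models) <- as.character(times)

  probes$value <- NA_real_
  for (i in seq_along(times)) {
    sel <- probes$time_min == times[i]
    probes$value[sel] <- normalize_to_background(probes$value_raw[sel],
                                                 bg_models[[i]])
  }

  p0 <- probes[probes$time_min == 0, ]
  sel_idx <- select_signal_probes(log2(p0$value_raw), bg_models[["0"]],
                                  fdr = fdr)
  signal_ids <- p0$probe_id[sel_idx]
  kept <- probes[probes$probe_id %in% signal_ids, ]
  log_msg("probe selection: %d / %d probes called signal at FDR %.3g",
          length(signal_ids), nrow(p0), fdr)

  series <- aggregate_to_locus(kept, peaks, fun = fun)
  list(series = series, background = bg_models,
       n_signal_probes = length(signal_ids), n_probes = nrow(p0))
}
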