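# Downstream comparative statistics: transcription efficiency, group
# contrasts (KS), rank correlations, label-permutation tests with
# Benjamini-Hochberg control, and quartile stratification.

#' Transcription efficiency
#'
#' RNA molecules synthesised per factor-chromatin binding event:
#' the product of the nascent transcription rate and the residence time,
#' `tr * t_half` (molecules, when `tr` is in molecules/min and `t_half`
#' in minutes).
#'
#' @param tr Transcription rate(s), molecules/min (>= 0).
#' @param t_half Residence time(s), minutes (> 0).
#' @return Efficiency in molecules; vectorised.
#' @export
transcription_efficiency <- function(tr, t_half) {
  check_nonnegative(tr)
  check_positive(t_half)
  tr * t_half
}

#' Binding events per RNA molecule
#'
#' The inverse of transcription efficiency: how many factor-chromatin
#' binding events occur per successfully synthesised RNA.
#'
#' @param efficiency Transcription efficiency in molecules (> 0).
#' @return Events per RNA; vectorised.
#' @export
binding_events_per_rna <- function(efficiency) {
  check_positive(efficiency)
  1 / efficiency
}

stat_result <- function(statistic, p_value, n_per_group, method,
                        fdr = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value, fdr = fdr,
                 n_per_group = n_per_group, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g%s (n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (is.finite(x$fdr)) sprintf(", fdr = %.3g", x$fdr) else "",
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b Numeric samples (each n >= 3; NAs dropped).
#' @return A `stat_result` with the KS statistic D and the asymptotic
#'   two-sided p-value.
#' @export
ks_compare <- function(a, b) {
  a <- as.numeric(na.omit(a)); b <- as.numeric(na.omit(b))
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  stat_result(unname(kt$statistic), kt$p.value, c(length(a), length(b)),
              "two-sample KS")
}

#' Spearman rank correlation
#'
#' Pairs with a missing value in either vector are dropped.  A constant
#' vector makes the rank correlation undefined: `NA` is returned with a
#' warning.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Label-permutation test for a group difference in means
#'
#' Tests whether loci with a factor present differ from loci with it
#' absent.  The observed statistic is `mean(values[present]) -
#' mean(values[absent])`; labels are permuted `n_perm` times and the
#' two-sided p-value uses the add-one correction
#' `p = (1 + #(|perm| >= |obs|)) / (n_perm + 1)`.
#'
#' @param values Numeric vector (one value per locus).
#' @param present_mask Logical vector, `TRUE` where the factor is present;
#'   both groups must be non-empty.
#' @param n_perm Number of label permutations (>= 1000; default 10000).
#' @param seed RNG seed (required; the test is deterministic given it).
#' @return A `stat_result` (method `"permutation"`).
#' @export
permutation_test <- function(values, present_mask, n_perm = 10000L, seed) {
  stopifnot(length(values) == length(present_mask),
            is.logical(present_mask))
  ok <- is.finite(values) & !is.na(present_mask)
  values <- values[ok]; present_mask <- present_mask[ok]
  n1 <- sum(present_mask); n0 <- sum(!present_mask)
  if (n1 == 0L || n0 == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (n_perm < 1000L) stop("`n_perm` must be >= 1000", call. = FALSE)
  n <- length(values)
  total <- sum(values)
  obs <- mean(values[present_mask]) - mean(values[!present_mask])
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s1 <- sum(values[sample.int(n, n1)])
    s1 / n1 - (total - s1) / n0
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  stat_result(obs, p, c(n1, n0), "permutation")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotonicity-enforced), order-
#' preserving with the input.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @return Adjusted values (FDR) in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Top/bottom quartile stratification
#'
#' Splits loci by a per-locus count (e.g. number of bound factors of a
#' class) into the upper and lower quartile sets.  Ties at a quartile
#' boundary are included in the respective set (so both sets can exceed a
#' strict 25%); with all-equal counts both sets equal all loci and the
#' result is flagged degenerate.
#'
#' @param counts Integer-like vector, one per locus (>= 8 loci).
#' @return List with integer index vectors `upper` and `lower`, and a
#'   logical `degenerate` flag.
#' @export
quartile_stratify <- function(counts) {
  if (length(counts) < 8L) stop("need at least 8 loci", call. = FALSE)
  check_nonnegative(counts)
  q <- quantile(counts, c(0.25, 0.75), names = FALSE)
  lower <- which(counts <= q[1])
  upper <- which(counts >= q[2])
  degenerate <- q[1] == q[2]
  if (degenerate) {
    warning("all counts in a single quartile band; stratification degenerate")
  }
  list(upper = upper, lower = lower, degenerate = degenerate)
}

#' Permutation screen across a panel of factors
#'
#' Runs [permutation_test()] of `values` against presence/absence for each
#' factor in a long-format presence table and applies [bh_adjust()] across
#' the panel.
#'
#' @param values Named numeric vector (names = locus ids).
#' @param tf_table Long data frame with columns `locus_id`, `tf_name`,
#'   `present` (logical or 0/1).
#' @param n_perm Permutations per factor.
#' @param seed Base seed; each factor uses a seed derived from it.
#' @return Data frame `tf_name, statistic, p, fdr, n_present, n_absent`.
#' @export
tf_permutation_screen <- function(values, tf_table, n_perm = 10000L, seed) {
  stopifnot(!is.null(names(values)),
            all(c("locus_id", "tf_name", "present") %in% names(tf_table)))
  tfs <- unique(tf_table$tf_name)
  rows <- lapply(tfs, function(tf) {
    sub <- tf_table[tf_table$tf_name == tf, ]
    mask <- as.logical(sub$present[match(names(values), sub$locus_id)])
    keep <- !is.na(mask)
    if (sum(mask[keep]) == 0L || sum(!mask[keep]) == 0L) {
      return(data.frame(tf_name = tf, statistic = NA_real_, p = NA_real_,
                        n_present = sum(mask[keep]),
                        n_absent = sum(!mask[keep])))
    }
    r <- permutation_test(values[keep], mask[keep], n_perm = n_perm,
                          seed = derive_seed(seed, tf))
    data.frame(tf_name = tf, statistic = r$statistic, p = r$p_value,
               n_present = r$n_per_group[1], n_absent = r$n_per_group[2])
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- is.finite(out$p)
  out$fdr[ok] <- bh_adjust(out$p[ok])
  out[c("tf_name", "statistic", "p", "fdr", "n_present", "n_absent")]
}

#' Read gene annotations / factor-presence tables
#'
#' Annotation TSV columns: `locus_id pol_class tata rp tr noise_ext`;
#' factor table (long format): `locus_id tf_name tf_class present`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "pol_class", "tata", "rp", "tr", "noise_ext")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotation table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_annotation_table
#' @export
read_tf_table <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "tf_name", "tf_class", "present")
  if (!all(need %in% names(df))) {
    stop(sprintf("factor table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$present <- as.logical(df$present)
  df
}
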