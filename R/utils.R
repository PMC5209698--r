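# Shared internal helpers: seeded evaluation, validation, TSV I/O with
# provenance headers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  All stochastic routines in the package route through this so
# no function leaves global side effects on .Random.seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label,
# without consuming RNG state.
derive_seed <- function(seed, stream) {
  chars <- utf8ToInt(as.character(stream))
  h <- as.double(seed %% 2147483647L)
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

check_positive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

#' Default competition ChIP sampling grid
#'
#' Induction time points, in minutes, at which the simulated and fitted
#' occupancy-ratio series are evaluated.  Denser early (5-min spacing while
#' the induction curve rises) and sparser late, ending at 70 min where the
#' competitor concentration has saturated.
#'
#' @return Numeric vector of times in minutes, starting at 0.
#' @export
default_time_grid <- function() {
  c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70)
}

# -- TSV I/O -----------------------------------------------------------------

# Read a tab-delimited table; '#'-prefixed lines are comments.
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Write a tab-delimited table with optional '# ' comment header lines.
write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stable md5 of an R object (via canonical JSON in a temp file); used for
# the config-hash provenance line in output headers.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config, seed) {
  c(sprintf("chipturnover %s",
            as.character(utils::packageVersion("chipturnover"))),
    sprintf("config_md5: %s", config_hash(config)),
    sprintf("seed: %s", format(seed)))
}

log_msg <- function(...) {
  message(sprintf(...))
}
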