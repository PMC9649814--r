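# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round half away from zero (10.5 -> 11, -10.5 -> -11), unlike base round()
# which rounds half to even.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# 75% quantile of the standard normal; converts sigma (log10 units) into the
# 50->75% distance of a cumulative Gaussian.
z75 <- qnorm(0.75)

# Classed error so callers can distinguish failure modes programmatically.
abort_ns <- function(msg, class) {
  stop(structure(
    class = c(class, "numsense_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    abs(x - round(x)) < 1e-8 && x >= if (positive) 1 else 0
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs the global stream.
with_seed <- function(seed, code) {
  if (!is_scalar_num(seed)) abort_ns("`seed` must be a single finite number", "numsense_invalid_argument")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Independent sub-seeds derived from a master seed.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# CSV writing that survives a read round trip bit-for-bit for doubles:
# numeric columns are rendered with 17 significant digits.
write_csv_ns <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- out[[j]]
      s <- sprintf("%.17g", x)
      s[is.na(x)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

read_csv_ns <- function(path) {
  if (!file.exists(path)) abort_ns(sprintf("file not found: %s", path), "numsense_io_error")
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
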