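#' @import methods
#' @importFrom stats rnorm runif rpois rbinom sd var coef optim optimize median
#'   pf pnorm qnbinom rnbinom dnbinom plogis qlogis quantile median acf
#'   kmeans predict aggregate lm setNames binomial
#' @importFrom utils read.csv write.csv head tail
NULL

# Smooth pseudo-fractal noise field: sum of box-smoothed white-noise octaves.
# Returns an n x m matrix with zero mean and unit sd. Consumes the current
# RNG stream, so callers control determinism via set.seed().
smoothNoise <- function(n, m = n, roughness = 2) {
  z <- matrix(rnorm(n * m), n, m)
  passes <- max(1L, as.integer(round(roughness)))
  for (p in seq_len(3L * passes)) {
    z <- (z + rbind(z[-1, , drop = FALSE], z[n, , drop = FALSE]) +
            rbind(z[1, , drop = FALSE], z[-n, , drop = FALSE])) / 3
    z <- (z + cbind(z[, -1, drop = FALSE], z[, m, drop = FALSE]) +
            cbind(z[, 1, drop = FALSE], z[, -m, drop = FALSE])) / 3
  }
  z / max(sd(z), .Machine$double.eps)
}

# Clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a reproducible 32-bit stage seed from a global seed and a label.
# Uses the md5 of the label so stage reordering cannot change streams.
stageSeed <- function(seed, label) {
  hex <- substr(digestString(paste0(label, ":", seed)), 1, 7)
  as.integer(strtoi(hex, 16L) %% .Machine$integer.max)
}

# md5 of a string without touching the filesystem is not in base R's API,
# so hash via a temporary file (tools::md5sum is file-based).
digestString <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

# stopifnot with a friendlier message
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
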