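# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic package code funnels through this so
# a single integer seed pins an entire run.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed and a label, staying inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 7919 + h * 104729 + 13) %% 2147483629)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-major flattening: the documented on-disk/in-vector layout of crops and
# feedback images. R stores matrices column-major, hence the transposes.
flatten_rowmajor <- function(m) as.vector(t(m))

unflatten_rowmajor <- function(v, side) matrix(v, nrow = side, byrow = TRUE)

# Content hash of an arbitrary R object (used for run manifests and caching).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Normal-approximation confidence interval for a mean.
mean_ci <- function(x, level = 0.99) {
  n <- length(x)
  m <- mean(x)
  se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean = m, lower = m - z * se, upper = m + z * se)
}
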