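# internal helpers

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the expression uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cheap content fingerprint used to detect stale segmentations.
grid_id <- function(grid) {
  v <- grid$values
  sprintf("%dx%dx%d|%.6g|%.10g|%.10g",
          dim(v)[1], dim(v)[2], dim(v)[3], prod(grid$spacing),
          sum(v), sum(v * v))
}

# one-sided truncated normal draw via rejection (narrow use: blob HU)
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}
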