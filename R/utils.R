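# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a parent seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

stop_forestmf <- function(msg, class = "forestmf_error") {
  abort(msg, class = c(class, "forestmf_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_forestmf(paste0("`", name, "` must be a single number"))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_forestmf(paste0(
      "`", name, "` = ", format(x), " is outside the admissible range [",
      format(lower), ", ", format(upper), "]"
    ))
  }
  invisible(x)
}

# trapezoidal rule
trapz_ <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
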