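# Internal helpers shared across the package.

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

#' @noRd
check_fraction <- function(x, what, allow_na = FALSE) {
  stop_if(!is.numeric(x), sprintf("'%s' must be numeric", what))
  bad <- if (allow_na) {
    !is.na(x) & (!is.finite(x) | x < 0 | x > 1)
  } else {
    !is.finite(x) | x < 0 | x > 1
  }
  stop_if(any(bad), sprintf("'%s' must lie in [0, 1]; offending value(s): %s",
                            what, paste(utils::head(x[bad], 3), collapse = ", ")))
  invisible(x)
}

check_count <- function(x, what, min = 1) {
  stop_if(!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min,
          sprintf("'%s' must be a single integer >= %d", what, min))
  invisible(as.integer(x))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of their arguments.
with_seed <- function(seed, code) {
  stop_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
          "'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# truncate to [0,1] and count how many values were clipped
truncate01 <- function(x) {
  n_clipped <- sum(x < 0 | x > 1, na.rm = TRUE)
  x[x < 0] <- 0
  x[x > 1] <- 1
  structure(x, n_truncated = n_clipped)
}
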