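# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed: polynomial rolling hash of the cohort seed
# plus arbitrary tags (strings or integers), mod 2^31 - 1. Keyed per animal
# and per context so adding animals never perturbs existing streams.
substream_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    bytes <- if (is.character(tag)) {
      utf8ToInt(paste(tag, collapse = "|"))
    } else {
      as.integer(tag)
    }
    h <- (h * 131 + 7) %% m
    for (b in bytes) h <- (h * 131 + (as.numeric(b) %% m)) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

stop_data <- function(msg) abort(msg, class = "ghbsa_data_error")
stop_usage <- function(msg) abort(msg, class = "ghbsa_usage_error")
stop_config <- function(msg) abort(msg, class = "ghbsa_config_error")

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(sprintf("config field `%s` must be a single number", name))
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    stop_config(sprintf(
      "config field `%s` = %g is outside its valid range", name, x
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_data(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
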