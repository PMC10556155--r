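# Internal helpers: deterministic sub-stream seeding, the weighted
# least-squares core, and small assertion utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_soilmrm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "soilmrm_error"))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          class = "soilmrm_domain_error") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort_soilmrm(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      class
    )
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_soilmrm(
      sprintf("%s is missing column(s): %s", what,
              paste(missing, collapse = ", ")),
      "soilmrm_validation_error"
    )
  }
  invisible(df)
}

# Deterministic 31-bit sub-stream seed from a base seed plus string keys.
# Keyed by content (not position) so draws tied to an id do not move when
# unrelated ids are added to a catalog.
hash_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(keys)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(1, h))
}

# Evaluate expr with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
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
  expr
}

# Multiplicative lognormal noise factor with mean 1 and coefficient of
# variation `cv`; exactly 1 when cv = 0 so noise-free runs are bit-exact.
lognormal_factor <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Closed-form weighted simple linear regression used internally where many
# small fits are needed; the public fitting path is fit_calibration().
wls_core <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - ybar)^2)
  list(
    slope = slope,
    intercept = intercept,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  )
}
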