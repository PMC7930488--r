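#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm rgamma optimize
#'   setNames complete.cases median quantile sd var cor lm resid plogis rlnorm
#' @importFrom utils head
NULL

# shared ordered category levels for the puberty category score
pds_category_levels <- c("prepubertal", "early", "mid", "late", "post")

`%||%` <- function(x, y) if (is.null(x)) y else x

# clock "HH:MM" -> minutes since midnight (NA passes through)
parse_clock_minutes <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) {
      abort(paste0("unparseable clock time(s): ",
                   paste(unique(x[ok][bad]), collapse = ", ")))
    }
    h <- as.numeric(vapply(parts, `[`, "", 1L))
    m <- as.numeric(vapply(parts, `[`, "", 2L))
    if (anyNA(h) || anyNA(m) || any(h < 0 | h > 23 | m < 0 | m > 59)) {
      abort("clock times must be HH:MM with 0<=HH<=23, 0<=MM<=59")
    }
    out[ok] <- h * 60 + m
  }
  out
}

minutes_to_clock <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

assert_prob_vector <- function(p, field) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort(paste0("configuration error: `", field,
                 "` must be a probability vector summing to 1"))
  }
  invisible(p)
}
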