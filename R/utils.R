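# internal helpers shared across stages

skel_abort <- function(message, class, ...) {
  abort(message, class = c(class, "skelegrow_error"), ...)
}

# standard error of the mean; 0 for n == 1 (reported, not dropped)
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  sd(x) / sqrt(length(x))
}

# truncated-normal draw by rejection; lower/upper are hard bounds
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    skel_abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "skelegrow_format_error"
    )
  }
  invisible(df)
}
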