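# internal helpers

# round half away from zero at `digits` decimals (the convention used by the
# printed reports; base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_num <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# derive a per-unit seed from a base seed; kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

is_odd_window <- function(w) {
  is.numeric(w) && length(w) == 1L && is.finite(w) && w == floor(w) &&
    w >= 3 && (w %% 2 == 1)
}

stop_poseagree <- function(msg, class) {
  abort(msg, class = c(class, "poseagree_error"))
}

# column presence check with a readable error
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_poseagree(
      sprintf("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", ")),
      "poseagree_input_error"
    )
  }
  invisible(df)
}
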