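# Internal helpers: log-scale tail probabilities and a minimal arbitrary-
# precision integer (base 1e7 limbs, little-endian) used for exact subset
# counts. Limb products stay below 2^53 for multipliers <= 1e8 and divisors
# <= 1e8, which covers every use here.

LOG10 <- log(10)

log10_pf_upper <- function(f, df1, df2) {
  pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / LOG10
}

log10_pchisq_upper <- function(x, df) {
  pchisq(x, df, lower.tail = FALSE, log.p = TRUE) / LOG10
}

# Linear-scale p-value with the legacy double-precision floor: values below
# the smallest normalised double are reported as exactly zero.
linear_p_floor <- 2.22e-308

linear_p <- function(log10_p) {
  ifelse(log10_p < log10(linear_p_floor), 0, 10^log10_p)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x < 1
}

## ---- big integers ------------------------------------------------------

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
    if (x == 0) break
  }
  limbs
}

big_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0) n <- n - 1L
  a[seq_len(n)]
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0) s <- c(s, big_from_int(carry))
  big_trim(s)
}

big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m <= 1e8)
  if (m == 0) return(0)
  carry <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    p <- a[i] * m + carry
    out[i] <- p %% BIG_BASE
    carry <- p %/% BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big_trim(out)
}

# Exact division; aborts if a is not divisible by d (never happens along the
# C(n,k) recurrence, where each partial product is an integer).
big_div_small <- function(a, d) {
  stopifnot(d >= 1, d == floor(d), d <= 1e8)
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  if (rem != 0) abort("internal error: inexact big-integer division")
  big_trim(out)
}

big_to_string <- function(a) {
  n <- length(a)
  head_limb <- format(a[n], scientific = FALSE)
  rest <- if (n > 1L) {
    paste0(formatC(rev(a[-n]), width = 7, flag = "0", format = "d"),
           collapse = "")
  } else ""
  paste0(head_limb, rest)
}

big_log10 <- function(a) {
  n <- length(a)
  top <- 0
  used <- 0L
  for (i in seq_len(min(3L, n))) {
    top <- top * BIG_BASE + a[n - i + 1L]
    used <- used + 1L
  }
  log10(top) + (n - used) * 7
}
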