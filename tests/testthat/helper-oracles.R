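# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, exact big-integer
# arithmetic, and hand enumerations.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Naive all-positions Hamming matcher (oracle for match_with_mismatches).
naive_match <- function(query, subject, max_mm) {
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  k <- length(qv)
  out <- data.frame(position = integer(0), mismatches = integer(0))
  for (i in seq_len(length(sv) - k + 1L)) {
    mm <- sum(qv != sv[i:(i + k - 1L)])
    if (mm <= max_mm)
      out <- rbind(out, data.frame(position = i, mismatches = mm))
  }
  out
}

# --- exact big-integer arithmetic (little-endian base-1e4 limbs) ---------

big_from_int <- function(x) {
  v <- integer(0)
  while (x > 0) { v <- c(v, x %% 10000L); x <- x %/% 10000L }
  if (!length(v)) v <- 0L
  v
}

big_mul_small <- function(v, m) {
  prod <- as.numeric(v) * m
  carry <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(prod) || carry > 0) {
    cur <- carry + if (i <= length(prod)) prod[i] else 0
    out[i] <- cur %% 10000
    carry <- cur %/% 10000
    i <- i + 1L
  }
  as.integer(out)
}

big_div_small <- function(v, d) {  # exact division only
  out <- integer(length(v))
  rem <- 0
  for (i in rev(seq_along(v))) {
    cur <- rem * 10000 + v[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  stopifnot(rem == 0)
  while (length(out) > 1L && out[length(out)] == 0L)
    out <- out[-length(out)]
  out
}

# Leading-digit representation: value = mantissa * 10^exp10.
big_to_sci <- function(v) {
  digs <- paste(c(sprintf("%d", v[length(v)]),
                  sprintf("%04d", rev(v[-length(v)]))), collapse = "")
  nd <- nchar(digs)
  take <- min(17L, nd)
  list(mantissa = as.numeric(substr(digs, 1L, take)) / 10^(take - 1L),
       exp10 = nd - 1L)
}

# Exact C(n, k) * 9^(n-k) / 10^n for p = 1/10, via exact integers.
exact_binom_tenth <- function(k, n) {
  num <- big_from_int(1L)
  for (i in seq_len(k)) {           # C(n, k) built stepwise, exactly
    num <- big_mul_small(num, n - k + i)
    num <- big_div_small(num, i)
  }
  for (i in seq_len(n - k)) num <- big_mul_small(num, 9L)
  sci <- big_to_sci(num)
  sci$mantissa * 10^(sci$exp10 - n)
}

# Interleaved-product oracle for general p: keeps the running product in
# range by alternating large and small factors.
interleaved_binom <- function(k, n, p) {
  acc <- 1
  for (i in seq_len(k)) acc <- acc * ((n - k + i) / i) * p
  acc * (1 - p)^(n - k)
}

# Exhaustive stem-loop enumeration over Watson-Crick + G:U pairs (oracle
# for the fold search). Returns every (i, j, stem, loop).
enumerate_stem_loops <- function(seq, stem_range, loop_range,
                                 min_start = 1L) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  n <- length(sv)
  out <- NULL
  for (s in stem_range) for (L in loop_range) {
    top <- n - 2L * s - L + 1L
    if (top < min_start) next
    for (i in min_start:top) {
      j <- i + s + L
      if (all(vapply(0:(s - 1L), function(q)
        ok(sv[i + q], sv[j + s - 1L - q]), TRUE)))
        out <- rbind(out, c(i = i, j = j, stem = s, loop = L))
    }
  }
  out
}

# Default 3 vs 3 case bipartition of the standard synthetic layout.
default_case_bipartition <- function() {
  list(side_a = c("S1", "S2", "S3"), side_b = c("S4", "S5", "S6"))
}
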