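## Independent oracle routines used to cross-check the package's statistics.
## They deliberately avoid the code paths they validate.

## Term-by-term evaluation of the bias-corrected excess kurtosis formula,
## accumulating the fourth-power sum in an explicit loop.
kurtosis_oracle <- function(a) {
  n <- length(a)
  abar <- sum(a) / n
  sd_ <- sqrt(sum((a - abar)^2) / (n - 1))
  num <- 0
  for (v in a) num <- num + (v - abar)^4
  n * (n + 1) * num / ((n - 1) * (n - 2) * (n - 3) * sd_^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

## Dense spatial-domain convolution with symmetric (edge-including) mirror
## boundary, quadruple loop.
reflect_idx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

dense_conv_oracle <- function(px, k) {
  m <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in -m:m) for (b in -m:m)
      s <- s + k[a + m + 1L, b + m + 1L] *
        px[reflect_idx(i - a, nr), reflect_idx(j - b, nc)]
    out[i, j] <- s
  }
  out
}

## Exact Mann-Whitney two-sided p by full subset enumeration (bitmask route,
## distinct from the package's combn enumeration).
mw_exact_oracle <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  subs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
  subs <- subs[rowSums(subs) == na, , drop = FALSE]
  Ud <- as.vector(subs %*% r) - na * (na + 1) / 2
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  eps <- 1e-8
  min(1, 2 * min(mean(Ud <= U + eps), mean(Ud >= U - eps)))
}

## Two-group log-rank chi-square by direct per-event-time observed-minus-
## expected summation with hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n1 <- sum(at & g == 1L); n <- sum(at)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

## Hand product-limit estimator (no censoring handling needed by its callers
## beyond risk-set bookkeeping).
km_oracle <- function(time, event) {
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
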