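# Exact big-integer rational arithmetic (base 1e4 limbs, little-endian),
# used as an independent oracle for the binomial point mass:
#   Pr(h; n, t) = C(n, h) * (t-1)^(n-h) / t^n
# Numerator and denominator are computed exactly as big integers and the
# quotient evaluated by long division to ~28 significant decimal digits.

bigFromInt <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0L)
  limbs <- integer(0)
  while (x > 0) {
    limbs <- c(limbs, as.integer(x %% 10000))
    x <- x %/% 10000
  }
  limbs
}

bigNorm <- function(a) {
  carry <- 0
  for (i in seq_along(a)) {
    v <- a[i] + carry
    a[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) {
    a <- c(a, carry %% 10000)
    carry <- carry %/% 10000
  }
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

bigMulSmall <- function(a, k) {
  if (k == 0) return(0L)
  bigNorm(a * k)
}

bigMul <- function(a, b) {
  # limbs < 1e4, so partial sums stay well below 2^53 for the sizes here
  res <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
  }
  bigNorm(res)
}

bigCmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(sign(la - lb))
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

bigSub <- function(a, b) {   # a - b, requires a >= b
  b <- c(b, rep(0L, length(a) - length(b)))
  borrow <- 0L
  for (i in seq_along(a)) {
    v <- a[i] - b[i] - borrow
    if (v < 0) { v <- v + 10000L; borrow <- 1L } else borrow <- 0L
    a[i] <- v
  }
  stopifnot(borrow == 0L)
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

bigDivSmall <- function(a, k) {
  q <- integer(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    v <- r * 10000 + a[i]
    q[i] <- v %/% k
    r <- v %% k
  }
  while (length(q) > 1 && q[length(q)] == 0) q <- q[-length(q)]
  list(q = q, r = r)
}

# exact C(n, h) via the multiplicative recurrence, staying integral
bigChoose <- function(n, h) {
  out <- bigFromInt(1)
  for (i in seq_len(h)) {
    out <- bigMulSmall(out, n - h + i)
    d <- bigDivSmall(out, i)
    stopifnot(d$r == 0)
    out <- d$q
  }
  out
}

bigPowSmall <- function(base, e) {
  out <- bigFromInt(1)
  for (i in seq_len(e)) out <- bigMulSmall(out, base)
  out
}

# N / D (N < D assumed or general) as double via long division
bigRatio <- function(N, D) {
  if (length(N) == 1 && N[1] == 0) return(0)
  intPart <- 0
  Nw <- N
  while (bigCmp(Nw, D) >= 0) {
    Nw <- bigSub(Nw, D)
    intPart <- intPart + 1
  }
  val <- intPart
  scale <- 1
  r <- Nw
  for (d in seq_len(7)) {            # 7 limbs of 4 digits = 28 digits
    r <- bigNorm(r * 10000)
    lo <- 0L; hi <- 9999L
    while (lo < hi) {                # binary-search the next limb
      mid <- as.integer((lo + hi + 1) %/% 2)
      if (bigCmp(bigMulSmall(D, mid), r) <= 0) lo <- mid else hi <- mid - 1L
    }
    r <- bigSub(r, bigMulSmall(D, lo))
    scale <- scale / 10000
    val <- val + lo * scale
  }
  val
}

exactBinomialMass <- function(h, n, t) {
  if (t == 1) return(as.numeric(h == n))
  N <- bigChoose(n, h)
  if (n - h > 0) N <- bigMul(N, bigPowSmall(t - 1, n - h))
  D <- bigPowSmall(t, n)
  bigRatio(N, D)
}
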