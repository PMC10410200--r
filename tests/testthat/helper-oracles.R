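# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's vectorised code paths.

# Textbook sums-of-squares decomposition of a complete 2 x 4 within-subject
# table; y is a vector indexed by (subj, cond, state) triples.
oracleRmAnova <- function(y, subj, cond, state) {
  n <- length(unique(subj))
  cell <- function(i, c, s) y[subj == i & cond == c & state == s]
  grand <- mean(y)
  mC <- sapply(1:2, function(c) mean(y[cond == c]))
  mS <- sapply(1:4, function(s) mean(y[state == s]))
  mI <- sapply(1:n, function(i) mean(y[subj == i]))
  ssC <- 4 * n * sum((mC - grand)^2)
  ssS <- 2 * n * sum((mS - grand)^2)
  ssSub <- 8 * sum((mI - grand)^2)
  ssCS <- 0; ssCsub <- 0; ssSsub <- 0; ssTot <- sum((y - grand)^2)
  for (c in 1:2) for (s in 1:4)
    ssCS <- ssCS + n * (mean(y[cond == c & state == s]) -
                          mC[c] - mS[s] + grand)^2
  for (c in 1:2) for (i in 1:n)
    ssCsub <- ssCsub + 4 * (mean(y[cond == c & subj == i]) -
                              mC[c] - mI[i] + grand)^2
  for (s in 1:4) for (i in 1:n)
    ssSsub <- ssSsub + 2 * (mean(y[state == s & subj == i]) -
                              mS[s] - mI[i] + grand)^2
  ssErr <- ssTot - ssC - ssS - ssSub - ssCS - ssCsub - ssSsub
  list(condition = (ssC / 1) / (ssCsub / (n - 1)),
       state = (ssS / 3) / (ssSsub / (3 * (n - 1))),
       interaction = (ssCS / 3) / (ssErr / (3 * (n - 1))))
}

# Naive flood-fill connected components of a logical 3-D array.
oracleClusterSizes <- function(supra, connectivity = 26) {
  d <- dim(supra)
  lab <- array(0L, dim = d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  nxt <- 0L
  sizes <- integer(0)
  for (idx in which(supra)) {
    if (lab[idx] > 0L) next
    nxt <- nxt + 1L
    queue <- idx
    lab[idx] <- nxt
    sz <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      sz <- sz + 1L
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- co + off[r, ]
        if (any(nb < 1) || any(nb > d)) next
        ni <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (supra[ni] && lab[ni] == 0L) {
          lab[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# First-principles paired t: mean difference, SE, two-sided p, CI.
oraclePairedT <- function(a, b, level = 0.95) {
  d <- a - b
  n <- length(d)
  md <- mean(d)
  se <- sqrt(sum((d - md)^2) / (n - 1)) / sqrt(n)
  tv <- md / se
  p <- 2 * (1 - pt(abs(tv), n - 1))
  q <- qt(1 - (1 - level) / 2, n - 1)
  list(md = md, se = se, t = tv, p = p, lo = md - q * se, hi = md + q * se)
}
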