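## Reference implementations used as oracles in the tests. Deliberately
## naive: triple loops and direct formulas, no shared code with the package.

## Adjusted Rand Index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

## Amari index between a true mixing A and an estimated unmixing W
## (0 for a perfect separation up to permutation and scale)
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(P / matrix(apply(P, 2, max), n, n, byrow = TRUE)) - 1)
  (r + c) / (2 * n * (n - 1))
}

## Brute-force weighted clustering coefficient (geometric-mean triangle
## intensity, Onnela-style), triple loop
brute_clustering <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + wh[i, j] * wh[i, h] * wh[j, h]
    }
    C[i] <- s / (k * (k - 1))
  }
  C
}

## Naive trial-then-bin averaged phase cross-spectrum at given DFT bins
naive_band_rho <- function(d, bins) {
  Tn <- dim(d)[1]; R <- dim(d)[2]; n <- dim(d)[3]
  rho <- matrix(0i, R, R)
  for (k in bins) {
    acc <- matrix(0i, R, R)
    for (tr in seq_len(Tn)) {
      cf <- complex(real = 0, imaginary = 0)
      cf <- vapply(seq_len(R), function(r)
        sum(d[tr, r, ] * exp(-2i * pi * k * (seq_len(n) - 1) / n)), complex(1))
      cf <- cf / Mod(cf)
      acc <- acc + outer(cf, Conj(cf))
    }
    rho <- rho + acc / Tn
  }
  rho / length(bins)
}

## Small test configuration helpers (kept tiny so unit tests stay fast)
tiny_config <- function(...) {
  sim_config(n_subjects = 4L, n_trials_per_condition = 10L, n_channels = 16L,
             n_rois = 8L, conditions = c("WE-IL", "WE-IT"),
             rt_link = list(roi = 5L, slope = 0.4, noise_sd = 0.11,
                            intercept = 0.8, base_mix = 0.3),
             ...)
}
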