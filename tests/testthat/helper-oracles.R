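# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately use naive double loops, never the package
# implementations.

make_trace <- function(p, sampling_rate = 200, ...) {
  sensor_trace(p, sampling_rate = sampling_rate, ...)
}

random_trace <- function(n, seed) {
  set.seed(seed)
  make_trace(matrix(rnorm(n * 6, sd = 10), n, 6))
}

naive_mean_pressure <- function(p, i) {
  s <- 0
  for (j in seq_len(nrow(p))) s <- s + p[j, i]
  s / nrow(p)
}

naive_fluctuations <- function(p, i) {
  m <- naive_mean_pressure(p, i)
  s <- 0
  for (j in seq_len(nrow(p))) s <- s + abs(p[j, i] - m)
  s / nrow(p)
}

naive_front_pressure <- function(p) {
  s <- 0
  for (j in seq_len(nrow(p))) s <- s + p[j, 1] + p[j, 2]
  s / (2 * nrow(p))
}

naive_asymmetry <- function(p, mode) {
  n <- nrow(p)
  s <- 0
  for (k in 1:3) {
    for (j in seq_len(n)) s <- s + (p[j, 2 * k - 1] - p[j, 2 * k])^2
  }
  s / switch(mode, pairmean = 3 * n, timemean = n, literal = n^3)
}

# Brute-force Kruskal-Wallis from the definition (mid-ranks, tie correction).
naive_kruskal <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  H <- 0
  for (lev in levels(g)) {
    idx <- g == lev
    H <- H + sum(idx) * (mean(r[idx]) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) 0 else H / C
}

# Chi-squared distances between row profiles of a contingency table.
profile_chisq_dist <- function(tab) {
  P <- tab / sum(tab)
  prof <- sweep(P, 1, rowSums(P), "/")
  cmass <- colSums(P)
  nr <- nrow(tab)
  D <- matrix(0, nr, nr)
  for (a in seq_len(nr)) {
    for (b in seq_len(nr)) {
      D[a, b] <- sqrt(sum((prof[a, ] - prof[b, ])^2 / cmass))
    }
  }
  D
}

# Minimal clean behaviour-event log fixture.
clean_events <- function(design) {
  data.frame(
    treatment = c("R1HP", "R1HP", "R1HP", "R1HP", "R1HP",
                  "R2BF", "R2BF", "R0HP", "R0HP", "R0HP"),
    replicate = c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 3L, 3L, 3L),
    metric = c("Iref", "Iref", "Iref", "Gdrift", "Gdrift",
               "Gref", "Isprint", "Idrift", "Isprint", "Gsprint"),
    start_time_s = c(10, 50, 100, 200, 300, 400, 500, 600, 700, 800),
    start_zone = c("C1", "C1", "C2", "C3", "C3", "C4", "C5", "C1", "C2", "C3"),
    group_size = c(1L, 1L, 1L, 3L, 4L, 2L, 1L, 1L, 1L, 5L),
    stringsAsFactors = FALSE
  )
}
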