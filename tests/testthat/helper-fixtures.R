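# Shared small fixtures, built in code and cached for the run.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_config <- function(...) {
  args <- list(seed = 42L, n_sequences = 2L, seq_length = 30000L,
               block_length = 6000L, n_genes = 10L, spike_in_length = 4000L)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# one small full dataset shared across test files
tiny_sim <- function() cached("tiny_sim", function() simulate_dataset(tiny_config()))

# a 4-site, 3-date hand-built series
toy_series <- function() {
  dates <- as.Date(c("2015-01-01", "2015-04-01", "2015-07-01"))
  rep1 <- tibble(seq_id = "c1", pos = c(2L, 5L, 9L), strand = c("+", "+", "-"),
                 n_meth = c(3L, 0L, 5L), n_unmeth = c(7L, 10L, 5L),
                 context = c("CG", "CHH", "CG"), trinucleotide = c("CGA", "CTT", "CGT"))
  rep2 <- rep1 |> mutate(n_meth = c(5L, 1L, 5L), n_unmeth = c(5L, 9L, 5L))
  rep3 <- rep1 |> mutate(n_meth = c(9L, 0L, 5L), n_unmeth = c(1L, 10L, 5L))
  build_series(list(rep1, rep2, rep3), dates)
}

# brute-force average-linkage clustering oracle: returns sorted merge heights
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) { best_h <- h; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# exhaustive two-sided Fisher p via dhyper enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# exhaustive rank-assignment Mann-Whitney two-sided p
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  u_of <- function(sel) sum(r[sel]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  us <- apply(idx, 2, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
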