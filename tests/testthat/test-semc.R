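# Fisher statistic, Storey q-values, detection, peaks, clustering, locations.

test_that("fisher_exact_2x2 reproduces known exact values", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # all-zero row: degenerate margins
  expect_equal(fisher_exact_2x2(0, 0, 3, 7), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_exact_2x2 agrees with dhyper enumeration and fisher.test", {
  set.seed(3)
  for (i in 1:200) {
    tab <- rpois(4, sample(c(2, 8, 25), 1))
    p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    if (sum(tab[1:2]) > 0 && sum(tab[3:4]) > 0) {
      ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
})

test_that("site statistic is the minimum over coverage-passing pairs", {
  # constant counts: every pairwise test is 1
  st <- site_statistic(rep(10L, 8), rep(20L, 8))
  expect_equal(st$p_min, 1)
  expect_equal(st$n_pairs, 28L)
  # one discordant date
  m <- c(rep(0L, 7), 20L); t <- rep(20L, 8)
  st2 <- site_statistic(m, t)
  expect_equal(st2$p_min, fisher.test(matrix(c(0, 20, 20, 0), 2))$p.value,
               tolerance = 1e-9)
  expect_equal(st2$p_min, 2 / choose(40, 20), tolerance = 1e-9)
  # a date failing the coverage filter drops its 7 pairs
  t3 <- c(3L, rep(20L, 7))
  st3 <- site_statistic(c(0L, rep(10L, 7)), t3, min_cov = 5)
  expect_equal(st3$n_pairs, 21L)
  # no testable pair -> NA, not p = 1
  st4 <- site_statistic(c(1L, 1L), c(2L, 2L), min_cov = 5)
  expect_true(is.na(st4$p_min))
  # with T = 2 the statistic reduces to the single Fisher test
  st5 <- site_statistic(c(3L, 9L), c(12L, 12L))
  expect_equal(st5$p_min, fisher_exact_2x2(3, 9, 9, 3))
})

test_that("storey q-values follow the defining formula", {
  # all p = 1
  st <- storey_qvalues(rep(1, 50))
  expect_equal(st$pi0, 1)
  expect_true(all(st$q == 1))
  # single p with pi0 forced to 1
  expect_equal(storey_qvalues(0.01, pi0 = 1)$q, 0.01)
  # uniform p-values: pi0 near 1, q monotone in p, matches direct formula
  set.seed(7)
  p <- runif(20000)
  st2 <- storey_qvalues(p)
  expect_gt(st2$pi0, 0.95)
  ord <- order(p)
  expect_true(all(diff(st2$q[ord]) >= -1e-12))
  direct <- rev(cummin(rev(st2$pi0 * length(p) * p[ord] / seq_along(p))))
  expect_equal(st2$q[ord], pmin(direct, 1))
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("q-value thresholding is anti-conservative on raw minima but calibrated after Sidak", {
  # mixture: 10% alternatives among Sidak-corrected pairwise minima
  set.seed(11)
  m <- c(rep(10L, 1800), rep(c(2L, 18L), each = 900))
  meth <- cbind(matrix(rbinom(1800 * 4, 20, 0.5), 1800, 4),
                matrix(rbinom(1800 * 4, 20, 0.5), 1800, 4))
  total <- matrix(20L, 1800, 8)
  # plant 10% of sites with a strong shift in half the dates
  alt <- 1:180
  meth[alt, 1:4] <- rbinom(length(alt) * 4, 20, 0.1)
  meth[alt, 5:8] <- rbinom(length(alt) * 4, 20, 0.9)
  st <- site_statistic(meth, total)
  p_sidak <- 1 - (1 - st$p_min)^st$n_pairs
  q <- storey_qvalues(p_sidak)$q
  called <- which(q < 0.2)
  expect_gt(length(called), 100) # power on the strong alternatives
  fdr <- mean(!called %in% alt)
  expect_lt(fdr, 0.25)
})

test_that("peak classification picks the maximum with earliest-date ties flagged", {
  dates <- default_dates <- seq(as.Date("2015-01-15"), by = "month",
                                length.out = 9)[c(1, 3, 5, 7, 9)]
  pk <- classify_peak(c(0.1, 0.2, 0.3, 0.9, 0.4), dates)
  expect_equal(pk$peak_date, dates[4])
  expect_false(pk$peak_tie)
  # exact tie: earliest wins, flagged
  pk2 <- classify_peak(c(0.1, 0.9, 0.2, 0.9, 0.1), dates)
  expect_equal(pk2$peak_date, dates[2])
  expect_true(pk2$peak_tie)
  expect_equal(pk2$peak_month, format(dates[2], "%B") |>
                 (\(x) month.name[as.integer(format(dates[2], "%m"))])())
  expect_error(classify_peak(rep(NA_real_, 5), dates), "undefined")
})

test_that("detection flags planted SeMCs and controls the null", {
  cfg <- tiny_config(semc_fraction = 0.01, semc_amplitude = 0.5,
                     coverage_mean = 30, n_genes = 6L)
  sim <- simulate_dataset(cfg)
  res <- detect_semcs(sim$series, sim$annotation,
                      exclude_seq = "spike_lambda")
  calls <- tidy(res) |>
    left_join(sim$truth$sites |> select(seq_id, pos, strand, is_semc),
              by = c("seq_id", "pos", "strand"), suffix = c("", "_true"))
  # power: most planted SeMCs at amplitude 0.5 / coverage 30 are recovered
  planted <- calls |> filter(is_semc_true)
  expect_gt(mean(planted$is_semc), 0.6)
  # in the calibrated (Sidak) mode the flagged set is dominated by planted
  # sites; the literal minimum-p mode is anti-conservative by construction
  res_s <- detect_semcs(sim$series, sim$annotation,
                        exclude_seq = "spike_lambda", correction = "sidak")
  flagged <- tidy(res_s) |>
    left_join(sim$truth$sites |> select(seq_id, pos, strand, is_semc),
              by = c("seq_id", "pos", "strand"), suffix = c("", "_true")) |>
    filter(is_semc)
  expect_gt(mean(flagged$is_semc_true), 0.7)
  # invariant: every SeMC satisfies both thresholds
  expect_true(all(flagged$p_min < res$params$alpha &
                    flagged$q < res$params$fdr_max))
})

test_that("detection output is invariant to site input order", {
  sim <- tiny_sim()
  ser <- subset_series(sim$series, seq_ids = "scf_1", contexts = "CG")
  set.seed(2)
  shuf <- sample(nrow(ser$sites))
  ser2 <- ser
  ser2$sites <- ser$sites[shuf, ]
  ser2$meth <- ser$meth[shuf, ]
  ser2$total <- ser$total[shuf, ]
  r1 <- detect_semcs(ser)
  r2 <- detect_semcs(ser2)
  a <- tidy(r1) |> arrange(seq_id, pos, strand)
  b <- tidy(r2) |> arrange(seq_id, pos, strand)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("omnibus G-test mode agrees with chisq likelihood ratio on a known table", {
  meth <- matrix(c(5L, 15L, 5L, 15L), 1)
  total <- matrix(20L, 1, 4)
  st <- gtest_omnibus <- detect_semcs(
    build_toy <- local({
      dates <- as.Date("2015-01-01") + (0:3) * 40
      r <- lapply(1:4, function(t) tibble(
        seq_id = "c", pos = 2L, strand = "+", n_meth = meth[1, t],
        n_unmeth = total[1, t] - meth[1, t], context = "CG",
        trinucleotide = "CGA"))
      build_series(r, dates)
    }), method = "omnibus")
  o <- rbind(meth[1, ], total[1, ] - meth[1, ])
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  g <- 2 * sum(o * log(o / e))
  expect_equal(st$calls$p_min, pchisq(g, df = 3, lower.tail = FALSE))
})

test_that("clustering matches a brute-force average-linkage oracle", {
  set.seed(4)
  mat <- matrix(rnorm(40), 5, 8)
  cl <- cluster_semcs(mat)
  d <- 1 - cor(t(mat))
  diag(d) <- 0
  expect_equal(sort(cl$hclust$height),
               average_linkage_heights(as.dist(d)), tolerance = 1e-12)
  expect_match(cl$newick, "^\\(.*\\);$")
  # identical rows merge first at distance 0
  mat2 <- rbind(mat[1, ], mat[1, ], mat[3:5, ])
  cl2 <- cluster_semcs(mat2)
  expect_equal(min(cl2$hclust$height), 0)
  expect_setequal(cl2$hclust$merge[1, ], c(-1, -2))
  # a row and its negation sit at distance 2, merged last in a 3-row set
  mat3 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4.01), c = -c(1, 2, 3, 4))
  cl3 <- cluster_semcs(mat3)
  expect_equal(max(cl3$hclust$height), mean(c(2, 2)), tolerance = 1e-6)
  # zero-variance rows get distance 1 to everything
  mat4 <- rbind(c(1, 1, 1, 1), c(0, 1, 2, 3), c(3, 2, 1, 0))
  cl4 <- cluster_semcs(mat4)
  expect_error(cluster_semcs(mat4[1, , drop = FALSE]), "at least 2")
})

test_that("location classes follow exon > intron > intergenic precedence", {
  sl <- c(chr = 1000L)
  ann <- genome_annotation(
    sl,
    genes = tibble(gene_id = "g1", seq_id = "chr", start = 100L, end = 500L,
                   strand = "+"),
    exons = tibble(gene_id = "g1", seq_id = "chr",
                   start = c(100L, 400L), end = c(200L, 500L)))
  # 1-based positions: 150 exon, 250 intron, 700 intergenic, 401 exon edge
  loc <- classify_location(ann, rep("chr", 4), c(150L, 250L, 700L, 401L))
  expect_equal(loc, c("exon", "intron", "intergenic", "exon"))
})

test_that("location breakdown proportions sum to one per context", {
  calls <- tibble(context = c("CG", "CG", "CG", "CHH"),
                  location = c("exon", "intron", "exon", "intergenic"),
                  is_semc = TRUE)
  lb <- location_breakdown(calls)
  sums <- lb |> group_by(context) |> summarise(s = sum(prop))
  expect_true(all(sums$s == 1))
  expect_equal(lb |> filter(context == "CG", location == "exon") |>
                 pull(prop), 2 / 3)
})

test_that("planted intergenic-repeat CHH SeMCs are classified intergenic", {
  cfg <- tiny_config(semc_fraction = 0.02, semc_amplitude = 0.5,
                     coverage_mean = 30, flc_like = FALSE)
  sim <- simulate_dataset(cfg)
  res <- detect_semcs(sim$series, sim$annotation,
                      exclude_seq = "spike_lambda")
  chh <- tidy(res) |> filter(is_semc, context == "CHH")
  expect_gt(nrow(chh), 10)
  expect_gt(mean(chh$location == "intergenic"), 0.95)
})
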