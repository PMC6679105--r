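# Pooled levels, windows, conversion rate, per-feature series.

test_that("methylation level is the pooled ratio, not a mean of ratios", {
  expect_equal(methylation_level(c(3, 2), c(7, 8)), 0.25)
  expect_equal(methylation_level(0, 10), 0)
  expect_equal(methylation_level(c(10, 0), c(0, 10)), 0.5)
  # the case where pooled and mean-of-ratios disagree: 10/40 vs 0.5
  expect_equal(methylation_level(c(10, 0), c(0, 30)), 0.25)
  expect_true(is.na(methylation_level(c(0, 0), c(0, 0))))
  expect_error(methylation_level(-1, 2), "non-negative")
})

test_that("pooled level of a union lies between the two regional levels", {
  set.seed(1)
  for (i in 1:20) {
    m1 <- rbinom(5, 20, 0.3); m2 <- rbinom(7, 20, 0.7)
    l1 <- methylation_level(m1, 20 - m1)
    l2 <- methylation_level(m2, 20 - m2)
    lu <- methylation_level(c(m1, m2), 20 - c(m1, m2))
    expect_gte(lu, min(l1, l2))
    expect_lte(lu, max(l1, l2))
  }
})

test_that("bulk levels cover exactly the contexts present", {
  s <- toy_series()
  bl <- bulk_levels(s)
  expect_setequal(unique(bl$context), c("CG", "CHH"))
  # single-site context: (5,5) at every date -> 0.5 throughout
  one <- subset_series(s, index = which(s$sites$pos == 9L))
  bl1 <- bulk_levels(one)
  expect_true(all(bl1$level == 0.5))
  expect_false("CHG" %in% bl1$context)
})

test_that("conversion rate inverts the spike-in pooled level", {
  sim <- tiny_sim()
  cr <- conversion_rate(sim$series)
  expect_true(all(cr$rate > 0.99)) # failure rate 0.005, tens of kcalls/date
  # all-methylated spike-in -> rate 0
  sp <- subset_series(sim$series, seq_ids = "spike_lambda")
  sp$meth <- sp$total
  expect_true(all(conversion_rate(sp)$rate == 0))
  expect_error(conversion_rate(subset_series(sim$series, seq_ids = "scf_1")),
               "no spike-in")
})

test_that("windows tile sequences without losing or duplicating sites", {
  sim <- tiny_sim()
  ann <- sim$annotation
  # length 30,000 with 12,500 bp windows -> 3 windows, last of span 5,000
  wp <- window_profiles(sim$series, ann, window_size = 12500,
                        exclude_seq = "spike_lambda")
  w1 <- wp |> filter(seq_id == "scf_1") |> distinct(start, end)
  expect_equal(nrow(w1), 3)
  expect_equal(w1$end - w1$start, c(12500L, 12500L, 5000L))
  # conservation: per context, window site counts add up to the series total
  per_ctx <- wp |>
    filter(date == sim$series$dates[1]) |>
    group_by(context) |>
    summarise(n = sum(n_sites), .groups = "drop")
  truth_n <- subset_series(sim$series, exclude_seq = "spike_lambda")$sites |>
    count(context)
  expect_equal(per_ctx$n, truth_n$n)
})

test_that("repeat density merges overlapping repeats before coverage", {
  sl <- c(chr = 1000L)
  dup <- tibble(repeat_id = c("r1", "r2"), seq_id = "chr",
                start = 0L, end = 500L, family = "LTR/Copia")
  ann <- genome_annotation(sl, repeats = dup)
  r <- tibble(seq_id = "chr", pos = c(10L, 700L), strand = "+",
              n_meth = 1L, n_unmeth = 1L, context = "CG",
              trinucleotide = "CGA")
  r$pos <- c(10L, 700L)
  s <- build_series(list(r, r), as.Date(c("2015-01-01", "2015-02-01")))
  wp <- window_profiles(s, ann, window_size = 1000)
  expect_equal(unique(wp$repeat_density), 0.5) # two identical repeats count once
  full <- genome_annotation(sl, repeats = tibble(
    repeat_id = "r1", seq_id = "chr", start = 0L, end = 1000L,
    family = "LTR/Copia"))
  expect_equal(unique(window_profiles(s, full, 1000)$repeat_density), 1)
})

test_that("window correlation handles degenerate inputs", {
  prof <- tibble(seq_id = "c", start = 0:3 * 100L, end = 1:4 * 100L,
                 repeat_density = c(0.1, 0.2, 0.3, 0.4),
                 context = "CG", date = as.Date("2015-01-01"),
                 level = c(0.1, 0.2, 0.3, 0.4), n_sites = 10L)
  expect_equal(window_correlation(prof, "CG", "2015-01-01"), 1)
  flat <- prof |> mutate(level = 0.5)
  expect_error(window_correlation(flat, "CG", "2015-01-01"), "zero variance")
  expect_error(window_correlation(prof[1:2, ], "CG", "2015-01-01"),
               "at least 3")
  # NA levels are excluded, not treated as zero
  prof$level[1] <- NA
  expect_equal(window_correlation(prof, "CG", "2015-01-01"), 1)
})

test_that("window levels track repeat density in the simulated genome", {
  sim <- tiny_sim()
  wp <- window_profiles(sim$series, sim$annotation, window_size = 6000,
                        exclude_seq = "spike_lambda")
  # heterochromatic blocks carry boosted methylation in all contexts
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_gt(window_correlation(wp, ctx, sim$series$dates[1]), 0.5)
  }
})

test_that("feature series pools per repeat and reports flat zeros faithfully", {
  sl <- c(chr = 1000L)
  ann <- genome_annotation(sl, repeats = tibble(
    repeat_id = c("rA", "rB"), seq_id = "chr", start = c(0L, 600L),
    end = c(100L, 700L), family = c("LINE/L1", "LTR/Gypsy")))
  r <- tibble(seq_id = "chr", pos = c(10L, 20L, 650L), strand = "+",
              n_meth = c(0L, 0L, 5L), n_unmeth = c(8L, 12L, 5L),
              context = "CHH", trinucleotide = "CTT")
  s <- build_series(list(r, r), as.Date(c("2015-01-01", "2015-02-01")))
  fs <- feature_series(s, ann, "repeat", context = "CHH")
  expect_equal(fs |> filter(feature_id == "rA") |> pull(level), c(0, 0))
  expect_equal(fs |> filter(feature_id == "rB") |> pull(level), c(0.5, 0.5))
  fm <- family_medians(fs)
  expect_equal(nrow(fm), 4)
  # a feature without sites of the requested context is dropped with a message
  expect_message(
    fs_cg <- feature_series(s, ann, "repeat", context = "CG"),
    "no sites")
  expect_equal(nrow(fs_cg), 0)
})

test_that("median repeat CHH series peaks at the planted season", {
  cfg <- tiny_config(semc_fraction = 0.15, semc_amplitude = 0.5,
                     semc_peak_bias = 1, coverage_mean = 30)
  sim <- simulate_dataset(cfg)
  fs <- suppressMessages(
    feature_series(sim$series, sim$annotation, "repeat", context = "CHH"))
  # restrict to repeats that actually carry planted SeMCs
  semc_rep <- sim$truth$sites |>
    filter(is_semc, context == "CHH") |>
    distinct(seq_id, pos)
  med <- fs |>
    group_by(date) |>
    summarise(level = median(level), .groups = "drop")
  # modal CHH peak is September (bias 1): the September date must be maximal
  sept <- sim$series$dates[format(sim$series$dates, "%m") == "09"]
  expect_equal(med$date[which.max(med$level)], sept)
})
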