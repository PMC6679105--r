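# Gene-body methylation, seasonal summaries, quintile bins, rank tests.

test_that("gene-body methylation pools per gene and recovers planted levels", {
  sim <- tiny_sim()
  gbm <- suppressMessages(gene_body_methylation(sim$series, sim$annotation))
  d <- inner_join(gbm, sim$truth$genes[, c("gene_id", "gbm")],
                  by = "gene_id", suffix = c("_est", "_true"))
  expect_equal(nrow(d), nrow(sim$annotation$genes))
  # every estimate close to its planted value (binomial SE on pooled calls);
  # the gene carrying the planted methylated intronic repeat deviates by
  # design and is excluded
  d <- d |> filter(gene_id != sim$flc_like$gene_id)
  calls <- d$n_sites * length(sim$series$dates) * 20
  se <- sqrt(d$gbm_true * (1 - d$gbm_true) / calls)
  expect_true(all(abs(d$gbm_est - d$gbm_true) < 4 * se))
  # a fully methylated gene gives gbm exactly 1
  ser <- subset_series(sim$series, contexts = "CG")
  ser$meth <- ser$total
  gbm1 <- suppressMessages(gene_body_methylation(ser, sim$annotation))
  expect_true(all(gbm1$gbm == 1))
})

test_that("genes without CG coverage are excluded with a message", {
  sl <- c(chr = 2000L)
  ann <- genome_annotation(sl, genes = tibble(
    gene_id = c("gA", "gB"), seq_id = "chr", start = c(0L, 1000L),
    end = c(500L, 1500L), strand = "+"))
  r <- tibble(seq_id = "chr", pos = c(10L, 1100L), strand = "+",
              n_meth = c(3L, 0L), n_unmeth = c(7L, 0L), context = "CG",
              trinucleotide = "CGA")
  s <- build_series(list(r, r), as.Date(c("2015-01-01", "2015-02-01")))
  expect_message(gbm <- gene_body_methylation(s, ann), "no CG coverage")
  expect_equal(gbm$gene_id, "gA")
  expect_equal(gbm$gbm, 0.3)
  # per-date output exposes the seasonal stability of gbM
  pd <- suppressMessages(gene_body_methylation(s, ann, per_date = TRUE))
  expect_equal(pd |> filter(gene_id == "gA") |> pull(level), c(0.3, 0.3))
})

test_that("seasonal summary computes smoothed range and raw average", {
  d5 <- tibble(gene_id = "g", date = as.Date("2015-01-01") + 0:4 * 30,
               expr = c(0, 0, 6, 0, 0))
  ss <- seasonal_summary(d5, smooth_window = 3)
  expect_equal(ss$average, 1.2)
  expect_equal(ss$range, 2) # smoothed series 0, 2, 2, 2, 0
  # window 1: raw max - min
  two <- tibble(gene_id = "g", date = as.Date("2015-01-01") + 0:1,
                expr = c(1, 5))
  expect_equal(seasonal_summary(two, smooth_window = 1)$range, 4)
  # constant series
  cst <- tibble(gene_id = "g", date = as.Date("2015-01-01") + 0:7,
                expr = 3.3)
  ss2 <- seasonal_summary(cst)
  expect_equal(ss2$average, 3.3)
  expect_equal(ss2$range, 0)
  expect_error(seasonal_summary(mutate(cst, expr = -1)), ">= 0")
  expect_error(seasonal_summary(cst, smooth_window = 2), "odd")
})

test_that("quintile bins partition expressed genes with ties going low", {
  gbm <- tibble(gene_id = paste0("g", 1:10), gbm = (1:10) / 10,
                n_sites = 10L)
  ss <- tibble(gene_id = paste0("g", 1:10), average = 2, range = 1,
               n_dates = 8L)
  bins <- quintile_bins(gbm, ss)
  expect_equal(as.integer(table(bins$bin)), rep(2L, 5))
  expect_equal(bins$bin[order(bins$gbm)], rep(1:5, each = 2))
  # every expressed gene in exactly one bin
  expect_setequal(bins$gene_id, gbm$gene_id)
  # below-threshold average is excluded
  ss2 <- ss |> mutate(average = ifelse(gene_id == "g1", 0.9, average))
  expect_false("g1" %in% quintile_bins(gbm, ss2)$gene_id)
  # degenerate gbM
  expect_error(quintile_bins(mutate(gbm, gbm = 0.5), ss), "identical")
  expect_error(quintile_bins(gbm[1:3, ], ss), "fewer than 5")
})

test_that("rank-sum p-values match exhaustive enumeration for small groups", {
  # the smallest possible two-sided p at n = 3 vs 3 is 0.1
  d <- tibble(bin = rep(c(1, 2), each = 3), value = c(1, 2, 3, 10, 11, 12))
  gt <- groupwise_tests(d, value = "value", group = "bin")
  expect_equal(gt$pairs$p, 0.1)
  expect_false(gt$pairs$significant)
  expect_equal(unique(gt$letters$letters), "a")
  # random tie-free samples against the enumeration oracle
  set.seed(12)
  for (i in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq(0, 1, by = 0.001), nx)
    y <- sample(seq(2, 3, by = 0.001), ny) - sample(c(0, 2.5), 1)
    p_pkg <- groupwise_tests(
      tibble(bin = rep(1:2, c(nx, ny)), value = c(x, y)),
      value = "value", group = "bin")$pairs$p
    expect_equal(p_pkg, mw_oracle(x, y), tolerance = 1e-12)
  }
  # identical samples: p = 1, shared letter
  d2 <- tibble(bin = rep(c(1, 2), each = 4), value = rep(2, 8))
  gt2 <- groupwise_tests(d2, value = "value", group = "bin")
  expect_equal(gt2$pairs$p_adj, 1)
  expect_equal(length(unique(gt2$letters$letters)), 1)
})

test_that("clearly shifted bins earn distinct letters", {
  set.seed(5)
  d <- tibble(bin = rep(1:5, each = 200),
              value = rnorm(1000, mean = rep(c(5, 4, 3, 2, 1), each = 200),
                            sd = 0.8))
  gt <- groupwise_tests(d, value = "value", group = "bin")
  expect_gte(length(unique(gt$letters$letters)), 2)
  # monotone shift: bins 1 and 5 must not share a letter
  l <- setNames(gt$letters$letters, gt$letters$group)
  shared <- intersect(strsplit(l[["1"]], "")[[1]], strsplit(l[["5"]], "")[[1]])
  expect_equal(length(shared), 0)
})

test_that("association analysis summarises bins and the gbM-range trend", {
  sim <- tiny_sim()
  gbm <- suppressMessages(gene_body_methylation(sim$series, sim$annotation))
  ss <- seasonal_summary(sim$expression)
  bins <- quintile_bins(gbm, ss)
  assoc <- association_analysis(bins)
  expect_equal(nrow(assoc$bin_summary), length(unique(bins$bin)))
  expect_lt(assoc$spearman$estimate, 0) # coupling 0.7 by default
  # single populated bin: trend reported as undefined
  one <- bins |> mutate(bin = 1)
  a1 <- association_analysis(one)
  expect_true(is.na(a1$spearman$estimate))
  expect_match(a1$spearman$note, "undefined")
})

test_that("feature association pairs series and flags degenerate input", {
  dates <- as.Date("2015-01-01") + 0:5 * 30
  meth <- tibble(date = dates, level = seq(0.1, 0.6, by = 0.1))
  expr <- tibble(date = dates, expr = 1 - meth$level)
  fa <- feature_association(meth, expr)
  expect_equal(fa$r, -1)
  expect_equal(nrow(fa$table), 6)
  flat <- mutate(meth, level = 0.3)
  fa2 <- feature_association(flat, expr)
  expect_true(fa2$flag_constant)
  expect_true(is.na(fa2$r))
  expect_error(feature_association(meth[1:2, ], expr[1:2, ]), "at least 3")
  expect_error(feature_association(meth, mutate(expr, date = date + 1)),
               "same dates")
})

test_that("the planted intronic repeat runs in anti-phase to its gene", {
  sim <- tiny_sim()
  expect_false(is.null(sim$flc_like))
  fs <- suppressMessages(
    feature_series(sim$series, sim$annotation, "repeat", context = "CHH",
                   family = "SINE/tRNA"))
  f <- fs |> filter(feature_id == sim$flc_like$repeat_id) |>
    select(date, level)
  e <- sim$expression |> filter(gene_id == sim$flc_like$gene_id) |>
    select(date, expr)
  fa <- feature_association(f, e)
  expect_lt(fa$r, 0)
})
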