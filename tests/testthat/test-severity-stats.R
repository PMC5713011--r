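test_that("conditional histograms decompose the marginal exactly", {
  set.seed(23)
  fs <- 10
  # single-level map: conditional equals marginal, prior 1
  a <- rexp(500, 2)
  m1 <- map_from_levels(rep(1, 500), fs)
  ch1 <- conditional_histograms(a, m1, fs)
  expect_equal(unname(ch1$priors), 1)
  expect_equal(unname(ch1$counts_by_level[1, ]), unname(marginal_histogram(ch1)))

  # two levels, 25% / 75% of the duration
  lev <- c(rep(0, 125), rep(2, 375))
  m2 <- map_from_levels(lev, fs)
  ch2 <- conditional_histograms(a, m2, fs)
  expect_equal(unname(ch2$priors), c(0.25, 0.75))

  # level-3 segments carrying 10x amplitude concentrate in the top bins
  amp <- c(rexp(300, 5), 10 * rexp(200, 5) + 1)
  m3 <- map_from_levels(c(rep(0, 300), rep(3, 200)), fs)
  ch3 <- conditional_histograms(amp, m3, fs)
  med0 <- median(amp[1:300])
  top <- ch3$bin_edges[-length(ch3$bin_edges)] >= med0
  expect_gt(sum(ch3$counts_by_level["level3", top]) /
            sum(ch3$counts_by_level["level3", ]), 0.9)
})

test_that("mixture identity holds for arbitrary maps (property)", {
  set.seed(29)
  fs <- 4
  for (i in 1:8) {
    n <- 400
    a <- abs(rnorm(n, sd = runif(1, 0.2, 2)))
    lev <- sample(0:4, n, replace = TRUE)
    m <- map_from_levels(lev, fs)
    edges <- seq(0, max(a) + 0.1, length.out = sample(10:40, 1))
    ch <- conditional_histograms(a, m, fs, bin_edges = edges)
    pooled <- hist(a, breaks = edges, plot = FALSE, right = FALSE)$counts / fs
    expect_equal(unname(marginal_histogram(ch)), pooled)
    expect_equal(sum(ch$priors), 1, tolerance = 1e-12)
    # counts are durations: total mass = n / fs seconds
    expect_equal(sum(ch$counts_by_level), n / fs, tolerance = 1e-9)
  }
})

test_that("duration summaries reproduce per-level percentages", {
  # single-level map -> 100%
  m <- map_from_levels(rep(2, 100), fs = 1)
  ds <- duration_summary(m)
  expect_equal(ds$percent, 100)

  # percentages recompute totals within 1 s per 1e5 s
  set.seed(3)
  durs <- runif(5, 1e3, 5e4)
  names(durs) <- 0:4
  ds2 <- duration_summary(durs)
  expect_equal(sum(ds2$percent), 100, tolerance = 1e-9)
  expect_equal(sum(durs) * ds2$percent / 100, unname(durs),
               tolerance = 1 / 1e5)
})

test_that("Cohen's kappa matches hand-computed and degenerate cases", {
  # 2x2 [[2,1],[1,2]]: Po = 2/3, Pe = 1/2, kappa = 1/3
  expect_equal(cohens_kappa(matrix(c(2, 1, 1, 2), 2)), 1 / 3)
  # perfect agreement
  expect_equal(cohens_kappa(diag(c(5, 2, 9))), 1)
  # independence-structured matrix -> kappa 0
  r <- c(4, 3, 2); c2 <- c(5, 1, 3)
  expect_equal(cohens_kappa(outer(r, c2)), 0, tolerance = 1e-12)
  # degenerate margins
  expect_error(cohens_kappa(matrix(c(3, 0, 0, 0), 2)), "undefined")
})

test_that("kappa is invariant to scaling and joint permutation (property)", {
  set.seed(37)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    m <- matrix(rexp(k * k), k) + diag(k) * 3
    base <- cohens_kappa(m)
    expect_equal(cohens_kappa(m * runif(1, 0.1, 50)), base, tolerance = 1e-12)
    p <- sample(k)
    expect_equal(cohens_kappa(m[p, p]), base, tolerance = 1e-12)
    expect_gte(base, -1)
    expect_lte(base, 1)
  }
})

test_that("class merging pools rows and columns of the partition", {
  m <- load_interobserver_matrix()
  merged <- merge_classes(m, list(1:2, 3, 4, 5))
  expect_equal(nrow(merged), 4)
  expect_equal(rownames(merged)[1], "Free-Low")
  expect_equal(merged["Free-Low", "Free-Low"], 3.67 + 1.86 + 0.30 + 20.46)
  expect_equal(sum(merged), sum(m))
  # identity partition leaves the matrix unchanged
  ident <- merge_classes(m, as.list(1:5))
  expect_equal(unclass(ident), unclass(m), ignore_attr = TRUE)
  # merging everything is rejected
  expect_error(merge_classes(m, list(1:5)), "single class")
  expect_error(merge_classes(m, list(1:2, 2:5)), "partition")
})

test_that("confusion matrix CSV round-trips", {
  m <- load_interobserver_matrix()
  p <- withr::local_tempfile(fileext = ".csv")
  write_confusion_matrix(m, p)
  back <- read_confusion_matrix(p)
  expect_equal(unclass(back), unclass(m))
})
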