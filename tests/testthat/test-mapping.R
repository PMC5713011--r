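test_that("run-length encoding of level series", {
  m <- map_from_levels(c(0, 0, 1, 1, 0), fs = 1)
  expect_equal(m$start_s, c(0, 2, 4))
  expect_equal(m$end_s, c(2, 4, 5))
  expect_equal(m$level, c(0, 1, 0))

  mc <- map_from_levels(rep(2, 100), fs = 10)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$end_s - mc$start_s, 10)

  ma <- map_from_levels(rep(c(0, 1), 3), fs = 1)
  expect_equal(nrow(ma), 6)
})

test_that("map_from_levels then expand_to_levels is identity (property)", {
  set.seed(13)
  for (i in 1:10) {
    lev <- sample(0:4, 200, replace = TRUE, prob = c(4, 3, 2, 1, 1))
    fs <- sample(c(1, 128, 200), 1)
    m <- map_from_levels(lev, fs)
    expect_equal(expand_to_levels(m, fs), lev)
  }
})

test_that("maps from tracks merge same-label neighbours and keep gaps", {
  trk <- label_track(c(0, 10), c(10, 20), c(1, 1))
  m <- map_from_track(trk)
  expect_equal(nrow(m), 1)
  expect_equal(m$end_s, 20)

  trk2 <- label_track(c(0, 20), c(10, 30), c(1, 2))
  m2 <- map_from_track(trk2)
  expect_equal(nrow(m2), 2)
  expect_equal(unname(attr(m2, "gaps")[1, ]), c(10, 20))

  empty <- label_track(numeric(0), numeric(0), integer(0))
  expect_equal(nrow(map_from_track(empty)), 0)
})

test_that("noise bars split, normalize and blank correctly", {
  # one 30 s bar, half level 0 / half level 2
  m <- noise_map(c(0, 15), c(15, 30), c(0, 2))
  b <- build_noise_bars(m, 30)
  expect_equal(nrow(b), 1)
  expect_equal(b$frac_level0, 0.5)
  expect_equal(b$frac_level2, 0.5)
  expect_false(b$is_blank)

  # a 30 s segment spanning two bars: 20/30 then 10/30 of fully labeled bars
  m2 <- noise_map(c(0, 10, 40), c(10, 40, 60), c(0, 3, 0))
  b2 <- build_noise_bars(m2, 30)
  expect_equal(b2$frac_level3, c(20 / 30, 10 / 30))

  # a bar wholly inside a gap is blank
  trk <- label_track(c(0, 70), c(30, 100), c(1, 2))
  b3 <- build_noise_bars(map_from_track(trk), 30)
  expect_equal(b3$is_blank, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(b3[2, paste0("frac_level", 0:4)])))
})

test_that("noise bars conserve per-level durations (property)", {
  set.seed(17)
  for (i in 1:10) {
    lev <- sample(0:4, 500, replace = TRUE)
    fs <- 2
    m <- map_from_levels(lev, fs)
    bar_s <- sample(c(7, 30, 60), 1)
    b <- build_noise_bars(m, bar_s)
    for (l in 0:4) {
      from_bars <- sum(b[[paste0("frac_level", l)]] * b$labeled_s, na.rm = TRUE)
      in_map <- sum((m$end_s - m$start_s)[m$level == l])
      expect_equal(from_bars, in_map, tolerance = 1e-9)
    }
    # non-blank fractions sum to 1
    fr <- as.matrix(b[!b$is_blank, paste0("frac_level", 0:4)])
    expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-9)
  }
})

test_that("bars are equivariant under t0 shifts by whole bars", {
  lev <- sample(0:3, 300, replace = TRUE)
  m0 <- map_from_levels(lev, fs = 2, t0 = 0)
  m1 <- map_from_levels(lev, fs = 2, t0 = 90)  # 3 bars of 30 s
  b0 <- build_noise_bars(m0, 30)
  b1 <- build_noise_bars(m1, 30)
  expect_equal(b1$bar_start_s, b0$bar_start_s + 90)
  expect_equal(b1[paste0("frac_level", 0:4)], b0[paste0("frac_level", 0:4)])
})

test_that("noise-bar CSV round-trips", {
  m <- map_from_levels(sample(0:4, 200, replace = TRUE), fs = 2)
  b <- build_noise_bars(m, 30)
  p <- withr::local_tempfile(fileext = ".csv")
  write_noise_bars(b, p)
  back <- read_noise_bars(p)
  expect_equal(attr(back, "bar_s"), 30)
  expect_equal(back$frac_level2, b$frac_level2, tolerance = 1e-9)
  expect_equal(back$is_blank, b$is_blank)
})

test_that("figure rendering produces image files", {
  m <- map_from_levels(c(rep(0, 30), rep(2, 20), rep(3, 10), rep(1, 15)), fs = 1)
  p1 <- withr::local_tempfile(fileext = ".png")
  render_figure(m, p1)
  expect_gt(file.size(p1), 0)
  b <- build_noise_bars(m, 15)
  p2 <- withr::local_tempfile(fileext = ".png")
  render_figure(b, p2)
  expect_gt(file.size(p2), 0)
})
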