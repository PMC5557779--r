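test_that("snp_index matches the hand-evaluated definitions", {
  sites <- make_sites(
    site_md(100, 30, 15, 0, 40),   # (2/3, 0, 2/3)
    site_md(200, 12, 12, 7, 7),    # equal depths -> (0.5, 0.5, 0)
    site_md(300, 0, 0, 5, 5))      # dominant bulk empty -> undefined
  idx <- snp_index(sites)
  expect_equal(idx$snp_index_dom, c(2 / 3, 0.5, NA), tolerance = 1e-12)
  expect_equal(idx$snp_index_rec, c(0, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(idx$delta, c(2 / 3, 0, NA), tolerance = 1e-12)

  bad <- sites
  bad$p1_allele[1] <- "N"
  expect_error(snp_index(bad), "A,C,G,T")
})

test_that("euclidean_distance uses within-bulk base frequencies", {
  sites <- make_sites(
    # dom A=40,T=20; rec T=50 -> ed = sqrt((2/3)^2 + (1/3 - 1)^2)
    site_md(100, 40, 20, 0, 50),
    site_md(200, 30, 30, 10, 10),  # identical frequency vectors
    # dom all A, rec all T -> maximum sqrt(2)
    site_md(300, 60, 0, 0, 45))
  ed <- euclidean_distance(sites)
  expect_equal(ed$ed, c(0.942809, 0, sqrt(2)), tolerance = 1e-6)
  expect_equal(ed$ed5, c(0.744936, 0, sqrt(2)^5), tolerance = 1e-6)
  expect_equal(ed$ed, ed$ed5^(1 / 5), tolerance = 1e-9)

  # zero-depth bulk -> undefined, never 0
  zero <- make_sites(site_md(100, 0, 0, 5, 5))
  expect_true(is.na(euclidean_distance(zero)$ed))
  # raw-depth mode keeps the unnormalized contrast
  expect_equal(euclidean_distance(zero, "depth")$ed, sqrt(50))
})

test_that("ed is bulk-symmetric, delta antisymmetric, ed bounded", {
  sites <- random_sites(60, seed = 11)
  swapped <- sites
  for (b in c("A", "C", "G", "T")) {
    swapped[[paste0("dom_", b)]] <- sites[[paste0("rec_", b)]]
    swapped[[paste0("rec_", b)]] <- sites[[paste0("dom_", b)]]
  }
  expect_equal(euclidean_distance(swapped)$ed, euclidean_distance(sites)$ed,
               tolerance = 1e-12)
  expect_equal(snp_index(swapped)$delta, -snp_index(sites)$delta,
               tolerance = 1e-12)
  ed <- euclidean_distance(sites)$ed
  expect_true(all(ed <= sqrt(2) + 1e-12))
  expect_true(all(abs(snp_index(sites)$delta) <= 1 + 1e-12))
})

test_that("sliding windows average correctly and respect chromosomes", {
  # hand-calculated means
  w <- sliding_window_mean(c(0, 1, 2, 3, 4), rep("1H", 5),
                           c(10, 20, 30, 40, 50), window_n = 3, step = 1)
  expect_equal(w$stat, c(1, 2, 3))
  expect_equal(w$pos, c(20, 30, 40))  # median position of each window

  # constant input -> every window mean is that constant
  wc <- sliding_window_mean(rep(0.4, 50), rep("1H", 50), 1:50, window_n = 10)
  expect_true(all(wc$stat == 0.4))

  # windows never span chromosomes
  w2 <- sliding_window_mean(rep(1, 400), rep(c("1H", "2H"), each = 200),
                            rep(1:200, 2), window_n = 200)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$chrom, c("1H", "2H"))

  # short chromosome -> one whole-chromosome window
  w3 <- sliding_window_mean(c(1, 2, 5), rep("1H", 3), c(10, 20, 30),
                            window_n = 200)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$stat, mean(c(1, 2, 5)))

  # missing values are excluded from the mean
  w4 <- sliding_window_mean(c(1, NA, 3), rep("1H", 3), c(10, 20, 30),
                            window_n = 3)
  expect_equal(w4$stat, 2)
  expect_equal(w4$n, 2L)
})

test_that("window means stay within the window's member range", {
  set.seed(5)
  v <- rnorm(300)
  w <- sliding_window_mean(v, rep("1H", 300), 1:300, window_n = 40)
  for (k in seq_len(nrow(w))) {
    j <- w$start_index[k]:(w$start_index[k] + 39)
    expect_gte(w$stat[k], min(v[j]))
    expect_lte(w$stat[k], max(v[j]))
  }
})

test_that("loess fit reproduces constants and lines at every span", {
  x <- as.numeric(1:60)
  fit_const <- loess_fit_aicc(x, rep(2.5, 60))
  expect_equal(fit_const$fitted, rep(2.5, 60), tolerance = 1e-10)
  y_lin <- 0.3 + 0.02 * x
  fit_lin <- loess_fit_aicc(x, y_lin)
  expect_equal(fit_lin$fitted, y_lin, tolerance = 1e-8)
  # local linear regression reproduces a line at any individual span
  for (sp in c(0.2, 0.5, 0.9)) {
    f <- loess_fit_aicc(x, y_lin, span_grid = sp)
    expect_equal(f$fitted, y_lin, tolerance = 1e-8)
  }
})

test_that("loess fit agrees with the brute-force WLS oracle", {
  set.seed(19)
  x <- sort(runif(200, 0, 100))
  y <- exp(-((x - 60) / 8)^2) + rnorm(200, sd = 0.1)
  fit <- loess_fit_aicc(x, y)
  expect_equal(fit$fitted, loess_oracle(x, y, fit$span), tolerance = 1e-8)
  # and at fixed spans away from the AICc optimum
  for (sp in c(0.15, 0.4, 0.75)) {
    f <- loess_fit_aicc(x, y, span_grid = sp)
    expect_equal(f$fitted, loess_oracle(x, y, sp), tolerance = 1e-8)
  }
})

test_that("loess AICc selection prefers small spans for sharp signals", {
  set.seed(23)
  x <- as.numeric(1:200)
  y <- exp(-((x - 120) / 5)^2) + rnorm(200, sd = 0.05)
  fit <- loess_fit_aicc(x, y)
  expect_lt(fit$span, 0.3)
  expect_equal(which.min(fit$aicc_grid$aicc),
               match(fit$span, fit$aicc_grid$span))
})

test_that("loess contract errors fire", {
  expect_error(loess_fit_aicc(1:5, rnorm(5)), "at least 10")
  x <- c(1:10, 10)
  expect_error(loess_fit_aicc(x, rnorm(11)), "strictly increasing")
  # spans all too small for a 3-point local window
  expect_error(loess_fit_aicc(as.numeric(1:20), rnorm(20),
                              span_grid = 0.05), "no valid span")
  # missing y values are excluded and carried through as NA
  y <- 0.1 * (1:30)
  y[4] <- NA
  f <- loess_fit_aicc(as.numeric(1:30), y)
  expect_true(is.na(f$fitted[4]))
  expect_equal(sum(is.na(f$fitted)), 1L)
})

test_that("smooth_association excludes unplaced chromosomes", {
  set.seed(3)
  sites <- random_sites(80, seed = 3)
  sites$chrom[1:20] <- "chrUn"
  sites$pos[1:20] <- 1:20 * 500L
  sites <- sites[order(sites$chrom, sites$pos), ]
  class(sites) <- c("snp_sites", "data.frame")
  assoc <- associate(sites)
  sm <- smooth_association(assoc, window_n = 10, span_grid = c(0.5, 0.9))
  un <- sm$assoc$chrom == "chrUn"
  expect_true(all(is.na(sm$assoc$loess_ed5[un])))
  expect_true(all(is.na(sm$assoc$window_delta[un])))
  expect_false("chrUn" %in% sm$delta_windows$chrom)
  # per-SNP statistics are still present for unplaced sites
  expect_true(all(!is.na(sm$assoc$ed[un])))
})
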