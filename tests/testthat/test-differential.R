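norm_track <- function(v, layout) {
  structure(list(norm = list(chrT = v), chip_total = 1, input_total = 1,
                 layout = layout),
            class = "normalized_track")
}

test_that("aggregate_regions is the interval union across conditions", {
  a <- data.frame(chrom = "chrT", start = 0, end = 100)
  b <- data.frame(chrom = "chrT", start = 50, end = 150)
  expect_equal(aggregate_regions(list(a, b))[, c("start", "end")],
               data.frame(start = 0, end = 150))
  expect_equal(aggregate_regions(list(a, a))[, c("start", "end")],
               data.frame(start = 0, end = 100))

  withr::local_seed(71)
  for (i in 1:5) {
    ra <- random_regions(25, 100000)
    rb <- random_regions(25, 100000)
    got <- aggregate_regions(list(ra, rb))
    want <- oracle_union(rbind(ra, rb)[, c("start", "end")])
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("long regions split into equal sub-regions, leftmost get remainder", {
  r <- data.frame(chrom = "chrT", start = 0, end = 120000)
  out <- split_large(r, max_len = 50000)
  expect_equal(nrow(out), 3L)                       # ceiling(120/50)
  expect_equal(out$end - out$start, rep(40000, 3))

  # "greater than 50 kb" is strict: exactly 50 kb is untouched
  r <- data.frame(chrom = "chrT", start = 10, end = 50010)
  expect_equal(split_large(r, 50000), r)

  r <- data.frame(chrom = "chrT", start = 0, end = 50001)
  out <- split_large(r, 50000)
  expect_equal(out$end - out$start, c(25001, 25000))
  expect_equal(out$start, c(0, 25001))
})

test_that("splitting conserves covered length over random inputs", {
  withr::local_seed(73)
  lens <- sample.int(200000, 1000)
  for (L in lens[1:50]) {   # spot-check contiguity on a subset
    out <- split_large(data.frame(chrom = "chrT", start = 100,
                                  end = 100 + L), 50000)
    expect_equal(sum(out$end - out$start), L)
    expect_equal(nrow(out), ceiling(L / 50000))
    expect_true(diff(range(out$end - out$start)) <= 1)
    expect_equal(out$start[-1], out$end[-nrow(out)])
  }
  # vectorized conservation for the full thousand
  tot <- vapply(lens, function(L) {
    out <- split_large(data.frame(chrom = "chrT", start = 0, end = L), 50000)
    sum(out$end - out$start)
  }, numeric(1))
  expect_identical(tot, as.numeric(lens))
})

test_that("region density is mean normalized coverage over the region", {
  layout <- tiny_layout(10000)
  trk <- norm_track(rep(2, 10000), layout)
  r <- data.frame(chrom = "chrT", start = 100, end = 900)
  expect_equal(region_density(r, trk), 2.0)

  withr::local_seed(79)
  v <- runif(10000)
  trk <- norm_track(v, layout)
  regs <- random_regions(20, 10000, max_len = 3000)
  got <- region_density(regs, trk)
  want <- vapply(seq_len(nrow(regs)), function(i) {
    mean(v[(regs$start[i] + 1):regs$end[i]])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # density of a region is the length-weighted mean of its split parts
  big <- data.frame(chrom = "chrT", start = 3, end = 9503)
  parts <- split_large(big, 2000)
  d_parts <- region_density(parts, trk)
  lens <- parts$end - parts$start
  expect_equal(region_density(big, trk), sum(d_parts * lens) / sum(lens),
               tolerance = 1e-12)
})

test_that("replicate densities average arithmetically", {
  expect_equal(average_replicates(c(1, 2)), c(1, 2))
  expect_equal(average_replicates(c(1, 5), c(3, 1)), c(2, 3))
  expect_equal(average_replicates(list(c(1, 5), c(3, 1))), c(2, 3))
  expect_equal(average_replicates(c(1, 5), c(3, 1)),
               average_replicates(c(3, 1), c(1, 5)))
  expect_error(average_replicates(1:3, 1:2), "differ in length")
})

test_that("the density line of fit matches an independent OLS oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  fit <- fit_and_score(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_true(fit$perfect_fit)
  expect_equal(fit$table$z, rep(0, 10))

  fit <- fit_and_score(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  withr::local_seed(83)
  x <- runif(100, 0.5, 3)
  y <- 1.3 * x + rnorm(100, 0, 0.1)
  fit <- fit_and_score(x, y)
  ref <- lm(y ~ x)
  expect_equal(fit$slope, unname(coef(ref)[2]))
  expect_equal(fit$intercept, unname(coef(ref)[1]))
  expect_equal(fit$residual_sd, summary(ref)$sigma)
  ord <- order(-abs(resid(ref)))
  expect_equal(fit$table$residual, unname(resid(ref)[ord]))
  expect_equal(sum(fit$table$residual), 0, tolerance = 1e-10)

  expect_error(fit_and_score(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_and_score(1:2, 1:2), "length")
})

test_that("a planted discordant region attains the extreme Z", {
  for (seed in 1:5) {
    withr::local_seed(100 + seed)
    x <- runif(200, 0.5, 3)
    y <- 1.1 * x + rnorm(200, 0, 0.05)
    # one region loses 10-fold in condition B
    x <- c(x, 2.5)
    y <- c(y, 2.5 * 1.1 / 10)
    regions <- data.frame(chrom = "chrT", start = seq_along(x) * 1000,
                          end = seq_along(x) * 1000 + 500)
    fit <- fit_and_score(x, y, regions = regions)
    top <- fit$table[1L, ]
    expect_equal(top$start, 201 * 1000)   # the planted region ranks first
    expect_gt(abs(top$z), 3)
    flagged <- flag_outliers(fit, 3)
    expect_true(201000 %in% flagged$start)
  }
})

test_that("flag_outliers respects thresholds and perfect fits", {
  x <- as.numeric(1:10)
  fit <- fit_and_score(x, x)
  expect_equal(nrow(flag_outliers(fit, 3)), 0L)
  expect_equal(nrow(flag_outliers(fit, 0)), 10L)   # threshold 0 keeps all
  fit2 <- fit_and_score(x, x + rnorm(10, 0, 0.1))
  expect_equal(nrow(flag_outliers(fit2, 0)), 10L)
})

test_that("outlier identity is stable under swapping the condition roles", {
  for (seed in 1:3) {
    withr::local_seed(200 + seed)
    x <- runif(150, 0.5, 3)
    y <- x + rnorm(150, 0, 0.05)
    x <- c(x, 2); y <- c(y, 0.4)
    fwd <- fit_and_score(x, y)
    rev <- fit_and_score(y, x)
    expect_equal(fwd$table$density_a[1], 2)
    expect_equal(rev$table$density_b[1], 2)
  }
})

test_that("orthogonal and robust scoring options behave sensibly", {
  withr::local_seed(91)
  x <- runif(100, 1, 3)
  y <- x + rnorm(100, 0, 0.05)
  x <- c(x, 2.5); y <- c(y, 0.5)
  vert <- fit_and_score(x, y)
  orth <- fit_and_score(x, y, method = "orthogonal")
  rob <- fit_and_score(x, y, robust = TRUE)
  # all three agree on the planted outlier's identity
  expect_equal(orth$table$density_a[1], 2.5)
  expect_equal(rob$table$density_a[1], 2.5)
  # MAD resists the outlier, so the robust Z is at least as extreme
  expect_gte(abs(rob$table$z[1]), abs(vert$table$z[1]))
  # orthogonal residuals are shorter than vertical ones for slope != 0
  expect_lt(abs(orth$table$residual[1]), abs(vert$table$residual[1]) + 1e-9)
})
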