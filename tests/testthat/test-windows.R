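norm_from_vectors <- function(vectors, layout) {
  structure(list(norm = vectors, chip_total = 1, input_total = 1,
                 layout = layout),
            class = "normalized_track")
}

test_that("window grid and sums follow the w/s contract", {
  layout <- tiny_layout(10000)
  trk <- norm_from_vectors(list(chrT = rep(1, 10000)), layout)
  ws <- window_sums(trk, w = 1000, s = 50)
  expect_equal(nrow(ws), 181)                 # floor((10000-1000)/50) + 1
  expect_equal(ws$start, seq(0, 9000, by = 50))
  expect_equal(ws$sum, rep(1000, 181))

  # chromosome shorter than the window yields zero windows
  short <- norm_from_vectors(list(chrT = rep(1, 999)), tiny_layout(999))
  expect_equal(nrow(window_sums(short, w = 1000, s = 50)), 0L)

  expect_error(window_sums(trk, w = 10, s = 50))  # needs w >= s
})

test_that("window sums equal brute-force per-window re-summation", {
  withr::local_seed(31)
  for (i in 1:5) {
    L <- sample(2000:50000, 1)
    layout <- tiny_layout(L)
    v <- runif(L)
    trk <- norm_from_vectors(list(chrT = v), layout)
    ws <- window_sums(trk, w = 1000, s = 50)
    br <- oracle_window_sums(v, 1000, 50)
    expect_equal(ws$start, br$start)
    expect_equal(ws$sum, br$sum, tolerance = 1e-12)
  }
})

test_that("the randomized-tag null is reproducible and well formed", {
  L <- 20000
  layout <- tiny_layout(L)
  withr::local_seed(41)
  ts <- random_tags(500, L, layout = layout)
  input <- positional_coverage(random_tags(800, L, layout = layout), layout)
  a <- build_null(ts, input, layout, w = 1000, s = 200, rounds = 3, seed = 9)
  b <- build_null(ts, input, layout, w = 1000, s = 200, rounds = 3, seed = 9)
  expect_identical(a$sums, b$sums)
  expect_false(is.unsorted(a$sums))
  expect_equal(length(a$sums), 3 * (floor((L - 1000) / 200) + 1))
  c <- build_null(ts, input, layout, w = 1000, s = 200, rounds = 3, seed = 10)
  expect_false(identical(a$sums, c$sums))
})

test_that("null sums match the analytic expectation on a flat input", {
  # with a flat input of depth d, a window sum under randomization is
  # sum over w positions of ((n(x)+1)/(d+1)) * Ni/N; E n(x) = count*len/L
  L <- 100000
  layout <- tiny_layout(L)
  d <- 5
  input <- track_from_vectors(list(chrT = rep(d, L)), layout)
  withr::local_seed(43)
  n_tag <- 2000
  len <- 200
  start <- sample.int(L - len, n_tag, TRUE) - 1L
  ts <- tag_set(data.frame(chrom = "chrT", start = start, end = start + len),
                layout)
  null <- build_null(ts, input, layout, w = 1000, s = 1000, rounds = 20,
                     seed = 3)
  N <- n_tag * len
  expected <- 1000 * ((n_tag * len / L + 1) / (d + 1)) * (input$total / N)
  se <- sd(null$sums) / sqrt(length(null$sums) / 20)  # rounds share tags
  expect_lt(abs(mean(null$sums) - expected), 3 * max(se, 1e-8))
})

test_that("one-tag null placements fall inside the exhaustive placement set", {
  # one 3 bp tag on a 12 bp chromosome: every placement is enumerable
  L <- 12
  layout <- tiny_layout(L)
  len <- 3
  w <- 4
  s <- 2
  input <- track_from_vectors(list(chrT = rep(1, L)), layout)
  ts <- tags_from(chrom = "chrT", start = 0, end = len, layout = layout)
  exhaustive <- unlist(lapply(0:(L - len), function(st) {
    n <- numeric(L)
    n[(st + 1):(st + len)] <- 1
    nn <- ((n + 1) / (rep(1, L) + 1)) * (sum(rep(1, L)) / len)
    oracle_window_sums(nn, w, s)$sum
  }))
  for (seed in 1:10) {
    null <- build_null(ts, input, layout, w = w, s = s, rounds = 1,
                       seed = seed)
    expect_true(all(vapply(null$sums, function(x) {
      any(abs(exhaustive - x) < 1e-12)
    }, logical(1))))
  }
})

test_that("empirical p-values use the add-one estimator", {
  null <- structure(list(sums = sort(runif(499)), rounds = 1, seed = 1,
                         w = 10, s = 10), class = "null_distribution")
  stats <- data.frame(chrom = "chrT", start = c(0, 10, 20),
                      sum = c(2, null$sums[250], -1))
  all_w <- call_windows(stats, null, alpha = 1)
  # naive recount of the estimator
  p_naive <- vapply(stats$sum, function(x) {
    (1 + sum(null$sums >= x)) / (1 + length(null$sums))
  }, numeric(1))
  expect_equal(all_w$p, p_naive)
  expect_equal(all_w$p[1], 1 / 500)   # exceeds all null sums
  expect_equal(all_w$p[3], 1)         # below all null sums
  expect_equal(nrow(all_w), 3L)       # alpha = 1 keeps everything
  expect_error(call_windows(stats, null, alpha = 0))
})

test_that("significant windows merge into maximal disjoint regions", {
  sig <- data.frame(chrom = "chrT", start = c(0, 50), sum = c(5, 5),
                    p = c(0.001, 0.0005))
  reg <- merge_windows(sig, w = 1000)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0)
  expect_equal(reg$end, 1050)
  expect_equal(reg$min_p, 0.0005)

  sig2 <- data.frame(chrom = "chrT", start = c(0, 10000), sum = c(5, 5),
                     p = c(0.001, 0.001))
  expect_equal(nrow(merge_windows(sig2, w = 1000, max_gap = 0)), 2L)
  expect_equal(nrow(merge_windows(sig2, w = 1000, max_gap = 9000)), 1L)
})

test_that("region cover equals the sweep-line union oracle", {
  withr::local_seed(53)
  for (i in 1:10) {
    starts <- sort(sample(seq(0, 20000, by = 50), 40))
    sig <- data.frame(chrom = "chrT", start = starts, sum = 1, p = 0.001)
    reg <- merge_windows(sig, w = 1000)
    un <- oracle_union(data.frame(start = starts, end = starts + 1000))
    expect_equal(reg$start, un$start)
    expect_equal(reg$end, un$end)
  }
})

test_that("replicate intersection keeps only jointly significant extent", {
  a <- data.frame(chrom = "chrT", start = 0, end = 100)
  b <- data.frame(chrom = "chrT", start = 50, end = 150)
  out <- intersect_replicates(a, b)
  expect_equal(out[, c("start", "end")],
               data.frame(start = 50, end = 100))

  expect_equal(intersect_replicates(a, a)[, c("start", "end")],
               data.frame(start = 0, end = 100))

  disj <- data.frame(chrom = "chrT", start = 500, end = 600)
  expect_equal(nrow(intersect_replicates(a, disj)), 0L)

  withr::local_seed(59)
  ra <- random_regions(30, 50000)
  rb <- random_regions(30, 50000)
  ua <- cbind(chrom = "chrT", oracle_union(ra))
  ub <- cbind(chrom = "chrT", oracle_union(rb))
  got <- intersect_replicates(ua, ub)
  want <- oracle_intersect(ua, ub)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("enriched span is monotone in alpha and order-invariant", {
  L <- 50000
  layout <- tiny_layout(L)
  withr::local_seed(61)
  # plant a hot interval on a background of uniform tags
  bg <- random_tags(600, L, layout = layout)$tags
  hot_start <- sample(20000:25000, 300, replace = TRUE) - 1L
  hot <- data.frame(chrom = "chrT", start = hot_start,
                    end = hot_start + sample(100:300, 300, TRUE))
  ts <- tag_set(rbind(bg, hot), layout)
  input <- positional_coverage(random_tags(1000, L, layout = layout), layout)
  cov <- positional_coverage(ts, layout)
  trk <- normalize_coverage(cov, input)
  stats <- window_sums(trk)
  null <- build_null(ts, input, layout, rounds = 2, seed = 5)
  spans <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 1), function(alpha) {
    reg <- merge_windows(call_windows(stats, null, alpha), w = 1000)
    sum(reg$end - reg$start)
  }, numeric(1))
  expect_true(all(diff(spans) >= 0))

  # shuffling tag input order changes nothing downstream
  perm <- tag_set(ts$tags[sample.int(nrow(ts$tags)), ], layout)
  cov2 <- positional_coverage(perm, layout)
  trk2 <- normalize_coverage(cov2, input)
  sig1 <- call_windows(stats, null, 1e-3)
  sig2 <- call_windows(window_sums(trk2), null, 1e-3)
  expect_equal(merge_windows(sig2, w = 1000), merge_windows(sig1, w = 1000))
})
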