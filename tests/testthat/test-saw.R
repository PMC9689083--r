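test_that("centroid is the per-feature mean, permutation invariant", {
  expect_equal(unname(centroid(data.frame(x = c(1, 3), y = c(2, 4)))), c(2, 3))
  one <- data.frame(x = 7, y = -1)
  expect_equal(unname(centroid(one)), c(7, -1))

  set.seed(21)
  m <- matrix(rnorm(50 * 4), 50, 4)
  expect_equal(unname(centroid(m)), colSums(m) / 50, tolerance = 1e-12)
  expect_equal(centroid(m[sample(50), ]), centroid(m), tolerance = 1e-12)

  expect_error(centroid(matrix(numeric(0), 0, 2)), "empty")
})

test_that("euclidean distance matches brute-force accumulation", {
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(22)
  a <- rnorm(10); b <- rnorm(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (a[i] - b[i])^2
  expect_equal(euclidean(a, b), sqrt(acc), tolerance = 1e-12)
  expect_equal(euclidean(a, b), euclidean(b, a))
  expect_error(euclidean(1:3, 1:4), "arity")
})

test_that("BRS selection filters by age and sorts by distance to the centroid", {
  cfg <- saw_config(ath = 4)
  st <- saw_state(cfg)
  st$features <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4), 4, 2, byrow = TRUE,
                        dimnames = list(NULL, c("x1", "x2")))
  st$arrival_index <- 1:4
  st$pia <- c(0L, 3L, 4L, 5L)   # only the first two are younger than ath = 4

  brs <- select_brs(st, c(0, 0))
  expect_equal(nrow(brs), 2)
  expect_equal(sort(brs$pia), c(0L, 3L))
  expect_equal(brs$arrival_index, 1:2)             # sorted by distance
  expect_true(all(diff(brs$distance) >= 0))

  # empty state
  expect_equal(nrow(select_brs(saw_state(cfg))), 0)

  # cap = top-k by distance, against an exhaustive sort oracle
  set.seed(23)
  st2 <- saw_state(saw_config(ath = 10, brs_cap = 5))
  st2$features <- matrix(rnorm(40), 20, 2,
                         dimnames = list(NULL, c("x1", "x2")))
  st2$arrival_index <- 1:20
  st2$pia <- rep(0L, 20)
  cvec <- c(0.3, -0.2)
  brs2 <- select_brs(st2, cvec)
  all_d <- apply(st2$features, 1, euclidean, b = cvec)
  expect_equal(sort(brs2$arrival_index), sort(order(all_d)[1:5]))
  expect_equal(brs2$distance, sort(all_d)[1:5], tolerance = 1e-12)
})

test_that("age-threshold filtering keeps only young positives", {
  # positives arriving in distinct chunks age by one per carry; with ath = 4
  # only those carried fewer than 4 times remain held
  stream <- make_stream(rep(list(c(1, 0, 0)), 7))
  res <- run_saw(stream, ath = 4)
  held <- res$final_state
  expect_true(all(held$pia < 4))
  # chunk 7's window carries positives from chunks 3..6 only
  w7 <- res$windows[[7]]
  expect_equal(sort(w7$arrival_index[w7$carried]),
               stream$arrival_index[stream$label == 1 & stream$tick %in% 3:6])
})

test_that("saw_step handles its four cases and the toy 6-to-7 example", {
  # case 1: all-negative chunk, empty state -> unchanged
  s <- make_stream(list(rep(0, 5)))
  step <- saw_step(saw_state(saw_config(4)), s)
  expect_equal(nrow(step$window), 5)
  expect_equal(step$trace$n_carried, 0L)
  expect_equal(length(step$state$pia), 0L)

  # case 2: state empty, chunk has positives -> window unchanged, state fed
  s2 <- make_stream(list(c(1, 0, 1, 0)))
  step2 <- saw_step(saw_state(saw_config(4)), s2)
  expect_equal(nrow(step2$window), 4)
  expect_equal(step2$state$pia, c(0L, 0L))

  # case 3: chunk all-negative, state non-empty -> all held carried
  s3 <- make_stream(list(c(1, 0), rep(0, 4)))
  st <- saw_state(saw_config(4))
  st <- saw_step(st, s3[s3$tick == 1, ])$state
  step3 <- saw_step(st, s3[s3$tick == 2, ])
  expect_equal(step3$trace$n_carried, 1L)
  expect_equal(nrow(step3$window), 5)

  # case 4 via the deterministic toy chunks: window grows from 6 to 7
  toy <- saw_toy_chunks()
  res <- run_saw(toy$chunks, ath = toy$ath)
  expect_equal(res$trace$window_size, c(6L, 7L))
  expect_equal(res$trace$n_carried, c(0L, 1L))
  w2 <- res$windows[[2]]
  expect_equal(w2$arrival_index[w2$carried], 2L)  # the chunk-1 positive
  expect_equal(w2$pia[w2$carried], 1L)            # aged once at carry
  expect_identical(run_saw(toy$chunks, ath = toy$ath)$trace, res$trace)

  # tick regression errors
  expect_error(saw_step(step2$state, s2), "tick regression")
})

test_that("negatives are conserved and positives live exactly ath+1 windows", {
  set.seed(24)
  stream <- generate_stream(stream_spec(n_chunks = 12, chunk_size = 80,
                                        positive_rate = 0.08, n_features = 3,
                                        seed = 24))
  ath <- 3
  res <- run_saw(stream, ath = ath)
  for (t in seq_along(res$windows)) {
    w <- res$windows[[t]]
    chunk <- stream[stream$tick == t, ]
    # conservation: window negatives are exactly the chunk's negatives
    expect_equal(sort(w$arrival_index[w$label == 0]),
                 chunk$arrival_index[chunk$label == 0])
    # natives appear exactly once
    expect_equal(sum(w$arrival_index %in% chunk$arrival_index &
                       !isTRUE_vec_test(w$carried)), nrow(chunk))
    # carried instances are all positives
    expect_true(all(w$label[isTRUE_vec_test(w$carried)] == 1L))
  }
  # lifetime: each positive appears in windows T .. T+ath and no others
  appearances <- lapply(res$windows, function(w) w$arrival_index)
  for (i in which(stream$label == 1L)) {
    ai <- stream$arrival_index[i]
    t0 <- stream$tick[i]
    in_w <- which(vapply(appearances, function(a) ai %in% a, logical(1)))
    expect_equal(in_w, seq(t0, min(t0 + ath, 12)))
  }
  # PIA bound inside the final state
  expect_true(all(res$final_state$pia < ath))
})

test_that("carried counts equal the lifetime counting oracle", {
  stream <- generate_stream(stream_spec(n_chunks = 30, chunk_size = 100,
                                        positive_rate = 0.05, n_features = 2,
                                        seed = 25))
  for (ath in c(1, 3, 6)) {
    res <- run_saw(stream, ath = ath)
    expect_equal(res$trace$n_carried, oracle_carried_counts(stream, ath),
                 ignore_attr = TRUE)
  }
})

test_that("mean window presence is monotone in the age threshold", {
  stream <- generate_stream(stream_spec(n_chunks = 25, chunk_size = 200,
                                        positive_rate = 0.02, n_features = 2,
                                        seed = 26))
  presences <- vapply(c(1, 2, 4, 8, 12), function(ath) {
    mean(run_saw(stream, ath = ath)$trace$positive_fraction)
  }, numeric(1))
  expect_true(all(diff(presences) >= 0))
})

test_that("steady-state presence matches the closed form under iid labels", {
  # small but converged configuration: p = 0.02, ath = 8
  p <- 0.02; ath <- 8
  stream <- generate_stream(stream_spec(n_chunks = 60, chunk_size = 400,
                                        positive_rate = p, n_features = 2,
                                        seed = 27))
  res <- run_saw(stream, ath = ath)
  late <- res$trace$positive_fraction[31:60]
  expect_lt(abs(mean(late) - p * (ath + 1) / (1 + p * ath)), 0.01)
})

test_that("distance standardization changes ranking but not membership", {
  stream <- make_stream(list(c(1, 1, 0, 0), c(1, 0, 0, 0)), n_features = 3)
  raw <- run_saw(stream, ath = 4)
  std <- run_saw(stream, ath = 4, standardize_distances = TRUE)
  expect_equal(sort(raw$windows[[2]]$arrival_index),
               sort(std$windows[[2]]$arrival_index))
})
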