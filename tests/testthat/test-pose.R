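test_that("confidence filtering keeps the boundary value and preserves order", {
  d <- detections(0, c("snout", "snout", "snout"), 1:3, 1:3,
                  c(0.59, 0.60, 0.61))
  kept <- filter_detections(d, match_config())
  expect_equal(kept$confidence, c(0.60, 0.61))
  empty <- detections(integer(0), character(0), numeric(0), numeric(0),
                      numeric(0))
  expect_equal(nrow(filter_detections(empty)), 0)
  # survivor count equals a brute-force scan on random confidence vectors
  set.seed(2)
  for (i in 1:20) {
    conf <- runif(30)
    d <- detections(0, rep("tail", 30), 1:30, 1:30, conf)
    expect_equal(nrow(filter_detections(d)), sum(conf >= 0.6))
  }
})

test_that("line pixel counts follow Bresenham with inclusive endpoints", {
  img0 <- matrix(0, 20, 20)
  expect_equal(line_pixel_count(img0, c(0, 0), c(10, 10), 1), 0)
  img255 <- matrix(255, 20, 20)
  expect_equal(line_pixel_count(img255, c(2, 5), c(12, 5), 100), 11)
  # count never exceeds the raster segment length
  set.seed(3)
  for (i in 1:20) {
    p1 <- sample(0:19, 2); p2 <- sample(0:19, 2)
    cnt <- line_pixel_count(img255, p1, p2, 1)
    expect_lte(cnt, max(abs(p2 - p1)) + 1)
    expect_equal(cnt, max(abs(p2 - p1)) + 1)  # all pixels bright
  }
  expect_error(line_pixel_count(img0, c(0, 0), c(25, 0), 1), "outside")
})

test_that("matching scores implement inverse distance with veto and cap", {
  cfg <- match_config()
  s <- list(part = "snout", x = 0, y = 0)
  t <- list(part = "tail", x = 3, y = 4)
  expect_equal(matching_score(s, t, NULL, cfg), 0.2)
  # blocked line: bright floor between the parts vetoes the pair
  img <- matrix(255, 30, 30)
  expect_equal(matching_score(s, t, img, cfg), 0)
  # dark line: no veto
  dark <- matrix(0, 30, 30)
  expect_equal(matching_score(s, t, dark, cfg), 0.2)
  # coincident points take the finite cap
  t0 <- list(part = "tail", x = 0, y = 0)
  expect_equal(matching_score(s, t0, NULL, cfg), cfg$zero_distance_cap)
  expect_error(matching_score(t, s), "snout and a tail")
})

test_that("pose vectors are unit length tail-to-snout", {
  sn <- detections(0, rep("snout", 2), c(10, 0), c(0, 5), c(1, 1))
  tl <- detections(0, rep("tail", 2), c(0, 0), c(0, 0), c(1, 1))
  m <- solve_matching(score_matrix(sn, tl))
  pv <- pose_vectors(m, sn, tl)
  i1 <- which(pv$tx == 10)
  expect_equal(c(pv$vx[i1], pv$vy[i1]), c(1, 0))
  i2 <- which(pv$ty == 5)
  expect_equal(c(pv$vx[i2], pv$vy[i2]), c(0, 1))
  set.seed(4)
  for (i in 1:25) {
    sn <- detections(0, "snout", runif(1, 1, 100), runif(1, 1, 100), 1)
    tl <- detections(0, "tail", runif(1, 1, 100), runif(1, 1, 100), 1)
    pv <- pose_vectors(solve_matching(score_matrix(sn, tl)), sn, tl)
    expect_equal(pv$vx^2 + pv$vy^2, 1)
  }
})

test_that("antenna choice reduces to the maximal dot product with tie to lowest index", {
  ant <- antenna_set()
  expect_equal(antenna_for_mouse(c(1, 0), ant)$index, 1L)
  expect_equal(antenna_for_mouse(c(0, 1), ant)$index, 3L)
  # diagonal pose ties +x with +y; lowest index wins
  expect_equal(antenna_for_mouse(c(1, 1) / sqrt(2), ant)$index, 1L)
  expect_true(is.na(antenna_for_mouse(c(NA, NA), ant)$index))
})

test_that("argmax-dot agrees with the numeric elevation-expectation oracle", {
  ant <- antenna_set()
  set.seed(5)
  z <- runif(2e4, 0, pi / 2)
  for (i in 1:25) {
    th <- runif(1, -pi, pi)
    v <- c(cos(th), sin(th))
    ed <- vapply(seq_len(4), function(a)
      expected_antenna_distance(v, ant[a, ], z), numeric(1))
    expect_equal(antenna_for_mouse(v, ant)$index, which.min(ed))
  }
})

test_that("majority vote resolves strict majorities, singletons and ties", {
  expect_equal(majority_vote(c(1, 1, 2, 3, 1))$winner, 1)
  expect_equal(majority_vote(4)$winner, 4)
  # tie 1-1 vs 2-2 with summed alignments 1.8 vs 1.9 goes to antenna 2
  v <- majority_vote(c(1, 1, 2, 2), alignments = c(0.9, 0.9, 0.95, 0.95))
  expect_equal(v$winner, 2)
  # equal alignments: lowest index
  v2 <- majority_vote(c(2, 2, 3, 3), alignments = rep(0.5, 4))
  expect_equal(v2$winner, 2)
  # all abstain: previous held
  h <- majority_vote(c(NA, NA), previous = 3L)
  expect_equal(h$winner, 3L)
  expect_true(h$held)
})

test_that("frame processing is deterministic and permutation invariant", {
  sc <- generate_scene(4, noise = no_noise(), seed = 9)
  r1 <- process_frame(sc$detections, sc$image)
  set.seed(99)
  shuffled <- sc$detections[sample(nrow(sc$detections)), ]
  r2 <- process_frame(shuffled, sc$image)
  expect_equal(r1$winner, r2$winner)
  expect_equal(r1$per_mouse, r2$per_mouse)
  # empty frame holds the previous antenna
  empty <- detections(integer(0), character(0), numeric(0), numeric(0),
                      numeric(0))
  held <- process_frame(empty, previous = 2L)
  expect_equal(held$winner, 2L)
  expect_true(held$held)
})

test_that("zero-noise scenes recover the ground-truth pairing and winner", {
  for (seed in c(3, 8, 15)) {
    sc <- generate_scene(5, noise = no_noise(), seed = seed)
    res <- process_frame(sc$detections, sc$image)
    expect_equal(res$winner, sc$truth$winner)
    expect_equal(sort(res$per_mouse$antenna), sort(sc$truth$antenna))
  }
})

test_that("activation runs and reactivation gaps partition the sequence", {
  rl <- activation_run_lengths(c(1, 1, 2, 2, 1))
  expect_equal(rl[["1"]], c(2L, 1L))
  expect_equal(rl[["2"]], 2L)
  expect_equal(activation_run_lengths(c(1, 1, 1))[["1"]], 3L)
  ri <- reactivation_intervals(c(1, 1, 2, 2, 1))
  expect_equal(ri[["1"]], 2L)
  expect_equal(ri[["2"]], integer(0))
  expect_equal(reactivation_intervals(c(4, 4, 4))[["4"]], integer(0))
  # runs sum to sequence length; runs + gaps tile first-to-last activation
  set.seed(6)
  w <- sample(1:4, 200, replace = TRUE)
  rl <- activation_run_lengths(w)
  expect_equal(sum(unlist(rl)), 200L)
  ri <- reactivation_intervals(w)
  for (a in names(rl)) {
    span <- max(which(w == as.integer(a))) - min(which(w == as.integer(a))) + 1
    expect_equal(sum(rl[[a]]) + sum(ri[[a]]), span)
  }
})

test_that("selection accuracy is the percentage of matching frames", {
  expect_equal(selection_accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(selection_accuracy(c(rep(1, 19), 2), rep(1, 20)), 95)
  expect_error(selection_accuracy(1:3, 1:4), "length")
  expect_error(selection_accuracy(integer(0), integer(0)), "undefined")
})

test_that("a five-mouse frame processes well inside the 40 ms real-time budget", {
  sc <- generate_scene(5, noise = noise_model(), seed = 21)
  elapsed <- system.time(for (i in 1:10) process_frame(sc$detections))[["elapsed"]]
  expect_lt(elapsed / 10, 0.04)
})
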