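# Ground-truthed synthetic cage scenes and keypoint streams, standing in
# for the trained detector and the video feed.

#' Detector noise model for synthetic keypoints
#'
#' @param jitter_sd Gaussian keypoint jitter (px)
#' @param miss_prob probability that a true body part goes undetected
#' @param spurious_rate expected number of spurious detections per frame
#'   (Poisson)
#' @param conf_true,conf_spurious Beta shape pairs for the confidence of
#'   true and spurious detections; defaults have means 0.9 and 0.4 so the
#'   0.6 confidence filter is exercised from both sides
#' @return a `noise_model`
#' @export
noise_model <- function(jitter_sd = 3, miss_prob = 0.05, spurious_rate = 0.02,
                        conf_true = c(9, 1), conf_spurious = c(2, 3)) {
  stopifnot(jitter_sd >= 0, miss_prob >= 0, miss_prob <= 1, spurious_rate >= 0)
  structure(list(jitter_sd = jitter_sd, miss_prob = miss_prob,
                 spurious_rate = spurious_rate, conf_true = conf_true,
                 conf_spurious = conf_spurious),
            class = "noise_model")
}

#' Zero-noise model (exact keypoints, no misses, no spurious detections)
#' @return a `noise_model`
#' @export
no_noise <- function() noise_model(0, 0, 0)

.truth_antennas <- function(headings, antennas) {
  vapply(headings, function(th)
    antenna_for_mouse(c(cos(th), sin(th)), antennas)$index, integer(1))
}

.truth_winner <- function(headings, antennas) {
  idx <- .truth_antennas(headings, antennas)
  al <- vapply(seq_along(headings), function(i)
    sum(antennas[idx[i], ] * c(cos(headings[i]), sin(headings[i]))),
    numeric(1))
  majority_vote(idx, al)$winner
}

.place_mice <- function(n_mice, frame_size, body_length, min_sep) {
  margin <- body_length
  for (attempt in seq_len(2000)) {
    cx <- stats::runif(n_mice, margin, frame_size[1] - margin)
    cy <- stats::runif(n_mice, margin, frame_size[2] - margin)
    if (n_mice == 1) return(cbind(cx, cy))
    d <- as.matrix(stats::dist(cbind(cx, cy)))
    diag(d) <- Inf
    if (min(d) >= min_sep) return(cbind(cx, cy))
  }
  stop("could not place mice without overlap after bounded retries")
}

.render_scene <- function(centers, headings, frame_size, body_length,
                          body_intensity = 30, bg_intensity = 220) {
  w <- frame_size[1]; h <- frame_size[2]
  img <- matrix(bg_intensity, nrow = h, ncol = w)
  a <- body_length / 2; b <- body_length / 5
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  for (m in seq_len(nrow(centers))) {
    dx <- xs - centers[m, 1]; dy <- ys - centers[m, 2]
    ct <- cos(headings[m]); st <- sin(headings[m])
    u <- dx * ct + dy * st; v <- -dx * st + dy * ct
    img[(u / a)^2 + (v / b)^2 <= 1] <- body_intensity
  }
  img
}

.noisy_detections <- function(frame, centers, headings, body_length, noise) {
  n_mice <- nrow(centers)
  rows <- list()
  for (m in seq_len(n_mice)) {
    pole <- body_length / 2 * c(cos(headings[m]), sin(headings[m]))
    pts <- list(snout = centers[m, ] + pole, tail = centers[m, ] - pole)
    for (part in names(pts)) {
      if (noise$miss_prob > 0 && stats::runif(1) < noise$miss_prob) next
      p <- pts[[part]] + stats::rnorm(2, sd = noise$jitter_sd)
      conf <- if (noise$jitter_sd == 0 && noise$miss_prob == 0 &&
                  noise$spurious_rate == 0) 1
              else stats::rbeta(1, noise$conf_true[1], noise$conf_true[2])
      rows[[length(rows) + 1]] <- data.frame(
        frame = frame, part = part, x = p[1], y = p[2], confidence = conf)
    }
  }
  n_spur <- if (noise$spurious_rate > 0) stats::rpois(1, noise$spurious_rate) else 0
  for (s in seq_len(n_spur)) {
    rows[[length(rows) + 1]] <- data.frame(
      frame = frame, part = sample(c("snout", "tail"), 1),
      x = stats::runif(1, 0, max(centers[, 1]) * 1.2),
      y = stats::runif(1, 0, max(centers[, 2]) * 1.2),
      confidence = stats::rbeta(1, noise$conf_spurious[1], noise$conf_spurious[2]))
  }
  if (length(rows) == 0)
    return(detections(integer(0), character(0), numeric(0), numeric(0),
                      numeric(0)))
  df <- do.call(rbind, rows)
  detections(df$frame, df$part, df$x, df$y, pmin(1, pmax(0, df$confidence)))
}

#' Generate one synthetic cage scene
#'
#' Up to five mice rendered as dark filled ellipses on a bright floor,
#' with snout/tail keypoints at the ellipse poles, degraded by the noise
#' model.  Dark-on-bright polarity makes the occlusion veto of
#' [matching_score()] work as intended: the line between a snout and a
#' tail of one animal stays on its own dark body, while a cross-animal
#' line crosses bright floor and is vetoed.  Deterministic for a fixed
#' seed.
#'
#' @param n_mice 1-5
#' @param frame_size c(width, height) in px; 640 x 480 by default
#' @param body_length px, default 60
#' @param noise a [noise_model()]
#' @param seed integer
#' @param antennas the [antenna_set()] defining the ground-truth choice
#' @return list: `truth` (centers, headings, per-mouse antenna, winner),
#'   `image`, `detections`
#' @export
generate_scene <- function(n_mice = 5, frame_size = c(640, 480),
                           body_length = 60, noise = noise_model(), seed = 1,
                           antennas = antenna_set()) {
  stopifnot(n_mice >= 1, n_mice <= 5)
  set.seed(seed)
  centers <- .place_mice(n_mice, frame_size, body_length, 2.2 * body_length)
  headings <- stats::runif(n_mice, -pi, pi)
  img <- .render_scene(centers, headings, frame_size, body_length)
  dets <- .noisy_detections(0L, centers, headings, body_length, noise)
  truth <- list(centers = centers, headings = headings,
                body_length = body_length, frame_size = frame_size,
                antenna = .truth_antennas(headings, antennas),
                winner = .truth_winner(headings, antennas))
  list(truth = truth, image = img, detections = dets)
}

#' Generate a synthetic multi-frame track
#'
#' Mice follow a bounded random walk: per-frame turn uniform within
#' `max_turn_rad`, constant speed, reflection at the cage walls; a step
#' that would bring two mice closer than two body lengths is skipped, so
#' inverse-distance matching provably recovers the true pairing on
#' noise-free frames.  Headings evolve continuously, so the
#' ground-truth antenna changes only when a heading crosses a 45-degree
#' decision boundary.  No images are rendered (the occlusion veto is an
#' option of the frame pipeline, not of the stream).
#'
#' @param n_frames >= 1
#' @inheritParams generate_scene
#' @param speed px per frame
#' @param max_turn_rad maximal heading change per frame (rad)
#' @return list: `detections` (all frames), `truth` (data.frame frame,
#'   mouse, heading, antenna), `truth_winner` (per-frame reference
#'   sequence)
#' @export
generate_track <- function(n_frames, n_mice = 5, frame_size = c(640, 480),
                           body_length = 60, speed = 2, max_turn_rad = 0.1,
                           noise = noise_model(), seed = 1,
                           antennas = antenna_set()) {
  stopifnot(n_frames >= 1, n_mice >= 1, n_mice <= 5)
  set.seed(seed)
  centers <- .place_mice(n_mice, frame_size, body_length, 2.2 * body_length)
  headings <- stats::runif(n_mice, -pi, pi)
  margin <- body_length / 2 + 1
  min_sep <- 2 * body_length

  det_list <- vector("list", n_frames)
  truth_list <- vector("list", n_frames)
  winners <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      headings <- headings + stats::runif(n_mice, -max_turn_rad, max_turn_rad)
      for (m in seq_len(n_mice)) {
        cand <- centers[m, ] + speed * c(cos(headings[m]), sin(headings[m]))
        # reflect off walls
        if (cand[1] < margin || cand[1] > frame_size[1] - margin) {
          headings[m] <- pi - headings[m]
          cand <- centers[m, ]
        }
        if (cand[2] < margin || cand[2] > frame_size[2] - margin) {
          headings[m] <- -headings[m]
          cand <- centers[m, ]
        }
        if (n_mice > 1) {
          others <- centers[-m, , drop = FALSE]
          dd <- sqrt((others[, 1] - cand[1])^2 + (others[, 2] - cand[2])^2)
          if (min(dd) < min_sep) cand <- centers[m, ]  # hold position
        }
        centers[m, ] <- cand
      }
    }
    det_list[[f]] <- .noisy_detections(f - 1L, centers, headings,
                                       body_length, noise)
    truth_list[[f]] <- data.frame(frame = f - 1L, mouse = seq_len(n_mice),
                                  heading = headings,
                                  antenna = .truth_antennas(headings, antennas))
    winners[f] <- .truth_winner(headings, antennas)
  }
  dets <- do.call(rbind, det_list)
  list(detections = detections(dets$frame, dets$part, dets$x, dets$y,
                               dets$confidence),
       truth = do.call(rbind, truth_list),
       truth_winner = winners)
}
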