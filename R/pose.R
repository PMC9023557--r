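# Real-time keypoint post-processing: confidence filtering, snout-tail
# matching scores, pose vectors, coil-antenna selection, majority vote,
# and the activation statistics.

#' Keypoint detections
#'
#' @param frame integer frame indices (0-based)
#' @param part `"snout"` or `"tail"`
#' @param x,y pixel coordinates (origin top-left, y downward)
#' @param confidence detector confidence in \[0, 1\]
#' @return data.frame of class `detections`
#' @export
detections <- function(frame, part, x, y, confidence) {
  part <- as.character(part)
  if (!all(part %in% c("snout", "tail")))
    stop("part must be 'snout' or 'tail'")
  if (any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]")
  structure(data.frame(frame = as.integer(frame), part = part,
                       x = as.numeric(x), y = as.numeric(y),
                       confidence = as.numeric(confidence)),
            class = c("detections", "data.frame"))
}

#' Matching configuration
#'
#' @param confidence_threshold detections below this confidence are
#'   dropped (kept when equal); default 0.6
#' @param intensity_threshold pixel intensity (0-255) above which a pixel
#'   counts as an obstacle on the snout-tail line
#' @param count_threshold number of bright on-line pixels at which a
#'   candidate pair is vetoed (score 0)
#' @param zero_distance_cap finite score assigned to coincident
#'   (zero-distance) pairs so the assignment stays well-posed
#' @return a `match_config`
#' @export
match_config <- function(confidence_threshold = 0.6, intensity_threshold = 128,
                         count_threshold = 5, zero_distance_cap = 1e6) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            intensity_threshold >= 0, intensity_threshold <= 255,
            count_threshold >= 0, zero_distance_cap > 0)
  structure(list(confidence_threshold = confidence_threshold,
                 intensity_threshold = intensity_threshold,
                 count_threshold = count_threshold,
                 zero_distance_cap = zero_distance_cap),
            class = "match_config")
}

#' Drop low-confidence detections
#'
#' Keeps exactly the detections with confidence >= the threshold (the
#' boundary value survives); input order is preserved.
#'
#' @param dets a [detections()] data.frame
#' @param cfg a [match_config()]
#' @return the filtered detections
#' @export
filter_detections <- function(dets, cfg = match_config()) {
  dets[dets$confidence >= cfg$confidence_threshold, , drop = FALSE]
}

#' Count bright pixels on a raster line segment
#'
#' Bresenham traversal between the two (rounded) endpoints, endpoints
#' inclusive; counts pixels with intensity >= `t_int`.
#'
#' @param img numeric matrix, `img[row, col]` = intensity at pixel
#'   (x = col - 1, y = row - 1), values 0-255
#' @param p1,p2 length-2 pixel coordinates (x, y), 0-based
#' @param t_int intensity threshold
#' @return integer count
#' @export
line_pixel_count <- function(img, p1, p2, t_int) {
  h <- nrow(img); w <- ncol(img)
  x0 <- round(p1[1]); y0 <- round(p1[2])
  x1 <- round(p2[1]); y1 <- round(p2[2])
  if (min(x0, x1) < 0 || max(x0, x1) >= w || min(y0, y1) < 0 || max(y0, y1) >= h)
    stop("segment endpoint outside the image")
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1 else -1
  sy <- if (y0 < y1) 1 else -1
  err <- dx + dy
  count <- 0L
  repeat {
    if (img[y0 + 1, x0 + 1] >= t_int) count <- count + 1L
    if (x0 == x1 && y0 == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  count
}

#' Matching score for one snout-tail pair
#'
#' Inverse Euclidean pixel distance, vetoed (score exactly 0) when the
#' straight line between the two points crosses `count_threshold` or more
#' above-threshold pixels of the frame image.  With dark animals on a
#' bright floor, bright pixels on the line are open floor: a snout and a
#' tail separated by floor cannot belong to one mouse, while a true
#' pair's line stays on the animal's own dark body.  Without an image the
#' veto is skipped.  Coincident points receive the finite
#' `zero_distance_cap`.
#'
#' @param snout,tail single-row [detections()] entries (or any list with
#'   `x`, `y`, `part`)
#' @param img optional frame image matrix (see [line_pixel_count()])
#' @param cfg a [match_config()]
#' @return score >= 0
#' @export
matching_score <- function(snout, tail, img = NULL, cfg = match_config()) {
  if (!identical(as.character(snout$part), "snout") ||
      !identical(as.character(tail$part), "tail"))
    stop("matching_score expects a snout and a tail, in that order")
  if (!is.null(img)) {
    cnt <- line_pixel_count(img, c(snout$x, snout$y), c(tail$x, tail$y),
                            cfg$intensity_threshold)
    if (cnt >= cfg$count_threshold) return(0)
  }
  d <- sqrt((tail$x - snout$x)^2 + (tail$y - snout$y)^2)
  if (d == 0) return(cfg$zero_distance_cap)
  min(1 / d, cfg$zero_distance_cap)
}

#' Score matrix over all snout-tail pairs of one frame
#'
#' @param snouts,tails [detections()] subsets of one frame
#' @inheritParams matching_score
#' @return matrix, snouts in rows
#' @export
score_matrix <- function(snouts, tails, img = NULL, cfg = match_config()) {
  m <- matrix(0, nrow(snouts), nrow(tails))
  for (i in seq_len(nrow(snouts)))
    for (j in seq_len(nrow(tails)))
      m[i, j] <- matching_score(snouts[i, ], tails[j, ], img, cfg)
  m
}

#' Pose vectors from a matching
#'
#' One unit vector per matched pair, pointing tail -> snout (the heading
#' of the mouse).  Zero-length pairs are flagged undefined.
#'
#' @param matching a [solve_matching()] result
#' @param snouts,tails the detections the score matrix was built from
#' @return data.frame: mouse, ox, oy (tail origin), tx, ty (snout tip),
#'   vx, vy (unit direction), defined
#' @export
pose_vectors <- function(matching, snouts, tails) {
  pr <- matching$pairs
  out <- data.frame(mouse = seq_len(nrow(pr)),
                    ox = tails$x[pr$tail], oy = tails$y[pr$tail],
                    tx = snouts$x[pr$snout], ty = snouts$y[pr$snout])
  dx <- out$tx - out$ox; dy <- out$ty - out$oy
  nrm <- sqrt(dx^2 + dy^2)
  out$defined <- nrm > 0
  out$vx <- ifelse(out$defined, dx / nrm, NA_real_)
  out$vy <- ifelse(out$defined, dy / nrm, NA_real_)
  out
}

#' The four coil-antenna direction vectors
#'
#' Defaults to unit vectors along +x, -x, +y, -y: two antenna pairs on the
#' x- and y-axes of the cage.
#'
#' @param vectors list of length-2 numeric vectors (normalized internally)
#' @return an `antenna_set` (2-column matrix, one row per antenna)
#' @export
antenna_set <- function(vectors = list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
  m <- do.call(rbind, lapply(vectors, function(v) {
    stopifnot(length(v) == 2)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("antenna vector must be non-zero")
    v / n
  }))
  if (anyDuplicated(round(m, 12))) stop("antenna vectors must be distinct")
  structure(m, class = c("antenna_set", "matrix"))
}

#' Best antenna for one pose vector
#'
#' The mouse's out-of-plane elevation is unobserved; modeling it as
#' uniform on \[0, 90) degrees (a mouse pitches upward but does not stand
#' on its head), the expected distance between the tilted heading and an
#' in-plane antenna vector is `E sqrt(2 - 2 cos(z) (v . a_i))`, which is
#' monotone decreasing in the dot product `v . a_i`.  Minimizing the
#' expectation therefore reduces to picking the antenna with the largest
#' dot product; ties go to the lowest index.
#'
#' @param v length-2 pose vector (need not be unit length); `NA` abstains
#' @param antennas an [antenna_set()]
#' @return list(index, alignment) — `index` is `NA` for an abstention
#' @export
antenna_for_mouse <- function(v, antennas = antenna_set()) {
  if (any(is.na(v))) return(list(index = NA_integer_, alignment = NA_real_))
  dots <- as.numeric(antennas %*% v)
  best <- which(dots >= max(dots) - 1e-12)[1]
  list(index = best, alignment = dots[best])
}

#' Majority vote over per-mouse antenna choices
#'
#' Modal antenna index; ties are broken by the greatest summed alignment
#' (dot product) over the voters of each tied antenna, then by the lowest
#' index.  With no valid votes the previously selected antenna is held
#' (one coil is always active).
#'
#' @param indices per-mouse antenna indices (`NA` = abstain)
#' @param alignments per-mouse alignment scores used by the tie rule
#' @param previous antenna held from the previous frame
#' @return list(winner, held, tally)
#' @export
majority_vote <- function(indices, alignments = NULL, previous = NA_integer_) {
  valid <- !is.na(indices)
  if (!any(valid))
    return(list(winner = previous, held = TRUE, tally = integer(0)))
  idx <- indices[valid]
  al <- if (is.null(alignments)) rep(0, length(idx)) else alignments[valid]
  tally <- table(idx)
  top <- as.integer(names(tally)[tally == max(tally)])
  if (length(top) > 1) {
    sums <- vapply(top, function(a) sum(al[idx == a]), numeric(1))
    top <- top[sums >= max(sums) - 1e-12]
  }
  list(winner = min(top), held = FALSE, tally = tally)
}

#' Process one frame end to end
#'
#' Confidence filter -> pairwise scores -> assignment -> pose vectors ->
#' per-mouse antenna -> majority vote.  Deterministic, and invariant to
#' the input order of detections (they are sorted canonically first).
#'
#' @param dets [detections()] of one frame
#' @param img optional frame image for the occlusion veto
#' @param cfg a [match_config()]
#' @param antennas an [antenna_set()]
#' @param previous previously active antenna (held on empty frames)
#' @return list: `winner`, `held`, `per_mouse` (antenna + alignment per
#'   matched pair), `poses`, `matching`, `tally`
#' @export
process_frame <- function(dets, img = NULL, cfg = match_config(),
                          antennas = antenna_set(), previous = NA_integer_) {
  kept <- filter_detections(dets, cfg)
  kept <- kept[order(kept$part, kept$x, kept$y, kept$confidence), , drop = FALSE]
  snouts <- kept[kept$part == "snout", , drop = FALSE]
  tails <- kept[kept$part == "tail", , drop = FALSE]
  if (nrow(snouts) == 0 || nrow(tails) == 0) {
    return(list(winner = previous, held = TRUE,
                per_mouse = data.frame(mouse = integer(0),
                                       antenna = integer(0),
                                       alignment = numeric(0)),
                poses = NULL, matching = NULL, tally = integer(0)))
  }
  sm <- score_matrix(snouts, tails, img, cfg)
  mt <- solve_matching(sm)
  poses <- pose_vectors(mt, snouts, tails)
  ant <- lapply(seq_len(nrow(poses)), function(i) {
    if (!poses$defined[i]) return(list(index = NA_integer_, alignment = NA_real_))
    antenna_for_mouse(c(poses$vx[i], poses$vy[i]), antennas)
  })
  per_mouse <- data.frame(mouse = poses$mouse,
                          antenna = vapply(ant, `[[`, integer(1), "index"),
                          alignment = vapply(ant, `[[`, numeric(1), "alignment"))
  vote <- majority_vote(per_mouse$antenna, per_mouse$alignment, previous)
  list(winner = vote$winner, held = vote$held, per_mouse = per_mouse,
       poses = poses, matching = mt, tally = vote$tally)
}

#' Process a multi-frame detection stream
#'
#' Runs [process_frame()] over every frame in order, carrying the active
#' antenna across frames where the pipeline abstains.
#'
#' @param dets [detections()] covering many frames
#' @param imgs optional named list of frame images (names = frame index)
#' @param frames frame indices to decide on; defaults to the frames
#'   present in `dets`, but a full range keeps frames on which every
#'   detection was missed (the previous antenna is held there)
#' @inheritParams process_frame
#' @return data.frame: frame, winner, held
#' @export
process_track <- function(dets, imgs = NULL, cfg = match_config(),
                          antennas = antenna_set(), previous = NA_integer_,
                          frames = NULL) {
  if (is.null(frames)) frames <- sort(unique(dets$frame))
  winners <- integer(length(frames))
  held <- logical(length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    img <- if (!is.null(imgs)) imgs[[as.character(f)]] else NULL
    res <- process_frame(dets[dets$frame == f, , drop = FALSE], img, cfg,
                         antennas, previous)
    winners[fi] <- res$winner
    held[fi] <- res$held
    previous <- res$winner
  }
  data.frame(frame = frames, winner = winners, held = held)
}

#' Per-antenna activation run lengths
#'
#' Lengths (in frames) of the maximal constant runs of each antenna in
#' the winner sequence: how long a selected antenna remains activated.
#'
#' @param winners per-frame winner indices
#' @return named list, one integer vector of run lengths per antenna
#' @export
activation_run_lengths <- function(winners) {
  if (length(winners) == 0) stop("empty winner sequence")
  r <- rle(winners)
  split(r$lengths, r$values)
}

#' Per-antenna reactivation intervals
#'
#' For each antenna, the gaps (in frames) separating two of its
#' activation runs: how long it takes between deactivation of an antenna
#' and its next reactivation.
#'
#' @inheritParams activation_run_lengths
#' @return named list, one integer vector of gap lengths per antenna
#' @export
reactivation_intervals <- function(winners) {
  if (length(winners) == 0) stop("empty winner sequence")
  r <- rle(winners)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (a in unique(r$values)) {
    runs <- which(r$values == a)
    if (length(runs) < 2) { out[[as.character(a)]] <- integer(0); next }
    out[[as.character(a)]] <-
      starts[runs[-1]] - ends[runs[-length(runs)]] - 1L
  }
  out
}

#' Antenna selection accuracy
#'
#' Percentage of frames on which the predicted winner equals the
#' reference winner.
#'
#' @param predicted,reference equal-length winner sequences (non-empty)
#' @return percent in \[0, 100\]
#' @export
selection_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference sequences differ in length")
  if (length(predicted) == 0)
    stop("accuracy is undefined for empty sequences")
  100 * mean(predicted == reference)
}
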