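# Readers and writers: keypoint CSV dialects, PGM frames, voxel volumes,
# run records.

.apply_alias <- function(part, alias) {
  if (length(alias) > 0) {
    hit <- match(part, names(alias))
    part[!is.na(hit)] <- unlist(alias)[hit[!is.na(hit)]]
  }
  unknown <- setdiff(unique(part), c("snout", "tail"))
  if (length(unknown) > 0)
    stop(sprintf("unknown bodypart label(s): %s (map them via the alias table)",
                 paste(unknown, collapse = ", ")))
  part
}

#' Read a keypoint detection stream
#'
#' Two dialects: `"long-csv"` is a flat table (frame, part, x, y,
#' confidence); `"dlc-csv"` is the wide pose-estimation export with three
#' header rows (scorer / bodyparts / coords) and x, y, likelihood columns
#' per part slot, the first column holding the frame index.  Frame
#' indices are 0-based and pass through unchanged; pixel origin is the
#' top-left corner with y increasing downward.
#'
#' @param path CSV file
#' @param dialect `"long-csv"` or `"dlc-csv"`
#' @param alias named character vector mapping foreign bodypart labels to
#'   `"snout"`/`"tail"`, e.g. `c(nose = "snout")`
#' @return a [detections()] data.frame
#' @export
read_keypoints <- function(path, dialect = c("long-csv", "dlc-csv"),
                           alias = character(0)) {
  dialect <- match.arg(dialect)
  if (dialect == "long-csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "part", "x", "y", "confidence")
    if (!all(need %in% names(df)))
      stop(sprintf("malformed header: expected columns %s",
                   paste(need, collapse = ", ")))
    if (nrow(df) == 0)
      return(detections(integer(0), character(0), numeric(0), numeric(0),
                        numeric(0)))
    return(detections(df$frame, .apply_alias(df$part, alias), df$x, df$y,
                      df$confidence))
  }
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 3 || raw[1, 1] != "scorer" || raw[2, 1] != "bodyparts" ||
      raw[3, 1] != "coords")
    stop("malformed header: expected scorer/bodyparts/coords rows")
  parts <- as.character(unlist(raw[2, -1]))
  coords <- as.character(unlist(raw[3, -1]))
  body <- raw[-(1:3), , drop = FALSE]
  rows <- list()
  j <- 1
  while (j <= length(coords)) {
    if (!identical(coords[j:(j + 2)], c("x", "y", "likelihood")))
      stop("malformed header: expected x, y, likelihood column triples")
    part <- parts[j]
    if (nrow(body) > 0) {
      xs <- as.numeric(body[, j + 1]); ys <- as.numeric(body[, j + 2])
      ls <- as.numeric(body[, j + 3]); fr <- as.integer(body[, 1])
      keep <- !is.na(xs) & !is.na(ys)
      if (any(keep))
        rows[[length(rows) + 1]] <- data.frame(
          frame = fr[keep], part = part, x = xs[keep], y = ys[keep],
          confidence = ls[keep])
    }
    j <- j + 3
  }
  if (length(rows) == 0)
    return(detections(integer(0), character(0), numeric(0), numeric(0),
                      numeric(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$frame, df$part, df$x), ]
  detections(df$frame, .apply_alias(df$part, alias), df$x, df$y, df$confidence)
}

#' Write a keypoint detection stream
#'
#' @param dets a [detections()] data.frame
#' @param path output CSV
#' @param dialect see [read_keypoints()]
#' @param scorer scorer tag written into the dlc-csv header
#' @return `path`, invisibly
#' @export
write_keypoints <- function(dets, path, dialect = c("long-csv", "dlc-csv"),
                            scorer = "pdtkit") {
  dialect <- match.arg(dialect)
  if (dialect == "long-csv") {
    utils::write.csv(as.data.frame(dets)[, c("frame", "part", "x", "y",
                                             "confidence")],
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  frames <- sort(unique(dets$frame))
  slots <- list()
  for (part in c("snout", "tail")) {
    n_slot <- max(c(0, table(dets$frame[dets$part == part])))
    for (s in seq_len(n_slot)) slots[[length(slots) + 1]] <- c(part, s)
  }
  header1 <- c("scorer", rep(scorer, 3 * length(slots)))
  header2 <- c("bodyparts", unlist(lapply(slots, function(sl) rep(sl[1], 3))))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(slots)))
  lines <- c(paste(header1, collapse = ","), paste(header2, collapse = ","),
             paste(header3, collapse = ","))
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  for (f in frames) {
    fd <- dets[dets$frame == f, , drop = FALSE]
    cells <- character(0)
    for (part in c("snout", "tail")) {
      pd <- fd[fd$part == part, , drop = FALSE]
      n_slot <- sum(vapply(slots, function(sl) sl[1] == part, logical(1)))
      for (s in seq_len(n_slot)) {
        if (s <= nrow(pd))
          cells <- c(cells, fmt(pd$x[s]), fmt(pd$y[s]), fmt(pd$confidence[s]))
        else cells <- c(cells, "", "", "")
      }
    }
    lines <- c(lines, paste(c(f, cells), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a grayscale frame as ASCII PGM (P2)
#'
#' @param img numeric matrix, values 0-255, `img[row, col]`
#' @param path .pgm file
#' @return `path` invisibly / the image matrix
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  apply(round(img), 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: pixel count mismatch")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write / read a voxel volume (flat binary + JSON sidecar)
#'
#' The grid is stored as little-endian doubles in Fortran (x-fastest)
#' order next to a `<path>.json` sidecar recording shape, voxel size and
#' axis order.  Round-trips are lossless; a sidecar with an unexpected
#' axis order is an explicit error (no silent transpose).
#'
#' @param grid numeric 3-d array
#' @param path output .bin file
#' @param voxel_size mm, recorded in the sidecar
#' @return `path` invisibly / list(grid, voxel_size)
#' @export
write_volume <- function(grid, path, voxel_size = NA_real_) {
  if (!is.array(grid) || length(dim(grid)) != 3 || any(dim(grid) == 0))
    stop("grid must be a non-empty 3-d array")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid), con, size = 8, endian = "little")
  jsonlite::write_json(list(shape = dim(grid), voxel_size_mm = voxel_size,
                            axis_order = "xyz", dtype = "float64le"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$shape) || length(meta$shape) != 3)
    stop("corrupt sidecar: missing shape")
  if (!identical(meta$axis_order, "xyz"))
    stop(sprintf("axis-order mismatch: sidecar says '%s', expected 'xyz'",
                 meta$axis_order))
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("corrupt volume: too few values")
  list(grid = array(vals, dim = meta$shape), voxel_size = meta$voxel_size_mm)
}

#' Write a JSON run record for a stochastic run
#'
#' @param path output JSON
#' @param command short command tag
#' @param config named list snapshot of the configuration
#' @param seeds named list of seeds used
#' @return `path` invisibly
#' @export
write_run_record <- function(path, command, config = list(), seeds = list()) {
  jsonlite::write_json(list(
    command = command, config = config, seeds = seeds,
    tool_version = as.character(utils::packageVersion("pdtkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
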