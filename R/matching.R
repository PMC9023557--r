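# Maximum weighted bipartite matching: O(n^3) shortest-augmenting-path
# assignment solver plus a lexicographic tie-break refinement.

# Minimum-cost perfect assignment on a square matrix (Jonker-Volgenant
# style dual potentials).  Returns list(col_of_row, total).
.assignment_min <- function(a) {
  n <- nrow(a)
  if (n == 0) return(list(col_of_row = integer(0), total = 0))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials; index 1 is the virtual column
  p <- integer(n + 1)    # p[j+1] = row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- a[i0, j] - u[i0] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          pj <- p[j + 1]
          if (pj > 0) u[pj] <- u[pj] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  col_of_row <- integer(n)
  for (j in seq_len(n)) col_of_row[p[j + 1]] <- j
  list(col_of_row = col_of_row,
       total = sum(a[cbind(seq_len(n), col_of_row)]))
}

.assignment_max_total <- function(s) {
  if (nrow(s) == 0) return(0)
  -.assignment_min(-s)$total
}

#' Solve the snout-tail assignment (maximum weighted bipartite matching)
#'
#' Finds the one-to-one snout-tail pairing maximizing the total matching
#' score.  Rectangular matrices are padded with zero-score dummy nodes;
#' dummy pairs are reported as unmatched.  Among score-equivalent optima
#' the lexicographically smallest pairing (by snout index, then tail
#' index) is returned, making the result fully deterministic.
#'
#' @param score_matrix non-negative finite matrix, snouts in rows, tails
#'   in columns
#' @param tol tolerance used when testing score-equivalence of optima
#' @return a `matching`: `pairs` (data.frame snout, tail, score),
#'   `unmatched_snouts`, `unmatched_tails`, `total`
#' @export
solve_matching <- function(score_matrix, tol = 1e-9) {
  s <- as.matrix(score_matrix)
  if (length(s) > 0 && (any(!is.finite(s)) || any(s < 0)))
    stop("matching scores must be non-negative and finite")
  ns <- nrow(s); nt <- ncol(s)
  empty <- function() structure(list(
    pairs = data.frame(snout = integer(0), tail = integer(0),
                       score = numeric(0)),
    unmatched_snouts = seq_len(ns), unmatched_tails = seq_len(nt),
    total = 0), class = "matching")
  if (ns == 0 || nt == 0) return(empty())
  n <- max(ns, nt)
  sq <- matrix(0, n, n)
  sq[seq_len(ns), seq_len(nt)] <- s

  total <- .assignment_max_total(sq)
  scale <- max(1, abs(total))
  # lexicographic refinement: fix rows in order, smallest feasible column
  avail <- seq_len(n)
  col_of_row <- integer(n)
  fixed_sum <- 0
  for (i in seq_len(n)) {
    rest_rows <- if (i < n) (i + 1):n else integer(0)
    for (j in avail) {
      sub <- sq[rest_rows, setdiff(avail, j), drop = FALSE]
      cand <- fixed_sum + sq[i, j] + .assignment_max_total(sub)
      if (cand >= total - tol * scale) {
        col_of_row[i] <- j
        fixed_sum <- fixed_sum + sq[i, j]
        avail <- setdiff(avail, j)
        break
      }
    }
  }
  real <- which(seq_len(n) <= ns & col_of_row <= nt)
  pairs <- data.frame(snout = real, tail = col_of_row[real],
                      score = sq[cbind(real, col_of_row[real])])
  structure(list(pairs = pairs,
                 unmatched_snouts = setdiff(seq_len(ns), pairs$snout),
                 unmatched_tails = setdiff(seq_len(nt), pairs$tail),
                 total = sum(pairs$score)),
            class = "matching")
}

#' @export
print.matching <- function(x, ...) {
  cat(sprintf("matching: %d pairs, total score %.6g\n", nrow(x$pairs), x$total))
  invisible(x)
}
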