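# Independent oracles used across the suite.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

.PERM_CACHE <- lapply(1:6, all_perms)

# brute-force maximum-total one-to-one assignment by permutation enumeration
brute_force_matching_total <- function(s) {
  ns <- nrow(s); nt <- ncol(s)
  if (ns == 0 || nt == 0) return(0)
  if (ns <= nt) {
    best <- -Inf
    for (p in .PERM_CACHE[[nt]]) {
      tot <- sum(s[cbind(seq_len(ns), p[seq_len(ns)])])
      if (tot > best) best <- tot
    }
  } else {
    best <- -Inf
    for (p in .PERM_CACHE[[ns]]) {
      tot <- sum(s[cbind(p[seq_len(nt)], seq_len(nt))])
      if (tot > best) best <- tot
    }
  }
  best
}

# numeric evaluation of the expected tilted-heading distance to an
# in-plane antenna vector, elevation uniform on [0, 90) degrees
expected_antenna_distance <- function(v, a, z) {
  mean(sqrt(pmax(0, 2 - 2 * cos(z) * sum(v * a))))
}

# fabricate a regimen_score carrying arbitrary criterion values
fake_score <- function(pen, absf, unif, ttt, dT) {
  structure(list(penetration_mm = pen, absorbance_fraction = absf,
                 uniformity = unif, time_to_target_s = ttt, delta_T_C = dT),
            class = "regimen_score")
}

# small homogeneous phantom with overridden optics at one wavelength
absorbing_phantom <- function(voxel = 0.1, cube = 10, mu_a = 1, mu_s = 0,
                              g = 0, n = 1, wl = 652) {
  ph <- build_preset_phantom("homogeneous", voxel, cube_mm = cube)
  set_optical_properties(ph, "dermis", wl, mu_a = mu_a, mu_s = mu_s,
                         g = g, n = n)
}
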