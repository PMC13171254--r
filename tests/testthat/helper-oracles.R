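# Independent brute-force / closed-form oracles used to cross-check the
# package's optimised paths. Deliberately written as plain loops over all
# pairs, sharing no code with the implementation.

oracle_count_clashes <- function(a, b, cutoff = 0.30, inclusive = FALSE) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      hit <- if (inclusive) d <= cutoff else d < cutoff
      if (hit) n <- n + 1L
    }
  }
  n
}

oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

# Horn's quaternion method for optimal superposition RMSD (independent of
# the SVD-based Kabsch path)
oracle_rmsd_quaternion <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  M <- crossprod(P, Q)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# brute-force hydrogen-bond detection: loops over donor/acceptor names,
# explicit angle at the hydrogen
oracle_hbonds <- function(structure, coords, res_a, res_b) {
  a <- structure$atoms
  donors <- c("N", "NE", "ND1", "NE2", "NH1", "NH2", "OG", "OG1", "OH")
  accs <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH")
  found <- character(0)
  pairs <- list()
  for (di in seq_len(nrow(a))) {
    if (!(a$atom_name[di] %in% donors)) next
    if (!(a$element[di] %in% c("N", "O"))) next
    for (ai in seq_len(nrow(a))) {
      if (ai == di) next
      if (!(a$atom_name[ai] %in% accs) || a$element[ai] != "O") next
      in_ab <- a$resnum[di] %in% res_a && a$resnum[ai] %in% res_b
      in_ba <- a$resnum[di] %in% res_b && a$resnum[ai] %in% res_a
      if (!in_ab && !in_ba) next
      if (a$resnum[di] == a$resnum[ai]) next
      d <- sqrt(sum((coords[di, ] - coords[ai, ])^2))
      if (d > 0.35) next
      ok <- FALSE
      for (hi in seq_len(nrow(a))) {
        if (a$element[hi] != "H") next
        dh <- sqrt(sum((coords[hi, ] - coords[di, ])^2))
        if (dh > 0.12) next
        # hydrogen must belong to this donor (nearest donor-capable atom)
        nearest <- Inf
        for (dj in seq_len(nrow(a))) {
          if (a$atom_name[dj] %in% donors && a$element[dj] %in% c("N", "O")) {
            nearest <- min(nearest, sqrt(sum((coords[hi, ] - coords[dj, ])^2)))
          }
        }
        if (dh > nearest + 1e-12) next
        v1 <- coords[di, ] - coords[hi, ]
        v2 <- coords[ai, ] - coords[hi, ]
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= 150) ok <- TRUE
      }
      if (ok) {
        key <- paste(sort(c(di, ai)), collapse = "-")
        if (!(key %in% found)) {
          found <- c(found, key)
          pairs[[length(pairs) + 1]] <- c(don = a$resnum[di],
                                          acc = a$resnum[ai])
        }
      }
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("don", "acc")))
}

oracle_salt_bridges <- function(structure, coords) {
  a <- structure$atoms
  cats <- c("LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2")
  anis <- c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2")
  key <- paste(a$resname, a$atom_name, sep = ":")
  pairs <- list()
  for (ci in which(key %in% cats)) {
    for (ai in which(key %in% anis)) {
      d <- sqrt(sum((coords[ci, ] - coords[ai, ])^2))
      if (d <= 0.35) {
        pairs[[length(pairs) + 1]] <- c(cat = a$resnum[ci],
                                        ani = a$resnum[ai])
      }
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("cat", "ani")))
}

oracle_rg <- function(coords, masses = rep(1, nrow(coords))) {
  com <- c(sum(coords[, 1] * masses), sum(coords[, 2] * masses),
           sum(coords[, 3] * masses)) / sum(masses)
  acc <- 0
  for (i in seq_len(nrow(coords))) {
    acc <- acc + masses[i] * sum((coords[i, ] - com)^2)
  }
  sqrt(acc / sum(masses))
}

# minimal structure builder for hand-made geometries
make_structure <- function(names, elements, resnames, resnums, xyz,
                           chain = "A") {
  n <- length(names)
  new_structure(
    data.frame(serial = seq_len(n), atom_name = names, element = elements,
               resname = resnames, resnum = resnums,
               chain = rep_len(chain, n), stringsAsFactors = FALSE),
    xyz)
}

# single-frame trajectory from a structure plus frame list
make_trajectory <- function(structure, frames, dt_ns = 1) {
  coords <- array(NA_real_, c(length(frames), n_atoms(structure), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  new_trajectory(structure, coords, dt_ns = dt_ns)
}

# evenly spread points on the unit sphere (for building cage geometries)
.sphere_points_for_test <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# rigid rotation helper
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}
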