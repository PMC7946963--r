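# Independent oracles used to check the package implementations.
# Each is a deliberately naive alternative route, kept free of the
# package's own scanning / geometry code paths.

# exhaustive per-window motif check
oracle_scan_positions <- function(residues, phospho = integer(0),
                                  allow_conditional = FALSE,
                                  theta = c("fir", "lir")) {
  theta <- match.arg(theta)
  th_set <- if (theta == "lir") c("F", "Y", "W") else c("I", "L", "V", "F", "Y", "W")
  n <- length(residues)
  hits <- integer(0)
  if (n < 5) return(hits)
  for (i in seq_len(n - 4)) {
    psi_ok <- residues[i] %in% c("D", "E") ||
      (residues[i] %in% c("S", "T") &&
         (i %in% phospho || allow_conditional))
    if (psi_ok && residues[i + 1] %in% th_set &&
        residues[i + 4] %in% c("L", "I", "V")) {
      hits <- c(hits, i)
    }
  }
  hits
}

random_peptide <- function(len, p_phospho = 0.3) {
  res <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE)
  sty <- which(res %in% c("S", "T", "Y"))
  ph <- sty[stats::runif(length(sty)) < p_phospho]
  fir_peptide(paste(res, collapse = ""), phospho = ph)
}

# accessible area of sphere 1 (radius R1) partially buried by sphere 2
# (radius R2) at center distance d: closed-form spherical cap
two_sphere_accessible <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  a <- (d^2 + R1^2 - R2^2) / (2 * d)   # distance to intersection plane
  h <- R1 - a                           # buried cap height
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Monte Carlo SASA with a random direction set (independent of the
# deterministic golden-spiral used by the implementation)
mc_sasa <- function(xyz, radii, probe, n_points = 10000, seed = 42) {
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rr <- unname(radii) + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    p <- sweep(dirs * rr[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      dj <- sweep(p, 2, xyz[j, ], `-`)
      free <- free & (rowSums(dj^2) >= rr[j]^2)
    }
    total <- total + 4 * pi * rr[i]^2 * mean(free)
  }
  total
}

# Horn's quaternion absolute-orientation method: RMSD of the optimal
# rigid superposition of Q onto P
quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  M <- t(Q0) %*% P0
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
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  Qr <- Q0 %*% t(R)
  sqrt(mean(rowSums((Qr - P0)^2)))
}

rigid_motion <- function(model, angle = 0.9, axis = c(0, 0, 1),
                         shift = c(7, -4, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}
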