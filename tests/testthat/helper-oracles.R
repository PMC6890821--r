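# Independent oracles and tiny fixture builders used across the suite.

# Quaternion (Kearsley) RMSD oracle: smallest eigenvalue of the 4x4
# residual matrix built from coordinate sums/differences. Independent of
# the SVD route used by kabsch_superpose().
quaternion_rmsd <- function(mobile, reference) {
  a <- sweep(as.matrix(reference), 2, colMeans(reference))
  b <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  xm <- a[, 1] - b[, 1]; ym <- a[, 2] - b[, 2]; zm <- a[, 3] - b[, 3]
  xp <- a[, 1] + b[, 1]; yp <- a[, 2] + b[, 2]; zp <- a[, 3] + b[, 3]
  q <- matrix(0, 4, 4)
  q[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  q[1, 2] <- q[2, 1] <- sum(yp * zm - ym * zp)
  q[1, 3] <- q[3, 1] <- sum(xm * zp - xp * zm)
  q[1, 4] <- q[4, 1] <- sum(xp * ym - xm * yp)
  q[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  q[2, 3] <- q[3, 2] <- sum(xm * ym - xp * yp)
  q[2, 4] <- q[4, 2] <- sum(xm * zm - xp * zp)
  q[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  q[3, 4] <- q[4, 3] <- sum(ym * zm - yp * zp)
  q[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  lam <- min(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(lam, 0) / nrow(a))
}

# Monte-Carlo sphere-intersection oracle: sample uniformly inside the
# smaller sphere, count the fraction falling inside the other. Attribute
# "se" carries the binomial standard error of the estimate.
mc_intersect_volume <- function(c1, r1, c2, r2, n = 1e6) {
  if (r2 < r1) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- r1; r1 <- r2; r2 <- tmp }
  u <- matrix(stats::rnorm(n * 3), n, 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- r1 * stats::runif(n)^(1 / 3)
  pts <- sweep(u * rad, 2, -c1)
  inside <- rowSums(sweep(pts, 2, c2)^2) <= r2^2
  p <- mean(inside)
  v1 <- 4 / 3 * pi * r1^3
  structure(p * v1, se = v1 * sqrt(p * (1 - p) / n))
}

# Independent dihedral formulation: atan2(|b2| * b1.(b2 x b3),
# (b1 x b2).(b2 x b3)) -- no normal/bisector construction shared with the
# implementation.
dihedral_oracle <- function(p) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  atan2(sqrt(sum(b2^2)) * sum(b1 * cross(b2, b3)),
        sum(cross(b1, b2) * cross(b2, b3))) * 180 / pi
}

# Small helical-ish test structure: n residues, one CA per residue unless
# backbone = TRUE (N, CA, C, O per residue).
make_test_model <- function(n = 10, backbone = FALSE, seed = 42) {
  set.seed(seed)
  t <- seq_len(n)
  base <- cbind(cos(t / 2) * 5 + t * 0.5, sin(t / 2) * 5, t * 1.5)
  if (!backbone) {
    at <- data.frame(serial = t, name = "CA", residue_name = "ALA",
                     chain = "A", residue_number = t,
                     x = base[, 1], y = base[, 2], z = base[, 3],
                     element = "C", het = FALSE)
  } else {
    off <- rbind(c(-1.2, 0.5, 0), c(0, 0, 0), c(1.2, 0.5, 0),
                 c(1.8, 1.6, 0))
    nm <- c("N", "CA", "C", "O")
    at <- do.call(rbind, lapply(t, function(i)
      data.frame(serial = (i - 1L) * 4L + 1:4, name = nm,
                 residue_name = "ALA", chain = "A", residue_number = i,
                 x = base[i, 1] + off[, 1], y = base[i, 2] + off[, 2],
                 z = base[i, 3] + off[, 3],
                 element = c("N", "C", "C", "O"), het = FALSE)))
  }
  structure_model(at)
}

# Trajectory of jittered copies of a model (seeded).
make_test_trajectory <- function(model, n_frames = 5, sigma = 0,
                                 seed = 7, frame_interval = 0.1) {
  set.seed(seed)
  x0 <- coords(model)
  frames <- lapply(seq_len(n_frames), function(i)
    x0 + matrix(stats::rnorm(length(x0), sd = sigma), nrow(x0), 3))
  trajectory(frames, frame_interval = frame_interval, atom_meta = model)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
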