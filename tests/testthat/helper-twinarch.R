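## Shared fixtures and independent oracles for the test suite.

## Independent ICC(A,1) oracle: mean squares from stats::aov on the long
## two-way layout, plugged into the absolute-agreement formula.
oracle_icc_a1 <- function(v1, v2) {
  n <- length(v1)
  d <- data.frame(value = c(v1, v2),
                  subject = factor(rep(seq_len(n), 2)),
                  occasion = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + occasion, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

## Independent one-way pair ICC oracle via stats::aov.
oracle_pair_icc <- function(x) {
  n <- nrow(x)
  d <- data.frame(value = c(x[, 1], x[, 2]), pair = factor(rep(seq_len(n), 2)))
  ms <- summary(stats::aov(value ~ pair, data = d))[[1]][, "Mean Sq"]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}

## Independent point-to-line distance oracle: |(p - a) x (b - a)| / |b - a|.
oracle_point_line <- function(p, a, b) {
  u <- b - a
  w <- p - a
  cr <- c(w[2] * u[3] - w[3] * u[2],
          w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  sqrt(sum(cr^2)) / sqrt(sum(u^2))
}

## Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(lms, rot, trans) {
  pts <- t(rot %*% t(lms$points)) + matrix(trans, nrow(lms$points), 3, byrow = TRUE)
  rownames(pts) <- rownames(lms$points)
  landmark_set(lms$subject_id, lms$stage, lms$arch, pts)
}

## A feasible, anatomically plausible trait target (permanent dentition).
example_target <- function(stage = "permanent") {
  if (stage == "primary") {
    list(maxillary_intercanine_width = 28.5, maxillary_intermolar_width = 40.9,
         maxillary_arch_length = 25.9, mandibular_intercanine_width = 22.8,
         mandibular_intermolar_width = 35.4, mandibular_arch_length = 23.6,
         overjet = 2.4, overbite = 1.1,
         molar_relationship_right = -0.03, molar_relationship_left = -0.02,
         stage = "primary")
  } else {
    list(maxillary_intercanine_width = 33.1, maxillary_intermolar_width = 50.5,
         maxillary_arch_length = 36.5, mandibular_intercanine_width = 25.3,
         mandibular_intermolar_width = 44.1, mandibular_arch_length = 32.8,
         overjet = 3.2, overbite = 2.2,
         molar_relationship_right = 0.6, molar_relationship_left = 0.5,
         stage = stage)
  }
}

## Small simulated AE dataset at the primary-stage sample size.
sim_gtd <- function(a2 = 0.85, c2 = 0, d2 = 0, n_mz = 90, n_dz = 98,
                    mean = 28.5, var = 2.1^2, seed = 1) {
  cfg <- twin_sim_config(n_pairs = c(MZF = n_mz, DZF = n_dz),
                         mean = mean, var = var,
                         a2 = a2, c2 = c2, d2 = d2, e2 = 1 - a2 - c2 - d2,
                         seed = seed)
  grouped_twin_data(simulate_twin_pairs(cfg))
}
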