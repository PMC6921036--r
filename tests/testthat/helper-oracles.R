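# Independent oracles used across tests.  Each deliberately takes a
# different computational route than the package implementation.

# PCA oracle: eigendecomposition of the correlation matrix of the raw table
# (the implementation uses SVD of the autoscaled matrix).
oracle_pca_scores <- function(x, k) {
  xs <- scale(x, center = TRUE, scale = TRUE)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  xs %*% eig$vectors[, seq_len(k), drop = FALSE]
}

# Helical-moment oracle: accumulate the complex sum H_n * exp(i n delta) and
# take its modulus.
oracle_moment <- function(h, delta_deg = 100) {
  ang <- seq_along(h) * delta_deg * pi / 180
  Mod(sum(h * exp(1i * ang)))
}

# Direct-formula classification metrics (plain arithmetic, no vectorized
# helper logic).
oracle_metrics <- function(tp, fn, tn, fp) {
  list(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    mcc = 100 * (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
}

# Forward-Euler integration of dC/dt = F*R0/V * 1(t <= Tinf) - k C.
oracle_euler_profile <- function(params, t_end, dt = 1e-4) {
  v <- params$vc_L_kg * params$body_weight_kg
  k <- params$clearance_L_h / v
  r0 <- params$dose_mg / params$infusion_h
  times <- seq(0, t_end, by = dt)
  conc <- numeric(length(times))
  for (i in seq_along(times)[-1]) {
    infusing <- times[i - 1] < params$infusion_h
    dcdt <- (if (infusing) params$f * r0 / v else 0) - k * conc[i - 1]
    conc[i] <- conc[i - 1] + dt * dcdt
  }
  list(times = times, conc = conc)
}

# z1 values typed directly off the packaged scale for hand summations.
Z1 <- c(A = -3.4535, R = 5.9227, N = 0.4104, D = 0.1502, C = -1.8132,
        Q = 2.5410, E = 1.4594, G = -3.2706, H = 1.4195, I = -1.3560,
        L = -1.5348, K = 2.7685, M = -0.0676, F = -0.0247, P = -3.3838,
        S = -1.6519, T = -1.3364, W = 1.7531, Y = 2.0819, V = -2.9262)

PEN <- "RQIKIWFQNRRMKWKK"
CYS_PEN <- "CRQIKIWFQNRRMKWKK"
PVEC <- "LLIILRRRIRKQAHAHSK"
CYS_PVEC <- "CLLIILRRRIRKQAHAHSK"

make_labeled_set <- function(pos, neg) {
  tibble::tibble(
    id = paste0("p", seq_len(length(pos) + length(neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(length(pos), length(neg)))
  )
}
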