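# Shared fixture builders: everything is generated in code at test time.

# A small registered pair with hand-placed class regions.
tiny_pair <- function(n = 8L, hu_in = -870, hu_ex = -780, spacing = c(1, 1, 1)) {
  paired_scan(
    ct_volume(array(hu_in, c(n, n, n)), spacing),
    ct_volume(array(hu_ex, c(n, n, n)), spacing),
    lung_mask(array(TRUE, c(n, n, n)), spacing))
}

# Random attenuation pair over plausible lung values (seeded by caller).
random_pair <- function(n = 8L) {
  paired_scan(
    ct_volume(array(runif(n^3, -1050, -700), c(n, n, n))),
    ct_volume(array(runif(n^3, -1000, -600), c(n, n, n))),
    lung_mask(array(runif(n^3) < 0.8, c(n, n, n)) |
                array(c(TRUE, rep(FALSE, n^3 - 1)), c(n, n, n))))
}

# Displacement field for the affine map x -> A x about the grid centre.
affine_field <- function(A, n = 12L, spacing = c(2, 1.5, 1)) {
  ctr <- (n - 1) / 2 * spacing
  ax <- lapply(1:3, function(k) (seq_len(n) - 1) * spacing[k] - ctr[k])
  X <- array(0, c(n, n, n, 3))
  X[, , , 1] <- ax[[1]]
  X[, , , 2] <- rep(ax[[2]], each = n)
  X[, , , 3] <- rep(ax[[3]], each = n * n)
  u <- array(0, c(n, n, n, 3))
  for (i in 1:3)
    u[, , , i] <- (A[i, 1] - (i == 1)) * X[, , , 1] +
      (A[i, 2] - (i == 2)) * X[, , , 2] +
      (A[i, 3] - (i == 3)) * X[, , , 3]
  displacement_field(u, spacing = spacing)
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Minimal network input with constant or supplied values.
const_input <- function(value, channels = 1L, label = "COPD",
                        id = "T001") {
  structure(list(values = array(value, c(channels, 32L, 32L, 32L)),
                 kind = "prm", id = id, label = label),
            class = "network_input")
}

# Trivially separable two-class toy set: constant high vs low intensity.
separable_inputs <- function(n_per_class = 10L) {
  c(lapply(seq_len(n_per_class), function(i)
      const_input(1.0, label = "COPD", id = sprintf("C%02d", i))),
    lapply(seq_len(n_per_class), function(i)
      const_input(0.125, label = "non-COPD", id = sprintf("N%02d", i))))
}

# Small phantom params for fast tests (same calibration, smaller grid).
fast_params <- function(...) phantom_params(shape = c(32L, 32L, 32L), ...)

# Brute-force concordant-pair AUC oracle (ties count half).
auc_pairs <- function(p, label) {
  pos <- p[label == "COPD"]; neg <- p[label != "COPD"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
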