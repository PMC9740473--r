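# Shared fixtures built in code; kept tiny so the default run stays fast.

fx_bead <- function() bead_structure(matrix(0, 1, 3), TRUE, 1, "atom")

fx_cloud <- function(n = 50, seed = 1) {
  set.seed(seed)
  bead_structure(matrix(rnorm(3 * n), n, 3), TRUE, runif(n, 0.5, 2), "cloud")
}

fx_random_config <- function(seed = 1, scale = 2) {
  set.seed(seed)
  config(rnorm(1, 0, scale), rnorm(1, 0, scale), rnorm(1, 0, scale),
         runif(1, -pi, pi), runif(1, -1.4, 1.4), runif(1, -pi, pi))
}

fx_random_pose <- function(seed = 1) {
  set.seed(seed)
  pose(rnorm(3), quat = as.numeric(random_quat(1)))
}

# Tiny 1D-like sample set on single beads: configs on the x axis.
fx_line_samples <- function(x, values, component = "A-B") {
  b <- fx_bead()
  sample_set(cbind(x, 0, 0, 0, 0, 0),
             matrix(values, ncol = 1, dimnames = list(NULL, component)),
             b, b)
}
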