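# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force confusion counts for the Dice
# score, and exhaustive sign-assignment enumeration for the Wilcoxon
# signed-rank null distribution.

dsc_brute <- function(a, b) {
  # confusion-count formulation for binary masks: 2TP / (2TP + FP + FN)
  tp <- sum(a == 1 & b == 1)
  fp <- sum(a == 0 & b == 1)
  fn <- sum(a == 1 & b == 0)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

wilcoxon_enum_p <- function(x, y) {
  # exact two-sided p by enumerating all 2^n sign assignments of |d|
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# small helpers for building label volumes by hand
lab_array <- function(codes, dim3 = NULL) {
  if (is.null(dim3)) {
    n <- ceiling(length(codes)^(1 / 3))
    dim3 <- c(n, n, n)
  }
  array(c(codes, rep(0L, prod(dim3) - length(codes))), dim3)
}

tiny_phantom_cfg <- function(...) {
  phantom_config(volume_shape = c(24, 24, 24), brain_radius = c(8, 10),
                 ncr_radius = c(1, 1.5), et_radius = c(2.5, 3.5),
                 ed_radius = c(4.5, 5.5), ...)
}

# one small cached case shared by model tests
fixture_case <- generate_case(tiny_phantom_cfg(), site_spec("FIX", 4),
                              seed = 404, case_id = "FIX_001")
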