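# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, exhaustive enumeration, and
# closed forms.

# per-voxel threshold scan: the segmentation oracle
oracle_threshold_mask <- function(values, threshold) {
  array(as.integer(values >= threshold), dim(values))
}

# exhaustive two-sided Fisher p: enumerate all 2x2 tables at fixed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs + 1e-12])
}

# exhaustive Mann-Whitney permutation p (all group relabelings via combn)
oracle_mwu_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  cmb <- utils::combn(n, nx)
  us <- apply(cmb, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# closed-form 2x2 Pearson chi-square
oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# random blob mask on a small grid (for Dice property tests)
random_mask <- function(dim3 = c(8, 8, 4), p = 0.3) {
  fet_mask(array(stats::runif(prod(dim3)) < p, dim3), spacing = c(2, 2, 2))
}

# small noiseless single-lesion phantom spec
tiny_phantom <- function(tbr = 2.5, seed = 1L, sd = 0) {
  phantom_spec(grid_shape = c(20, 20, 10), spacing = c(2, 2, 2),
               background_mean = 1, background_sd = sd,
               lesions = list(list(centre = c(6, 10, 5),
                                   semi_axes_mm = c(6, 6, 6),
                                   tbr = tbr, sd = sd)),
               seed = seed)
}
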