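# Independent brute-force oracles, coded directly from the defining
# formulas and kept free of any package internals.

# Two-sided signed-rank p by full enumeration of all 2^n sign assignments.
enumerate_wilcoxon_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Two-stage step-up rejection set, written step by step from the
# definition (stage 1 at q/(1+q); stage 2 at q' * m/(m - r1)).
brute_bky_reject <- function(p, q = 0.05) {
  m <- length(p)
  step_up <- function(level) {
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= level * i / m) k <- i
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  q1 <- q / (1 + q)
  s1 <- step_up(q1)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(q1 * m / (m - r1))
}

# Jensen-Shannon divergence, elementwise from the definition.
brute_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * log2(q[i] / m[i])
  }
  acc
}

# Small helper: noiseless, motion-free angiography fixture.
noiseless_angio <- function(h = 64, w = 64, n_frames = 60,
                            injection_frame = 10, leak_k = 0.05,
                            texture_sd = 0, seed = 42, ...) {
  gen_angiography(angio_sim_params(
    image_height = h, image_width = w, n_frames = n_frames,
    injection_frame = injection_frame, leak_k = leak_k,
    noise_sd = 0, texture_sd = texture_sd, seed = seed, ...))
}
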