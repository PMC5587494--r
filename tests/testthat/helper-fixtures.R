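# shared fixtures, built in code

# bivariate plasma table with a known ln-scale correlation structure
make_plasma <- function(n, rho = -0.46, sd1 = 0.5, sd2 = 0.35, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(bird_id = sprintf("P%03d", seq_len(n)),
             triglyceride = exp(1.17 + sd1 * z1) - 1,
             bohb = exp(0.96 + sd2 * z2) - 1,
             bleedtime = runif(n, 2, 15),
             daytime = runif(n, 60, 540),
             season = sample(90:130, n, replace = TRUE),
             year = sample(2008:2011, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# brute-force CJS history probability by enumerating latent presence
# sequences; independent of the package's chi-recursion
brute_cjs_prob <- function(history, phi1, phi2, p) {
  K <- length(history)
  stopifnot(history[1] == 1)
  total <- 0
  # d = last occasion the bird is present (d in 1..K)
  for (d in 1:K) {
    if (any(history[seq_len(K) > d] == 1)) next
    pr <- 1
    for (t in seq_len(K - 1)) {
      phi_t <- if (t == 1) phi1 else phi2
      if (t < d) pr <- pr * phi_t else if (t == d && d < K) pr <- pr * (1 - phi_t)
      if (t == d && d < K) break
    }
    # detection terms while present
    for (t in 2:K) {
      if (t <= d) pr <- pr * (if (history[t] == 1) p else 1 - p)
    }
    total <- total + pr
  }
  total
}

all_histories <- function(K) {
  tails <- expand.grid(rep(list(0:1), K - 1))
  H <- cbind(1, as.matrix(tails))
  colnames(H) <- paste0("occ", 1:K)
  H
}
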