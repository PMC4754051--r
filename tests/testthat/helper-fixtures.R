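# small builders shared across test files

tiny_ct <- function(ct, batch = "batch1") {
  ct_matrix(ct, batch)
}

# wells x genes matrix with named entries detected at the given Ct
ct_from_detected <- function(wells, genes, detected, ct = 20) {
  m <- matrix(cortid::CT_SENTINEL, length(wells), length(genes),
              dimnames = list(wells, genes))
  for (i in seq_len(nrow(detected))) {
    m[detected[i, 1], detected[i, 2]] <- ct
  }
  m
}

# a ct_matrix whose second chip is a +shift copy of the first
shifted_two_chip <- function(n_wells = 50, shift = 2, seed = 11) {
  cfg <- qpcr_sim_config(n_wells = n_wells, p_detect = 1,
                         batch_shifts = c(chipA = 0), seed = seed)
  sim <- simulate_qpcr(cfg)
  a <- sim$ct$ct
  b <- a
  nonsent <- b != cortid::CT_SENTINEL
  b[nonsent] <- b[nonsent] + shift
  rownames(b) <- paste0(rownames(b), "_B")
  ct_matrix(rbind(a, b), c(rep("chipA", nrow(a)), rep("chipB", nrow(b))))
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) {
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
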