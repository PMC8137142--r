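# Independent oracles used across the suite. Each is deliberately naive
# (enumeration / closed form / brute force) and shares no code path with
# the implementation it checks.

# exhaustive gated matching: enumerate every partial injective pairing
# with all distances <= gate; return max cardinality, then min total cost
brute_force_match <- function(pa, pb, gate) {
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0L || nb == 0L) return(list(cardinality = 0L, cost = 0))
  d <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
  best <- list(cardinality = 0L, cost = 0)
  recurse <- function(i, used_b, card, cost) {
    if (card > best$cardinality ||
        (card == best$cardinality && cost < best$cost))
      best <<- list(cardinality = card, cost = cost)
    if (i > na) return()
    recurse(i + 1L, used_b, card, cost)          # leave A_i unmatched
    for (j in seq_len(nb)) {
      if (used_b[j] || d[i, j] > gate) next
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, card + 1L, cost + d[i, j])
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nb), 0L, 0)
  best
}

# point-in-mask lookup, one spot at a time, direct triple indexing
assign_oracle <- function(spots, geometry) {
  vs <- geometry$voxel_size
  out <- rep(NA_integer_, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    vox <- floor(c(spots$z_um[i], spots$y_um[i], spots$x_um[i]) / vs)
    for (region in geometry$regions) {
      loc <- vox - region$offset + 1
      if (any(loc < 1) || any(loc > dim(region$cell))) next
      if (region$cell[loc[1], loc[2], loc[3]]) {
        out[i] <- region$cell_id
        break
      }
    }
  }
  out
}

# conditional two-sided exact p-value from the closed-form conditional
# law: for two independent NB(r_i, same p) counts summing to s, the
# conditional probability of k successes is a Polya (negative
# hypergeometric) mass computed directly from log-gamma functions.
nb_conditional_oracle <- function(a, b, phi, n_rep_a = 1, n_rep_b = 1) {
  s <- a + b
  if (s == 0) return(1)
  ra <- n_rep_a / phi; rb <- n_rep_b / phi
  k <- 0:s
  lm <- lgamma(k + ra) - lgamma(k + 1) - lgamma(ra) +
    lgamma(s - k + rb) - lgamma(s - k + 1) - lgamma(rb)
  pr <- exp(lm - max(lm)); pr <- pr / sum(pr)
  p_obs <- pr[a + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# textbook Welch t-test
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# match detected spots to true positions within a tolerance (greedy by
# nearest distance); returns recall/precision bookkeeping
match_to_truth <- function(detected, truth_um, tol_um) {
  if (nrow(detected) == 0L)
    return(list(tp = 0L, fp = 0L, fn = nrow(truth_um)))
  dpos <- as.matrix(detected[, c("z_um", "y_um", "x_um")])
  used <- rep(FALSE, nrow(truth_um))
  tp <- 0L
  for (i in seq_len(nrow(dpos))) {
    d <- sqrt(colSums((t(truth_um) - dpos[i, ])^2))
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(dpos) - tp, fn = nrow(truth_um) - tp)
}

# deterministic small-seed helper for parameterized loops
seeds_for <- function(n, base = 1000L) base + seq_len(n)
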