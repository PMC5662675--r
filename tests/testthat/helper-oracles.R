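# Independent reference implementations used as oracles. These are kept
# deliberately naive (loops, enumeration, dense grids) and separate from
# the package's own code paths.

# split-chain rank-normalized potential scale reduction, transcribed
# directly from the defining formulas with explicit loops
ref_split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2
  chains <- list()
  for (ch in seq_len(ncol(mat))) {
    chains[[length(chains) + 1]] <- mat[1:half, ch]
    chains[[length(chains) + 1]] <- mat[(n - half + 1):n, ch]
  }
  all_vals <- unlist(chains)
  r <- rank(all_vals, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(all_vals) + 1 / 4))
  zch <- split(z, rep(seq_along(chains), each = half))
  m <- length(zch); nn <- half
  means <- sapply(zch, mean)
  vars <- sapply(zch, var)
  W <- mean(vars)
  B <- nn * var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# brute-force total likelihood: product of Bernoulli masses, looped
ref_brute_loglik <- function(alpha, gamma, beta, responses) {
  total <- 0
  for (r in seq_len(nrow(responses))) {
    j <- responses$j[r]; k <- responses$item_id[r]
    p <- 1 / (1 + exp(-gamma[k] * (alpha[j] - beta[k])))
    total <- total + log(ifelse(responses$response[r] == 1, p, 1 - p))
  }
  total
}

# dense-grid quadrature for the J x K no-random-effect model with fixed
# discriminations and free (b0, beta_1, ..., beta_K). Exploits the
# factorization over items given b0: the posterior is
#   N(b0) prod_k [ sum_beta N(beta) f_k(b0 - beta) ]
# with f_k the item-k Bernoulli likelihood as a function of b0 - beta_k.
# Returns posterior means of b0 and each beta_k.
ref_grid_posterior <- function(successes, totals, gamma, b0_sd, beta_sd,
                               lim = 8, step = 0.02) {
  grid <- seq(-lim, lim, by = step)
  K <- length(successes)
  f <- function(k, t) {
    p <- plogis(gamma[k] * t)
    p^successes[k] * (1 - p)^(totals[k] - successes[k])
  }
  pb <- dnorm(grid, 0, beta_sd)
  # A[k, i] = sum_beta pb * f_k(b0_i - beta);  M[k, i] same with beta factor
  A <- matrix(NA_real_, K, length(grid))
  M <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    for (i in seq_along(grid)) {
      fk <- f(k, grid[i] - grid)
      A[k, i] <- sum(pb * fk)
      M[k, i] <- sum(pb * fk * grid)
    }
  }
  pb0 <- dnorm(grid, 0, b0_sd)
  joint_b0 <- pb0 * apply(A, 2, prod)
  norm <- sum(joint_b0)
  e_b0 <- sum(grid * joint_b0) / norm
  e_beta <- sapply(seq_len(K), function(k) {
    sum(pb0 * M[k, ] * apply(A[-k, , drop = FALSE], 2, prod)) / norm
  })
  list(b0 = e_b0, beta = e_beta)
}

# 1-d quadrature posterior mean of plogis(b0) for the Bernoulli reduction
ref_bernoulli_posterior_mean_p <- function(n_success, n_total, b0_sd,
                                           lim = 12, step = 0.005) {
  grid <- seq(-lim, lim, by = step)
  p <- plogis(grid)
  post <- dnorm(grid, 0, b0_sd) * p^n_success * (1 - p)^(n_total - n_success)
  sum(p * post) / sum(post)
}

# narrowest-window HPDI by full enumeration of contiguous windows
ref_enumerate_hpdi <- function(samples, mass) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- NULL; best_w <- Inf
  for (i in 1:(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best_w) { # strict: keeps the leftmost among ties
      best_w <- w
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# Monte-Carlo standard error of one parameter's posterior mean, from the
# package's ESS on its iteration-by-chain draw matrix
mcse_par <- function(fit, par) {
  m <- fit$draws[, , par]
  sd(as.vector(m)) / sqrt(max(1, compute_ess(m)))
}
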