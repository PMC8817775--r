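# Independent brute-force oracles and small fixtures used across the suite.

study_labels <- c("asc", "c_chw", "c_expert", "l_home", "s_phcall", "s_tvouch")

# Explicit-loop panel mixed-logit simulated log-likelihood:
# SLL = sum_i log( (1/R) sum_r prod_t P_it(chosen | mu + sigma * z_ir) ).
oracle_sll <- function(mu, sigma, data, Z) {
  R <- dim(Z)[1L]
  ids <- unique(data$respondent_id)
  ll <- 0
  for (i in seq_along(ids)) {
    di <- data[data$respondent_id == ids[i], , drop = FALSE]
    Xi <- as.matrix(di[, names(mu), drop = FALSE])
    psum <- 0
    for (r in seq_len(R)) {
      b <- mu
      b[names(sigma)] <- b[names(sigma)] + sigma * Z[r, , i]
      prod_t <- 1
      for (tt in unique(di$task_id)) {
        rows <- which(di$task_id == tt)
        u <- drop(Xi[rows, , drop = FALSE] %*% b)
        p <- exp(u) / sum(exp(u))
        prod_t <- prod_t * p[di$chosen[rows] == 1]
      }
      psum <- psum + prod_t
    }
    ll <- ll + log(psum / R)
  }
  unname(ll)
}

# Explicit-summation multinomial-logit information matrix at zero priors
# over the K indicator columns (opt-out utility 0, all alternatives equally
# likely at the utility-neutral point).
oracle_information <- function(design) {
  X <- design_matrix(design)
  Xi <- X[, -1L, drop = FALSE]
  task <- attr(X, "task_id")
  K <- ncol(Xi)
  info <- matrix(0, K, K)
  for (tt in unique(task)) {
    rows <- which(task == tt)
    J <- length(rows)
    p <- rep(1 / J, J)
    for (a in seq_len(J)) {
      info <- info + p[a] * tcrossprod(Xi[rows[a], ])
    }
    xbar <- colSums(Xi[rows, , drop = FALSE] * p)
    info <- info - tcrossprod(xbar)
  }
  info
}

# A two-attribute scheme for small examples.
toy_scheme <- function() {
  attribute_scheme(list(price = c("low", "high"),
                        brand = c("A", "B", "C")))
}

# Fixed-coefficient study population (sigma = 0 everywhere).
fixed_population <- function(mu = c(0.52, 1.13, 0.89, 1.25, 0.70, 1.35)) {
  population_preferences(mu, rep(0, 6), labels = study_labels)
}
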