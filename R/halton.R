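#' Halton low-discrepancy sequence
#'
#' Radical-inverse (van der Corput) sequence in a prime base: element `i` is
#' obtained by writing `i` in base `base` and mirroring its digits about the
#' radix point. Returns elements `burn_in + 1` through `burn_in + n`; all
#' values lie strictly inside (0, 1).
#'
#' @param base Prime base (>= 2).
#' @param n Number of sequence elements.
#' @param burn_in Number of initial elements to discard (default 0).
#' @return Numeric vector of length `n`.
#' @examples
#' halton(2, 4)  # 1/2, 1/4, 3/4, 1/8
#' @export
halton <- function(base, n, burn_in = 0) {
  base <- as.integer(base)
  if (length(base) != 1L || is.na(base) || base < 2L || !is_prime(base))
    stop("'base' must be a prime number")
  stopifnot(n >= 1, burn_in >= 0)
  i <- (burn_in + 1):(burn_in + n)
  out <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0L)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

is_prime <- function(x) {
  if (x < 2L) return(FALSE)
  if (x < 4L) return(TRUE)
  if (x %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= x) {
    if (x %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

halton_primes <- function(k) {
  p <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L,
         47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L)
  if (k > length(p)) stop("at most ", length(p), " Halton dimensions supported")
  p[seq_len(k)]
}

#' Halton-based standard-normal draws for simulated likelihood
#'
#' Generates the quasi-random draws used to simulate the mixing integral of
#' the mixed logit: per random coefficient one Halton sequence (bases taken
#' from the first primes, in coefficient order), mapped through the standard
#' normal inverse CDF. Respondent `i` receives the `i`-th contiguous block of
#' `n_draws` values of each dimension. Entirely deterministic: no RNG is
#' consumed.
#'
#' @param n_resp Number of respondents.
#' @param n_dim Number of random coefficients.
#' @param n_draws Draws per respondent (default 1000).
#' @param burn_in Initial Halton elements discarded per dimension
#'   (default 10).
#' @param primes Optional prime bases, one per dimension; defaults to the
#'   first `n_dim` primes (2, 3, 5, 7, 11, ...).
#' @return Numeric array of dimension `c(n_draws, n_dim, n_resp)`.
#' @export
halton_normal_draws <- function(n_resp, n_dim, n_draws = 1000, burn_in = 10,
                                primes = NULL) {
  stopifnot(n_resp >= 1, n_dim >= 1, n_draws >= 1, burn_in >= 0)
  if (is.null(primes)) primes <- halton_primes(n_dim)
  if (length(primes) < n_dim)
    stop("more random dimensions (", n_dim, ") than configured primes (",
         length(primes), ")")
  if (anyDuplicated(primes)) stop("'primes' must be distinct")
  z <- array(0, dim = c(n_draws, n_dim, n_resp))
  for (d in seq_len(n_dim)) {
    u <- halton(primes[d], n_resp * n_draws, burn_in = burn_in)
    z[, d, ] <- qnorm(u)
  }
  attr(z, "primes") <- primes[seq_len(n_dim)]
  attr(z, "burn_in") <- burn_in
  z
}
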