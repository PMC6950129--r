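# Independent oracles and generators used across the suite. These stay free
# of the code paths they check: conversions are done with bare arithmetic.

# Random positive ratio triple in a given parameterization, near natural lead.
random_ratios <- function(param = "ref204") {
  base <- switch(param,
    ref204 = c(37.5, 15.5, 17.9),
    chain204 = c(0.058, 1.17, 0.417)
  )
  r <- base * exp(stats::rnorm(3, sd = 0.03))
  ratio_triple(r[1], r[2], r[3], param = param)
}

# Abundance oracle for ref204 ratios (r208, r207, r206): plain normalization.
oracle_abundance_ref204 <- function(r208, r207, r206) {
  v <- c(1, r206, r207, r208)
  v / sum(v)
}

# Build a fingerprint directly from abundances (x208 implied).
fp_from_abundances <- function(x204, x206, x207) {
  x208 <- 1 - x204 - x206 - x207
  ratios_from_abundances(abundance_vector(x204, x206, x207, x208), "ref204")
}

# Uniform draw from the n-simplex.
random_simplex <- function(n) {
  g <- stats::rgamma(n, 1, 1)
  g / sum(g)
}

# Cramer's-rule solve of the 3x3 Gobeil system; independent of solve().
cramer_gobeil <- function(R, N, Rs, Ns) {
  det3 <- function(M) {
    M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  }
  A <- rbind(R, N, c(1, 1, 1))
  b <- c(Rs, Ns, 1)
  d <- det3(A)
  vapply(1:3, function(j) {
    Aj <- A
    Aj[, j] <- b
    det3(Aj) / d
  }, numeric(1))
}

# Well-posed random mixing instance: a source set whose reduced design is not
# nearly collinear. In double precision the forward error of any exact solver
# is of order condition x machine-eps, so exact-agreement properties are only
# meaningful below a conditioning ceiling; 1e4 leaves an order of magnitude of
# headroom against the 1e-10 agreement bound.
well_posed_sources <- function(n, seed) {
  repeat {
    s <- generate_sources(n, seed = seed)
    M <- s$abundances[, -n, drop = FALSE] - s$abundances[, n]
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[1] / sv[length(sv)] < 1e4) return(s)
    seed <- seed + 1000000L
  }
}

# Well-posed Gobeil instance: reject nearly collinear (R, N) triples, for the
# same conditioning reason (ceiling 2e3 against the 1e-12 agreement bound).
random_gobeil_RN <- function() {
  repeat {
    R <- stats::runif(3, 1.1, 1.3)
    N <- stats::runif(3, 1.9, 2.2)
    if (kappa(rbind(R, N, 1), exact = TRUE) < 2e3) return(list(R = R, N = N))
  }
}

# Case-study fixtures, loaded once.
gz_table <- guanzhong_survey()
gz_sources <- table_sources(gz_table)
gz_samples <- table_samples(gz_table)
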