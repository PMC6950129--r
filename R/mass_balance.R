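#' Define a set of end-member pollution sources
#'
#' Bundles the named isotope fingerprints of the candidate lead pollution
#' sources (end-members). Sources must be pairwise distinct in abundance
#' space: two identical fingerprints make the mixing problem degenerate.
#'
#' @param fingerprints A list of [ratio_triple()] fingerprints, one per
#'   source. Names of the list (or `names`) label the sources.
#' @param names Optional character vector of unique source names; defaults
#'   to the list names or `source1`, `source2`, ...
#' @return An object of class `"pb_sources"`: list with elements `names`,
#'   `fingerprints` and the 4 x n abundance matrix `abundances` (rows are
#'   isotopes 204/206/207/208, columns are sources).
#' @examples
#' s <- source_set(list(
#'   coal = ratio_triple(37.27, 15.59, 17.07),
#'   ore  = ratio_triple(38.64, 15.95, 18.40)
#' ))
#' s
#' @export
source_set <- function(fingerprints, names = NULL) {
  if (!is.list(fingerprints) || length(fingerprints) < 2L) {
    stop_pb("pb_validation_error", "need a list of at least 2 source fingerprints")
  }
  if (is.null(names)) names <- base::names(fingerprints)
  if (is.null(names)) names <- paste0("source", seq_along(fingerprints))
  if (anyDuplicated(names) || any(!nzchar(names))) {
    stop_pb("pb_validation_error", "source names must be unique and non-empty")
  }
  fingerprints <- lapply(fingerprints, as_pb_ratio)
  X <- vapply(fingerprints, function(fp) as.numeric(abundances_from_ratios(fp)),
              numeric(4L))
  dimnames(X) <- list(PB_ISOTOPES, names)
  n <- ncol(X)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (max(abs(X[, i] - X[, j])) < 1e-10) {
        stop_pb("pb_degenerate_error", sprintf(
          "sources '%s' and '%s' have indistinguishable fingerprints (within 1e-10)",
          names[i], names[j]))
      }
    }
  }
  structure(list(names = names, fingerprints = stats::setNames(fingerprints, names),
                 abundances = X),
            class = "pb_sources")
}

#' @export
print.pb_sources <- function(x, ...) {
  cat(sprintf("<pb_sources> %d end-members\n", length(x$names)))
  print(round(t(x$abundances), 6))
  invisible(x)
}

#' @export
length.pb_sources <- function(x) length(x$names)

#' Define a contaminated mixture sample
#'
#' A measured sample whose lead is assumed to be a mixture of the
#' end-members in a [source_set()]. Total lead concentration is carried as
#' metadata only; the apportionment depends solely on the fingerprint.
#'
#' @param fingerprint A [ratio_triple()].
#' @param id Sample label.
#' @param concentration Optional total lead concentration (ppm), `>= 0`.
#' @param total_mass Total lead mass `m` of the sample; defaults to 1 and
#'   cancels from all contribution fractions.
#' @return An object of class `"pb_sample"`.
#' @export
mixture_sample <- function(fingerprint, id = "sample", concentration = NULL,
                           total_mass = 1) {
  fingerprint <- as_pb_ratio(fingerprint)
  if (!is.null(concentration)) {
    if (!is.numeric(concentration) || length(concentration) != 1L ||
        !is.finite(concentration) || concentration < 0) {
      stop_pb("pb_validation_error", "concentration must be a non-negative number")
    }
  }
  if (!is.numeric(total_mass) || length(total_mass) != 1L ||
      !is.finite(total_mass) || total_mass <= 0) {
    stop_pb("pb_validation_error", "total_mass must be a positive number")
  }
  structure(list(id = as.character(id), fingerprint = fingerprint,
                 concentration = concentration, total_mass = total_mass),
            class = "pb_sample")
}

#' @export
print.pb_sample <- function(x, ...) {
  cat(sprintf("<pb_sample> %s\n", x$id))
  print(x$fingerprint)
  if (!is.null(x$concentration)) cat(sprintf("  concentration: %g ppm\n", x$concentration))
  invisible(x)
}

#' Equation-versus-unknown analysis of the mass-balance system
#'
#' For n sources the mass-balance formulation has 5n unknowns (four isotope
#' masses plus one contribution fraction per source) and 4n + 4 equations
#' (one mass-sum and three ratio equations per source, three mixture-ratio
#' equations, and the normalization of the fractions). The system is
#' solvable while unknowns do not exceed equations, i.e. up to n = 4; at
#' n = 4 it is exactly determined, and for n >= 5 the fractions are not
#' identifiable from lead isotopes alone.
#'
#' @param n Number of candidate sources, integer `>= 2`.
#' @return An object of class `"pb_sysdim"`: list with `n_sources`,
#'   `n_unknowns` (= 5n), `n_equations` (= 4n + 4), `solvable` and
#'   `identifiable` (both `n <= 4`).
#' @examples
#' system_dimensions(4)
#' @export
system_dimensions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n) || n < 2) {
    stop_pb("pb_validation_error", "n must be an integer >= 2")
  }
  n <- as.integer(n)
  structure(list(
    n_sources = n,
    n_unknowns = 5L * n,
    n_equations = 4L * n + 4L,
    solvable = n <= 4L,
    identifiable = n <= 4L
  ), class = "pb_sysdim")
}

#' @export
print.pb_sysdim <- function(x, ...) {
  cat(sprintf(
    "<pb_sysdim> %d sources: %d unknowns, %d equations -> %s\n",
    x$n_sources, x$n_unknowns, x$n_equations,
    if (x$solvable) "solvable (identifiable)" else "NOT solvable (unidentifiable)"))
  invisible(x)
}

# Guard shared by the solvers: refuse configurations the dimension analysis
# rules out, citing the counts.
check_identifiable <- function(n) {
  dims <- system_dimensions(n)
  if (!dims$solvable) {
    stop_pb("pb_unidentifiable_error", sprintf(
      paste0("%d sources give %d unknowns but only %d equations; ",
             "contribution fractions are not identifiable from lead isotopes ",
             "alone for more than 4 sources"),
      n, dims$n_unknowns, dims$n_equations))
  }
  invisible(dims)
}

# Reduced design: eliminate per-source masses; the system collapses to
# abundance mixing  sum_i f_i x^(i) = x^(mix)  with  sum_i f_i = 1.
# The normalization is enforced exactly by substituting f_n = 1 - sum(f_-n);
# the remaining 4 x (n-1) system is solved by least squares (exact when the
# data are consistent).
solve_reduced <- function(X, p, source_names) {
  n <- ncol(X)
  M <- X[, -n, drop = FALSE] - X[, n]
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-12 * sv[1L]) {
    stop_pb("pb_degenerate_error",
            "source fingerprints are collinear in abundance space; the reduced design matrix is rank deficient")
  }
  cond <- sv[1L] / sv[length(sv)]
  if (cond > 1e10) {
    warning(sprintf(
      "reduced design matrix is ill-conditioned (condition number %.3g); fractions are poorly determined",
      cond), call. = FALSE)
  }
  dqr <- qr(M)
  rhs <- p - X[, n]
  g <- qr.coef(dqr, rhs)
  # one refinement step tightens the least-squares solution on
  # poorly-conditioned (nearly collinear) source sets
  g <- g + qr.coef(dqr, rhs - M %*% g)
  f <- c(g, 1 - sum(g))
  names(f) <- source_names
  list(fractions = f, condition_number = cond,
       residuals = stats::setNames(as.numeric(p - X %*% f), PB_ISOTOPES))
}

#' Apportion a sample's lead among sources by mass balance
#'
#' Solves the mass-balance mixing system for the contribution fraction of
#' each source: the sample's isotope abundance vector is expressed as the
#' fraction-weighted sum of the source abundance vectors, subject to the
#' fractions summing to 1. After eliminating the per-source isotope masses
#' the system reduces to four isotope-balance equations in the fractions;
#' the normalization is enforced exactly and the balance equations are
#' solved by least squares, which coincides with the exact solution whenever
#' the sample is a true mixture of the sources. Fractions are
#' sign-unrestricted: a negative fraction signals lead from sources outside
#' the candidate set and is flagged, not clipped.
#'
#' @param sources A [source_set()] of 2 to 4 end-members.
#' @param sample A [mixture_sample()] (or a bare [ratio_triple()]).
#' @param nonnegative If `TRUE`, additionally computes a non-negative
#'   constrained fit (beyond the plain mass-balance model) and returns it in
#'   the `nonnegative_fractions` field; the primary `fractions` stay
#'   unconstrained.
#' @return An object of class `"pb_apportion"`: list with `fractions`
#'   (named, summing to 1), `residuals` (per-isotope balance residuals),
#'   `condition_number` of the reduced design matrix, `negative_flags`,
#'   `method`, `sample_id`, and optionally `nonnegative_fractions`.
#' @examples
#' s <- source_set(list(a = ratio_triple(37.27, 15.59, 17.07),
#'                      b = ratio_triple(38.64, 15.95, 18.40)))
#' mix <- forward_mix(s, c(0.3, 0.7))
#' solve_mass_balance(s, mix)
#' @export
solve_mass_balance <- function(sources, sample, nonnegative = FALSE) {
  if (!inherits(sources, "pb_sources")) {
    stop_pb("pb_validation_error", "sources must be a source_set()")
  }
  if (inherits(sample, "pb_ratio")) sample <- mixture_sample(sample)
  if (!inherits(sample, "pb_sample")) {
    stop_pb("pb_validation_error", "sample must be a mixture_sample() or ratio_triple()")
  }
  n <- length(sources)
  check_identifiable(n)
  X <- sources$abundances
  p <- as.numeric(abundances_from_ratios(sample$fingerprint))
  sol <- solve_reduced(X, p, sources$names)
  res <- structure(list(
    fractions = sol$fractions,
    residuals = sol$residuals,
    condition_number = sol$condition_number,
    negative_flags = sol$fractions < 0,
    method = "mass_balance_reduced",
    sample_id = sample$id
  ), class = "pb_apportion")
  if (isTRUE(nonnegative)) {
    res$nonnegative_fractions <- nonnegative_fractions(X, p, sources$names)
  }
  res
}

# Beyond the plain model: non-negative fit via NNLS on the isotope-balance
# rows with a heavily weighted normalization row, then renormalized. Not the
# mass-balance solution when the unconstrained fractions are negative.
nonnegative_fractions <- function(X, p, source_names) {
  w <- 1e6
  A <- rbind(X, rep(w, ncol(X)))
  b <- c(p, w)
  f <- pracma::lsqnonneg(A, b)$x
  s <- sum(f)
  if (s > 0) f <- f / s
  stats::setNames(f, source_names)
}

#' @export
print.pb_apportion <- function(x, ...) {
  cat(sprintf("<pb_apportion> sample '%s' (%s)\n", x$sample_id, x$method))
  pf <- sprintf("%+.2f%%", 100 * x$fractions)
  flg <- ifelse(x$negative_flags, " [negative]", "")
  cat(paste0("  ", format(names(x$fractions)), "  ", pf, flg, collapse = "\n"), "\n")
  cat(sprintf("  residual norm %.3g, condition number %.3g\n",
              sqrt(sum(x$residuals^2)), x$condition_number))
  invisible(x)
}

#' Solve the full mass-balance system with per-source isotope masses
#'
#' Independently coded companion to [solve_mass_balance()]: instead of
#' eliminating the per-source isotope masses, it assembles and solves the
#' literal linear system in all 5n unknowns (four isotope masses and one
#' fraction per source). The 4n + 4 equations are: per source, the mass sum
#' defining its fraction and the three chained ratio constraints fixing its
#' internal isotope proportions; the three mixture-ratio constraints tying
#' the summed masses to the sample fingerprint; and the normalization of the
#' fractions. Solved by least squares on the stacked system (exact for
#' consistent data).
#'
#' @inheritParams solve_mass_balance
#' @return An object of class `"pb_full_solution"`: list with `masses`
#'   (n x 4 matrix of per-source isotope masses, rows named by source),
#'   `fractions`, `total_mass`, and `max_equation_residual`.
#' @export
solve_full_system <- function(sources, sample) {
  if (!inherits(sources, "pb_sources")) {
    stop_pb("pb_validation_error", "sources must be a source_set()")
  }
  if (inherits(sample, "pb_ratio")) sample <- mixture_sample(sample)
  n <- length(sources)
  check_identifiable(n)
  m_total <- sample$total_mass
  # unknown vector z = (m_1^204, m_1^206, m_1^207, m_1^208, ..., f_1..f_n)
  n_unk <- 5L * n
  n_eq <- 4L * n + 4L
  A <- matrix(0, n_eq, n_unk)
  b <- numeric(n_eq)
  midx <- function(i) (i - 1L) * 4L + 1:4 # mass columns of source i
  fidx <- 4L * n + seq_len(n)             # fraction columns
  row <- 0L
  for (i in seq_len(n)) {
    # f_i * m = m_i^204 + m_i^206 + m_i^207 + m_i^208
    row <- row + 1L
    A[row, fidx[i]] <- m_total
    A[row, midx(i)] <- -1
    # chained ratio constraints of source i's fingerprint
    k <- as.numeric(convert_ratios(sources$fingerprints[[i]], "chain204"))
    mi <- midx(i)
    row <- row + 1L; A[row, mi[1L]] <- 1; A[row, mi[2L]] <- -k[1L]
    row <- row + 1L; A[row, mi[2L]] <- 1; A[row, mi[3L]] <- -k[2L]
    row <- row + 1L; A[row, mi[3L]] <- 1; A[row, mi[4L]] <- -k[3L]
  }
  # mixture-ratio constraints from the sample fingerprint
  kp <- as.numeric(convert_ratios(sample$fingerprint, "chain204"))
  for (j in 1:3) {
    row <- row + 1L
    for (i in seq_len(n)) {
      mi <- midx(i)
      A[row, mi[j]] <- 1
      A[row, mi[j + 1L]] <- -kp[j]
    }
  }
  # normalization of fractions
  row <- row + 1L
  A[row, fidx] <- 1
  b[row] <- 1
  # column equilibration: the mass unknowns (e.g. m^204 ~ 0.01) and fraction
  # unknowns live on different scales; scaling columns to unit norm keeps the
  # least-squares solve near the conditioning of the underlying mixing problem
  cs <- sqrt(colSums(A^2))
  As <- sweep(A, 2L, cs, "/")
  z <- qr.coef(qr(As, LAPACK = TRUE), b) / cs
  if (anyNA(z)) {
    stop_pb("pb_degenerate_error",
            "full mass-balance system is rank deficient (collinear source fingerprints)")
  }
  # one step of iterative refinement against the unscaled system
  r <- b - A %*% z
  dz <- tryCatch(qr.coef(qr(As, LAPACK = TRUE), as.numeric(r)) / cs,
                 error = function(e) NULL)
  if (!is.null(dz) && !anyNA(dz)) z <- z + dz
  masses <- matrix(z[seq_len(4L * n)], nrow = n, ncol = 4L, byrow = TRUE,
                   dimnames = list(sources$names, c("m204", "m206", "m207", "m208")))
  fractions <- stats::setNames(z[fidx], sources$names)
  structure(list(masses = masses, fractions = fractions, total_mass = m_total,
                 max_equation_residual = max(abs(A %*% z - b))),
            class = "pb_full_solution")
}

#' @export
print.pb_full_solution <- function(x, ...) {
  cat(sprintf("<pb_full_solution> total mass %g\n", x$total_mass))
  print(round(cbind(x$masses, fraction = x$fractions), 6))
  cat(sprintf("  max equation residual %.3g\n", x$max_equation_residual))
  invisible(x)
}

#' Closed-form two-source apportionment
#'
#' Implements the printed closed-form solution of the two-source
#' mass-balance system. With the chained ratios k1..k3 of source A, k4..k6
#' of source B and k7..k9 of the sample (each triple being
#' 204Pb/206Pb, 206Pb/207Pb, 207Pb/208Pb), the contribution of A is
#' \deqn{f_A = \frac{(k_1k_2k_3+k_2k_3+k_3+1)(k_7k_8k_9-k_4k_5k_6)}
#'  {(k_1k_2k_3+k_2k_3+k_3+1)(k_7k_8k_9-k_4k_5k_6)+(k_4k_5k_6+k_5k_6+k_6+1)(k_1k_2k_3-k_7k_8k_9)}}
#' and \eqn{f_B = 1 - f_A} by construction.
#'
#' @param fa,fb Fingerprints ([ratio_triple()]) of the two sources.
#' @param fp Fingerprint of the mixture sample.
#' @return Named numeric `c(fA = ..., fB = ...)`, summing to 1 exactly.
#' @examples
#' a <- ratio_triple(37.27, 15.59, 17.07); b <- ratio_triple(38.64, 15.95, 18.40)
#' mix <- forward_mix(source_set(list(A = a, B = b)), c(0.3, 0.7))
#' solve_two_source_closed_form(a, b, mix$fingerprint)
#' @export
solve_two_source_closed_form <- function(fa, fb, fp) {
  ka <- as.numeric(convert_ratios(as_pb_ratio(fa), "chain204"))
  kb <- as.numeric(convert_ratios(as_pb_ratio(fb), "chain204"))
  kp <- as.numeric(convert_ratios(as_pb_ratio(fp), "chain204"))
  pa <- ka[1L] * ka[2L] * ka[3L] # = x204/x208 of A
  pb <- kb[1L] * kb[2L] * kb[3L]
  pp <- kp[1L] * kp[2L] * kp[3L]
  if (abs(pa - pb) <= 1e-14 * max(abs(pa), abs(pb))) {
    stop_pb("pb_unidentifiable_error",
            "sources have identical 204Pb/208Pb products (k1*k2*k3 = k4*k5*k6); the two-source closed form divides by zero")
  }
  ca <- pa + ka[2L] * ka[3L] + ka[3L] + 1
  cb <- pb + kb[2L] * kb[3L] + kb[3L] + 1
  num_a <- ca * (pp - pb)
  num_b <- cb * (pa - pp)
  den <- num_a + num_b
  if (den == 0) {
    stop_pb("pb_unidentifiable_error", "closed-form denominator is zero")
  }
  fA <- num_a / den
  c(fA = fA, fB = 1 - fA)
}

#' Apportion a batch of samples against one source set
#'
#' Runs [solve_mass_balance()] for every sample, collecting per-sample
#' failures instead of aborting the batch, and summarizes mean contribution
#' fractions over the samples that pass the validity filter (all fractions
#' non-negative and no solver error).
#'
#' @param sources A [source_set()].
#' @param samples A list of [mixture_sample()] objects.
#' @return A data frame of class `"pb_batch"` with one row per sample:
#'   `sample_id`, one fraction column per source, `negative` (any negative
#'   fraction), `residual_norm`, `condition_number`, `error` (NA or the
#'   failure message). Attributes: `summary` (mean fractions over valid
#'   samples, or NULL if none), `n_valid`, `source_names`.
#' @export
batch_apportion <- function(sources, samples) {
  if (!inherits(sources, "pb_sources")) {
    stop_pb("pb_validation_error", "sources must be a source_set()")
  }
  if (inherits(samples, "pb_sample")) samples <- list(samples)
  nsrc <- length(sources)
  rows <- lapply(samples, function(s) {
    r <- tryCatch(solve_mass_balance(sources, s), error = function(e) e)
    if (inherits(r, "error")) {
      cbind(data.frame(sample_id = if (inherits(s, "pb_sample")) s$id else NA_character_,
                       stringsAsFactors = FALSE),
            stats::setNames(as.data.frame(as.list(rep(NA_real_, nsrc))), sources$names),
            data.frame(negative = NA, residual_norm = NA_real_,
                       condition_number = NA_real_,
                       error = conditionMessage(r), stringsAsFactors = FALSE))
    } else {
      cbind(data.frame(sample_id = r$sample_id, stringsAsFactors = FALSE),
            stats::setNames(as.data.frame(as.list(unname(r$fractions))), sources$names),
            data.frame(negative = any(r$negative_flags),
                       residual_norm = sqrt(sum(r$residuals^2)),
                       condition_number = r$condition_number,
                       error = NA_character_, stringsAsFactors = FALSE))
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cbind(data.frame(sample_id = character(0)),
          stats::setNames(as.data.frame(replicate(nsrc, numeric(0), simplify = FALSE)),
                          sources$names),
          data.frame(negative = logical(0), residual_norm = numeric(0),
                     condition_number = numeric(0), error = character(0)))
  }
  valid <- !is.na(out$negative) & !out$negative & is.na(out$error)
  summary_row <- if (any(valid)) {
    colMeans(out[valid, sources$names, drop = FALSE])
  } else NULL
  structure(out, summary = summary_row, n_valid = sum(valid),
            source_names = sources$names, class = c("pb_batch", "data.frame"))
}

#' @export
print.pb_batch <- function(x, ...) {
  cat(sprintf("<pb_batch> %d samples, %d valid (no negative fraction)\n",
              nrow(x), attr(x, "n_valid")))
  print(as.data.frame(x), ...)
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("mean fractions over valid samples:\n")
    print(round(s, 4))
  }
  invisible(x)
}
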