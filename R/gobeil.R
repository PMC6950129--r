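#' Gobeil ratio fingerprint
#'
#' The classical ratio-balance model characterizes a source or sample by the
#' pair R = 206Pb/207Pb and N = 208Pb/206Pb only.
#'
#' @param R 206Pb/207Pb ratio, strictly positive and finite.
#' @param N 208Pb/206Pb ratio, strictly positive and finite.
#' @return Named numeric of class `"pb_gobeil"`.
#' @export
gobeil_fingerprint <- function(R, N) {
  for (v in list(R = R, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_pb("pb_validation_error", "R and N must be strictly positive finite numbers")
    }
  }
  structure(c(R = as.numeric(R), N = as.numeric(N)), class = "pb_gobeil")
}

as_pb_gobeil <- function(x) {
  if (inherits(x, "pb_gobeil")) return(x)
  if (inherits(x, "pb_ratio") || inherits(x, "pb_abundance")) {
    g <- gobeil_projection(x)
    return(gobeil_fingerprint(g[["R"]], g[["N"]]))
  }
  if (is.numeric(x) && length(x) == 2L) return(gobeil_fingerprint(x[[1L]], x[[2L]]))
  stop_pb("pb_validation_error", "cannot interpret input as a Gobeil (R, N) fingerprint")
}

#' Solve the classical three-source Gobeil ratio-balance model
#'
#' The Gobeil model treats the sample's ratio pair as the fraction-weighted
#' average of the sources' ratio pairs:
#' \deqn{R_s = f_1 R_1 + f_2 R_2 + f_3 R_3, \quad
#'       N_s = f_1 N_1 + f_2 N_2 + f_3 N_3, \quad f_1 + f_2 + f_3 = 1.}
#' This balances the *ratios* directly rather than the isotope masses; it is
#' exact only under special conditions (see [compare_models()]). The 3 x 3
#' linear system is solved exactly; fractions may be negative.
#'
#' @param sources A list of exactly three Gobeil fingerprints (anything
#'   [gobeil_fingerprint()]-coercible, e.g. [ratio_triple()] objects or a
#'   3-source [source_set()]).
#' @param sample The sample's Gobeil fingerprint (same coercions).
#' @return Named numeric fractions `(f1, f2, f3)` summing to 1.
#' @export
solve_gobeil <- function(sources, sample) {
  if (inherits(sources, "pb_sources")) sources <- sources$fingerprints
  if (!is.list(sources) || length(sources) != 3L) {
    stop_pb("pb_validation_error", "the Gobeil model takes exactly three sources")
  }
  G <- vapply(sources, function(s) as.numeric(as_pb_gobeil(s)), numeric(2L))
  gs <- as.numeric(as_pb_gobeil(sample))
  A <- rbind(G[1L, ], G[2L, ], c(1, 1, 1))
  if (abs(det(A)) < 1e-12 * max(abs(A))^3) {
    stop_pb("pb_unidentifiable_error",
            "source (R, N) fingerprints are collinear; the Gobeil system is singular")
  }
  f <- solve(A, c(gs, 1))
  nm <- names(sources)
  if (is.null(nm)) nm <- paste0("f", 1:3)
  stats::setNames(f, nm)
}

#' Compare the mass-balance and Gobeil models on a known mixture
#'
#' Builds a mixture from three sources with known contribution fractions
#' using the mass-balance forward model (isotope masses add), then solves
#' for the fractions with both models. The mass-balance solver recovers the
#' truth by construction; the deviation of the Gobeil solution
#' operationalizes the critique that ratio balance is not mass balance.
#' The Gobeil model is exact on such mixtures only when the sources share
#' the same 206Pb abundance (then the ratio weights coincide with the mass
#' weights); its deviation grows with the spread of the sources' 206Pb
#' abundances.
#'
#' @param sources A [source_set()] of exactly three end-members.
#' @param true_fractions Numeric length-3 simplex point (non-negative,
#'   summing to 1 within 1e-8).
#' @return A list of class `"pb_model_comparison"`: `true_fractions`,
#'   `mass_balance` and `gobeil` fraction vectors, per-source signed
#'   `gobeil_deviation` (gobeil - true) and `max_abs_deviation`.
#' @export
compare_models <- function(sources, true_fractions) {
  if (!inherits(sources, "pb_sources") || length(sources) != 3L) {
    stop_pb("pb_validation_error", "sources must be a source_set() of exactly 3 end-members")
  }
  f <- as.numeric(true_fractions)
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop_pb("pb_validation_error", "true_fractions must be a length-3 point on the simplex")
  }
  mix <- forward_mix(sources, f)
  f_mb <- solve_mass_balance(sources, mix)$fractions
  f_g <- solve_gobeil(sources$fingerprints, mix$fingerprint)
  dev <- as.numeric(f_g) - f
  structure(list(
    true_fractions = stats::setNames(f, sources$names),
    mass_balance = f_mb,
    gobeil = stats::setNames(as.numeric(f_g), sources$names),
    gobeil_deviation = stats::setNames(dev, sources$names),
    max_abs_deviation = max(abs(dev))
  ), class = "pb_model_comparison")
}

#' @export
print.pb_model_comparison <- function(x, ...) {
  cat("<pb_model_comparison>\n")
  tab <- rbind(true = x$true_fractions, mass_balance = x$mass_balance,
               gobeil = x$gobeil, gobeil_deviation = x$gobeil_deviation)
  print(round(tab, 6))
  cat(sprintf("max |gobeil - true| = %.6g\n", x$max_abs_deviation))
  invisible(x)
}
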