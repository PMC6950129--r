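# Supported ratio parameterizations of a lead fingerprint.
# ref204:   (208Pb/204Pb, 207Pb/204Pb, 206Pb/204Pb)  -- all ratios to 204Pb
# chain204: (204Pb/206Pb, 206Pb/207Pb, 207Pb/208Pb)  -- a chain down the masses
PB_PARAMS <- c("ref204", "chain204")

PB_ISOTOPES <- c("x204", "x206", "x207", "x208")

ratio_labels <- function(param) {
  switch(param,
    ref204   = c("Pb208_204", "Pb207_204", "Pb206_204"),
    chain204 = c("Pb204_206", "Pb206_207", "Pb207_208")
  )
}

# Classed error helper so callers can condition on failure category.
stop_pb <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "pb_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_param <- function(param) {
  if (!is.character(param) || length(param) != 1L || !param %in% PB_PARAMS) {
    stop_pb("pb_validation_error", sprintf(
      "unknown parameterization %s; valid tags are: %s",
      deparse(substitute(param)), paste(PB_PARAMS, collapse = ", ")
    ))
  }
  param
}

#' Lead isotope ratio fingerprint
#'
#' A lead "fingerprint" is the relative composition of the four stable lead
#' isotopes, reduced to three independent ratios. Two parameterizations are
#' supported: `"ref204"` gives all ratios relative to the rare 204Pb isotope,
#' in the order (208Pb/204Pb, 207Pb/204Pb, 206Pb/204Pb) — the common way
#' MC-ICP-MS results are tabulated for natural lead (values near 37, 15.5,
#' 18); `"chain204"` chains down the mass numbers, in the order
#' (204Pb/206Pb, 206Pb/207Pb, 207Pb/208Pb) (values near 0.06, 1.1, 0.42).
#' The two carry identical information and conversion is exact.
#'
#' @param r1,r2,r3 Strictly positive, finite dimensionless isotope ratios, in
#'   the order defined by `param`.
#' @param param Parameterization tag, one of `"ref204"` or `"chain204"`.
#' @return A named numeric vector of class `"pb_ratio"` with a
#'   `"param"` attribute.
#' @examples
#' bg <- ratio_triple(37.8781, 15.2643, 18.8265, param = "ref204")
#' abundances_from_ratios(bg)
#' @seealso [abundances_from_ratios()], [ratios_from_abundances()],
#'   [convert_ratios()]
#' @export
ratio_triple <- function(r1, r2, r3, param = c("ref204", "chain204")) {
  param <- match.arg(param)
  vals <- c(r1, r2, r3)
  nm <- c("r1", "r2", "r3")
  for (i in seq_len(3L)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_pb("pb_validation_error", sprintf(
        "ratio '%s' must be a strictly positive finite number (got %s)",
        nm[[i]], format(v)
      ))
    }
  }
  structure(stats::setNames(as.numeric(vals), ratio_labels(param)),
            param = param, class = "pb_ratio")
}

#' @export
print.pb_ratio <- function(x, ...) {
  cat(sprintf("<pb_ratio> parameterization: %s\n", attr(x, "param")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Lead isotope abundance vector
#'
#' The mass fractions of the four stable lead isotopes (204Pb, 206Pb, 207Pb,
#' 208Pb) in total lead. Components must be strictly positive and sum to 1
#' within 1e-12 — natural lead sits near (1.4%, 24%, 22%, 52%).
#'
#' @param x204,x206,x207,x208 Mass fractions in (0, 1).
#' @return A named numeric vector of class `"pb_abundance"`.
#' @examples
#' abundance_vector(0.25, 0.25, 0.25, 0.25)
#' @export
abundance_vector <- function(x204, x206, x207, x208) {
  x <- c(x204, x206, x207, x208)
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x))) {
    stop_pb("pb_validation_error", "abundances must be four finite numbers")
  }
  if (any(x <= 0)) {
    bad <- PB_ISOTOPES[which(x <= 0)[1L]]
    stop_pb("pb_validation_error", sprintf(
      "abundance '%s' must be strictly positive for physical lead", bad))
  }
  if (abs(sum(x) - 1) > 1e-12) {
    stop_pb("pb_validation_error", sprintf(
      "abundances must sum to 1 within 1e-12 (sum = %.15g)", sum(x)))
  }
  structure(stats::setNames(as.numeric(x), PB_ISOTOPES), class = "pb_abundance")
}

#' @export
print.pb_abundance <- function(x, ...) {
  cat("<pb_abundance> isotope mass fractions\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Convert an isotope-ratio fingerprint to an abundance vector
#'
#' Inverts the ratio reduction: the three ratios imply the relative masses of
#' the four isotopes up to scale, and normalizing those to sum to 1 recovers
#' the mass-fraction abundance vector. For `ref204` ratios
#' (r208, r207, r206) the implied masses are (1, r206, r207, r208) per unit
#' 204Pb; for `chain204` ratios (y1, y2, y3) they are
#' (y1*y2*y3, y2*y3, y3, 1) per unit 208Pb.
#'
#' @param ratios A [ratio_triple()].
#' @return A [abundance_vector()] that reproduces the input ratios exactly.
#' @examples
#' abundances_from_ratios(ratio_triple(1, 1, 1, param = "ref204"))
#' @export
abundances_from_ratios <- function(ratios) {
  ratios <- as_pb_ratio(ratios)
  r <- as.numeric(ratios)
  m <- switch(attr(ratios, "param"),
    # (r208, r207, r206): masses per unit 204Pb, ordered (204, 206, 207, 208)
    ref204 = c(1, r[3L], r[2L], r[1L]),
    # (y1, y2, y3): masses per unit 208Pb
    chain204 = c(r[1L] * r[2L] * r[3L], r[2L] * r[3L], r[3L], 1)
  )
  x <- m / sum(m)
  abundance_vector(x[1L], x[2L], x[3L], x[4L])
}

#' Convert an abundance vector to an isotope-ratio fingerprint
#'
#' Ratios are exact quotients of the isotope mass fractions, in the order the
#' chosen parameterization defines. Inverse of [abundances_from_ratios()].
#'
#' @param x A [abundance_vector()].
#' @param param Target parameterization tag.
#' @return A [ratio_triple()].
#' @export
ratios_from_abundances <- function(x, param = c("ref204", "chain204")) {
  param <- match.arg(param)
  x <- as_pb_abundance(x)
  v <- as.numeric(x) # (x204, x206, x207, x208)
  r <- switch(param,
    ref204   = c(v[4L] / v[1L], v[3L] / v[1L], v[2L] / v[1L]),
    chain204 = c(v[1L] / v[2L], v[2L] / v[3L], v[3L] / v[4L])
  )
  ratio_triple(r[1L], r[2L], r[3L], param = param)
}

#' Re-express a fingerprint in another parameterization
#'
#' The conversion goes through the abundance vector and is a bijection on
#' strictly positive ratios.
#'
#' @param ratios A [ratio_triple()].
#' @param param Target parameterization tag.
#' @return A [ratio_triple()] in the target parameterization.
#' @export
convert_ratios <- function(ratios, param = c("ref204", "chain204")) {
  param <- match.arg(param)
  if (identical(attr(ratios, "param"), param)) return(ratios)
  ratios_from_abundances(abundances_from_ratios(ratios), param = param)
}

#' Project a fingerprint onto the Gobeil ratio pair
#'
#' The classical ratio-balance model works with the pair
#' R = 206Pb/207Pb and N = 208Pb/206Pb rather than a full fingerprint.
#'
#' @param x A [abundance_vector()] or [ratio_triple()].
#' @return Named numeric `c(R = x206/x207, N = x208/x206)`.
#' @examples
#' gobeil_projection(abundance_vector(0.25, 0.25, 0.25, 0.25))
#' @export
gobeil_projection <- function(x) {
  if (inherits(x, "pb_ratio")) x <- abundances_from_ratios(x)
  x <- as_pb_abundance(x)
  c(R = x[["x206"]] / x[["x207"]], N = x[["x208"]] / x[["x206"]])
}

as_pb_ratio <- function(x) {
  if (inherits(x, "pb_ratio")) return(x)
  stop_pb("pb_validation_error",
          "expected a ratio_triple(); construct one with ratio_triple()")
}

as_pb_abundance <- function(x) {
  if (inherits(x, "pb_abundance")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(abundance_vector(x[[1L]], x[[2L]], x[[3L]], x[[4L]]))
  }
  stop_pb("pb_validation_error",
          "expected an abundance_vector() or a numeric vector of length 4")
}
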