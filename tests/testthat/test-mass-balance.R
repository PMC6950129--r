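test_that("equation/unknown counts follow the 5n and 4n+4 rules", {
  expect_identical(
    lapply(2:5, function(n) {
      d <- system_dimensions(n)
      c(d$n_unknowns, d$n_equations, d$solvable)
    }),
    list(c(10L, 12L, 1L), c(15L, 16L, 1L), c(20L, 20L, 1L), c(25L, 24L, 0L))
  )
  expect_true(system_dimensions(4)$identifiable)
  expect_false(system_dimensions(7)$identifiable)
  expect_error(system_dimensions(1), class = "pb_validation_error")
  expect_error(system_dimensions(2.5), class = "pb_validation_error")
})

test_that("noiseless forward mixtures are recovered exactly for 2 to 4 sources", {
  set.seed(11)
  for (n in 2:4) {
    for (i in 1:50) {
      s <- generate_sources(n, seed = 1000 * n + i)
      f <- random_simplex(n)
      mix <- forward_mix(s, f)
      fit <- solve_mass_balance(s, mix)
      expect_lt(max(abs(fit$fractions - f)), 1e-10)
      expect_lt(abs(sum(fit$fractions) - 1), 1e-10)
      expect_lt(max(abs(fit$residuals)), 1e-10)
      expect_identical(unname(fit$negative_flags), unname(fit$fractions < 0))
    }
  }
})

test_that("apportionment is equivariant under source permutation and invariant to mass scale", {
  s <- generate_sources(4, seed = 5)
  f <- c(0.1, 0.2, 0.3, 0.4)
  mix <- forward_mix(s, f)
  fit <- solve_mass_balance(s, mix)
  perm <- c(3, 1, 4, 2)
  s_perm <- source_set(s$fingerprints[perm], names = s$names[perm])
  fit_perm <- solve_mass_balance(s_perm, mix)
  expect_equal(unname(fit_perm$fractions), unname(fit$fractions[perm]),
               tolerance = 1e-10)
  # total mass and concentration are metadata only
  heavy <- mixture_sample(mix$fingerprint, id = "heavy", concentration = 500,
                          total_mass = 7)
  expect_equal(solve_mass_balance(s, heavy)$fractions, fit$fractions,
               tolerance = 1e-12)
})

test_that("a sample at a source vertex gets that source's full contribution", {
  s <- generate_sources(3, seed = 9)
  fit <- solve_mass_balance(s, mixture_sample(s$fingerprints[[2]]))
  expect_equal(unname(fit$fractions), c(0, 1, 0), tolerance = 1e-10)
})

test_that("the full per-mass system agrees with the reduced solver", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:4, 1)
    s <- generate_sources(n, seed = 300 + i)
    f <- random_simplex(n)
    mix <- forward_mix(s, f)
    full <- solve_full_system(s, mix)
    red <- solve_mass_balance(s, mix)
    expect_lt(max(abs(full$fractions - red$fractions)), 1e-10)
    expect_lt(full$max_equation_residual, 1e-10)
    # per-source isotope masses reproduce each source's abundance pattern
    expect_equal(unname(rowSums(full$masses)), unname(f), tolerance = 1e-10)
  }
})

test_that("full-system masses scale with total mass, fractions do not", {
  s <- generate_sources(2, seed = 2)
  fp <- forward_mix(s, c(0.5, 0.5))$fingerprint
  m1 <- solve_full_system(s, mixture_sample(fp, total_mass = 1))
  m2 <- solve_full_system(s, mixture_sample(fp, total_mass = 2))
  expect_equal(m2$masses, 2 * m1$masses, tolerance = 1e-10)
  expect_equal(m2$fractions, m1$fractions, tolerance = 1e-10)
  # 50/50 mixture: each source contributes half its abundance vector
  X <- s$abundances
  expect_equal(unname(m1$masses), unname(t(X) / 2), tolerance = 1e-10)
})

test_that("the closed two-source formula matches forward mixing and the general solver", {
  s2 <- generate_sources(2, seed = 77)
  fa <- s2$fingerprints[[1]]
  fb <- s2$fingerprints[[2]]
  # sample at source A
  expect_equal(unname(solve_two_source_closed_form(fa, fb, fa)), c(1, 0),
               tolerance = 1e-12)
  set.seed(78)
  for (i in 1:50) {
    s <- generate_sources(2, seed = 500 + i)
    f <- random_simplex(2)
    mix <- forward_mix(s, f)
    cf <- solve_two_source_closed_form(s$fingerprints[[1]], s$fingerprints[[2]],
                                       mix$fingerprint)
    expect_lt(max(abs(cf - f)), 1e-10)
    expect_equal(sum(cf), 1, tolerance = 1e-15)
    gen <- solve_mass_balance(s, mix)$fractions
    expect_lt(max(abs(cf - gen)), 1e-10)
  }
})

test_that("unidentifiable and degenerate configurations are refused", {
  s5 <- generate_sources(5, seed = 3)
  mix <- forward_mix(s5, rep(0.2, 5))
  err <- expect_error(solve_mass_balance(s5, mix), class = "pb_unidentifiable_error")
  expect_match(conditionMessage(err), "25 unknowns")
  expect_match(conditionMessage(err), "24 equations")
  expect_error(solve_full_system(s5, mix), class = "pb_unidentifiable_error")
  # identical sources are rejected at construction
  fp <- ratio_triple(37.5, 15.5, 17.9)
  expect_error(source_set(list(a = fp, b = fp)), class = "pb_degenerate_error")
  # collinear-but-distinct triple is refused by the solver
  x1 <- c(0.0138, 0.240, 0.220)
  d <- c(0.0002, 0.004, 0.002)
  s_col <- source_set(list(a = fp_from_abundances(x1[1], x1[2], x1[3]),
                           b = fp_from_abundances(x1[1] + d[1], x1[2] + d[2], x1[3] + d[3]),
                           c = fp_from_abundances(x1[1] + 2 * d[1], x1[2] + 2 * d[2], x1[3] + 2 * d[3])))
  expect_error(solve_mass_balance(s_col, forward_mix(s_col, c(1, 0, 0))),
               class = "pb_degenerate_error")
  # two-source closed form: equal 204/208 products divide by zero
  fa <- fp_from_abundances(0.014, 0.245, 0.216)
  fb <- fp_from_abundances(0.014 * 0.525 / 0.525, 0.250, 0.211) # same x204 and x208
  expect_error(solve_two_source_closed_form(fa, fb, fa),
               class = "pb_unidentifiable_error")
})

test_that("batch apportionment collects rows, flags negatives and summarizes valid samples", {
  s <- generate_sources(3, seed = 31)
  inside <- forward_mix(s, c(0.2, 0.5, 0.3), id = "inside")
  # a sample outside the source simplex: signed mixing weights
  outside <- forward_mix(s, c(-0.15, 0.75, 0.4), id = "outside")
  res <- batch_apportion(s, list(inside, outside, inside))
  expect_identical(nrow(res), 3L)
  expect_identical(res$sample_id, c("inside", "outside", "inside"))
  expect_identical(res$negative, c(FALSE, TRUE, FALSE))
  # identical inputs give identical rows
  expect_identical(unname(unlist(res[1, ])), unname(unlist(res[3, ])))
  expect_equal(unname(rowSums(res[, s$names])), rep(1, 3), tolerance = 1e-10)
  # summary averages only the valid (non-negative) rows
  expect_identical(attr(res, "n_valid"), 2L)
  expect_equal(unname(attr(res, "summary")), c(0.2, 0.5, 0.3), tolerance = 1e-10)
  # empty batch: empty table, no summary
  empty <- batch_apportion(s, list())
  expect_identical(nrow(empty), 0L)
  expect_null(attr(empty, "summary"))
})
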