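test_that("split-ratio propagation reproduces the hand-evaluated example", {
  net <- illustration_net()
  V <- fluxes_from_fsr(net,
    list(X2 = c(V2 = 0.8, D = 0.2), X4 = c(V4 = 0.5, V5 = 0.5)),
    c(Vin1 = 100, Vin2 = 100))
  expect_equal(V[c("V1", "D", "V2", "V3", "V4", "V5")],
               c(V1 = 100, D = 20, V2 = 80, V3 = 100, V4 = 60, V5 = 60))
})

test_that("no-split and full-split limits behave as the formulas dictate", {
  net <- illustration_net()
  # A1 = 0: no diffusion, V2 = V1
  V <- fluxes_from_fsr(net, list(X2 = c(V2 = 1, D = 0), X4 = c(V4 = 0.3, V5 = 0.7)))
  expect_equal(unname(V["D"]), 0)
  expect_equal(unname(V["V2"]), unname(V["V1"]))
  # A2 = 1: V5 = 0, V4 = V3 + D
  V <- fluxes_from_fsr(net, list(X2 = c(V2 = 0.6, D = 0.4), X4 = c(V4 = 1, V5 = 0)))
  expect_equal(unname(V["V5"]), 0)
  expect_equal(unname(V["V4"]), unname(V["V3"] + V["D"]))
})

test_that("propagation matches the literal split-ratio formulas on 1000 draws", {
  net <- illustration_net()
  set.seed(2024)
  for (i in 1:1000) {
    A1 <- runif(1); A2 <- runif(1)
    V <- fluxes_from_fsr(net,
      list(X2 = c(V2 = 1 - A1, D = A1), X4 = c(V4 = A2, V5 = 1 - A2)))
    expect_equal(V, illustration_formulas(A1, A2), tolerance = 1e-12)
  }
})

test_that("mismatched split-ratio vectors are rejected with a named failure", {
  net <- illustration_net()
  expect_error(fluxes_from_fsr(net, list(X2 = c(V2 = 0.5, D = 0.5))),
               class = "lignflux_fsr_mismatch")
  expect_error(fluxes_from_fsr(net,
    list(X2 = c(V2 = 0.5, D = 0.5), X4 = c(V4 = 0.5, V5 = 0.5),
         X1 = c(V1 = 1))), class = "lignflux_fsr_mismatch")
  expect_error(fluxes_from_fsr(net,
    list(X2 = c(V2 = 0.7, D = 0.5), X4 = c(V4 = 0.5, V5 = 0.5))),
    class = "lignflux_fsr_mismatch")
})

test_that("unconstrained sampling accepts everything on a DAG", {
  net <- illustration_net()
  ens <- sample_admissible_fluxes(net, NULL, n_samples = 1000, seed = 5)
  expect_equal(ens$accepted, 1000L)
  expect_true(all(ens$members >= 0))
})

test_that("accepted members satisfy mass balance and the acceptance fraction
          of a flux-ratio constraint matches its closed form", {
  net <- illustration_net()
  # V5/V4 = (1 - A2)/A2 = 3 +- 0.1  <=>  A2 in [1/4.1, 1/3.9]
  cs <- constraint_set(data.frame(
    name = "flux_ratio", experiment = NA_character_, value = 3, tol = 0.1,
    mode = "absolute", num = "V5", den = "V4", stringsAsFactors = FALSE))
  n <- 40000
  ens <- sample_admissible_fluxes(net, cs, n_samples = n, seed = 31)
  p_expected <- 1 / 3.9 - 1 / 4.1
  p_hat <- ens$accepted / n
  expect_lt(abs(p_hat - p_expected), 4 * sqrt(p_expected / n))
  S <- build_stoichiometric_matrix(net)
  expect_lt(max(abs(S %*% t(ens$members))), 1e-9)
  ratios <- ens$members[, "V5"] / ens$members[, "V4"]
  expect_true(all(abs(ratios - 3) <= 0.1 + 1e-9))
})

test_that("an unsatisfiable constraint yields an empty ensemble with a warning", {
  net <- illustration_net()
  cs <- constraint_set(data.frame(
    name = "flux_ratio", experiment = NA_character_, value = 10, tol = 0.5,
    mode = "absolute", num = "V2", den = "V1", stringsAsFactors = FALSE))
  expect_warning(ens <- sample_admissible_fluxes(net, cs, 500, seed = 3),
                 class = "lignflux_empty_ensemble")
  expect_equal(ens$accepted, 0L)
  expect_equal(nrow(ens$members), 0L)
})

test_that("acceptance is monotone non-increasing as tolerance shrinks", {
  net <- illustration_net()
  acc <- vapply(c(1, 0.5, 0.2, 0.05), function(tol) {
    cs <- constraint_set(data.frame(
      name = "flux_ratio", experiment = NA_character_, value = 3, tol = tol,
      mode = "absolute", num = "V5", den = "V4", stringsAsFactors = FALSE))
    suppressWarnings(sample_admissible_fluxes(net, cs, 4000, seed = 17)$accepted)
  }, 0L)
  expect_true(all(diff(acc) <= 0))
})

test_that("identical seeds give byte-identical ensemble CSVs", {
  net <- illustration_net()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(sample_admissible_fluxes(net, NULL, 200, seed = 77), p1)
  write_ensemble_csv(sample_admissible_fluxes(net, NULL, 200, seed = 77), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # and a different seed differs
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(sample_admissible_fluxes(net, NULL, 200, seed = 78), p3)
  expect_false(identical(readLines(p1)[-(1:4)], readLines(p3)[-(1:4)]))
})

test_that("feasibility_report is deterministic and separates the schemes", {
  net <- illustration_net()
  rep2 <- feasibility_report(list(net, net), NULL, n_samples = 300, seed = 4)
  expect_equal(rep2$accepted[1], rep2$accepted[2])
  expect_equal(rep2$accepted[1], 300L)  # empty constraints accept everything
})
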