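test_that("the illustration network loads with the documented structure", {
  net <- illustration_net()
  expect_s3_class(net, "pathway_network")
  expect_setequal(net$metabolites$id, c("X1", "X2", "X3", "X4"))
  expect_equal(nrow(net$fluxes), 8L)
  expect_equal(sum(net$fluxes$kind == "input"), 2L)
  expect_equal(sum(net$fluxes$kind == "efflux"), 3L)
  expect_equal(net$fluxes$id[net$fluxes$kind == "diffusion_net"], "D")
})

test_that("a minimal single-metabolite network is valid", {
  net <- load_network(net_json("tiny", list(met("a")),
    list(edge("in", "input", to = "a"), edge("out", "efflux", "a"))))
  expect_equal(nrow(net$metabolites), 1L)
  expect_equal(nrow(net$fluxes), 2L)
  S <- build_stoichiometric_matrix(net)
  expect_equal(S["a", ], c(`in` = 1L, out = -1L))
})

test_that("validation failures carry distinct condition classes", {
  # diffusion edge joining two cytosol pools
  expect_error(load_network(net_json("bad",
    list(met("a"), met("b", species = "a")),
    list(edge("in", "input", to = "a"), edge("d", "diffusion_net", "a", "b"),
         edge("out", "efflux", "b")))),
    class = "lignflux_bad_diffusion")
  # diffusion edge joining different species
  expect_error(load_network(net_json("bad",
    list(met("a"), met("b", compartment = "ER", species = "other")),
    list(edge("in", "input", to = "a"), edge("d", "diffusion_net", "a", "b"),
         edge("out", "efflux", "b")))),
    class = "lignflux_bad_diffusion")
  # duplicate ids
  expect_error(load_network(net_json("bad", list(met("a"), met("a")),
    list(edge("in", "input", to = "a"), edge("out", "efflux", "a")))),
    class = "lignflux_duplicate_id")
  # cycle in the net-flux graph
  expect_error(load_network(net_json("bad", list(met("a"), met("b")),
    list(edge("in", "input", to = "a"), edge("v1", "enzymatic", "a", "b"),
         edge("v2", "enzymatic", "b", "a"), edge("out", "efflux", "b")))),
    class = "lignflux_cyclic_network")
  # orphan metabolite
  expect_error(load_network(net_json("bad", list(met("a"), met("b")),
    list(edge("in", "input", to = "a"), edge("out", "efflux", "a")))),
    class = "lignflux_dangling_metabolite")
  # non-monomolecular coefficient
  bad <- net_json("bad", list(met("a")),
    list(edge("in", "input", to = "a"), edge("out", "efflux", "a")))
  bad <- sub('"coefficient":-1', '"coefficient":-2', bad, fixed = TRUE)
  expect_error(load_network(bad), class = "lignflux_bad_stoichiometry")
  # input with a substrate
  expect_error(load_network(net_json("bad", list(met("a"), met("b")),
    list(list(id = "in", kind = "input",
              substrates = list(list(metabolite = "a", coefficient = -1)),
              products = list(list(metabolite = "b", coefficient = 1))),
         edge("out", "efflux", "b")))),
    class = "lignflux_schema_error")
})

test_that("the illustration stoichiometric matrix reproduces the toy ODEs", {
  S <- build_stoichiometric_matrix(illustration_net())
  # Xdot1 = Vin - V1 ; Xdot2 = V1 - V2 - D ; Xdot3 = Vin - V3 ;
  # Xdot4 = V3 + D - V4 - V5
  expect_equal(S["X1", ], c(Vin1 = 1, Vin2 = 0, V1 = -1, V2 = 0, V3 = 0,
                            D = 0, V4 = 0, V5 = 0), ignore_attr = FALSE)
  expect_equal(S["X2", c("V1", "V2", "D")], c(V1 = 1, V2 = -1, D = -1))
  expect_equal(unname(S["X3", ]), c(0, 1, 0, 0, -1, 0, 0, 0))
  expect_equal(S["X4", c("V3", "D", "V4", "V5")],
               c(V3 = 1, D = 1, V4 = -1, V5 = -1))
})

test_that("stoichiometric columns balance by kind for every shipped network", {
  for (nm in c("illustration", "brachy_fig4", "brachy_fig5", "brachy_fig6")) {
    net <- load_network(lignflux_file(nm))
    S <- build_stoichiometric_matrix(net)
    cs <- colSums(S)
    expect_true(all(abs(S) <= 1))
    for (j in seq_len(ncol(S))) {
      expected <- switch(net$fluxes$kind[j], input = 1L, efflux = -1L, 0L)
      expect_equal(unname(cs[j]), expected)
      if (net$fluxes$kind[j] %in% c("enzymatic", "diffusion_net"))
        expect_equal(sort(unname(S[S[, j] != 0, j])), c(-1L, 1L))
    }
  }
})

test_that("branch points come in topological order with k-1 dof per split", {
  bp <- branch_points(illustration_net())
  expect_equal(vapply(bp, `[[`, "", "metabolite"), c("X2", "X4"))
  expect_setequal(bp[[1]]$out, c("V2", "D"))
  expect_setequal(bp[[2]]$out, c("V4", "V5"))
  expect_equal(attr(bp, "dof"), 2L)

  expect_length(branch_points(linear_chain_net()), 0L)
  expect_equal(attr(branch_points(linear_chain_net()), "dof"), 0L)

  bp3 <- branch_points(three_way_net())
  expect_length(bp3, 1L)
  expect_equal(attr(bp3, "dof"), 2L)
})

test_that("serialization round-trips every shipped network", {
  for (nm in c("illustration", "brachy_fig4", "brachy_fig5", "brachy_fig6")) {
    net <- load_network(lignflux_file(nm))
    back <- load_network(write_network(net))
    expect_equal(back, net)
  }
})

test_that("every shipped network admits a strictly positive steady state", {
  for (nm in c("illustration", "brachy_fig4", "brachy_fig5", "brachy_fig6")) {
    net <- load_network(lignflux_file(nm))
    set.seed(99)
    ens <- sample_admissible_fluxes(net, NULL, n_samples = 20, seed = 99)
    S <- build_stoichiometric_matrix(net)
    # interior FSR draws give strictly positive fluxes with S V = 0
    strictly_pos <- apply(ens$members, 1, function(v) all(v > 0))
    expect_true(any(strictly_pos))
    v <- ens$members[which(strictly_pos)[1], ]
    expect_lt(max(abs(S %*% v)), 1e-9)
  }
})

test_that("stoichiometric TSV export writes metabolite rows and flux columns", {
  net <- illustration_net()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_stoichiometric_tsv(build_stoichiometric_matrix(net), p)
  tab <- utils::read.delim(p, check.names = FALSE)
  expect_equal(tab$metabolite, net$metabolites$id)
  expect_equal(colnames(tab)[-1], net$fluxes$id)
})
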