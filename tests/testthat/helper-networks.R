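# Programmatic fixture networks used across the suite.

net_json <- function(name, mets, fluxes, r = 1) {
  as.character(jsonlite::toJSON(list(name = name, r = r, metabolites = mets,
                                     fluxes = fluxes),
                                auto_unbox = TRUE, digits = NA))
}

met <- function(id, compartment = "cytosol", species = id, roles = NULL) {
  m <- list(id = id, compartment = compartment, species = species)
  if (!is.null(roles)) m$roles <- as.list(roles)
  m
}

edge <- function(id, kind, from = NULL, to = NULL, enzyme = NULL, tracer = NULL) {
  f <- list(id = id, kind = kind)
  if (!is.null(from)) f$substrates <- list(list(metabolite = from, coefficient = -1))
  if (!is.null(to)) f$products <- list(list(metabolite = to, coefficient = 1))
  if (!is.null(enzyme)) f$enzyme <- enzyme
  if (!is.null(tracer)) f$tracer <- tracer
  f
}

illustration_net <- function() load_network(lignflux_file("illustration"))
fig4_net <- function() load_network(lignflux_file("brachy_fig4"))
fig5_net <- function() load_network(lignflux_file("brachy_fig5"))
fig6_net <- function() load_network(lignflux_file("brachy_fig6"))
table1 <- function() load_constraints(lignflux_file("table1_constraints"))

# in -> a -> b -> out: no branch points
linear_chain_net <- function() {
  load_network(net_json("chain",
    list(met("a"), met("b")),
    list(edge("in", "input", to = "a"),
         edge("v1", "enzymatic", "a", "b"),
         edge("out", "efflux", "b"))))
}

# one pool splitting three ways
three_way_net <- function() {
  load_network(net_json("threeway",
    list(met("a"), met("b1"), met("b2"), met("b3")),
    list(edge("in", "input", to = "a"),
         edge("v1", "enzymatic", "a", "b1"),
         edge("v2", "enzymatic", "a", "b2"),
         edge("v3", "enzymatic", "a", "b3"),
         edge("o1", "efflux", "b1"), edge("o2", "efflux", "b2"),
         edge("o3", "efflux", "b3"))))
}

# single input feeding H/G/S sink pools, G and S symmetric
sink_toy_net <- function() {
  load_network(net_json("sinktoy",
    list(met("core"),
         met("h", roles = "H_sink"), met("g", roles = "G_sink"),
         met("s", roles = "S_sink")),
    list(edge("in", "input", to = "core", tracer = "feed"),
         edge("vh", "enzymatic", "core", "h"),
         edge("vg", "enzymatic", "core", "g"),
         edge("vs", "enzymatic", "core", "s"),
         edge("eh", "efflux", "h"), edge("eg", "efflux", "g"),
         edge("es", "efflux", "s"))))
}

phe_feed <- function(frac = 0.35) list(tracer = "phe", fraction = frac, baseline = 0)
tyr_feed <- function(frac = 0.35) list(tracer = "tyr", fraction = frac, baseline = 0)

# literal split-ratio formulas for the illustration network
illustration_formulas <- function(A1, A2, Vin = 100) {
  V1 <- Vin; V3 <- Vin
  D <- A1 * V1
  c(Vin1 = Vin, Vin2 = Vin, V1 = V1, V2 = (1 - A1) * V1, V3 = V3,
    D = D, V4 = A2 * (V3 + D), V5 = (1 - A2) * (V3 + D))
}

# independent Newton solve of the raw node balances of the illustration
# pair (total balance of pool 2, label balances of pools 2 and 4);
# unknowns (D_f, D_r, L4).  Deliberately avoids the closed-form
# elimination used by the implementation.
newton_node_balances <- function(L1, L2, L3, V1, V2, V3, V4, V5,
                                 max_iter = 100, tol = 1e-13) {
  x <- c(Df = max(V1 - V2, 0) + 1, Dr = 1, L4 = 0.5)
  for (it in seq_len(max_iter)) {
    r <- c(V1 + x[2] - V2 - x[1],
           L1 * V1 + x[3] * x[2] - L2 * V2 - L2 * x[1],
           L3 * V3 + L2 * x[1] - x[3] * (V4 + V5) - x[3] * x[2])
    if (max(abs(r)) < tol) break
    J <- rbind(c(-1, 1, 0),
               c(-L2, x[3], x[2]),
               c(L2, -x[3], -(V4 + V5) - x[2]))
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    x <- x - step
  }
  if (max(abs(r)) >= 1e-10) return(NULL)
  x
}
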