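## Flux-split-ratio (FSR) parameterization of the underdetermined steady
## state.  At each diverging branch point the fractions of inflow routed
## to the outgoing edges are the free coordinates; propagating them down
## the net-flux DAG yields a full steady-state flux vector with S.V = 0
## by construction.

#' Compute a steady-state flux vector from flux split ratios
#'
#' Propagates material down the net-flux DAG: inputs are fixed, each
#' node's total inflow is distributed over its outgoing edges according to
#' the split fractions, single-exit nodes pass everything on.  The result
#' satisfies the mass balance `S %*% V = 0` exactly up to floating point.
#'
#' @param net A validated `pathway_network`.
#' @param fsr Named list: one element per branch-point metabolite, each a
#'   named numeric vector of fractions over that branch's outgoing flux
#'   ids, summing to 1.
#' @param inputs Named numeric vector of magnitudes for every input flux
#'   (default: 100 units of mass per unit time on each input).
#' @return Named numeric vector of flux magnitudes (class `flux_vector`).
#' @export
fluxes_from_fsr <- function(net, fsr, inputs = NULL) {
  bp <- branch_points(net)
  bmets <- vapply(bp, `[[`, "", "metabolite")
  if (!setequal(names(fsr), bmets))
    lf_stop("lignflux_fsr_mismatch",
            "fsr must cover exactly the branch points (%s); got (%s)",
            paste(bmets, collapse = ", "), paste(names(fsr), collapse = ", "))
  for (b in bp) {
    fr <- fsr[[b$metabolite]]
    if (!setequal(names(fr), b$out))
      lf_stop("lignflux_fsr_mismatch",
              "fsr for %s must name fluxes {%s}", b$metabolite,
              paste(b$out, collapse = ", "))
    if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-12)
      lf_stop("lignflux_fsr_mismatch",
              "fsr fractions for %s must lie in [0,1] and sum to 1", b$metabolite)
  }
  frac <- fsr_to_matrix(net, list(fsr))
  drop(propagate_fluxes(net, frac, default_inputs(net, inputs)))
}

default_inputs <- function(net, inputs = NULL) {
  ids <- net$fluxes$id[net$fluxes$kind == "input"]
  if (is.null(inputs)) return(setNames(rep(100, length(ids)), ids))
  if (!setequal(names(inputs), ids))
    lf_stop("lignflux_fsr_mismatch", "inputs must name exactly: %s",
            paste(ids, collapse = ", "))
  inputs[ids]
}

## fractions for a list of FSR draws -> matrix [n_flux x n_samples],
## rows only meaningful for branch out-edges
fsr_to_matrix <- function(net, fsr_list) {
  n <- length(fsr_list)
  frac <- matrix(NA_real_, nrow = nrow(net$fluxes), ncol = n,
                 dimnames = list(net$fluxes$id, NULL))
  for (s in seq_len(n)) {
    for (m in names(fsr_list[[s]])) {
      fr <- fsr_list[[s]][[m]]
      frac[names(fr), s] <- fr
    }
  }
  frac
}

## Vectorized propagation: frac is [n_flux x S]; returns [n_flux x S].
propagate_fluxes <- function(net, frac, inputs) {
  fl <- net$fluxes
  nb <- edges_by_node(net)
  S <- ncol(frac)
  Fm <- matrix(0, nrow = nrow(fl), ncol = S, dimnames = list(fl$id, NULL))
  for (i in which(fl$kind == "input")) Fm[i, ] <- inputs[[fl$id[i]]]
  for (m in topological_order(net)) {
    ins <- nb$into[[m]]
    if (!length(ins)) next
    inflow <- if (length(ins) == 1L) Fm[ins, ] else colSums(Fm[ins, , drop = FALSE])
    outs <- nb$out[[m]]
    if (length(outs) == 1L) {
      Fm[outs, ] <- inflow
    } else if (length(outs) > 1L) {
      for (e in outs) Fm[e, ] <- inflow * frac[e, ]
    }
  }
  Fm
}

## Uniform sampling of split fractions: each k-way branch is a uniform
## point on the (k-1)-simplex (Dirichlet(1,...,1); U[0,1] for k = 2).
sample_fsr_matrix <- function(net, n) {
  bp <- branch_points(net)
  frac <- matrix(NA_real_, nrow = nrow(net$fluxes), ncol = n,
                 dimnames = list(net$fluxes$id, NULL))
  for (b in bp) {
    k <- length(b$out)
    g <- matrix(-log(stats::runif(k * n)), nrow = k)
    frac[b$out, ] <- sweep(g, 2, colSums(g), "/")
  }
  frac
}

## extract per-branch FSR list for one column of a fraction matrix
fsr_from_matrix <- function(net, frac, col) {
  bp <- branch_points(net)
  out <- lapply(bp, function(b) setNames(frac[b$out, col], b$out))
  names(out) <- vapply(bp, `[[`, "", "metabolite")
  out
}

#' Monte-Carlo sampling of admissible steady-state flux vectors
#'
#' Draws `n_samples` FSR vectors (uniform on each branch simplex),
#' propagates each to a full flux vector with the inputs normalized to
#' `input_value`, and retains the members that are non-negative and meet
#' every constraint in `constraints` that is computable from total fluxes
#' alone (monomer composition, S/G ratio, flux ratios).  Label
#' incorporation targets require the labeling stage and are enforced by
#' [run_pipeline()] / [sample_label_states()].
#'
#' Zero acceptances return an empty ensemble with a classed warning
#' (`lignflux_empty_ensemble`), not an error: emptiness is the scientific
#' result for an infeasible scheme.
#'
#' @param net A validated `pathway_network`.
#' @param constraints A `constraint_set` (see [load_constraints()]) or
#'   `NULL` for non-negativity only.
#' @param n_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical arguments give identical ensembles.
#' @param input_value Magnitude assigned to each input flux (default 100).
#' @return A `flux_ensemble`: list with `members` (accepted flux vectors
#'   as a samples-by-fluxes matrix), `fsr` (their split fractions),
#'   `n_samples`, `accepted`, `seed`, `network`.
#' @export
sample_admissible_fluxes <- function(net, constraints = NULL, n_samples = 1000L,
                                     seed = 1L, input_value = 100) {
  stopifnot(n_samples >= 1L)
  set.seed(seed)
  frac <- sample_fsr_matrix(net, n_samples)
  inputs <- default_inputs(net) * 0 + input_value
  Fm <- propagate_fluxes(net, frac, as.list(inputs))
  keep <- colSums(Fm < 0) == 0L          # non-negativity (holds by construction)
  if (!is.null(constraints)) {
    ok <- steady_constraints_ok(net, Fm, constraints)
    keep <- keep & ok
  }
  members <- t(Fm[, keep, drop = FALSE])
  ens <- structure(list(
    members = members,
    fsr = t(frac[, keep, drop = FALSE]),
    n_samples = n_samples, accepted = sum(keep),
    seed = seed, network = net$name, input_value = input_value
  ), class = "flux_ensemble")
  if (ens$accepted == 0L)
    lf_warn("lignflux_empty_ensemble",
            "no admissible flux vector among %d samples for network '%s'",
            n_samples, net$name)
  ens
}

## vectorized evaluation of total-flux-level constraints over columns of Fm
steady_constraints_ok <- function(net, Fm, constraints) {
  keep <- rep(TRUE, ncol(Fm))
  tg <- constraints$targets
  comp_names <- c("H_frac", "G_frac", "S_frac", "SG_ratio")
  need_comp <- any(tg$name %in% comp_names)
  if (need_comp) {
    sinks <- sink_effluxes(net)
    hv <- Fm[sinks[["H_sink"]], ]; gv <- Fm[sinks[["G_sink"]], ]; sv <- Fm[sinks[["S_sink"]], ]
    tot <- hv + gv + sv
    vals <- list(H_frac = 100 * hv / tot, G_frac = 100 * gv / tot,
                 S_frac = 100 * sv / tot, SG_ratio = sv / gv)
  }
  for (i in seq_len(nrow(tg))) {
    if (!is.na(tg$experiment[i])) next  # labeling-stage target
    v <- if (tg$name[i] == "flux_ratio") {
      Fm[tg$num[i], ] / Fm[tg$den[i], ]
    } else if (tg$name[i] %in% comp_names) {
      vals[[tg$name[i]]]
    } else next
    keep <- keep & target_ok(v, tg$value[i], tg$tol[i], tg$mode[i])
  }
  keep
}

target_ok <- function(v, value, tol, mode) {
  dev <- abs(v - value)
  lim <- if (mode == "relative") tol * abs(value) else tol
  !is.na(v) & dev <= lim + 1e-12
}

## efflux edge index of each sink role
sink_effluxes <- function(net) {
  roles <- c("H_sink", "G_sink", "S_sink")
  out <- list()
  for (r in roles) {
    m <- role_metabolite(net, r)
    if (is.na(m)) next
    e <- which(net$fluxes$kind == "efflux" & net$fluxes$from == m)
    if (length(e) != 1L)
      lf_stop("lignflux_missing_role",
              "%s pool '%s' must have exactly one efflux", r, m)
    out[[r]] <- e
  }
  out
}

role_metabolite <- function(net, role) {
  hit <- vapply(net$metabolites$roles, function(r) role %in% r, TRUE)
  if (!any(hit)) return(NA_character_)
  net$metabolites$id[hit]
}

#' Per-network feasibility comparison under shared constraints
#'
#' Runs the full two-stage pipeline (FSR sampling, then label resolution
#' for every feeding experiment in the constraint set) on each network
#' with an identical sampling budget and seed, and reports the number of
#' samples drawn and fully accepted.  This is the channel-versus-no-channel
#' comparison: a scheme that cannot meet the observations returns zero.
#'
#' @param nets List of `pathway_network` objects.
#' @param constraints A `constraint_set`.
#' @param n_samples Monte-Carlo draws per network.
#' @param seed Integer seed (reused for every network).
#' @param label_tries Label draws attempted per surviving flux vector and
#'   experiment.
#' @return Data frame with columns `network`, `drawn`, `accepted`.
#' @export
feasibility_report <- function(nets, constraints, n_samples = 10000L, seed = 1L,
                               label_tries = 200L) {
  rows <- lapply(nets, function(net) {
    ens <- suppressWarnings(
      sample_ensemble(net, constraints, n_samples = n_samples, seed = seed,
                      label_tries = label_tries))
    data.frame(network = net$name, drawn = n_samples,
               accepted = ens$accepted, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a flux ensemble as CSV
#'
#' One row per accepted member, one column per flux id; sampler metadata
#' (`network`, `seed`, samples drawn/accepted) on `#`-prefixed header
#' lines.  Numbers are written with full precision so that identical
#' seeds give byte-identical files.
#'
#' @param ens A `flux_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network: %s", ens$network), con)
  writeLines(sprintf("# seed: %d", ens$seed), con)
  writeLines(sprintf("# samples: %d accepted: %d", ens$n_samples, ens$accepted), con)
  writeLines(paste(colnames(ens$members), collapse = ","), con)
  if (nrow(ens$members))
    writeLines(apply(ens$members, 1L, function(r)
      paste(sprintf("%.15g", r), collapse = ",")), con)
  invisible(path)
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf("<flux_ensemble> %s: %d / %d samples accepted (seed %d)\n",
              x$network, x$accepted, x$n_samples, x$seed))
  invisible(x)
}
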