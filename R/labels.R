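## 13C-label bookkeeping.  Pool enrichments L_i propagate down the
## net-flux DAG; at each diffusion-coupled pool pair the two label
## balances leave one degree of freedom (the exchange magnitude), which
## Monte-Carlo sampling explores.  Resolving a pair yields the two
## unidirectional diffusion components D_f (along the net direction) and
## D_r (against it), with D_f - D_r equal to the net flux.

EPS_LABEL <- 1e-9

#' Label fraction of the diffusion partner pool
#'
#' Closed-form solution for the enrichment of the second pool of a
#' diffusion-coupled pair, obtained by combining the labeled mass
#' balances of both pools so that the unknown exchange flux cancels:
#' \deqn{L_4 = (L_2 V_2 - L_1 V_1 - L_3 V_3) / (V_2 - V_1 - V_3)}
#' in the illustration network's notation, where pool 2 (label `L2`,
#' inflow `V1` at label `L1`, outflow `V2`) exchanges with pool 4
#' (inflow `V3` at label `L3`).
#'
#' @param L1,L2,L3 Label fractions in `[0,1]`: inflow to the first pool,
#'   the first pool itself, and the inflow to the partner pool.
#' @param V1,V2,V3 Flux magnitudes: inflow and outflow of the first pool
#'   and inflow of the partner.
#' @param strict If `TRUE` (default, direct calls) a partner label
#'   outside `[0,1]` raises a classed `lignflux_infeasible_label` error;
#'   if `FALSE` the value is returned with attribute `feasible = FALSE`
#'   (the rejection signal used inside sampling).
#' @return The partner pool's label fraction `L4`.
#' @export
partner_label <- function(L1, L2, L3, V1, V2, V3, strict = TRUE) {
  den <- V2 - V1 - V3
  if (abs(den) < EPS_LABEL)
    lf_stop("lignflux_degenerate_topology",
            "V2 - V1 - V3 = 0: partner pool has no efflux to carry label")
  L4 <- (L2 * V2 - L1 * V1 - L3 * V3) / den
  feasible <- L4 >= -EPS_LABEL && L4 <= 1 + EPS_LABEL
  if (!feasible && strict)
    lf_stop("lignflux_infeasible_label",
            "partner label %.4f outside [0,1]", L4)
  attr(L4, "feasible") <- feasible
  L4
}

#' Resolve a net diffusion flux into forward and reverse components
#'
#' Given the enrichments of a diffusion-coupled pool pair and its
#' neighbours, the labeled and total mass balances of the first pool give
#' \deqn{D_r = (L_2 - L_1) V_1 / (L_4 - L_2), \quad
#'       D_f = (L_4 - L_1) V_1 / (L_4 - L_2) - V_2,}
#' so that `D_f - D_r = V1 - V2` (the net flux) by construction.  When
#' `L4 = L2` the exchange is unidentifiable; under uniform labeling
#' (`L1 = L2 = L4`) the documented fallback returns the net-only
#' resolution `D_f = max(D, 0)`, `D_r = 0`, otherwise a classed
#' `lignflux_degenerate_label` error is raised.
#'
#' @param L1 Label of the inflow to the first pool.
#' @param L2,L4 Labels of the pool and its diffusion partner.
#' @param V1,V2 Inflow and (non-diffusion) outflow of the first pool.
#' @return A `diffusion_resolution`: list with `D_f`, `D_r`, `net`
#'   (= `D_f - D_r`) and `feasible` (`FALSE` when either component is
#'   negative; a rejection signal, not an error).
#' @export
resolve_diffusion <- function(L1, L2, L4, V1, V2) {
  net <- V1 - V2
  if (abs(L4 - L2) < EPS_LABEL) {
    if (abs(L1 - L2) < EPS_LABEL) {
      return(structure(list(D_f = max(net, 0), D_r = 0, net = max(net, 0) - 0,
                            feasible = net >= -EPS_LABEL),
                       class = "diffusion_resolution"))
    }
    lf_stop("lignflux_degenerate_label",
            "L4 = L2 with unequal inflow label: exchange unidentifiable")
  }
  D_r <- unname((L2 - L1) * V1 / (L4 - L2))
  D_f <- unname((L4 - L1) * V1 / (L4 - L2) - V2)
  structure(list(D_f = D_f, D_r = D_r, net = D_f - D_r,
                 feasible = D_f >= -EPS_LABEL && D_r >= -EPS_LABEL),
            class = "diffusion_resolution")
}

#' Split every flux into labeled and unlabeled components
#'
#' Each flux's labeled part is its source pool's label times its
#' magnitude (input edges carry the feeding label).  For diffusion edges
#' the two directions are labeled separately -- `L_src * D_f` forward and
#' `L_tgt * D_r` reverse -- so the net labeled diffusion is
#' `L_src * D_f - L_tgt * D_r`, which differs from the naive
#' `L_src * (D_f - D_r)` whenever the pools are unequally enriched and
#' exchange is non-zero.
#'
#' @param net A validated `pathway_network`.
#' @param flux Named flux vector (e.g. from [fluxes_from_fsr()]).
#' @param labels Named vector of pool label fractions covering every
#'   metabolite.
#' @param feeding Feeding descriptor `list(labeled_input=, fraction=,
#'   baseline=)`; see [sample_label_states()].
#' @param diffusion Named list per diffusion edge id:
#'   `list(D_f=, D_r=)` (e.g. from [resolve_diffusion()]); required when
#'   the network has diffusion edges.
#' @return Data frame with columns `flux`, `total`, `labeled`,
#'   `unlabeled` (net components for diffusion edges, plus rows
#'   `<id>.f`/`<id>.r` for each direction).
#' @export
split_labeled_fluxes <- function(net, flux, labels, feeding, diffusion = list()) {
  fl <- net$fluxes
  miss <- setdiff(fl$from[!is.na(fl$from)], names(labels))
  if (length(miss))
    lf_stop("lignflux_missing_label", "no label for pool(s): %s",
            paste(miss, collapse = ", "))
  feed <- input_labels(net, feeding)
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    id <- fl$id[i]; v <- flux[[id]]
    if (fl$kind[i] == "diffusion_net") {
      d <- diffusion[[id]]
      if (is.null(d))
        lf_stop("lignflux_missing_label", "no diffusion resolution for edge %s", id)
      lf_ <- labels[[fl$from[i]]] * d$D_f
      lr_ <- labels[[fl$to[i]]] * d$D_r
      rows[[length(rows) + 1L]] <- data.frame(
        flux = c(id, paste0(id, ".f"), paste0(id, ".r")),
        total = c(d$D_f - d$D_r, d$D_f, d$D_r),
        labeled = c(lf_ - lr_, lf_, lr_),
        stringsAsFactors = FALSE)
    } else {
      L <- if (fl$kind[i] == "input") feed[[id]] else labels[[fl$from[i]]]
      rows[[length(rows) + 1L]] <- data.frame(
        flux = id, total = v, labeled = L * v, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$unlabeled <- out$total - out$labeled
  out
}

## label carried by each input edge under a feeding descriptor
input_labels <- function(net, feeding) {
  ids <- net$fluxes$id[net$fluxes$kind == "input"]
  baseline <- if (is.null(feeding$baseline)) 0 else feeding$baseline
  lab <- setNames(rep(baseline, length(ids)), ids)
  tgt <- feeding$labeled_input
  if (!is.null(feeding$tracer) && is.null(tgt)) {
    tgt <- net$fluxes$id[!is.na(net$fluxes$tracer) &
                           net$fluxes$tracer == feeding$tracer]
  }
  if (is.null(tgt) || !length(tgt) || !all(tgt %in% ids))
    lf_stop("lignflux_schema_error",
            "feeding must name an input flux (labeled_input or tracer)")
  lab[tgt] <- feeding$fraction
  lab
}

## ---- pair-resolution plan -----------------------------------------------

## Precomputed per-network structure describing how labels are resolved:
## topological node order, diffusion pairs with their external in/out edge
## indices, and which nodes are plain (deterministic mixing).
label_plan <- function(net) {
  prs <- diffusion_pairs(net)
  pair_mets <- unlist(lapply(prs, function(p) c(p$source, p$target)))
  if (anyDuplicated(pair_mets))
    lf_stop("lignflux_bad_diffusion",
            "a metabolite participates in more than one diffusion pair")
  nb <- edges_by_node(net)
  prs <- lapply(prs, function(p) {
    p$ext_in_P <- setdiff(nb$into[[p$source]], p$edge_idx)
    p$ext_out_P <- setdiff(nb$out[[p$source]], p$edge_idx)
    p$ext_in_Q <- setdiff(nb$into[[p$target]], p$edge_idx)
    p$ext_out_Q <- setdiff(nb$out[[p$target]], p$edge_idx)
    p
  })
  ## Pair-condensed topological order: both pools of a pair become
  ## resolvable only together, so each pair is one node of the
  ## dependency graph and downstream consumers of either pool wait for
  ## the joint resolution.
  mets <- net$metabolites$id
  group <- setNames(mets, mets)
  for (k in seq_along(prs))
    group[c(prs[[k]]$source, prs[[k]]$target)] <- sprintf("pair:%d", k)
  fl <- net$fluxes
  gedges <- unique(data.frame(
    from = unname(group[fl$from[!is.na(fl$from) & !is.na(fl$to)]]),
    to = unname(group[fl$to[!is.na(fl$from) & !is.na(fl$to)]]),
    stringsAsFactors = FALSE))
  gedges <- gedges[gedges$from != gedges$to, , drop = FALSE]
  gnodes <- unique(unname(group))
  indeg <- setNames(integer(length(gnodes)), gnodes)
  tab <- table(gedges$to)
  indeg[names(tab)] <- as.integer(tab)
  queue <- gnodes[indeg == 0L]; gorder <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    gorder <- c(gorder, v)
    for (w in gedges$to[gedges$from == v]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(gorder) != length(gnodes))
    lf_stop("lignflux_cyclic_network",
            "diffusion pairing induces a cyclic label dependency")
  steps <- lapply(gorder, function(g) {
    if (startsWith(g, "pair:"))
      list(type = "pair", k = as.integer(sub("pair:", "", g)))
    else list(type = "plain", met = g)
  })
  list(steps = steps, pairs = prs, nb = nb)
}

## Vectorized label resolution for one total-flux vector.
##   V: named flux vector;  feed: per-input-edge labels;
##   U: [n_pairs x n] uniforms driving the free pair labels.
## Returns L [mets x n], Df/Dr [pairs x n], ok (logical n).
resolve_labels <- function(net, plan, V, feed, U) {
  fl <- net$fluxes
  n <- if (length(plan$pairs)) ncol(U) else attr(U, "n")
  mets <- net$metabolites$id
  L <- matrix(NA_real_, length(mets), n, dimnames = list(mets, NULL))
  np <- length(plan$pairs)
  Df <- matrix(NA_real_, max(np, 1L), n)
  Dr <- matrix(NA_real_, max(np, 1L), n)
  ok <- rep(TRUE, n)

  # labeled inflow along edge j (vector over draws)
  edge_labeled <- function(j) {
    if (fl$kind[j] == "input") rep(feed[[fl$id[j]]] * V[[j]], n)
    else L[fl$from[j], ] * V[[j]]
  }
  ext_sums <- function(idx) {
    tot <- sum(V[idx])
    lab <- rep(0, n)
    for (j in idx) lab <- lab + edge_labeled(j)
    list(tot = tot, lab = lab)
  }

  for (step in plan$steps) {
    if (step$type == "plain") {
      m <- step$met
      ins <- plan$nb$into[[m]]
      s <- ext_sums(ins)
      L[m, ] <- if (s$tot > EPS_LABEL) s$lab / s$tot else 0
      next
    }
    k <- step$k
    p <- plan$pairs[[k]]
    sP <- ext_sums(p$ext_in_P); sQ <- ext_sums(p$ext_in_Q)
    O_P <- sum(V[p$ext_out_P]); O_Q <- sum(V[p$ext_out_Q])
    Dnet <- V[[p$edge_idx]]
    T_P <- sP$tot; T_Q <- sQ$tot
    if (T_P + T_Q < EPS_LABEL) {          # zero throughput: inert pair
      L[p$source, ] <- 0; L[p$target, ] <- 0
      Df[k, ] <- 0; Dr[k, ] <- 0
      next
    }
    M <- (sP$lab + sQ$lab) / (O_P + O_Q)
    L_P0 <- if (T_P > EPS_LABEL) sP$lab / T_P else M
    L_Q0 <- if (O_Q > EPS_LABEL) (sQ$lab + L_P0 * Dnet) / O_Q else M
    # degenerate Q side (no external outflow => zero net throughput there)
    if (O_Q <= EPS_LABEL) {
      L[p$source, ] <- L_P0; L[p$target, ] <- L_P0
      Df[k, ] <- max(Dnet, 0); Dr[k, ] <- 0
      next
    }
    cyt_is_P <- identical(p$cytosol, p$source)
    Lc0 <- if (cyt_is_P) L_P0 else L_Q0
    Le0 <- if (cyt_is_P) L_Q0 else L_P0
    wc <- abs(Lc0 - M); we <- abs(Le0 - M)
    u <- U[k, ]
    LP <- LQ <- rep(NA_real_, n)
    sel_c <- wc > 1e-9
    sel_e <- !sel_c & (we > 1e-9)
    det <- !sel_c & !sel_e
    O_c <- if (cyt_is_P) O_P else O_Q
    O_e <- if (cyt_is_P) O_Q else O_P
    # sample the member with genuine freedom; derive the partner from the
    # pair-sum balance  I_P + I_Q = L_P O_P + L_Q O_Q
    Itot <- sP$lab + sQ$lab
    Lc <- Le <- rep(NA_real_, n)
    ## The admissible interval for the sampled label is known in closed
    ## form: one endpoint is the zero-exchange value, the other the
    ## complete-mixing value M.  The uniform draw u is placed directly on
    ## it (u = 0: no exchange, u = 1: full mixing) rather than on [0,1]
    ## with near-certain rejection; constraint screening still rejects.
    if (any(sel_c)) {
      v <- Lc0 + u * (M - Lc0)
      Lc[sel_c] <- v[sel_c]
      Le[sel_c] <- if (O_e > EPS_LABEL) (Itot[sel_c] - v[sel_c] * O_c) / O_e else M[sel_c]
    }
    if (any(sel_e)) {
      v <- Le0 + u * (M - Le0)
      Le[sel_e] <- v[sel_e]
      Lc[sel_e] <- if (O_c > EPS_LABEL) (Itot[sel_e] - v[sel_e] * O_e) / O_c else M[sel_e]
    }
    if (any(det)) { Lc[det] <- Lc0[det]; Le[det] <- Le0[det] }
    LP <- if (cyt_is_P) Lc else Le
    LQ <- if (cyt_is_P) Le else Lc
    # exchange from the source-pool label balance
    dL <- LQ - LP
    dr <- ifelse(abs(dL) > 1e-12,
                 (LP * (O_P + Dnet) - sP$lab) / dL,
                 0)
    dr[det] <- 0
    df <- Dnet + dr
    ok <- ok & !is.na(LP) & !is.na(LQ) &
      LP >= -EPS_LABEL & LP <= 1 + EPS_LABEL &
      LQ >= -EPS_LABEL & LQ <= 1 + EPS_LABEL &
      dr >= -1e-7 & df >= -1e-7
    L[p$source, ] <- LP; L[p$target, ] <- LQ
    Df[k, ] <- pmax(df, 0); Dr[k, ] <- pmax(dr, 0)
  }
  list(L = L, Df = Df, Dr = Dr, ok = ok & !is.na(ok))
}

#' Labeled mass-balance residuals at every pool
#'
#' Verification helper: for each internal metabolite, labeled inflow
#' minus labeled outflow under the bidirectional diffusion model.  Both
#' should vanish (to numerical precision) for any resolved label state.
#'
#' @param net A validated `pathway_network`.
#' @param flux Named total-flux vector.
#' @param labels Named pool-label vector.
#' @param feeding Feeding descriptor (for input-edge labels).
#' @param D_f,D_r Named vectors over diffusion edge ids.
#' @return Named numeric vector of residuals per metabolite.
#' @export
label_balance_residuals <- function(net, flux, labels, feeding, D_f, D_r) {
  fl <- net$fluxes
  feed <- input_labels(net, feeding)
  res <- setNames(numeric(nrow(net$metabolites)), net$metabolites$id)
  for (j in seq_len(nrow(fl))) {
    id <- fl$id[j]
    if (fl$kind[j] == "diffusion_net") {
      src <- fl$from[j]; tgt <- fl$to[j]
      res[tgt] <- res[tgt] + labels[[src]] * D_f[[id]] - labels[[tgt]] * D_r[[id]]
      res[src] <- res[src] + labels[[tgt]] * D_r[[id]] - labels[[src]] * D_f[[id]]
    } else {
      lab <- if (fl$kind[j] == "input") feed[[id]] else labels[[fl$from[j]]]
      if (!is.na(fl$to[j])) res[fl$to[j]] <- res[fl$to[j]] + lab * flux[[id]]
      if (!is.na(fl$from[j])) res[fl$from[j]] <- res[fl$from[j]] - lab * flux[[id]]
    }
  }
  res
}

#' Monte-Carlo sampling of label states conditional on a flux vector
#'
#' For each diffusion-coupled pool pair the label of the member with
#' genuine freedom (the cytosol pool when both qualify) is drawn uniform
#' on `[0,1]`; the partner follows from the joint label balance of the
#' pair, and the forward/reverse diffusion components from the
#' source-pool balance.  Pools outside pairs mix deterministically from
#' their labeled inflows.  Draws are rejected when any label leaves
#' `[0,1]`, any diffusion component is negative, or a label-incorporation
#' constraint fails.
#'
#' @param net A validated `pathway_network`.
#' @param flux Named admissible flux vector.
#' @param feeding `list(labeled_input = <input flux id>, fraction = 0.35)`
#'   or `list(tracer = "phe", fraction = 0.35)`; unlabeled inputs carry
#'   `baseline` (default 0).
#' @param n_samples Label draws.
#' @param seed Integer seed.
#' @param constraints Optional `constraint_set`; only its incorporation
#'   targets for `experiment_tag` are enforced here.
#' @param experiment_tag Tag selecting which incorporation targets apply.
#' @param pair_u Optional fixed exchange coordinate in `[0,1]` applied to
#'   every pool pair instead of a random draw: 0 pins each pair at its
#'   zero-exchange endpoint, 1 at complete mixing.
#' @return A `label_ensemble`: `labels` (accepted draws x metabolites),
#'   `D_f`, `D_r` (draws x diffusion edges), `tried`, `accepted`.
#' @export
sample_label_states <- function(net, flux, feeding, n_samples = 1000L,
                                seed = 1L, constraints = NULL,
                                experiment_tag = NULL, pair_u = NULL) {
  set.seed(seed)
  plan <- label_plan(net)
  np <- length(plan$pairs)
  U <- if (is.null(pair_u)) {
    matrix(stats::runif(max(np, 1L) * n_samples), nrow = max(np, 1L))
  } else {
    stopifnot(pair_u >= 0, pair_u <= 1)
    matrix(pair_u, nrow = max(np, 1L), ncol = n_samples)
  }
  attr(U, "n") <- n_samples
  feed <- input_labels(net, feeding)
  V <- setNames(as.numeric(flux[net$fluxes$id]), net$fluxes$id)
  res <- resolve_labels(net, plan, V, feed, U)
  keep <- res$ok
  if (!is.null(constraints))
    keep <- keep & incorporation_ok(net, V, res$L, constraints, experiment_tag)
  edge_ids <- vapply(plan$pairs, `[[`, "", "edge")
  structure(list(
    labels = t(res$L[, keep, drop = FALSE]),
    D_f = `colnames<-`(t(res$Df[seq_len(np), keep, drop = FALSE]), edge_ids),
    D_r = `colnames<-`(t(res$Dr[seq_len(np), keep, drop = FALSE]), edge_ids),
    tried = n_samples, accepted = sum(keep), seed = seed,
    feeding = feeding, network = net$name
  ), class = "label_ensemble")
}

#' @export
print.label_ensemble <- function(x, ...) {
  cat(sprintf("<label_ensemble> %s: %d / %d label draws accepted\n",
              x$network, x$accepted, x$tried))
  invisible(x)
}
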