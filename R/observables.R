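## Observables of the lignin system: monomer composition of the
## monolignol effluxes (H/G/S as % of total, S/G ratio) and per-feeding-
## experiment label incorporation (% of a flux carried by the fed 13C
## label), plus the threshold screening that defines admissibility.

OBS_INC_NAMES <- c("H", "G", "S", "total_lignin", "wall_coumaric", "wall_ferulic")

#' Load a constraint set from JSON
#'
#' The schema mirrors the published observation table:
#' \preformatted{
#' { "name": "...",
#'   "experiments": [ {"tag": "phe", "tracer": "phe", "fraction": 0.35} ],
#'   "targets": [
#'     {"name": "H_frac", "value": 4, "tol": 2, "mode": "absolute"},
#'     {"name": "SG_ratio", "value": 1.09, "tol": 0.10, "mode": "relative"},
#'     {"name": "G", "experiment": "phe", "value": 22.3, "tol": 5,
#'      "mode": "absolute"},
#'     {"name": "flux_ratio", "num": "V5", "den": "V4", "value": 3,
#'      "tol": 0.1, "mode": "absolute"} ] }
#' }
#' Composition targets (`H_frac`, `G_frac`, `S_frac`, `SG_ratio`) and
#' `flux_ratio` targets apply to total fluxes; targets named after an
#' incorporation observable (`H`, `G`, `S`, `total_lignin`,
#' `wall_coumaric`, `wall_ferulic`) carry an `experiment` tag and apply
#' to the labeling stage.
#'
#' @param config File path or JSON text.
#' @return A `constraint_set`.
#' @export
load_constraints <- function(config) {
  raw <- if (file.exists(config)) jsonlite::read_json(config, simplifyVector = FALSE)
  else jsonlite::fromJSON(config, simplifyVector = FALSE)
  opt <- function(x, default = NA_character_)
    if (is.null(x) || length(x) == 0L) default else x
  exps <- do.call(rbind, lapply(raw$experiments, function(e) data.frame(
    tag = e$tag,
    tracer = opt(e$tracer),
    labeled_input = opt(e$labeled_input),
    fraction = e$fraction,
    baseline = opt(e$baseline, 0),
    stringsAsFactors = FALSE)))
  tg <- do.call(rbind, lapply(raw$targets, function(t) data.frame(
    name = t$name,
    experiment = opt(t$experiment),
    value = as.numeric(t$value), tol = as.numeric(t$tol),
    mode = opt(t$mode, "absolute"),
    num = opt(t$num), den = opt(t$den),
    stringsAsFactors = FALSE)))
  constraint_set(targets = tg, experiments = exps,
                 name = if (is.null(raw$name)) "unnamed" else raw$name)
}

#' Construct a constraint set
#'
#' @param targets Data frame with columns `name`, `experiment`, `value`,
#'   `tol`, `mode` (and `num`/`den` for flux-ratio targets).
#' @param experiments Data frame of feeding experiments (`tag`, `tracer`
#'   or `labeled_input`, `fraction`, `baseline`); may be `NULL` when no
#'   incorporation targets are present.
#' @param name Label for reports.
#' @return A `constraint_set`.
#' @export
constraint_set <- function(targets, experiments = NULL, name = "constraints") {
  valid <- c("H_frac", "G_frac", "S_frac", "SG_ratio", "flux_ratio", OBS_INC_NAMES)
  if (!all(targets$name %in% valid))
    lf_stop("lignflux_schema_error", "unknown observable in targets: %s",
            paste(setdiff(targets$name, valid), collapse = ", "))
  if (any(targets$tol <= 0))
    lf_stop("lignflux_schema_error", "tolerances must be > 0")
  inc <- targets$name %in% OBS_INC_NAMES
  if (any(inc & is.na(targets$experiment)))
    lf_stop("lignflux_schema_error",
            "incorporation targets need an experiment tag")
  if (!is.null(experiments)) {
    bad <- setdiff(stats::na.omit(targets$experiment), experiments$tag)
    if (length(bad))
      lf_stop("lignflux_schema_error", "targets reference unknown experiment: %s",
              paste(bad, collapse = ", "))
  }
  structure(list(name = name, targets = targets, experiments = experiments,
                 nonnegative = TRUE),
            class = "constraint_set")
}

feeding_of <- function(constraints, tag) {
  e <- constraints$experiments
  row <- e[e$tag == tag, , drop = FALSE]
  if (nrow(row) != 1L)
    lf_stop("lignflux_schema_error", "no experiment tagged '%s'", tag)
  list(tag = tag,
       tracer = if (is.na(row$tracer)) NULL else row$tracer,
       labeled_input = if (is.na(row$labeled_input)) NULL else row$labeled_input,
       fraction = row$fraction, baseline = row$baseline)
}

#' Compute composition and incorporation observables
#'
#' Monomer fractions are the H/G/S sink effluxes as percentages of their
#' sum; incorporation is 100 x labeled / total flux for each observable
#' efflux, with `total_lignin` pooling the three monolignol sinks.
#'
#' @param net A `pathway_network` with sink roles assigned.
#' @param flux Named total-flux vector.
#' @param labels Optional named list: per experiment tag, a named vector
#'   of pool label fractions (e.g. a row of a `label_ensemble`).
#' @return List with `H_frac`, `G_frac`, `S_frac`, `SG_ratio` and, when
#'   labels are given, `label_incorporation[[tag]]` named vectors over
#'   `r paste(OBS_INC_NAMES, collapse=", ")`.
#' @export
compute_observables <- function(net, flux, labels = NULL) {
  sinks <- sink_effluxes(net)
  if (length(sinks) < 3L)
    lf_stop("lignflux_missing_role",
            "network must assign H_sink, G_sink and S_sink roles")
  V <- setNames(as.numeric(flux[net$fluxes$id]), net$fluxes$id)
  hv <- V[[sinks$H_sink]]; gv <- V[[sinks$G_sink]]; sv <- V[[sinks$S_sink]]
  tot <- hv + gv + sv
  obs <- list(H_frac = 100 * hv / tot, G_frac = 100 * gv / tot,
              S_frac = 100 * sv / tot, SG_ratio = sv / gv)
  if (!is.null(labels)) {
    obs$label_incorporation <- lapply(labels, function(L) {
      Lm <- matrix(L, ncol = 1, dimnames = list(names(L), NULL))
      drop(incorporation_values(net, V, Lm))
    })
  }
  obs
}

## vectorized incorporation observables: Lmat is [mets x n]
incorporation_values <- function(net, V, Lmat) {
  sinks <- sink_effluxes(net)
  fl <- net$fluxes
  pool_of <- function(eidx) fl$from[eidx]
  out <- matrix(NA_real_, length(OBS_INC_NAMES), ncol(Lmat),
                dimnames = list(OBS_INC_NAMES, NULL))
  sink_map <- c(H = "H_sink", G = "G_sink", S = "S_sink")
  for (nm in names(sink_map)) {
    e <- sinks[[sink_map[[nm]]]]
    out[nm, ] <- 100 * Lmat[pool_of(e), ]
  }
  vs <- vapply(sinks, function(e) V[[e]], 0)
  labsum <- rep(0, ncol(Lmat))
  for (e in sinks) labsum <- labsum + Lmat[pool_of(e), ] * V[[e]]
  out["total_lignin", ] <- 100 * labsum / sum(vs)
  for (nm in c("wall_coumaric", "wall_ferulic")) {
    m <- role_metabolite(net, nm)
    if (!is.na(m)) out[nm, ] <- 100 * Lmat[m, ]
  }
  out
}

## vectorized check of incorporation targets for one experiment tag
incorporation_ok <- function(net, V, Lmat, constraints, tag) {
  tg <- constraints$targets
  tg <- tg[!is.na(tg$experiment) & tg$experiment == tag, , drop = FALSE]
  keep <- rep(TRUE, ncol(Lmat))
  if (!nrow(tg)) return(keep)
  vals <- incorporation_values(net, V, Lmat)
  for (i in seq_len(nrow(tg)))
    keep <- keep & target_ok(vals[tg$name[i], ], tg$value[i], tg$tol[i], tg$mode[i])
  keep
}

#' Check observables against a constraint set
#'
#' Evaluates every target and reports per-target residuals; the overall
#' verdict is the conjunction.  Passing is monotone in tolerance: any
#' pass at tolerance t also passes at t' > t.
#'
#' @param obs Observables from [compute_observables()].
#' @param constraints A `constraint_set`.
#' @param flux Optional named total-flux vector, needed only for
#'   `flux_ratio` targets.
#' @return List with `pass` (logical) and `residuals` (data frame with
#'   `name`, `experiment`, `value`, `target`, `tol`, `mode`, `residual`,
#'   `ok`).
#' @export
check_constraints <- function(obs, constraints, flux = NULL) {
  tg <- constraints$targets
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    nm <- tg$name[i]
    v <- if (nm == "flux_ratio") {
      if (is.null(flux)) NA_real_ else flux[[tg$num[i]]] / flux[[tg$den[i]]]
    } else if (!is.na(tg$experiment[i])) {
      inc <- obs$label_incorporation[[tg$experiment[i]]]
      if (is.null(inc)) NA_real_ else inc[[nm]]
    } else obs[[nm]]
    data.frame(name = nm, experiment = tg$experiment[i], value = v,
               target = tg$value[i], tol = tg$tol[i], mode = tg$mode[i],
               residual = v - tg$value[i],
               ok = isTRUE(target_ok(v, tg$value[i], tg$tol[i], tg$mode[i])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  list(pass = all(res$ok), residuals = res)
}
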