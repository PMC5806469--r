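#' @importFrom jsonlite fromJSON toJSON read_json write_json
#' @importFrom stats median quantile runif rnorm setNames
#' @importFrom utils write.table read.csv
NULL

## Condition helper: every validation failure carries a distinct class so
## callers can discriminate failure modes programmatically.
lf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lignflux_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

lf_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "lignflux_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

VALID_COMPARTMENTS <- c("cytosol", "ER", "external")
VALID_KINDS <- c("enzymatic", "diffusion_net", "efflux", "input")
VALID_ROLES <- c("H_sink", "G_sink", "S_sink",
                 "wall_ferulic", "wall_coumaric", "input_pool")

#' Load and validate a pathway network from a JSON description
#'
#' Reads a compartmental metabolic network -- metabolites tagged with a
#' compartment (`cytosol`, `ER` or `external`) and typed flux edges
#' (`enzymatic`, `diffusion_net`, `input`, `efflux`) -- and checks all
#' structural invariants: unique ids, monomolecular stoichiometry (all
#' coefficients +-1), diffusion edges joining exactly one cytosol and one
#' ER pool of the same chemical species, acyclicity of the net-flux graph,
#' and every internal pool having at least one producing and one consuming
#' edge.
#'
#' The JSON schema is:
#' \preformatted{
#' { "name": "...", "r": 1,
#'   "metabolites": [ {"id": "x1", "name": "...", "compartment": "cytosol",
#'                     "species": "x", "roles": ["G_sink"]} , ... ],
#'   "fluxes": [ {"id": "V_1", "kind": "enzymatic", "enzyme": "PAL",
#'                "substrates": [{"metabolite": "x1", "coefficient": -1}],
#'                "products":   [{"metabolite": "x2", "coefficient":  1}],
#'                "tracer": null, "volume_factor": 1}, ... ] }
#' }
#' `species` defaults to the metabolite id; it identifies the chemical
#' entity so that a diffusion edge can be checked to connect two pools of
#' the same compound.  `tracer` tags input edges that a feeding experiment
#' can label (e.g. `"phe"`, `"tyr"`).  `r` (or per-edge `volume_factor`)
#' is the compartment-volume compensation constant for diffusion edges; it
#' is carried on the object but inert in steady-state analyses.
#'
#' @param config Path to a JSON file, or a length-one character scalar of
#'   JSON text.
#' @return A validated object of class `pathway_network`.
#' @export
load_network <- function(config) {
  if (length(config) != 1L || !is.character(config))
    lf_stop("lignflux_schema_error", "config must be a file path or JSON string")
  raw <- if (file.exists(config)) {
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  parse_network(raw)
}

parse_network <- function(raw) {
  if (is.null(raw$metabolites) || is.null(raw$fluxes))
    lf_stop("lignflux_schema_error",
            "network config must contain 'metabolites' and 'fluxes'")
  r_default <- if (is.null(raw$r)) 1 else as.numeric(raw$r)

  mets <- lapply(raw$metabolites, function(m) {
    if (is.null(m$id))
      lf_stop("lignflux_schema_error", "metabolite without an id")
    list(
      id          = as.character(m$id),
      name        = if (is.null(m$name)) as.character(m$id) else as.character(m$name),
      compartment = if (is.null(m$compartment)) "cytosol" else as.character(m$compartment),
      species     = if (is.null(m$species)) as.character(m$id) else as.character(m$species),
      roles       = as.character(unlist(m$roles))
    )
  })
  met_ids <- vapply(mets, `[[`, "", "id")
  if (anyDuplicated(met_ids))
    lf_stop("lignflux_duplicate_id", "duplicate metabolite id: %s",
            paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  comps <- vapply(mets, `[[`, "", "compartment")
  if (!all(comps %in% VALID_COMPARTMENTS))
    lf_stop("lignflux_schema_error", "invalid compartment: %s",
            paste(setdiff(comps, VALID_COMPARTMENTS), collapse = ", "))
  all_roles <- unlist(lapply(mets, `[[`, "roles"))
  if (!all(all_roles %in% VALID_ROLES))
    lf_stop("lignflux_schema_error", "unknown role: %s",
            paste(setdiff(all_roles, VALID_ROLES), collapse = ", "))
  if (anyDuplicated(all_roles))
    lf_stop("lignflux_role_conflict",
            "role assigned to more than one metabolite: %s",
            paste(unique(all_roles[duplicated(all_roles)]), collapse = ", "))

  side <- function(entries, want_sign, flux_id, what) {
    if (is.null(entries) || length(entries) == 0L) return(character(0))
    vapply(entries, function(e) {
      if (is.null(e$metabolite) || is.null(e$coefficient))
        lf_stop("lignflux_schema_error",
                "flux %s: %s entries need 'metabolite' and 'coefficient'",
                flux_id, what)
      if (abs(abs(as.numeric(e$coefficient)) - 1) > 0)
        lf_stop("lignflux_bad_stoichiometry",
                "flux %s: coefficient must be +1 or -1 (monomolecular pathway)",
                flux_id)
      as.character(e$metabolite)
    }, "")
  }

  fls <- lapply(raw$fluxes, function(f) {
    if (is.null(f$id) || is.null(f$kind))
      lf_stop("lignflux_schema_error", "flux without id or kind")
    kind <- as.character(f$kind)
    if (!kind %in% VALID_KINDS)
      lf_stop("lignflux_schema_error", "flux %s: invalid kind '%s'", f$id, kind)
    subs <- side(f$substrates, -1, f$id, "substrate")
    prods <- side(f$products, +1, f$id, "product")
    if (kind == "input" && length(subs) > 0L)
      lf_stop("lignflux_schema_error", "input flux %s must have no substrates", f$id)
    if (kind == "efflux" && length(prods) > 0L)
      lf_stop("lignflux_schema_error", "efflux %s must have no products", f$id)
    if (kind != "input" && length(subs) != 1L)
      lf_stop("lignflux_bad_stoichiometry",
              "flux %s: exactly one substrate required (monomolecular)", f$id)
    if (kind != "efflux" && length(prods) != 1L)
      lf_stop("lignflux_bad_stoichiometry",
              "flux %s: exactly one product required (monomolecular)", f$id)
    list(
      id = as.character(f$id), kind = kind,
      from = if (length(subs)) subs else NA_character_,
      to   = if (length(prods)) prods else NA_character_,
      enzyme = if (is.null(f$enzyme)) NA_character_ else as.character(f$enzyme),
      tracer = if (is.null(f$tracer)) NA_character_ else as.character(f$tracer),
      volume_factor = if (is.null(f$volume_factor)) r_default else as.numeric(f$volume_factor)
    )
  })
  flux_ids <- vapply(fls, `[[`, "", "id")
  if (anyDuplicated(flux_ids))
    lf_stop("lignflux_duplicate_id", "duplicate flux id: %s",
            paste(unique(flux_ids[duplicated(flux_ids)]), collapse = ", "))
  if (anyDuplicated(c(flux_ids, met_ids)))
    lf_stop("lignflux_duplicate_id", "flux id collides with metabolite id")

  met_tab <- data.frame(
    id = met_ids,
    name = vapply(mets, `[[`, "", "name"),
    compartment = comps,
    species = vapply(mets, `[[`, "", "species"),
    stringsAsFactors = FALSE
  )
  met_tab$roles <- lapply(mets, `[[`, "roles")

  flux_tab <- data.frame(
    id = flux_ids,
    kind = vapply(fls, `[[`, "", "kind"),
    from = vapply(fls, `[[`, "", "from"),
    to = vapply(fls, `[[`, "", "to"),
    enzyme = vapply(fls, `[[`, "", "enzyme"),
    tracer = vapply(fls, `[[`, "", "tracer"),
    volume_factor = vapply(fls, `[[`, 0, "volume_factor"),
    stringsAsFactors = FALSE
  )

  net <- structure(list(
    name = if (is.null(raw$name)) "unnamed" else as.character(raw$name),
    r = r_default,
    metabolites = met_tab,
    fluxes = flux_tab
  ), class = "pathway_network")
  validate_network(net)
  net
}

#' Validate structural invariants of a pathway network
#'
#' Called by [load_network()]; exported so that programmatically built
#' networks can be checked too.  Raises classed conditions
#' (`lignflux_bad_diffusion`, `lignflux_cyclic_network`,
#' `lignflux_dangling_metabolite`, ...) on violation.
#'
#' @param net A `pathway_network`.
#' @return `net`, invisibly, if valid.
#' @export
validate_network <- function(net) {
  met <- net$metabolites
  fl <- net$fluxes
  refd <- c(fl$from, fl$to)
  refd <- refd[!is.na(refd)]
  if (!all(refd %in% met$id))
    lf_stop("lignflux_schema_error", "flux references unknown metabolite: %s",
            paste(setdiff(refd, met$id), collapse = ", "))

  comp_of <- setNames(met$compartment, met$id)
  spec_of <- setNames(met$species, met$id)
  for (i in which(fl$kind == "diffusion_net")) {
    a <- fl$from[i]; b <- fl$to[i]
    if (is.na(a) || is.na(b))
      lf_stop("lignflux_bad_diffusion",
              "diffusion edge %s must have one substrate and one product", fl$id[i])
    if (!setequal(c(comp_of[[a]], comp_of[[b]]), c("cytosol", "ER")))
      lf_stop("lignflux_bad_diffusion",
              "diffusion edge %s must join one cytosol and one ER pool", fl$id[i])
    if (spec_of[[a]] != spec_of[[b]])
      lf_stop("lignflux_bad_diffusion",
              "diffusion edge %s joins pools of different species (%s, %s)",
              fl$id[i], spec_of[[a]], spec_of[[b]])
  }

  internal <- met$id[met$compartment != "external"]
  produced <- fl$to[!is.na(fl$to)]
  consumed <- fl$from[!is.na(fl$from)]
  orphan <- setdiff(internal, intersect(produced, consumed))
  if (length(orphan))
    lf_stop("lignflux_dangling_metabolite",
            "metabolite(s) without both a producing and a consuming edge: %s",
            paste(orphan, collapse = ", "))

  topological_order(net)  # raises lignflux_cyclic_network on a cycle
  invisible(net)
}

#' Topological order of the net-flux DAG
#'
#' Kahn's algorithm over metabolite pools, treating every edge (including
#' net diffusion) as directed from its substrate to its product.
#'
#' @param net A `pathway_network`.
#' @return Character vector of metabolite ids in topological order.
#' @keywords internal
topological_order <- function(net) {
  met <- net$metabolites$id
  fl <- net$fluxes
  edges <- fl[!is.na(fl$from) & !is.na(fl$to), c("from", "to")]
  indeg <- setNames(integer(length(met)), met)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- met[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    outs <- edges$to[edges$from == v]
    for (w in outs) {
      indeg_left[[w]] <- indeg_left[[w]] - 1L
      if (indeg_left[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != length(met))
    lf_stop("lignflux_cyclic_network",
            "net-flux graph contains a cycle through: %s",
            paste(setdiff(met, order), collapse = ", "))
  order
}

#' Build the stoichiometric matrix of a network
#'
#' Returns the signed incidence matrix S with one row per metabolite and
#' one column per flux: `S[i, j]` is +1 if flux j produces metabolite i,
#' -1 if it consumes it, 0 otherwise, so that pool dynamics obey
#' \eqn{\dot X = S V}.  Internal-conversion columns sum to 0, input
#' columns to +1 and efflux columns to -1.
#'
#' @param net A validated `pathway_network`.
#' @return An integer matrix with dimnames (metabolite ids, flux ids).
#' @export
build_stoichiometric_matrix <- function(net) {
  met <- net$metabolites$id
  fl <- net$fluxes
  S <- matrix(0L, nrow = length(met), ncol = nrow(fl),
              dimnames = list(met, fl$id))
  for (j in seq_len(nrow(fl))) {
    if (!is.na(fl$from[j])) S[fl$from[j], j] <- S[fl$from[j], j] - 1L
    if (!is.na(fl$to[j]))   S[fl$to[j], j]   <- S[fl$to[j], j] + 1L
  }
  S
}

#' Write a stoichiometric matrix as TSV
#'
#' Plain tab-separated export with metabolite rows and flux columns.
#'
#' @param S Matrix from [build_stoichiometric_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stoichiometric_tsv <- function(S, path) {
  df <- data.frame(metabolite = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Diverging branch points of a network
#'
#' Every metabolite with two or more outgoing net edges, in topological
#' order of the net-flux DAG.  Each k-way branch contributes k - 1 degrees
#' of freedom to the underdetermined steady state; these are the
#' coordinates that flux split ratios parameterize.
#'
#' @param net A validated `pathway_network`.
#' @return A list with one element per branch metabolite: `list(metabolite
#'   = id, out = character vector of outgoing flux ids)`.  The total
#'   degrees of freedom are `sum(lengths - 1)` and are attached as
#'   attribute `"dof"`.
#' @export
branch_points <- function(net) {
  ord <- topological_order(net)
  fl <- net$fluxes
  out <- lapply(ord, function(m) {
    ids <- fl$id[!is.na(fl$from) & fl$from == m]
    if (length(ids) >= 2L) list(metabolite = m, out = ids) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  attr(out, "dof") <- sum(vapply(out, function(b) length(b$out) - 1L, 0L))
  out
}

#' Serialize a pathway network back to JSON
#'
#' Inverse of [load_network()]: the emitted text parses to a network equal
#' to the original (round-trip property).
#'
#' @param net A `pathway_network`.
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to a file).
#' @export
write_network <- function(net, path = NULL) {
  met <- net$metabolites
  fl <- net$fluxes
  obj <- list(
    name = net$name,
    r = net$r,
    metabolites = lapply(seq_len(nrow(met)), function(i) {
      m <- list(id = met$id[i], name = met$name[i],
                compartment = met$compartment[i], species = met$species[i])
      if (length(met$roles[[i]])) m$roles <- as.list(met$roles[[i]])
      m
    }),
    fluxes = lapply(seq_len(nrow(fl)), function(i) {
      f <- list(id = fl$id[i], kind = fl$kind[i])
      if (!is.na(fl$from[i]))
        f$substrates <- list(list(metabolite = fl$from[i], coefficient = -1))
      if (!is.na(fl$to[i]))
        f$products <- list(list(metabolite = fl$to[i], coefficient = 1))
      if (!is.na(fl$enzyme[i])) f$enzyme <- fl$enzyme[i]
      if (!is.na(fl$tracer[i])) f$tracer <- fl$tracer[i]
      f$volume_factor <- fl$volume_factor[i]
      f
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Path to a network or constraint file shipped with the package
#'
#' Available names: `"illustration"`, `"brachy_fig4"`, `"brachy_fig5"`,
#' `"brachy_fig6"` (networks) and `"table1_constraints"` (constraint set).
#'
#' @param name File stem, without extension.
#' @return Absolute path to the installed JSON file.
#' @export
lignflux_file <- function(name) {
  p <- system.file("extdata", paste0(name, ".json"), package = "lignflux")
  if (p == "")
    lf_stop("lignflux_schema_error", "no shipped file named '%s'", name)
  p
}

## --- internal topology helpers shared by the samplers --------------------

# out-edges / in-edges per metabolite, as flux row indices
edges_by_node <- function(net) {
  fl <- net$fluxes
  list(
    out = lapply(setNames(net$metabolites$id, net$metabolites$id),
                 function(m) which(!is.na(fl$from) & fl$from == m)),
    into = lapply(setNames(net$metabolites$id, net$metabolites$id),
                  function(m) which(!is.na(fl$to) & fl$to == m))
  )
}

# diffusion-coupled pool pairs: source pool (edge substrate), target pool
diffusion_pairs <- function(net) {
  fl <- net$fluxes
  idx <- which(fl$kind == "diffusion_net")
  lapply(idx, function(i) {
    comp_from <- net$metabolites$compartment[net$metabolites$id == fl$from[i]]
    list(edge = fl$id[i], edge_idx = i,
         source = fl$from[i], target = fl$to[i],
         cytosol = if (comp_from == "cytosol") fl$from[i] else fl$to[i],
         er      = if (comp_from == "cytosol") fl$to[i] else fl$from[i])
  })
}

#' @export
print.pathway_network <- function(x, ...) {
  bp <- branch_points(x)
  cat(sprintf("<pathway_network> %s\n", x$name))
  cat(sprintf("  %d metabolites (%d cytosol, %d ER), %d fluxes\n",
              nrow(x$metabolites),
              sum(x$metabolites$compartment == "cytosol"),
              sum(x$metabolites$compartment == "ER"),
              nrow(x$fluxes)))
  cat(sprintf("  %d diffusion edge(s), %d branch point(s), %d degrees of freedom\n",
              sum(x$fluxes$kind == "diffusion_net"),
              length(bp), attr(bp, "dof")))
  invisible(x)
}
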