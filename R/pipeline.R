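## Orchestration: FSR sampling -> per-experiment label resolution ->
## constraint filtering -> ensemble summaries and boxplot reports.

DEFAULT_TOL_COMP <- 2     # percentage points, monomer fractions
DEFAULT_TOL_SG   <- 0.10  # relative, S/G ratio
DEFAULT_TOL_INC  <- 5     # percentage points, label incorporation

#' Sample a fully constrained flux + label ensemble
#'
#' Two-stage conditional Monte-Carlo: split-ratio vectors are drawn and
#' propagated to total fluxes, screened against the composition and flux
#' constraints; for each survivor, label states are drawn for every
#' feeding experiment in the constraint set and screened against the
#' incorporation constraints.  A flux vector joins the ensemble when at
#' least one label draw passes for every experiment (joint filtering);
#' the first passing label state per experiment is recorded.
#'
#' @param net A validated `pathway_network`.
#' @param constraints A `constraint_set` (may be `NULL`: non-negativity
#'   only, no labeling stage).
#' @param n_samples FSR draws.
#' @param seed Integer seed controlling both stages.
#' @param label_tries Label draws attempted per survivor and experiment.
#' @param input_value Magnitude of each input flux.
#' @return A `lignflux_ensemble`: accepted total fluxes (`flux`), their
#'   split ratios (`fsr`), per-experiment label states and diffusion
#'   components (`experiments`), and sampler metadata.
#' @export
sample_ensemble <- function(net, constraints = NULL, n_samples = 10000L,
                            seed = 1L, label_tries = 200L, input_value = 100) {
  stage1 <- suppressWarnings(
    sample_admissible_fluxes(net, constraints, n_samples, seed, input_value))
  tags <- if (!is.null(constraints) && !is.null(constraints$experiments))
    constraints$experiments$tag else character(0)
  # experiments matter only if any incorporation target references them
  tags <- tags[tags %in% constraints$targets$experiment]
  n1 <- nrow(stage1$members)
  if (n1 == 0L || length(tags) == 0L) {
    ens <- structure(list(
      network = net$name, constraints = if (is.null(constraints)) NA else constraints$name,
      n_samples = n_samples, seed = seed, accepted = n1,
      flux = stage1$members, fsr = stage1$fsr,
      experiments = setNames(list(), character(0)),
      input_value = input_value, stage1_accepted = n1,
      label_tries = label_tries
    ), class = "lignflux_ensemble")
    if (ens$accepted == 0L)
      lf_warn("lignflux_empty_ensemble",
              "empty ensemble for network '%s'", net$name)
    return(ens)
  }
  plan <- label_plan(net)
  np <- length(plan$pairs)
  edge_ids <- vapply(plan$pairs, `[[`, "", "edge")
  keep <- rep(TRUE, n1)
  lab_keep <- lapply(tags, function(t)
    list(labels = matrix(NA_real_, n1, nrow(net$metabolites),
                         dimnames = list(NULL, net$metabolites$id)),
         D_f = matrix(NA_real_, n1, np, dimnames = list(NULL, edge_ids)),
         D_r = matrix(NA_real_, n1, np, dimnames = list(NULL, edge_ids))))
  names(lab_keep) <- tags
  feeds <- lapply(setNames(tags, tags), function(t) feeding_of(constraints, t))
  for (i in seq_len(n1)) {
    V <- setNames(stage1$members[i, ], colnames(stage1$members))
    for (t in tags) {
      if (!keep[i]) break
      sub_seed <- (seed * 48271 + i * 127 + match(t, tags)) %% 2147483629L
      le <- sample_label_states(net, V, feeds[[t]], n_samples = label_tries,
                                seed = sub_seed, constraints = constraints,
                                experiment_tag = t)
      if (le$accepted == 0L) { keep[i] <- FALSE; break }
      lab_keep[[t]]$labels[i, ] <- le$labels[1L, ]
      if (np) {
        lab_keep[[t]]$D_f[i, ] <- le$D_f[1L, ]
        lab_keep[[t]]$D_r[i, ] <- le$D_r[1L, ]
      }
    }
  }
  ens <- structure(list(
    network = net$name, constraints = constraints$name,
    n_samples = n_samples, seed = seed, accepted = sum(keep),
    flux = stage1$members[keep, , drop = FALSE],
    fsr = stage1$fsr[keep, , drop = FALSE],
    experiments = lapply(lab_keep, function(x)
      list(labels = x$labels[keep, , drop = FALSE],
           D_f = x$D_f[keep, , drop = FALSE],
           D_r = x$D_r[keep, , drop = FALSE])),
    input_value = input_value, stage1_accepted = n1,
    label_tries = label_tries
  ), class = "lignflux_ensemble")
  if (ens$accepted == 0L)
    lf_warn("lignflux_empty_ensemble", "empty ensemble for network '%s'", net$name)
  ens
}

#' @export
print.lignflux_ensemble <- function(x, ...) {
  cat(sprintf("<lignflux_ensemble> %s vs %s: %d accepted (of %d FSR draws; %d passed the steady-state stage)\n",
              x$network, x$constraints, x$accepted, x$n_samples, x$stage1_accepted))
  invisible(x)
}

## matrix of all summarizable columns of an ensemble: total fluxes,
## diffusion directions, observables, per-experiment labeled percentages
ensemble_columns <- function(net, ens) {
  if (ens$accepted == 0L) lf_stop("lignflux_empty_ensemble", "empty ensemble")
  cols <- list()
  Fm <- ens$flux
  for (j in colnames(Fm)) cols[[j]] <- Fm[, j]
  fl <- net$fluxes
  has_roles <- length(sink_effluxes(net)) == 3L
  if (has_roles) {
    sinks <- sink_effluxes(net)
    hv <- Fm[, sinks$H_sink]; gv <- Fm[, sinks$G_sink]; sv <- Fm[, sinks$S_sink]
    tot <- hv + gv + sv
    cols$H_frac <- 100 * hv / tot
    cols$G_frac <- 100 * gv / tot
    cols$S_frac <- 100 * sv / tot
    cols$SG_ratio <- sv / gv
  }
  for (t in names(ens$experiments)) {
    ex <- ens$experiments[[t]]
    for (d in colnames(ex$D_f)) {
      cols[[sprintf("%s.f|%s", d, t)]] <- ex$D_f[, d]
      cols[[sprintf("%s.r|%s", d, t)]] <- ex$D_r[, d]
    }
    # labeled percentage of each flux: 100 * L(source pool)
    for (j in which(!is.na(fl$from) & fl$kind != "diffusion_net")) {
      cols[[sprintf("pct_labeled:%s|%s", fl$id[j], t)]] <-
        100 * ex$labels[, fl$from[j]]
    }
    if (has_roles) {
      V <- colMeans(Fm)  # incorporation uses member fluxes below
      inc <- vapply(seq_len(nrow(Fm)), function(i)
        incorporation_values(net, setNames(Fm[i, ], colnames(Fm)),
                             matrix(ex$labels[i, ], ncol = 1,
                                    dimnames = list(colnames(ex$labels), NULL)))[, 1],
        numeric(length(OBS_INC_NAMES)))
      for (nm in OBS_INC_NAMES)
        if (!all(is.na(inc[nm, ])))
          cols[[sprintf("inc:%s|%s", nm, t)]] <- inc[nm, ]
    }
  }
  do.call(cbind, cols)
}

#' Five-number summaries of an admissible ensemble
#'
#' Classical boxplot statistics (quartiles, median, 1.5 x IQR whiskers
#' clamped to the data range) for every total flux, both directions of
#' every diffusion flux per experiment, composition observables, labeled
#' percentages and incorporation observables.
#'
#' @param ens A non-empty `lignflux_ensemble` (or `flux_ensemble`).
#' @param net The `pathway_network` the ensemble was sampled from.
#' @return Data frame with columns `column`, `n`, `min`, `lo_whisker`,
#'   `q1`, `median`, `q3`, `hi_whisker`, `max`.
#' @export
summarize_ensemble <- function(ens, net) {
  M <- if (inherits(ens, "flux_ensemble")) {
    if (nrow(ens$members) == 0L) lf_stop("lignflux_empty_ensemble", "empty ensemble")
    ens$members
  } else ensemble_columns(net, ens)
  rows <- lapply(colnames(M), function(cn) {
    x <- M[, cn]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.frame(column = cn, n = length(x), min = min(x),
               lo_whisker = max(min(x), q[1] - 1.5 * iqr),
               q1 = q[1], median = q[2], q3 = q[3],
               hi_whisker = min(max(x), q[3] + 1.5 * iqr),
               max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median observables of an ensemble
#'
#' Convenience accessor: ensemble medians of the composition observables
#' and of each experiment's incorporation observables, on the percentage
#' scale of the published table.
#'
#' @param ens A non-empty `lignflux_ensemble`.
#' @param net The source `pathway_network`.
#' @return Named list: `H_frac`, `G_frac`, `S_frac`, `SG_ratio`,
#'   `label_incorporation[[tag]]`.
#' @export
ensemble_median_observables <- function(ens, net) {
  sm <- summarize_ensemble(ens, net)
  med <- setNames(sm$median, sm$column)
  out <- list(H_frac = med[["H_frac"]], G_frac = med[["G_frac"]],
              S_frac = med[["S_frac"]], SG_ratio = med[["SG_ratio"]])
  out$label_incorporation <- lapply(setNames(nm = names(ens$experiments)), function(t) {
    keys <- sprintf("inc:%s|%s", OBS_INC_NAMES, t)
    present <- keys %in% names(med)
    setNames(med[keys[present]], OBS_INC_NAMES[present])
  })
  out
}

#' Boxplot of ensemble distributions
#'
#' Distributions of admissible values, one box per column (1.5 x IQR
#' whiskers).  With `what = "pct_labeled"` the panel mirrors the
#' labeled-flow comparison across feeding experiments; `what = "flux"`
#' shows total steady-state fluxes.
#'
#' @param ens Non-empty `lignflux_ensemble`.
#' @param net Source network.
#' @param what One of `"flux"`, `"pct_labeled"`, `"diffusion"`.
#' @return A `ggplot` object.
#' @export
plot_ensemble <- function(ens, net, what = c("flux", "pct_labeled", "diffusion")) {
  what <- match.arg(what)
  M <- ensemble_columns(net, ens)
  cn <- colnames(M)
  sel <- switch(what,
    flux = cn %in% net$fluxes$id,
    pct_labeled = grepl("^pct_labeled:", cn),
    diffusion = grepl("^D[^|]*\\.[fr]\\|", cn))
  long <- do.call(rbind, lapply(cn[sel], function(c2) {
    parts <- strsplit(sub("^pct_labeled:", "", c2), "|", fixed = TRUE)[[1]]
    data.frame(column = parts[1],
               experiment = if (length(parts) > 1) parts[2] else "total",
               value = M[, c2], stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$value,
                                     fill = .data$experiment)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, coef = 1.5) +
    ggplot2::labs(
      x = NULL,
      y = switch(what, flux = "steady-state flux (input = 100)",
                 pct_labeled = "labeled share of flux (%)",
                 diffusion = "diffusion component magnitude"),
      caption = "boxes: quartiles; whiskers: 1.5 x IQR") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 .data
NULL

#' Run the full analysis pipeline and write its artifacts
#'
#' Loads a network and constraint set, samples the admissible ensemble,
#' and writes to `out_dir`: the total-flux ensemble CSV, a per-experiment
#' labeled ensemble CSV, the summary table, per-member residual report,
#' boxplot figures and a machine-readable manifest from which the run can
#' be reproduced exactly.
#'
#' @param network_file Path to a network JSON.
#' @param constraints_file Path to a constraint JSON (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param n_samples,seed,label_tries,input_value Sampler settings, see
#'   [sample_ensemble()].
#' @param plots Write boxplot PNGs (skipped silently if no graphics
#'   device is available).
#' @return Invisibly, a list with the ensemble, summary, manifest path
#'   and `status` (0 = non-empty ensemble, 3 = empty).
#' @export
run_pipeline <- function(network_file, constraints_file = NULL, out_dir,
                         n_samples = 10000L, seed = 1L, label_tries = 200L,
                         input_value = 100, plots = TRUE) {
  net <- load_network(network_file)
  constraints <- if (!is.null(constraints_file)) load_constraints(constraints_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- suppressWarnings(
    sample_ensemble(net, constraints, n_samples = n_samples, seed = seed,
                    label_tries = label_tries, input_value = input_value))

  manifest <- list(
    tool = "lignflux", version = as.character(utils::packageVersion("lignflux")),
    network = jsonlite::fromJSON(write_network(net), simplifyVector = FALSE),
    constraints = if (is.null(constraints)) NULL else constraint_set_json(constraints),
    n_samples = n_samples, seed = seed, label_tries = label_tries,
    input_value = input_value,
    stage1_accepted = ens$stage1_accepted, accepted = ens$accepted)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  write_flux_csv(ens, file.path(out_dir, "ensemble_flux.csv"))
  for (t in names(ens$experiments))
    write_labeled_csv(ens, net, t,
                      file.path(out_dir, sprintf("ensemble_labeled_%s.csv", t)))

  status <- if (ens$accepted > 0L) 0L else 3L
  summary_df <- NULL
  if (ens$accepted > 0L) {
    summary_df <- summarize_ensemble(ens, net)
    utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(constraints))
      write_residuals(ens, net, constraints, file.path(out_dir, "residuals.tsv"))
    if (plots) try(silent = TRUE, {
      ggplot2::ggsave(file.path(out_dir, "boxplot_total_flux.png"),
                      plot_ensemble(ens, net, "flux"),
                      width = 9, height = 4, dpi = 120)
      if (length(ens$experiments))
        ggplot2::ggsave(file.path(out_dir, "boxplot_labeled_pct.png"),
                        plot_ensemble(ens, net, "pct_labeled"),
                        width = 9, height = 4, dpi = 120)
    })
  } else {
    writeLines(sprintf(
      "network '%s' admits no solution satisfying '%s' (%d samples, seed %d)",
      net$name, if (is.null(constraints)) "non-negativity" else constraints$name,
      n_samples, seed),
      file.path(out_dir, "EMPTY_ENSEMBLE.txt"))
  }
  invisible(list(ensemble = ens, summary = summary_df, status = status,
                 manifest = file.path(out_dir, "manifest.json"),
                 out_dir = out_dir))
}

constraint_set_json <- function(constraints) {
  row_list <- function(df, i) {
    l <- lapply(as.list(df[i, , drop = FALSE]), `[[`, 1L)
    l[!vapply(l, function(x) length(x) != 1L || is.na(x), TRUE)]
  }
  list(name = constraints$name,
       experiments = if (is.null(constraints$experiments)) NULL else
         lapply(seq_len(nrow(constraints$experiments)),
                function(i) row_list(constraints$experiments, i)),
       targets = lapply(seq_len(nrow(constraints$targets)),
                        function(i) row_list(constraints$targets, i)))
}

#' Re-run a pipeline from its manifest
#'
#' The manifest embeds the network, the constraint set and every sampler
#' setting, so a run is exactly reproducible from it alone.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Output directory for the reproduced run.
#' @return As [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  nf <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(man$network, auto_unbox = TRUE,
                                           digits = NA)), nf)
  cf <- NULL
  if (!is.null(man$constraints)) {
    cf <- tempfile(fileext = ".json")
    writeLines(as.character(jsonlite::toJSON(man$constraints, auto_unbox = TRUE,
                                             digits = NA)), cf)
  }
  run_pipeline(nf, cf, out_dir, n_samples = man$n_samples, seed = man$seed,
               label_tries = man$label_tries, input_value = man$input_value)
}

write_flux_csv <- function(ens, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# network: %s", ens$network), con)
  writeLines(sprintf("# seed: %d", ens$seed), con)
  writeLines(sprintf("# samples: %d accepted: %d", ens$n_samples, ens$accepted), con)
  writeLines(paste(colnames(ens$flux), collapse = ","), con)
  if (nrow(ens$flux))
    writeLines(apply(ens$flux, 1L, function(r)
      paste(sprintf("%.15g", r), collapse = ",")), con)
  invisible(path)
}

write_labeled_csv <- function(ens, net, tag, path) {
  ex <- ens$experiments[[tag]]
  fl <- net$fluxes
  lab <- matrix(NA_real_, nrow(ens$flux), nrow(fl), dimnames = list(NULL, fl$id))
  for (j in seq_len(nrow(fl))) {
    id <- fl$id[j]
    lab[, id] <- if (fl$kind[j] == "diffusion_net") {
      ex$labels[, fl$from[j]] * ex$D_f[, id] - ex$labels[, fl$to[j]] * ex$D_r[, id]
    } else if (fl$kind[j] == "input") {
      NA_real_  # input edges carry the feeding label; totals suffice
    } else ex$labels[, fl$from[j]] * ens$flux[, id]
  }
  cols <- cbind(ens$flux,
                `colnames<-`(lab, paste0(fl$id, ",L")),
                `colnames<-`(ex$D_f, paste0(colnames(ex$D_f), ".f")),
                `colnames<-`(ex$D_r, paste0(colnames(ex$D_r), ".r")),
                `colnames<-`(ex$labels, paste0("L_", colnames(ex$labels))))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# network: %s experiment: %s", ens$network, tag), con)
  writeLines(sprintf("# seed: %d", ens$seed), con)
  writeLines(paste(colnames(cols), collapse = ";"), con)
  if (nrow(cols))
    writeLines(apply(cols, 1L, function(r)
      paste(sprintf("%.15g", r), collapse = ";")), con)
  invisible(path)
}

write_residuals <- function(ens, net, constraints, path) {
  rows <- lapply(seq_len(ens$accepted), function(i) {
    V <- setNames(ens$flux[i, ], colnames(ens$flux))
    labs <- lapply(ens$experiments, function(ex) {
      setNames(ex$labels[i, ], colnames(ex$labels))
    })
    obs <- compute_observables(net, V,
                               if (length(labs)) labs else NULL)
    r <- check_constraints(obs, constraints, flux = V)$residuals
    r$member <- i
    r
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
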