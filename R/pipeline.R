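# Config-driven orchestration. A run config is a plain YAML file (or the
# equivalent nested list); every stage writes deterministic TSV/JSON plus a
# manifest of output hashes, and logs progress to stderr.

#' Default run configuration
#'
#' All defaults mirror the analysis constants: the five monitored
#' phosphopeptide/arrestin contacts (pS350-R77, pS350-R148, pS350-R166,
#' pT352-R166, E358-R394), a 4.0 Angstrom salt-bridge cutoff, RMSD cluster
#' cutoffs of 3.7 (rebinding) / 1.0 (relaxation) Angstrom, a 6.0 Angstrom
#' engaged/disengaged threshold, and an `"all"` analysis window.
#'
#' @param out_dir output directory
#' @param seed integer seed recorded in reports
#' @return nested list of class `run_config`
#' @export
default_run_config <- function(out_dir = "results", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    window = "all",
    contact_cutoff = 4.0,
    cluster_cutoff = 3.7,
    state_threshold = 6.0,
    polar_core = list(switch_residue = 394L, switch_atom = "CZ",
                      gate_residue = 299L, gate_atom = "CG"),
    contacts = list(
      list(name = "pS350-R77",
           sel_a = "resid 350 and name O1P O2P O3P",
           sel_b = "resid 77 and name NH1 NH2", mode = "min-group"),
      list(name = "pS350-R148",
           sel_a = "resid 350 and name O1P O2P O3P",
           sel_b = "resid 148 and name NH1 NH2", mode = "min-group"),
      list(name = "pS350-R166",
           sel_a = "resid 350 and name O1P O2P O3P",
           sel_b = "resid 166 and name NH1 NH2", mode = "min-group"),
      list(name = "pT352-R166",
           sel_a = "resid 352 and name O1P O2P O3P",
           sel_b = "resid 166 and name NH1 NH2", mode = "min-group"),
      list(name = "E358-R394",
           sel_a = "resid 358 and name OE1 OE2",
           sel_b = "resid 394 and name NH1 NH2", mode = "min-group")),
    cluster_selection = "resid 394",
    cluster_max_frames = 2000L,
    conditions = list(),
    itc = list(isotherm_csv = NULL, cell_volume_uL = 200,
               macromolecule_uM = 200, syringe_uM = 1000,
               temperature_K = 298),
    hdx = list(uptake_csv = NULL, state_a = "apo", state_b = "bound",
               delta_floor = 0.2, alpha = 0.05)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the [default_run_config()] values;
#' the config round-trips through [yaml::as.yaml()] unchanged.
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg[names(user)] <- user
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration as YAML
#' @param config a `run_config`
#' @param path output path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_info <- function(fmt, ...) message(sprintf(paste0("[arrswitch] ", fmt), ...))

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, files) {
  files <- files[file.exists(files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
}

resolve_contacts <- function(top, config) {
  out <- list()
  for (cd in config$contacts) {
    sel_a <- suppressWarnings(select_atoms(top, cd$sel_a))
    sel_b <- suppressWarnings(select_atoms(top, cd$sel_b))
    if (length(sel_a$indices) == 0L || length(sel_b$indices) == 0L) {
      log_info("contact %s: selection unresolved in topology, skipped", cd$name)
      next
    }
    out[[length(out) + 1L]] <- contact_definition(
      cd$name, sel_a, sel_b, mode = cd$mode, cutoff = config$contact_cutoff)
  }
  out
}

load_condition <- function(cond_name, cond, config) {
  paths <- cond$trajectories
  if (length(paths) == 0L)
    stop(sprintf("condition '%s': no trajectory files configured", cond_name))
  trajs <- lapply(seq_along(paths), function(i) {
    tr <- read_trajectory(paths[[i]], replicate_id = sprintf("rep%d", i),
                          condition = cond_name)
    if (!is.null(cond$dt_ns))
      tr$frame_times <- seq_len(n_frames(tr)) * cond$dt_ns
    apply_window(tr, config$window)
  })
  trajs
}

#' Run the full switch-dynamics analysis chain
#'
#' For every configured condition: load the replicate trajectories, apply
#' the analysis window, compute the polar-core distance series and the
#' configured contact series, contact-stability fractions, engaged /
#' disengaged state summaries, and quality-threshold clustering of the
#' switch-residue conformers on pooled frames; then compare the polar-core
#' distance distributions between all condition pairs with the two-sided
#' Mann-Whitney U test. Writes tidy TSV tables, a JSON report, a
#' human-readable summary and a hash manifest into `config$out_dir`.
#'
#' @param config a `run_config` with a non-empty `conditions` list; each
#'   condition is `list(trajectories = <paths>, dt_ns = <optional>)`
#' @return the report list, invisibly
#' @export
run_switch_analysis <- function(config) {
  if (length(config$conditions) == 0L)
    stop("switch analysis aborted at stage 'load': no conditions configured")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc_spec <- polar_core_spec(
    switch_residue = config$polar_core$switch_residue,
    switch_atom = config$polar_core$switch_atom,
    gate_residue = config$polar_core$gate_residue,
    gate_atom = config$polar_core$gate_atom)

  per_cond <- list()
  for (cn in names(config$conditions)) {
    log_info("condition %s: loading trajectories", cn)
    trajs <- tryCatch(load_condition(cn, config$conditions[[cn]], config),
                      error = function(e) stop(sprintf(
                        "switch analysis aborted at stage 'load' (%s): %s",
                        cn, conditionMessage(e))))
    top <- trajs[[1]]$topology
    contacts <- resolve_contacts(top, config)
    pc_series <- lapply(trajs, polar_core_series, spec = pc_spec)
    fractions <- lapply(contacts, function(cd) {
      contact_fraction(lapply(trajs, distance_series, contact = cd),
                       cutoff = config$contact_cutoff)
    })
    states <- switch_state_summary(pc_series, config$state_threshold)
    pooled <- pool_frames(trajs)
    # cap the pairwise-RMSD problem by even-stride subsampling
    if (n_frames(pooled) > config$cluster_max_frames) {
      keep <- unique(round(seq(1, n_frames(pooled),
                               length.out = config$cluster_max_frames)))
      pooled$coords <- pooled$coords[keep, , , drop = FALSE]
      if (!is.null(pooled$frame_times))
        pooled$frame_times <- pooled$frame_times[keep]
    }
    clus <- cluster_conformers(
      pooled, select_atoms(top, config$cluster_selection),
      cutoff = config$cluster_cutoff)
    per_cond[[cn]] <- list(trajs = trajs, contacts = contacts,
                           pc_series = pc_series, fractions = fractions,
                           states = states, clusters = clus)
    log_info("condition %s: %d replicates, %d frames pooled, %d clusters",
             cn, length(trajs), n_frames(pooled), length(clus$sizes))
  }

  # condition comparisons on pooled polar-core distances
  comparisons <- list()
  cns <- names(per_cond)
  if (length(cns) >= 2L) {
    for (i in seq_len(length(cns) - 1L)) for (j in (i + 1L):length(cns)) {
      xi <- unlist(lapply(per_cond[[cns[i]]]$pc_series, `[[`, "values"))
      xj <- unlist(lapply(per_cond[[cns[j]]]$pc_series, `[[`, "values"))
      mw <- mann_whitney_u(xi, xj)
      comparisons[[paste(cns[i], "vs", cns[j])]] <- list(
        condition_a = cns[i], condition_b = cns[j],
        mean_a = mean(xi), mean_b = mean(xj),
        U = mw$statistic, p_value = mw$p_value, method = mw$method)
    }
  }

  # tidy outputs
  dist_rows <- do.call(rbind, lapply(cns, function(cn) {
    do.call(rbind, lapply(per_cond[[cn]]$pc_series, function(s)
      data.frame(condition = s$condition, replicate = s$replicate_id,
                 frame = seq_along(s$values), contact_name = s$name,
                 distance_A = s$values)))
  }))
  utils::write.table(dist_rows, file.path(out_dir, "polar_core_distances.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  frac_rows <- do.call(rbind, lapply(cns, function(cn) {
    do.call(rbind, lapply(per_cond[[cn]]$fractions, function(fr)
      data.frame(condition = cn, contact_name = fr$contact,
                 cutoff_A = fr$cutoff, fraction = fr$fraction,
                 n_frames = fr$n_frames)))
  }))
  utils::write.table(frac_rows, file.path(out_dir, "contact_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state_rows <- do.call(rbind, lapply(cns, function(cn) per_cond[[cn]]$states))
  utils::write.table(state_rows, file.path(out_dir, "switch_states.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  report <- list(
    seed = config$seed,
    window = config$window,
    state_threshold_A = config$state_threshold,
    contact_cutoff_A = config$contact_cutoff,
    cluster_cutoff_A = config$cluster_cutoff,
    config_hash = unname(config_hash(config)),
    conditions = lapply(per_cond, function(pc) list(
      n_replicates = length(pc$trajs),
      mean_polar_core_A = mean(unlist(lapply(pc$pc_series, `[[`, "values"))),
      engaged_fraction =
        pc$states$engaged_fraction[pc$states$replicate == "pooled"],
      contact_fractions = stats::setNames(
        lapply(pc$fractions, `[[`, "fraction"),
        vapply(pc$fractions, `[[`, character(1), "contact")),
      clusters = list(
        populations_pct = pc$clusters$populations,
        center_frames = pc$clusters$centers))),
    comparisons = comparisons)
  write_json_report(report, file.path(out_dir, "switch_report.json"))

  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c("Switch-dynamics analysis summary", "")
  for (cn in cns) {
    pc <- per_cond[[cn]]
    lines <- c(lines, sprintf(
      "%s: mean polar-core distance %.2f A, engaged fraction %.3f, largest cluster %.1f%%",
      cn, report$conditions[[cn]]$mean_polar_core_A,
      report$conditions[[cn]]$engaged_fraction,
      if (length(pc$clusters$populations)) pc$clusters$populations[1] else NA))
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    lines <- c(lines, sprintf("%s: U = %g, p = %.3g (%s)",
                              nm, cmp$U, cmp$p_value, cmp$method))
  }
  writeLines(lines, summary_path)
  write_manifest(out_dir, file.path(out_dir, c(
    "polar_core_distances.tsv", "contact_summary.tsv", "switch_states.tsv",
    "switch_report.json", "summary.txt")))
  log_info("switch analysis written to %s", out_dir)
  invisible(report)
}

# hash of the analysis-relevant config (output location excluded, so the
# same analysis written elsewhere hashes identically)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  tools::md5sum(tmp)
}

#' Run the ITC fitting stage
#'
#' Reads the configured isotherm CSV, fits one- and two-site models,
#' selects between them by the extra-sum-of-squares F test, and writes a
#' JSON fit report.
#'
#' @param config a `run_config` with `itc$isotherm_csv` set
#' @return the report list, invisibly
#' @export
run_itc <- function(config) {
  ic <- config$itc
  if (is.null(ic$isotherm_csv))
    stop("ITC stage aborted: no isotherm_csv configured")
  iso <- read_isotherm_csv(ic$isotherm_csv)
  exp <- itc_experiment(cell_volume_uL = ic$cell_volume_uL,
                        macromolecule_uM = ic$macromolecule_uM,
                        syringe_uM = ic$syringe_uM,
                        injection_volumes_uL = iso$volume_uL,
                        temperature_K = ic$temperature_K)
  cmp <- compare_models(iso, exp)
  fit <- if (cmp$preferred == "two_site") cmp$fit_two else cmp$fit_one
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    model = cmp$preferred,
    kd1_uM = fit$params$kd1, kd2_uM = fit$params$kd2,
    dh1_kcal_mol = fit$params$dh1, dh2_kcal_mol = fit$params$dh2,
    n1 = fit$params$n1, n2 = fit$params$n2,
    ssr = fit$ssr, converged = fit$converged,
    f_stat = cmp$f_stat, f_p_value = cmp$p_value,
    no_binding = cmp$no_binding, seed = config$seed)
  path <- file.path(config$out_dir, "itc_report.json")
  write_json_report(report, path)
  write_manifest(config$out_dir, path)
  log_info("ITC: preferred %s (kd1 = %.3g uM), report at %s",
           cmp$preferred, fit$params$kd1, path)
  invisible(report)
}

#' Run the differential HDX stage
#'
#' Reads the configured uptake CSV, applies the significance rule
#' (p < alpha AND |delta| >= 0.2 Da), classifies peptides by direction of
#' change, and writes the comparison CSV plus a JSON report.
#'
#' @param config a `run_config` with `hdx$uptake_csv` set
#' @return the report list, invisibly
#' @export
run_hdx <- function(config) {
  hc <- config$hdx
  if (is.null(hc$uptake_csv))
    stop("HDX stage aborted: no uptake_csv configured")
  data <- read_hdx_csv(hc$uptake_csv)
  cmp <- hdx_compare(data, hc$state_a, hc$state_b,
                     delta_floor = hc$delta_floor, alpha = hc$alpha)
  cls <- hdx_classify_regions(cmp)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- file.path(config$out_dir, "hdx_comparison.csv")
  merged <- merge(cmp, cls, by = c("peptide_start", "peptide_end"))
  merged <- merged[order(merged$peptide_start, merged$timepoint_s), ]
  utils::write.csv(merged, out_csv, row.names = FALSE)
  report <- list(
    states = c(hc$state_a, hc$state_b),
    delta_floor_Da = hc$delta_floor, alpha = hc$alpha,
    n_peptides = nrow(cls),
    classes = as.list(table(cls$peptide_class)),
    peptides = lapply(seq_len(nrow(cls)), function(i) list(
      start = cls$peptide_start[i], end = cls$peptide_end[i],
      class = cls$peptide_class[i])),
    seed = config$seed)
  path <- file.path(config$out_dir, "hdx_report.json")
  write_json_report(report, path)
  write_manifest(config$out_dir, c(out_csv, path))
  log_info("HDX: %d peptides (%s), report at %s", nrow(cls),
           paste(sprintf("%s=%d", names(table(cls$peptide_class)),
                         as.integer(table(cls$peptide_class))),
                 collapse = ", "), path)
  invisible(report)
}
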