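# Study orchestration: run every analysis stage over every system from a
# single declarative config, writing flat CSV/JSON outputs plus a run
# manifest. Stage outputs are plain text by design: inspectability over
# speed at this scale.

#' Assemble a study configuration
#'
#' @param systems list of system entries; each a list with \code{name},
#'   \code{topology} (a \code{topology} or a structure file path),
#'   \code{trajectory} (an \code{ensemble} or a trajectory file path),
#'   optional \code{region_config} (YAML path) and \code{dt} (ns).
#' @param outdir output directory.
#' @param trim_ns equilibration discard (ns, default 50 — the usual
#'   relaxation allowance for large complexes).
#' @param stages character vector of stages to run; any of
#'   \code{"rmsd"}, \code{"rmsf"}, \code{"ed"}, \code{"ccmap"},
#'   \code{"network"}, \code{"hbonds"}, \code{"zernike"},
#'   \code{"energies"}, \code{"membrane"}.
#' @param combined_groups list of character vectors of system names to
#'   combine into common essential subspaces.
#' @param params named list of per-stage parameter blocks.
#' @param seed global seed.
#' @return object of class \code{"study_config"}.
#' @export
study_config <- function(systems, outdir, trim_ns = 50,
                         stages = c("rmsd", "rmsf", "ed", "ccmap",
                                    "network"),
                         combined_groups = list(), params = list(),
                         seed = 1L) {
  structure(list(systems = systems, outdir = outdir, trim_ns = trim_ns,
                 stages = stages, combined_groups = combined_groups,
                 params = params, seed = seed),
            class = "study_config")
}

#' Validate a study configuration
#'
#' @param cfg a \code{study_config}.
#' @return character vector of diagnostics; empty when the config is
#'   runnable.
#' @export
validate_config <- function(cfg) {
  diag <- character(0)
  if (!length(cfg$systems)) diag <- c(diag, "systems: none declared")
  nm <- vapply(cfg$systems, function(s) s$name %||% "", "")
  if (any(nm == "")) diag <- c(diag, "systems: every system needs a name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    diag <- c(diag, paste0("systems: duplicate name(s): ",
                           paste(dup, collapse = ", ")))
  for (s in cfg$systems) {
    for (fld in c("topology", "trajectory", "region_config")) {
      v <- s[[fld]]
      if (is.character(v) && !file.exists(v))
        diag <- c(diag, paste0(s$name, ": ", fld, " file not found: ", v))
    }
  }
  bad_stage <- setdiff(cfg$stages,
                       c("rmsd", "rmsf", "ed", "ccmap", "network", "hbonds",
                         "zernike", "energies", "membrane"))
  if (length(bad_stage))
    diag <- c(diag, paste0("stages: unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  for (g in cfg$combined_groups) {
    missing <- setdiff(g, nm)
    if (length(missing)) {
      diag <- c(diag, paste0("combined group: unknown system(s): ",
                             paste(missing, collapse = ", ")))
      next
    }
    counts <- vapply(g, function(n) {
      s <- cfg$systems[[match(n, nm)]]
      if (inherits(s$topology, "topology")) nrow(s$topology$atoms) else NA_integer_
    }, 1L)
    if (!anyNA(counts) && length(unique(counts)) > 1L)
      diag <- c(diag, paste0(
        "combined group (", paste(g, collapse = ","),
        "): common subspaces require equal alpha-carbon counts; got ",
        paste(counts, collapse = "/")))
  }
  diag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_system <- function(s) {
  top <- s$topology
  if (is.character(top)) top <- read_structure(top)$topology
  if (!is.null(s$region_config))
    top <- read_region_config(top, s$region_config)
  traj <- s$trajectory
  if (is.character(traj))
    traj <- read_trajectory(top, traj, dt = s$dt %||% 1)
  else
    traj <- ensemble(top, traj$coords, times = traj$times, box = traj$box)
  list(name = s$name, topology = top, ensemble = traj)
}

.fingerprint <- function(ens)
  sprintf("n_atoms=%d;n_frames=%d;coordsum=%.10g",
          n_atoms(ens), n_frames(ens), sum(ens$coords))

#' Run the full study workflow
#'
#' Loads (or accepts in-memory) systems, discards the equilibration
#' segment, and executes every enabled stage on every system plus the
#' combined essential-dynamics stage on declared groups. A failed stage is
#' recorded in the manifest; independent stages still run.
#'
#' @param cfg a \code{study_config}; must validate.
#' @return the run manifest (list), also written to
#'   \code{outdir/manifest.json}. All stage outputs are CSV/JSON under
#'   \code{outdir/<system>/}.
#' @export
run_study <- function(cfg) {
  t_start <- Sys.time()
  diag <- validate_config(cfg)
  if (length(diag))
    stop("config invalid:\n  ", paste(diag, collapse = "\n  "))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  p <- cfg$params
  manifest <- list(stages = list(), parameters = cfg$params,
                   trim_ns = cfg$trim_ns, seed = cfg$seed)
  loaded <- list()
  record <- function(system, stage, status, outputs = character(0),
                     message = NULL) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      system = system, stage = stage, status = status,
      outputs = as.list(outputs), message = message)
  }
  run_stage <- function(system, stage, fun) {
    res <- tryCatch(list(ok = TRUE, out = fun()),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) record(system, stage, "ok", res$out)
    else record(system, stage, "failed", message = res$msg)
  }
  for (s in cfg$systems) {
    sys <- .load_system(s)
    ens <- trim_equilibration(sys$ensemble, cfg$trim_ns)
    loaded[[sys$name]] <- list(topology = sys$topology, ensemble = ens)
    manifest$inputs[[sys$name]] <- .fingerprint(sys$ensemble)
    sdir <- file.path(cfg$outdir, sys$name)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    top <- sys$topology
    out <- function(f) file.path(sdir, f)

    if ("rmsd" %in% cfg$stages) run_stage(sys$name, "rmsd", function() {
      r <- rmsd_series(ens, sel = NULL, fit = p$rmsd$fit %||% TRUE)
      utils::write.csv(as.data.frame(r), out("rmsd.csv"), row.names = FALSE)
      out("rmsd.csv")
    })
    if ("rmsf" %in% cfg$stages) run_stage(sys$name, "rmsf", function() {
      r <- rmsf_profile(ens, fit = p$rmsf$fit %||% TRUE,
                        reference_mode = p$rmsf$reference_mode %||% "initial")
      utils::write.csv(as.data.frame(r), out("rmsf_atom.csv"),
                       row.names = FALSE)
      utils::write.csv(rmsf_by_residue(r), out("rmsf_residue.csv"),
                       row.names = FALSE)
      c(out("rmsf_atom.csv"), out("rmsf_residue.csv"))
    })
    if ("ed" %in% cfg$stages) run_stage(sys$name, "ed", function() {
      ss <- essential_dynamics(ens, fit = p$ed$fit %||% TRUE,
                               system = sys$name)
      proj <- project_ensemble(ens, ss, k = p$ed$k %||% 2,
                               system = sys$name)
      utils::write.csv(data.frame(mode = seq_along(ss$values),
                                  eigenvalue = ss$values),
                       out("ed_eigenvalues.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(proj), out("ed_projection.csv"),
                       row.names = FALSE)
      c(out("ed_eigenvalues.csv"), out("ed_projection.csv"))
    })
    if ("ccmap" %in% cfg$stages) run_stage(sys$name, "ccmap", function() {
      C <- cross_correlation_matrix(ens, fit = p$ccmap$fit %||% TRUE)
      utils::write.csv(unclass(C), out("ccmap.csv"), row.names = FALSE)
      utils::write.csv(classify_correlations(C), out("ccmap_class.csv"),
                       row.names = FALSE)
      outs <- c(out("ccmap.csv"), out("ccmap_class.csv"))
      if (length(top$region_map) >= 2) {
        bs <- region_block_summary(C, top)
        jsonlite::write_json(bs, out("ccmap_blocks.json"), dataframe = "rows",
                             auto_unbox = TRUE, digits = NA)
        outs <- c(outs, out("ccmap_blocks.json"))
      }
      outs
    })
    if ("network" %in% cfg$stages) run_stage(sys$name, "network", function() {
      d <- metric_distributions(ens, sample_n = p$network$sample_n %||% 100L,
                                cutoff = p$network$cutoff %||% 0.6)
      utils::write.csv(d, out("network_distributions.csv"),
                       row.names = FALSE)
      utils::write.csv(metric_summary(d), out("network_summary.csv"),
                       row.names = FALSE)
      c(out("network_distributions.csv"), out("network_summary.csv"))
    })
    if ("hbonds" %in% cfg$stages) run_stage(sys$name, "hbonds", function() {
      groups <- p$hbonds$partners %||%
        intersect(c("groove", "TCRa", "TCRb"), names(top$region_map))
      if (is.null(top$region_map[["peptide"]]) || !length(groups))
        stop("hbonds stage needs a peptide region and partner regions")
      psel <- lapply(groups, function(g) select_atoms(top, region = g))
      names(psel) <- groups
      occ <- occupancy_table(ens, psel,
                             d_cut = p$hbonds$d_cut %||% 0.35,
                             angle_cut = p$hbonds$angle_cut %||% 30)
      utils::write.csv(as.data.frame(occ), out("hbond_occupancy.csv"),
                       row.names = FALSE)
      pm <- presence_matrix(occ, p$hbonds$min_occupancy %||% 0.1)
      utils::write.csv(pm, out("hbond_presence.csv"))
      c(out("hbond_occupancy.csv"), out("hbond_presence.csv"))
    })
    if ("zernike" %in% cfg$stages) run_stage(sys$name, "zernike", function() {
      reg <- p$zernike$region %||% "groove"
      if (is.null(top$region_map[[reg]]))
        stop("zernike stage: region '", reg, "' not defined")
      sel <- select_atoms(top, region = reg)
      desc <- shape_descriptor(get_frame(ens, 1L), top, sel,
                               M = p$zernike$M %||% 64L,
                               N = p$zernike$N %||% 20L)
      utils::write.csv(data.frame(invariant = names(unclass(desc)),
                                  value = as.numeric(desc)),
                       out("zernike_shape.csv"), row.names = FALSE)
      out("zernike_shape.csv")
    })
    if ("energies" %in% cfg$stages) run_stage(sys$name, "energies", function() {
      pairs <- p$energies$pairs %||% list(c("peptide", "groove"))
      ed <- energy_distribution(ens, pairs,
                                cutoff = p$energies$cutoff %||% 1.2,
                                dielectric = p$energies$dielectric %||% 1)
      utils::write.csv(ed$series, out("energy_series.csv"),
                       row.names = FALSE)
      utils::write.csv(ed$summary, out("energy_summary.csv"),
                       row.names = FALSE)
      c(out("energy_series.csv"), out("energy_summary.csv"))
    })
    if ("membrane" %in% cfg$stages) run_stage(sys$name, "membrane", function() {
      cmp <- thickness_comparison(ens,
                                  n_x = p$membrane$n_x %||% 100L,
                                  n_y = p$membrane$n_y %||% 100L)
      utils::write.csv(cmp, out("membrane_thickness_halves.csv"),
                       row.names = FALSE)
      out("membrane_thickness_halves.csv")
    })
  }
  # combined essential dynamics across declared groups
  for (g in cfg$combined_groups) {
    label <- paste(g, collapse = "+")
    run_stage(label, "combined_ed", function() {
      ens_list <- lapply(loaded[g], `[[`, "ensemble")
      cs <- combined_subspace(ens_list, fit = p$ed$fit %||% TRUE,
                              k = p$ed$k %||% 2)
      gdir <- file.path(cfg$outdir, paste0("combined_", gsub("\\+", "_", label)))
      dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data.frame(mode = seq_along(cs$subspace$values),
                                  eigenvalue = cs$subspace$values),
                       file.path(gdir, "eigenvalues.csv"), row.names = FALSE)
      proj <- do.call(rbind, lapply(cs$projections, as.data.frame))
      utils::write.csv(proj, file.path(gdir, "projections.csv"),
                       row.names = FALSE)
      ov <- outer(seq_along(g), seq_along(g), Vectorize(function(i, j)
        subspace_overlap(cs$projections[[i]], cs$projections[[j]])))
      dimnames(ov) <- list(g, g)
      utils::write.csv(ov, file.path(gdir, "overlap.csv"))
      file.path(gdir, c("eigenvalues.csv", "projections.csv", "overlap.csv"))
    })
  }
  manifest$wall_time_s <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  mpath <- file.path(cfg$outdir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, mpath)
  invisible(manifest)
}
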