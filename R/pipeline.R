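#' Configuration for a full comparative analysis run
#'
#' Either a list of replicate input files (`replicates`: each a list with
#' `structure`, optional `trajectory`, optional `dssp`) or a list of
#' generator configurations (`generators`: [generator_config()] objects) for
#' synthetic runs. Cutoffs default to the package-wide conventions: 0.6 nm
#' contacts, 0.3 nm clustering, 0.60 persistence.
#'
#' @param replicates List of per-replicate input paths, or NULL.
#' @param generators List of [generator_config()]s, or NULL.
#' @param contact_cutoff,cluster_cutoff Cutoffs in nm.
#' @param persistence_threshold Occupancy flagging threshold.
#' @param window_start_fraction Start of the shape/SASA analysis window as a
#'   fraction of frames (default 0.15, i.e. the final 85%).
#' @param landscape_bins Bins per landscape axis.
#' @param landscape_k K-means centroid count.
#' @param hamming_range Residue window for Hamming variability (default:
#'   residues 28 to chain length, the C-terminal window).
#' @param hydrophobic_set Residue names counted as hydrophobic.
#' @param max_cluster_frames Frames subsampled (evenly) for RMSD clustering.
#' @param seed Integer seed for every stochastic stage.
#' @param output_dir Where [run_full_analysis()] writes tables; NULL keeps
#'   results in memory only.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(replicates = NULL, generators = NULL,
                            contact_cutoff = 0.6, cluster_cutoff = 0.3,
                            persistence_threshold = 0.60,
                            window_start_fraction = 0.15,
                            landscape_bins = 50L, landscape_k = 2L,
                            hamming_range = NULL,
                            hydrophobic_set = hydrophobic_residues,
                            max_cluster_frames = 200L,
                            seed = 1L, output_dir = NULL) {
  if (is.null(replicates) && is.null(generators)) {
    abort("provide either `replicates` (files) or `generators` (synthetic)")
  }
  if (contact_cutoff <= 0 || cluster_cutoff <= 0) {
    abort("cutoffs must be > 0")
  }
  if (window_start_fraction < 0 || window_start_fraction >= 1) {
    abort("window_start_fraction must be in [0, 1)")
  }
  structure(
    list(replicates = replicates, generators = generators,
         contact_cutoff = contact_cutoff, cluster_cutoff = cluster_cutoff,
         persistence_threshold = persistence_threshold,
         window_start_fraction = window_start_fraction,
         landscape_bins = as.integer(landscape_bins),
         landscape_k = as.integer(landscape_k),
         hamming_range = hamming_range,
         hydrophobic_set = hydrophobic_set,
         max_cluster_frames = as.integer(max_cluster_frames),
         seed = as.integer(seed), output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()]; `generators` entries are expanded through
#'   [generator_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$generators)) {
    raw$generators <- lapply(raw$generators, function(g) {
      do.call(generator_config, g)
    })
  }
  known <- names(formals(analysis_config))
  do.call(analysis_config, raw[intersect(names(raw), known)])
}

# load or generate the replicate trajectories (+ optional SS series / truth)
.load_replicates <- function(config) {
  if (!is.null(config$generators)) {
    reps <- lapply(config$generators, function(g) {
      out <- generate_hexamer_trajectory(g)
      ss <- generate_ss_series(g$n_frames, g$n_chains, g$n_residues,
                               g$ss_transition,
                               seed = (g$seed * 31L + 7L) %% 2147483647L)
      list(trajectory = out$trajectory, ss = ss, truth = out$truth)
    })
  } else {
    reps <- lapply(config$replicates, function(r) {
      traj <- load_trajectory(r$structure, r$trajectory)
      ss <- if (!is.null(r$dssp)) {
        load_dssp_table(r$dssp, n_chains(traj), n_residues(traj))
      } else {
        assign_ss_dihedral(traj)
      }
      list(trajectory = traj, ss = ss, truth = NULL)
    })
  }
  reps
}

# concatenate ss_series along frames
.bind_ss <- function(ss_list) {
  d <- dim(ss_list[[1]])
  total <- sum(vapply(ss_list, function(s) dim(s)[1], 1L))
  arr <- array("C", c(total, d[2], d[3]))
  at <- 0L
  for (s in ss_list) {
    arr[at + seq_len(dim(s)[1]), , ] <- unclass(s)
    at <- at + dim(s)[1]
  }
  ss_series(arr, source = attr(ss_list[[1]], "source"))
}

#' Run the full comparative-analysis pipeline
#'
#' Executes every stage — secondary structure, contacts, shape and SASA,
#' clustering, conformational landscape — over the configured replicates,
#' pooling frames across replicates for the stages that are computed as
#' composites (interaction maps, landscapes, Hamming variability) and also
#' emitting per-replicate tables. A failed stage is logged into the manifest
#' and its tables are marked absent; configuration errors abort before any
#' computation. Given the same config and seed the bundle (and any files
#' written) is byte-identical across runs.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_bundle`: named list of result tables plus `manifest`
#'   (parameters, seed, per-stage status and timings, collected warnings).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  manifest <- list(
    parameters = config[setdiff(names(unclass(config)),
                                c("replicates", "generators"))],
    n_replicates = length(config$generators %||% config$replicates),
    stages = list(), warnings = character()
  )
  bundle <- list()
  t0 <- proc.time()[["elapsed"]]

  run_stage <- function(name, expr) {
    tick <- proc.time()[["elapsed"]]
    res <- tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$stages[[name]] <<- list(
          status = "failed", error = conditionMessage(e),
          seconds = round(proc.time()[["elapsed"]] - tick, 3)
        )
        NULL
      }
    )
    if (!is.null(res)) {
      manifest$stages[[name]] <<- list(
        status = "ok", seconds = round(proc.time()[["elapsed"]] - tick, 3)
      )
    }
    res
  }

  reps <- .load_replicates(config)
  pooled_traj <- bind_frames(lapply(reps, `[[`, "trajectory"))
  pooled_ss <- .bind_ss(lapply(reps, `[[`, "ss"))
  nr <- n_residues(pooled_traj)
  hamming_range <- config$hamming_range %||% seq(min(28L, nr), nr)

  # --- secondary structure ---------------------------------------------
  bundle$ss_composition <- run_stage("ss_composition", {
    per_rep <- purrr::imap_dfr(reps, function(r, i) {
      dplyr::mutate(ss_composition(r$ss), replicate = i, .before = 1)
    })
    pooled <- dplyr::mutate(ss_composition(pooled_ss), replicate = "pooled",
                            .before = 1)
    # replicate-mean variant emitted alongside the pooled-frames default
    mean_row <- tibble(
      replicate = "replicate_mean",
      coil = mean(per_rep$coil), sheet = mean(per_rep$sheet),
      helix = mean(per_rep$helix), n_frames = sum(per_rep$n_frames)
    )
    dplyr::bind_rows(
      dplyr::mutate(per_rep, replicate = as.character(.data$replicate)),
      pooled, mean_row
    )
  })
  bundle$ss_propensity <- run_stage("ss_propensity", ss_propensity(pooled_ss))
  bundle$ss_pca <- run_stage("ss_pca", {
    p <- ss_pca(pooled_ss)
    dplyr::mutate(tidy(p),
                  var_pc1 = p$explained_variance[[1]],
                  var_pc2 = p$explained_variance[[2]])
  })
  bundle$hamming <- run_stage("hamming", {
    hv <- hamming_variability(pooled_ss, chain = NULL,
                              residue_range = hamming_range,
                              seed = config$seed)
    dplyr::mutate(hv, residue_start = min(hamming_range),
                  residue_end = max(hamming_range))
  })
  bundle$strand_pairs <- run_stage("strand_pairs", {
    sp <- intermolecular_strand_pairs(pooled_ss, pooled_traj,
                                      cutoff = config$contact_cutoff)
    sp$per_residue
  })

  # --- contacts ---------------------------------------------------------
  bundle$intra_heatmap <- run_stage("intra_heatmap", {
    tidy(interaction_heatmap(pooled_traj, "intramolecular",
                             config$contact_cutoff))
  })
  inter_map <- run_stage("inter_heatmap", {
    interaction_heatmap(pooled_traj, "intermolecular", config$contact_cutoff)
  })
  bundle$inter_heatmap <- if (!is.null(inter_map)) tidy(inter_map)
  bundle$occupancy <- run_stage("occupancy", {
    if (is.null(inter_map)) abort("intermolecular map unavailable")
    df <- tidy(inter_map)
    df <- df[df$res_i <= df$res_j, ]
    dplyr::mutate(df, persistent = .data$occupancy >=
                    config$persistence_threshold)
  })
  bundle$salt_bridges <- run_stage("salt_bridges", salt_bridges(pooled_traj))
  bundle$hydrogen_bonds <- run_stage("hydrogen_bonds",
                                     hydrogen_bonds(pooled_traj))
  bundle$pi_stacking <- run_stage("pi_stacking", pi_stacking(pooled_traj))

  # --- shape / SASA -----------------------------------------------------
  window <- analysis_window(pooled_traj, config$window_start_fraction)
  shape_tbl <- run_stage("shape_series", shape_series(pooled_traj))
  bundle$shape_series <- shape_tbl
  sasa_mat <- run_stage("sasa_per_atom", trajectory_sasa(pooled_traj, window))
  bundle$sasa_residue <- run_stage("sasa_residue", {
    residue_sasa_normalized(pooled_traj, window, per_atom_sasa = sasa_mat)
  })
  hs <- run_stage("hydrophobic_sasa", {
    hydrophobic_sasa(pooled_traj, window,
                     hydrophobic_set = config$hydrophobic_set,
                     per_atom_sasa = sasa_mat)
  })
  bundle$hydrophobic_sasa <- if (!is.null(hs)) hs$per_frame
  bundle$hydrophobic_sasa_summary <- if (!is.null(hs)) hs$summary

  # --- clustering / landscape ------------------------------------------
  bundle$clusters <- run_stage("clusters", {
    nf <- n_frames(pooled_traj)
    pick <- if (nf > config$max_cluster_frames) {
      unique(round(seq(1, nf, length.out = config$max_cluster_frames)))
    } else seq_len(nf)
    cl <- daura_cluster(pooled_traj[pick], cutoff = config$cluster_cutoff)
    dplyr::mutate(tidy(cl), frame = pick[.data$frame])
  })
  landscape_inputs <- if (!is.null(shape_tbl)) {
    list(x = shape_tbl$eccentricity, y = strand_fraction(pooled_ss))
  }
  bundle$landscape <- run_stage("landscape", {
    if (is.null(landscape_inputs)) abort("shape series unavailable")
    tidy(boltzmann_surface(landscape_inputs$x, landscape_inputs$y,
                           bins = config$landscape_bins))
  })
  bundle$centroids <- run_stage("centroids", {
    if (is.null(landscape_inputs)) abort("shape series unavailable")
    landscape_centroids(landscape_inputs$x, landscape_inputs$y,
                        k = config$landscape_k, seed = config$seed)
  })

  manifest$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  status <- vapply(manifest$stages, `[[`, "", "status")
  table_stages <- setdiff(names(manifest$stages), "sasa_per_atom")
  manifest$tables_present <- table_stages[status[table_stages] == "ok"]
  manifest$tables_absent <- table_stages[status[table_stages] != "ok"]
  bundle <- bundle[!vapply(bundle, is.null, TRUE)]
  bundle$manifest <- manifest

  if (!is.null(config$output_dir)) {
    .write_bundle(bundle, config$output_dir)
  }
  structure(bundle, class = "analysis_bundle")
}

.write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(bundle), "manifest")) {
    tbl <- bundle[[nm]]
    if (is.null(tbl) || !nrow(tbl)) next
    write_table(tbl, file.path(dir, paste0(nm, ".csv")), "csv")
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  present <- x$manifest$tables_present
  cat(sprintf("<analysis_bundle> %d table families (%d absent)\n",
              length(present), length(x$manifest$tables_absent)))
  cat(" ", paste(present, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two analysis bundles
#'
#' Side-by-side means and standard deviations for the scalar result families
#' of two runs, with a difference test per family: Welch's t-test when both
#' samples pass Shapiro-Wilk normality and an F-test of equal variances
#' (parametric route), otherwise a Wilcoxon rank-sum test. Differences are
#' flagged at p < 0.05.
#'
#' @param bundle_a,bundle_b `analysis_bundle`s with matching schemas.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble: `family`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `test`,
#'   `p_value`, `significant`.
#' @export
compare_systems <- function(bundle_a, bundle_b, alpha = 0.05) {
  fams <- list(
    hydrophobic_sasa = function(b) b$hydrophobic_sasa$hydrophobic_sasa,
    eccentricity = function(b) b$shape_series$eccentricity,
    rg_total = function(b) b$shape_series$rg_total,
    strand_percent = function(b) {
      b$ss_propensity$sheet * 100
    }
  )
  purrr::imap_dfr(fams, function(getter, fam) {
    a <- getter(bundle_a); b <- getter(bundle_b)
    if (is.null(a) || is.null(b)) {
      return(tibble(family = fam, mean_a = NA_real_, sd_a = NA_real_,
                    mean_b = NA_real_, sd_b = NA_real_, test = "absent",
                    p_value = NA_real_, significant = NA))
    }
    if (identical(a, b)) {
      # identical inputs: zero difference by construction
      return(tibble(family = fam, mean_a = mean(a), sd_a = sd(a),
                    mean_b = mean(b), sd_b = sd(b), test = "identical",
                    p_value = 1, significant = FALSE))
    }
    parametric <- .is_parametric(a, b)
    ht <- if (parametric) t.test(a, b) else wilcox.test(a, b, exact = FALSE)
    tibble(
      family = fam, mean_a = mean(a), sd_a = sd(a),
      mean_b = mean(b), sd_b = sd(b),
      test = if (parametric) "t.test" else "wilcox.test",
      p_value = ht$p.value,
      significant = ht$p.value < alpha
    )
  })
}

.is_parametric <- function(a, b) {
  sub <- function(v) if (length(v) > 4000) v[seq_len(4000)] else v
  ok <- tryCatch({
    pa <- shapiro.test(sub(a))$p.value
    pb <- shapiro.test(sub(b))$p.value
    pv <- var.test(a, b)$p.value
    pa > 0.05 && pb > 0.05 && pv > 0.05
  }, error = function(e) FALSE)
  isTRUE(ok)
}
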