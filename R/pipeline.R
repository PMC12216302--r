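# End-to-end orchestration of the two workflows: the connectivity-domain
# pipeline (tabulate -> aggregate -> detect -> reorder -> render) and the
# morphology pipeline (features + tropism -> typing -> group statistics).
# Every run emits a manifest (all parameters, seeds, package version, and
# an input digest) sufficient to reproduce it exactly.

.run_manifest <- function(stage, params, inputs) {
  list(stage = stage,
       package = "thalamap",
       version = as.character(utils::packageVersion("thalamap")),
       params = params,
       input_digest = .manifest_digest(inputs))
}

#' Run the connectivity-domain pipeline
#'
#' With `simulate = TRUE` (the default), planted-domain injection rows are
#' generated; otherwise `rows` (a list of [tabulate_grid()] rows) or a
#' `matrix_csv` path must be supplied. Stages: aggregate into the
#' injection x grid matrix, Louvain domain detection at `gamma`, community
#' reordering, and the per-grid domain map.
#'
#' @param simulate generate synthetic injection rows.
#' @param rows list of `injection_grid_row`s (when `simulate = FALSE`).
#' @param matrix_csv path to a matrix CSV (alternative input).
#' @param gamma Louvain resolution (default 0.75).
#' @param seed integer seed (drives both simulation and Louvain).
#' @param n_injections,planted_domains,grid_shape,noise_sd passed to
#'   [generate_grid_cases()] when simulating.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list with `matrix`, `partition`, `reordered`, `domain_map`,
#'   `manifest` (invisibly when writing to `out_dir`).
#' @export
run_domain_pipeline <- function(simulate = TRUE, rows = NULL, matrix_csv = NULL,
                                gamma = 0.75, seed = 1L,
                                n_injections = 19L, planted_domains = 4L,
                                grid_shape = c(4L, 8L), noise_sd = 0.05,
                                out_dir = NULL) {
  params <- list(simulate = simulate, gamma = gamma, seed = seed,
                 n_injections = n_injections, planted_domains = planted_domains,
                 grid_shape = grid_shape, noise_sd = noise_sd)
  if (simulate) {
    rows <- generate_grid_cases(n_injections, planted_domains, grid_shape,
                                noise_sd, seed)
    mat <- aggregate_matrix(rows)
  } else if (!is.null(rows)) {
    mat <- aggregate_matrix(rows)
  } else if (!is.null(matrix_csv)) {
    if (!file.exists(matrix_csv)) {
      .fail("domain pipeline: matrix_csv not found: ", matrix_csv)
    }
    mat <- read_grid_matrix_csv(matrix_csv, rescale = TRUE)
  } else {
    .fail("domain pipeline: supply rows, matrix_csv, or simulate = TRUE")
  }
  partition <- detect_domains(mat, gamma = gamma, seed = seed)
  reordered <- reorder_matrix(mat, partition)
  domain_map <- render_domain_map(partition, mat$grid)
  manifest <- .run_manifest("domains", params, mat$values)
  res <- list(matrix = mat, partition = partition, reordered = reordered,
              domain_map = domain_map, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_grid_matrix_csv(mat, file.path(out_dir, "matrix.csv"))
    write_grid_matrix_csv(reordered, file.path(out_dir, "matrix_reordered.csv"))
    write_partition_json(partition, file.path(out_dir, "partition.json"))
    utils::write.csv(domain_map, file.path(out_dir, "domain_map.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Run the morphology pipeline
#'
#' Computes per-neuron morphometric features, Sholl profiles, tropism
#' profiles, two-type K-means classification, the edge vs non-edge
#' pooled-t contrasts (on features, angular deviation, and
#' proportion-closer, FDR adjusted as one family), pairwise-nucleus
#' rank-sum contrasts on total length (FDR adjusted per feature family),
#' and the soma-distance vs deviation correlation.
#'
#' @param preset cohort preset for simulation (see [generate_cohort()]).
#' @param seed integer seed.
#' @param swc_dir optional directory of SWC files to analyze instead of
#'   simulating (requires `geometry_json`).
#' @param geometry_json path to a geometry JSON (with `swc_dir`).
#' @param shell_um Sholl shell spacing (default 50 um).
#' @param restarts K-means restarts.
#' @param out_dir optional output directory for CSV artifacts.
#' @return list with `features`, `sholl`, `tropism`, `typing`, `stats`
#'   (data.frame of contrasts), `correlation`, `manifest`.
#' @export
run_morphology_pipeline <- function(preset = "amd-edge-study", seed = 1L,
                                    swc_dir = NULL, geometry_json = NULL,
                                    shell_um = 50, restarts = 50L,
                                    out_dir = NULL) {
  params <- list(preset = preset, seed = seed, shell_um = shell_um,
                 restarts = restarts)
  if (!is.null(swc_dir)) {
    if (is.null(geometry_json)) {
      .fail("morphology pipeline: geometry_json required with swc_dir")
    }
    files <- list.files(swc_dir, pattern = "\\.swc$", full.names = TRUE)
    if (!length(files)) .fail("no SWC files in ", swc_dir)
    neurons <- lapply(files, read_swc)
    geometry <- read_geometry_json(geometry_json)
    metadata <- NULL
  } else {
    cohort <- generate_cohort(preset, seed = seed)
    neurons <- cohort$neurons
    geometry <- cohort$geometry
    metadata <- cohort$metadata
  }

  features <- do.call(rbind, lapply(neurons, morphometric_profile,
                                    shell_um = shell_um))
  sholl <- do.call(rbind, lapply(neurons, function(n) {
    pr <- sholl_profile(n, shell_um = shell_um)
    if (nrow(pr)) cbind(neuron_label = n$label, pr)
  }))
  tropism <- do.call(rbind, lapply(neurons, tropism_profile, geometry = geometry))

  typing <- if (nrow(features) >= 2L) {
    kmeans_two_types(features[, c("total_length", "branch_count")],
                     seed = seed, restarts = restarts)
  }

  ## edge vs non-edge contrasts (pooled t, one FDR family)
  stats_rows <- list()
  edge <- tropism$edge_class == "edge"
  if (sum(edge) >= 2L && sum(!edge) >= 2L) {
    contrasts <- list(
      total_length = features$total_length,
      branch_count = features$branch_count,
      angular_deviation = tropism$average_angular_deviation,
      proportion_closer = tropism$proportion_closer
    )
    res <- lapply(names(contrasts), function(nm) {
      v <- contrasts[[nm]]
      s <- pooled_t_test(v[edge], v[!edge])
      data.frame(comparison = paste0("edge-vs-nonedge:", nm),
                 n_a = sum(edge), n_b = sum(!edge),
                 statistic = s$statistic, df = s$df, p = s$p_value,
                 method = s$method, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, res)
    fam$p_adjusted <- bh_fdr(fam$p)
    stats_rows[["edge"]] <- fam
  }

  ## pairwise nucleus contrasts on total length (rank-sum, one FDR family)
  nuclei <- unique(features$nucleus[!is.na(features$nucleus)])
  if (length(nuclei) >= 2L) {
    pairs <- utils::combn(sort(nuclei), 2, simplify = FALSE)
    res <- lapply(pairs, function(pr) {
      va <- features$total_length[features$nucleus == pr[1]]
      vb <- features$total_length[features$nucleus == pr[2]]
      if (length(va) < 2 || length(vb) < 2) return(NULL)
      s <- rank_sum_test(va, vb)
      data.frame(comparison = paste0("length:", pr[1], "-vs-", pr[2]),
                 n_a = length(va), n_b = length(vb),
                 statistic = s$statistic, df = NA_real_, p = s$p_value,
                 method = s$method, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, res)
    if (!is.null(fam) && nrow(fam)) {
      fam$p_adjusted <- bh_fdr(fam$p)
      stats_rows[["nucleus"]] <- fam
    }
  }
  stats_df <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats_df)) rownames(stats_df) <- NULL

  correlation <- if (nrow(tropism) >= 3L) deviation_vs_distance(tropism)

  manifest <- .run_manifest("morphology", params,
                            list(labels = features$neuron_label))
  res <- list(features = features, sholl = sholl, tropism = tropism,
              typing = typing, stats = stats_df, correlation = correlation,
              metadata = metadata, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    if (!is.null(sholl)) {
      utils::write.csv(sholl, file.path(out_dir, "sholl.csv"), row.names = FALSE)
    }
    utils::write.csv(tropism, file.path(out_dir, "tropism.csv"), row.names = FALSE)
    if (!is.null(typing)) {
      utils::write.csv(
        data.frame(neuron_label = features$neuron_label, type = typing$type),
        file.path(out_dir, "types.csv"), row.names = FALSE)
    }
    if (!is.null(stats_df)) {
      utils::write.csv(stats_df, file.path(out_dir, "stats.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
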