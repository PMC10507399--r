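# Checkpointed, resumable pipeline driver. Stage numbering is fixed:
#   1 ingest + transform   2 embedding        3 resolution sweep
#   4 clustering           5 summaries        6 landmark assignment
#   7 evaluation           8 final export
# Each stage writes checkpoint<k>.rds under output_dir and may run only
# when its predecessor checkpoint exists. After stage 3 an interactive run
# pauses so the user can pick a grid from the cluster-vs-DBI plot; stage 4
# therefore requires an explicit grid (or the CLARA backend).

checkpoint_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf("checkpoint%d.rds", stage))
}

read_checkpoint <- function(out_dir, stage) {
  p <- checkpoint_path(out_dir, stage)
  if (!file.exists(p)) {
    stop(sprintf("required checkpoint%d.rds not found in %s; run stage %d first",
                 stage, out_dir, stage), call. = FALSE)
  }
  readRDS(p)
}

load_run_config <- function(config_path, overrides = list()) {
  cfg <- read_config(config_path)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  validate_config(cfg)
  if (is.null(cfg$output_dir)) stop("config: output_dir is required",
                                    call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg
}

update_manifest <- function(cfg, stage, extra = list()) {
  mpath <- file.path(cfg$output_dir, "manifest.json")
  manifest <- if (file.exists(mpath)) {
    jsonlite::read_json(mpath, simplifyVector = TRUE)
  } else {
    list(tool_version = as.character(utils::packageVersion("cytosweep")),
         stages_completed = integer(0), seeds = list(), files = list())
  }
  manifest$stages_completed <- sort(unique(c(manifest$stages_completed, stage)))
  manifest$seeds$umap <- cfg$umap$seed
  manifest$seeds$som <- cfg$som$seed
  manifest$seeds$clara <- cfg$clara$seed
  for (nm in names(extra)) manifest[[nm]] <- extra[[nm]]
  exports <- list.files(cfg$output_dir, pattern = "\\.(csv|png|json)$",
                        full.names = TRUE)
  exports <- setdiff(exports, mpath)
  manifest$files <- as.list(tools::md5sum(exports))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Executes stage `stage` (1..8) of the checkpointed pipeline against the
#' configuration in `config_path`, writing `checkpoint<stage>.rds` plus the
#' stage's exports under `output_dir` and updating `manifest.json`.
#'
#' Stage 1 ingests FCS files (or, when the config sets `matrix_path`, a
#' pre-computed matrix with optional `already_transformed` flag), attaches
#' barcodes, optionally removes controls and subsamples, and applies the
#' arcsinh transform. Stage 4 requires `xdim`/`ydim` (chosen from the
#' stage-3 sweep) unless the backend is CLARA.
#'
#' @param stage integer 1..8.
#' @param config_path path to `config.yml`.
#' @param xdim,ydim grid selection for stage 4 (SOM backend).
#' @param force rerun even if this stage's checkpoint already exists.
#' @param overrides named list merged into the configuration (e.g. seeds).
#' @return the stage's checkpoint payload, invisibly.
#' @export
run_stage <- function(stage, config_path, xdim = NULL, ydim = NULL,
                      force = FALSE, overrides = list()) {
  stopifnot(stage %in% 1:8)
  cfg <- load_run_config(config_path, overrides)
  out <- cfg$output_dir
  cp <- checkpoint_path(out, stage)
  if (file.exists(cp) && !force) {
    message(sprintf("stage %d already complete (use force = TRUE to rerun)",
                    stage))
    return(invisible(readRDS(cp)))
  }
  if (stage > 1) prev <- read_checkpoint(out, stage - 1)

  payload <- switch(as.character(stage),
    "1" = {
      files <- read_file_metadata(cfg$file_metadata_path)
      markers <- read_marker_metadata(cfg$marker_metadata_path)
      table <- if (!is.null(cfg$matrix_path)) {
        load_matrix(cfg$matrix_path, cfg$cell_meta_path %||% NULL, markers,
                    already_transformed = isTRUE(cfg$already_transformed))
      } else {
        load_fcs_directory(cfg$fcs_dir, files, markers)
      }
      if (isTRUE(cfg$remove_controls)) table <- remove_controls(table)
      if (!is.null(cfg$subsample_per_file)) {
        table <- subsample_per_file(table, cfg$subsample_per_file,
                                    seed = cfg$som$seed)
      }
      table <- transform_cells(table, cfg$arcsinh_cofactor)
      list(table = table, files = files, markers = markers)
    },
    "2" = {
      emb <- compute_embedding(prev$table, prev$markers, cfg$umap)
      prev$table <- add_embedding(prev$table, emb)
      prev$embedding <- emb
      prev
    },
    "3" = {
      grids <- default_grid_sizes(cfg$grid_sizes_path)
      sweep <- grid_sweep(prev$table, prev$markers, grids, cfg$som)
      write.csv(sweep, file.path(out, "grid_sweep.csv"), row.names = FALSE)
      ggplot2::ggsave(file.path(out, "cluster_vs_dbi.png"), plot_sweep(sweep),
                      width = 7, height = 5, dpi = 120)
      prev$sweep <- sweep
      message("sweep complete; inspect cluster_vs_dbi.png and rerun stage 4 ",
              "with the selected grid")
      prev
    },
    "4" = {
      X <- clustering_matrix(prev$table, prev$markers)
      if (cfg$backend == "clara") {
        asg <- clara_cluster(X, k = cfg$clara$k, metric = cfg$clara$metric,
                             samples = cfg$clara$samples,
                             seed = cfg$clara$seed)
        model <- NULL
      } else {
        if (is.null(xdim) || is.null(ydim)) {
          stop(paste0("stage 4 needs a grid: pass xdim/ydim chosen from the ",
                      "stage-3 sweep table (grid_sweep.csv)"), call. = FALSE)
        }
        model <- train_som(X, xdim, ydim, cfg$som)
        asg <- assign_bmu(model, X)
        if (isTRUE(cfg$som$meta_clustering)) {
          asg <- apply_metaclusters(asg, metacluster_codes(model, cfg$som$k))
        }
        write.csv(model$codebook, file.path(out, "som_codebook.csv"))
      }
      prev$table$cell_meta$cluster <- asg$labels
      prev$model <- model
      prev$assignment <- asg
      prev
    },
    "5" = {
      summary <- summarize_clusters(prev$table, prev$assignment, prev$markers)
      write_summary(summary, out)
      save_heatmap(summary$freq_norm,
                   file.path(out, "file_by_cluster_heatmap.png"),
                   "Normalized cluster frequency per file")
      me <- summary$median_expr
      save_heatmap(me, file.path(out, "median_expression_heatmap.png"),
                   "Median arcsinh expression per cluster (unscaled)")
      prev$summary <- summary
      prev
    },
    "6" = {
      if (is.null(cfg$landmark_dir)) {
        prev$landmark_assignment <- NULL
        prev
      } else {
        lmk <- load_landmarks(cfg$landmark_dir, prev$markers,
                              cfg$arcsinh_cofactor)
        la <- assign_landmarks(prev$summary, lmk, prev$markers)
        write.csv(la, file.path(out, "landmark_assignment.csv"),
                  row.names = FALSE)
        prev$landmark_assignment <- la
        prev
      }
    },
    "7" = {
      if (is.null(cfg$truth_labels_path)) {
        prev$concordance <- NULL
        prev
      } else {
        truth <- read.csv(cfg$truth_labels_path, stringsAsFactors = FALSE)
        pred <- cluster_label_table(prev$table, prev$landmark_assignment)
        rep <- concordance_report(truth, pred, seed = cfg$som$seed)
        out_df <- rbind(rep$per_repeat,
                        data.frame(repeat_id = NA, seed = NA,
                                   t(rep$means)))
        write.csv(out_df, file.path(out, "concordance_report.csv"),
                  row.names = FALSE)
        prev$concordance <- rep
        prev
      }
    },
    "8" = {
      write.csv(prev$table$cell_meta, file.path(out, "cell_metadata.csv"),
                row.names = FALSE)
      if (!is.null(prev$table$cell_meta$umap1)) {
        ggplot2::ggsave(file.path(out, "umap_by_cluster.png"),
                        plot_embedding(prev$table, prev$assignment),
                        width = 7, height = 6, dpi = 120)
        ggplot2::ggsave(file.path(out, "umap_by_batch.png"),
                        plot_embedding(prev$table, prev$assignment,
                                       split_by = "pool_id"),
                        width = 9, height = 5, dpi = 120)
      }
      prev
    })

  saveRDS(payload, cp)
  update_manifest(cfg, stage)
  invisible(payload)
}

# Per-cell predicted label table: landmark names when a landmark assignment
# exists, otherwise cluster ids as strings.
cluster_label_table <- function(table, landmark_assignment = NULL) {
  lab <- as.character(table$cell_meta$cluster)
  if (!is.null(landmark_assignment)) {
    map <- setNames(landmark_assignment$landmark,
                    as.character(landmark_assignment$cluster))
    hit <- lab %in% names(map)
    lab[hit] <- map[lab[hit]]
  }
  data.frame(cell_id = table$cell_meta$cell_id, label = lab,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline end to end
#'
#' Convenience driver running stages 1..8 in order, bypassing the
#' interactive pause by supplying the grid up front (or by using grid
#' selection mode `"global_min"` on the stage-3 sweep when `grid` is NULL
#' and the backend is SOM).
#'
#' @param config_path path to `config.yml`.
#' @param grid `c(xdim, ydim)` for stage 4, or NULL to auto-select the
#'   global DBI minimum from the sweep.
#' @param force rerun stages whose checkpoints already exist.
#' @param overrides named list merged into the configuration.
#' @return the final stage-8 payload, invisibly.
#' @export
run_pipeline <- function(config_path, grid = NULL, force = TRUE,
                         overrides = list()) {
  cfg <- load_run_config(config_path, overrides)
  for (stage in 1:3) run_stage(stage, config_path, force = force,
                               overrides = overrides)
  if (is.null(grid) && cfg$backend == "som") {
    ck3 <- read_checkpoint(cfg$output_dir, 3)
    grid <- select_grid(ck3$sweep, mode = "global_min")
  }
  run_stage(4, config_path, xdim = grid[1], ydim = grid[2], force = force,
            overrides = overrides)
  for (stage in 5:8) run_stage(stage, config_path, force = force,
                               overrides = overrides)
  invisible(read_checkpoint(cfg$output_dir, 8))
}
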