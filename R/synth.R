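# Seeded synthetic multi-sample cytometry data with known population
# structure: Gaussian-mixture populations on the arcsinh scale with
# on/off marker signature profiles, per-batch additive shifts, optional
# control files, and per-cell ground-truth labels. Signals are generated
# on the arcsinh scale and inverse-transformed to raw counts so that the
# pipeline's forward transform recovers Gaussian populations, which makes
# separability analytically controllable.

#' Default synthetic population panel
#'
#' Five immune-like populations over a 10-marker panel. Each population is
#' "high" (arcsinh mean `high`) on its signature markers and "low"
#' (mean `low`) elsewhere, with a common per-marker spread, so adjacent
#' populations are separated by `(high - low) / sd` standard deviations
#' (11.7 sd at the defaults).
#'
#' @param high,low arcsinh-scale means for positive/negative markers.
#' @param spread per-marker standard deviation on the arcsinh scale.
#' @return list with `markers` (marker metadata data.frame), `signatures`
#'   (population x marker means), `spreads` (same shape, sds),
#'   `proportions` (named numeric).
#' @export
default_populations <- function(high = 4, low = 0.5, spread = 0.3) {
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD19", "CD20", "CD14", "CD16",
               "CD56", "HLADR")
  pops <- list(
    T_CD4 = c("CD45", "CD3", "CD4"),
    T_CD8 = c("CD45", "CD3", "CD8"),
    B = c("CD45", "CD19", "CD20", "HLADR"),
    Monocyte = c("CD45", "CD14", "CD16", "HLADR"),
    NK = c("CD45", "CD16", "CD56")
  )
  sig <- matrix(low, length(pops), length(markers),
                dimnames = list(names(pops), markers))
  for (p in names(pops)) sig[p, pops[[p]]] <- high
  list(
    markers = data.frame(channel_name = markers, marker_name = markers,
                         used_for_UMAP = TRUE, used_for_clustering = TRUE,
                         used_for_scaffold = TRUE, stringsAsFactors = FALSE),
    signatures = sig,
    spreads = matrix(spread, length(pops), length(markers),
                     dimnames = dimnames(sig)),
    proportions = c(T_CD4 = 0.30, T_CD8 = 0.25, B = 0.20, Monocyte = 0.15,
                    NK = 0.10)
  )
}

#' Describe a synthetic multi-sample cytometry dataset
#'
#' Captures everything [generate_dataset()] needs: the population panel,
#' the file/batch layout, batch shifts and the arcsinh cofactor.
#'
#' @param populations a panel as returned by [default_populations()].
#' @param n_files number of FCS files (default 4).
#' @param events_per_file events per file (default 10000).
#' @param n_batches files are assigned to batches round-robin (default 2).
#' @param batch_shifts additive arcsinh-scale shift per batch (default 0
#'   for batch 1, +0.15 for each later batch).
#' @param control_files integer indices of control files (default none).
#' @param cofactor arcsinh cofactor used for the inverse transform
#'   (default 5).
#' @param seed integer RNG seed.
#' @return list of class `synth_design`.
#' @export
synth_design <- function(populations = default_populations(),
                         n_files = 4L, events_per_file = 10000L,
                         n_batches = 2L, batch_shifts = NULL,
                         control_files = integer(0), cofactor = 5,
                         seed = 42L) {
  stopifnot(n_files >= 1, events_per_file >= 1, n_batches >= 1)
  pr <- populations$proportions
  if (abs(sum(pr) - 1) > 1e-9) {
    stop("population proportions must sum to 1", call. = FALSE)
  }
  if (any(populations$spreads <= 0)) {
    stop("population spreads must be positive", call. = FALSE)
  }
  if (is.null(batch_shifts)) {
    batch_shifts <- 0.15 * (seq_len(n_batches) - 1)
  }
  structure(list(populations = populations, n_files = n_files,
                 events_per_file = events_per_file, n_batches = n_batches,
                 batch_shifts = batch_shifts,
                 control_files = as.integer(control_files),
                 cofactor = cofactor, seed = seed),
            class = "synth_design")
}

#' Generate a synthetic dataset
#'
#' For each event: a population is drawn from the design proportions, the
#' arcsinh-scale value is Normal(signature + batch shift, spread), and the
#' raw value is `cofactor * sinh(value)` truncated at 0 (counts are
#' non-negative). Ground-truth population labels are stored in the cell
#' metadata.
#'
#' @param design a `synth_design`.
#' @return list with `table` (a `cell_table` with `raw_expr` and a
#'   `truth_label` metadata column), `files` (file metadata data.frame) and
#'   `markers` (marker metadata data.frame).
#' @export
generate_dataset <- function(design) {
  pop <- design$populations
  pnames <- rownames(pop$signatures)
  nm <- ncol(pop$signatures)
  batches <- rep_len(seq_len(design$n_batches), design$n_files)

  files <- data.frame(
    file_name = sprintf("sample%02d.fcs", seq_len(design$n_files)),
    donor_id = sprintf("donor%02d", seq_len(design$n_files)),
    pool_id = sprintf("batch%d", batches),
    control_sample = seq_len(design$n_files) %in% design$control_files,
    stringsAsFactors = FALSE
  )

  chunks <- vector("list", design$n_files)
  metas <- vector("list", design$n_files)
  for (f in seq_len(design$n_files)) {
    nev <- design$events_per_file
    draw <- with_seed(design$seed + f, {
      lab <- sample(pnames, nev, replace = TRUE, prob = pop$proportions)
      eps <- matrix(rnorm(nev * nm), nev, nm)
      list(lab = lab, eps = eps)
    })
    mu <- pop$signatures[draw$lab, , drop = FALSE] +
      design$batch_shifts[batches[f]]
    sdv <- pop$spreads[draw$lab, , drop = FALSE]
    trans <- mu + draw$eps * sdv
    raw <- pmax(design$cofactor * sinh(trans), 0)
    colnames(raw) <- colnames(pop$signatures)
    chunks[[f]] <- raw
    metas[[f]] <- data.frame(file_name = files$file_name[f],
                             donor_id = files$donor_id[f],
                             pool_id = files$pool_id[f],
                             control_sample = files$control_sample[f],
                             truth_label = draw$lab,
                             stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  table <- assign_cell_ids(cell_table(raw_expr = do.call(rbind, chunks),
                                      cell_meta = meta))
  list(table = table, files = files, markers = pop$markers)
}

#' Write a synthetic dataset as a run-ready input directory
#'
#' Emits the exact file set a real run needs: an FCS directory (FCS 3.1,
#' float data), `file_metadata.csv`, `marker_metadata.csv`, `config.yml`,
#' a `truth_labels.csv` barcode/label table, and (optionally) a landmark
#' directory with one gated FCS file per population drawn from its pure
#' signature.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created).
#' @param design the `synth_design` used (for cofactor/seed/landmarks).
#' @param landmarks write the per-population landmark FCS directory.
#' @param landmark_events events per landmark file (default 200).
#' @param config_overrides named list merged into the written config.
#' @return named list of the written paths.
#' @export
write_dataset <- function(dataset, dir, design, landmarks = TRUE,
                          landmark_events = 200L,
                          config_overrides = list()) {
  fcs_dir <- file.path(dir, "fcs")
  dir.create(fcs_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dataset$table$cell_meta
  for (f in dataset$files$file_name) {
    rows <- which(meta$file_name == f)
    write_fcs(dataset$table$raw_expr[rows, , drop = FALSE],
              file.path(fcs_dir, f),
              marker_names = dataset$markers$marker_name)
  }
  paths <- list(
    fcs_dir = fcs_dir,
    file_metadata = file.path(dir, "file_metadata.csv"),
    marker_metadata = file.path(dir, "marker_metadata.csv"),
    config = file.path(dir, "config.yml"),
    truth_labels = file.path(dir, "truth_labels.csv")
  )
  write.csv(dataset$files, paths$file_metadata, row.names = FALSE)
  write.csv(dataset$markers, paths$marker_metadata, row.names = FALSE)
  write.csv(data.frame(cell_id = meta$cell_id, label = meta$truth_label),
            paths$truth_labels, row.names = FALSE)

  if (landmarks) {
    lm_dir <- file.path(dir, "landmarks")
    dir.create(lm_dir, showWarnings = FALSE)
    pop <- design$populations
    for (p in rownames(pop$signatures)) {
      vals <- with_seed(design$seed + 10000L + match(p, rownames(pop$signatures)), {
        matrix(rnorm(landmark_events * ncol(pop$signatures),
                     mean = rep(pop$signatures[p, ], each = landmark_events),
                     sd = rep(pop$spreads[p, ], each = landmark_events)),
               landmark_events, ncol(pop$signatures))
      })
      raw <- pmax(design$cofactor * sinh(vals), 0)
      colnames(raw) <- colnames(pop$signatures)
      write_fcs(raw, file.path(lm_dir, paste0(p, ".fcs")))
    }
    paths$landmark_dir <- lm_dir
  }

  cfg <- utils::modifyList(list(
    fcs_dir = fcs_dir,
    output_dir = file.path(dir, "out"),
    file_metadata_path = paths$file_metadata,
    marker_metadata_path = paths$marker_metadata,
    arcsinh_cofactor = design$cofactor,
    truth_labels_path = paths$truth_labels,
    landmark_dir = if (landmarks) paths$landmark_dir else NULL
  ), config_overrides)
  yaml::write_yaml(cfg, paths$config)
  paths
}

#' Generate a synthetic imaging-style table with regions and centroids
#'
#' Emulates a segmented multiplexed-immunofluorescence intake: per-cell
#' mean intensities already on the arcsinh scale, x/y centroids placed
#' uniformly in a rectangle, and a region label assigned by a vertical
#' split (left fraction = stroma, right = tumor). Per-population stroma
#' placement probabilities can plant spatial enrichment.
#'
#' @param design a `synth_design` (a single file's worth of events is
#'   generated: `events_per_file` cells, batch 1).
#' @param width,height extent of the tissue rectangle in pixels.
#' @param stroma_fraction vertical split position (default 0.5).
#' @param stroma_bias named per-population probability of placement in the
#'   stroma compartment (default: uniform placement for every population).
#' @return list with `expr` (cell x marker data.frame of arcsinh values,
#'   plus `cell_id`), `regions` (data.frame `cell_id`, `x`, `y`, `region`)
#'   and `truth` (per-cell population labels).
#' @export
generate_imaging_table <- function(design, width = 1000, height = 1000,
                                   stroma_fraction = 0.5,
                                   stroma_bias = NULL) {
  pop <- design$populations
  pnames <- rownames(pop$signatures)
  nm <- ncol(pop$signatures)
  nev <- design$events_per_file
  if (is.null(stroma_bias)) {
    stroma_bias <- setNames(rep(stroma_fraction, length(pnames)), pnames)
  }
  out <- with_seed(design$seed, {
    lab <- sample(pnames, nev, replace = TRUE, prob = pop$proportions)
    trans <- pop$signatures[lab, , drop = FALSE] +
      matrix(rnorm(nev * nm), nev, nm) * pop$spreads[lab, , drop = FALSE]
    in_stroma <- runif(nev) < stroma_bias[lab]
    x <- ifelse(in_stroma,
                runif(nev, 0, width * stroma_fraction),
                runif(nev, width * stroma_fraction, width))
    y <- runif(nev, 0, height)
    list(lab = lab, trans = trans, x = x, y = y)
  })
  ids <- paste0("roi_", seq_len(nev))
  expr <- as.data.frame(out$trans)
  names(expr) <- colnames(pop$signatures)
  expr <- cbind(cell_id = ids, expr, stringsAsFactors = FALSE)
  regions <- data.frame(
    cell_id = ids, x = out$x, y = out$y,
    region = ifelse(out$x < width * stroma_fraction, "stroma", "tumor"),
    stringsAsFactors = FALSE
  )
  list(expr = expr, regions = regions, truth = out$lab)
}
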