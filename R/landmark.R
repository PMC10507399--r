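# Landmark assignment: anchor each unsupervised cluster to its closest
# expert-gated reference population by cosine similarity of median
# transformed expression over the used_for_scaffold markers.

#' Load gated landmark populations from a directory of FCS files
#'
#' Each FCS file is one landmark population (named by its filename stem).
#' Events are arcsinh transformed and the per-channel median over the
#' `used_for_scaffold` markers forms the population's profile.
#'
#' @param dir directory of gated landmark FCS files.
#' @param markers marker metadata data.frame.
#' @param cofactor arcsinh cofactor (must match the run's).
#' @return list of class `landmark_set` with `names` and `profiles`
#'   (landmark x marker matrix).
#' @export
load_landmarks <- function(dir, markers, cofactor = 5) {
  paths <- list.files(dir, pattern = "\\.fcs$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0) stop("no FCS files in landmark directory: ", dir,
                               call. = FALSE)
  nms <- tools::file_path_sans_ext(basename(paths))
  if (anyDuplicated(nms)) stop("duplicate landmark filename stems",
                               call. = FALSE)
  chan <- markers$channel_name[markers$used_for_scaffold]
  if (length(chan) == 0) stop("no markers flagged used_for_scaffold",
                              call. = FALSE)
  profiles <- t(vapply(paths, function(p) {
    fcs <- read_fcs(p)
    absent <- setdiff(chan, colnames(fcs$data))
    if (length(absent)) {
      stop(sprintf("landmark file %s lacks channel '%s'", basename(p),
                   absent[1]), call. = FALSE)
    }
    apply(arcsinh_transform(fcs$data[, chan, drop = FALSE], cofactor), 2,
          median)
  }, numeric(length(chan))))
  rownames(profiles) <- nms
  structure(list(names = nms, profiles = profiles), class = "landmark_set")
}

#' Cosine similarity between two marker vectors
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Assign clusters to their closest landmark population
#'
#' For each non-empty cluster, the landmark with maximal cosine similarity
#' between the cluster's median transformed profile and the landmark profile
#' (both restricted to `used_for_scaffold` markers) is chosen. Ties go to
#' the lexicographically first landmark name. Clusters with a zero-norm
#' profile are assigned `"unassigned"` with a warning.
#'
#' @param summary a `cluster_summary` (for `median_expr`).
#' @param landmarks a `landmark_set`.
#' @param markers marker metadata data.frame.
#' @return data.frame of class `landmark_assignment` with columns `cluster`,
#'   `landmark`, `cosine`.
#' @export
assign_landmarks <- function(summary, landmarks, markers) {
  chan <- markers$channel_name[markers$used_for_scaffold]
  prof <- summary$median_expr[, chan, drop = FALSE]
  lmk <- landmarks$profiles[, chan, drop = FALSE]
  ord <- order(rownames(lmk))  # lexicographic tie-break
  lmk <- lmk[ord, , drop = FALSE]

  rows <- lapply(seq_len(nrow(prof)), function(c) {
    v <- prof[c, ]
    if (anyNA(v)) return(NULL)  # empty cluster
    if (sqrt(sum(v^2)) == 0) {
      warning(sprintf("cluster %d has a zero-norm profile; unassigned", c),
              call. = FALSE)
      return(data.frame(cluster = c, landmark = "unassigned",
                        cosine = NA_real_))
    }
    sims <- apply(lmk, 1, cosine_similarity, b = v)
    best <- which.max(sims)  # first max = lexicographically first name
    data.frame(cluster = c, landmark = rownames(lmk)[best],
               cosine = unname(sims[best]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("landmark_assignment", "data.frame")
  out
}
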