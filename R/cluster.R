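#' Extract feature vectors from Gramian angular field images
#'
#' Reduces each participant's GAF to a fixed-length feature vector for
#' clustering. Three extractors are available, all deterministic:
#'
#' * `"flatten_pca"` (default) flattens the upper triangle of each field
#'   matrix and projects onto the leading principal components fitted on
#'   the cohort itself. It preserves where in the study period structure
#'   occurs, but is therefore sensitive to the calendar position of play
#'   episodes: two sparse players with the same behavior on different days
#'   land far apart.
#' * `"quantiles"` summarizes each field by the quantile profile of its
#'   entries — a position-invariant signature of how much of the image sits
#'   at the no-play end, the long-play end, and in between. Participants
#'   with the same playing pattern at shifted calendar positions map to
#'   nearby features, which makes the downstream clustering markedly more
#'   stable.
#' * `"vgg16"` reproduces a deep pretrained-network pipeline and requires a
#'   user-supplied function (R has no bundled pretrained VGG16 weights):
#'   pass it via `extractor_fn`, taking the list of fields and returning a
#'   numeric matrix with one row per participant.
#'
#' @param gafs Named list of `gaf_matrix` (or `gaf_image`) objects, one per
#'   participant, all with identical dimensions.
#' @param extractor_name `"flatten_pca"` (default), `"quantiles"` or
#'   `"vgg16"`.
#' @param dim Feature dimensionality: the PCA rank for `"flatten_pca"`
#'   (capped at the cohort rank) or the number of quantile knots for
#'   `"quantiles"` (default 8 and 16 respectively; `dim < 16` is raised to
#'   16 for quantiles).
#' @param extractor_fn Optional function implementing a custom extractor
#'   (required for `"vgg16"`).
#' @return A numeric matrix of class `gaf_features` (rows = participants,
#'   named), with attribute `extractor_name`.
#' @export
extract_features <- function(gafs,
                             extractor_name = c("flatten_pca", "quantiles", "vgg16"),
                             dim = 8, extractor_fn = NULL) {
  extractor_name <- match.arg(extractor_name)
  if (length(gafs) == 0L) abort("`gafs` must be a nonempty list.")
  if (is.null(names(gafs))) names(gafs) <- paste0("p", seq_along(gafs))
  upper <- function(g) {
    m <- as.matrix(g)
    m[upper.tri(m, diag = TRUE)]
  }
  if (extractor_name == "vgg16") {
    if (is.null(extractor_fn)) {
      abort(paste(
        "The \"vgg16\" extractor needs pretrained weights that are not",
        "bundled with this package; supply `extractor_fn` wrapping your own",
        "pretrained network, or use the default \"flatten_pca\" extractor."
      ))
    }
    feats <- as.matrix(extractor_fn(gafs))
  } else if (extractor_name == "quantiles") {
    knots <- max(16L, as.integer(dim))
    feats <- t(vapply(
      gafs,
      function(g) stats::quantile(upper(g), probs = seq(0, 1, length.out = knots),
                                  names = FALSE),
      numeric(knots)
    ))
  } else {
    flat <- do.call(rbind, map(gafs, upper))
    keep_dim <- max(1L, min(dim, nrow(flat) - 1L, ncol(flat)))
    pca <- stats::prcomp(flat, center = TRUE, scale. = FALSE, rank. = keep_dim)
    feats <- pca$x[, seq_len(min(keep_dim, ncol(pca$x))), drop = FALSE]
  }
  if (!all(is.finite(feats))) abort("Extractor produced non-finite features.")
  rownames(feats) <- names(gafs)
  structure(feats, class = c("gaf_features", "matrix"),
            extractor_name = extractor_name)
}

#' Cluster participants on their GAF features
#'
#' K-means (10 random restarts under a fixed seed) on the per-participant
#' feature matrix, grouping participants with similar playing patterns.
#' Features are processed in participant-name order so the assignment is
#' invariant to the input row ordering (up to the inherent label
#' permutation of K-means).
#'
#' @param features A `gaf_features` matrix (rows named by participant).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed for the restarts.
#' @param study_ids Optional named vector participant -> study label, stored
#'   alongside the assignment for cross-study source selection.
#' @return A tibble of class `cluster_assignment` with columns
#'   `participant_id`, `study_id`, `cluster` (integers `1..k`).
#' @export
cluster_participants <- function(features, k = 4, seed = 1L, study_ids = NULL) {
  assert_number(k, "k", 1)
  feats <- as.matrix(features)
  if (is.null(rownames(feats))) rownames(feats) <- paste0("p", seq_len(nrow(feats)))
  feats <- feats[order(rownames(feats)), , drop = FALSE]
  n <- nrow(feats)
  if (n < k) {
    abort(sprintf("Cannot form %d clusters from %d participants.", k, n))
  }
  n_distinct_rows <- nrow(unique(feats))
  fit <- local_seed(seed, {
    if (n_distinct_rows < k) {
      # degenerate: fewer distinct points than clusters; assign by
      # distinct-row identity and leave the remaining clusters empty
      ids <- match(
        apply(feats, 1, paste, collapse = "\r"),
        unique(apply(feats, 1, paste, collapse = "\r"))
      )
      list(cluster = ids, empty = k - n_distinct_rows)
    } else {
      km <- stats::kmeans(feats, centers = k, nstart = 10, iter.max = 100)
      list(cluster = km$cluster, empty = sum(tabulate(km$cluster, k) == 0))
    }
  })
  if (fit$empty > 0) {
    warn(sprintf("%d of %d clusters are empty (degenerate feature geometry).",
                 fit$empty, k))
  }
  pid <- rownames(feats)
  sid <- if (is.null(study_ids)) NA_character_ else unname(study_ids[pid])
  structure(
    tibble(
      participant_id = pid,
      study_id = sid,
      cluster = as.integer(fit$cluster)
    ),
    class = c("cluster_assignment", class(tibble())),
    k = as.integer(k), seed = as.integer(seed)
  )
}

#' Source participants for a target
#'
#' Returns the other members of the target's cluster — the participants
#' whose playing patterns are similar enough to transfer from. With
#' `restrict_study`, only participants from a *different* study than the
#' given one are returned, implementing the cross-study protocol in which
#' source data must come from the other trial.
#'
#' @param assignment A `cluster_assignment` from [cluster_participants()].
#' @param target Participant id of the target.
#' @param restrict_study Optional study id; when given, same-study
#'   participants are excluded from the pool.
#' @return Character vector of source participant ids (possibly empty).
#' @export
source_pool <- function(assignment, target, restrict_study = NULL) {
  if (!target %in% assignment$participant_id) {
    abort(sprintf("Target %s is not in the cluster assignment.", deparse(target)))
  }
  cl <- assignment$cluster[assignment$participant_id == target]
  pool <- filter(
    assignment, .data$cluster == cl, .data$participant_id != target
  )
  if (!is.null(restrict_study)) {
    pool <- filter(pool, .data$study_id != restrict_study)
  }
  pool$participant_id
}

#' Full clustering pipeline for a cohort
#'
#' Composes [cohort_gafs()], [extract_features()] and
#' [cluster_participants()]: play-time series -> GAF -> features -> K-means.
#'
#' @inheritParams cohort_gafs
#' @inheritParams cluster_participants
#' @inheritParams extract_features
#' @return A `cluster_assignment` tibble with the per-cluster silhouette
#'   mean stored in attribute `"silhouette"`.
#' @export
cluster_cohort <- function(cohort, k = 4, seed = 1L,
                           extractor_name = "flatten_pca", dim = 8,
                           span = "full", train_days = 30,
                           encoding = "symmetric") {
  gafs <- cohort_gafs(cohort, span = span, train_days = train_days,
                      encoding = encoding)
  feats <- extract_features(gafs, extractor_name, dim = dim)
  study_ids <- cohort |>
    distinct(.data$participant_id, .data$study_id) |>
    (\(d) stats::setNames(d$study_id, d$participant_id))()
  assignment <- cluster_participants(feats, k = k, seed = seed,
                                     study_ids = study_ids)
  attr(assignment, "silhouette") <- silhouette_means(
    as.matrix(feats)[order(rownames(feats)), , drop = FALSE],
    assignment$cluster
  )
  assignment
}

# Mean silhouette width per cluster (simple O(n^2) computation).
silhouette_means <- function(feats, cluster) {
  n <- nrow(feats)
  if (n < 3L || length(unique(cluster)) < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(feats))
  s <- vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(
      setdiff(unique(cluster), cluster[i]),
      function(cl) mean(d[i, cluster == cl]), numeric(1)
    ))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  tapply(s, cluster, mean)
}
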