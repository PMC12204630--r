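#' Normalize a unit shape for similarity comparison
#'
#' Over the comparison window, the mean waveform is centered (mean voltage
#' zero) and scaled to unit L2 norm. Centering alone cannot bound the dot
#' product of two shapes, so the unit-norm scaling is what pins the
#' similarity score to \[-1, 1\]; it also removes raw amplitude, which mostly
#' reflects electrode-to-cell distance rather than cell type.
#'
#' @param waveform Numeric mean waveform.
#' @param window Optional integer index range into `waveform` (default: all).
#'
#' @return Centered, unit-norm shape over the window.
#' @export
normalize_shape <- function(waveform, window = NULL) {
  v <- if (is.null(window)) waveform else waveform[window]
  if (length(v) < 4) abort("comparison window must span at least 4 samples.")
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("constant waveform has no shape to normalize.")
  v / nrm
}

#' Spike-shape similarity between two units
#'
#' The two units' mean waveforms are compared over the union of their spike
#' windows — from the earlier spike start `min(tau_i)` to the later spike
#' end `max(tau_R)` — with both waveforms aligned at their alignment
#' extremum (time 0) on the common 2 ms extraction frame. Each is centered
#' and unit-normalized over that window, and the similarity is their dot
#' product: 1 for identical shapes, -1 for identical inverted shapes, 0 for
#' complete dissimilarity, independent of raw amplitude.
#'
#' @param unit_a,unit_b [spike_unit()] objects (or lists with
#'   `mean_waveform`, `tau_i`, `tau_R`, `rate`).
#'
#' @return Similarity score in \[-1, 1\].
#' @export
similarity <- function(unit_a, unit_b) {
  rate <- unit_a$rate
  geom <- frame_geometry(rate)
  i0 <- geom$i0
  lo <- min(unit_a$idx_start, unit_b$idx_start)
  hi <- max(unit_a$idx_end, unit_b$idx_end)
  win <- lo:hi
  a <- normalize_shape(unit_a$mean_waveform, win)
  b <- normalize_shape(unit_b$mean_waveform, win)
  sum(a * b)
}

#' Pairwise similarity matrix over sorted units
#'
#' @param units List of [spike_unit()] objects (>= 2).
#'
#' @return A symmetric matrix of similarity scores with unit diagonal;
#'   row/column names are the unit ids.
#' @export
similarity_matrix <- function(units) {
  n <- length(units)
  if (n < 2) abort("at least 2 units are required.")
  s <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <- similarity(units[[i]], units[[j]])
    }
  }
  ids <- vapply(units, function(u) as.character(u$unit_id), character(1))
  dimnames(s) <- list(ids, ids)
  s
}

#' Distance matrix for shape clustering
#'
#' Negative similarities are clamped to zero *before* the distance is formed
#' (an anti-similar pair is maximally distant, not super-distant), then
#' `d = 1 - s`. Distances lie in \[0, 1\] with a zero diagonal.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#'
#' @return Distance matrix of the same dimension.
#' @export
distance_matrix <- function(sim) {
  d <- 1 - pmax(sim, 0)
  diag(d) <- 0
  d
}

#' Agglomerative average-linkage clustering of unit shapes
#'
#' Standard agglomerative clustering where the distance between two clusters
#' is the average distance between all cross-cluster pairs (UPGMA).
#'
#' @param distances Distance matrix from [distance_matrix()].
#'
#' @return An `hclust` merge tree.
#' @export
hierarchical_cluster <- function(distances) {
  stats::hclust(stats::as.dist(distances), method = "average")
}

#' Intra-cluster distance curve and elbow-based cluster count
#'
#' Computes the mean within-cluster pairwise distance for each candidate cut
#' `k = 1..k_max` and picks the elbow: the `k` whose point on the curve has
#' maximum perpendicular distance to the chord joining the curve's endpoints
#' (the kneedle criterion, an automated stand-in for choosing the elbow by
#' eye). A manual `k` override is supported downstream in [cluster_shapes()].
#'
#' @param tree `hclust` tree from [hierarchical_cluster()].
#' @param distances The distance matrix the tree was built from.
#' @param k_max Largest cut considered (default 10, capped at `n`).
#'
#' @return A list: `k` (chosen count), `curve` (tibble of `k`,
#'   `intra_distance`).
#' @export
select_k_elbow <- function(tree, distances, k_max = 10) {
  n <- length(tree$order)
  if (n < 3) {
    inform("fewer than 3 units: every unit is its own cluster.")
    return(list(k = n, curve = tibble::tibble(k = n, intra_distance = 0)))
  }
  k_max <- min(k_max, n)
  ks <- seq_len(k_max)
  w <- vapply(ks, function(k) {
    labels <- stats::cutree(tree, k = k)
    vals <- c()
    for (g in unique(labels)) {
      sel <- which(labels == g)
      if (length(sel) > 1) {
        dsub <- distances[sel, sel]
        vals <- c(vals, dsub[upper.tri(dsub)])
      }
    }
    if (length(vals) == 0) 0 else mean(vals)
  }, numeric(1))
  curve <- tibble::tibble(k = ks, intra_distance = w)
  if (max(w) - min(w) < 1e-12) {
    return(list(k = 1L, curve = curve))
  }
  # perpendicular distance of each point to the chord between the endpoints,
  # on axes normalized to [0, 1]
  x <- (ks - ks[1]) / (ks[k_max] - ks[1])
  rng <- max(w) - min(w)
  y <- (w - min(w)) / rng
  chord <- y[1] + (y[k_max] - y[1]) * x
  dist_to_chord <- (chord - y) / sqrt(1 + ((y[k_max] - y[1]))^2)
  k_best <- ks[which.max(dist_to_chord)]
  list(k = as.integer(k_best), curve = curve)
}

#' Cut the shape tree and summarize clusters
#'
#' Cuts the average-linkage tree at `k` clusters and computes the mean
#' normalized shape of each cluster over the common extraction frame.
#'
#' @param units List of [spike_unit()] objects.
#' @param k Number of clusters (1..n), e.g. from [select_k_elbow()] or a
#'   manual override.
#' @param tree Optional precomputed `hclust` tree; rebuilt from the units
#'   when `NULL`.
#'
#' @return A `shape_clusters` object: `labels` tibble (`unit_id`, `cluster`),
#'   `k`, `tree`, `mean_shapes` (matrix, one normalized mean shape per
#'   cluster row), `sizes`, `similarity`, `distance`, `curve` (when computed
#'   via the elbow), `rate`.
#' @export
cluster_shapes <- function(units, k = NULL, tree = NULL) {
  n <- length(units)
  sim <- similarity_matrix(units)
  d <- distance_matrix(sim)
  if (is.null(tree)) tree <- hierarchical_cluster(d)
  curve <- NULL
  if (is.null(k)) {
    sel <- select_k_elbow(tree, d)
    k <- sel$k
    curve <- sel$curve
  }
  if (k < 1 || k > n) abort("`k` must lie in 1..n.")
  labels <- stats::cutree(tree, k = k)
  geom <- frame_geometry(units[[1]]$rate)
  # normalized full-frame waveforms for averaging within clusters
  norm_wf <- t(vapply(units, function(u) normalize_shape(u$mean_waveform),
                      numeric(geom$len)))
  mean_shapes <- matrix(0, k, geom$len)
  for (g in seq_len(k)) {
    mean_shapes[g, ] <- colMeans(norm_wf[labels == g, , drop = FALSE])
  }
  ids <- vapply(units, function(u) u$unit_id, numeric(1))
  structure(
    list(labels = tibble::tibble(unit_id = ids, cluster = as.integer(labels)),
         k = as.integer(k), tree = tree, mean_shapes = mean_shapes,
         sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
         similarity = sim, distance = d, curve = curve,
         rate = units[[1]]$rate),
    class = "shape_clusters"
  )
}

#' @export
print.shape_clusters <- function(x, ...) {
  cat(sprintf("<shape_clusters> %d units in %d cluster(s); sizes: %s\n",
              nrow(x$labels), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @method tidy shape_clusters
#' @export
tidy.shape_clusters <- function(x, ...) x$labels

#' @method glance shape_clusters
#' @export
glance.shape_clusters <- function(x, ...) {
  tibble::tibble(n_units = nrow(x$labels), k = x$k,
                 mean_intra_distance = if (!is.null(x$curve)) {
                   x$curve$intra_distance[x$curve$k == x$k]
                 } else NA_real_)
}

#' Plot mean cluster shapes with member waveforms
#'
#' @param object A `shape_clusters` object.
#' @param units The unit list the clustering was built from (for member
#'   waveforms); omit to plot mean shapes only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_clusters
#' @export
autoplot.shape_clusters <- function(object, units = NULL, ...) {
  geom <- frame_geometry(object$rate)
  tms <- (seq_len(geom$len) - geom$i0) / object$rate * 1000
  mean_df <- purrr::map_dfr(seq_len(object$k), function(g) {
    tibble::tibble(cluster = g, t_ms = tms, shape = object$mean_shapes[g, ])
  })
  p <- ggplot2::ggplot(mean_df, ggplot2::aes(.data$t_ms, .data$shape))
  if (!is.null(units)) {
    mem <- purrr::map_dfr(seq_along(units), function(i) {
      tibble::tibble(cluster = object$labels$cluster[i], unit = i, t_ms = tms,
                     shape = normalize_shape(units[[i]]$mean_waveform))
    })
    p <- p + ggplot2::geom_line(data = mem, ggplot2::aes(group = .data$unit),
                                colour = "grey70", linewidth = 0.2)
  }
  p +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.7) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time from alignment extremum (ms)",
                  y = "Normalized shape",
                  title = "Mean cluster shapes") +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' @param sim Similarity matrix.
#' @param order Optional unit ordering (e.g. `tree$order` from the cluster
#'   tree) so cluster blocks appear on the diagonal.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(sim, order = NULL) {
  if (!is.null(order)) sim <- sim[order, order]
  df <- tibble::as_tibble(as.table(sim), .name_repair = ~c("unit_a", "unit_b", "similarity"))
  df$unit_a <- factor(df$unit_a, levels = rownames(sim))
  df$unit_b <- factor(df$unit_b, levels = colnames(sim))
  ggplot2::ggplot(df, ggplot2::aes(.data$unit_a, .data$unit_b, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Spike-shape similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Depth profile of clustered units
#'
#' Per-unit table of depth, cluster label, firing rate, and mean ISI, plus a
#' per-cluster summary (mean +/- SEM of firing rate and ISI) — the depth
#' layout used to relate spike shapes to anatomical structure along the
#' recording track.
#'
#' @param clusters A `shape_clusters` object.
#' @param depths_mm Per-unit depth in mm (NA allowed; such units are kept in
#'   the table but excluded from depth ordering).
#' @param spike_times List of per-unit spike-time vectors (seconds).
#' @param duration_s Recording duration(s) per unit in seconds (recycled).
#'
#' @return A list of tibbles: `units` (per-unit rows, ordered by depth) and
#'   `clusters` (per-cluster mean +/- SEM summaries).
#' @export
depth_profile <- function(clusters, depths_mm, spike_times, duration_s) {
  stopifnot(inherits(clusters, "shape_clusters"))
  n <- nrow(clusters$labels)
  duration_s <- rep_len(duration_s, n)
  units <- tibble::tibble(
    unit_id = clusters$labels$unit_id,
    cluster = clusters$labels$cluster,
    depth_mm = as.numeric(depths_mm),
    n_spikes = vapply(spike_times, length, integer(1)),
    firing_rate_hz = vapply(spike_times, length, integer(1)) / duration_s,
    mean_isi_s = vapply(spike_times, function(t) {
      if (length(t) < 2) NA_real_ else mean(diff(sort(t)))
    }, numeric(1))
  )
  units <- dplyr::arrange(units, !is.na(.data$depth_mm), dplyr::desc(.data$depth_mm))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  summary <- units |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      mean_rate_hz = mean(.data$firing_rate_hz),
      sem_rate_hz = sem(.data$firing_rate_hz),
      mean_isi_s = mean(.data$mean_isi_s, na.rm = TRUE),
      sem_isi_s = sem(.data$mean_isi_s),
      .groups = "drop"
    )
  list(units = units, clusters = summary)
}

#' Hungarian (optimal one-to-one) label matching
#'
#' Solves the linear assignment problem minimizing total cost with the
#' Munkres algorithm; used to align two clustering label sets before scoring
#' their agreement.
#'
#' @param cost Square cost matrix.
#' @return Integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
hungarian_assign <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  C <- cost
  # step 1-2: row/column reduction
  C <- C - apply(C, 1, min)
  C <- sweep(C, 2, apply(C, 2, min))
  starred <- matrix(FALSE, n, n)
  primed <- matrix(FALSE, n, n)
  row_cov <- rep(FALSE, n)
  col_cov <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (C[i, j] == 0 && !row_cov[i] && !col_cov[j]) {
        starred[i, j] <- TRUE
        row_cov[i] <- TRUE
        col_cov[j] <- TRUE
      }
    }
  }
  row_cov[] <- FALSE
  col_cov[] <- FALSE
  repeat {
    col_cov <- apply(starred, 2, any)
    if (sum(col_cov) == n) break
    repeat {
      # find an uncovered zero
      z <- which(C == 0 & !row_cov[row(C)] & !col_cov[col(C)], arr.ind = TRUE)
      if (nrow(z) == 0) {
        # adjust matrix by the smallest uncovered value
        mn <- min(C[!row_cov, !col_cov, drop = FALSE])
        C[row_cov, ] <- C[row_cov, ] + mn
        C[, !col_cov] <- C[, !col_cov] - mn
        next
      }
      i <- z[1, 1]; j <- z[1, 2]
      primed[i, j] <- TRUE
      sj <- which(starred[i, ])
      if (length(sj) == 0) {
        # augmenting path starting at primed zero (i, j)
        path <- matrix(c(i, j), 1, 2)
        repeat {
          si <- which(starred[, path[nrow(path), 2]])
          if (length(si) == 0) break
          path <- rbind(path, c(si, path[nrow(path), 2]))
          pj <- which(primed[si, ])
          path <- rbind(path, c(si, pj[1]))
        }
        for (r in seq_len(nrow(path))) {
          pi <- path[r, 1]; pj <- path[r, 2]
          if (starred[pi, pj]) starred[pi, pj] <- FALSE else starred[pi, pj] <- TRUE
        }
        primed[] <- FALSE
        row_cov[] <- FALSE
        col_cov[] <- FALSE
        break
      } else {
        row_cov[i] <- TRUE
        col_cov[sj[1]] <- FALSE
      }
    }
  }
  apply(starred, 1, which)
}

#' Compare shape clustering to PCA + k-means
#'
#' The conventional alternative: project (optionally unit-normalized) mean
#' waveforms onto their first two principal components, k-means cluster the
#' scores, then align the k-means labels to the reference labels with the
#' Hungarian method and report the percentage of units on which the two
#' clusterings agree. Without normalization the comparison is dominated by
#' raw amplitude.
#'
#' @param units List of [spike_unit()] objects.
#' @param reference_labels Integer labels to compare against (e.g.
#'   `tidy(clusters)$cluster`).
#' @param k Number of k-means clusters.
#' @param normalize Normalize waveforms (center + unit norm) before PCA?
#' @param seed Seed for the k-means restarts.
#'
#' @return A list: `labels` (aligned k-means labels), `overlap_pct`,
#'   `assignment` (cluster index mapping).
#' @export
compare_pca_kmeans <- function(units, reference_labels, k, normalize = FALSE,
                               seed = 1) {
  n <- length(units)
  if (k > n) abort("`k` exceeds the number of units.")
  wf <- t(vapply(units, function(u) {
    if (normalize) normalize_shape(u$mean_waveform) else u$mean_waveform
  }, numeric(length(units[[1]]$mean_waveform))))
  pc <- prcomp(wf, center = TRUE, rank. = 2)
  scores <- pc$x
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  km <- with_seed(seed, kmeans(scores, centers = k, nstart = 10))
  raw <- km$cluster
  # confusion matrix; Hungarian maximizes agreement = minimizes (max - counts)
  conf <- table(factor(raw, levels = seq_len(k)),
                factor(reference_labels, levels = seq_len(max(reference_labels, k))))
  kk <- max(dim(conf))
  cost <- matrix(max(conf), kk, kk)
  cost[seq_len(nrow(conf)), seq_len(ncol(conf))] <- max(conf) - as.matrix(conf)
  perm <- hungarian_assign(cost)
  aligned <- perm[raw]
  list(labels = as.integer(aligned),
       overlap_pct = 100 * mean(aligned == reference_labels),
       assignment = perm)
}
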