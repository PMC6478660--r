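#' Threshold specification
#'
#' A (p, k) segmentation setting: voxel-level significance `p` (with optional
#' Bonferroni family-wise correction) plus minimum cluster extent `k` in
#' voxels.
#'
#' @param p significance level in (0, 1).
#' @param k minimum cluster extent, voxels (>= 1).
#' @param correction `"none"` or `"bonferroni"`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(p, k, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  structure(list(p = p, k = as.integer(k), correction = correction),
            class = "threshold_spec")
}

#' Supra-threshold binary map
#'
#' Voxels whose hypometabolism t statistic reaches the threshold implied by
#' the spec (see [t_threshold()]), intersected with the analysis mask.
#'
#' @param tm a [tmap()] result.
#' @param spec a [threshold_spec()].
#' @param m in-mask voxel count used for Bonferroni; defaults to the t-map's
#'   own mask size.
#' @return Binary `pet_volume`.
#' @export
threshold_map <- function(tm, spec, m = NULL) {
  stopifnot(inherits(tm, "t_stat_map"), inherits(spec, "threshold_spec"))
  if (is.null(m)) m <- sum(tm$mask$data != 0)
  thr <- t_threshold(spec$p, tm$df, spec$correction, m)
  with_data(tm$t, (tm$t$data >= thr & tm$mask$data != 0) * 1)
}

#' Connected components of a binary volume
#'
#' Partitions the foreground into maximal connected sets under 6-, 18- or
#' 26-connectivity.  Components are found as the connected components of the
#' voxel adjacency graph.
#'
#' @param binary a binary [volume()] or 3-D array/logical array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighborhood;
#'   the default — most inclusive, so clusters are never split on diagonals).
#' @return List of integer vectors of linear voxel indices (1-based), each a
#'   component, ordered by first voxel index.
#' @export
connected_components <- function(binary, connectivity = 26) {
  if (inherits(binary, "pet_volume")) binary <- binary$data
  stopifnot(length(dim(binary)) == 3)
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  d <- dim(binary)
  idx <- which(binary != 0)
  if (!length(idx)) return(list())
  lut <- integer(prod(d))
  lut[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ni <- co[, 1] + o[1]; nj <- co[, 2] + o[2]; nk <- co[, 3] + o[3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    if (!any(ok)) next
    nlin <- (ni[ok] - 1L) + d[1] * ((nj[ok] - 1L) + d[2] * (nk[ok] - 1L)) + 1L
    nb <- lut[nlin]
    keep <- nb > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, nb[keep])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_along(idx)]
  } else {
    memb <- seq_along(idx)
  }
  comps <- split(idx, memb)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  names(comps) <- NULL
  lapply(comps, as.integer)
}

# half set of neighbor offsets (undirected edges built once per pair)
connectivity_offsets <- function(connectivity) {
  all_off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  all_off <- all_off[rowSums(abs(all_off)) > 0, , drop = FALSE]
  if (connectivity == 6) all_off <- all_off[rowSums(abs(all_off)) == 1, , drop = FALSE]
  if (connectivity == 18) all_off <- all_off[rowSums(abs(all_off)) <= 2, , drop = FALSE]
  keep <- all_off[, 3] > 0 |
    (all_off[, 3] == 0 & (all_off[, 2] > 0 | (all_off[, 2] == 0 & all_off[, 1] > 0)))
  all_off[keep, , drop = FALSE]
}

#' Build cluster records from voxel components
#'
#' @param components list of linear-index vectors (from
#'   [connected_components()]).
#' @param tm the originating [tmap()].
#' @param atlas a [label_atlas()] on the same grid.
#' @return List of `ez_cluster` records with fields `voxels`, `size`,
#'   `peak_t`, `peak_voxel` (0-based ijk), `centroid_mm`, `label_counts`
#'   (named by label id).
#' @export
build_clusters <- function(components, tm, atlas) {
  d <- dim(tm$t$data)
  lapply(components, function(vox) {
    tv <- tm$t$data[vox]
    pk <- vox[order(-tv, vox)[1]]
    ijk <- arrayInd(pk, d) - 1L
    co <- arrayInd(vox, d)
    centroid <- tm$t$origin + (colMeans(co) - 1) * tm$t$spacing
    labs <- atlas$labels$data[vox]
    lc <- table(labs)
    structure(list(voxels = vox, size = length(vox), peak_t = max(tv),
                   peak_voxel = as.integer(ijk), centroid_mm = centroid,
                   label_counts = lc),
              class = "ez_cluster")
  })
}

#' Extent and anatomical exclusion filters
#'
#' Applies, in order, the three exclusion rules: components smaller than `k`
#' voxels (reason `"extent"`); components with more than half their voxels on
#' non-cortical labels, i.e. outside the cerebral cortex (reason
#' `"extracortical"`); components with more than half their voxels within
#' `midline_margin` mm of the x = 0 plane, i.e. interhemispheric (reason
#' `"interhemispheric"`).
#'
#' @param clusters list of `ez_cluster` records ([build_clusters()]).
#' @param k minimum extent in voxels.
#' @param atlas a [label_atlas()] on the cluster grid.
#' @param tm the originating [tmap()] (grid geometry for the midline test).
#' @param midline_margin mm half-width of the interhemispheric slab
#'   (default 6).
#' @param overlap_vote fraction of voxels that must violate a rule for the
#'   cluster to be excluded (default 0.5).
#' @return List with `kept` (cluster list) and `excluded` (list of
#'   `list(cluster, reason)`).
#' @export
filter_clusters <- function(clusters, k, atlas, tm, midline_margin = 6,
                            overlap_vote = 0.5) {
  wx <- voxel_world_x(tm$t)
  cortical_ids <- atlas$table$id[atlas$table$cortical]
  kept <- list(); excluded <- list()
  for (cl in clusters) {
    reason <- NULL
    if (cl$size < k) {
      reason <- "extent"
    } else {
      labs <- atlas$labels$data[cl$voxels]
      if (mean(!(labs %in% cortical_ids)) > overlap_vote) {
        reason <- "extracortical"
      } else if (mean(abs(wx[cl$voxels]) <= midline_margin) > overlap_vote) {
        reason <- "interhemispheric"
      }
    }
    if (is.null(reason)) kept[[length(kept) + 1]] <- cl
    else excluded[[length(excluded) + 1]] <- list(cluster = cl, reason = reason)
  }
  list(kept = kept, excluded = excluded)
}

#' Rank clusters into a segmentation
#'
#' Ranking key (total order): size descending, then peak t descending, then
#' lexicographic peak voxel index.  Rank 1 is the presurgical-EZ candidate —
#' the biggest, most significant cluster.
#'
#' @param kept list of `ez_cluster` records.
#' @param spec the generating [threshold_spec()].
#' @param excluded optional exclusion list from [filter_clusters()].
#' @return An object of class `ez_segmentation` with ranked `clusters`,
#'   `excluded`, `spec`.
#' @export
rank_clusters <- function(kept, spec = NULL, excluded = list()) {
  if (length(kept) > 1) {
    key <- order(-vapply(kept, function(c) c$size, numeric(1)),
                 -vapply(kept, function(c) c$peak_t, numeric(1)),
                 vapply(kept, function(c) c$peak_voxel[1], numeric(1)),
                 vapply(kept, function(c) c$peak_voxel[2], numeric(1)),
                 vapply(kept, function(c) c$peak_voxel[3], numeric(1)))
    kept <- kept[key]
  }
  structure(list(spec = spec, clusters = kept, excluded = excluded),
            class = "ez_segmentation")
}

#' @export
print.ez_segmentation <- function(x, ...) {
  cat(sprintf("<ez_segmentation> %d cluster(s), %d excluded\n",
              length(x$clusters), length(x$excluded)))
  if (length(x$clusters)) print(tidy_segmentation(x))
  invisible(x)
}

#' Tidy cluster table of a segmentation
#' @param seg an `ez_segmentation`.
#' @return Tibble with one row per ranked cluster.
#' @export
tidy_segmentation <- function(seg) {
  if (!length(seg$clusters))
    return(tibble::tibble(rank = integer(), size = integer(),
                          peak_t = numeric(), x_mm = numeric(),
                          y_mm = numeric(), z_mm = numeric()))
  tibble::tibble(
    rank = seq_along(seg$clusters),
    size = vapply(seg$clusters, function(c) c$size, numeric(1)),
    peak_t = vapply(seg$clusters, function(c) c$peak_t, numeric(1)),
    x_mm = vapply(seg$clusters, function(c) c$centroid_mm[1], numeric(1)),
    y_mm = vapply(seg$clusters, function(c) c$centroid_mm[2], numeric(1)),
    z_mm = vapply(seg$clusters, function(c) c$centroid_mm[3], numeric(1)))
}

#' Segment a t-map at one threshold specification
#'
#' Convenience chain: [threshold_map()] -> [connected_components()] ->
#' [build_clusters()] -> [filter_clusters()] -> [rank_clusters()].
#'
#' @param tm a [tmap()] result.
#' @param spec a [threshold_spec()].
#' @param atlas a [label_atlas()].
#' @param connectivity cluster connectivity (default 26).
#' @param midline_margin interhemispheric slab half-width, mm (default 6).
#' @param m Bonferroni voxel count override.
#' @return An `ez_segmentation`.
#' @export
segment_tmap <- function(tm, spec, atlas, connectivity = 26,
                         midline_margin = 6, m = NULL) {
  bin <- threshold_map(tm, spec, m)
  comps <- connected_components(bin, connectivity)
  clusters <- build_clusters(comps, tm, atlas)
  f <- filter_clusters(clusters, spec$k, atlas, tm, midline_margin)
  rank_clusters(f$kept, spec, f$excluded)
}

#' Side and sublobar EZ call from a segmentation
#'
#' An empty segmentation yields the Negative call.  Otherwise the rank-1
#' cluster determines the call: the side of its majority atlas label and the
#' majority sublobar class of its cortical voxels.  If mesial-temporal and
#' lateral-temporal labels each cover at least `mlt_share` of the cluster's
#' cortical voxels, the combined class `MLT` is called.
#'
#' @param seg an `ez_segmentation`.
#' @param atlas the [label_atlas()] used to build it.
#' @param mlt_share dual-involvement share for the MLT call (default 0.3).
#' @return Canonical call string (`"Neg"` or e.g. `"L/MT"`).
#' @export
ez_call <- function(seg, atlas, mlt_share = 0.3) {
  if (!length(seg$clusters)) return("Neg")
  cl <- seg$clusters[[1]]
  lc <- cl$label_counts
  ids <- as.integer(names(lc))
  info <- atlas_lookup(atlas, ids)
  cort <- !is.na(info$cortical) & info$cortical
  if (!any(cort))
    stop("rank-1 cluster has only non-cortical labels; it should have been excluded upstream")
  counts <- as.numeric(lc)[cort]
  info <- info[cort, , drop = FALSE]
  maj <- which.max(counts)
  side <- info$side[maj]
  shares <- tapply(counts, info$sublobar, sum) / sum(counts)
  sub <- names(shares)[which.max(shares)]
  mt <- if ("MT" %in% names(shares)) shares[["MT"]] else 0
  lt <- if ("LT" %in% names(shares)) shares[["LT"]] else 0
  if (mt >= mlt_share && lt >= mlt_share) sub <- "MLT"
  paste0(side, "/", sub)
}

#' Dynamic multi-threshold sweep
#'
#' The programmatic counterpart of scrollbar-driven re-thresholding: the
#' t-map is computed once and only re-thresholded and re-segmented for every
#' (p, k) combination of the grids.  Default grids span the study's dynamic
#' range, p in {0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001} and k in
#' {50, 100, 150, 200}.
#'
#' @param tm a [tmap()] result.
#' @param atlas a [label_atlas()].
#' @param p_grid,k_grid numeric grids.
#' @param correction `"none"` or `"bonferroni"` (applied to every p).
#' @param connectivity,midline_margin,mlt_share passed through.
#' @return Tibble of class `ez_sweep` with one row per (p, k): `p`, `k`,
#'   `t_threshold`, `n_clusters`, `largest`, `peak_t`, `ez` (call string).
#' @export
threshold_sweep <- function(tm, atlas,
                            p_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4),
                            k_grid = c(50, 100, 150, 200),
                            correction = "none",
                            connectivity = 26, midline_margin = 6,
                            mlt_share = 0.3) {
  if (!length(p_grid) || !length(k_grid)) stop("threshold grids must be nonempty")
  m <- sum(tm$mask$data != 0)
  rows <- vector("list", length(p_grid) * length(k_grid))
  i <- 0L
  for (p in p_grid) {
    bin <- threshold_map(tm, threshold_spec(p, 1, correction), m)
    comps <- connected_components(bin, connectivity)
    clusters <- build_clusters(comps, tm, atlas)
    for (k in k_grid) {
      spec <- threshold_spec(p, k, correction)
      f <- filter_clusters(clusters, k, atlas, tm, midline_margin)
      seg <- rank_clusters(f$kept, spec, f$excluded)
      call <- ez_call(seg, atlas, mlt_share)
      i <- i + 1L
      rows[[i]] <- tibble::tibble(
        p = p, k = as.integer(k),
        t_threshold = t_threshold(p, tm$df, correction, m),
        n_clusters = length(seg$clusters),
        largest = if (length(seg$clusters)) seg$clusters[[1]]$size else 0L,
        peak_t = if (length(seg$clusters)) seg$clusters[[1]]$peak_t else NA_real_,
        ez = call)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ez_sweep", class(out))
  out
}

#' Plot a threshold sweep
#'
#' Tile map of the EZ call across the (p, k) grid, annotated with the kept
#' cluster count — the static analogue of the interactive two-scrollbar view.
#'
#' @param object an `ez_sweep` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ez_sweep <- function(object, ...) {
  df <- object
  df$p_lab <- factor(format(df$p, scientific = FALSE, drop0trailing = TRUE),
                     levels = unique(format(sort(unique(df$p), decreasing = TRUE),
                                            scientific = FALSE, drop0trailing = TRUE)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_lab, y = factor(.data$k),
                                   fill = .data$ez)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_clusters), size = 3) +
    ggplot2::labs(x = "voxel-level p", y = "cluster extent k (voxels)",
                  fill = "EZ call",
                  title = "Dynamic segmentation sweep",
                  subtitle = "tile label = kept cluster count") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity t-map slice plot
#'
#' @param tm a [tmap()] result.
#' @param z_index 1-based axial slice; defaults to the slice containing the
#'   global peak.
#' @return A ggplot object.
#' @export
plot_tmap_slice <- function(tm, z_index = NULL) {
  d <- dim(tm$t$data)
  if (is.null(z_index)) z_index <- arrayInd(which.max(tm$t$data), d)[3]
  sl <- tm$t$data[, , z_index]
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$t <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("t-map, axial slice %d (df = %d)", z_index, tm$df),
                  x = "x (voxels, +x = Right)", y = "y (voxels)") +
    ggplot2::theme_minimal()
}
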