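#' Detect clusters in a trajectory frame
#'
#' Clusters are the connected components of the clathrin-clathrin bond
#' graph; a clathrin carrying a bound AP-2 but no clathrin partner is a
#' (membrane-bound) cluster of one. Completely unbonded clathrins are not
#' reported. A cluster is membrane-bound when it contains at least one
#' AP-2, and "large" when it holds more than `large_threshold` clathrins
#' (the size class used for cluster-number statistics).
#'
#' @param frame an [fcl_frame()].
#' @param geometry a [clathrin_geometry()] (for the area footprint).
#' @param large_threshold clathrin count above which a cluster is counted
#'   as large (default 10, i.e. "more than 10 clathrins").
#' @return data.frame with one row per cluster: `cluster`, `n_clathrin`,
#'   `n_ap2`, `is_membrane_bound`, `is_large`, `area` (um^2, `NA` for
#'   clusters not on the membrane) and a list column `member_ids`.
#' @export
find_clusters <- function(frame, geometry = clathrin_geometry(),
                          large_threshold = 10) {
  n <- frame$n_clathrin
  b <- frame$bonds
  in_play <- union(unique(c(b[, "mol_a"], b[, "mol_b"])),
                   which(frame$ap2_bound != 0))
  if (length(in_play) == 0) {
    return(data.frame(cluster = integer(0), n_clathrin = integer(0),
                      n_ap2 = integer(0), is_membrane_bound = logical(0),
                      is_large = logical(0), area = numeric(0),
                      member_ids = I(list())))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(b) > 0) {
    g <- igraph::add_edges(g, rbind(b[, "mol_a"], b[, "mol_b"]))
  }
  comp <- igraph::components(g)$membership
  comp_ids <- sort(unique(comp[in_play]))
  out <- lapply(comp_ids, function(cid) {
    mem <- which(comp == cid)
    nc <- length(mem)
    na2 <- sum(frame$ap2_bound[mem] != 0)
    memb <- na2 >= 1
    area <- if (memb) {
      cluster_area(frame$pos[mem, , drop = FALSE],
                   geometry$footprint_radius)
    } else NA_real_
    data.frame(cluster = cid, n_clathrin = nc, n_ap2 = na2,
               is_membrane_bound = memb, is_large = nc > large_threshold,
               area = area)
  })
  res <- do.call(rbind, out)
  res$member_ids <- I(lapply(comp_ids, function(cid) which(comp == cid)))
  res$cluster <- seq_len(nrow(res))
  res
}

#' Number of membrane-bound clathrins in a frame
#'
#' Clathrins belonging to an AP-2-containing cluster, including single
#' AP-2-bound clathrins. Never exceeds the (conserved) clathrin count.
#'
#' @inheritParams find_clusters
#' @return integer count.
#' @export
membrane_bound_clathrin_count <- function(frame,
                                          geometry = clathrin_geometry()) {
  cl <- find_clusters(frame, geometry)
  sum(cl$n_clathrin[cl$is_membrane_bound])
}

#' Projected membrane area of a cluster
#'
#' Area of the convex hull of the member x-y center projections, dilated by
#' the clathrin footprint disc (Minkowski sum): `A_hull + P_hull r + pi
#' r^2`, with degenerate hulls (single member, collinear members) handled
#' in closed form.
#'
#' @param pos member positions, m x 3 (or m x 2) matrix, nm.
#' @param footprint_radius dilation radius, nm.
#' @return area in um^2.
#' @export
cluster_area <- function(pos, footprint_radius = 12.5) {
  xy <- unique(pos[, 1:2, drop = FALSE])
  r <- footprint_radius
  m <- nrow(xy)
  if (m == 1) return(pi * r^2 * 1e-6)
  hull_area <- 0
  perimeter <- 0
  if (m == 2) {
    perimeter <- 2 * sqrt(sum((xy[1, ] - xy[2, ])^2))
  } else {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    hp <- xy[h, , drop = FALSE]
    k <- nrow(hp)
    if (k <= 2) {
      perimeter <- 2 * max(stats::dist(xy))
    } else {
      nx <- c(hp[-1, 1], hp[1, 1])
      ny <- c(hp[-1, 2], hp[1, 2])
      hull_area <- abs(sum(hp[, 1] * ny - nx * hp[, 2])) / 2
      perimeter <- sum(sqrt((nx - hp[, 1])^2 + (ny - hp[, 2])^2))
      if (hull_area < 1e-9) {  # numerically collinear
        hull_area <- 0
        perimeter <- 2 * max(stats::dist(xy))
      }
    }
  }
  (hull_area + perimeter * r + pi * r^2) * 1e-6
}

#' Membrane recruitment time t_c
#'
#' First time at which the membrane-bound clathrin count strictly exceeds
#' `fraction` (default 90 %) of its value in the reference frame (by
#' default the last frame). Statistics downstream are restricted to frames
#' after t_c, where recruitment has plateaued.
#'
#' @param counts membrane-bound clathrin count per frame.
#' @param times frame times (any unit; returned in the same unit).
#' @param fraction plateau fraction.
#' @param reference index of the reference frame (default: last).
#' @return the time of the first frame above threshold, or `NA` when the
#'   reference count is zero (t_c undefined).
#' @export
compute_tc <- function(counts, times, fraction = 0.9,
                       reference = length(counts)) {
  stopifnot(length(counts) == length(times), length(counts) > 0)
  ref <- counts[reference]
  if (ref == 0) return(NA_real_)
  idx <- which(counts > fraction * ref)
  if (length(idx) == 0) return(NA_real_)
  times[idx[1]]
}

#' Cluster-number pattern statistics
#'
#' A pattern is the set of frames sharing one counted-cluster number. The
#' pattern with the highest frame frequency is the most possible pattern
#' (ties resolved toward the smaller cluster number).
#'
#' @param cluster_numbers counted-cluster number per frame (frames after
#'   t_c).
#' @return list with `frequencies` (named numeric, sums to 1) and
#'   `most_possible_pattern` (integer).
#' @export
pattern_statistics <- function(cluster_numbers) {
  if (length(cluster_numbers) == 0) {
    stop("no frames supplied: need at least one frame after t_c")
  }
  tab <- table(cluster_numbers)
  freq <- as.numeric(tab) / length(cluster_numbers)
  names(freq) <- names(tab)
  vals <- as.integer(names(tab))
  best <- vals[which.max(freq)]  # which.max takes the first (smallest) tie
  list(frequencies = freq, most_possible_pattern = best)
}

#' Mean cluster size of a frame
#'
#' Total area of the counted clusters divided by their number. Counted
#' clusters are the large membrane-bound ones (more than `large_threshold`
#' clathrins).
#'
#' @inheritParams find_clusters
#' @param clusters optional precomputed [find_clusters()] table.
#' @return mean area in um^2, or `NA` if the frame has no counted cluster.
#' @export
mean_cluster_size <- function(frame = NULL, geometry = clathrin_geometry(),
                              large_threshold = 10, clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- find_clusters(frame, geometry, large_threshold)
  }
  counted <- clusters[clusters$is_large & clusters$is_membrane_bound, ]
  if (nrow(counted) == 0) return(NA_real_)
  sum(counted$area) / nrow(counted)
}

#' Dwelling times of the cluster-number series
#'
#' Lengths of the maximal runs over which the counted-cluster number stays
#' constant. Runs truncated by the start or end of the analysis window are
#' flagged censored (and excluded from mean dwell times by default
#' downstream).
#'
#' @param cluster_numbers counted-cluster number per frame.
#' @param times frame times (uniform spacing assumed; a run of k frames
#'   dwells k * spacing).
#' @param pattern optional: restrict to runs at this cluster number.
#' @return data.frame with `pattern`, `start_time`, `duration`, `censored`.
#' @export
dwelling_times <- function(cluster_numbers, times, pattern = NULL) {
  stopifnot(length(cluster_numbers) == length(times))
  if (length(cluster_numbers) == 0) {
    return(data.frame(pattern = integer(0), start_time = numeric(0),
                      duration = numeric(0), censored = logical(0)))
  }
  spacing <- if (length(times) > 1) times[2] - times[1] else NA_real_
  r <- rle(cluster_numbers)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(pattern = r$values,
                    start_time = times[starts],
                    duration = r$lengths * spacing,
                    censored = seq_along(r$values) %in%
                      c(1, length(r$values)))
  if (!is.null(pattern)) out <- out[out$pattern == pattern, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a trajectory into cluster-dynamics statistics
#'
#' Computes, per frame, the counted-cluster number, the membrane-bound
#' clathrin count and the mean cluster size; then t_c, the pattern
#' frequencies after t_c, the most possible pattern, and the mean cluster
#' size and mean dwelling time of that pattern (censored dwells excluded
#' from the mean).
#'
#' @param traj an `fcl_trajectory` from [run_simulation()].
#' @param large_threshold counted-cluster size threshold (exclusive).
#' @param tc_fraction plateau fraction defining t_c.
#' @return an object of class `fcl_summary`.
#' @export
analyze_trajectory <- function(traj, large_threshold = 10,
                               tc_fraction = 0.9) {
  geometry <- traj$config$geometry
  frames <- traj$frames
  times_min <- vapply(frames, function(f) f$time_us, numeric(1)) / 6e7
  per_frame <- lapply(frames, function(f) {
    cl <- find_clusters(f, geometry, large_threshold)
    counted <- cl[cl$is_large & cl$is_membrane_bound, , drop = FALSE]
    data.frame(
      n_counted_clusters = nrow(counted),
      membrane_bound = sum(cl$n_clathrin[cl$is_membrane_bound]),
      mean_cluster_size = mean_cluster_size(clusters = cl,
                                            large_threshold = large_threshold))
  })
  pf <- do.call(rbind, per_frame)
  pf$time_min <- times_min

  tc <- compute_tc(pf$membrane_bound, times_min, tc_fraction)
  post <- if (is.na(tc)) pf[0, ] else pf[pf$time_min >= tc, , drop = FALSE]
  if (nrow(post) > 0) {
    pat <- pattern_statistics(post$n_counted_clusters)
    dw <- dwelling_times(post$n_counted_clusters, post$time_min)
    dw_pat <- dw[dw$pattern == pat$most_possible_pattern & !dw$censored, ]
    size_pat <- post$mean_cluster_size[post$n_counted_clusters ==
                                         pat$most_possible_pattern]
    mean_size <- if (all(is.na(size_pat))) NA_real_ else
      mean(size_pat, na.rm = TRUE)
    mean_dwell <- if (nrow(dw_pat) == 0) NA_real_ else mean(dw_pat$duration)
  } else {
    pat <- list(frequencies = numeric(0), most_possible_pattern = NA_integer_)
    dw <- dwelling_times(integer(0), numeric(0))
    mean_size <- NA_real_
    mean_dwell <- NA_real_
  }
  structure(list(per_frame = pf, t_c = tc,
                 pattern_frequencies = pat$frequencies,
                 most_possible_pattern = pat$most_possible_pattern,
                 mean_cluster_size_most_possible = mean_size,
                 mean_dwelling_time_most_possible = mean_dwell,
                 dwelling = dw, large_threshold = large_threshold,
                 tc_fraction = tc_fraction,
                 frame_interval_min = traj$config$frame_interval / 6e7),
            class = "fcl_summary")
}

#' @export
print.fcl_summary <- function(x, ...) {
  cat("fclsim cluster-dynamics summary\n")
  cat("  frames:", nrow(x$per_frame), " (interval",
      signif(x$frame_interval_min, 3), "min)\n")
  cat("  t_c:", signif(x$t_c, 4), "min\n")
  cat("  most possible pattern:", x$most_possible_pattern,
      "counted cluster(s)\n")
  cat("  mean cluster size (pattern):",
      signif(x$mean_cluster_size_most_possible, 4), "um^2\n")
  cat("  mean dwelling time (pattern):",
      signif(x$mean_dwelling_time_most_possible, 4), "min\n")
  invisible(x)
}

#' Plot cluster and membrane-recruitment dynamics
#'
#' Two-panel base-graphics display: counted-cluster number and
#' membrane-bound clathrins against time (with t_c marked), and the
#' cluster-number frequency histogram after t_c.
#'
#' @param x an `fcl_summary`.
#' @param ... unused.
#' @export
plot.fcl_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pf <- x$per_frame
  graphics::plot(pf$time_min, pf$n_counted_clusters, type = "s",
                 col = "blue", xlab = "time (min)",
                 ylab = "counted clusters")
  graphics::par(new = TRUE)
  graphics::plot(pf$time_min, pf$membrane_bound, type = "l", col = "red",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "red")
  if (!is.na(x$t_c)) graphics::abline(v = x$t_c, lty = 2)
  if (length(x$pattern_frequencies) > 0) {
    graphics::barplot(x$pattern_frequencies, xlab = "cluster number",
                      ylab = "frequency")
  }
  invisible(x)
}
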