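# Per-window one-sided periodogram power at 0.5 Hz resolution (full 2 s
# window, rectangular taper): average power per frequency bin.
window_periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  p <- Mod(X)^2 / n^2                 # average power per bin
  half <- seq_len(n %/% 2 + 1L)
  p <- p[half]
  p[-1L] <- 2 * p[-1L]
  if (n %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  list(freq = (half - 1L) * fs / n, power = p)
}

band_power <- function(pg, lo, hi) sum(pg$power[pg$freq >= lo & pg$freq <= hi])

#' State-map features for EMG-informed cluster labeling
#'
#' Computes, per 2 s window, the four coordinates of the two cluster maps
#' used for EMG-informed labeling: map 1 plots EMG power (sum of the EMG
#' trace's average power per frequency bin over 30-60 Hz plus 60-250 Hz)
#' against the RMS of one selected reference region's trace; map 2 plots
#' the reference trace's band-power ratios (0.5-4.5 Hz)/(0.5-9 Hz) against
#' (0.5-20 Hz)/(0.5-55 Hz), band edges inclusive. Spectral quantities come
#' from a full-window periodogram (0.5 Hz resolution at 2 s, 1 kHz), fine
#' enough to represent the 0.5 Hz band edges.
#'
#' @param rec An `lfp_recording` with an EMG channel (use the supervised
#'   autoencoder classifier when no EMG was recorded).
#' @param reference_region Region whose trace supplies the LFP RMS and the
#'   spectral ratios (e.g. `"CxPrL"`).
#' @param window_s Window length in seconds (default 2).
#' @return Data frame of class `statemap_points` with columns
#'   `window_index`, `emg_power`, `lfp_rms`, `ratio_x`, `ratio_y`.
#' @export
statemap_features <- function(rec, reference_region, window_s = 2) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(rec$emg_channel)) {
    stop("recording has no EMG channel; EMG-informed labeling is not ",
         "possible -- use the supervised autoencoder classifier instead",
         call. = FALSE)
  }
  ridx <- which(rownames(rec$signals) == reference_region)
  if (!length(ridx)) stop("reference region ", reference_region,
                          " not in recording", call. = FALSE)
  fs <- rec$fs
  wlen <- as.integer(window_s * fs)
  n_win <- ncol(rec$signals) %/% wlen
  emg <- rec$signals[rec$emg_channel, ]
  ref <- rec$signals[ridx[1L], ]
  out <- data.frame(window_index = seq_len(n_win) - 1L,
                    emg_power = NA_real_, lfp_rms = NA_real_,
                    ratio_x = NA_real_, ratio_y = NA_real_)
  for (w in seq_len(n_win)) {
    sel <- (w - 1L) * wlen + seq_len(wlen)
    pg_emg <- window_periodogram(emg[sel], fs)
    out$emg_power[w] <- band_power(pg_emg, 30, 60) +
      band_power(pg_emg, 60 + 1e-9, 250)
    out$lfp_rms[w] <- sqrt(mean(ref[sel]^2))
    pg <- window_periodogram(ref[sel], fs)
    out$ratio_x[w] <- band_power(pg, 0.5, 4.5) / band_power(pg, 0.5, 9)
    out$ratio_y[w] <- band_power(pg, 0.5, 20) / band_power(pg, 0.5, 55)
  }
  out$window_s <- window_s
  class(out) <- c("statemap_points", "data.frame")
  out
}

# Even-odd point-in-polygon; points on an edge count as inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary test: point within the segment's bounding box and collinear
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    tol <- 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1)
    onseg <- abs(cross) <= tol &
      px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_edge <- on_edge | onseg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Construct a polygon set for state-map labeling
#'
#' @param segments List of per-segment entries; each entry is a list with
#'   `map1` (named list of polygons per state; each polygon a 2-column
#'   matrix of `(lfp_rms, emg_power)` vertices) and `map2` (list with at
#'   most an `NREM` polygon over `(ratio_x, ratio_y)`).
#' @param segment_windows Number of windows per segment (default 1800,
#'   i.e. 60 min of 2 s windows).
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(segments, segment_windows = 1800L) {
  for (seg in segments) {
    for (st in names(seg$map1)) {
      if (!st %in% sleep_states()) stop("unknown state in polygon set: ", st,
                                        call. = FALSE)
      if (!is.null(seg$map1[[st]]) && nrow(seg$map1[[st]]) < 3L) {
        stop("polygons need at least 3 vertices", call. = FALSE)
      }
    }
  }
  structure(list(segments = segments,
                 segment_windows = as.integer(segment_windows)),
            class = "polygon_set")
}

#' Automatic polygon initialization from state-map points
#'
#' Replaces interactive cluster annotation: per segment of
#' `segment_windows` windows, the map-1 points (log LFP RMS x log EMG
#' power) are clustered into three groups; the highest-EMG centroid is
#' assigned WAKE, and of the two low-EMG centroids the one with higher LFP
#' RMS is NREM and the other REM. Each state's polygon is the convex hull
#' of the cluster's central 90% of members (by distance to its centroid).
#' The map-2 NREM polygon is built the same way from the higher-ratio_y
#' group of a 2-way clustering of `(ratio_x, ratio_y)`. Deterministic given
#' the seed.
#'
#' @param points A `statemap_points` data frame.
#' @param segment_windows Windows per segment (default 1800 = 60 min).
#' @param core_quantile Fraction of members kept for the hull (default 0.9).
#' @param seed Integer seed for the clustering initialization.
#' @return A `polygon_set`; segments that cannot be separated into three
#'   clusters are marked `unlabelable` and get no polygons.
#' @export
auto_polygons <- function(points, segment_windows = 1800L,
                          core_quantile = 0.9, seed = 1L) {
  stopifnot(inherits(points, "statemap_points"))
  n <- nrow(points)
  seg_id <- (points$window_index %/% segment_windows) + 1L
  segments <- vector("list", max(seg_id))
  for (s in seq_len(max(seg_id))) {
    pts <- points[seg_id == s, ]
    if (nrow(pts) < 100L) {
      segments[[s]] <- list(unlabelable = TRUE,
                            reason = "fewer than 100 points in segment")
      next
    }
    X <- cbind(log(pts$lfp_rms), log(pts$emg_power))
    Xs <- scale(X)
    # iteratively shed tiny outlier clusters (isolated artifact windows)
    # before accepting a 3-way split
    use <- seq_len(nrow(Xs))
    km <- NULL
    set.seed(derive_seed(seed, paste0("map1-", s)))
    for (attempt in 1:3) {
      km <- tryCatch(stats::kmeans(Xs[use, , drop = FALSE], centers = 3L,
                                   nstart = 10L, iter.max = 100L),
                     error = function(e) NULL)
      if (is.null(km) || min(km$size) >= 10L) break
      use <- use[!km$cluster %in% which(km$size < 10L)]
      if (length(use) < 100L) { km <- NULL; break }
    }
    # genuine clusters explain most variance; an unstructured blob does not
    sep_ok <- !is.null(km) && km$betweenss / km$totss > 0.8 &&
      min(km$size) >= 10L
    if (!sep_ok) {
      segments[[s]] <- list(unlabelable = TRUE,
                            reason = "fewer than 3 separable clusters")
      next
    }
    cen <- km$centers
    wake_k <- unname(which.max(cen[, 2L]))     # highest EMG
    low <- setdiff(1:3, wake_k)
    nrem_k <- low[which.max(cen[low, 1L])]     # higher LFP RMS
    rem_k <- setdiff(low, nrem_k)
    assign_k <- c(WAKE = wake_k, NREM = nrem_k, REM = rem_k)
    map1 <- lapply(assign_k, function(kk) {
      mem <- use[km$cluster == kk]
      dcen <- sqrt(rowSums((Xs[mem, , drop = FALSE] -
                              matrix(cen[kk, ], length(mem), 2L,
                                     byrow = TRUE))^2))
      core <- mem[dcen <= stats::quantile(dcen, core_quantile, type = 1)]
      hull <- grDevices::chull(X[core, 1L], X[core, 2L])
      # vertices back on the raw axes
      cbind(lfp_rms = exp(X[core[hull], 1L]),
            emg_power = exp(X[core[hull], 2L]))
    })
    names(map1) <- names(assign_k)
    # map 2: NREM = higher ratio_y cluster of a 2-way split
    Y <- cbind(pts$ratio_x, pts$ratio_y)
    set.seed(derive_seed(seed, paste0("map2-", s)))
    km2 <- stats::kmeans(scale(Y), centers = 2L, nstart = 10L,
                         iter.max = 100L)
    nrem2 <- which.max(tapply(Y[, 2L], km2$cluster, mean))
    mem2 <- which(km2$cluster == nrem2)
    c2 <- colMeans(Y[mem2, , drop = FALSE])
    d2 <- sqrt(rowSums((Y[mem2, , drop = FALSE] -
                          matrix(c2, length(mem2), 2L, byrow = TRUE))^2))
    core2 <- mem2[d2 <= stats::quantile(d2, core_quantile, type = 1)]
    hull2 <- grDevices::chull(Y[core2, 1L], Y[core2, 2L])
    map2 <- list(NREM = cbind(ratio_x = Y[core2[hull2], 1L],
                              ratio_y = Y[core2[hull2], 2L]))
    segments[[s]] <- list(unlabelable = FALSE, map1 = map1, map2 = map2)
  }
  polygon_set(segments, segment_windows)
}

#' Assign state labels by polygon membership
#'
#' A window receives a state only if its map-1 point lies inside that
#' state's polygon; an NREM candidate must additionally fall inside the
#' segment's map-2 NREM polygon (the second map refines NREM only -- it is
#' not used to separate wake from REM). All other windows are UNKNOWN.
#' Membership in several same-map polygons is resolved by the priority
#' NREM > WAKE > REM.
#'
#' @param points A `statemap_points` data frame.
#' @param polygons A `polygon_set` covering the points' segments.
#' @param priority State priority for overlapping polygons.
#' @return A [hypnogram()].
#' @export
assign_by_polygons <- function(points, polygons,
                               priority = c("NREM", "WAKE", "REM")) {
  stopifnot(inherits(points, "statemap_points"),
            inherits(polygons, "polygon_set"))
  n <- nrow(points)
  labels <- rep(unknown_state(), n)
  seg_id <- (points$window_index %/% polygons$segment_windows) + 1L
  for (s in unique(seg_id)) {
    seg <- if (s <= length(polygons$segments)) polygons$segments[[s]] else NULL
    if (is.null(seg) || isTRUE(seg$unlabelable)) next
    idx <- which(seg_id == s)
    member <- sapply(priority, function(st) {
      poly <- seg$map1[[st]]
      if (is.null(poly)) return(rep(FALSE, length(idx)))
      point_in_polygon(points$lfp_rms[idx], points$emg_power[idx],
                       poly[, 1L], poly[, 2L])
    })
    member <- matrix(member, nrow = length(idx))
    pick <- apply(member, 1L, function(r) {
      h <- which(r)
      if (length(h)) priority[h[1L]] else unknown_state()
    })
    # map-2 refinement: NREM must also sit in the map-2 NREM polygon
    if (!is.null(seg$map2$NREM)) {
      isn <- pick == "NREM"
      if (any(isn)) {
        in2 <- point_in_polygon(points$ratio_x[idx[isn]],
                                points$ratio_y[idx[isn]],
                                seg$map2$NREM[, 1L], seg$map2$NREM[, 2L])
        pick[isn][!in2] <- unknown_state()
      }
    }
    labels[idx] <- pick
  }
  hypnogram(labels, window_s = points$window_s[1L])
}

#' Cohen's kappa between two label sequences
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, with expected
#' agreement `pe` from the marginal label frequencies. Windows where either
#' sequence is UNKNOWN are dropped pairwise.
#'
#' @param labels_a,labels_b Hypnograms or character label vectors of equal
#'   length.
#' @return The kappa statistic (scalar).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as_state_labels(labels_a)
  b <- as_state_labels(labels_b)
  if (length(a) != length(b)) stop("label sequences differ in length",
                                   call. = FALSE)
  keep <- a != unknown_state() & b != unknown_state()
  if (!any(keep)) stop("no overlapping labeled windows", call. = FALSE)
  a <- factor(a[keep], levels = sleep_states())
  b <- factor(b[keep], levels = sleep_states())
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Write / read a polygon set as JSON
#' @param polygons A `polygon_set`.
#' @param path JSON file path.
#' @return `path` (write) or a `polygon_set` (read).
#' @export
write_polygons <- function(polygons, path) {
  stopifnot(inherits(polygons, "polygon_set"))
  segs <- lapply(polygons$segments, function(seg) {
    if (isTRUE(seg$unlabelable)) return(list(unlabelable = TRUE,
                                             reason = seg$reason))
    list(unlabelable = FALSE,
         map1 = lapply(seg$map1, function(p) unname(apply(p, 1L, c,
                                                          simplify = FALSE))),
         map2 = lapply(seg$map2, function(p) unname(apply(p, 1L, c,
                                                          simplify = FALSE))))
  })
  jsonlite::write_json(list(segment_windows = polygons$segment_windows,
                            segments = segs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  segs <- lapply(obj$segments, function(seg) {
    if (isTRUE(seg$unlabelable)) return(list(unlabelable = TRUE))
    tomat <- function(p) do.call(rbind, lapply(p, unlist))
    list(unlabelable = FALSE,
         map1 = lapply(seg$map1, tomat),
         map2 = lapply(seg$map2, tomat))
  })
  polygon_set(segs, as.integer(obj$segment_windows))
}
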