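#' Construct a profile from (s, h) coordinates
#'
#' A profile is an ordered planar polyline from a mid-plane cross-section
#' of an endplate: `s` is the position along the in-plane horizontal axis
#' (mm, increasing posterior-to-anterior for sagittal profiles and
#' right-to-left for coronal ones) and `h` the superior coordinate (mm).
#' Stored as a tibble subclass so profiles pipe into the morphometry
#' functions and plot with [ggplot2::autoplot()].
#'
#' @param x a data frame with numeric columns `s` and `h` (at least 3
#'   rows, finite, `s` strictly increasing after sorting).
#' @param plane `"sagittal"` or `"coronal"`.
#' @return An `endplate_profile` tibble with attributes `plane` and
#'   `end_labels`.
#' @export
as_profile <- function(x, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  x <- as.data.frame(x)
  if (!all(c("s", "h") %in% names(x))) stopf("profile needs columns s and h")
  new_profile(x$s, x$h, plane, sort = TRUE)
}

new_profile <- function(s, h, plane, sort = FALSE) {
  if (sort) {
    o <- order(s)
    s <- s[o]; h <- h[o]
  }
  if (length(s) < 3) stopf("a profile needs at least 3 points",
                           class = "epmorph_degenerate_section")
  if (!all(is.finite(s)) || !all(is.finite(h))) {
    stopf("profile coordinates must be finite", class = "epmorph_input_error")
  }
  if (any(diff(s) <= 0)) {
    keep <- !duplicated(s)
    s <- s[keep]; h <- h[keep]
    if (length(s) < 3 || any(diff(s) <= 0)) {
      stopf("profile s-coordinates must be strictly increasing",
            class = "epmorph_input_error")
    }
  }
  labels <- if (plane == "sagittal") c("posterior", "anterior") else c("right", "left")
  structure(tibble(s = s, h = h),
            plane = plane, end_labels = labels,
            class = c("endplate_profile", class(tibble())))
}

profile_plane <- function(profile) attr(profile, "plane", exact = TRUE)

#' @export
print.endplate_profile <- function(x, ...) {
  lab <- attr(x, "end_labels")
  cat(sprintf("<endplate_profile> %s, %d points, s: %s -> %s\n",
              profile_plane(x), nrow(x), lab[1], lab[2]))
  NextMethod()
}

#' Extract a mid-plane cross-section profile from a mesh
#'
#' Intersects the endplate surface with the plane through the mesh
#' centroid orthogonal to the lateral axis (sagittal section) or to the
#' anterior-posterior axis (coronal section), chains the per-triangle
#' intersection segments into polylines (endpoints matched within
#' 1e-6 mm), and returns the polyline of greatest horizontal extent, with
#' ties broken by greater arc length. Points are expressed in the mesh's
#' anatomical frame, ordered posterior-to-anterior (sagittal) or
#' right-to-left (coronal).
#'
#' @param mesh a [triangle_mesh()] with an anatomical frame.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return An `endplate_profile` tibble.
#' @examples
#' m <- generate_surface(endplate_spec(depth_sagittal = 2, resolution = 32))
#' p <- extract_profile(m, "sagittal")
#' round(min(p$h), 2)
#' @export
extract_profile <- function(mesh, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  segs <- profile_sections(mesh, plane)
  if (!nrow(segs)) {
    stopf("the %s mid-plane does not intersect the mesh", plane,
          class = "epmorph_no_section")
  }
  chains <- chain_segments(segs)
  extent <- vapply(chains, function(p) diff(range(p[, 1])), numeric(1))
  arclen <- vapply(chains, polyline_length, numeric(1))
  best <- which(extent > max(extent) - 1e-9)
  best <- best[which.max(arclen[best])]
  pts <- chains[[best]]
  if (nrow(pts) < 3) {
    stopf("longest %s section has fewer than 3 points", plane,
          class = "epmorph_degenerate_section")
  }
  if (pts[1, 1] > pts[nrow(pts), 1]) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  if (any(diff(pts[, 1]) <= 0)) {
    # not monotone in s along the walk (possible on closed/folded sections):
    # fall back to ordering by s
    o <- order(pts[, 1])
    pts <- pts[o, , drop = FALSE]
  }
  new_profile(pts[, 1], pts[, 2], plane)
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Per-triangle plane intersection segments, projected to (s, h).
# Returns a tibble s1,h1,s2,h2 with exact duplicates removed.
profile_sections <- function(mesh, plane, tol_on = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  A <- anatomical_coords(mesh)   # columns lateral, ap, si
  cut_col <- if (plane == "sagittal") 1L else 2L
  s_col <- if (plane == "sagittal") 2L else 1L
  centroid <- colMeans(A)
  d <- A[, cut_col] - centroid[cut_col]
  f <- mesh$faces
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  on1 <- abs(d1) <= tol_on; on2 <- abs(d2) <= tol_on; on3 <- abs(d3) <= tol_on
  n_on <- on1 + on2 + on3
  P <- cbind(A[, s_col], A[, 3])   # (s, h) per vertex

  segs <- list()

  # bulk case: no vertex on the plane, triangle straddles it
  simple <- n_on == 0L & (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (any(simple)) {
    fi <- f[simple, , drop = FALSE]
    dd <- cbind(d1[simple], d2[simple], d3[simple])
    pts_s <- matrix(NA_real_, nrow(fi), 2)
    pts_h <- matrix(NA_real_, nrow(fi), 2)
    filled <- integer(nrow(fi))
    edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    for (ep in edge_pairs) {
      i <- ep[1]; j <- ep[2]
      cross <- dd[, i] * dd[, j] < 0
      if (!any(cross)) next
      t <- dd[cross, i] / (dd[cross, i] - dd[cross, j])
      vi <- fi[cross, i]; vj <- fi[cross, j]
      s <- (1 - t) * P[vi, 1] + t * P[vj, 1]
      h <- (1 - t) * P[vi, 2] + t * P[vj, 2]
      slot <- filled[cross] + 1L
      idx <- which(cross)
      pts_s[cbind(idx, slot)] <- s
      pts_h[cbind(idx, slot)] <- h
      filled[cross] <- slot
    }
    ok <- filled == 2L
    segs[[length(segs) + 1L]] <- tibble(s1 = pts_s[ok, 1], h1 = pts_h[ok, 1],
                                        s2 = pts_s[ok, 2], h2 = pts_h[ok, 2])
  }

  # rare cases: vertices on the plane
  special <- which(n_on > 0L)
  for (k in special) {
    vid <- f[k, ]
    dv <- c(d1[k], d2[k], d3[k])
    onv <- abs(dv) <= tol_on
    if (sum(onv) == 3L) {
      # coplanar triangle: contribute its two longest boundary edges
      e <- rbind(vid[c(1, 2)], vid[c(2, 3)], vid[c(3, 1)])
      lens <- sqrt(rowSums((P[e[, 1], , drop = FALSE] - P[e[, 2], , drop = FALSE])^2))
      for (ei in order(lens, decreasing = TRUE)[1:2]) {
        segs[[length(segs) + 1L]] <- tibble(
          s1 = P[e[ei, 1], 1], h1 = P[e[ei, 1], 2],
          s2 = P[e[ei, 2], 1], h2 = P[e[ei, 2], 2])
      }
    } else if (sum(onv) == 2L) {
      a <- vid[onv][1]; b <- vid[onv][2]
      segs[[length(segs) + 1L]] <- tibble(s1 = P[a, 1], h1 = P[a, 2],
                                          s2 = P[b, 1], h2 = P[b, 2])
    } else {
      # one vertex on the plane; a segment only if the other two straddle
      a <- vid[onv]
      rest <- vid[!onv]
      drest <- dv[!onv]
      if (prod(drest) < 0) {
        t <- drest[1] / (drest[1] - drest[2])
        s <- (1 - t) * P[rest[1], 1] + t * P[rest[2], 1]
        h <- (1 - t) * P[rest[1], 2] + t * P[rest[2], 2]
        segs[[length(segs) + 1L]] <- tibble(s1 = P[a, 1], h1 = P[a, 2], s2 = s, h2 = h)
      }
    }
  }

  if (!length(segs)) {
    return(tibble(s1 = numeric(), h1 = numeric(), s2 = numeric(), h2 = numeric()))
  }
  out <- dplyr::bind_rows(segs)
  # drop zero-length segments and exact duplicates (either orientation)
  len <- sqrt((out$s1 - out$s2)^2 + (out$h1 - out$h2)^2)
  out <- out[len > tol_on, , drop = FALSE]
  key_f <- paste(round(out$s1 * 1e8), round(out$h1 * 1e8),
                 round(out$s2 * 1e8), round(out$h2 * 1e8))
  key_r <- paste(round(out$s2 * 1e8), round(out$h2 * 1e8),
                 round(out$s1 * 1e8), round(out$h1 * 1e8))
  key <- ifelse(key_f < key_r, key_f, key_r)
  out[!duplicated(key), , drop = FALSE]
}

# Chain intersection segments into polylines by matching endpoints within
# `tol` mm. Returns a list of 2-column matrices (s, h), one per polyline.
chain_segments <- function(segs, tol = 1e-6) {
  m <- nrow(segs)
  if (!m) return(list())
  ends <- rbind(cbind(segs$s1, segs$h1), cbind(segs$s2, segs$h2))
  # cluster endpoints within tol (small m: linear scan against representatives)
  n_pts <- nrow(ends)
  cluster <- integer(n_pts)
  rep_s <- numeric(0); rep_h <- numeric(0)
  for (i in seq_len(n_pts)) {
    if (length(rep_s)) {
      hit <- which(abs(rep_s - ends[i, 1]) <= tol & abs(rep_h - ends[i, 2]) <= tol)
    } else hit <- integer(0)
    if (length(hit)) {
      cluster[i] <- hit[1]
    } else {
      rep_s <- c(rep_s, ends[i, 1]); rep_h <- c(rep_h, ends[i, 2])
      cluster[i] <- length(rep_s)
    }
  }
  a <- cluster[seq_len(m)]          # cluster id of each segment's first end
  b <- cluster[m + seq_len(m)]      # ... and second end
  n_nodes <- length(rep_s)
  adj <- vector("list", n_nodes)
  for (i in seq_len(m)) {
    adj[[a[i]]] <- c(adj[[a[i]]], i)
    adj[[b[i]]] <- c(adj[[b[i]]], i)
  }
  deg <- lengths(adj)
  used <- logical(m)
  chains <- list()
  walk <- function(start_node) {
    path <- start_node
    node <- start_node
    repeat {
      nxt_seg <- adj[[node]][!used[adj[[node]]]]
      if (!length(nxt_seg)) break
      sg <- nxt_seg[1]
      used[sg] <<- TRUE
      node <- if (a[sg] == node) b[sg] else a[sg]
      path <- c(path, node)
    }
    path
  }
  # open chains first (start at odd-degree nodes), then any remaining cycles
  for (start in order(deg != 1)) {
    if (deg[start] == 1 && any(!used[adj[[start]]])) {
      p <- walk(start)
      chains[[length(chains) + 1L]] <- cbind(rep_s[p], rep_h[p])
    }
  }
  for (i in seq_len(m)) {
    if (!used[i]) {
      p <- walk(a[i])
      chains[[length(chains) + 1L]] <- cbind(rep_s[p], rep_h[p])
    }
  }
  chains
}

#' Read / write a profile as 2-column CSV
#'
#' Plain `s,h` CSV so profiles can be inspected externally or toy
#' profiles fed to the morphometry functions without a mesh.
#'
#' @param profile an `endplate_profile`.
#' @param path CSV path.
#' @param plane plane label to attach on read.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns an `endplate_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(tibble(s = profile$s, h = profile$h), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_profile(df, plane)
}
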