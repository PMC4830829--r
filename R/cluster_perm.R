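# Group-level pattern discovery: point-wise one-sample t-tests on stacked
# per-subject coefficient maps, combined with cluster-based sign-flip
# permutation inference using a pooled max-cluster-mass null.

# Half-space neighbour offsets for a connectivity scheme (one of each +/-
# pair; the union operation is symmetric).
conn_offsets <- function(conn) {
  offsets <- switch(as.character(conn),
    "8"  = as.matrix(expand.grid(dx = -1:1, dy = -1:1)),
    "26" = as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)),
    "6"  = cbind(dx = c(-1, 1, 0, 0, 0, 0), dy = c(0, 0, -1, 1, 0, 0),
                 dz = c(0, 0, 0, 0, -1, 1)),
    stop("unsupported connectivity: ", conn))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  lex <- offsets %*% (3^(seq_len(ncol(offsets)) - 1L))
  offsets[lex > 0, , drop = FALSE]
}

# Connected components among active grid cells.
# coords: k x 2 (fi, ti) or k x 3 (i, j, k) integer matrix; dims matches.
# offsets: from conn_offsets(). Returns integer labels 1..ncl in
# deterministic scan order (cluster 1 contains the smallest linear index).
label_components <- function(coords, dims, offsets) {
  k <- nrow(coords)
  if (k == 0L) return(integer(0))
  nd <- ncol(coords)
  mult <- cumprod(c(1, dims[-nd]))
  key <- as.numeric(coords[, 1] - 1)
  for (d in seq_len(nd)[-1]) key <- key + (coords[, d] - 1) * mult[d]
  ord <- order(key)
  keys <- key[ord]

  parent <- seq_len(k)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    ok <- rep(TRUE, k)
    okey <- 0
    for (d in seq_len(nd)) {
      shifted_d <- coords[, d] + off[d]
      ok <- ok & shifted_d >= 1L & shifted_d <= dims[d]
      okey <- okey + off[d] * mult[d]
    }
    if (!any(ok)) next
    nkey <- key[ok] + okey
    pos <- findInterval(nkey, keys)
    hit <- pos >= 1L & keys[pmax(pos, 1L)] == nkey
    a <- which(ok)[hit]
    b <- ord[pos[hit]]
    for (m in seq_along(a)) {
      ra <- find_root(a[m]); rb <- find_root(b[m])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find_root, integer(1))
  # deterministic labels: clusters numbered by their smallest member's key
  match(roots, unique(roots[ord]))
}

# Max cluster mass among active cells split by (phase, sign); returns 0 when
# nothing is active. Used for the permutation null.
max_cluster_mass <- function(tvec, active, phase_post, coord_mat, dims,
                             offsets) {
  if (!any(active)) return(0)
  best <- 0
  pos_t <- tvec > 0
  for (ph in c(FALSE, TRUE)) {
    for (sg in c(TRUE, FALSE)) {
      sel <- which(active & phase_post == ph & pos_t == sg)
      if (length(sel) == 0L) next
      labs <- label_components(coord_mat[sel, , drop = FALSE], dims, offsets)
      mass <- rowsum(abs(tvec[sel]), labs)
      best <- max(best, max(mass))
    }
  }
  best
}

#' Cluster-based sign-flip permutation test on coefficient maps
#'
#' Performs a point-wise one-sample t-test of each feature's coefficient
#' against zero across subjects, thresholds at the two-tailed `point_alpha`,
#' and groups supra-threshold features into clusters by grid connectivity,
#' separately for positive and negative effects and separately per phase
#' (pre/post), so a pre-stimulus cluster never merges with a post-stimulus
#' one. Each cluster's mass (sum of |t|) is compared against a pooled null
#' distribution of the maximum cluster mass obtained by randomly flipping the
#' sign of entire subject maps, which preserves within-map correlation while
#' enforcing the symmetric null. Cluster p-values are
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param maps Subjects x features matrix (e.g. from
#'   [subject_coefficient_maps()]).
#' @param coords Per-feature coordinate data.frame (`fi`,`ti` or `i`,`j`,`k`).
#' @param phase Per-feature `"pre"`/`"post"` tags.
#' @param grid Grid descriptor with `type` (`"tf"` or `"voxel"`) and `dims`.
#' @param point_alpha Two-tailed cluster-forming threshold (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 1000; below 100 a
#'   warning is emitted).
#' @param seed Integer seed; results are exactly reproducible given the seed.
#' @param conn Grid connectivity: defaults to 8-neighbour on the 2-D
#'   time-frequency grid and 6-neighbour on the 3-D voxel grid.
#' @return Object of class `group_pattern_map`: `tmap`, `point_p`, `df`,
#'   `clusters` (list with `features`, `mass`, `sign`, `phase`, `p`),
#'   `null_max`, plus the inputs needed to extract patterns.
#' @export
cluster_permutation_test <- function(maps, coords, phase, grid,
                                     point_alpha = 0.05, n_perm = 1000L,
                                     seed = 1L, conn = NULL) {
  maps <- as.matrix(maps)
  S <- nrow(maps)
  nfeat <- ncol(maps)
  stopifnot(nfeat == nrow(coords), nfeat == length(phase))
  if (S < 3L) stop("need at least 3 subjects")
  if (n_perm < 100L) warning("n_perm < 100 gives coarse cluster p-values")
  if (is.null(conn)) conn <- if (grid$type == "tf") 8L else 6L
  coord_mat <- if (grid$type == "tf") {
    as.matrix(coords[, c("fi", "ti")])
  } else {
    as.matrix(coords[, c("i", "j", "k")])
  }
  dims <- grid$dims

  mu <- colMeans(maps)
  ss <- colSums(maps^2)
  varv <- (ss - S * mu^2) / (S - 1)
  excl <- varv <= 0                            # zero-variance features carry no evidence
  tmap <- numeric(nfeat)
  tmap[!excl] <- mu[!excl] / sqrt(varv[!excl] / S)
  df <- S - 1L
  point_p <- rep(1, nfeat)
  point_p[!excl] <- 2 * stats::pt(-abs(tmap[!excl]), df)
  tcrit <- stats::qt(1 - point_alpha / 2, df)
  active <- abs(tmap) > tcrit & !excl
  offsets <- conn_offsets(conn)
  phase_post <- phase == "post"

  clusters <- list()
  for (ph in c("pre", "post")) {
    for (sg in c(1, -1)) {
      sel <- which(active & phase == ph & sign(tmap) == sg)
      if (length(sel) == 0L) next
      labs <- label_components(coord_mat[sel, , drop = FALSE], dims, offsets)
      for (l in sort(unique(labs))) {
        feats <- sel[labs == l]
        clusters[[length(clusters) + 1L]] <- list(
          features = feats, mass = sum(abs(tmap[feats])),
          sign = sg, phase = ph)
      }
    }
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  chunk <- 100L
  done <- 0L
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    flips <- matrix(sample(c(-1, 1), nb * S, replace = TRUE), nb, S)
    mu_p <- (flips %*% maps) / S               # sum of squares is flip-invariant
    var_p <- sweep(-S * mu_p^2, 2L, ss, `+`) / (S - 1)
    t_p <- mu_p / sqrt(pmax(var_p, .Machine$double.eps) / S)
    if (any(excl)) t_p[, excl] <- 0
    for (b in seq_len(nb)) {
      tv <- t_p[b, ]
      null_max[done + b] <- max_cluster_mass(tv, abs(tv) > tcrit, phase_post,
                                             coord_mat, dims, offsets)
    }
    done <- done + nb
  }

  for (ci in seq_along(clusters)) {
    clusters[[ci]]$p <- (1 + sum(null_max >= clusters[[ci]]$mass)) / (n_perm + 1)
  }
  structure(
    list(tmap = tmap, point_p = point_p, df = df, clusters = clusters,
         null_max = null_max, n_perm = as.integer(n_perm), seed = seed,
         point_alpha = point_alpha, conn = conn, coords = coords,
         phase = phase, grid = grid, excluded_features = which(excl)),
    class = "group_pattern_map"
  )
}

#' @export
print.group_pattern_map <- function(x, ...) {
  cat(sprintf("<group_pattern_map> %d features, df=%d, %d cluster(s), n_perm=%d\n",
              length(x$tmap), x$df, length(x$clusters), x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  %-4s sign %+d  size %4d  mass %8.1f  p = %.4g\n",
                cl$phase, cl$sign, length(cl$features), cl$mass, cl$p))
  invisible(x)
}

#' Extract significant patterns from a group map
#'
#' Turns each cluster with permutation p below `cluster_alpha` into a named
#' `pattern` holding its feature coordinates, phase, modulation sign (sign of
#' the mean t inside the cluster) and cluster p-value. Names are
#' auto-generated from the phase and, on a time-frequency grid, the frequency
#' band of the cluster (`pre_alpha`, `post_gamma`, ...), unless supplied.
#'
#' @param map A `group_pattern_map`.
#' @param cluster_alpha Cluster-level significance threshold (default 0.05).
#' @param names Optional character vector of names, one per significant
#'   cluster in map order.
#' @return List of `pattern` objects (possibly empty).
#' @export
extract_patterns <- function(map, cluster_alpha = 0.05, names = NULL) {
  stopifnot(inherits(map, "group_pattern_map"))
  sig <- Filter(function(cl) cl$p < cluster_alpha, map$clusters)
  if (length(sig) == 0L) return(list())
  out <- vector("list", length(sig))
  auto <- character(length(sig))
  for (i in seq_along(sig)) {
    cl <- sig[[i]]
    feats <- cl$features
    auto[i] <- if (map$grid$type == "tf" && !is.null(map$coords$freq_hz)) {
      paste0(cl$phase, "_", band_label(map$coords$freq_hz[feats]))
    } else if (map$grid$type == "tf") {
      paste0(cl$phase, "_cluster")
    } else {
      paste0(cl$phase, "_blob")
    }
  }
  # disambiguate duplicated auto names deterministically
  dup <- stats::ave(seq_along(auto), auto, FUN = seq_along)
  auto <- ifelse(stats::ave(seq_along(auto), auto, FUN = length) > 1,
                 paste0(auto, dup), auto)
  if (!is.null(names)) {
    stopifnot(length(names) == length(sig))
    auto <- names
  }
  for (i in seq_along(sig)) {
    cl <- sig[[i]]
    mean_t <- mean(map$tmap[cl$features])
    out[[i]] <- structure(
      list(name = auto[i], phase = cl$phase, features = cl$features,
           coords = map$coords[cl$features, , drop = FALSE],
           sign = as.integer(sign(mean_t)), cluster_p = cl$p,
           mass = cl$mass),
      class = "pattern")
  }
  out
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("<pattern> %s (%s, sign %+d, %d features, cluster p = %.4g)\n",
              x$name, x$phase, x$sign, length(x$features), x$cluster_p))
  invisible(x)
}

#' Serialize a group map and patterns to JSON
#'
#' @param map A `group_pattern_map`.
#' @param patterns Optional list of `pattern`s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_group_map <- function(map, patterns = NULL, path) {
  obj <- list(
    tmap = map$tmap, point_p = map$point_p, df = map$df,
    n_perm = map$n_perm, seed = map$seed, point_alpha = map$point_alpha,
    conn = map$conn, grid = map$grid[c("type", "dims")],
    clusters = lapply(map$clusters, function(cl)
      cl[c("features", "mass", "sign", "phase", "p")]),
    patterns = lapply(patterns %||% list(), function(p)
      list(name = p$name, phase = p$phase, features = p$features,
           sign = p$sign, cluster_p = p$cluster_p))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
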