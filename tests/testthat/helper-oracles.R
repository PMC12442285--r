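# Independent brute-force oracles, written without reference to the
# package internals.

# full (both-direction) neighbour offsets for a 3D connectivity
oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  unname(g)
}

# plain breadth-first flood fill over a 3D binary array
flood_fill_components <- function(arr, connectivity) {
  dims <- dim(arr)
  offs <- oracle_offsets(connectivity)
  visited <- array(FALSE, dim = dims)
  comps <- list()
  fg <- which(arr != 0)
  for (start in fg) {
    if (visited[start]) next
    queue <- matrix(arrayInd(start, dims), ncol = 3)
    visited[start] <- TRUE
    members <- queue
    while (nrow(queue) > 0) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (arr[nb[1], nb[2], nb[3]] != 0 && !visited[nb[1], nb[2], nb[3]]) {
          visited[nb[1], nb[2], nb[3]] <- TRUE
          queue <- rbind(queue, nb)
          members <- rbind(members, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- members
  }
  canonicalize_components(comps)
}

# sort voxels within each component and components by their first voxel,
# so two component lists can be compared as sets
canonicalize_components <- function(comps) {
  comps <- lapply(comps, function(cm) {
    cm <- as.matrix(cm)
    dimnames(cm) <- NULL
    cm[order(cm[, 1], cm[, 2], cm[, 3]), , drop = FALSE]
  })
  if (length(comps) == 0) return(comps)
  firsts <- t(vapply(comps, function(cm) cm[1, ], numeric(3)))
  comps[order(firsts[, 1], firsts[, 2], firsts[, 3])]
}

# exhaustive pairwise maximum centroid separation, in cm
brute_dmax_cm <- function(centroids_mm) {
  n <- nrow(centroids_mm)
  if (n < 2) return(0)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((centroids_mm[i, ] - centroids_mm[j, ])^2))
      best <- max(best, d)
    }
  }
  best / 10
}

random_mask_array <- function(dims, p) {
  array(as.integer(runif(prod(dims)) < p), dim = dims)
}
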