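# Internal helpers shared across modules: seeds, masks, connectivity.

# Derive a reproducible 32-bit sub-seed from a master seed and stream tags.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  tags <- c(...)
  x <- as.double(master) %% 2147483629
  for (t in tags) {
    x <- (x * 48271 + as.double(t) * 9973 + 1) %% 2147483629
  }
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 26-connected binary dilation of a 3-D logical array.
dilate26 <- function(mask, steps = 1L) {
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  out <- mask
  for (s in seq_len(steps)) {
    cur <- out
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      out <- out | cur[xs, ys, zs]
    }
  }
  out
}

# 26-connected component of `candidates` (logical 3-D array) containing the
# voxel with linear index `start`. Returns sorted linear indices.
connected_component26 <- function(candidates, start) {
  d <- dim(candidates)
  stopifnot(length(d) == 3, isTRUE(candidates[start]))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  visited[start] <- TRUE
  frontier <- matrix(arrayInd(start, d), ncol = 3)
  comp <- start
  while (nrow(frontier) > 0) {
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
      sweep(frontier, 2, offs[i, ], "+")
    }))
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    if (nrow(nb) == 0) break
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
    lin <- unique(lin)
    lin <- lin[candidates[lin] & !visited[lin]]
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    comp <- c(comp, lin)
    frontier <- matrix(arrayInd(lin, d), ncol = 3)
  }
  sort(comp)
}

# Normalise a group label vector to the canonical "MHE"/"NMHE" factor.
normalize_group <- function(group) {
  g <- toupper(trimws(as.character(group)))
  bad <- !(g %in% c("MHE", "NMHE"))
  if (any(bad)) {
    stop("unknown group label(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  factor(g, levels = c("NMHE", "MHE"))
}
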