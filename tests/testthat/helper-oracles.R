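# Independent oracles used to cross-check the package implementations.

# Brute-force marker-controlled immersion flooding: a flat priority queue
# (level, then insertion sequence) scanned with which.min at every step.
# Same flooding semantics as the production bucket-queue implementation,
# realised with a naive data structure.
flood_oracle <- function(landscape, markers, connectivity = 8L) {
  lv <- landscape$levels
  nr <- nrow(lv); nc <- ncol(lv)
  labels <- matrix(0L, nr, nc)
  dam <- matrix(FALSE, nr, nc)
  queued <- matrix(FALSE, nr, nc)
  midx <- (markers$col - 1L) * nr + markers$row
  labels[midx] <- as.integer(markers$marker_id)

  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nbrs <- function(idx) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  q_idx <- integer(); q_level <- integer(); q_seq <- integer()
  q_done <- logical(); seq_no <- 0L
  push <- function(idx, level) {
    seq_no <<- seq_no + 1L
    q_idx <<- c(q_idx, idx); q_level <<- c(q_level, level)
    q_seq <<- c(q_seq, seq_no); q_done <<- c(q_done, FALSE)
    queued[idx] <<- TRUE
  }
  for (i in seq_along(midx)) {
    for (nb in nbrs(midx[i])) {
      if (labels[nb] == 0L && !queued[nb]) push(nb, lv[nb])
    }
  }
  repeat {
    open <- which(!q_done)
    if (length(open) == 0) break
    cand <- open[q_level[open] == min(q_level[open])]
    pick <- cand[which.min(q_seq[cand])]
    q_done[pick] <- TRUE
    idx <- q_idx[pick]
    level <- q_level[pick]
    if (labels[idx] != 0L || dam[idx]) next
    nbs <- nbrs(idx)
    labs <- unique(labels[nbs])
    labs <- labs[labs != 0L]
    if (length(labs) == 0L) next
    if (length(labs) >= 2L) {
      dam[idx] <- TRUE
    } else {
      labels[idx] <- labs
      for (nb in nbs) {
        if (labels[nb] == 0L && !dam[nb] && !queued[nb])
          push(nb, max(lv[nb], level))
      }
    }
  }
  list(labels = labels, dam = dam)
}

# Naive double-loop GLCM and texture features, literal formula
# transcriptions (no vectorisation shared with the implementation).
glcm_oracle <- function(patch, levels = 16L, distance = 1L,
                        angles = c(0, 45, 90, 135), symmetric = TRUE) {
  lo <- min(patch); hi <- max(patch)
  nr <- nrow(patch); nc <- ncol(patch)
  q <- matrix(0L, nr, nc)
  if (hi > lo) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      q[r, c] <- min(floor((patch[r, c] - lo) / (hi - lo) * levels),
                     levels - 1)
    }
  }
  off_of <- function(a) switch(as.character(a),
                               "0" = c(0, distance),
                               "45" = c(-distance, distance),
                               "90" = c(-distance, 0),
                               "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (a in angles) {
    off <- off_of(a)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        counts[q[r, c] + 1, q[r2, c2] + 1] <-
          counts[q[r, c] + 1, q[r2, c2] + 1] + 1
        if (symmetric) {
          counts[q[r2, c2] + 1, q[r, c] + 1] <-
            counts[q[r2, c2] + 1, q[r, c] + 1] + 1
        }
      }
    }
  }
  counts / sum(counts)
}

texture_oracle <- function(G) {
  k <- nrow(G)
  con <- 0; asm <- 0; hom <- 0; ent <- 0; sij <- 0
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    g <- G[i + 1, j + 1]
    con <- con + (i - j)^2 * g
    asm <- asm + g^2
    hom <- hom + g / (1 + abs(i - j))
    if (g > 0) ent <- ent - g * log2(g)
    sij <- sij + i * j * g
  }
  p_i <- rowSums(G); p_j <- colSums(G)
  u_i <- sum((0:(k - 1)) * p_i); u_j <- sum((0:(k - 1)) * p_j)
  s_i <- sqrt(sum(((0:(k - 1)) - u_i)^2 * p_i))
  s_j <- sqrt(sum(((0:(k - 1)) - u_j)^2 * p_j))
  cor <- if (s_i < 1e-12 || s_j < 1e-12) 0 else (sij - u_i * u_j) / (s_i * s_j)
  list(contrast = con, correlation = cor, energy = asm,
       homogeneity = hom, entropy = ent)
}

# Synthetic candidate feature table with the class structure of the CAD
# problem: malignant SUVmax above 2.5, benign below, and class-distinct
# texture statistics.
synthetic_feature_table <- function(n = 219L, n_malignant = 120L, seed = 1L,
                                    separable = TRUE) {
  set.seed(seed)
  lab <- c(rep("malignant", n_malignant), rep("benign", n - n_malignant))
  noise <- if (separable) 1 else 6
  data.frame(
    contrast = stats::rnorm(n, ifelse(lab == "malignant", 2.0, 1.1), 0.25 * noise),
    correlation = stats::rnorm(n, ifelse(lab == "malignant", 0.85, 0.55), 0.06 * noise),
    energy = stats::rnorm(n, ifelse(lab == "malignant", 0.08, 0.25), 0.03 * noise),
    homogeneity = stats::rnorm(n, 0.74, 0.05),
    entropy = stats::rnorm(n, ifelse(lab == "malignant", 3.1, 2.2), 0.2 * noise),
    suvmax = ifelse(lab == "malignant",
                    stats::runif(n, 2.5, 8), stats::runif(n, 0.5, 2.4)),
    label = lab)
}
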