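# Independent brute-force oracles: explicit per-pixel loops and elementary
# arithmetic only, sharing no code path with the package implementations.

oracle_dilate <- function(m, r, se = "disk") {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (dy in -r:r) {
      for (dx in -r:r) {
        if (se == "disk" && dy * dy + dx * dx > r * r) next
        ii <- i + dy; jj <- j + dx
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj]) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    out[i, j] <- hit
  }
  out
}

oracle_erode <- function(m, r, se = "disk") {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (dy in -r:r) {
      for (dx in -r:r) {
        if (se == "disk" && dy * dy + dx * dx > r * r) next
        ii <- i + dy; jj <- j + dx
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj]) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    out[i, j] <- ok
  }
  out
}

# same ring definition as the package (dilate r_out minus the union of all
# eroded interiors; contested pixels to the nearest cell, ties to the
# smaller label), but computed with the loop-based morphology above
oracle_donut <- function(grid, r_in, r_out, se = "disk") {
  nr <- nrow(grid); nc <- ncol(grid)
  labs <- sort(unique(grid[grid > 0]))
  out <- matrix(0L, nr, nc)
  if (!length(labs)) return(out)
  er_any <- matrix(FALSE, nr, nc)
  for (k in labs) er_any <- er_any | oracle_erode(grid == k, r_in, se)
  rings <- lapply(labs, function(k)
    oracle_dilate(grid == k, r_out, se) & !er_any)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    claimants <- labs[vapply(rings, function(rg) rg[i, j], NA)]
    if (length(claimants) == 1L) out[i, j] <- claimants
    if (length(claimants) > 1L) {
      dbest <- Inf; kbest <- claimants[1L]
      for (k in claimants) {
        pts <- which(grid == k, arr.ind = TRUE)
        d <- min((pts[, 1] - i)^2 + (pts[, 2] - j)^2)
        if (d < dbest || (d == dbest && k < kbest)) {
          dbest <- d; kbest <- k
        }
      }
      out[i, j] <- kbest
    }
  }
  out
}

oracle_overlap <- function(grid, marker) {
  labs <- sort(unique(grid[grid > 0]))
  data.frame(
    label = labs,
    area_px = vapply(labs, function(k) sum(grid == k), 0),
    overlap_px = vapply(labs, function(k) sum(grid == k & marker), 0))
}

# stack-based 8-connected flood fill
oracle_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!bin[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        ii <- p[1] + dy; jj <- p[2] + dx
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            bin[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

oracle_count_outside <- function(bin, center_um, radius_um, pixel_size_um,
                                 min_area_px) {
  lab <- oracle_components(bin)
  n <- 0L
  for (k in seq_len(max(lab, 0L))) {
    pts <- which(lab == k, arr.ind = TRUE)
    if (nrow(pts) < min_area_px) next
    x <- (mean(pts[, 2]) - 1) * pixel_size_um
    y <- (mean(pts[, 1]) - 1) * pixel_size_um
    if (sqrt((x - center_um[1])^2 + (y - center_um[2])^2) >= radius_um)
      n <- n + 1L
  }
  n
}

# exact two-sided Wilcoxon rank-sum p by enumeration (tie-free data)
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  allv <- c(x, y)
  r <- rank(allv)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# permutation p for the unpaired pooled-variance t statistic
oracle_perm_t_p <- function(x, y, n_perm = 4000, seed = 1) {
  withr::with_seed(seed, {
    allv <- c(x, y); nx <- length(x)
    tstat <- function(ix) {
      a <- allv[ix]; b <- allv[-ix]
      sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                   (length(a) + length(b) - 2))
      (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
    }
    t_obs <- tstat(seq_len(nx))
    ts <- replicate(n_perm,
                    tstat(sample(length(allv), nx)))
    mean(abs(ts) >= abs(t_obs) - 1e-12)
  })
}

# Monte-Carlo power of the two-sided paired t-test
oracle_mc_paired_power <- function(n, d, alpha = 0.05, n_sim = 4000,
                                   seed = 99) {
  withr::with_seed(seed, {
    mean(replicate(n_sim, {
      diffs <- rnorm(n, d, 1)
      t.test(diffs)$p.value < alpha
    }))
  })
}

# random label grid: a few rectangular-ish cells dropped on a small grid
random_label_grid <- function(nr, nc, n_cells = 3, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(0L, nr, nc)
    for (k in seq_len(n_cells)) {
      h <- sample(2:4, 1); w <- sample(2:4, 1)
      i <- sample(seq_len(max(1, nr - h)), 1)
      j <- sample(seq_len(max(1, nc - w)), 1)
      patch <- g[i:(i + h - 1), j:(j + w - 1)]
      patch[patch == 0L] <- k
      g[i:(i + h - 1), j:(j + w - 1)] <- patch
    }
    g
  })
}
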