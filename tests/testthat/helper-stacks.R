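# Fixture builders: small digitized phantoms constructed in code, plus an
# independent pure-R component-labeling oracle for cross-checking the
# compiled path.

# Digitize one or more balls/ellipsoids into a stack. `centers` is a matrix
# with one row (row_mm, col_mm, slice_mm) per body; `semi` a matrix of
# semi-axes (row, col, slice) in mm.
make_ellipsoid_stack <- function(centers, semi, dims = c(40, 60, 30),
                                 spacing = c(2, 2, 2), sequence = "AX_T2",
                                 orientation = "axial") {
  centers <- rbind(centers); semi <- rbind(semi)
  rows <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cols <- (seq_len(dims[2]) - 0.5) * spacing[2]
  slcs <- (seq_len(dims[3]) - 0.5) * spacing[3]
  mask <- array(0L, dims)
  for (b in seq_len(nrow(centers))) {
    for (k in seq_along(slcs)) {
      dz2 <- ((slcs[k] - centers[b, 3]) / semi[b, 3])^2
      if (dz2 > 1) next
      dr <- (rows - centers[b, 1]) / semi[b, 1]
      dc <- (cols - centers[b, 2]) / semi[b, 2]
      sl <- outer(dr^2, dc^2, "+") + dz2 <= 1
      mask[, , k] <- mask[, , k] | sl
    }
  }
  slice_stack(mask, positions_mm = slcs, pixel_spacing_mm = spacing[1:2],
              nominal_spacing_mm = spacing[3], orientation = orientation,
              sequence = sequence)
}

# Independent 26-connectivity component labeling: plain R BFS, used only as
# an oracle on tiny masks.
oracle_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %/% (d[1] * d[2])
      rem <- (v - 1) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        w <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (mask[w] > 0 && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Small generator config used across tests: fewer, coarser voxels than the
# package default so unit tests stay fast; geometry logic is identical.
test_config <- function(...) {
  synthetic_config(...)
}
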