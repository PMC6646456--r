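# Small shift-based binary morphology on logical matrices/arrays.
# Out-of-bounds neighbours count as background for dilation and as foreground
# for erosion, so dilation never invents labels outside the volume and
# closing remains extensive (X is always contained in closing(X)) at the
# border. Structuring elements are the smallest standard ones: the in-plane
# 3x3 cross and the 3-D 6-neighbourhood.

shift2 <- function(m, dx, dy, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)) - dx
  ys <- seq_len(ncol(m)) - dy
  okx <- xs >= 1 & xs <= nrow(m)
  oky <- ys >= 1 & ys <= ncol(m)
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

neigh2 <- function(connectivity) {
  if (connectivity == 4) cbind(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  else if (connectivity == 8)
    cbind(dx = rep(-1:1, 3), dy = rep(-1:1, each = 3))[-5, , drop = FALSE]
  else va_stop("validation", "connectivity must be 4 or 8")
}

dilate2 <- function(m, connectivity = 4) {
  out <- m
  nb <- neigh2(connectivity)
  for (i in seq_len(nrow(nb))) out <- out | shift2(m, nb[i, 1], nb[i, 2])
  out
}

erode2 <- function(m, connectivity = 4) {
  out <- m
  nb <- neigh2(connectivity)
  for (i in seq_len(nrow(nb)))
    out <- out & shift2(m, nb[i, 1], nb[i, 2], fill = TRUE)
  out
}

shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  out <- array(fill, dim(a))
  d <- dim(a)
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy; zs <- seq_len(d[3]) - dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- a[xs[okx], ys[oky], zs[okz]]
  out
}

NB6 <- cbind(dx = c(-1, 1, 0, 0, 0, 0),
             dy = c(0, 0, -1, 1, 0, 0),
             dz = c(0, 0, 0, 0, -1, 1))

dilate3 <- function(a) {
  out <- a
  for (i in seq_len(nrow(NB6))) out <- out | shift3(a, NB6[i, 1], NB6[i, 2],
                                                    NB6[i, 3])
  out
}

erode3 <- function(a) {
  out <- a
  for (i in seq_len(nrow(NB6)))
    out <- out & shift3(a, NB6[i, 1], NB6[i, 2], NB6[i, 3], fill = TRUE)
  out
}

# In-slice connected component of `seed` (1-based c(row, col)) within the
# candidate mask, grown to a fixed point.
connected_component2 <- function(candidate, seed, connectivity = 4) {
  comp <- matrix(FALSE, nrow(candidate), ncol(candidate))
  if (!candidate[seed[1], seed[2]]) return(comp)
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- dilate2(comp, connectivity) & candidate
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}
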