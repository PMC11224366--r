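## Independent brute-force oracles. These deliberately avoid the code
## paths they check: erosion by per-pixel neighbourhood scans, overlap
## by direct voxel counting, Spearman by full permutation enumeration
## with stats::cor.

## 2D binary erosion: pixel survives iff every offset neighbour is TRUE
## (out-of-bounds counts as FALSE). O(n * |offsets|) scan.
brute_erode2d <- function(m, offsets) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    if (!m[x, y]) next
    keep <- TRUE
    for (r in seq_len(nrow(offsets))) {
      xx <- x + offsets[r, 1]; yy <- y + offsets[r, 2]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || !m[xx, yy]) {
        keep <- FALSE; break
      }
    }
    out[x, y] <- keep
  }
  out
}

brute_overlap <- function(a, b) {
  ni <- sum(a & b); na <- sum(a); nb <- sum(b)
  c(dice = 2 * ni / (na + nb), jaccard = ni / (na + nb - ni))
}

## All permutations of 1..n by recursive insertion (independent of
## e1071, which the implementation uses).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- all_perms(length(y))
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

## Pixels whose unit cell could straddle a circle of radius r (centre
## cx, cy, in mm): conservative discretization error bound for CSA.
straddle_count <- function(cx, cy, r, spacing, dims) {
  halfdiag <- sqrt(sum((spacing[1:2] / 2)^2))
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  dist <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  sum(abs(dist - r) <= halfdiag)
}
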