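## Rigid 3D transforms and intensity-based registration.
##
## A rigid_transform maps physical points of a *reference* (fixed) frame
## into the *moving* frame: q = R (p - c) + c + t, with R = Rz Ry Rx
## built from angles in degrees and t, c in mm. This is the pull-back
## convention used for resampling: the value of the resampled moving
## image at fixed grid point p is moving(q). Voxel (i, j, k) sits at
## physical ((i-1) sx, (j-1) sy, (k-1) sz).

#' Construct a rigid transform
#'
#' @param angles_deg rotations about the x, y, z image axes in degrees;
#'   applied as `Rz %*% Ry %*% Rx`.
#' @param translation_mm length-3 translation in mm.
#' @param center_mm rotation centre in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(angles_deg) == 3, length(translation_mm) == 3,
            length(center_mm) == 3)
  structure(list(angles_deg = as.numeric(angles_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

angles_from_matrix <- function(R) {
  ## inverse of rotation_matrix for |pitch| < 90 degrees
  b <- asin(pmin(1, pmax(-1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c) * 180 / pi
}

#' Apply a rigid transform to physical points
#'
#' @param tf a [rigid_transform].
#' @param pts n x 3 matrix of points in mm (reference frame).
#' @return n x 3 matrix in the moving frame.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  R <- rotation_matrix(tf$angles_deg)
  sweep(t(R %*% (t(pts) - tf$center_mm)), 2,
        -(tf$center_mm + tf$translation_mm))
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first:
#' `(t2 o t1)(p) = t2(t1(p))`. The composition/inverse is returned with
#' centre 0 and equivalent angles/translation.
#'
#' @param t2,t1,tf [rigid_transform]s.
#' @return a [rigid_transform].
#' @export
compose_transforms <- function(t2, t1) {
  R1 <- rotation_matrix(t1$angles_deg); R2 <- rotation_matrix(t2$angles_deg)
  M <- R2 %*% R1
  ## offset: q = M p + o
  o1 <- -R1 %*% t1$center_mm + t1$center_mm + t1$translation_mm
  o <- R2 %*% o1 - R2 %*% t2$center_mm + t2$center_mm + t2$translation_mm
  rigid_transform(angles_from_matrix(M), as.numeric(o), c(0, 0, 0))
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  R <- rotation_matrix(tf$angles_deg)
  rigid_transform(angles_from_matrix(t(R)),
                  as.numeric(-t(R) %*% tf$translation_mm),
                  tf$center_mm)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (%.3f, %.3f, %.3f) deg, translation (%.3f, %.3f, %.3f) mm, centre (%.1f, %.1f, %.1f) mm\n",
              x$angles_deg[1], x$angles_deg[2], x$angles_deg[3],
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3],
              x$center_mm[1], x$center_mm[2], x$center_mm[3]))
  invisible(x)
}

#' Read/write a rigid transform as JSON
#' @param tf a [rigid_transform]; `path` a JSON file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::fromJSON(path)
  rigid_transform(x$angles_deg, x$translation_mm, x$center_mm)
}

## ---- sampling ---------------------------------------------------------

## Trilinear interpolation of vol (3D array with spacing/origin in mm)
## at physical points (n x 3). Points outside the grid return NA.
sample_trilinear <- function(vol, spacing, pts, origin = c(0, 0, 0)) {
  d <- dim(vol)
  ci <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1
  i0 <- floor(ci)
  fr <- ci - i0
  ## tolerate points exactly on the upper grid boundary
  for (ax in 1:3) {
    hi <- abs(ci[, ax] - d[ax]) < 1e-9
    i0[hi, ax] <- d[ax] - 1; fr[hi, ax] <- 1
  }
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fr <- fr[ok, , drop = FALSE]
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) - 1 + d[2] * ((i0[, 3] + dz) - 1))
  v <- vol[idx(0, 0, 0)] * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
       vol[idx(1, 0, 0)] * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
       vol[idx(0, 1, 0)] * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
       vol[idx(1, 1, 0)] * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
       vol[idx(0, 0, 1)] * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
       vol[idx(1, 0, 1)] * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
       vol[idx(0, 1, 1)] * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
       vol[idx(1, 1, 1)] * fr[, 1] * fr[, 2] * fr[, 3]
  out[ok] <- v
  out
}

## Nearest-neighbour sampling (for label maps).
sample_nearest <- function(vol, spacing, pts, origin = c(0, 0, 0)) {
  d <- dim(vol)
  ci <- round(sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1)
  ok <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
        ci[, 2] >= 1 & ci[, 2] <= d[2] &
        ci[, 3] >= 1 & ci[, 3] <= d[3]
  out <- rep(0L, nrow(pts))
  if (any(ok)) {
    cio <- ci[ok, , drop = FALSE]
    out[ok] <- vol[cio[, 1] + d[1] * (cio[, 2] - 1 + d[2] * (cio[, 3] - 1))]
  }
  out
}

## Block-mean pooling by integer factor f (crops to a multiple of f).
## The pooled grid's origin shifts by (f-1)/2 voxel per axis.
pool_volume <- function(vol, spacing, f, origin = c(0, 0, 0)) {
  if (f == 1L) return(list(data = vol, spacing = spacing, origin = origin))
  d <- dim(vol)
  m <- pmax(1L, d %/% f)
  vol <- vol[seq_len(m[1] * f), seq_len(m[2] * f), seq_len(m[3] * f), drop = FALSE]
  pool1 <- function(a, f) {
    d <- dim(a)
    m1 <- d[1] %/% f
    x <- array(a, c(f, m1, d[2], d[3]))
    array(colMeans(x), c(m1, d[2], d[3]))
  }
  vol <- pool1(vol, f)
  vol <- aperm(pool1(aperm(vol, c(2, 1, 3)), f), c(2, 1, 3))
  vol <- aperm(pool1(aperm(vol, c(3, 2, 1)), f), c(3, 2, 1))
  list(data = vol, spacing = spacing * f, origin = origin + (f - 1) / 2 * spacing)
}

grid_points <- function(d, spacing, origin = c(0, 0, 0)) {
  cbind(rep((seq_len(d[1]) - 1) * spacing[1] + origin[1], times = d[2] * d[3]),
        rep(rep((seq_len(d[2]) - 1) * spacing[2] + origin[2], each = d[1]), times = d[3]),
        rep((seq_len(d[3]) - 1) * spacing[3] + origin[3], each = d[1] * d[2]))
}

## ---- similarity metrics ----------------------------------------------

metric_mse <- function(fv, mv) {
  ok <- !is.na(mv)
  if (mean(ok) < 0.25) return(.Machine$double.xmax / 1e6)
  mean((fv[ok] - mv[ok])^2)
}

## Negative mutual information from a 32x32 joint histogram.
metric_nmi <- function(fv, mv, nbins = 32L, frange, mrange) {
  ok <- !is.na(mv)
  if (mean(ok) < 0.25) return(.Machine$double.xmax / 1e6)
  fv <- fv[ok]; mv <- mv[ok]
  bi <- function(v, r) pmax(1L, pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)))
  jf <- bi(fv, frange); jm <- bi(mv, mrange)
  cnt <- tabulate(jf + nbins * (jm - 1L), nbins = nbins * nbins)
  p <- cnt / sum(cnt)
  pj <- matrix(p, nbins, nbins)
  pf <- rowSums(pj); pm <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (pf[row(pj)[nz]] * pm[col(pj)[nz]])))
  -mi
}

## Separable Gaussian smoothing, sigma in voxels per axis. Matched
## pre-smoothing of both volumes before metric evaluation suppresses
## the interpolation-blur asymmetry that otherwise attracts
## variance-based similarity metrics to grid-aligned poses.
gauss_smooth_vox <- function(a, sigma_vox = 0.6) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  one_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, d[1], d[2] * d[3])
    mp <- rbind(m[rep(1, r), , drop = FALSE], m,
                m[rep(d[1], r), , drop = FALSE])
    f <- stats::filter(mp, kern, sides = 2)
    aperm(array(f[(r + 1):(r + d[1]), ], d), order(perm))
  }
  one_axis(one_axis(one_axis(a, 1L), 2L), 3L)
}

## Correlation ratio 1 - eta^2(M | bin(F)): fraction of moving-sample
## variance not explained by the fixed-intensity bin. Smooth and robust
## when the two modalities are functionally related.
metric_cr <- function(fv_bin, mv, nbins) {
  ok <- !is.na(mv)
  if (mean(ok) < 0.25) return(.Machine$double.xmax / 1e6)
  m <- mv[ok]; b <- fv_bin[ok]
  n <- length(m)
  agg <- rowsum(cbind(m, m^2, 1), b)
  within <- sum(agg[, 2] - agg[, 1]^2 / agg[, 3])
  total <- sum(m^2) - sum(m)^2 / n
  if (total <= 0) return(.Machine$double.xmax / 1e6)
  within / total
}

com_of <- function(vol, spacing) {
  d <- dim(vol)
  w <- pmax(vol, 0)
  tot <- sum(w)
  if (tot == 0) return((d - 1) * spacing / 2)
  ax <- function(k) {
    m <- apply(w, k, sum)
    sum(m * (seq_len(d[k]) - 1) * spacing[k]) / tot
  }
  c(ax(1), ax(2), ax(3))
}

#' Rigid registration of a moving volume to a fixed volume
#'
#' 6-DOF intensity-based registration: centre-of-mass initialization,
#' matched Gaussian pre-smoothing of both volumes, block-mean
#' multi-resolution pyramid, and Nelder--Mead optimization of the
#' chosen similarity metric: `"cr"` (correlation ratio, default; smooth
#' and well-suited when the two modalities are functionally related, as
#' Dixon water and STIR are), `"mi"` (negative mutual information) or
#' `"mse"` (same-modality only). Sampling is a deterministic stride
#' over foreground voxels of the fixed image, so results are
#' reproducible without RNG.
#'
#' @param moving,fixed [volumetric_image]s with overlapping anatomy.
#' @param metric `"cr"`, `"mi"` or `"mse"`.
#' @param levels integer pooling factors, coarse to fine.
#' @param max_points sampling budget per level.
#' @param maxit Nelder--Mead iteration cap per level.
#' @param presmooth_sigma_vox Gaussian pre-smoothing SD in voxels,
#'   applied identically to both volumes; damps the attraction of
#'   intensity metrics toward grid-aligned (interpolation-blur-free)
#'   poses.
#' @param init optional initial [rigid_transform] (overrides the
#'   centre-of-mass initialization).
#' @param global_init evaluate a coarse grid of angles and axial
#'   offsets at the coarsest level before local optimization; the
#'   similarity surface has shallow interpolation ripples that can trap
#'   a purely local search started at zero rotation.
#' @return a [rigid_transform] mapping fixed-frame points into the
#'   moving frame (ready for [resample_labels] / [resample_volume]);
#'   `attr(, "metric_trace")` records per-level convergence.
#' @export
register_rigid <- function(moving, fixed, metric = c("cr", "mi", "mse"),
                           levels = c(4L, 2L, 1L), max_points = 20000L,
                           maxit = 400L, init = NULL, global_init = TRUE,
                           presmooth_sigma_vox = 0.6) {
  metric <- match.arg(metric)
  if (is.null(init)) {
    com_f <- com_of(fixed$data, fixed$spacing)
    com_m <- com_of(moving$data, moving$spacing)
    init <- rigid_transform(c(0, 0, 0), com_m - com_f, com_f)
  }
  center <- init$center_mm
  par <- c(init$angles_deg, init$translation_mm)
  fixed_s <- gauss_smooth_vox(fixed$data, presmooth_sigma_vox)
  moving_s <- gauss_smooth_vox(moving$data, presmooth_sigma_vox)
  mrange <- range(moving_s)
  trace <- list()
  for (lev in levels) {
    pf <- pool_volume(fixed_s, fixed$spacing, lev)
    pm <- pool_volume(moving_s, moving$spacing, lev)
    thr <- 0.05 * max(pf$data)
    d <- dim(pf$data)
    fg <- which(pf$data > thr)
    if (length(fg) < 50L) fg <- seq_along(pf$data)
    ## half the budget from the strongest axial-gradient voxels: axial
    ## structure (muscle ends, lesion margins) is sparse relative to
    ## in-plane edges, and uniform sampling leaves the axial component
    ## of the transform poorly constrained
    gz <- array(0, d)
    if (d[3] > 2)
      gz[, , 2:(d[3] - 1)] <- pf$data[, , 3:d[3], drop = FALSE] -
        pf$data[, , 1:(d[3] - 2), drop = FALSE]
    n_half <- min(length(fg), ceiling(max_points / 2))
    edge <- fg[order(abs(gz[fg]), decreasing = TRUE)[seq_len(n_half)]]
    stride <- max(1L, ceiling(length(fg) / (max_points - n_half + 1L)))
    fg <- union(edge, fg[seq(1L, length(fg), by = stride)])
    k <- (fg - 1L) %/% (d[1] * d[2])
    j <- ((fg - 1L) %/% d[1]) %% d[2]
    i <- (fg - 1L) %% d[1]
    pts <- cbind(i * pf$spacing[1] + pf$origin[1],
                 j * pf$spacing[2] + pf$origin[2],
                 k * pf$spacing[3] + pf$origin[3])
    fv <- pf$data[fg]
    frange <- range(fv)
    nb <- 32L
    fv_bin <- pmax(1L, pmin(nb, 1L + floor((fv - frange[1]) /
                                             diff(frange) * nb)))
    cost <- function(p) {
      tf <- rigid_transform(p[1:3], p[4:6], center)
      mv <- sample_trilinear(pm$data, pm$spacing, transform_points(tf, pts),
                             pm$origin)
      switch(metric,
             mse = metric_mse(fv, mv),
             mi = metric_nmi(fv, mv, frange = frange, mrange = mrange),
             cr = metric_cr(fv_bin, mv, nb))
    }
    if (global_init && lev == levels[1]) {
      grid <- expand.grid(rx = c(-3, 0, 3), ry = c(-3, 0, 3),
                          rz = c(-6, -3, 0, 3, 6), dz = c(-5, 0, 5))
      vals <- apply(grid, 1, function(g)
        cost(c(par[1] + g[1], par[2] + g[2], par[3] + g[3],
               par[4], par[5], par[6] + g[4])))
      best <- grid[which.min(vals), ]
      par <- c(par[1] + best$rx, par[2] + best$ry, par[3] + best$rz,
               par[4], par[5], par[6] + best$dz)
      mq_log(sprintf("registration global init: angles (%g, %g, %g), dz %g",
                     par[1], par[2], par[3], best$dz))
    }
    ## parscale widens the initial simplex (degrees/mm are ~unit scale,
    ## but starting angles of 0 would otherwise get 0.1-unit steps);
    ## restarts at shrinking scales guard against premature collapse
    opt <- optim(par, cost, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = rep(4, 6)))
    for (ps in c(1, 0.25)) {
      opt2 <- optim(opt$par, cost, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10,
                                   parscale = rep(ps, 6)))
      if (opt2$value < opt$value) opt <- opt2
    }
    par <- opt$par
    trace[[length(trace) + 1L]] <- data.frame(level = lev, value = opt$value,
                                              evaluations = opt$counts[1])
    mq_log(sprintf("registration level %d: metric %.6g after %d evals",
                   lev, opt$value, opt$counts[1]))
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "metric_trace") <- do.call(rbind, trace)
  out
}

#' Resample a label map through a rigid transform
#'
#' Resamples integer labels onto the reference grid; points mapping
#' outside the moving field of view become background. The resampled
#' code set is always a subset of the original. `method = "nearest"` is
#' plain nearest-neighbour sampling at voxel centres; `method = "vote"`
#' samples a sub-voxel grid per reference voxel and assigns the
#' majority code, which suppresses the half-voxel aliasing of muscle
#' boundaries (notably the first/last occupied slice) that centre
#' sampling exhibits.
#'
#' @param labelmap a [muscle_labelmap] in the moving (Dixon) frame.
#' @param transform [rigid_transform] mapping reference-frame points
#'   into the moving frame (as returned by [register_rigid]).
#' @param reference [volumetric_image] defining the output grid.
#' @param method `"nearest"` or `"vote"`.
#' @param supersample per-axis sub-voxel sampling factor for the vote.
#' @return a `muscle_labelmap` on the reference grid.
#' @export
resample_labels <- function(labelmap, transform, reference,
                            method = c("nearest", "vote"),
                            supersample = 3L) {
  method <- match.arg(method)
  d <- dim(reference$data)
  pts <- grid_points(d, reference$spacing)
  if (method == "nearest") {
    lab <- sample_nearest(labelmap$labels, labelmap$spacing,
                          transform_points(transform, pts))
  } else {
    offs <- supersample_offsets(rep(as.integer(supersample), 3L),
                                reference$spacing)
    codes <- sort(unique(as.vector(labelmap$labels)))
    tally <- matrix(0L, nrow(pts), length(codes))
    for (o in seq_len(nrow(offs))) {
      lo <- sample_nearest(labelmap$labels, labelmap$spacing,
                           transform_points(transform,
                                            sweep(pts, 2, -offs[o, ])))
      tally <- tally + outer(lo, codes, "==")
    }
    lab <- codes[max.col(tally, ties.method = "first")]
  }
  muscle_labelmap(array(as.integer(lab), d), labelmap$dictionary,
                  reference$spacing,
                  superior_direction = reference$superior_direction)
}

#' Resample a signal volume through a rigid transform
#'
#' Trilinear interpolation onto the reference grid; out-of-field voxels
#' are filled with `fill` (default 0).
#'
#' @inheritParams resample_labels
#' @param volume moving-frame [volumetric_image].
#' @param fill out-of-field value.
#' @return a `volumetric_image` on the reference grid.
#' @export
resample_volume <- function(volume, transform, reference, fill = 0) {
  d <- dim(reference$data)
  pts <- transform_points(transform, grid_points(d, reference$spacing))
  v <- sample_trilinear(volume$data, volume$spacing, pts)
  v[is.na(v)] <- fill
  volumetric_image(array(v, d), reference$spacing,
                   superior_direction = reference$superior_direction,
                   kind = volume$kind)
}
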