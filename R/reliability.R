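## Agreement and repeatability statistics.

#' Overlap between two segmentations of one muscle
#'
#' Jaccard is intersection over union, Dice is 2|A∩B| / (|A| + |B|);
#' the two satisfy dice = 2 j / (1 + j). Overlap studies in this field
#' sometimes print the IoU form under the name "Dice", so both are
#' always reported.
#'
#' @param map_a,map_b [muscle_labelmap]s on the same grid.
#' @param code muscle code present in both dictionaries.
#' @return one-row data.frame: `code`, `dice`, `jaccard`, voxel counts.
#' @export
overlap <- function(map_a, map_b, code) {
  if (!identical(dim(map_a$labels), dim(map_b$labels)))
    mq_stop("label maps are not on the same grid", "mq_alignment_error")
  a <- code_mask(map_a, code)
  b <- code_mask(map_b, code)
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L)
    mq_stop(sprintf("code %d empty in both maps: overlap undefined", code),
            "mq_undefined_overlap_error")
  ni <- sum(a & b)
  data.frame(code = as.integer(code),
             dice = 2 * ni / (na + nb),
             jaccard = ni / (na + nb - ni),
             n_a = na, n_b = nb, n_intersection = ni)
}

#' Absolute volume error of a repeat pair (%)
#'
#' The absolute difference divided by the mean of the two observations,
#' in percent: `100 |a - b| / ((a + b) / 2)`.
#'
#' @param a,b paired positive volumes (vectorized).
#' @return percent error(s).
#' @export
abs_volume_error <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    mq_stop("volumes must be finite and positive", "mq_domain_error")
  100 * abs(a - b) / ((a + b) / 2)
}

#' Absolute fat-fraction difference (percentage points)
#'
#' @param a,b paired FF values in [0, 100] (vectorized).
#' @return `|a - b|` in percentage points.
#' @export
abs_ff_difference <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) ||
      any(a < 0 | a > 100) || any(b < 0 | b > 100))
    mq_stop("fat fractions must lie in [0, 100]", "mq_domain_error")
  abs(a - b)
}

#' Bland--Altman agreement analysis
#'
#' Differences (b - a) against means ((a + b)/2). Fixed bias is tested
#' with a one-sample t on the differences (df = n - 1); proportional
#' bias with the least-squares slope of difference on mean (df = n - 2).
#' Both tests are always reported. Limits of agreement are
#' bias +- 1.96 SD.
#'
#' @param a,b paired measurements, length n >= 3.
#' @param one_sided if `TRUE`, halve the two-sided p values.
#' @return object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa` (length 2), `fixed_t`, `fixed_df`, `fixed_p`, `slope`,
#'   `intercept`, `slope_t`, `slope_df`, `slope_p`, `degenerate`.
#' @export
bland_altman <- function(a, b, one_sided = FALSE) {
  if (length(a) != length(b) || length(a) < 3L)
    mq_stop("need >= 3 pairs of equal length", "mq_parameter_error")
  d <- b - a
  m <- (a + b) / 2
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  out <- list(n = n, bias = bias, sd_diff = s,
              loa = bias + c(-1.96, 1.96) * s,
              degenerate = s == 0)
  if (out$degenerate) {
    out[c("fixed_t", "fixed_p", "slope_t", "slope_p")] <- NA_real_
    out$fixed_df <- n - 1L; out$slope_df <- n - 2L
    out$slope <- 0; out$intercept <- bias
  } else {
    tt <- t.test(d)
    out$fixed_t <- unname(tt$statistic)
    out$fixed_df <- n - 1L
    out$fixed_p <- if (one_sided) tt$p.value / 2 else tt$p.value
    fit <- lm(d ~ m)
    ## exactly collinear differences (constructed fixtures) trigger the
    ## "essentially perfect fit" warning; the slope itself is still valid
    sm <- suppressWarnings(summary(fit))$coefficients
    out$intercept <- unname(sm[1, 1])
    if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sd(m) == 0) {
      out$slope <- 0; out$slope_t <- NA_real_; out$slope_p <- NA_real_
    } else {
      out$slope <- unname(sm[2, 1])
      out$slope_t <- unname(sm[2, 3])
      p2 <- unname(sm[2, 4])
      out$slope_p <- if (one_sided) p2 / 2 else p2
    }
    out$slope_df <- n - 2L
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4g (LoA %.4g..%.4g) fixed t=%.3g (df=%d, p=%.3g) slope=%.4g (t=%.3g, df=%d, p=%.3g)\n",
              x$n, x$bias, x$loa[1], x$loa[2],
              ifelse(is.na(x$fixed_t), NaN, x$fixed_t), x$fixed_df,
              ifelse(is.na(x$fixed_p), NaN, x$fixed_p),
              x$slope, ifelse(is.na(x$slope_t), NaN, x$slope_t),
              x$slope_df, ifelse(is.na(x$slope_p), NaN, x$slope_p)))
  invisible(x)
}

#' Bland--Altman plot
#' @param x a [bland_altman] result; `a`, `b` the original pairs.
#' @param ... passed to `plot`.
#' @export
plot.bland_altman <- function(x, a = NULL, b = NULL, ...) {
  if (is.null(a) || is.null(b))
    mq_stop("supply the original pairs a and b for plotting", "mq_parameter_error")
  graphics::plot((a + b) / 2, b - a, xlab = "mean of pair",
                 ylab = "difference (b - a)", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "firebrick")
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p
#'
#' Rho uses average ranks for ties. For n <= `exact_max` (default 9) the
#' p value is an exact two-sided permutation probability obtained by
#' enumerating all n! orderings of one margin (ties handled naturally by
#' average ranks); for larger n the usual t approximation with
#' df = n - 2 is used.
#'
#' @param x,y equal-length vectors, n >= 3; ordinal or continuous.
#' @param exact_max largest n for exact enumeration.
#' @return list: `rho`, `p`, `n`, `method`; `rho` is `NA` with
#'   `method = "undefined"` when either input is constant.
#' @export
spearman_cor <- function(x, y, exact_max = 9L) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    mq_stop("need equal-length inputs with n >= 3", "mq_parameter_error")
  if (sd(x) == 0 || sd(y) == 0) {
    mq_warn("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- e1071::permutations(n)
    ## rho for every permutation of ry against fixed rx, vectorized
    rp <- matrix(ry[perms], nrow(perms), n)
    mx <- mean(rx); sx <- sqrt(sum((rx - mx)^2))
    my <- mean(ry); sy <- sqrt(sum((ry - my)^2))
    rhos <- (rp %*% (rx - mx)) / (sx * sy)  # centred y has same spread per row
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Map volumetric fat fraction to the ordinal clinical fat rating (1-6)
#'
#' Monotone step function anchored at the published 30% and 60%
#' boundaries (rating 4 spans 30-60% of muscle volume, 5-6 above 60%).
#' The sub-30% boundaries between ratings 1/2/3 and the 5/6 boundary
#' have no published percentage anchors; the defaults (5, 15, 85) are
#' package choices and configurable.
#'
#' @param ff_pct fat fraction(s) in percent.
#' @param cuts boundaries between ratings 1|2, 2|3, 3|4, 4|5, 5|6.
#' @return integer rating(s) 1-6.
#' @export
fat_rating_from_ff <- function(ff_pct, cuts = c(5, 15, 30, 60, 85)) {
  if (any(ff_pct < 0 | ff_pct > 100, na.rm = TRUE))
    mq_stop("fat fraction out of [0, 100]", "mq_domain_error")
  ## rating 4 spans [30, 60] inclusive per the published scale wording
  ## ("30-60% of muscle volume"; 5 is "> 60%"), hence the mixed openness
  as.integer(1L + (ff_pct > cuts[1]) + (ff_pct > cuts[2]) +
               (ff_pct >= cuts[3]) + (ff_pct > cuts[4]) + (ff_pct > cuts[5]))
}

#' Map STIR content (%) to the modified ordinal STIR grade (0-4)
#'
#' 0: no STIR+ content; 2: < 30% of the muscle volume; 3: 30-60%;
#' 4: > 60%. Grade 1 (mild diffuse elevation without discrete lesions)
#' is categorical, not a content band: it is assigned only when
#' `mild_diffuse` is `TRUE` and the content is otherwise at grade 0.
#'
#' @param stir_pct STIR content(s) in percent.
#' @param mild_diffuse logical flag(s) for diffuse mild elevation.
#' @return integer grade(s) 0-4.
#' @export
stir_grade_from_pct <- function(stir_pct, mild_diffuse = FALSE) {
  if (any(stir_pct < 0 | stir_pct > 100, na.rm = TRUE))
    mq_stop("STIR content out of [0, 100]", "mq_domain_error")
  g <- ifelse(stir_pct <= 0, 0L,
       ifelse(stir_pct < 30, 2L,
       ifelse(stir_pct <= 60, 3L, 4L)))
  ifelse(g == 0L & mild_diffuse, 1L, g)
}

#' Reliability report across repeated runs
#'
#' Given two per-muscle metric tables from repeated observations (scan
#' and rescan, two observers, the same observer twice, or raw AI output
#' against vetted labels), computes per-muscle absolute volume error and
#' absolute FF difference, optional Dice/Jaccard overlap when label
#' maps are supplied, and pooled Bland--Altman bias tests for volume
#' and FF. The difference orientation is fixed as run b minus run a.
#'
#' @param run_a,run_b [composition_table] outputs sharing muscle codes.
#' @param design study design label, one of `"scan_rescan"`,
#'   `"inter_observer"`, `"intra_observer"`, `"ai_vs_vetted"`.
#' @param labels_a,labels_b optional [muscle_labelmap]s for overlap.
#' @return object of class `reliability_report`: `per_muscle`
#'   data.frame (ordered by code), `volume_ba` and `ff_ba`
#'   [bland_altman] results, `design`, `sign_convention`.
#' @export
reliability_report <- function(run_a, run_b,
                               design = c("scan_rescan", "inter_observer",
                                          "intra_observer", "ai_vs_vetted"),
                               labels_a = NULL, labels_b = NULL) {
  design <- match.arg(design)
  shared <- sort(intersect(run_a$code[run_a$present & run_a$tp > 0],
                           run_b$code[run_b$present & run_b$tp > 0]))
  if (length(shared) < 2L)
    mq_stop("fewer than 2 shared muscles between runs", "mq_insufficient_data_error")
  ia <- match(shared, run_a$code); ib <- match(shared, run_b$code)
  per <- data.frame(code = shared,
                    name = run_a$name[ia],
                    side = run_a$side[ia],
                    volume_a = run_a$boundary_volume_mm3[ia],
                    volume_b = run_b$boundary_volume_mm3[ib],
                    ff_a = run_a$fat_fraction_pct[ia],
                    ff_b = run_b$fat_fraction_pct[ib],
                    stringsAsFactors = FALSE)
  per$abs_volume_error_pct <- abs_volume_error(per$volume_a, per$volume_b)
  per$abs_ff_difference_pp <- abs_ff_difference(per$ff_a, per$ff_b)
  if (!is.null(labels_a) && !is.null(labels_b)) {
    ov <- do.call(rbind, lapply(shared, function(code)
      overlap(labels_a, labels_b, code)))
    per$dice <- ov$dice[match(per$code, ov$code)]
    per$jaccard <- ov$jaccard[match(per$code, ov$code)]
  }
  structure(list(per_muscle = per,
                 volume_ba = if (nrow(per) >= 3)
                   bland_altman(per$volume_a, per$volume_b) else NULL,
                 ff_ba = if (nrow(per) >= 3)
                   bland_altman(per$ff_a, per$ff_b) else NULL,
                 design = design,
                 sign_convention = "second minus first (b - a)"),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> design=%s, %d muscles; median |dV|=%.3g%%, median |dFF|=%.3g pp\n",
              x$design, nrow(x$per_muscle),
              stats::median(x$per_muscle$abs_volume_error_pct),
              stats::median(x$per_muscle$abs_ff_difference_pp)))
  if (!is.null(x$volume_ba)) print(x$volume_ba)
  if (!is.null(x$ff_ba)) print(x$ff_ba)
  invisible(x)
}
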