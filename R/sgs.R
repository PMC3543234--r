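#' Equal-count distance classes
#'
#' Builds distance-class upper edges for spatial autocorrelation: equal-count
#' quantile bins over the pairwise distances up to `max_distance`, after
#' which the first edge is widened (if needed) until at least `nn_fraction`
#' of nearest-neighbor pairs fall inside class 1, so the first class
#' captures the local-neighborhood kinship `F_A`.
#'
#' @param distances individuals x individuals distance matrix in meters.
#' @param n_classes number of classes; defaults to
#'   `min(10, floor(n_pairs / min_pairs))`.
#' @param min_pairs minimum pair count per class (default 100).
#' @param nn_fraction fraction of nearest-neighbor pairs the first class
#'   must contain (default 0.9).
#' @param max_distance pairs beyond this distance are ignored (default
#'   10,000 m).
#' @return Numeric vector of strictly increasing class upper edges.
#' @export
make_distance_classes <- function(distances, n_classes = NULL, min_pairs = 100,
                                  nn_fraction = 0.9, max_distance = 10000) {
  d <- as.matrix(distances)
  pr <- d[upper.tri(d)]
  pr <- pr[pr > 0 & pr <= max_distance]
  if (length(unique(pr)) < 2)
    stop("degenerate geometry: all pairs equidistant, single class only")
  if (is.null(n_classes)) n_classes <- min(10L, floor(length(pr) / min_pairs))
  if (n_classes < 2 || length(pr) < 2 * min_pairs)
    stop("too few pairs for 2 classes of ", min_pairs, " pairs")
  edges <- unname(stats::quantile(pr, probs = seq_len(n_classes) / n_classes,
                                  type = 1))
  # nearest-neighbor rule: >= nn_fraction of NN pairs inside class 1
  dd <- d
  diag(dd) <- Inf
  dd[dd == 0] <- Inf
  nn <- apply(dd, 1, min)
  nn <- nn[is.finite(nn)]
  e1 <- sort(nn)[ceiling(nn_fraction * length(nn))]
  edges[1] <- max(edges[1], e1)
  edges <- unique(pmax(edges, edges[1]))
  if (length(edges) < 2)
    stop("degenerate geometry: nearest-neighbor rule leaves a single class")
  edges
}

slope_r2 <- function(xv, yv) {
  vx <- sum((xv - mean(xv))^2)
  b <- sum((xv - mean(xv)) * (yv - mean(yv))) / vx
  ss_res <- sum((yv - mean(yv) - b * (xv - mean(xv)))^2)
  ss_tot <- sum((yv - mean(yv))^2)
  c(b = b, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Kinship-distance regression and the Sp statistic
#'
#' Regresses pairwise kinship \eqn{F_{ij}} on the natural log of pairwise
#' geographic distance over all retained pairs (distance in (0,
#' `max_distance`]), the standard description of within-population spatial
#' genetic structure.  Reports the slope `b_ld`, its delete-one-locus
#' jackknife SE, a one-sided permutation p-value (spatial locations shuffled
#' among individuals; the lower tail, since restricted dispersal predicts a
#' kinship decline), the per-class average curve, the first-class mean
#' kinship `F_A`, and `Sp = -b_ld / (1 - F_A)`.
#'
#' @param kinship a `kinship_matrix` (from [loiselle_kinship()] or
#'   [organelle_kinship_analogue()]) or a plain symmetric matrix of pairwise
#'   coefficients (then no jackknife SE is available).
#' @param distances individuals x individuals geographic distances in meters.
#' @param classes class upper edges; computed by [make_distance_classes()]
#'   when `NULL`.
#' @param n_perm permutations for the slope test (default 10,000).
#' @param seed optional RNG seed.
#' @param max_distance pair-distance cutoff in meters (default 10,000).
#' @param min_pairs,nn_fraction passed to [make_distance_classes()].
#' @return An object of class `sgs_result` with `class_edges`,
#'   `class_mean_kinship`, `class_n_pairs`, `class_mean_distance`, `b_ld`,
#'   `R2_ld`, `SE_b`, `p_perm`, `F_A`, `Sp`, `n_perm`, `max_distance`, and
#'   `n_zero_dropped` (co-located pairs excluded from the regression).
#' @export
kinship_distance_regression <- function(kinship, distances, classes = NULL,
                                        n_perm = 10000, seed = NULL,
                                        max_distance = 10000, min_pairs = 100,
                                        nn_fraction = 0.9) {
  Fm <- if (inherits(kinship, "kinship_matrix")) kinship$F else as.matrix(kinship)
  d <- as.matrix(distances)
  stopifnot(identical(dim(Fm), dim(d)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(classes))
    classes <- make_distance_classes(d, min_pairs = min_pairs,
                                     nn_fraction = nn_fraction,
                                     max_distance = max_distance)
  ut <- upper.tri(d)
  dv <- d[ut]; fv <- Fm[ut]
  n_zero <- sum(dv == 0 & !is.na(fv))
  keep <- dv > 0 & dv <= max_distance & !is.na(fv)
  if (sum(keep) < 3) stop("too few pairs for a kinship-distance regression")
  cls <- findInterval(dv[keep], c(0, classes), left.open = TRUE)
  cls[cls > length(classes)] <- length(classes)
  if (length(unique(cls)) < 3)
    stop("fewer than 3 distance classes contain pairs")
  xv <- log(dv[keep]); yv <- fv[keep]
  ob <- slope_r2(xv, yv)
  class_stats <- vapply(seq_along(classes), function(k) {
    ix <- cls == k
    c(mean_kinship = if (any(ix)) mean(yv[ix]) else NA_real_,
      n_pairs = sum(ix),
      mean_distance = if (any(ix)) mean(dv[keep][ix]) else NA_real_)
  }, numeric(3))
  F_A <- class_stats["mean_kinship", 1]
  # delete-one-locus jackknife on the slope
  SE_b <- NA_real_
  if (inherits(kinship, "kinship_matrix") && length(kinship$den) > 1) {
    L <- length(kinship$den)
    bj <- numeric(L)
    for (l in seq_len(L)) {
      Fl <- kinship_from_parts(kinship$num[, , -l, drop = FALSE],
                               kinship$den[-l],
                               kinship$typed[, -l, drop = FALSE])
      yl <- Fl[ut][keep]
      ok <- !is.na(yl)
      bj[l] <- slope_r2(xv[ok], yl[ok])[["b"]]
    }
    SE_b <- jackknife_se(bj)
  }
  # permute locations among individuals, one-sided lower tail
  p_perm <- NA_real_
  if (n_perm > 0) {
    n <- nrow(d)
    le <- 0L
    for (b in seq_len(n_perm)) {
      prm <- sample.int(n)
      dp <- d[prm, prm][ut]
      kp <- dp > 0 & dp <= max_distance & !is.na(fv)
      bp <- slope_r2(log(dp[kp]), fv[kp])[["b"]]
      if (bp <= ob[["b"]] + 1e-15) le <- le + 1L
    }
    p_perm <- (1 + le) / (n_perm + 1)
  }
  structure(list(class_edges = classes,
                 class_mean_kinship = unname(class_stats["mean_kinship", ]),
                 class_n_pairs = unname(class_stats["n_pairs", ]),
                 class_mean_distance = unname(class_stats["mean_distance", ]),
                 b_ld = ob[["b"]], R2_ld = ob[["r2"]], SE_b = SE_b,
                 p_perm = p_perm, F_A = F_A,
                 Sp = sp_statistic(ob[["b"]], F_A),
                 n_perm = n_perm, max_distance = max_distance,
                 n_zero_dropped = n_zero),
            class = "sgs_result")
}

#' @export
print.sgs_result <- function(x, ...) {
  cat("Spatial genetic structure (kinship vs ln distance)\n")
  cat(sprintf("  b_ld = %.4f (R2 = %.4f, jackknife SE = %s, perm p = %s)\n",
              x$b_ld, x$R2_ld,
              if (is.na(x$SE_b)) "NA" else sprintf("%.4f", x$SE_b),
              if (is.na(x$p_perm)) "NA" else format.pval(x$p_perm)))
  cat(sprintf("  F_A (first class, <= %.0f m) = %.3f;  Sp = %.3f\n",
              x$class_edges[1], x$F_A, x$Sp))
  if (x$n_zero_dropped > 0)
    cat("  note:", x$n_zero_dropped, "co-located pairs (distance 0) excluded\n")
  invisible(x)
}

#' Sp statistic
#'
#' Dispersal-limitation index comparable across studies:
#' \eqn{Sp = -b_{ld} / (1 - F_A)}, where \eqn{b_{ld}} is the slope of the
#' kinship vs ln(distance) regression and \eqn{F_A} the mean kinship among
#' first-distance-class (near-neighbor) pairs.
#'
#' @param b_ld regression slope per ln(meters).
#' @param f_a mean first-class kinship, must be < 1.
#' @return The Sp statistic (0 when `b_ld` is 0).
#' @export
sp_statistic <- function(b_ld, f_a) {
  if (any(f_a >= 1)) stop("F_A must be < 1")
  -b_ld / (1 - f_a)
}
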