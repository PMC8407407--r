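# Mock-community benchmarking and community ecology statistics.

#' Observed/expected recovery ratio for a mock community
#'
#' Per replicate, the ratio `100 * observed / expected` (both in percent
#' relative abundance), where 100 means perfect recovery; summarised as
#' mean +/- SD across replicates.
#'
#' @param observed Numeric vector (or matrix replicates x species) of
#'   observed relative abundances in percent.
#' @param expected Expected relative abundances in percent (> 0), recycled
#'   across replicates.
#' @return For a vector: numeric ratios. For a matrix: list with `ratios`
#'   (replicates x species), `mean`, `sd` per species.
#' @export
#' @examples
#' observed_expected_ratio(0.2575, 6.25)  # 4.12
observed_expected_ratio <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected abundances must be > 0")
  if (is.matrix(observed)) {
    ratios <- sweep(observed, 2, expected, "/") * 100
    list(ratios = ratios, mean = colMeans(ratios),
         sd = apply(ratios, 2, stats::sd))
  } else {
    100 * observed / expected
  }
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both all-zero.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(1, 1, 0), c(0, 1, 1))  # 0.5
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis distance matrix of an abundance table
#'
#' @param table An `abundance_table` or matrix (samples as rows).
#' @return A `dist` object.
#' @export
bray_curtis_matrix <- function(table) {
  vegan::vegdist(as.matrix(table), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical double-centred eigendecomposition of a distance matrix. When
#' negative eigenvalues arise (non-Euclidean distances such as Bray-Curtis),
#' the additive (Cailliez) correction is applied to the off-diagonal
#' distances and the constant recorded.
#'
#' @param d A `dist` object or symmetric matrix with zero diagonal.
#' @param k Number of axes (default all positive-eigenvalue axes).
#' @return List with `points` (coordinates), `eig` (eigenvalues) and
#'   `correction` (additive constant, 0 if none needed).
#' @export
pcoa <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0))
      stop("distance matrix must be symmetric with zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  kk <- k %||% max(1L, n - 1L)
  if (all(d == 0)) {
    pts <- matrix(0, n, kk,
                  dimnames = list(attr(d, "Labels"), paste0("Axis", 1:kk)))
    return(list(points = pts, eig = rep(0, n), correction = 0))
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = kk, eig = TRUE))
  correction <- 0
  if (any(fit$eig < -sqrt(.Machine$double.eps) * max(abs(fit$eig)))) {
    fit <- suppressWarnings(stats::cmdscale(d, k = kk, eig = TRUE, add = TRUE))
    correction <- fit$ac
  }
  pts <- fit$points
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig, correction = correction)
}

#' Beta dispersion of groups in a distance matrix
#'
#' Multivariate homogeneity of group dispersions: per-sample distance to the
#' group's spatial median in principal-coordinate space (the conventional
#' default; `center = "centroid"` is available), group dispersion = mean of
#' those distances, and, for exactly two groups, a two-sided Mann-Whitney U
#' test on the per-sample distances.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   every group in a two-group comparison must have at least 2 members.
#' @param center `"median"` (default) or `"centroid"`.
#' @return List of class `dispersion_result`: `distances` (per sample),
#'   `dispersions` (mean per group), `U`, `p_value` (two-group case only).
#' @export
beta_dispersion <- function(d, groups, center = c("median", "centroid")) {
  center <- match.arg(center)
  if (is.matrix(d)) d <- stats::as.dist(d)
  groups <- factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("one group label per sample required")
  sizes <- table(groups)
  bd <- vegan::betadisper(d, groups, type = center)
  distances <- bd$distances
  dispersions <- tapply(distances, groups, mean)
  U <- NA_real_; p <- NA_real_
  if (nlevels(groups) == 2) {
    if (any(sizes < 2))
      stop("singleton group in a two-group comparison: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    mw <- mann_whitney_u(distances[groups == levels(groups)[1]],
                         distances[groups == levels(groups)[2]])
    U <- mw$U; p <- mw$p_value
  }
  structure(list(distances = distances, dispersions = dispersions,
                 groups = groups, U = U, p_value = p, center = center),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("<dispersion_result> center =", x$center, "\n")
  print(round(x$dispersions, 4))
  if (!is.na(x$U))
    cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.4g\n", x$U, x$p_value))
  invisible(x)
}

# Exact permutation distribution of the first-sample rank sum for scaled
# integer ranks (handles ties); returns two-sided p for the observed sum.
exact_ranksum_p <- function(ranks2, n, obs2) {
  N <- length(ranks2)
  maxs <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n)])
  # ways[c + 1, s + 1] = number of c-subsets with scaled rank sum s
  ways <- matrix(0, nrow = n + 1, ncol = maxs + 1)
  ways[1, 1] <- 1
  for (r in ranks2) {
    for (cc in min(n, N):1) {      # descending so each item used once
      if (r + 1 <= maxs + 1) {
        src <- ways[cc, 1:(maxs + 1 - r)]
        ways[cc + 1, (r + 1):(maxs + 1)] <-
          ways[cc + 1, (r + 1):(maxs + 1)] + src
      }
    }
  }
  counts <- ways[n + 1, ]
  sums <- 0:maxs
  total <- sum(counts)
  mu <- sum(counts * sums) / total
  dev_obs <- abs(obs2 - mu)
  sum(counts[abs(sums - mu) >= dev_obs - 1e-9]) / total
}

#' Mann-Whitney U test
#'
#' Rank-sum test reporting `U` for the first sample (number of pairs where
#' `a` beats `b`, ties counting one half). The p-value is exact (full
#' enumeration of the permutation distribution, valid under ties) when
#' `n * m <= 400`, otherwise a tie-corrected normal approximation with
#' continuity correction. Two-sided throughout.
#'
#' @param a,b Numeric samples, each non-empty.
#' @return List with `U`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n)])
  U1 <- R1 - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n * m <= 400) {
    if (!ties) {
      # tie-free: U follows the standard Wilcoxon rank sum distribution
      p <- 2 * min(stats::pwilcox(U1, n, m),
                   1 - stats::pwilcox(U1 - 1, n, m))
      p <- min(1, p)
      method <- "exact"
    } else {
      ranks2 <- as.integer(round(2 * r))  # midranks doubled -> integers
      p <- exact_ranksum_p(ranks2, n, as.integer(round(2 * R1)))
      method <- "exact (permutation, ties)"
    }
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
    if (sigma == 0) { p <- 1 } else {
      z <- (U1 - mu - sign(U1 - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U1, p_value = p, method = method)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation by iterative majorisation from multiple
#' random starts; the seed is mandatory so ordinations are reproducible.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Embedding dimension (default 2); must be < number of samples.
#' @param restarts Number of random starts (default 20).
#' @param seed RNG seed (mandatory).
#' @return List with `points`, `stress` (fractional stress-1) and
#'   `converged`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed) {
  stopifnot(!missing(seed))
  if (is.matrix(d)) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  fit <- with_seed(seed, suppressMessages(suppressWarnings(
    vegan::metaMDS(d, k = k, try = restarts, trymax = restarts,
                   autotransform = FALSE, wascores = FALSE, trace = 0))))
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || is.numeric(fit$converged))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1` singletons and `F2`
#' doubletons; always at least `S_obs`, with equality when there are fewer
#' than two singletons.
#'
#' @param counts Nonnegative integer vector of per-species counts.
#' @return Richness estimate.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 2))  # 4.333...
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Analytic rarefaction curve
#'
#' Expected species richness in random subsamples of the given depths,
#' computed from the hypergeometric expectation
#' `E[S(d)] = sum_i (1 - choose(N - n_i, d) / choose(N, d))`.
#'
#' @param counts Nonnegative integer vector of per-species counts.
#' @param depths Integer subsample depths, each `<=` the total count.
#' @return Data frame `depth`, `richness`.
#' @export
#' @examples
#' rarefaction_curve(c(5, 5), 2)  # 1.777...
rarefaction_curve <- function(counts, depths) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds total count")
  if (any(depths < 1)) stop("depths must be >= 1")
  # rarefy's advisory about count magnitudes is irrelevant for expectation
  # curves over arbitrary (including tiny) count vectors
  rich <- vapply(depths, function(d)
    as.numeric(suppressWarnings(vegan::rarefy(counts, sample = d))), 0)
  data.frame(depth = depths, richness = unname(rich))
}

#' qPCR standard curve
#'
#' Least-squares fit of `CT = slope * log10(quantity) + intercept` and the
#' amplification efficiency `E = (10^(-1/slope) - 1) * 100` (100% means
#' perfect doubling per cycle, slope -3.32).
#'
#' @param log10_quantity Numeric: log10 starting quantities (e.g. log10
#'   CFU/g); at least 3 points spanning at least 2 log units.
#' @param ct Numeric cycle thresholds.
#' @return List of class `qpcr_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency` (percent).
#' @export
qpcr_standard_curve <- function(log10_quantity, ct) {
  stopifnot(length(log10_quantity) == length(ct))
  if (length(ct) < 3) stop("at least 3 points required")
  if (diff(range(log10_quantity)) < 2)
    stop("standard curve must span at least 2 log units")
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps)
    stop("degenerate fit (zero or undefined slope)")
  if (slope >= 0)
    warning("positive slope: not a valid dilution curve")
  # collinear dilution standards are a legitimate input (R2 exactly 1)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = (10^(-1 / slope) - 1) * 100),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf("<qpcr_curve> CT = %.4f * log10(q) + %.4f  (R2 = %.3f, E = %.1f%%)\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Efficiency of a dilution-curve slope (and its inverse)
#'
#' @param slope Dilution-curve slope (negative).
#' @param efficiency Efficiency in percent.
#' @return `qpcr_efficiency` returns percent efficiency;
#'   `qpcr_slope_for_efficiency` the slope giving that efficiency.
#' @export
qpcr_efficiency <- function(slope) (10^(-1 / slope) - 1) * 100

#' @rdname qpcr_efficiency
#' @export
qpcr_slope_for_efficiency <- function(efficiency)
  -1 / log10(efficiency / 100 + 1)

#' Absolute taxon abundance from total load and relative abundance
#'
#' Multiplies a qPCR-derived total load (CFU/g) by a relative abundance in
#' percent.
#'
#' @param total_cfu Total load (CFU/g), nonnegative.
#' @param relative_percent Relative abundance in percent, in `[0, 100]`.
#' @return Taxon load in CFU/g.
#' @export
#' @examples
#' absolute_abundance(1.10e8, 0.381)  # ~4.19e5
absolute_abundance <- function(total_cfu, relative_percent) {
  if (any(total_cfu < 0)) stop("total load must be nonnegative")
  if (any(relative_percent < 0 | relative_percent > 100))
    stop("relative abundance must be within [0, 100] percent")
  total_cfu * relative_percent / 100
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson product-moment correlation.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}
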