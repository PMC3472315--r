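# Normalization, rarefaction, diversity and ordination.

#' Two-step abundance normalization
#'
#' Each feature value is divided by its sample's total read count, and the
#' resulting fractions are multiplied by the average total over all samples,
#' so that every column sums to the mean sequencing depth (retaining a sense
#' of depth while removing per-sample depth differences).
#'
#' @param m An [abundance_matrix()] of raw counts.
#' @return A normalized `abundance_matrix` (`raw = FALSE`).
#' @export
normalize_abundance <- function(m) {
  totals <- colSums(m)
  if (any(totals == 0)) {
    mc_stop("zero-total sample: ", paste(colnames(m)[totals == 0], collapse = ", "))
  }
  out <- sweep(unclass(m), 2L, totals, "/") * mean(totals)
  abundance_matrix(out, sample_groups(m), raw = FALSE)
}

#' Log10(x + 1) transform
#'
#' @param m Abundance matrix (non-negative values).
#' @return The transformed matrix; zeros map to zero, so absent features stay
#'   at zero rather than negative infinity.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) mc_stop("negative input to log_transform")
  out <- log10(unclass(m) + 1)
  if (inherits(m, "abundance_matrix")) {
    abundance_matrix(out, sample_groups(m), raw = FALSE)
  } else out
}

#' Rarefy one sample's counts to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), so the
#' result always sums exactly to `depth`.
#'
#' @param counts Named non-negative integer vector of feature counts.
#' @param depth Number of reads to draw (`<=` the sample total).
#' @return Rarefied count vector (same names, sums to `depth`).
#' @export
rarefy <- function(counts, depth) {
  total <- sum(counts)
  if (depth > total) mc_stop("rarefaction depth ", depth, " exceeds sample total ", total)
  if (depth == total) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  drawn <- pool[sample.int(length(pool), depth)]
  out <- tabulate(drawn, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Expected richness under rarefaction (closed form)
#'
#' The expected number of features observed when `depth` reads are drawn
#' without replacement: `sum_i (1 - C(N - N_i, n) / C(N, n))` with `N` the
#' sample total, `N_i` the feature counts and `n` the depth.
#'
#' @param counts Non-negative integer feature counts.
#' @param depth Draw size.
#' @return Expected number of features observed (numeric scalar).
#' @export
expected_richness <- function(counts, depth) {
  total <- sum(counts)
  if (depth > total) mc_stop("depth exceeds total")
  counts <- counts[counts > 0]
  p_absent <- exp(lchoose(total - counts, depth) - lchoose(total, depth))
  p_absent[total - counts < depth] <- 0
  sum(1 - p_absent)
}

#' Rarefaction curve over a depth grid
#'
#' @param m Raw-count abundance matrix (features x samples).
#' @param depths Depth grid; defaults to 10 points up to the smallest sample
#'   total.
#' @return `data.frame(sample, depth, expected_richness)`.
#' @export
rarefaction_curve <- function(m, depths = NULL) {
  if (!isTRUE(attr(m, "raw"))) mc_stop("rarefaction requires raw counts")
  if (is.null(depths)) {
    depths <- unique(round(seq(1, min(colSums(m)), length.out = 10)))
  }
  do.call(rbind, lapply(colnames(m), function(s) {
    ok <- depths <= sum(m[, s])
    data.frame(sample = s, depth = depths[ok],
               expected_richness = vapply(depths[ok], function(d)
                 expected_richness(m[, s], d), numeric(1)))
  }))
}

#' Richness, Chao1 and Simpson diversity of one sample
#'
#' Chao1 uses the classic estimator `S + F1^2 / (2 F2)` (singletons F1,
#' doubletons F2), falling back to the bias-corrected `S + F1 (F1 - 1) / 2`
#' when there are no doubletons. Simpson diversity is the Gini-Simpson index
#' `1 - sum p_i^2`, so larger values mean more diversity.
#'
#' @param counts Non-negative integer feature counts (typically rarefied).
#' @return `data.frame(richness, chao1, simpson)`.
#' @export
diversity_metrics <- function(counts) {
  if (sum(counts) == 0) mc_stop("all-zero sample")
  s <- sum(counts >= 1)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
  p <- counts[counts > 0] / sum(counts)
  simpson <- 1 - sum(p^2)
  data.frame(richness = s, chao1 = chao1, simpson = simpson)
}

#' Per-sample diversity summary of a raw-count matrix
#'
#' Optionally rarefies every sample to a common depth first (one draw per
#' sample), then computes richness, Chao1 and Simpson diversity.
#'
#' @param m Raw-count abundance matrix.
#' @param depth Rarefaction depth, or `NULL` to skip rarefaction. Samples
#'   with fewer reads than `depth` are dropped with a warning.
#' @return `data.frame(sample, group, richness, chao1, simpson)`.
#' @export
diversity_summary <- function(m, depth = NULL) {
  if (!isTRUE(attr(m, "raw"))) mc_stop("diversity is computed on raw counts")
  groups <- sample_groups(m)
  keep <- colnames(m)
  if (!is.null(depth)) {
    enough <- colSums(m) >= depth
    if (!all(enough)) {
      mc_warn("dropping samples below rarefaction depth: ",
              paste(colnames(m)[!enough], collapse = ", "))
    }
    keep <- colnames(m)[enough]
  }
  do.call(rbind, lapply(keep, function(s) {
    x <- m[, s]
    if (!is.null(depth)) x <- rarefy(x, depth)
    cbind(data.frame(sample = s, group = unname(groups[s])), diversity_metrics(x))
  }))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`, computed over all features;
#' symmetric with zero diagonal, values in `[0, 1]`.
#'
#' @param m Abundance matrix (features x samples, non-negative).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(m) {
  if (any(m < 0)) mc_stop("negative values in bray_curtis")
  zero <- colSums(m) == 0
  if (sum(zero) >= 2L) {
    mc_stop("Bray-Curtis undefined between all-zero samples: ",
            paste(colnames(m)[zero], collapse = ", "))
  }
  vegan::vegdist(t(unclass(m)), method = "bray")
}

#' Ordinate a distance matrix by PCoA or NMDS
#'
#' PCoA is the eigendecomposition of the double-centered squared-distance
#' matrix (coordinates ordered by decreasing eigenvalue, negative eigenvalues
#' reported). NMDS minimizes stress-1 starting from the PCoA configuration,
#' which makes it deterministic.
#'
#' @param d A `dist` object (or symmetric matrix with zero diagonal).
#' @param method `"PCoA"` (default) or `"NMDS"`.
#' @param k Number of dimensions.
#' @return A list with `points` (samples x k coordinate matrix),
#'   `eigenvalues` (PCoA; includes any negative ones) and `stress`
#'   (NMDS stress-1, `NA` for PCoA).
#' @export
ordinate <- function(d, method = c("PCoA", "NMDS"), k = 2L) {
  method <- match.arg(method)
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k >= n) mc_stop("k must be smaller than the number of samples")
  pcoa <- cmdscale(d, k = k, eig = TRUE)
  if (method == "PCoA") {
    return(list(points = pcoa$points, eigenvalues = pcoa$eig, stress = NA_real_))
  }
  fit <- vegan::monoMDS(d, y = pcoa$points, k = k)
  list(points = fit$points, eigenvalues = NULL, stress = fit$stress)
}

#' Between- vs within-group distance separation
#'
#' @param d `dist` over samples.
#' @param groups Named group labels covering the samples of `d`.
#' @return `data.frame(mean_within, mean_between, separated)` where
#'   `separated` flags `mean_between > mean_within`.
#' @export
group_separation <- function(d, groups) {
  dm <- as.matrix(d)
  g <- groups[rownames(dm)]
  same <- outer(g, g, "==")
  ut <- upper.tri(dm)
  data.frame(mean_within = mean(dm[ut & same]),
             mean_between = mean(dm[ut & !same]),
             separated = mean(dm[ut & !same]) > mean(dm[ut & same]))
}
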