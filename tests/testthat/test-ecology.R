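am <- function(m, groups = NULL, raw = TRUE) {
  if (is.null(groups)) groups <- setNames(rep("A", ncol(m)), colnames(m))
  abundance_matrix(m, groups, raw = raw)
}

test_that("two-step normalization rescales to the mean sequencing depth", {
  m <- am(matrix(c(10, 90, 30, 270), 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  norm <- normalize_abundance(m)
  # totals (100, 300), mean 200: 10/100 * 200 = 20
  expect_equal(norm["f1", "s1"], 20)
  expect_equal(unname(colSums(norm)), c(200, 200))
  # equal totals: normalization is the identity
  m2 <- am(matrix(c(10, 90, 30, 70), 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  expect_equal(unclass(normalize_abundance(m2)), unclass(m2), ignore_attr = TRUE)
  # within-sample ratios of nonzero features are preserved
  expect_equal(norm["f1", "s1"] / norm["f2", "s1"], m["f1", "s1"] / m["f2", "s1"])
  m3 <- am(matrix(c(1, 0, 0, 0), 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  expect_error(normalize_abundance(m3), "zero-total sample: s2")
})

test_that("log transform maps x to log10(x + 1)", {
  m <- matrix(c(0, 9, 99, 999), 2)
  expect_equal(log_transform(m), matrix(c(0, 1, 2, 3), 2))
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("rarefaction draws without replacement and sums to depth", {
  counts <- c(a = 2, b = 2)
  expect_equal(rarefy(counts, 4), counts) # full depth is exact
  set.seed(30)
  for (i in 1:20) {
    r <- rarefy(c(a = 5, b = 3, c = 10), 7)
    expect_equal(sum(r), 7)
    expect_true(all(r <= c(5, 3, 10)))
  }
  expect_error(rarefy(counts, 5), "exceeds")
})

test_that("expected richness matches exhaustive enumeration of draws", {
  # enumerate all C(4,2) = 6 unordered draws of 2 reads from (2,2)
  reads <- c("a", "a", "b", "b")
  combos <- utils::combn(4, 2)
  rich <- apply(combos, 2, function(idx) length(unique(reads[idx])))
  expect_equal(mean(rich), 5 / 3)
  expect_equal(expected_richness(c(2, 2), 2), 5 / 3)
})

test_that("Monte-Carlo rarefied richness converges to the closed form", {
  set.seed(31)
  rich <- replicate(10000, sum(rarefy(c(2, 2), 2) > 0))
  expect_equal(mean(rich), 5 / 3, tolerance = 0.02 / (5 / 3))
})

test_that("expected richness is monotone in depth and exact at full depth", {
  set.seed(32)
  counts <- c(rmultinom(1, 200, prob = runif(20)))
  er <- vapply(c(10, 50, 100, 200), function(d) expected_richness(counts, d),
               numeric(1))
  expect_true(all(diff(er) >= 0))
  expect_equal(er[4], sum(counts > 0))
})

test_that("diversity metrics match their closed forms", {
  # S = 10 with 4 singletons and 2 doubletons: Chao1 = 10 + 16/4 = 14
  counts <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  dm <- diversity_metrics(counts)
  expect_equal(dm$chao1, 14)
  expect_equal(dm$richness, 10)
  expect_equal(diversity_metrics(c(5, 5))$simpson, 0.5)
  single <- diversity_metrics(c(0, 7, 0))
  expect_equal(single$simpson, 0)
  expect_equal(single$chao1, 1)
  expect_equal(single$richness, 1)
  # no doubletons: bias-corrected fallback, still >= richness
  nof2 <- diversity_metrics(c(1, 1, 1, 5))
  expect_equal(nof2$chao1, 4 + 3 * 2 / 2)
  expect_error(diversity_metrics(c(0, 0)), "all-zero")
})

test_that("Gini-Simpson agrees with the community-ecology reference", {
  set.seed(33)
  for (i in 1:5) {
    x <- c(rmultinom(1, 500, runif(15)))
    expect_equal(diversity_metrics(x)$simpson,
                 unname(vegan::diversity(x, index = "simpson")))
    expect_true(diversity_metrics(x)$chao1 >= sum(x > 0))
  }
})

test_that("Bray-Curtis matches its defining formula", {
  m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(as.numeric(bray_curtis(m)), 1)
  m2 <- matrix(c(2, 1, 2, 1), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(as.numeric(bray_curtis(m2)), 0)
  m3 <- matrix(c(2, 1, 1, 1), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(as.numeric(bray_curtis(m3)), 0.2) # (1+0)/(3+2)
  # independent oracle: direct formula on random matrices
  set.seed(34)
  r <- matrix(runif(40), 8, 5, dimnames = list(NULL, paste0("s", 1:5)))
  d <- as.matrix(bray_curtis(r))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sum(abs(r[, i] - r[, j])) / sum(r[, i] + r[, j]))
  }
  mz <- matrix(0, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(bray_curtis(mz), "all-zero")
})

test_that("PCoA places two points at +/- d/2 and respects symmetry", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  ord <- ordinate(d, k = 1)
  expect_equal(unname(sort(ord$points[, 1])), c(-1.5, 1.5))
  # three equidistant points: all pairwise coordinate distances equal
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord3 <- ordinate(d3, k = 2)
  dd <- dist(ord3$points)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-10)
  expect_error(ordinate(d3, k = 3), "smaller")
})

test_that("PCoA reproduces Euclidean-embeddable distances; NMDS stress is tiny", {
  set.seed(35)
  pts <- matrix(rnorm(20), 10, 2)
  rownames(pts) <- paste0("s", 1:10)
  d <- dist(pts)
  pcoa <- ordinate(d, "PCoA", k = 2)
  expect_equal(as.numeric(dist(pcoa$points)), as.numeric(d), tolerance = 1e-8)
  nmds <- ordinate(d, "NMDS", k = 2)
  expect_lt(nmds$stress, 0.01)
  # NMDS from a PCoA start is deterministic
  nmds2 <- ordinate(d, "NMDS", k = 2)
  expect_equal(nmds$points, nmds2$points)
})

test_that("distinct group compositions separate in Bray-Curtis space", {
  spec <- community_spec(
    taxa = data.frame(taxon = c("PhyA", "PhyB", "PhyC", "PhyD"),
                      base_a = c(0.6, 0.2, 0.1, 0.1),
                      base_b = c(0.1, 0.1, 0.2, 0.6),
                      sigma_a = 0.3, sigma_b = 0.3),
    n_individuals_a = 16L, n_individuals_b = 16L,
    pool_sizes_a = rep(4L, 4L), seed = 36L)
  set.seed(spec$seed)
  ia <- sample_individuals(spec, "a")
  ib <- sample_individuals(spec, "b")
  m <- t(rbind(ia, ib))
  groups <- setNames(rep(c("A", "B"), each = 16), colnames(m))
  sep <- group_separation(bray_curtis(m), groups)
  expect_true(sep$separated)
})

test_that("rarefaction curves and diversity summaries are well-formed", {
  set.seed(37)
  counts <- matrix(rpois(40, 40) + 1, 10, 4,
                   dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  m <- am(counts)
  rc <- rarefaction_curve(m, depths = c(10, 50, 100))
  expect_true(all(rc$expected_richness <= 10))
  expect_true(all(tapply(rc$expected_richness, rc$sample, function(x) all(diff(x) >= 0))))
  ds <- diversity_summary(m, depth = min(colSums(m)))
  expect_equal(nrow(ds), 4)
  expect_true(all(ds$chao1 >= ds$richness))
  expect_true(all(ds$simpson >= 0 & ds$simpson < 1))
  expect_warning(diversity_summary(m, depth = max(colSums(m))), "dropping")
})
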