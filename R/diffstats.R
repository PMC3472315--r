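# Two-group differential abundance: Wilcoxon rank-sum + Benjamini-Hochberg,
# with the dual significance rule p <= 0.05 AND q <= 0.1.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact by enumeration when the pooled size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. Identical multisets return p = 1 with a warning.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) mc_stop("empty group")
  if (length(x) == length(y) && all(sort(x) == sort(y)) &&
      length(unique(x)) == 1L) {
    mc_warn("both groups constant and identical; p = 1")
    return(1)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1,
#' with the original order restored. `family_size` may exceed the number of
#' supplied p-values, which adjusts a printed subset of a larger test family
#' (the supplied values are then treated as the smallest members of the
#' family, keeping their within-subset ranks).
#'
#' @param p P-values in `(0, 1]`.
#' @param family_size Total number of tests `m` (default `length(p)`).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p, family_size = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) mc_stop("p-values must lie in (0, 1]")
  if (family_size < length(p)) mc_stop("family_size smaller than the number of p-values")
  p.adjust(p, method = "BH", n = family_size)
}

star_annotation <- function(q) {
  ifelse(q < 0.01, "***", ifelse(q < 0.05, "**", ifelse(q < 0.1, "*", "")))
}

#' Two-group differential-abundance table
#'
#' For every feature of a two-group normalized abundance matrix: per-group
#' mean and sample SD (reported on the normalized scale), a two-sided
#' Wilcoxon rank-sum p-value computed on the log10(x+1)-transformed values
#' (rank-based, so the monotone transform leaves p unchanged; carried for
#' consistency with how the matrices are plotted), a BH q-value over all
#' tested features, the direction (group with the larger mean), and the dual
#' significance rule `p <= 0.05 AND q <= 0.1`. Star annotation follows the
#' figure convention (* q < 0.1, ** q < 0.05, *** q < 0.01).
#'
#' Features that are all-zero in both groups are excluded with a warning.
#'
#' @param m Normalized [abundance_matrix()] with exactly two groups, each
#'   with at least 2 samples.
#' @param family_size BH family size (default: number of features tested).
#' @param p_cut,q_cut Dual-rule cutoffs (inclusive).
#' @return `data.frame` with columns `feature`, `mean_<A>`, `sd_<A>`,
#'   `mean_<B>`, `sd_<B>`, `p_value`, `q_value`, `direction`, `significant`,
#'   `stars`, sorted by ascending p then feature id.
#' @export
differential_table <- function(m, family_size = NULL, p_cut = 0.05, q_cut = 0.1) {
  groups <- sample_groups(m)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) mc_stop("exactly two groups required")
  a <- colnames(m)[groups == lv[1]]
  b <- colnames(m)[groups == lv[2]]
  if (length(a) < 2L || length(b) < 2L) mc_stop("each group needs >= 2 samples")
  allzero <- rowSums(m) == 0
  if (any(allzero)) {
    mc_warn("excluding features all-zero in both groups: ",
            paste(head(rownames(m)[allzero], 5L), collapse = ", "))
  }
  feats <- rownames(m)[!allzero]
  lt <- log10(unclass(m) + 1)
  rows <- lapply(feats, function(f) {
    xa <- m[f, a]; xb <- m[f, b]
    data.frame(feature = f,
               mean_a = mean(xa), sd_a = sd(xa),
               mean_b = mean(xb), sd_b = sd(xb),
               p_value = wilcoxon_rank_sum(lt[f, a], lt[f, b]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(family_size)) family_size <- nrow(tab)
  tab$q_value <- bh_adjust(tab$p_value, family_size)
  tab$direction <- ifelse(tab$mean_a >= tab$mean_b, lv[1], lv[2])
  tab$significant <- tab$p_value <= p_cut & tab$q_value <= q_cut
  tab$stars <- star_annotation(tab$q_value)
  names(tab)[names(tab) == "mean_a"] <- paste0("mean_", lv[1])
  names(tab)[names(tab) == "sd_a"] <- paste0("sd_", lv[1])
  names(tab)[names(tab) == "mean_b"] <- paste0("mean_", lv[2])
  names(tab)[names(tab) == "sd_b"] <- paste0("sd_", lv[2])
  tab <- tab[order(tab$p_value, tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "groups") <- lv
  tab
}

#' Count significant features by direction
#'
#' @param table A differential table (any `data.frame` with `significant` and
#'   `direction` columns).
#' @param groups Optional character vector of the two group labels (defaults
#'   to the table's `groups` attribute, else the labels present).
#' @return `data.frame(significant_total, higher_in_<A>, higher_in_<B>)`.
#' @export
count_significant <- function(table, groups = NULL) {
  if (is.null(groups)) groups <- attr(table, "groups")
  if (is.null(groups)) groups <- sort(unique(table$direction))
  sig <- table[table$significant, , drop = FALSE]
  out <- data.frame(significant_total = nrow(sig))
  for (g in groups) {
    out[[paste0("higher_in_", g)]] <- sum(sig$direction == g)
  }
  out
}

#' Apply the dual significance rule to a printed test table
#'
#' Convenience for re-analyzing an already-computed table of per-feature
#' group means and p/q values: flags rows with `p <= p_cut` and `q <= q_cut`
#' and assigns direction by comparing the two mean columns.
#'
#' @param table `data.frame` with columns `feature`, two mean columns named
#'   `mean_<A>` / `mean_<B>`, `p_value`, `q_value`.
#' @param p_cut,q_cut Inclusive cutoffs.
#' @return The table with `direction` and `significant` columns added and a
#'   `groups` attribute.
#' @export
flag_significant <- function(table, p_cut = 0.05, q_cut = 0.1) {
  mean_cols <- grep("^mean_", names(table), value = TRUE)
  if (length(mean_cols) != 2L) mc_stop("expected exactly two mean_ columns")
  gl <- sub("^mean_", "", mean_cols)
  table$direction <- ifelse(table[[mean_cols[1]]] >= table[[mean_cols[2]]],
                            gl[1], gl[2])
  table$significant <- table$p_value <= p_cut & table$q_value <= q_cut
  attr(table, "groups") <- gl
  table
}
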