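# Best-hit ortholog-group assignment and hierarchical category aggregation.

#' Best-hit ortholog-group assignment
#'
#' Hits are filtered at `evalue <= evalue_cutoff` (inclusive); the best
#' remaining hit per gene (smallest e-value, ties by larger bit-score, then
#' smaller group id) determines the gene's ortholog group. Genes with no
#' passing hit are unassigned.
#'
#' @param hits `data.frame` with columns `gene_id`, `group_id`, `evalue` and
#'   optionally `bitscore`.
#' @param gene_ids Universe of gene ids (genes absent from `hits` are
#'   unassigned); defaults to the genes present in `hits`.
#' @param evalue_cutoff E-value cutoff (default `1e-5`, inclusive).
#' @return `data.frame(gene_id, group_id)` (`NA` group = unassigned), with
#'   attribute `unassigned_fraction`.
#' @export
assign_best_ortholog <- function(hits, gene_ids = NULL, evalue_cutoff = 1e-5) {
  if (any(hits$evalue < 0)) mc_stop("negative e-value")
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  if (is.null(hits$bitscore)) hits$bitscore <- 0
  pass <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  out <- data.frame(gene_id = gene_ids, group_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(pass) > 0L) {
    ord <- order(pass$gene_id, pass$evalue, -pass$bitscore, pass$group_id)
    pass <- pass[ord, , drop = FALSE]
    best <- pass[!duplicated(pass$gene_id), , drop = FALSE]
    idx <- match(best$gene_id, out$gene_id)
    out$group_id[idx[!is.na(idx)]] <- best$group_id[!is.na(idx)]
  }
  attr(out, "unassigned_fraction") <- mean(is.na(out$group_id))
  out
}

#' Aggregate ortholog-group abundances into categories
#'
#' Each group's abundance is split evenly among all the categories it maps
#' to, then summed per category. Groups absent from the map are collected in
#' an explicit `unmapped` row, so total mass is conserved exactly:
#' column sums of the output equal column sums of the input.
#'
#' @param og_abundance Matrix of ortholog-group x sample abundances
#'   (row names = group ids).
#' @param category_map `data.frame(group_id, category)` (one row per
#'   group-category link; a group in `k` categories contributes `1/k` of its
#'   abundance to each).
#' @return Category x sample matrix, including the `unmapped` row.
#' @export
aggregate_categories <- function(og_abundance, category_map) {
  if (any(og_abundance < 0)) mc_stop("negative abundance")
  if (any(is.na(category_map$category) | !nzchar(category_map$category))) {
    mc_stop("group mapped to empty category")
  }
  map <- category_map[category_map$group_id %in% rownames(og_abundance), , drop = FALSE]
  n_cat <- table(map$group_id)
  cats <- sort(unique(map$category))
  out <- matrix(0, nrow = length(cats) + 1L, ncol = ncol(og_abundance),
                dimnames = list(c(cats, "unmapped"), colnames(og_abundance)))
  for (i in seq_len(nrow(map))) {
    g <- map$group_id[i]
    out[map$category[i], ] <- out[map$category[i], ] +
      og_abundance[g, ] / n_cat[[g]]
  }
  unmapped <- setdiff(rownames(og_abundance), map$group_id)
  if (length(unmapped) > 0L) {
    out["unmapped", ] <- colSums(og_abundance[unmapped, , drop = FALSE])
  }
  out
}

#' Unassigned fraction per sample
#'
#' @param assigned Named numeric vector of assigned counts per sample.
#' @param universe Named numeric vector of total counts per sample
#'   (`universe >= assigned`, element-wise).
#' @return Named numeric vector `(universe - assigned) / universe`.
#' @export
unassigned_fraction <- function(assigned, universe) {
  universe <- universe[names(assigned)]
  if (any(universe == 0)) mc_stop("zero universe for sample: ",
                                  paste(names(universe)[universe == 0], collapse = ", "))
  if (any(assigned > universe)) mc_stop("assigned exceeds universe")
  (universe - assigned) / universe
}
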