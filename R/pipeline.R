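# End-to-end composition of the pipeline stages, used by the analysis
# drivers and the recovery experiments.

#' Build the classifier index for a simulated experiment
#'
#' Only taxa flagged `in_database` enter the reference index, so reads from
#' excluded taxa surface as unassigned (emulating reference-database bias).
#'
#' @param refs Reference set from [make_reference_set()].
#' @param k Classifier word size.
#' @return Index for [classify_reads()].
#' @export
reference_index <- function(refs, k = 12L) {
  keep <- refs$taxa$in_database
  build_taxon_index(refs$genomes[refs$taxa$ref_id[keep]],
                    refs$taxa[keep, , drop = FALSE], k = k)
}

#' Taxonomic profile of a simulated experiment
#'
#' Classifies all reads with the k-mer classifier, applies the confidence
#' cutoff, and tabulates per-rank abundances with unassigned reads carried
#' as an explicit `Unclassified` pseudo-taxon.
#'
#' @param sim Output of [simulate_metagenome()].
#' @param rank Taxonomic rank for the abundance table.
#' @param k Classifier word size.
#' @param confidence_cutoff Per-rank confidence cutoff.
#' @param index Optional prebuilt [reference_index()] (saves rebuilding the
#'   k-mer index across replicate runs on the same genomes).
#' @return A list with `abundance` (raw-count [abundance_matrix()] including
#'   the `Unclassified` row), `rank_abundance` (full
#'   [build_rank_abundance()] output) and `assignments`.
#' @export
profile_taxa <- function(sim, rank = "phylum", k = 12L,
                         confidence_cutoff = 0.7, index = NULL) {
  if (is.null(index)) index <- reference_index(sim$refs, k = k)
  ranks <- TAXON_RANKS[seq_len(match(rank, TAXON_RANKS))]
  asg <- classify_reads(sim$reads, index, sample_of = sim$sample_of,
                        ranks = ranks)
  asg <- filter_by_confidence(asg, cutoff = confidence_cutoff)
  ra <- build_rank_abundance(asg, rank, mode = "with_unclassified")
  am <- abundance_matrix(ra$counts, sim$groups, raw = TRUE)
  list(abundance = am, rank_abundance = ra, assignments = asg)
}

#' Run the full two-group comparison on a simulated experiment
#'
#' classify -> per-rank abundance -> two-step normalization -> Wilcoxon +
#' BH differential table, plus Bray-Curtis group separation.
#'
#' @inheritParams profile_taxa
#' @param family_size BH family size passed to [differential_table()].
#' @return A list with `profile`, `normalized`, `difftest` and `separation`.
#' @export
run_comparison <- function(sim, rank = "phylum", k = 12L,
                           confidence_cutoff = 0.7, family_size = NULL,
                           index = NULL) {
  prof <- profile_taxa(sim, rank = rank, k = k,
                       confidence_cutoff = confidence_cutoff, index = index)
  norm <- normalize_abundance(prof$abundance)
  dt <- differential_table(norm, family_size = family_size)
  d <- bray_curtis(log_transform(norm))
  sep <- group_separation(d, sim$groups)
  list(profile = prof, normalized = norm, difftest = dt, separation = sep)
}

#' Plant a redundant gene catalogue with known cluster structure
#'
#' Generates `n_clusters` unrelated base genes plus redundant copies (exact
#' duplicates or slightly diverged, optionally reverse-complemented copies)
#' attached to randomly chosen base genes, so the true number of clusters is
#' known by construction.
#'
#' @param n_genes Total gene count.
#' @param dup_fraction Fraction of genes that are redundant copies.
#' @param min_len,max_len Base gene length range.
#' @param divergence Substitution rate applied to non-exact copies (must stay
#'   well inside the clustering identity threshold).
#' @param exact_fraction Fraction of copies that are exact duplicates.
#' @param rc_fraction Fraction of copies that are reverse-complemented.
#' @return A list with `genes` (named vector), `truth` (`data.frame(gene_id,
#'   cluster)`) and `n_clusters`.
#' @export
plant_redundant_catalogue <- function(n_genes = 1000L, dup_fraction = 0.2,
                                      min_len = 200L, max_len = 600L,
                                      divergence = 0.01, exact_fraction = 0.5,
                                      rc_fraction = 0.25) {
  n_dup <- round(n_genes * dup_fraction)
  n_base <- n_genes - n_dup
  base <- random_genes(n_base, min_len, max_len, prefix = "base")
  parents <- sample(names(base), n_dup, replace = TRUE)
  copies <- setNames(vapply(seq_len(n_dup), function(i) {
    s <- base[[parents[i]]]
    if (runif(1) > exact_fraction) s <- mutate_sequence(s, divergence)
    if (runif(1) < rc_fraction) s <- reverse_complement(s)
    s
  }, character(1)), sprintf("copy%05d", seq_len(n_dup)))
  truth <- data.frame(gene_id = c(names(base), names(copies)),
                      cluster = c(names(base), parents),
                      stringsAsFactors = FALSE)
  list(genes = c(base, copies), truth = truth, n_clusters = n_base)
}

#' Simulate an ortholog hit table with planted unannotatable genes
#'
#' Fabricates BLAST-style best-hit input: a chosen fraction of genes gets no
#' hit passing the e-value cutoff (either no hit at all or a weak decoy hit),
#' the rest get a strong hit to their planted ortholog group.
#'
#' @param gene_ids Gene ids.
#' @param orthologs Named character vector gene id -> true ortholog group
#'   (genes may be missing).
#' @param unannotatable_fraction Fraction of genes made unannotatable.
#' @return `data.frame(gene_id, group_id, evalue, bitscore)` plus attribute
#'   `truth` (named vector of the annotatable genes' groups).
#' @export
simulate_ortholog_hits <- function(gene_ids, orthologs,
                                   unannotatable_fraction = 0.4) {
  n <- length(gene_ids)
  bad <- sample(gene_ids, round(n * unannotatable_fraction))
  rows <- lapply(gene_ids, function(g) {
    if (g %in% bad) {
      if (runif(1) < 0.5) return(NULL) # no hit at all
      data.frame(gene_id = g, group_id = "KO9999",
                 evalue = 10^-runif(1, 0, 4), bitscore = runif(1, 20, 40),
                 stringsAsFactors = FALSE)
    } else {
      grp <- if (!is.null(orthologs) && g %in% names(orthologs) &&
                 !is.na(orthologs[[g]])) orthologs[[g]] else sprintf("KO%04d", sample(500L, 1L))
      data.frame(gene_id = g, group_id = grp,
                 evalue = 10^-runif(1, 8, 50), bitscore = runif(1, 80, 400),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "planted_unannotatable") <- bad
  out
}
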