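# Non-redundant gene catalogue construction.
#
# Predicted ORFs are compared all-against-all; gene pairs exceeding an
# identity threshold with the aligned span covering more than a set fraction
# of the shorter gene are grouped, groups sharing genes are merged
# (single-linkage / connected components), and the longest member represents
# each merged group. Representatives shorter than a minimum length are then
# filtered out.

#' Group redundant genes by identity and coverage
#'
#' Builds the redundancy graph over a set of genes: an edge joins two genes
#' iff their best pairwise identity exceeds `id_threshold` and the aligned
#' span covers more than `cov_threshold` of the shorter gene. Clusters are the
#' connected components of this graph (transitive merging of groups sharing
#' genes); singletons are retained as their own clusters. With
#' `inclusive = TRUE` the comparisons become `>=` (used for contig-level
#' redundancy removal, where the overlap rule is "at least").
#'
#' @param genes Named character vector of nucleotide gene sequences.
#' @param id_threshold Identity threshold in percent (default 95; edges
#'   require identity strictly greater than this).
#' @param cov_threshold Minimum coverage of the shorter gene as a fraction
#'   (default 0.90, strict).
#' @param min_seed Seed word size for candidate discovery.
#' @param inclusive Use `>=` instead of `>` for both thresholds (the contig
#'   parameterization: identity 90, overlap "at least" 30 bp).
#' @param min_overlap If given, replaces the coverage rule with an absolute
#'   aligned-length rule in bases (contig-level redundancy removal).
#' @param min_seed_hits Distinct shared seed words required before a pair is
#'   aligned (passed to the matcher; 1 recovers every seeded pair).
#' @param matches Optional precomputed match table (as returned by the
#'   internal matcher); mainly for testing.
#' @return A list with `clusters` (list of character vectors of member ids,
#'   each sorted, list ordered by smallest member id) and `edges` (the match
#'   table of passing pairs).
#' @export
build_gene_groups <- function(genes, id_threshold = 95, cov_threshold = 0.90,
                              min_seed = 11L, inclusive = FALSE,
                              min_overlap = NULL, min_seed_hits = 2L,
                              matches = NULL) {
  if (anyDuplicated(names(genes))) mc_stop("gene ids must be unique")
  check_nucleotide(genes, "gene")
  if (is.null(matches)) {
    matches <- identity_matches(genes, genes, min_seed = min_seed, self = TRUE,
                                min_seed_hits = min_seed_hits)
  }
  cover <- if (is.null(min_overlap)) {
    if (inclusive) matches$coverage_shorter >= cov_threshold
    else matches$coverage_shorter > cov_threshold
  } else {
    if (inclusive) matches$aligned_length >= min_overlap
    else matches$aligned_length > min_overlap
  }
  pass <- cover & if (inclusive) matches$identity >= id_threshold
                  else matches$identity > id_threshold
  edges <- matches[pass, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(genes))
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$query, edges$subject))
  }
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  clusters <- unname(clusters[order(vapply(clusters, `[`, "", 1L))])
  mc_log("build_gene_groups: %d genes -> %d clusters (%d redundant edges)",
         length(genes), length(clusters), nrow(edges))
  list(clusters = clusters, edges = edges)
}

#' Select cluster representatives and build the non-redundant gene set
#'
#' The longest member of each cluster represents it (ties broken by
#' lexicographically smallest id). Representatives shorter than `min_length`
#' are filtered out *after* selection.
#'
#' @param clusters List of character vectors of member ids (from
#'   [build_gene_groups()]).
#' @param genes Named character vector of gene sequences covering all members.
#' @param min_length Minimum representative length in bases; representatives
#'   with length < `min_length` are dropped (length exactly `min_length` is
#'   kept).
#' @param complete Optional named logical vector flagging complete ORFs
#'   (start and stop codon present), used only for the summary statistics.
#' @return A list with `representatives` (named character vector of retained
#'   representative sequences), `membership` (data.frame gene_id, cluster_id,
#'   representative, is_representative) and `stats` (input count, cluster
#'   count, retained count, percent complete among retained representatives).
#' @export
select_representatives <- function(clusters, genes, min_length = 100L,
                                   complete = NULL) {
  if (any(lengths(clusters) == 0L)) mc_stop("empty cluster")
  reps <- vapply(clusters, function(members) {
    len <- nchar(genes[members])
    cand <- members[len == max(len)]
    sort(cand)[1L]
  }, character(1))
  keep <- nchar(genes[reps]) >= min_length
  membership <- data.frame(
    gene_id = unlist(clusters),
    cluster_id = rep(sprintf("cluster_%05d", seq_along(clusters)), lengths(clusters)),
    representative = rep(reps, lengths(clusters)),
    stringsAsFactors = FALSE)
  membership$is_representative <- membership$gene_id == membership$representative
  retained <- reps[keep]
  pct_complete <- if (!is.null(complete) && length(retained) > 0L) {
    100 * mean(complete[retained])
  } else NA_real_
  mc_log("select_representatives: %d clusters -> %d representatives retained",
         length(clusters), length(retained))
  list(representatives = genes[retained],
       membership = membership,
       stats = data.frame(n_input = length(unlist(clusters)),
                          n_clusters = length(clusters),
                          n_retained = length(retained),
                          pct_complete = pct_complete))
}

#' Translate a coding sequence with the bacterial genetic code
#'
#' Translation uses NCBI genetic code 11 (bacterial/archaeal/plant plastid).
#' A trailing stop codon is removed; internal stops are retained as `*` and
#' flagged; codons containing N translate to `X`; 1-2 leftover trailing bases
#' are ignored with a warning. When `is_start = TRUE` and the first codon is
#' one of code 11's alternative initiation codons, it translates to M.
#'
#' @param seq Nucleotide coding sequence (length >= 3).
#' @param is_start Treat the first codon as the initiation codon.
#' @return The amino-acid string, with attribute `internal_stop` (logical).
#' @export
translate_cds <- function(seq, is_start = TRUE) {
  seq <- toupper(as.character(seq)[1])
  n <- nchar(seq)
  if (n < 3L) mc_stop("sequence shorter than one codon")
  check_nucleotide(seq)
  if (n %% 3L != 0L) {
    mc_warn("translate_cds: ignoring ", n %% 3L, " trailing base(s)")
    seq <- substr(seq, 1L, n - n %% 3L)
    n <- nchar(seq)
  }
  code <- Biostrings::getGeneticCode("11")
  starts <- attr(code, "alt_init_codons")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X", unname(code[codons]))
  if (is_start && codons[1L] %in% c(starts, "ATG") && !grepl("N", codons[1L], fixed = TRUE)) {
    aa[1L] <- "M"
  }
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal_stop <- any(aa == "*")
  if (internal_stop) mc_warn("translate_cds: internal stop codon retained")
  structure(paste(aa, collapse = ""), internal_stop = internal_stop)
}

#' Map reads to a gene catalogue
#'
#' Each read is assigned to the best-identity catalogue gene meeting
#' `identity >= id_threshold` and `aligned length > min_overlap` (ties broken
#' by longer overlap, then smallest gene id). Supports cross-catalogue runs
#' (reads of one host against the catalogue of another).
#'
#' @param reads Named character vector of read sequences.
#' @param catalogue Named character vector of catalogue gene sequences.
#' @param id_threshold Minimum identity in percent (inclusive).
#' @param min_overlap Reads must align over strictly more than this many
#'   columns.
#' @param sample_of Optional named character vector mapping read id to sample
#'   id; per-sample assigned fractions are reported when given.
#' @param min_seed Seed word size.
#' @return A list with `assignments` (data.frame read_id, gene_id, identity,
#'   aligned_length; unassigned reads have `NA` gene), `gene_counts` (named
#'   integer vector over catalogue genes), `assigned_fraction` (overall) and
#'   `per_sample` (data.frame sample, n_reads, assigned_fraction).
#' @export
map_reads_to_catalogue <- function(reads, catalogue, id_threshold = 95,
                                   min_overlap = 100L, sample_of = NULL,
                                   min_seed = 11L) {
  if (length(catalogue) == 0L) mc_stop("catalogue is empty")
  if (min_overlap > max(nchar(reads))) {
    mc_stop("min_overlap (", min_overlap, ") exceeds the longest read (",
            max(nchar(reads)), "); no read could ever be assigned")
  }
  m <- identity_matches(reads, catalogue, min_seed = min_seed)
  pass <- m[m$identity >= id_threshold & m$aligned_length > min_overlap, , drop = FALSE]
  best <- NULL
  if (nrow(pass) > 0L) {
    data.table::setorder(pass, query, -identity, -aligned_length, subject)
    best <- unique(pass, by = "query")
  }
  assignments <- data.frame(read_id = names(reads), gene_id = NA_character_,
                            identity = NA_real_, aligned_length = NA_integer_,
                            stringsAsFactors = FALSE)
  if (!is.null(best) && nrow(best) > 0L) {
    idx <- match(best$query, assignments$read_id)
    assignments$gene_id[idx] <- best$subject
    assignments$identity[idx] <- best$identity
    assignments$aligned_length[idx] <- best$aligned_length
  }
  gene_counts <- table(factor(assignments$gene_id, levels = names(catalogue)))
  gene_counts <- setNames(as.integer(gene_counts), names(catalogue))
  per_sample <- NULL
  if (!is.null(sample_of)) {
    sm <- sample_of[assignments$read_id]
    per_sample <- do.call(rbind, lapply(split(seq_along(sm), sm), function(i) {
      data.frame(sample = sm[i][1], n_reads = length(i),
                 assigned_fraction = mean(!is.na(assignments$gene_id[i])),
                 stringsAsFactors = FALSE)
    }))
    rownames(per_sample) <- NULL
  }
  mc_log("map_reads_to_catalogue: %d/%d reads assigned",
         sum(!is.na(assignments$gene_id)), length(reads))
  list(assignments = assignments, gene_counts = gene_counts,
       assigned_fraction = mean(!is.na(assignments$gene_id)),
       per_sample = per_sample)
}
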