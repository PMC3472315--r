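# Taxonomic read assignment and per-rank abundance tables.
#
# Two assignment routes mirror common practice for shotgun reads:
#  * a strict identity/overlap best-hit rule applied to an alignment hit
#    table (high-confidence, species-level, low assigned fraction), and
#  * a composition-based classifier with a per-rank confidence score and a
#    confidence cutoff (lower precision, much higher assigned fraction).

TAXON_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

rank_col <- function(rank) paste0("rank_", rank)
conf_col <- function(rank) paste0("conf_", rank)

split_taxon_path <- function(path) {
  parts <- strsplit(path, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- length(TAXON_RANKS)
    p
  }, character(length(TAXON_RANKS))))
}

#' Read an alignment hit table
#'
#' Expects a TSV with columns `read_id`, `subject_id`, `identity`,
#' `aln_length`, `confidence`, `taxon_path` (semicolon-separated ranks,
#' phylum first).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of hits.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("read_id", "subject_id", "identity", "aln_length", "taxon_path")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) mc_stop("hit table missing columns: ", paste(miss, collapse = ", "))
  for (cn in c("identity", "aln_length")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      mc_stop("malformed hit row at line ", bad[1L] + 1L, " (column ", cn, ")")
    }
    df[[cn]] <- v
  }
  df
}

#' Strict best-hit taxonomic assignment
#'
#' Applies the high-confidence rule: a read is assigned to the taxon of its
#' best hit among hits with `identity >= id_threshold` and
#' `aln_length > min_overlap`; best = highest identity, then longest overlap,
#' then smallest subject id. Reads with no passing hit are unassigned.
#'
#' @param hits Hit `data.frame` (see [read_hit_table()]); may cover only a
#'   subset of reads.
#' @param read_ids Character vector of all read ids in the universe (reads
#'   absent from `hits` are unassigned). Defaults to the reads present in
#'   `hits`.
#' @param id_threshold Identity cutoff in percent (inclusive).
#' @param min_overlap Overlap cutoff in bases (strict `>`).
#' @param sample_of Optional named vector read id -> sample id.
#' @return A `data.frame` with one row per read: `read_id`, `sample`,
#'   rank columns `rank_phylum` ... `rank_species` (NA when unassigned),
#'   `identity`, `aln_length`; attribute `assigned_fraction`.
#' @export
assign_strict <- function(hits, read_ids = NULL, id_threshold = 95,
                          min_overlap = 100, sample_of = NULL) {
  if (is.null(read_ids)) read_ids <- unique(hits$read_id)
  pass <- hits[hits$identity >= id_threshold & hits$aln_length > min_overlap, , drop = FALSE]
  out <- data.frame(read_id = read_ids, stringsAsFactors = FALSE)
  out$sample <- if (!is.null(sample_of)) unname(sample_of[read_ids]) else "sample1"
  ranks <- matrix(NA_character_, nrow = length(read_ids), ncol = length(TAXON_RANKS),
                  dimnames = list(NULL, rank_col(TAXON_RANKS)))
  out$identity <- NA_real_
  out$aln_length <- NA_real_
  if (nrow(pass) > 0L) {
    ord <- order(pass$read_id, -pass$identity, -pass$aln_length, pass$subject_id)
    pass <- pass[ord, , drop = FALSE]
    best <- pass[!duplicated(pass$read_id), , drop = FALSE]
    idx <- match(best$read_id, read_ids)
    ok <- !is.na(idx)
    ranks[idx[ok], ] <- split_taxon_path(best$taxon_path[ok])
    out$identity[idx[ok]] <- best$identity[ok]
    out$aln_length[idx[ok]] <- best$aln_length[ok]
  }
  out <- cbind(out, as.data.frame(ranks, stringsAsFactors = FALSE))
  attr(out, "assigned_fraction") <- mean(!is.na(out$rank_phylum))
  out
}

#' Blank assignment ranks below a confidence cutoff
#'
#' Keeps an assignment at a rank iff its confidence at that rank is
#' `>= cutoff` (inclusive). Once a rank is blanked, all lower ranks are
#' blanked too, so absent ranks always form a contiguous suffix.
#'
#' @param assignments Assignment `data.frame` with `rank_*` and `conf_*`
#'   columns (see [classify_reads()]).
#' @param cutoff Confidence cutoff in `[0, 1]` (default 0.7).
#' @return The filtered assignment `data.frame`.
#' @export
filter_by_confidence <- function(assignments, cutoff = 0.7) {
  ranks <- TAXON_RANKS[conf_col(TAXON_RANKS) %in% names(assignments)]
  confs <- as.matrix(assignments[, conf_col(ranks), drop = FALSE])
  if (any(confs < 0 | confs > 1, na.rm = TRUE)) {
    mc_stop("confidence outside [0, 1]")
  }
  keep <- !is.na(confs) & confs >= cutoff
  # contiguous suffix: a rank survives only if all ranks above it survive
  keep <- matrix(t(apply(keep, 1L, cumprod)) > 0, nrow = nrow(keep))
  for (i in seq_along(ranks)) {
    blank <- !keep[, i]
    assignments[[rank_col(ranks[i])]][blank] <- NA_character_
    assignments[[conf_col(ranks[i])]][blank] <- NA_real_
  }
  assignments
}

#' Per-rank taxon abundance table
#'
#' Tabulates assignments into a taxon x sample count matrix at one rank,
#' tracking unassigned reads per sample.
#'
#' @param assignments Assignment `data.frame` with a `sample` column and
#'   `rank_*` columns.
#' @param rank One of `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`.
#' @param mode `"counts"`: taxon counts with unassigned tracked separately;
#'   `"fraction_excluding"`: per-sample fractions renormalized over assigned
#'   reads only (composition-plot mode); `"with_unclassified"`: counts with
#'   unassigned carried as an explicit `Unclassified` pseudo-taxon row so
#'   that differential tests can include it.
#' @return A list with `counts` (taxon x sample matrix), `unassigned`
#'   (per-sample counts), `assigned_fraction` (per sample), `rank`, `mode`.
#' @export
build_rank_abundance <- function(assignments, rank,
                                 mode = c("counts", "fraction_excluding",
                                          "with_unclassified")) {
  mode <- match.arg(mode)
  if (!rank %in% TAXON_RANKS) mc_stop("unknown rank: ", rank)
  taxa <- assignments[[rank_col(rank)]]
  samples <- assignments$sample
  sample_levels <- unique(samples)
  totals <- table(factor(samples, levels = sample_levels))
  assigned <- !is.na(taxa)
  tab <- table(factor(taxa[assigned]), factor(samples[assigned], levels = sample_levels))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab), ncol = ncol(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  unassigned <- as.numeric(totals) - colSums(counts)
  names(unassigned) <- sample_levels
  stopifnot(all(colSums(counts) + unassigned == as.numeric(totals)))
  if (mode == "fraction_excluding") {
    ca <- colSums(counts)
    if (any(ca == 0)) mc_stop("sample with no assigned reads at rank ", rank, ": ",
                              paste(colnames(counts)[ca == 0], collapse = ", "))
    counts <- sweep(counts, 2L, ca, "/")
  } else if (mode == "with_unclassified") {
    counts <- rbind(counts, Unclassified = unassigned)
  }
  list(counts = counts, unassigned = unassigned,
       assigned_fraction = 1 - unassigned / as.numeric(totals),
       rank = rank, mode = mode)
}

#' Build a k-mer reference index for the naive classifier
#'
#' @param references Named character vector of reference genome sequences.
#' @param taxa `data.frame` with column `ref_id` and either a `taxon_path`
#'   column (semicolon-separated, phylum first) or the six rank columns.
#' @param k Word size (default 12).
#' @return An opaque index object for [classify_reads()].
#' @export
build_taxon_index <- function(references, taxa, k = 12L) {
  kmer <- NULL # data.table NSE
  if (!all(names(references) %in% taxa$ref_id)) {
    mc_stop("references without taxon paths: ",
            paste(setdiff(names(references), taxa$ref_id), collapse = ", "))
  }
  if ("taxon_path" %in% names(taxa)) {
    rk <- split_taxon_path(taxa$taxon_path)
    colnames(rk) <- rank_col(TAXON_RANKS)
    taxa <- cbind(taxa[, "ref_id", drop = FALSE], as.data.frame(rk, stringsAsFactors = FALSE))
  }
  idx <- data.table::rbindlist(lapply(names(references), function(id) {
    data.table::data.table(kmer = seq_kmers(references[[id]], k), ref = id)
  }))
  data.table::setkey(idx, kmer)
  list(index = idx, taxa = taxa, k = as.integer(k))
}

read_kmer_table <- function(reads, k) {
  n <- nchar(reads)
  if (any(n < k)) mc_stop("k (", k, ") larger than shortest read (", min(n), ")")
  ids <- names(reads)
  both <- c(reads, setNames(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads))),
    ids))
  dts <- lapply(unique(nchar(both)), function(len) {
    sel <- both[nchar(both) == len]
    offs <- seq_len(len - k + 1L)
    # loop over offsets, not reads: one vectorized substring call per offset
    data.table::data.table(
      read = rep(names(sel), times = length(offs)),
      kmer = unlist(lapply(offs, function(o) substring(sel, o, o + k - 1L)),
                    use.names = FALSE))
  })
  dt <- unique(data.table::rbindlist(dts))
  dt[!grepl("N", dt$kmer, fixed = TRUE)]
}

#' Classify reads by shared k-mer counts against a reference index
#'
#' A deliberately simple composition-based classifier: each read is scored
#' against every reference by the number of distinct shared k-mers (both
#' strands). At each rank, scores are summed over references belonging to the
#' same taxon; the best-scoring taxon is assigned with confidence
#' `best / (best + runner_up)` (0.5 for an exact tie, 1 when there is no
#' competitor). Reads sharing no k-mer with any reference are unassigned.
#'
#' @param reads Named character vector of reads.
#' @param index Index from [build_taxon_index()].
#' @param sample_of Optional named vector read id -> sample id.
#' @param ranks Ranks to assign (default: all six); restricting to the ranks
#'   actually tabulated saves time on large runs.
#' @return Assignment `data.frame` with `read_id`, `sample`, and per-rank
#'   `rank_*` / `conf_*` columns.
#' @export
classify_reads <- function(reads, index, sample_of = NULL,
                           ranks = TAXON_RANKS) {
  read <- ref <- score <- taxon <- NULL # data.table NSE
  if (!all(ranks %in% TAXON_RANKS)) mc_stop("unknown rank in ranks")
  kt <- read_kmer_table(reads, index$k)
  hits <- index$index[kt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  scores <- if (nrow(hits) > 0L) {
    hits[, list(score = .N), by = list(read, ref)]
  } else {
    data.table::data.table(read = character(), ref = character(), score = integer())
  }
  out <- data.frame(read_id = names(reads), stringsAsFactors = FALSE)
  out$sample <- if (!is.null(sample_of)) unname(sample_of[out$read_id]) else "sample1"
  tax <- index$taxa
  for (rk in ranks) {
    out[[rank_col(rk)]] <- NA_character_
    out[[conf_col(rk)]] <- NA_real_
    if (nrow(scores) == 0L) next
    taxon_of <- setNames(tax[[rank_col(rk)]], tax$ref_id)
    sc <- scores[, list(read, taxon = unname(taxon_of[ref]), score)]
    sc <- sc[!is.na(taxon), list(score = sum(score)), by = list(read, taxon)]
    if (nrow(sc) == 0L) next
    data.table::setorder(sc, read, -score, taxon)
    best <- sc[!duplicated(read)]
    runner <- sc[duplicated(read)][!duplicated(read)]
    conf <- setNames(rep(1, nrow(best)), best$read)
    r_match <- match(best$read, runner$read)
    has_r <- !is.na(r_match)
    conf[has_r] <- best$score[has_r] / (best$score[has_r] + runner$score[r_match[has_r]])
    idx <- match(best$read, out$read_id)
    out[[rank_col(rk)]][idx] <- best$taxon
    out[[conf_col(rk)]][idx] <- unname(conf)
  }
  out
}
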