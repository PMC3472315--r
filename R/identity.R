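# Seed-and-extend pairwise identity.
#
# Candidate pairs must share at least one exact k-mer of length `min_seed`
# (on either strand); candidates are then extended by local (Smith-Waterman)
# alignment. Identity is matches / alignment columns, gap columns and N
# counting as mismatch. Coverage is the aligned span on the shorter sequence
# divided by its length.

# alignment scoring: +1 match, -2 mismatch (N never matches), gap open 4 /
# extend 2 -- high-identity gene redundancy, not remote homology
.mc_env <- new.env(parent = emptyenv())

submat <- function() {
  if (is.null(.mc_env$submat)) {
    m <- matrix(-2, 5, 5, dimnames = list(NUC_ALPHABET, NUC_ALPHABET))
    diag(m) <- 1
    m["N", "N"] <- -2
    .mc_env$submat <- m
  }
  .mc_env$submat
}

# all distinct seed k-mers of a sequence (k-mers containing N cannot seed)
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), k:n)
  km <- unique(km)
  km[!grepl("N", km, fixed = TRUE)]
}

# batched local alignment of several queries against one subject string;
# returns per-pair identity/overlap statistics
align_against <- function(queries, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = submat(),
    gapOpening = 4, gapExtension = 2)
  cols <- Biostrings::nchar(pa) # alignment columns, gaps included
  matches <- Biostrings::nmatch(pa)
  # nmatch counts N==N columns as matches; N must count as mismatch
  has_n <- grepl("N", queries, fixed = TRUE) | grepl("N", subject, fixed = TRUE)
  if (any(has_n)) {
    ap <- as.character(Biostrings::alignedPattern(pa[has_n]))
    as_ <- as.character(Biostrings::alignedSubject(pa[has_n]))
    matches[has_n] <- mapply(function(p, s) {
      pc <- strsplit(p, "", fixed = TRUE)[[1]]
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      sum(pc == sc & pc %in% c("A", "C", "G", "T"))
    }, ap, as_, USE.NAMES = FALSE)
  }
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  data.frame(identity = ifelse(cols > 0, 100 * matches / cols, 0),
             aligned_length = cols,
             score = Biostrings::score(pa),
             span_query = Biostrings::end(pr) - Biostrings::start(pr) + 1L,
             span_subject = Biostrings::end(sr) - Biostrings::start(sr) + 1L)
}

#' Seed-and-extend pairwise sequence identity
#'
#' Computes a local alignment between two nucleotide sequences, provided they
#' share at least one exact `min_seed`-mer on either strand. Identity is
#' matches divided by alignment columns (gap columns count as mismatch, as do
#' columns involving N); coverage is the aligned span on the shorter sequence
#' divided by the shorter sequence's length. Both orientations are tried and
#' the best-identity one kept. The statistic is symmetric in its arguments.
#'
#' @param a,b Nucleotide sequences (length-1 character vectors; names, if
#'   present, become the query/subject ids).
#' @param min_seed Minimum exact shared word size to attempt alignment
#'   (must be >= 8).
#' @return A one-row `data.frame` with columns `query`, `subject`,
#'   `identity` (percent), `aligned_length` (alignment columns),
#'   `coverage_shorter` (fraction) and `strand`; or `NULL` if no seed k-mer
#'   is shared.
#' @export
pairwise_identity <- function(a, b, min_seed = 11L) {
  if (min_seed < 8L) mc_stop("min_seed must be >= 8")
  ida <- if (!is.null(names(a))) names(a)[1] else "query"
  idb <- if (!is.null(names(b))) names(b)[1] else "subject"
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) mc_stop("empty sequence in pairwise_identity")
  check_nucleotide(c(a, b))
  ka <- seq_kmers(a, min_seed)
  kb <- seq_kmers(b, min_seed)
  cand <- character(0)
  if (any(ka %in% kb)) cand <- "+"
  arc <- reverse_complement(a)
  if (any(seq_kmers(arc, min_seed) %in% kb)) cand <- c(cand, "-")
  if (length(cand) == 0L) return(NULL)
  rows <- lapply(cand, function(strand) {
    q <- if (strand == "+") a else arc
    st <- align_against(q, b)
    data.frame(query = ida, subject = idb,
               identity = st$identity,
               aligned_length = st$aligned_length,
               coverage_shorter = min(st$span_query, st$span_subject) /
                 min(nchar(a), nchar(b)),
               strand = strand, score = st$score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # best orientation = highest-scoring alignment
  best <- res[order(-res$score, res$strand)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best[, setdiff(names(best), "score")]
}

# Candidate (query, subject, strand) triples sharing >= min_seed_hits
# distinct seed k-mers. A pair that can pass a high identity/coverage
# threshold shares many exact words, so requiring two seeds discards chance
# single-word matches between unrelated sequences without affecting true
# redundancy. `self = TRUE` restricts to unordered pairs within one set.
seed_candidates <- function(query_seqs, subject_seqs, min_seed, self = FALSE,
                            both_strands = TRUE, min_seed_hits = 1L) {
  kmer <- qid <- sid <- strand <- n_seeds <- NULL # data.table NSE
  sub_dt <- data.table::rbindlist(lapply(names(subject_seqs), function(id) {
    data.table::data.table(kmer = seq_kmers(subject_seqs[[id]], min_seed), sid = id)
  }))
  if (nrow(sub_dt) == 0L) return(data.table::data.table(qid = character(), sid = character(), strand = character()))
  data.table::setkey(sub_dt, kmer)
  q_one <- function(seqs, str) {
    dt <- data.table::rbindlist(lapply(names(seqs), function(id) {
      data.table::data.table(kmer = seq_kmers(seqs[[id]], min_seed), qid = id)
    }))
    if (nrow(dt) == 0L) return(NULL)
    hits <- sub_dt[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(NULL)
    out <- hits[, list(n_seeds = .N), by = list(qid, sid)]
    out <- out[n_seeds >= min_seed_hits, list(qid, sid)]
    out[, strand := str]
    out
  }
  fwd <- q_one(query_seqs, "+")
  res <- fwd
  if (both_strands) {
    rc <- setNames(as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(unlist(query_seqs)))),
      names(query_seqs))
    rev <- q_one(as.list(rc), "-")
    res <- data.table::rbindlist(list(fwd, rev))
  }
  if (is.null(res) || nrow(res) == 0L) {
    return(data.table::data.table(qid = character(), sid = character(), strand = character()))
  }
  res <- unique(res)
  if (self) res <- res[qid < sid]
  res
}

# Compute identity statistics for all seed-sharing pairs, batched by subject
# for speed. Returns a data.table(query, subject, identity, aligned_length,
# coverage_shorter, strand) with one row per seeded (query, subject,
# orientation) triple; callers filter by their thresholds and then pick a
# best hit, so a long imperfect alignment on one strand is never shadowed by
# a short perfect one on the other.
identity_matches <- function(query_seqs, subject_seqs, min_seed = 11L,
                             self = FALSE, both_strands = TRUE,
                             min_seed_hits = 2L) {
  identity <- aligned_length <- NULL # data.table NSE
  query_seqs <- as.list(query_seqs); subject_seqs <- as.list(subject_seqs)
  cand <- seed_candidates(query_seqs, subject_seqs, min_seed, self = self,
                          both_strands = both_strands,
                          min_seed_hits = min_seed_hits)
  if (nrow(cand) == 0L) {
    return(data.table::data.table(query = character(), subject = character(),
                                  identity = numeric(), aligned_length = integer(),
                                  coverage_shorter = numeric(), strand = character()))
  }
  qlen <- vapply(query_seqs, nchar, 1L)
  slen <- vapply(subject_seqs, nchar, 1L)
  rc_cache <- new.env(parent = emptyenv())
  rows <- vector("list", 0L)
  for (sid_i in unique(cand$sid)) {
    sub_cand <- cand[cand$sid == sid_i, ]
    qseq <- vapply(seq_len(nrow(sub_cand)), function(i) {
      q <- sub_cand$qid[i]
      if (sub_cand$strand[i] == "+") return(query_seqs[[q]])
      key <- q
      if (is.null(rc_cache[[key]])) rc_cache[[key]] <- reverse_complement(query_seqs[[q]])
      rc_cache[[key]]
    }, character(1))
    st <- align_against(qseq, subject_seqs[[sid_i]])
    rows[[length(rows) + 1L]] <- data.table::data.table(
      query = sub_cand$qid, subject = sid_i,
      identity = st$identity, aligned_length = st$aligned_length,
      coverage_shorter = pmin(st$span_query, st$span_subject) /
        pmin(qlen[sub_cand$qid], slen[sid_i]),
      strand = sub_cand$strand)
  }
  res <- data.table::rbindlist(rows)
  data.table::setorder(res, query, subject, -identity, -aligned_length)
  res
}
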