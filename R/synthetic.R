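# Synthetic two-host-group metagenome generator.
#
# Emulates the sampling design the comparative analysis assumes: one host
# group sequenced as pooled libraries (60 individuals pooled 7-8 at a time
# into 8 libraries) versus one group of single-individual samples; lognormal
# inter-individual variation around group base compositions; one synthetic
# reference genome per taxon; fixed-length single-end reads with i.i.d.
# substitution errors; and complete ground-truth tables so every downstream
# stage can be checked against planted truth.

#' Printed phylum-level differential-abundance table of the two hosts
#'
#' The 27-row phylum table (taxon, per-group mean and SD of normalized
#' abundance in percent, raw Wilcoxon p, printed BH q), including the
#' `Unclassified` pseudo-taxon row. Used both as the in-package reanalysis
#' input and to parameterize the `table1`-style community preset.
#'
#' @return `data.frame` with columns `taxon`, `mean_guinea_pig`,
#'   `sd_guinea_pig`, `mean_human`, `sd_human`, `p_value`, `q_printed`.
#' @export
table1_phyla <- function() {
  path <- system.file("extdata", "phylum_difftable.tsv", package = "metacompare",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Construct a community specification
#'
#' Defines the two-group study design the generator emulates. Defaults follow
#' the sequencing design being modelled: group A ("guinea_pig") has 60
#' individuals pooled 7-8 at a time into 8 libraries; group B ("human") is
#' sequenced as single-individual samples.
#'
#' @param taxa `data.frame` with columns `taxon` (phylum label), `base_a`,
#'   `base_b` (group base relative abundances; each column must sum to 1),
#'   `sigma_a`, `sigma_b` (lognormal dispersion of inter-individual
#'   variation) and optionally `in_database` (logical; taxa absent from the
#'   classifier's reference database, emulating unclassifiable reads).
#' @param n_individuals_a,n_individuals_b Individuals per group.
#' @param pool_sizes_a Pooling sizes for group A (must partition
#'   `n_individuals_a`); group B samples are single individuals.
#' @param reads_per_library Reads generated per sequenced sample.
#' @param read_length Read length in bases (single-end).
#' @param error_rate Per-base substitution error rate.
#' @param genome_length Length of each synthetic reference genome.
#' @param group_names Labels of the two groups.
#' @param seed Integer seed making the whole simulation deterministic.
#' @return A `community_spec` list.
#' @export
community_spec <- function(taxa,
                           n_individuals_a = 60L,
                           n_individuals_b = 124L,
                           pool_sizes_a = c(8L, 8L, 8L, 8L, 7L, 7L, 7L, 7L),
                           reads_per_library = 2000L,
                           read_length = 75L,
                           error_rate = 0.01,
                           genome_length = 50000L,
                           group_names = c("guinea_pig", "human"),
                           seed = 1L) {
  stopifnot(is.data.frame(taxa),
            all(c("taxon", "base_a", "base_b", "sigma_a", "sigma_b") %in% names(taxa)))
  if (is.null(taxa$in_database)) taxa$in_database <- TRUE
  if (any(taxa$sigma_a < 0) || any(taxa$sigma_b < 0)) mc_stop("sigma < 0")
  if (abs(sum(taxa$base_a) - 1) > 1e-8 || abs(sum(taxa$base_b) - 1) > 1e-8) {
    mc_stop("base abundances must sum to 1 within each group")
  }
  if (sum(pool_sizes_a) != n_individuals_a) {
    mc_stop("pool sizes must partition the group-A individuals (",
            sum(pool_sizes_a), " != ", n_individuals_a, ")")
  }
  structure(list(taxa = taxa,
                 n_individuals_a = as.integer(n_individuals_a),
                 n_individuals_b = as.integer(n_individuals_b),
                 pool_sizes_a = as.integer(pool_sizes_a),
                 reads_per_library = as.integer(reads_per_library),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 genome_length = as.integer(genome_length),
                 group_names = group_names,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' The phylum-table community preset
#'
#' Builds a [community_spec()] whose 27 taxa carry the printed per-group mean
#' abundances as base compositions (renormalized to sum 1) and whose
#' lognormal dispersions are calibrated from the printed SD/mean ratios via
#' `sigma = sqrt(log(1 + cv^2))`. The `Unclassified` row becomes a taxon
#' whose genome is excluded from the classifier reference database, so its
#' reads surface as unassigned.
#'
#' @param dispersion_scale Multiplier on the calibrated sigmas (1 = printed
#'   dispersion).
#' @param ... Passed on to [community_spec()] (e.g. `n_individuals_b`,
#'   `reads_per_library`, `seed`).
#' @return A `community_spec`.
#' @export
table1_community_spec <- function(dispersion_scale = 1, ...) {
  t1 <- table1_phyla()
  cv_a <- t1$sd_guinea_pig / t1$mean_guinea_pig
  cv_b <- t1$sd_human / t1$mean_human
  taxa <- data.frame(
    taxon = t1$taxon,
    base_a = t1$mean_guinea_pig / sum(t1$mean_guinea_pig),
    base_b = t1$mean_human / sum(t1$mean_human),
    sigma_a = dispersion_scale * sqrt(log(1 + cv_a^2)),
    sigma_b = dispersion_scale * sqrt(log(1 + cv_b^2)),
    in_database = t1$taxon != "Unclassified",
    stringsAsFactors = FALSE)
  community_spec(taxa = taxa, ...)
}

#' Write / read a community spec as YAML
#'
#' @param spec A `community_spec`.
#' @param path File path.
#' @return `path` (write) or a `community_spec` (read).
#' @export
write_community_spec <- function(spec, path) {
  x <- unclass(spec)
  x$taxa <- as.list(x$taxa)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_community_spec
#' @export
read_community_spec <- function(path) {
  x <- yaml::read_yaml(path)
  taxa <- as.data.frame(x$taxa, stringsAsFactors = FALSE)
  do.call(community_spec, c(list(taxa = taxa),
                            x[setdiff(names(x), "taxa")]))
}

#' Sample per-individual taxon compositions
#'
#' Each individual's composition is the group base profile perturbed by
#' independent lognormal(0, sigma) factors per taxon and renormalized to sum
#' to 1.
#'
#' @param spec A [community_spec()].
#' @param group `"a"` or `"b"`.
#' @param n Number of individuals (defaults to the spec's group size).
#' @return Individuals x taxa matrix of relative abundances (rows sum to 1).
#' @export
sample_individuals <- function(spec, group = c("a", "b"), n = NULL) {
  group <- match.arg(group)
  base <- spec$taxa[[paste0("base_", group)]]
  sigma <- spec$taxa[[paste0("sigma_", group)]]
  if (any(sigma < 0)) mc_stop("sigma < 0")
  if (is.null(n)) n <- if (group == "a") spec$n_individuals_a else spec$n_individuals_b
  m <- t(vapply(seq_len(n), function(i) {
    x <- base * rlnorm(length(base), meanlog = 0, sdlog = sigma)
    x / sum(x)
  }, numeric(length(base))))
  colnames(m) <- spec$taxa$taxon
  rownames(m) <- sprintf("%s_ind%03d", spec$group_names[if (group == "a") 1 else 2],
                         seq_len(n))
  m
}

#' Pool individual compositions into libraries
#'
#' A library's composition is the unweighted mean of its member individuals,
#' emulating equal-mass DNA pooling.
#'
#' @param individuals Individuals x taxa composition matrix.
#' @param sizes Integer pooling sizes; must partition the individuals.
#' @return Libraries x taxa composition matrix.
#' @export
pool_libraries <- function(individuals, sizes) {
  if (sum(sizes) != nrow(individuals)) {
    mc_stop("pool sizes (sum ", sum(sizes), ") do not partition ",
            nrow(individuals), " individuals")
  }
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  out <- t(vapply(seq_along(sizes), function(i) {
    colMeans(individuals[starts[i]:stops[i], , drop = FALSE])
  }, numeric(ncol(individuals))))
  rownames(out) <- sprintf("library%02d", seq_along(sizes))
  out
}

#' A random nucleotide sequence
#' @param n Length in bases.
#' @return A single sequence string (uniform A/C/G/T).
#' @export
random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Random gene set
#' @param n Number of genes.
#' @param min_len,max_len Length range in bases.
#' @param prefix Id prefix.
#' @return Named character vector of sequences.
#' @export
random_genes <- function(n, min_len = 150L, max_len = 600L, prefix = "gene") {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  setNames(vapply(lens, random_sequence, character(1)),
           sprintf("%s%05d", prefix, seq_len(n)))
}

#' Apply i.i.d. substitution errors to a sequence
#' @param seq Sequence string.
#' @param rate Per-base substitution probability.
#' @return Mutated sequence.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Build the synthetic reference set for a community spec
#'
#' One random genome per taxon, with `genes_per_genome` non-overlapping gene
#' loci planted on it; every third gene carries no ortholog label (emulating
#' genes without database homologs), the rest are labelled with synthetic
#' ortholog-group ids.
#'
#' @param spec A [community_spec()].
#' @param genes_per_genome Number of planted gene loci per genome.
#' @return A list with `genomes` (named by ref id), `taxa` (`ref_id`,
#'   `taxon_path`, `in_database`), and `genes` (`gene_id`, `ref_id`, `start`,
#'   `end`, `ortholog`).
#' @export
make_reference_set <- function(spec, genes_per_genome = 10L) {
  taxa <- spec$taxa
  ref_ids <- sprintf("ref_%s", gsub("[^A-Za-z0-9]", "_", taxa$taxon))
  genomes <- setNames(vapply(seq_len(nrow(taxa)), function(i)
    random_sequence(spec$genome_length), character(1)), ref_ids)
  paths <- vapply(taxa$taxon, function(tx) {
    paste(c(tx, paste0(tx, c("_cls", "_ord", "_fam", "_gen", "_sp"))), collapse = ";")
  }, character(1))
  gene_len <- 300L
  stride <- spec$genome_length %/% (genes_per_genome + 1L)
  if (stride <= gene_len) mc_stop("genome too short for ", genes_per_genome, " gene loci")
  genes <- do.call(rbind, lapply(seq_along(ref_ids), function(i) {
    starts <- stride * seq_len(genes_per_genome) - gene_len %/% 2L
    data.frame(gene_id = sprintf("%s_g%02d", ref_ids[i], seq_len(genes_per_genome)),
               ref_id = ref_ids[i], start = starts, end = starts + gene_len - 1L,
               ortholog = ifelse(seq_len(genes_per_genome) %% 3L == 0L,
                                 NA_character_,
                                 sprintf("KO%04d", (i * 97L + seq_len(genes_per_genome)) %% 500L)),
               stringsAsFactors = FALSE)
  }))
  list(genomes = genomes,
       taxa = data.frame(ref_id = ref_ids, taxon_path = unname(paths),
                         in_database = taxa$in_database, stringsAsFactors = FALSE),
       genes = genes)
}

#' Generate reads from one library
#'
#' Reads are drawn from the reference genomes proportional to the library's
#' taxon composition, with uniform start positions, a uniformly random
#' strand, and i.i.d. substitution errors.
#'
#' @param lib_fracs Named numeric vector of taxon relative abundances (names
#'   matching `spec$taxa$taxon`).
#' @param refs Reference set from [make_reference_set()].
#' @param spec The [community_spec()].
#' @param n_reads Number of reads (default `spec$reads_per_library`).
#' @param prefix Read id prefix.
#' @return A list with `reads` (named character vector) and `truth`
#'   (`data.frame(read_id, taxon, ref_id, start, strand, n_errors)`).
#' @export
generate_reads <- function(lib_fracs, refs, spec, n_reads = NULL,
                           prefix = "read") {
  if (is.null(n_reads)) n_reads <- spec$reads_per_library
  if (n_reads < 1L) mc_stop("n_reads must be >= 1")
  L <- spec$read_length
  if (L > spec$genome_length) mc_stop("read length exceeds genome length")
  taxa <- names(lib_fracs)
  ref_of <- setNames(refs$taxa$ref_id,
                     vapply(strsplit(refs$taxa$taxon_path, ";", fixed = TRUE),
                            `[`, "", 1L))
  pick <- sample(taxa, n_reads, replace = TRUE, prob = lib_fracs)
  glen <- nchar(refs$genomes)
  starts <- 1L + floor(runif(n_reads) * (glen[ref_of[pick]] - L + 1L))
  frags <- substring(refs$genomes[ref_of[pick]], starts, starts + L - 1L)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  rev <- strands == "-"
  if (any(rev)) {
    frags[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(frags[rev])))
  }
  # vectorized substitution errors over the read x position character matrix
  nerr <- integer(n_reads)
  seqs <- frags
  if (spec$error_rate > 0) {
    chars <- matrix(unlist(strsplit(frags, "", fixed = TRUE), use.names = FALSE),
                    nrow = n_reads, byrow = TRUE)
    hit <- which(matrix(runif(n_reads * L) < spec$error_rate, nrow = n_reads))
    if (length(hit) > 0L) {
      alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                    nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
      chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)),
                              sample.int(3L, length(hit), replace = TRUE))]
      seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
      nerr <- tabulate((hit - 1L) %% n_reads + 1L, nbins = n_reads)
    }
  }
  ids <- sprintf("%s_%06d", prefix, seq_len(n_reads))
  list(reads = setNames(seqs, ids),
       truth = data.frame(read_id = ids, taxon = pick,
                          ref_id = unname(ref_of[pick]), start = starts,
                          strand = strands, n_errors = nerr,
                          stringsAsFactors = FALSE))
}

#' Simulate a full two-group metagenome experiment
#'
#' Samples individual compositions for both groups, pools group A into
#' libraries, generates reads for every sequenced sample, and returns the
#' reads together with complete ground truth. Deterministic under
#' `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @param refs Optional pre-built reference set (rebuilt from the spec
#'   otherwise; passing one keeps the genomes fixed across replicate runs).
#' @param n_samples_b Number of group-B samples to sequence (defaults to all
#'   `spec$n_individuals_b`).
#' @return A list: `reads` (named vector over all samples), `sample_of`
#'   (read id -> sample), `groups` (sample -> group label), `truth`
#'   (per-read ground truth incl. sample), `library_fracs` (sample x taxon
#'   expected composition), `refs`, `spec`.
#' @export
simulate_metagenome <- function(spec, refs = NULL, n_samples_b = NULL) {
  set.seed(spec$seed)
  if (is.null(refs)) refs <- make_reference_set(spec)
  if (is.null(n_samples_b)) n_samples_b <- spec$n_individuals_b
  ind_a <- sample_individuals(spec, "a")
  lib_a <- pool_libraries(ind_a, spec$pool_sizes_a)
  rownames(lib_a) <- sprintf("%s_lib%02d", spec$group_names[1], seq_len(nrow(lib_a)))
  lib_b <- sample_individuals(spec, "b", n = n_samples_b)
  rownames(lib_b) <- sprintf("%s_s%03d", spec$group_names[2], seq_len(nrow(lib_b)))
  fracs <- rbind(lib_a, lib_b)
  groups <- setNames(rep(spec$group_names, c(nrow(lib_a), nrow(lib_b))),
                     rownames(fracs))
  all_reads <- list(); all_truth <- list()
  for (s in rownames(fracs)) {
    out <- generate_reads(fracs[s, ], refs, spec, prefix = s)
    out$truth$sample <- s
    all_reads[[s]] <- out$reads
    all_truth[[s]] <- out$truth
  }
  reads <- unlist(unname(all_reads))
  truth <- do.call(rbind, all_truth)
  rownames(truth) <- NULL
  list(reads = reads,
       sample_of = setNames(truth$sample, truth$read_id),
       groups = groups,
       truth = truth,
       library_fracs = fracs,
       refs = refs,
       spec = spec)
}
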