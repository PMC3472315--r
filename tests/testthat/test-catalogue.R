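test_that("identical genes group together and unrelated genes stay apart", {
  set.seed(10)
  x <- random_sequence(300)
  genes <- c(A = x, B = x, C = random_sequence(300))
  cl <- build_gene_groups(genes)$clusters
  expect_equal(cl, list(c("A", "B"), "C"))
})

test_that("groups sharing genes merge transitively", {
  set.seed(11)
  a <- random_sequence(300)
  b <- substitute_at(a, seq(5, 300, by = 25))   # 12 subs: ~96% to a
  c_ <- substitute_at(b, seq(15, 300, by = 25)) # 12 more: ~92% to a
  genes <- c(A = a, B = b, C = c_)
  # confirm the intended pass/fail pattern of the three edges
  expect_gt(pairwise_identity(genes["A"], genes["B"])$identity, 95)
  expect_gt(pairwise_identity(genes["B"], genes["C"])$identity, 95)
  expect_lt(pairwise_identity(genes["A"], genes["C"])$identity, 95)
  cl <- build_gene_groups(genes)$clusters
  expect_equal(cl, list(c("A", "B", "C")))
})

test_that("identity exactly at the threshold is excluded unless inclusive", {
  set.seed(12)
  a <- random_sequence(300)
  b <- substitute_at(a, seq(10, 300, by = 20)) # 15 subs: exactly 95.0%
  genes <- c(A = a, B = b)
  expect_equal(pairwise_identity(genes["A"], genes["B"])$identity, 95)
  expect_length(build_gene_groups(genes)$clusters, 2L)
  expect_length(build_gene_groups(genes, inclusive = TRUE)$clusters, 1L)
})

test_that("clustering is invariant to input order", {
  set.seed(13)
  genes <- random_cluster_instance(15)
  cl1 <- build_gene_groups(genes)$clusters
  cl2 <- build_gene_groups(genes[rev(seq_along(genes))])$clusters
  expect_equal(cl1, cl2)
})

test_that("clustering agrees with the brute-force union-find oracle", {
  set.seed(14)
  for (i in 1:10) {
    genes <- random_cluster_instance(sample(5:20, 1))
    impl <- build_gene_groups(genes)$clusters
    expect_equal(impl, oracle_gene_groups(genes))
  }
})

test_that("cluster count never increases when the identity threshold drops", {
  set.seed(15)
  genes <- random_cluster_instance(20)
  n98 <- length(build_gene_groups(genes, id_threshold = 98)$clusters)
  n95 <- length(build_gene_groups(genes, id_threshold = 95)$clusters)
  n90 <- length(build_gene_groups(genes, id_threshold = 90)$clusters)
  expect_true(n98 >= n95 && n95 >= n90)
  # partition property: cluster sizes sum to the input size
  expect_equal(sum(lengths(build_gene_groups(genes)$clusters)), length(genes))
})

test_that("contig parameterization uses an absolute overlap rule", {
  set.seed(16)
  a <- random_sequence(200)
  contigs <- c(A = a, B = paste0(substr(a, 161, 200), random_sequence(160)))
  # the 40 bp shared end exceeds the 30 bp overlap rule at full identity
  cl <- build_gene_groups(contigs, id_threshold = 90, min_overlap = 30,
                          inclusive = TRUE, min_seed_hits = 1L)
  expect_length(cl$clusters, 1L)
  # but fails the 90%-coverage gene rule
  cl2 <- build_gene_groups(contigs)
  expect_length(cl2$clusters, 2L)
})

test_that("representatives are the longest members, ties by smallest id", {
  genes <- c(x = paste(rep("ACGTA", 50), collapse = ""),
             b = paste(rep("AACGT", 60), collapse = ""),
             a = paste(rep("GACGT", 60), collapse = ""))
  out <- select_representatives(list(c("x", "b", "a")), genes, min_length = 100)
  expect_equal(names(out$representatives), "a")
  expect_true(all(out$membership$representative == "a"))
})

test_that("the length filter drops representatives under 100 bp, keeping 100", {
  set.seed(17)
  genes <- setNames(vapply(c(99, 100, 150), random_sequence, character(1)),
                    c("g1", "g2", "g3"))
  out <- select_representatives(list("g1", "g2", "g3"), genes, min_length = 100)
  expect_equal(sort(names(out$representatives)), c("g2", "g3"))
  expect_equal(out$stats$n_retained, 2L)
  expect_error(select_representatives(list(character(0)), genes), "empty cluster")
})

test_that("translation follows the bacterial code with ambiguity handling", {
  expect_equal(as.character(translate_cds("ATGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("ATGNNNTAA")), "MX")
  # GTG is an alternative initiation codon in the bacterial code
  expect_equal(as.character(translate_cds("GTGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("GTGAAATAA", is_start = FALSE)), "VK")
  expect_warning(tr <- translate_cds("ATGTAAAAATAA"), "internal stop")
  expect_equal(as.character(tr), "M*K")
  expect_true(attr(tr, "internal_stop"))
  expect_warning(translate_cds("ATGAAAT"), "trailing")
  expect_error(translate_cds("AT"), "shorter")
})

test_that("cross-catalogue mapping recovers the planted shared fraction", {
  set.seed(1)
  cat_a <- random_genes(60, 300, 600, prefix = "a")
  cat_b <- random_genes(60, 300, 600, prefix = "b")
  n_reads <- 5000
  from_b <- runif(n_reads) < 0.10
  src <- ifelse(from_b, sample(names(cat_b), n_reads, replace = TRUE),
                sample(names(cat_a), n_reads, replace = TRUE))
  pool <- c(cat_a, cat_b)
  starts <- vapply(src, function(g) sample.int(nchar(pool[[g]]) - 149L, 1L), 1L)
  reads <- setNames(vapply(seq_len(n_reads), function(i)
    mutate_sequence(substr(pool[[src[i]]], starts[i], starts[i] + 149L), 0.005),
    character(1)), sprintf("r%05d", seq_len(n_reads)))
  res <- map_reads_to_catalogue(reads, cat_b, id_threshold = 95, min_overlap = 100)
  expect_equal(res$assigned_fraction, 0.10, tolerance = 0.02 / 0.10)
  # reads drawn from catalogue B overwhelmingly map back to their source gene
  hit <- res$assignments$gene_id[match(names(reads)[from_b], res$assignments$read_id)]
  expect_gt(mean(hit == src[from_b], na.rm = TRUE), 0.99)
})

test_that("reads map to the best catalogue gene over the overlap cutoff", {
  set.seed(18)
  catalogue <- random_genes(4, 300, 400, prefix = "g")
  g <- catalogue[["g00002"]]
  reads <- c(r1 = substr(g, 51, 170),          # exact 120-base substring
             r2 = mutate_sequence(substr(g, 1, 90), 0.04), # short overlap
             r3 = random_sequence(120))
  res <- map_reads_to_catalogue(reads, catalogue, min_overlap = 100)
  expect_equal(res$assignments$gene_id[res$assignments$read_id == "r1"], "g00002")
  expect_true(is.na(res$assignments$gene_id[res$assignments$read_id == "r2"]))
  expect_true(is.na(res$assignments$gene_id[res$assignments$read_id == "r3"]))
  expect_equal(unname(res$gene_counts["g00002"]), 1L)
  expect_error(map_reads_to_catalogue(reads, catalogue, min_overlap = 121),
               "min_overlap")
})
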