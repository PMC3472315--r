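# Independent oracles used to cross-check the implementation.

# plain union-find over ids
uf_new <- function(ids) setNames(ids, ids)
uf_find <- function(uf, x) {
  while (uf[[x]] != x) x <- uf[[x]]
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[rb]] <- ra
  uf
}

# brute-force clustering oracle: all unordered pairs through
# pairwise_identity, union-find over passing pairs, canonicalized partition
oracle_gene_groups <- function(genes, id_threshold = 95, cov_threshold = 0.90,
                               min_seed = 11L, inclusive = FALSE) {
  ids <- names(genes)
  uf <- uf_new(ids)
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        pm <- pairwise_identity(genes[i], genes[j], min_seed = min_seed)
        if (is.null(pm)) next
        ok <- if (inclusive) {
          pm$identity >= id_threshold && pm$coverage_shorter >= cov_threshold
        } else {
          pm$identity > id_threshold && pm$coverage_shorter > cov_threshold
        }
        if (ok) uf <- uf_union(uf, ids[i], ids[j])
      }
    }
  }
  roots <- vapply(ids, function(x) uf_find(uf, x), character(1))
  cl <- lapply(split(ids, roots), function(x) sort(unname(x)))
  unname(cl[order(vapply(cl, `[`, "", 1L))])
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration (no ties)
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# direct Benjamini-Hochberg step-up
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  q <- ps * m / seq_len(k)
  for (i in rev(seq_len(k - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(k)
  out[o] <- q
  out
}

# deterministic mutant with an exact number of substitutions at fixed spacing
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

# random clustering instance: a few unrelated templates, plus copies mutated
# across a divergence range straddling the identity threshold, some
# reverse-complemented
random_cluster_instance <- function(n, n_templates = 3L) {
  tpl <- random_genes(n_templates, 150, 400, prefix = "tpl")
  n_extra <- n - n_templates
  extra <- setNames(vapply(seq_len(n_extra), function(i) {
    if (runif(1) < 0.3) return(random_sequence(sample(150:400, 1)))
    s <- mutate_sequence(tpl[[sample(n_templates, 1)]], runif(1, 0, 0.1))
    if (runif(1) < 0.3) s <- metacompare:::reverse_complement(s)
    s
  }, character(1)), sprintf("ex%03d", seq_len(n_extra)))
  c(tpl, extra)
}
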