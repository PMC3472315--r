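hit <- function(read, subj, id, len, path) {
  data.frame(read_id = read, subject_id = subj, identity = id,
             aln_length = len, taxon_path = path, stringsAsFactors = FALSE)
}

test_that("strict assignment picks the best passing hit", {
  hits <- rbind(hit("r1", "s1", 96, 150, "PhyX;ClsX;OrdX;FamX;GenX;SpX"),
                hit("r1", "s2", 98, 120, "PhyY;ClsY;OrdY;FamY;GenY;SpY"),
                hit("r2", "s3", 99, 90, "PhyZ"),   # overlap too short
                hit("r3", "s4", 95, 150, "PhyW"))  # identity exactly at cutoff
  asg <- assign_strict(hits, read_ids = c("r1", "r2", "r3", "r4"))
  expect_equal(asg$rank_species[asg$read_id == "r1"], "SpY")
  expect_true(is.na(asg$rank_phylum[asg$read_id == "r2"]))
  # "cutoff of 95%" is inclusive for read assignment
  expect_equal(asg$rank_phylum[asg$read_id == "r3"], "PhyW")
  expect_true(is.na(asg$rank_phylum[asg$read_id == "r4"])) # no hits at all
  expect_equal(attr(asg, "assigned_fraction"), 0.5)
})

test_that("strict assignment breaks ties by overlap then subject id", {
  hits <- rbind(hit("r1", "s2", 97, 150, "PhyA"),
                hit("r1", "s1", 97, 180, "PhyB"),
                hit("r2", "s9", 97, 150, "PhyC"),
                hit("r2", "s3", 97, 150, "PhyD"))
  asg <- assign_strict(hits)
  expect_equal(asg$rank_phylum[asg$read_id == "r1"], "PhyB") # longer overlap
  expect_equal(asg$rank_phylum[asg$read_id == "r2"], "PhyD") # smaller subject id
})

test_that("malformed hit tables are rejected with a line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tsubject_id\tidentity\taln_length\ttaxon_path",
               "r1\ts1\t96\t150\tPhyX",
               "r2\ts2\tnot_a_number\t150\tPhyY"), tf)
  expect_error(read_hit_table(tf), "line 3")
})

test_that("confidence filtering is inclusive at the cutoff and keeps suffix structure", {
  asg <- data.frame(read_id = c("r1", "r2", "r3"), sample = "s1",
                    stringsAsFactors = FALSE)
  for (rk in metacompare:::TAXON_RANKS) {
    asg[[paste0("rank_", rk)]] <- c("A", "B", "C")
    asg[[paste0("conf_", rk)]] <- c(0.65, 0.70, 1.0)
  }
  # make r3's class rank uncertain: everything below must blank as well
  asg$conf_class[3] <- 0.5
  out <- filter_by_confidence(asg, cutoff = 0.7)
  expect_true(is.na(out$rank_phylum[1]))          # 0.65 < 0.7
  expect_equal(out$rank_species[2], "B")          # 0.70 kept (inclusive)
  expect_equal(out$rank_phylum[3], "C")
  expect_true(all(is.na(out[3, paste0("rank_", metacompare:::TAXON_RANKS[-1])])))
  bad <- asg; bad$conf_phylum[1] <- 1.3
  expect_error(filter_by_confidence(bad), "outside")
})

test_that("raising the confidence cutoff never increases any taxon count", {
  set.seed(20)
  asg <- data.frame(read_id = sprintf("r%03d", 1:200), sample = "s1",
                    stringsAsFactors = FALSE)
  for (rk in metacompare:::TAXON_RANKS) {
    asg[[paste0("rank_", rk)]] <- sample(LETTERS[1:4], 200, replace = TRUE)
    asg[[paste0("conf_", rk)]] <- runif(200)
  }
  prev <- NULL
  for (cut in c(0.3, 0.5, 0.7, 0.9)) {
    ra <- build_rank_abundance(filter_by_confidence(asg, cut), "genus")
    counts <- ra$counts[sort(rownames(ra$counts)), , drop = FALSE]
    if (!is.null(prev)) {
      shared <- intersect(rownames(prev), rownames(counts))
      expect_true(all(counts[shared, ] <= prev[shared, ]))
    }
    prev <- counts
  }
})

test_that("rank abundance conserves reads and renormalizes correctly", {
  asg <- data.frame(read_id = sprintf("r%02d", 1:10), sample = "s1",
                    stringsAsFactors = FALSE)
  for (rk in metacompare:::TAXON_RANKS) {
    asg[[paste0("rank_", rk)]] <- c(rep("Firmicutes", 6), rep(NA, 4))
    asg[[paste0("conf_", rk)]] <- 1
  }
  ra <- build_rank_abundance(asg, "phylum")
  expect_equal(unname(ra$assigned_fraction), 0.6)
  expect_equal(unname(ra$counts["Firmicutes", "s1"]), 6)
  expect_equal(unname(ra$unassigned["s1"]), 4)
  frac <- build_rank_abundance(asg, "phylum", mode = "fraction_excluding")
  expect_equal(unname(frac$counts["Firmicutes", "s1"]), 1)
  tab1 <- build_rank_abundance(asg, "phylum", mode = "with_unclassified")
  expect_equal(unname(tab1$counts["Unclassified", "s1"]), 4)
  expect_equal(sum(tab1$counts[, "s1"]), 10)
  expect_error(build_rank_abundance(asg, "kingdom"), "unknown rank")
})

test_that("the k-mer classifier recovers verbatim and planted reads", {
  set.seed(21)
  refs <- setNames(vapply(rep(20000L, 3), random_sequence, character(1)),
                   c("refA", "refB", "refC"))
  taxa <- data.frame(ref_id = names(refs),
                     taxon_path = c("PhyA;ClsA;OrdA;FamA;GenA;SpA",
                                    "PhyB;ClsB;OrdB;FamB;GenB;SpB",
                                    "PhyC;ClsC;OrdC;FamC;GenC;SpC"),
                     stringsAsFactors = FALSE)
  idx <- build_taxon_index(refs, taxa, k = 12)
  # verbatim read
  r <- setNames(substr(refs[["refB"]], 501, 575), "v1")
  asg <- classify_reads(r, idx)
  expect_equal(asg$rank_species, "SpB")
  expect_gte(asg$conf_species, 0.5)
  # error-free reads: all correct at species rank
  n <- 300
  src <- sample(names(refs), n, replace = TRUE)
  starts <- sample(1:19900, n, replace = TRUE)
  reads <- setNames(substring(refs[src], starts, starts + 74),
                    sprintf("r%04d", 1:n))
  asg <- classify_reads(reads, idx)
  truth <- sub("ref", "Sp", src)
  expect_equal(asg$rank_species, truth)
  expect_error(classify_reads(setNames("ACGTACGT", "tiny"), idx), "larger than")
})

test_that("reads torn between two phyla get confidence 0.5 and are blanked", {
  set.seed(22)
  g <- random_sequence(5000)
  refs <- c(refA = g, refB = g) # identical genomes, different labels
  taxa <- data.frame(ref_id = c("refA", "refB"),
                     taxon_path = c("PhyA;ClsA;OrdA;FamA;GenA;SpA",
                                    "PhyB;ClsB;OrdB;FamB;GenB;SpB"),
                     stringsAsFactors = FALSE)
  idx <- build_taxon_index(refs, taxa, k = 12)
  r <- setNames(substr(g, 101, 175), "r1")
  asg <- classify_reads(r, idx)
  expect_equal(asg$conf_phylum, 0.5)
  out <- filter_by_confidence(asg, 0.7)
  expect_true(is.na(out$rank_phylum))
})

test_that("planted phylum proportions are recovered from classified reads", {
  spec <- community_spec(
    taxa = data.frame(taxon = c("PhyA", "PhyB", "PhyC"),
                      base_a = c(0.4, 0.35, 0.25), base_b = c(0.4, 0.35, 0.25),
                      sigma_a = 0, sigma_b = 0),
    genome_length = 20000L, reads_per_library = 10000L, error_rate = 0.01,
    seed = 23L)
  set.seed(spec$seed)
  refs <- make_reference_set(spec)
  out <- generate_reads(c(PhyA = 0.4, PhyB = 0.35, PhyC = 0.25), refs, spec)
  idx <- build_taxon_index(refs$genomes, refs$taxa, k = 12)
  asg <- classify_reads(out$reads, idx, ranks = "phylum")
  ra <- build_rank_abundance(asg, "phylum", mode = "fraction_excluding")
  expect_equal(unname(ra$counts[c("PhyA", "PhyB", "PhyC"), "sample1"]),
               c(0.4, 0.35, 0.25), tolerance = 0.02)
})
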