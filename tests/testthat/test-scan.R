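scan_refset <- function(seed = 21) {
  set.seed(seed)
  make_reference(c("zen", "pb", "Dfd"), n_species = 1)
}

test_that("an exactly planted homeodomain is recovered at its interval", {
  refset <- scan_refset()
  set.seed(22)
  zen <- refset$sequence[refset$family == "zen"]
  g <- plant_genome(zen, pos = 40000, len = 1e5)
  hits <- scan_genome(g, refset)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$score), ]
  expect_equal(c(best$start, best$end), c(40000, 40180))
  expect_equal(best$identity_pct, 100)
  expect_true(all(hits$evalue <= 1e-5))
})

test_that("a 20%-diverged domain is found with ~80% identity", {
  refset <- scan_refset()
  set.seed(23)
  zen <- refset$sequence[refset$family == "zen"]
  div <- mutate_interior(zen, 12)  # 12/60 = 20% substitution
  g <- plant_genome(div, pos = 51000, len = 1e5)
  hits <- scan_genome(g, refset)
  hits <- hits[hits$family == "zen", ]
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$score), ]
  expect_lt(best$start, 51180)
  expect_gt(best$end, 51000)
  expect_lt(abs(best$identity_pct - 80), 2.5)
})

test_that("random sequence yields no hits at 1e-5", {
  refset <- scan_refset()
  for (s in 1:3) {
    set.seed(100 + s)
    g <- stats::setNames(paste(sample(c("A", "C", "G", "T"), 1e5, TRUE),
                               collapse = ""), "rand")
    expect_equal(nrow(scan_genome(g, refset)), 0L)
  }
})

test_that("empty genome warns and returns an empty hit table", {
  expect_warning(h <- scan_genome(stats::setNames(character(0),
                                                  character(0)),
                                  scan_refset()),
                 "empty genome")
  expect_equal(nrow(h), 0L)
})

test_that("scanning the reverse-complemented genome mirrors the loci", {
  refset <- scan_refset()
  set.seed(24)
  zen <- refset$sequence[refset$family == "zen"]
  pb <- refset$sequence[refset$family == "pb"]
  g <- plant_genome(zen, pos = 20000, len = 8e4)
  bases <- strsplit(g[[1]], "")[[1]]
  dna2 <- homeoscan:::.reverse_translate(pb, 0.4)
  bases[59001:59180] <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dna2))), "")[[1]]
  g[1] <- paste(bases, collapse = "")
  loci <- merge_overlapping_hits(scan_genome(g, refset))
  g_rc <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g[[1]]))), names(g))
  loci_rc <- merge_overlapping_hits(scan_genome(g_rc, refset))
  L <- nchar(g[[1]])
  expect_equal(nrow(loci_rc), nrow(loci))
  m <- loci[order(-loci$start), ]
  expect_equal(loci_rc$start, L - m$end)
  expect_equal(loci_rc$end, L - m$start)
  expect_equal(loci_rc$strand, ifelse(m$strand == "+", "-", "+"))
  expect_equal(loci_rc$family, m$family)
  expect_equal(loci_rc$score, m$score)
})

test_that("overlapping hits merge by transitive closure", {
  # two disjoint hits stay two loci
  expect_equal(nrow(merge_overlapping_hits(mk_hits(c(100, 500),
                                                   c(280, 700)))), 2L)
  # longest match wins over higher score
  h <- mk_hits(c(100, 150), c(280, 300), score = c(90, 95))
  m <- merge_overlapping_hits(h)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end, m$score), c(100, 280, 90))
  expect_equal(c(m$region_start, m$region_end), c(100, 300))
  # chain A-B, B-C with A,C disjoint still forms one locus
  h3 <- mk_hits(c(100, 250, 400), c(300, 450, 600))
  m3 <- merge_overlapping_hits(h3)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$n_hits, 3L)
  # oracle: connected components of the interval overlap graph
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    s <- sample(0:2000, n)
    e <- s + sample(50:400, n, TRUE)
    adj <- outer(seq_len(n), seq_len(n),
                 function(i, j) s[i] < e[j] & s[j] < e[i])
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(nrow(merge_overlapping_hits(mk_hits(s, e))),
                 igraph::components(g)$no)
  }
})

test_that("merging already-merged loci is a no-op", {
  set.seed(31)
  s <- sample(0:5000, 15)
  h <- mk_hits(s, s + sample(100:500, 15, TRUE))
  m1 <- merge_overlapping_hits(h)
  m2 <- merge_overlapping_hits(m1)
  expect_equal(m2[, c("contig", "start", "end", "query_id")],
               m1[, c("contig", "start", "end", "query_id")])
})

test_that("flank rescan recovers a weak tandem copy missed at 1e-5", {
  # a full-strength domain plus, 600 bp away, a 16-residue fragment
  # confined by stop codons whose score sits between the strict and
  # permissive E-value cutoffs
  set.seed(33)
  frag16 <- paste(rep("T", 16), collapse = "")
  full <- paste0(frag16, random_peptide(44))
  rs <- reference_set("zen_1", "zen", "sp1", full)
  g <- plant_genome(full, pos = 30000, len = 1e5)
  bases <- strsplit(g[[1]], "")[[1]]
  frag_dna <- paste0("TAATAATAA", homeoscan:::.reverse_translate(frag16, 0.4),
                     "TAATAATAA")
  frag_pos <- 30180 + 600
  bases[(frag_pos + 1):(frag_pos + nchar(frag_dna))] <-
    strsplit(frag_dna, "")[[1]]
  g[1] <- paste(bases, collapse = "")
  hits <- scan_genome(g, rs)
  loci <- merge_overlapping_hits(hits)
  expect_equal(nrow(loci), 1L)  # fragment absent at 1e-5
  extra <- rescan_flanks(g, loci, rs, flank = 1000, evalue_max = 1e-3)
  expect_gte(nrow(extra), 1L)
  expect_true(any(extra$start >= frag_pos &
                    extra$end <= frag_pos + nchar(frag_dna)))
  loci2 <- merge_overlapping_hits(rbind(hits, extra))
  expect_equal(nrow(loci2), 2L)
})

test_that("flank rescan clamps at contig edges and no-ops without homology", {
  set.seed(34)
  rs <- reference_set("zen_1", "zen", "sp1", random_peptide(60))
  g <- plant_genome(rs$sequence, pos = 300, len = 3e4)
  loci <- merge_overlapping_hits(scan_genome(g, rs))
  expect_equal(loci$start, 300)
  extra <- rescan_flanks(g, loci, rs, flank = 1000)
  expect_true(all(extra$start >= 0))
  # no additional homology: second merge leaves the loci unchanged
  loci2 <- merge_overlapping_hits(rbind(
    scan_genome(g, rs), extra))
  expect_equal(loci2[, c("start", "end")], loci[, c("start", "end")])
})

test_that("seeded scan agrees with exhaustive DP on a small fixture", {
  refset <- scan_refset(seed = 35)
  set.seed(36)
  g <- plant_genome(mutate_interior(refset$sequence[1], 6), pos = 5000,
                    len = 2e4)
  fast <- scan_genome(g, refset)
  slow <- scan_genome(g, refset, exhaustive = TRUE)
  cols <- c("contig", "start", "end", "strand", "query_id", "score")
  expect_equal(fast[, cols], slow[, cols])
})
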