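# Independent oracles and fixture builders shared across tests.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(aa20, n, TRUE), collapse = "")

blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Brute-force optimal local alignment score: O(n*m*(n+m)) DP that tries
# every explicit gap length instead of the affine E/F recurrences.
bf_local_score <- function(q, t, gap_open = 11, gap_ext = 1) {
  S <- blosum62_matrix()
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(0, H[i, j] + S[qc[i], tc[j]])
      for (k in seq_len(i - 1)) {
        best <- max(best, H[i - k, j + 1] - gap_open - k * gap_ext)
      }
      for (k in seq_len(j - 1)) {
        best <- max(best, H[i + 1, j - k] - gap_open - k * gap_ext)
      }
      H[i + 1, j + 1] <- best
    }
  }
  max(H)
}

# Exact two-sided rank-sum p by full enumeration of rank assignments
# (tie-free inputs only), mirroring the U-statistic convention.
enum_wilcox <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  us <- apply(splits, 2, function(s) sum(s) - n * (n + 1) / 2)
  p <- if (u_obs > n * m / 2) mean(us >= u_obs) else mean(us <= u_obs)
  list(U = u_obs, p = min(1, 2 * p))
}

# Reverse-translate through the generator's internals so planted fixtures
# share the package's codon conventions.
plant_genome <- function(aa, pos, len = 1e5, strand = "+", gc = 0.4,
                         contig = "ctg") {
  bases <- sample(c("A", "C", "G", "T"), len, TRUE)
  dna <- homeoscan:::.reverse_translate(aa, gc)
  if (strand == "-") {
    dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
  }
  bases[(pos + 1):(pos + nchar(dna))] <- strsplit(dna, "")[[1]]
  stats::setNames(paste(bases, collapse = ""), contig)
}

# Minimal raw-hit table for merge logic tests.
mk_hits <- function(start, end, score = 50, query_id = paste0("q", seq_along(start)),
                    contig = "ctg", strand = "+", family = "zen") {
  df <- data.frame(contig = contig, start = as.integer(start),
                   end = as.integer(end), strand = strand, frame = 0L,
                   query_id = query_id, family = family,
                   score = as.integer(score),
                   bitscore = score * 0.4, evalue = 1e-10,
                   identity_pct = 90, q_start = 0L,
                   q_end = as.integer(end - start) %/% 3L,
                   aa = "M", stringsAsFactors = FALSE)
  class(df) <- c("homeobox_hits", "data.frame")
  df
}

# Minimal classified-loci table for cluster-architecture tests.
mk_classified <- function(family, start, end = start + 180L,
                          strand = "+", contig = "chr1",
                          status = "ASSIGNED") {
  n <- length(family)
  df <- data.frame(
    locus_id = sprintf("%s:%d-%d", rep(contig, length.out = n), start, end),
    contig = rep(contig, length.out = n), start = as.integer(start),
    end = as.integer(end), strand = rep(strand, length.out = n),
    forward_family = family, reverse_family = family,
    identity_pct = rep(95, n), status = rep(status, length.out = n),
    family = family, aa = rep("M", n), stringsAsFactors = FALSE)
  df$family[df$status != "ASSIGNED"] <- NA
  class(df) <- c("classified_loci", "data.frame")
  df
}

mk_repeat_annotation <- function(df) {
  df$name <- if (is.null(df$name)) df$te_class else df$name
  if (is.null(df$strand)) df$strand <- "+"
  class(df) <- c("repeat_annotation", "data.frame")
  df
}

# Substitute exactly k interior positions (never the two terminal residues)
# so the local alignment cannot trim the ends.
mutate_interior <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(2:(length(ch) - 1), k)
  for (p in pos) ch[p] <- sample(setdiff(aa20, ch[p]), 1)
  paste(ch, collapse = "")
}
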