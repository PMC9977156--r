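rm_out_fixture <- function(rows) {
  path <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin  end (left)   ID",
    "", rows), path)
  path
}

test_that("RepeatMasker .out rows parse with class prefixes and strand", {
  path <- rm_out_fixture(c(
    "  463  15.4  1.2  0.9  chr_hox   1001  1300  (5000)  +  CR1-1   LINE/CR1     1  300  (0)   1",
    "  210  20.0  0.0  0.0  chr_hox   2001  2040  (4000)  C  tRNA-x  SINE/tRNA    1   40  (0)   2",
    "  180  11.0  0.0  0.0  chr_hox   3001  3200  (3000)  +  (AT)n   Simple_repeat 1 200  (0)   3"))
  expect_message(rep_ <- load_repeats(path), "dropped 1")
  expect_equal(nrow(rep_), 2L)  # the 40-bp SINE is below the length filter
  expect_equal(attr(rep_, "n_dropped"), 1L)
  line <- rep_[rep_$te_class == "LINE", ]
  expect_equal(c(line$start, line$end), c(1000L, 1300L))
  expect_equal(line$strand, "+")
  expect_equal(rep_$te_class[rep_$name == "(AT)n"], "other")
})

test_that("BED repeat annotations parse and filter by length", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr_hox\t100\t600\tLINE/CR1\t0\t+",
               "chr_hox\t700\t740\tLTR/Gypsy\t0\t-",
               "chr_hox\t900\t1400\tDNA/hAT\t0\t-"), path)
  expect_message(rep_ <- load_repeats(path), "dropped 1")
  expect_equal(nrow(rep_), 2L)
  expect_setequal(rep_$te_class, c("LINE", "DNA"))
  bad <- tempfile()
  writeLines("not an annotation at all", bad)
  expect_error(load_repeats(bad), "unrecognized")
})

test_that("window densities tile, merge coverage, and keep half-windows", {
  reps <- mk_repeat_annotation(data.frame(
    contig = "c", start = c(10000L, 100L, 400L),
    end = c(15000L, 600L, 900L),
    te_class = c("LINE", "LINE", "LINE"), stringsAsFactors = FALSE))
  # one 5-kb LINE exactly covering window index 3 (0-based 2)
  d <- window_density(reps, c(0, 25000), "LINE")
  expect_length(d, 5L)
  expect_equal(d[3], 1.0)
  # two overlapping LINEs union to 800 bp in window 1
  expect_equal(d[1], 800 / 5000)
  # no repeats of a class: all-zero vector
  expect_true(all(window_density(reps, c(0, 25000), "SINE") == 0))
  # terminal 3-kb window is kept with its own width as denominator
  reps2 <- mk_repeat_annotation(data.frame(
    contig = "c", start = 10000L, end = 13000L, te_class = "LINE",
    stringsAsFactors = FALSE))
  d2 <- window_density(reps2, c(0, 13000), "LINE")
  expect_length(d2, 3L)
  expect_equal(d2[3], 1.0)
  # a sub-half-window terminal is dropped
  expect_length(window_density(reps2, c(0, 12000), "LINE"), 2L)
  expect_error(window_density(reps2, c(0, 2000), "LINE"), "shorter")
})

test_that("density times width conserves merged coverage", {
  set.seed(60)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    s <- sample(0:90000, n)
    reps <- mk_repeat_annotation(data.frame(
      contig = "c", start = s, end = s + sample(60:4000, n, TRUE),
      te_class = "LINE", stringsAsFactors = FALSE))
    region <- c(0, 100000)
    d <- window_density(reps, region, "LINE")
    w <- attr(d, "windows")
    ir <- IRanges::reduce(IRanges::IRanges(reps$start + 1L, reps$end))
    clip <- IRanges::restrict(ir, region[1] + 1L, region[2])
    expect_equal(sum(d * (w$end - w$start)), sum(IRanges::width(clip)))
  }
})

test_that("rank-sum p-values are exact where claimed and sane elsewhere", {
  # identical samples: no shift signal
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # fully separated minimal case: exact two-sided p = 2/20
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  expect_equal(w$p, 0.1)
  # strong shift at n = 50: far beyond any exact regime
  set.seed(61)
  x <- rnorm(50); y <- rnorm(50, mean = 2)
  expect_lt(wilcoxon_rank_sum(x, y)$p, 1e-6)
})

test_that("exact p equals full rank enumeration for tie-free small splits", {
  for (n in 1:4) {
    for (m in n:(10 - n)) {
      vals <- seq_len(n + m)
      splits <- utils::combn(n + m, n)
      for (col in seq_len(ncol(splits))) {
        x <- vals[splits[, col]]
        y <- vals[-splits[, col]]
        got <- wilcoxon_rank_sum(x, y)
        want <- enum_wilcox(x, y)
        expect_equal(got$U, want$U)
        expect_equal(got$p, want$p)
      }
    }
  }
})

shx_arch_fixture <- function(n_shx_windows = 20, n_rest_windows = 100) {
  # Shx region on the pb side, cluster tiled from the ro edge
  shx_len <- n_shx_windows * 5000L
  total <- (n_shx_windows + n_rest_windows) * 5000L
  fams <- c("ro", "pb", "ShxA", "ShxD", "zen", "Abd-B")
  starts <- c(0L, 6000L, 12000L, shx_len + 11820L, shx_len + 20000L,
              total - 180L)
  build_cluster(mk_classified(fams, starts, contig = "chr_hox"), "HOX")
}

sample_class_repeats <- function(contig, lo, hi, cov, cls,
                                 len_range = c(80, 400)) {
  n <- rpois(1, cov * (hi - lo) / mean(len_range))
  if (n == 0) return(NULL)
  l <- as.integer(round(runif(n, len_range[1], len_range[2])))
  s <- as.integer(floor(runif(n, lo, hi - l)))
  data.frame(contig = contig, start = s, end = s + l, te_class = cls,
             name = cls, strand = "+", stringsAsFactors = FALSE)
}

test_that("tripled LINE coverage in the Shx region is called enriched", {
  set.seed(62)
  arch <- shx_arch_fixture()
  sct <- shx_copy_table(arch)
  rr <- list()
  for (cls in c("LINE", "SINE", "LTR", "DNA")) {
    cov <- if (cls == "LINE") 0.05 else 0.02
    rr[[cls]] <- sample_class_repeats("chr_hox", 0, 600000, cov, cls)
    if (cls == "LINE") {
      rr$LINE_extra <- sample_class_repeats("chr_hox", sct$shx_region[1],
                                            sct$shx_region[2], 0.10, cls)
    }
  }
  reps <- mk_repeat_annotation(do.call(rbind, rr))
  enr <- shx_enrichment(reps, arch)
  expect_s3_class(enr, "enrichment_result")
  expect_equal(enr$n_shx[1] + enr$n_rest[1], 120L)
  expect_true(enr$enriched[enr$te_class == "LINE"])
  expect_false(any(enr$enriched[enr$te_class != "LINE"]))
  expect_equal(enr$p_bonferroni, pmin(1, enr$p_raw * 4))
})

test_that("uniform landscapes and depletion are not called enriched", {
  set.seed(63)
  arch <- shx_arch_fixture()
  flat <- mk_repeat_annotation(do.call(rbind, lapply(
    c("LINE", "SINE", "LTR", "DNA"), function(cls) {
      sample_class_repeats("chr_hox", 0, 600000, 0.04, cls)
    })))
  enr <- shx_enrichment(flat, arch)
  expect_false(any(enr$enriched))
  # strong SINE depletion in the Shx region: significant but not enriched
  sct <- shx_copy_table(arch)
  dep <- rbind(
    sample_class_repeats("chr_hox", sct$shx_region[2], 600000, 0.25,
                         "SINE"),
    sample_class_repeats("chr_hox", 0, 600000, 0.03, "LINE"))
  enr2 <- shx_enrichment(mk_repeat_annotation(dep), arch)
  sine <- enr2[enr2$te_class == "SINE", ]
  expect_lt(sine$p_bonferroni, 0.05)
  expect_lt(sine$median_shx, sine$median_rest)
  expect_false(sine$enriched)
})

test_that("enrichment requires a defined Shx region", {
  arch <- build_cluster(mk_classified(c("ro", "pb", "zen", "Abd-B"),
                                      seq(0, by = 50000L, length.out = 4),
                                      contig = "chr_hox"), "HOX")
  reps <- mk_repeat_annotation(data.frame(
    contig = "chr_hox", start = 0L, end = 500L, te_class = "LINE",
    stringsAsFactors = FALSE))
  expect_error(shx_enrichment(reps, arch), "Shx region undefined")
})
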