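# classified table laid out in canonical lepidopteran Hox order with lab
# displaced beyond Abd-B
canonical_hox_classified <- function(gap = 50000L, lab_offset = 7e6,
                                     contig = "chr1") {
  fams <- canonical_orders()$LEP_HOX
  starts <- seq(10000L, by = gap, length.out = length(fams))
  abdb_end <- starts[length(fams)] + 180L
  mk_classified(c(fams, "lab"), c(starts, as.integer(abdb_end + lab_offset)),
                contig = contig)
}

test_that("a canonical genome reconstructs the Hox architecture", {
  cl <- canonical_hox_classified()
  arch <- build_cluster(cl, "HOX")
  expect_equal(arch$members$family, canonical_orders()$LEP_HOX)
  expect_equal(arch$external_members$family, "lab")
  expect_equal(length(arch$intergenic_bp), nrow(arch$members) - 1L)
  # span = last end - first start, lab excluded
  expect_equal(arch$span_bp, 13L * 50000L + 180L)
  rep_ <- detect_rearrangements(arch)
  expect_equal(nrow(rep_$broken_adjacencies), 0L)
  expect_equal(rep_$translocated, "lab")
})

test_that("member loci split across contigs resolve to the modal contig", {
  fams <- canonical_orders()$LEP_HOX
  cl <- rbind(mk_classified(fams[1:10], seq(0, by = 5e4, length.out = 10),
                            contig = "chrA"),
              mk_classified(fams[11:13], seq(0, by = 5e4, length.out = 3),
                            contig = "chrB"))
  class(cl) <- c("classified_loci", "data.frame")
  arch <- build_cluster(cl, "HOX")
  expect_equal(arch$contig, "chrA")
  expect_equal(nrow(arch$members), 10L)
  expect_setequal(arch$external_members$family, fams[11:13])
})

test_that("single-member and empty clusters degrade gracefully", {
  arch1 <- build_cluster(mk_classified("Antp", 1000L), "HOX")
  expect_equal(arch1$span_bp, 180L)
  expect_length(arch1$intergenic_bp, 0L)
  expect_warning(arch0 <- build_cluster(mk_classified(character(0),
                                                      integer(0)), "HOX"),
                 "no assigned loci")
  expect_equal(nrow(arch0$members), 0L)
})

test_that("hox span is the outermost Abd-B to ro distance", {
  cl <- mk_classified(c("ro", "Abd-B"), c(0L, 1219000L),
                      end = c(1000L, 1220000L))
  expect_equal(hox_span(build_cluster(cl, "HOX")), 1220000L)
  # mirror the contig: the span is orientation-invariant
  C <- 2e6L
  cl_m <- mk_classified(c("Abd-B", "ro"), C - c(1220000L, 1000L),
                        end = C - c(1219000L, 0L), strand = "-")
  expect_equal(hox_span(build_cluster(cl_m, "HOX")), 1220000L)
  expect_error(hox_span(build_cluster(mk_classified("Abd-B", 0L), "HOX")),
               "ro missing")
})

test_that("span and gaps are invariant under shift and reflection", {
  set.seed(50)
  fams <- c("pb", "zen", "Dfd", "Scr")
  starts <- cumsum(c(5000L, sample(2000:40000, 3)))
  arch <- build_cluster(mk_classified(fams, starts), "HOX")
  shift <- build_cluster(mk_classified(fams, starts + 77777L), "HOX")
  C <- 1e6L
  refl <- build_cluster(mk_classified(rev(fams), C - rev(starts + 180L),
                                      end = C - rev(starts)), "HOX")
  expect_equal(shift$span_bp, arch$span_bp)
  expect_equal(refl$span_bp, arch$span_bp)
  expect_equal(shift$intergenic_bp, arch$intergenic_bp)
  expect_equal(refl$intergenic_bp, rev(arch$intergenic_bp))
  # conservation: gaps plus gene bodies tile the span exactly
  expect_equal(sum(arch$intergenic_bp) + nrow(arch$members) * 180L,
               arch$span_bp)
})

test_that("Shx copy table counts singletons, arrays and the region", {
  cl4 <- canonical_hox_classified()
  sct <- shx_copy_table(build_cluster(cl4, "HOX"))
  expect_equal(unname(sct$counts), rep(1L, 4))
  expect_true(all(sct$arrays$n == 1L))
  m <- build_cluster(cl4, "HOX")$members
  shx <- m[m$family %in% c("ShxA", "ShxB", "ShxC", "ShxD"), ]
  expect_equal(sct$shx_region, c(min(shx$start), max(shx$end)))

  # 25-copy tandem ShxA array: one run of 25
  fams <- c("ro", "pb", rep("ShxA", 25), "ShxB", "ShxC", "ShxD", "zen",
            "Abd-B")
  cl25 <- mk_classified(fams, seq(0, by = 4000L, length.out = length(fams)))
  sct25 <- shx_copy_table(build_cluster(cl25, "HOX"))
  expect_equal(unname(sct25$counts["ShxA"]), 25L)
  expect_equal(sct25$arrays$n[sct25$arrays$family == "ShxA"], 25L)

  # no Shx at all: empty table, undefined region
  cl0 <- mk_classified(c("ro", "pb", "zen", "Abd-B"),
                       seq(0, by = 4000L, length.out = 4))
  sct0 <- shx_copy_table(build_cluster(cl0, "HOX"))
  expect_true(all(sct0$counts == 0L))
  expect_null(sct0$shx_region)
})

test_that("relocating ro breaks the ro-pb adjacency", {
  fams <- canonical_orders()$LEP_HOX
  inner <- setdiff(fams, "ro")
  starts <- seq(10000L, by = 50000L, length.out = length(inner))
  # ro moved beyond Abd-B (between Abd-B and the distant lab)
  cl <- mk_classified(c(inner, "ro", "lab"),
                      c(starts, starts[length(inner)] + 300000L, 8e6L))
  rep_ <- detect_rearrangements(build_cluster(cl, "HOX"))
  expect_equal(nrow(rep_$broken_adjacencies), 1L)
  expect_equal(sort(unlist(rep_$broken_adjacencies[1, ])),
               sort(c("ro", "pb")), ignore_attr = TRUE)
})

test_that("moving the NK slou/Hmx/ems block breaks the Lbx-NK1 boundary", {
  canon <- unique(canonical_orders()$NK)
  moved <- c("NK1", "Hmx", "Emx", "Tlx", "Msx", "NK4", "NK3", "Lbx")
  cl <- mk_classified(moved, seq(0, by = 40000L, length.out = length(moved)))
  rep_ <- detect_rearrangements(build_cluster(cl, "NK"), canon)
  expect_equal(nrow(rep_$broken_adjacencies), 1L)
  expect_equal(sort(unlist(rep_$broken_adjacencies[1, ])),
               sort(c("Lbx", "NK1")), ignore_attr = TRUE)
})

test_that("k adjacent transpositions break between 1 and 2k adjacencies", {
  canon <- unique(canonical_orders()$NK)
  set.seed(51)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    ord <- canon
    for (i in seq_len(k)) {
      j <- sample(length(ord) - 1L, 1)
      ord[c(j, j + 1L)] <- ord[c(j + 1L, j)]
    }
    cl <- mk_classified(ord, seq(0, by = 30000L, length.out = length(ord)))
    rep_ <- detect_rearrangements(build_cluster(cl, "NK"), canon)
    # independent oracle: direct adjacency-set difference
    pairs <- function(o) paste(pmin(o[-length(o)], o[-1]),
                               pmax(o[-length(o)], o[-1]))
    oracle <- sum(!(pairs(canon) %in% pairs(ord)))
    expect_equal(nrow(rep_$broken_adjacencies), oracle)
    if (!identical(ord, canon)) {
      expect_gte(oracle, 1L)
    }
    expect_lte(oracle, 2L * k)
  }
})

test_that("hbn-Rx-otp order is canonical forwards and mirrored", {
  starts <- c(0L, 170000L, 347820L)
  arch <- prd_trio(mk_classified(c("hbn", "Rx", "otp"), starts))
  expect_true(arch$canonical_order)
  expect_equal(arch$span_bp, 348000L)
  # exact reverse order is the mirrored, still-canonical arrangement
  arch_rev <- prd_trio(mk_classified(c("otp", "Rx", "hbn"), starts))
  expect_true(arch_rev$canonical_order)
  # a shuffled order is flagged
  arch_bad <- prd_trio(mk_classified(c("hbn", "otp", "Rx"), starts))
  expect_false(arch_bad$canonical_order)
})
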