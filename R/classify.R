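#' Reciprocally classify a candidate locus
#'
#' The translated locus sequence is aligned back against every reference
#' homeodomain (the reciprocal search).  The locus is ASSIGNED to a family
#' only when the best reverse hit's family agrees with the forward query's
#' family and the reverse alignment identity is strictly greater than the
#' threshold; otherwise it is flagged DIVERGENT_UNCLASSIFIED, retaining
#' both candidate families.  Ties in the reverse search are broken by
#' score, then reference id, so classification is order-independent.
#'
#' @param aa translated peptide of the locus (representative hit match).
#' @param forward_family family of the best forward query for this locus.
#' @param refset a [reference_set()].
#' @param identity_min identity threshold in percent; assignment requires
#'   identity strictly greater (default 70).
#' @return A list: `forward_family`, `reverse_family`, `identity_pct`,
#'   `status` (`"ASSIGNED"` or `"DIVERGENT_UNCLASSIFIED"`), `family`
#'   (assigned family or `NA`).
#' @export
reciprocal_classify <- function(aa, forward_family, refset,
                                identity_min = 70) {
  stopifnot(inherits(refset, "reference_set"))
  if (nrow(refset) == 0L) stop("reference set is empty")
  best <- NULL
  for (i in order(refset$id)) {
    al <- local_align(aa, refset$sequence[i])
    if (is.null(best) || al$score > best$score) {
      best <- list(score = al$score, family = refset$family[i],
                   identity = al$identity_pct)
    }
  }
  assigned <- identical(best$family, forward_family) &&
    !is.na(best$identity) && best$identity > identity_min
  list(forward_family = forward_family,
       reverse_family = best$family,
       identity_pct = best$identity,
       status = if (assigned) "ASSIGNED" else "DIVERGENT_UNCLASSIFIED",
       family = if (assigned) best$family else NA_character_)
}

#' Classify all candidate loci
#'
#' Applies [reciprocal_classify()] to every locus.
#'
#' @param loci `homeobox_loci` from [merge_overlapping_hits()].
#' @param refset a [reference_set()].
#' @param identity_min identity threshold (percent, strict; default 70).
#' @return A `classified_loci` data.frame: locus coordinates and strand
#'   plus `forward_family`, `reverse_family`, `identity_pct`, `status`,
#'   `family`, and the translated sequence `aa`.
#' @export
classify_loci <- function(loci, refset, identity_min = 70) {
  res <- lapply(seq_len(nrow(loci)), function(i) {
    cl <- reciprocal_classify(loci$aa[i], loci$family[i], refset,
                              identity_min = identity_min)
    data.frame(locus_id = loci$locus_id[i], contig = loci$contig[i],
               start = loci$start[i], end = loci$end[i],
               strand = loci$strand[i],
               forward_family = cl$forward_family,
               reverse_family = cl$reverse_family,
               identity_pct = cl$identity_pct, status = cl$status,
               family = cl$family, aa = loci$aa[i],
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(locus_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               forward_family = character(), reverse_family = character(),
               identity_pct = numeric(), status = character(),
               family = character(), aa = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("classified_loci", "data.frame")
  out
}

#' Export divergent loci for external phylogenetics
#'
#' Writes all DIVERGENT_UNCLASSIFIED peptide sequences to a protein FASTA
#' with provenance headers (`contig:start-end`, candidate families), for
#' tree-based identification outside this package.
#'
#' @param classified a `classified_loci` data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.  An empty divergent set writes an empty file.
#' @export
export_divergent <- function(classified, path) {
  div <- classified[classified$status == "DIVERGENT_UNCLASSIFIED", ,
                    drop = FALSE]
  aa <- Biostrings::AAStringSet(div$aa)
  names(aa) <- sprintf("%s:%d-%d fwd=%s rev=%s identity=%.1f",
                       div$contig, div$start, div$end, div$forward_family,
                       div$reverse_family, div$identity_pct)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Census of classified homeobox loci
#'
#' Counts assigned loci per family and per homeodomain class, with the
#' grand total of all loci (assigned plus divergent), the Shx total
#' (sum over ShxA-D) and the zen/Shx total (Shx plus zen copies).  The
#' census counts loci, which may include functional genes, partial genes
#' and pseudogenes.
#'
#' @param classified a `classified_loci` data.frame.
#' @return A `homeobox_census` list with `by_family` (family, hclass, n),
#'   `by_class`, `total`, `n_divergent`, `shx_total`, `zen_shx_total`.
#' @export
census <- function(classified) {
  cat_tab <- homeobox_families()
  fam <- classified$family[classified$status == "ASSIGNED"]
  n <- vapply(cat_tab$family, function(f) sum(fam == f), integer(1))
  by_family <- data.frame(family = cat_tab$family, hclass = cat_tab$hclass,
                          n = as.integer(n), stringsAsFactors = FALSE)
  by_class <- aggregate(n ~ hclass, data = by_family, FUN = sum)
  shx_total <- sum(by_family$n[cat_tab$is_shx])
  out <- list(by_family = by_family, by_class = by_class,
              total = nrow(classified),
              n_assigned = sum(classified$status == "ASSIGNED"),
              n_divergent = sum(classified$status ==
                                  "DIVERGENT_UNCLASSIFIED"),
              shx_total = shx_total,
              zen_shx_total = shx_total +
                by_family$n[by_family$family == "zen"])
  class(out) <- "homeobox_census"
  out
}

#' @export
print.homeobox_census <- function(x, ...) {
  cat("Homeobox census:", x$total, "loci (", x$n_assigned, "assigned,",
      x$n_divergent, "divergent )\n")
  cat("Shx total:", x$shx_total, " zen/Shx total:", x$zen_shx_total, "\n")
  nz <- x$by_family[x$by_family$n > 0, , drop = FALSE]
  if (nrow(nz)) print(nz, row.names = FALSE)
  invisible(x)
}
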