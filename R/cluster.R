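.cluster_families <- function(cluster_name) {
  co <- canonical_orders()
  switch(cluster_name,
    # architecture members: the 13 in-cluster Hox families plus ro;
    # lab is handled separately (external unless found inside the cluster)
    HOX = unique(co$LEP_HOX),
    NK = unique(co$NK),
    PRD_TRIO = co$PRD_TRIO,
    stop("unknown cluster name: ", cluster_name))
}

.empty_members <- function() {
  data.frame(family = character(), locus_id = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Reconstruct the architecture of a gene cluster
#'
#' Collects ASSIGNED loci of the cluster's member families, picks the modal
#' contig (the contig holding the most member loci), orders members by
#' start coordinate, and computes the cluster span and intergenic gaps.
#' Member loci on other contigs are reported as external.  For the Hox
#' cluster, `lab` is included as a member only when it lies between the
#' outermost cluster members on the modal contig; otherwise it is reported
#' in `external_members` (the usual lepidopteran state, with `lab`
#' relocated far beyond `Abd-B`).  The span always excludes `lab`.
#'
#' @param classified a `classified_loci` data.frame from [classify_loci()].
#' @param cluster_name one of `"HOX"`, `"NK"`, `"PRD_TRIO"`.
#' @return A `cluster_architecture` object: list with `cluster_name`,
#'   `contig`, `members` (ordered data.frame: family, locus_id, contig,
#'   start, end, strand), `span_bp`, `intergenic_bp` (length = members - 1),
#'   `external_members`.
#' @export
build_cluster <- function(classified,
                          cluster_name = c("HOX", "NK", "PRD_TRIO")) {
  cluster_name <- match.arg(cluster_name)
  fams <- .cluster_families(cluster_name)
  asg <- classified[classified$status == "ASSIGNED", , drop = FALSE]
  mem_all <- asg[asg$family %in% fams, , drop = FALSE]
  cols <- c("family", "locus_id", "contig", "start", "end", "strand")
  if (nrow(mem_all) == 0L) {
    warning("no assigned loci for cluster ", cluster_name)
    arch <- list(cluster_name = cluster_name, contig = NA_character_,
                 members = .empty_members(), span_bp = NA_integer_,
                 intergenic_bp = integer(0),
                 external_members = .empty_members())
    class(arch) <- "cluster_architecture"
    return(arch)
  }
  modal <- names(which.max(table(mem_all$contig)))
  members <- mem_all[mem_all$contig == modal, cols, drop = FALSE]
  external <- mem_all[mem_all$contig != modal, cols, drop = FALSE]
  members <- members[order(members$start), , drop = FALSE]
  if (cluster_name == "HOX") {
    lab <- asg[asg$family == "lab", cols, drop = FALSE]
    if (nrow(lab) > 0L && nrow(members) > 0L) {
      inside <- lab$contig == modal &
        lab$start >= min(members$start) & lab$end <= max(members$end)
      members <- rbind(members, lab[inside, , drop = FALSE])
      members <- members[order(members$start), , drop = FALSE]
      external <- rbind(external, lab[!inside, , drop = FALSE])
    }
  }
  rownames(members) <- rownames(external) <- NULL
  core <- members[members$family != "lab", , drop = FALSE]
  span <- if (nrow(core)) max(core$end) - min(core$start) else NA_integer_
  gaps <- if (nrow(core) > 1L) {
    pmax(0L, core$start[-1] - core$end[-nrow(core)])
  } else integer(0)
  arch <- list(cluster_name = cluster_name, contig = modal,
               members = members, span_bp = as.integer(span),
               intergenic_bp = as.integer(gaps),
               external_members = external)
  class(arch) <- "cluster_architecture"
  arch
}

#' @export
print.cluster_architecture <- function(x, ...) {
  cat(x$cluster_name, "cluster on", x$contig, ":", nrow(x$members),
      "members, span", x$span_bp, "bp,", nrow(x$external_members),
      "external\n")
  if (nrow(x$members)) {
    cat(paste(x$members$family, collapse = " - "), "\n")
  }
  invisible(x)
}

#' Hox cluster span from Abd-B to ro
#'
#' Unsigned distance between the outermost coordinates of the `Abd-B` and
#' `ro` genes, inclusive of both gene bodies (orientation-invariant).
#'
#' @param arch a HOX `cluster_architecture`.
#' @return Span in bp.
#' @export
hox_span <- function(arch) {
  stopifnot(inherits(arch, "cluster_architecture"))
  for (f in c("Abd-B", "ro")) {
    if (!f %in% arch$members$family) {
      stop("endpoint family ", f, " missing")
    }
  }
  ends <- arch$members[arch$members$family %in% c("Abd-B", "ro"), ,
                       drop = FALSE]
  as.integer(max(ends$end) - min(ends$start))
}

#' Shx copy counts and tandem arrays
#'
#' Counts loci per Shx family and reports maximal runs of consecutive
#' same-family loci (tandem arrays) with their genomic extent, plus the
#' Shx region (first-to-last Shx coordinate on the cluster contig).
#'
#' @param arch a HOX `cluster_architecture`.
#' @return A `shx_copy_table`: list with `counts` (named integer, ShxA-D),
#'   `arrays` (data.frame family, n, start, end), and `shx_region`
#'   (`c(start, end)` or `NULL` when no Shx locus is present).
#' @export
shx_copy_table <- function(arch) {
  stopifnot(inherits(arch, "cluster_architecture"))
  shx_fams <- c("ShxA", "ShxB", "ShxC", "ShxD")
  m <- arch$members
  counts <- vapply(shx_fams, function(f) sum(m$family == f), integer(1))
  is_shx <- m$family %in% shx_fams
  arrays <- data.frame(family = character(), n = integer(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  if (any(is_shx)) {
    r <- rle(m$family)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    keep <- r$values %in% shx_fams
    arrays <- data.frame(family = r$values[keep],
                         n = r$lengths[keep],
                         start = m$start[lo[keep]],
                         end = m$end[hi[keep]],
                         stringsAsFactors = FALSE)
    region <- c(min(m$start[is_shx]), max(m$end[is_shx]))
  } else {
    region <- NULL
  }
  out <- list(counts = counts, arrays = arrays, shx_region = region)
  class(out) <- "shx_copy_table"
  out
}

#' @export
print.shx_copy_table <- function(x, ...) {
  cat("Shx copies:", paste(names(x$counts), x$counts, sep = "=",
                           collapse = " "), "\n")
  if (nrow(x$arrays)) {
    runs <- x$arrays[x$arrays$n > 1, , drop = FALSE]
    if (nrow(runs)) {
      cat("Tandem arrays:\n"); print(runs, row.names = FALSE)
    }
  }
  invisible(x)
}

# For order comparison each multi-copy family collapses to one block,
# anchored at the copy closest to a locus of one of its canonical
# neighbours (first copy when no neighbour is present).
.anchor_positions <- function(members, canonical) {
  fams <- unique(members$family)
  pos <- numeric(length(fams))
  names(pos) <- fams
  canon <- unique(canonical)
  for (f in fams) {
    copies <- members[members$family == f, , drop = FALSE]
    if (nrow(copies) == 1L) { pos[f] <- copies$start; next }
    i <- match(f, canon)
    nb <- canon[c(i - 1L, i + 1L)]
    nb <- nb[!is.na(nb)]
    nb_loci <- members[members$family %in% nb, , drop = FALSE]
    if (nrow(nb_loci) == 0L) { pos[f] <- copies$start[1]; next }
    mid_nb <- (nb_loci$start + nb_loci$end) / 2
    mid_cp <- (copies$start + copies$end) / 2
    d <- vapply(mid_cp, function(m) min(abs(m - mid_nb)), numeric(1))
    pos[f] <- copies$start[which.min(d)]
  }
  pos
}

.adjacency_pairs <- function(ord) {
  if (length(ord) < 2L) {
    return(data.frame(family1 = character(), family2 = character(),
                      stringsAsFactors = FALSE))
  }
  a <- ord[-length(ord)]
  b <- ord[-1]
  data.frame(family1 = pmin(a, b), family2 = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' Detect rearrangements relative to a canonical order
#'
#' Compares the observed family order (multi-copy families collapsed to one
#' block) against a canonical order restricted to the families actually
#' present, and reports canonical neighbour pairs that are no longer
#' adjacent, per-gene orientation flips relative to the majority
#' orientation, and families found on a different contig.  No minimal
#' event scenario is computed.
#'
#' @param arch a `cluster_architecture`.
#' @param canonical character vector giving the canonical family order
#'   (defaults to the order for `arch$cluster_name` from
#'   [canonical_orders()]).
#' @return A `rearrangement_report`: list with `observed_order`,
#'   `broken_adjacencies` (data.frame family1/family2),
#'   `orientation_flips` (families on the minority strand), `translocated`
#'   (external families), `shx_region`.
#' @export
detect_rearrangements <- function(arch, canonical = NULL) {
  stopifnot(inherits(arch, "cluster_architecture"))
  if (is.null(canonical)) {
    canonical <- switch(arch$cluster_name,
                        HOX = canonical_orders()$LEP_HOX,
                        NK = canonical_orders()$NK,
                        PRD_TRIO = canonical_orders()$PRD_TRIO)
  }
  m <- arch$members[arch$members$family %in% canonical, , drop = FALSE]
  anchors <- .anchor_positions(m, canonical)
  observed <- names(sort(anchors))
  canon_present <- unique(canonical)[unique(canonical) %in% observed]
  canon_adj <- .adjacency_pairs(canon_present)
  obs_adj <- .adjacency_pairs(observed)
  obs_key <- paste(obs_adj$family1, obs_adj$family2)
  broken <- canon_adj[!(paste(canon_adj$family1, canon_adj$family2) %in%
                          obs_key), , drop = FALSE]
  rownames(broken) <- NULL
  flips <- character(0)
  if (nrow(m)) {
    maj <- names(which.max(table(m$strand)))
    flips <- unique(m$family[m$strand != maj])
  }
  shx <- m[m$family %in% c("ShxA", "ShxB", "ShxC", "ShxD"), , drop = FALSE]
  report <- list(
    observed_order = observed,
    broken_adjacencies = broken,
    orientation_flips = flips,
    translocated = unique(arch$external_members$family),
    shx_region = if (nrow(shx)) c(min(shx$start), max(shx$end)) else NULL)
  class(report) <- "rearrangement_report"
  report
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat("Observed order:", paste(x$observed_order, collapse = " - "), "\n")
  cat("Broken adjacencies:", nrow(x$broken_adjacencies), "\n")
  if (nrow(x$broken_adjacencies)) print(x$broken_adjacencies,
                                        row.names = FALSE)
  if (length(x$orientation_flips)) {
    cat("Orientation flips:", paste(x$orientation_flips, collapse = ", "),
        "\n")
  }
  if (length(x$translocated)) {
    cat("Translocated:", paste(x$translocated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Architecture of the hbn-Rx-otp trio
#'
#' Builds the PRD-class `hbn`-`Rx`-`otp` cluster architecture and checks
#' whether the observed gene order is canonical (`hbn`, `Rx`, `otp`, or its
#' exact mirror).
#'
#' @param classified a `classified_loci` data.frame.
#' @return A `cluster_architecture` with an extra logical element
#'   `canonical_order`.
#' @export
prd_trio <- function(classified) {
  arch <- build_cluster(classified, "PRD_TRIO")
  ord <- arch$members$family
  canon <- canonical_orders()$PRD_TRIO
  arch$canonical_order <- identical(ord, canon) ||
    identical(ord, rev(canon))
  arch
}
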