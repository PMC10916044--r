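# Genomic-context annotation of probe target positions.
#
# Positions are 1-based cytosine coordinates; overlap uses closed
# containment of the point after conversion to interval space
# (GenomicRanges). Feature BEDs are 0-based half-open and converted at
# the boundary by rtracklayer.

positions_to_granges <- function(positions) {
  stopifnot(all(c("chrom", "mapinfo") %in% names(positions)))
  GenomicRanges::GRanges(
    seqnames = positions$chrom,
    ranges = IRanges::IRanges(start = positions$mapinfo,
                              end = positions$mapinfo))
}

#' Assign genic context (TSS / gene body / intergenic)
#'
#' Classifies each position against transcript models with precedence
#' TSS > gene body > intergenic. The TSS window is strand-aware:
#' `[-tss_upstream, +tss_downstream]` around each transcript start
#' (defaults -1500/+500, a common convention; the published analyses do
#' not pin this down, so it is a parameter, not a constant). Gene bodies
#' are the transcript spans. Positions on contigs absent from the models
#' are intergenic.
#'
#' @param positions tibble with `chrom` and `mapinfo` (1-based C
#'   position); extra columns are preserved.
#' @param gene_models a GTF path, or a `GRanges` of transcript records
#'   (must carry `type == "transcript"` rows or be all transcripts).
#' @param tss_upstream,tss_downstream TSS window in bp.
#' @return the input tibble with a `genic` column
#'   (`TSS`/`gene_body`/`intergenic`); attribute `"summary"` holds
#'   per-category counts and the number of unique TSSs covered.
#' @export
assign_genic_context <- function(positions, gene_models,
                                 tss_upstream = 1500L,
                                 tss_downstream = 500L) {
  gr <- if (is.character(gene_models)) {
    rtracklayer::import(gene_models, format = "gtf")
  } else {
    gene_models
  }
  if ("type" %in% names(GenomicRanges::mcols(gr))) {
    tx <- gr[GenomicRanges::mcols(gr)$type == "transcript"]
  } else {
    tx <- gr
  }
  if (length(tx) == 0L) abort("gene models contain no transcript features")
  tss_pos <- ifelse(as.character(GenomicRanges::strand(tx)) == "-",
                    GenomicRanges::end(tx), GenomicRanges::start(tx))
  minus <- as.character(GenomicRanges::strand(tx)) == "-"
  tss <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tx),
    ranges = IRanges::IRanges(
      start = pmax(1L, tss_pos - ifelse(minus, tss_downstream,
                                        tss_upstream)),
      end = tss_pos + ifelse(minus, tss_upstream, tss_downstream)))
  pos <- positions_to_granges(positions)
  in_tss <- IRanges::overlapsAny(pos, tss, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(pos, tx, ignore.strand = TRUE)
  out <- positions
  out$genic <- dplyr::case_when(in_tss ~ "TSS",
                                in_body ~ "gene_body",
                                TRUE ~ "intergenic")
  hits <- GenomicRanges::findOverlaps(pos, tss, ignore.strand = TRUE)
  attr(out, "summary") <- list(
    counts = table(out$genic),
    unique_tss_covered = length(unique(S4Vectors::subjectHits(hits))))
  as_tibble(out)
}

#' Assign CpG-island context (island / shore / open sea)
#'
#' A position is `island` if inside a CpG island, `shore` if within
#' `shore_bp` (default 2000 bp) of the nearest island edge, `open_sea`
#' otherwise. Island takes precedence over shore.
#'
#' @param positions tibble with `chrom`, `mapinfo`.
#' @param islands a BED path or `GRanges` of CpG islands.
#' @param shore_bp shore width either side of each island (bp).
#' @return the input tibble with a `cpg` column.
#' @export
assign_cpg_context <- function(positions, islands, shore_bp = 2000L) {
  isl <- if (is.character(islands)) {
    rtracklayer::import(islands, format = "bed")
  } else {
    islands
  }
  pos <- positions_to_granges(positions)
  out <- positions
  if (length(isl) == 0L) {
    out$cpg <- rep("open_sea", nrow(positions))
    return(as_tibble(out))
  }
  in_island <- IRanges::overlapsAny(pos, isl, ignore.strand = TRUE)
  d <- GenomicRanges::distanceToNearest(pos, isl, ignore.strand = TRUE)
  dist <- rep(NA_integer_, length(pos))
  dist[S4Vectors::queryHits(d)] <- GenomicRanges::mcols(d)$distance
  # a point k bp beyond an island edge has gap distance k - 1 to the
  # island range; the shore spans k in [1, shore_bp]
  out$cpg <- dplyr::case_when(
    in_island ~ "island",
    !is.na(dist) & dist < shore_bp ~ "shore",
    TRUE ~ "open_sea")
  as_tibble(out)
}

#' Overlap summary between positions and a feature set
#'
#' Flags each position overlapping at least one feature, counts probes
#' per feature (on merged, deduplicated intervals for the
#' "unique features covered" view), and builds the probes-per-feature
#' histogram.
#'
#' @param positions tibble with `chrom`, `mapinfo`.
#' @param features a BED path or `GRanges` (e.g. FANTOM5 enhancers,
#'   super-enhancers — same operation, different BED).
#' @param label feature-source label stored in the outputs.
#' @return the input tibble with logical column `in_<label>`; attributes
#'   `"per_feature"` (tibble: feature index/coords, probe count) and
#'   `"histogram"` (tibble: `k` probes, `n_features`, including `k = 0`),
#'   and `"n_features_covered"`.
#' @export
feature_overlap_summary <- function(positions, features,
                                    label = "feature") {
  fr <- if (is.character(features)) {
    rtracklayer::import(features, format = "bed")
  } else {
    features
  }
  fr <- GenomicRanges::reduce(fr, ignore.strand = TRUE)
  pos <- positions_to_granges(positions)
  out <- positions
  flag_col <- paste0("in_", label)
  if (length(fr) == 0L) {
    out[[flag_col]] <- rep(FALSE, nrow(positions))
    res <- as_tibble(out)
    attr(res, "per_feature") <- tibble(chrom = character(),
                                       start = integer(), end = integer(),
                                       n_probes = integer())
    attr(res, "histogram") <- tibble(k = integer(), n_features = integer())
    attr(res, "n_features_covered") <- 0L
    return(res)
  }
  out[[flag_col]] <- IRanges::overlapsAny(pos, fr, ignore.strand = TRUE)
  k <- GenomicRanges::countOverlaps(fr, pos, ignore.strand = TRUE)
  per_feature <- tibble(
    chrom = as.character(GenomicRanges::seqnames(fr)),
    start = GenomicRanges::start(fr), end = GenomicRanges::end(fr),
    n_probes = as.integer(k))
  hist <- per_feature |>
    dplyr::count(k = .data$n_probes, name = "n_features") |>
    arrange(.data$k)
  res <- as_tibble(out)
  attr(res, "per_feature") <- per_feature
  attr(res, "histogram") <- hist
  attr(res, "n_features_covered") <- sum(k > 0L)
  res
}
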