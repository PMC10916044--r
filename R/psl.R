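# PSL (BLAT tabular alignment) ingestion, so genome-scale external BLAT
# runs can feed the off-target pipeline in place of the built-in aligner.

PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd", "tName",
              "tSize", "tStart", "tEnd", "blockCount", "blockSizes",
              "qStarts", "tStarts")

#' Read a PSL alignment file
#'
#' Parses standard 21-column PSL (with or without the 5-line header)
#' into the package alignment frame. Minus-strand records (query
#' reverse-complemented by BLAT) are remapped so that block coordinates
#' are plus-strand and query offsets are in original probe orientation;
#' round-tripping a coordinate through the blocks is then
#' orientation-free.
#'
#' @param path PSL file path.
#' @param variant label for the genome build the run was made against
#'   (`"fwd"`, `"fwd_bis"`, `"rev"`, `"rev_bis"`; stored verbatim).
#' @return alignment tibble as from [align_probe()].
#' @export
read_psl <- function(path, variant = "fwd") {
  lines <- readr::read_lines(path)
  # optional 5-line header: "psLayout ..." then dashes line
  dash <- which(grepl("^-{5,}", lines))
  if (length(dash)) lines <- lines[-seq_len(dash[1L])]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 21L)
  if (length(bad)) {
    abort(sprintf("PSL format error at line %d: expected 21 columns, got %d",
                  bad[1L], lengths(fields)[bad[1L]]))
  }
  raw <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(raw) <- PSL_COLS
  ints <- function(x) as.integer(x)
  split_ints <- function(x) lapply(strsplit(x, ",", fixed = TRUE), ints)
  sizes <- split_ints(raw$blockSizes)
  qstarts <- split_ints(raw$qStarts)
  tstarts <- split_ints(raw$tStarts)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    minus <- raw$strand[i] == "-"
    qsz <- ints(raw$qSize[i]); tsz <- ints(raw$tSize[i])
    bs <- sizes[[i]]; qs <- qstarts[[i]]; ts <- tstarts[[i]]
    if (minus) {
      # PSL gives qStarts in reverse-complemented query coordinates and
      # tStarts on the forward target; convert to original query coords,
      # mapping q0+j <-> pstart+len-1-j (strand "-")
      qs <- qsz - qs - bs
      ord <- order(qs)
      bs <- bs[ord]; qs <- qs[ord]; ts <- ts[ord]
    }
    blocks <- data.frame(qstart = qs, pstart = ts, len = bs)
    tibble(
      probe_id = raw$qName[i],
      variant = variant,
      chrom = raw$tName[i],
      strand = raw$strand[i],
      matches = ints(raw$matches[i]) + ints(raw$repMatches[i]),
      mismatches = ints(raw$misMatches[i]),
      qgap_open = ints(raw$tNumInsert[i]),   # skipped target bases
      tgap_open = ints(raw$qNumInsert[i]),   # unaligned query bases
      score = ints(raw$matches[i]) + ints(raw$repMatches[i]) -
        ints(raw$misMatches[i]) - ints(raw$qNumInsert[i]) -
        ints(raw$tNumInsert[i]),
      plus_start = ints(raw$tStart[i]) + 1L,
      plus_end = ints(raw$tEnd[i]),
      blocks = list(blocks))
  })
  bind_rows(rows)
}
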