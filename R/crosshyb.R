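# In-silico cross-hybridisation mapping.
#
# Probe 50-mers are aligned against four genome variants (forward and
# reverse, bisulphite-converted and unconverted); passing off-target
# alignments have the target-cytosine query offset transposed through
# their blocks to a single plus-strand nucleotide, which is then read
# from the unconverted genome and classified (CpG / CpH / nonC).
#
# Alignment records use one coordinate frame: blocks carry the 0-based
# query start, the 0-based plus-strand start of the block, and its
# length; `strand` gives the orientation of the query on the plus strand
# ("+": q0+j <-> p0+j; "-": q0+j <-> p0+len-1-j). The built-in aligner is
# for toy genomes and tests (exhaustive within an edit budget); genome
# scale runs are delegated to external BLAT and ingested via read_psl().

VARIANT_KEYS <- c("fwd", "fwd_bis", "rev", "rev_bis")

#' Build the four-variant genome set for cross-hybridisation scans
#'
#' Constructs forward, forward-bisulphite (every C converted to T, the
#' fully unmethylated limit; the unconverted genome serves as the fully
#' methylated proxy), reverse-complement, and reverse-complement
#' bisulphite variants, with coordinate maps back to plus-strand 1-based
#' positions.
#'
#' @param genome a FASTA path, a named character vector of chromosome
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @return An object of class `genome_variants`: list with `plus` (named
#'   character, unconverted plus strand), `lengths`, and `dna` (list of
#'   four `DNAStringSet`s keyed fwd/fwd_bis/rev/rev_bis).
#' @export
build_genome_variants <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    plus <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    plus <- setNames(as.character(genome),
                     sub("\\s.*$", "", names(genome)))
  } else {
    plus <- genome
  }
  plus <- toupper(plus)
  if (length(plus) == 0L || any(!nzchar(plus))) {
    abort("genome contains an empty sequence")
  }
  if (is.null(names(plus))) names(plus) <- paste0("chr", seq_along(plus))
  assert_dna(plus, c("A", "C", "G", "T", "N"), "genome")
  rev <- revcomp_n(plus)
  seqs <- list(fwd = plus,
               fwd_bis = chartr("C", "T", plus),
               rev = rev,
               rev_bis = chartr("C", "T", rev))
  structure(list(plus = plus,
                 lengths = setNames(nchar(plus), names(plus)),
                 dna = lapply(seqs, Biostrings::DNAStringSet)),
            class = "genome_variants")
}

# revcomp tolerating N (genome scale); probe sequences use revcomp()
revcomp_n <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @export
print.genome_variants <- function(x, ...) {
  cat(sprintf("<genome_variants> %d sequence(s), total %d nt\n",
              length(x$plus), sum(x$lengths)))
  invisible(x)
}

empty_alignments <- function() {
  tibble(probe_id = character(), variant = character(), chrom = character(),
         strand = character(), matches = integer(), mismatches = integer(),
         qgap_open = integer(), tgap_open = integer(), score = integer(),
         plus_start = integer(), plus_end = integer(), blocks = list())
}

# degenerate-aware base comparison table: probe char -> matching set
PROBE_MATCH_SET <- list(A = "A", C = "C", G = "G", T = "T",
                        R = c("A", "G"), Y = c("C", "T"),
                        N = c("A", "C", "G", "T"))

# Global-in-query / local-in-window alignment maximising the PSL-style
# score (matches - mismatches - gap openings; extension free, mirroring
# the score formula), with match count as tie-break: lexicographic
# (score, matches) via match +1001, mismatch -999, gap open -1000.
# Returns NULL or list(blocks, matches, mismatches, qgap_open, tgap_open,
# tstart, tend) with window-local 0-based target coordinates.
align_in_window <- function(probe_chars, window_chars) {
  n <- length(probe_chars); w <- length(window_chars)
  if (w == 0L) return(NULL)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, w + 1L)  # probe i aligned to window j
  X <- matrix(NEG, n + 1L, w + 1L)  # probe i unaligned (gap in target)
  Y <- matrix(NEG, n + 1L, w + 1L)  # window j skipped (gap in query)
  M[1L, ] <- 0  # free leading window bases (local in window)
  ptrM <- matrix(0L, n + 1L, w + 1L)
  ptrX <- matrix(0L, n + 1L, w + 1L)
  ptrY <- matrix(0L, n + 1L, w + 1L)
  msets <- PROBE_MATCH_SET[probe_chars]
  for (i in seq_len(n)) {
    hit <- vapply(seq_len(w),
                  function(j) window_chars[j] %in% msets[[i]], logical(1))
    sub <- ifelse(hit, 1001L, -999L)
    # X: consume probe base i without window (gap open -1000, extend 0)
    xm <- M[i, ] - 1000L; xx <- X[i, ]; xy <- Y[i, ] - 1000L
    X[i + 1L, ] <- pmax(xm, xx, xy)
    ptrX[i + 1L, ] <- ifelse(xm >= pmax(xx, xy), 1L,
                             ifelse(xx >= xy, 2L, 3L))
    # M: diagonal
    dm <- M[i, seq_len(w)]; dx <- X[i, seq_len(w)]; dy <- Y[i, seq_len(w)]
    best <- pmax(dm, dx, dy)
    M[i + 1L, 1L + seq_len(w)] <- best + sub
    ptrM[i + 1L, 1L + seq_len(w)] <- ifelse(dm >= pmax(dx, dy), 1L,
                                            ifelse(dx >= dy, 2L, 3L))
    # Y: consume window base j without probe (internal only), left-to-right
    for (j in seq_len(w)) {
      cand <- c(M[i + 1L, j] - 1000L, X[i + 1L, j] - 1000L, Y[i + 1L, j])
      k <- which.max(cand)
      Y[i + 1L, j + 1L] <- cand[k]
      ptrY[i + 1L, j + 1L] <- c(1L, 2L, 3L)[k]
    }
  }
  finals <- pmax(M[n + 1L, ], X[n + 1L, ])
  j <- which.max(finals)
  if (finals[j] <= NEG / 2) return(NULL)
  state <- if (M[n + 1L, j] >= X[n + 1L, j]) 1L else 2L
  # traceback
  ops <- character(0); qpos <- integer(0); tpos <- integer(0)
  i <- n + 1L
  while (i > 1L || (state == 3L)) {
    if (state == 1L) {
      if (i == 1L) break  # reached the free leading row: start anchor
      ops <- c("M", ops); qpos <- c(i - 1L, qpos); tpos <- c(j - 1L, tpos)
      state <- ptrM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ops <- c("X", ops); qpos <- c(i - 1L, qpos); tpos <- c(NA, tpos)
      state <- ptrX[i, j]; i <- i - 1L
    } else {
      ops <- c("Y", ops); qpos <- c(NA, qpos); tpos <- c(j - 1L, tpos)
      state <- ptrY[i, j]; j <- j - 1L
    }
  }
  if (!length(ops) || !any(ops == "M")) return(NULL)
  # stats
  mi <- which(ops == "M")
  qi <- qpos[mi]; ti <- tpos[mi]
  hit <- vapply(seq_along(mi), function(k) {
    window_chars[ti[k]] %in% msets[[qi[k]]]
  }, logical(1))
  matches <- sum(hit); mismatches <- sum(!hit)
  rle_ops <- rle(ops)
  tgap_open <- sum(rle_ops$values == "X")
  qgap_open <- sum(rle_ops$values == "Y")
  # blocks: maximal runs of M on one diagonal
  dg <- ti - qi
  newblk <- c(TRUE, diff(mi) != 1L | diff(dg) != 0L)
  bid <- cumsum(newblk)
  blocks <- data.frame(
    qstart = tapply(qi, bid, function(v) v[1L] - 1L),
    tstart = tapply(ti, bid, function(v) v[1L] - 1L),
    len = as.integer(table(bid)))
  rownames(blocks) <- NULL
  list(blocks = blocks, matches = matches, mismatches = mismatches,
       qgap_open = qgap_open, tgap_open = tgap_open,
       tstart = blocks$tstart[1L],
       tend = blocks$tstart[nrow(blocks)] + blocks$len[nrow(blocks)])
}

# convert window-local blocks to the plus-strand frame
blocks_to_plus <- function(blocks, window_start0, variant, L) {
  local <- blocks
  local$tstart <- local$tstart + window_start0
  if (variant %in% c("fwd", "fwd_bis")) {
    data.frame(qstart = local$qstart, pstart = local$tstart,
               len = local$len)
  } else {
    data.frame(qstart = local$qstart,
               pstart = L - local$tstart - local$len,
               len = local$len)
  }
}

#' Align a probe 50-mer against the four genome variants
#'
#' Finds all alignments with at least `min_matches` matching nucleotides
#' across the four variants, allowing substitutions and indels within an
#' edit budget (`max_edits`, default `50 - min_matches`). Candidate loci
#' are discovered exhaustively (`Biostrings::matchPattern` with indels;
#' degenerate probe bases R/Y match either alternative, never counted as
#' mismatches) and refined with a gapped alignment that maximises matches
#' and then the score `matches - mismatches - gap openings`. Coordinates
#' are reported on the plus strand.
#'
#' @param probe_seq 50-character probe sequence over A/C/G/T/R/Y.
#' @param variants `genome_variants` object.
#' @param min_matches minimum matching nucleotides (default 47).
#' @param max_edits candidate-search edit budget; alignments requiring
#'   more edits than this are the domain of external BLAT via
#'   [read_psl()].
#' @param probe_id identifier stored in the output.
#' @return An alignment tibble: `probe_id`, `variant`, `chrom`, `strand`,
#'   `matches`, `mismatches`, `qgap_open` (gap openings in the query:
#'   skipped genome bases), `tgap_open` (gap openings in the genome:
#'   unaligned probe bases), `score`, `plus_start`/`plus_end` (1-based),
#'   and list-column `blocks` (`qstart`, `pstart` 0-based, `len`).
#' @export
align_probe <- function(probe_seq, variants, min_matches = 47L,
                        max_edits = NULL, probe_id = "probe") {
  if (nchar(probe_seq) != 50L) abort("probe length must be 50")
  assert_dna(probe_seq, c("A", "C", "G", "T", "R", "Y"), "probe")
  if (is.null(max_edits)) max_edits <- max(0L, 50L - as.integer(min_matches))
  # Like BLAT, both query orientations are searched. The unconverted
  # genome is reverse-complement symmetric, so searching `fwd` with the
  # reversed query IS the `rev` variant (labelled so); the converted
  # genomes are not symmetric and each needs both orientations.
  searches <- list(
    list(store = "fwd", ori = "+", label = "fwd"),
    list(store = "fwd", ori = "-", label = "rev"),
    list(store = "fwd_bis", ori = "+", label = "fwd_bis"),
    list(store = "fwd_bis", ori = "-", label = "fwd_bis"),
    list(store = "rev_bis", ori = "+", label = "rev_bis"),
    list(store = "rev_bis", ori = "-", label = "rev_bis"))
  pats <- list("+" = probe_seq, "-" = revcomp(probe_seq))
  out <- list()
  for (srch in searches) {
    ss <- variants$dna[[srch$store]]
    pat <- Biostrings::DNAString(pats[[srch$ori]])
    pchars <- strsplit(pats[[srch$ori]], "", fixed = TRUE)[[1L]]
    for (ci in seq_along(ss)) {
      chrom <- names(variants$plus)[ci]
      L <- variants$lengths[[ci]]
      m <- Biostrings::matchPattern(pat, ss[[ci]],
                                    max.mismatch = max_edits,
                                    with.indels = TRUE, fixed = "subject")
      if (length(m) == 0L) next
      cl <- IRanges::reduce(IRanges::ranges(m) + max_edits)
      for (k in seq_along(cl)) {
        ws <- max(1L, IRanges::start(cl)[k])
        we <- min(L, IRanges::end(cl)[k])
        win <- substr(as.character(ss[[ci]]), ws, we)
        aln <- align_in_window(pchars, strsplit(win, "", fixed = TRUE)[[1L]])
        if (is.null(aln) || aln$matches < min_matches) next
        blk <- aln$blocks
        blk$tstart <- blk$tstart + ws - 1L  # variant-local, 0-based
        if (srch$ori == "-") {
          # pattern was the reverse complement: map pattern offsets back
          # to probe offsets; the mapping flips within each block
          blk$qstart <- 50L - blk$qstart - blk$len
          blk <- blk[order(blk$qstart), , drop = FALSE]
        }
        plus_flip <- srch$store == "rev_bis"
        blocks <- data.frame(
          qstart = blk$qstart,
          pstart = if (plus_flip) L - blk$tstart - blk$len else blk$tstart,
          len = blk$len)
        strand <- if ((srch$ori == "+") == !plus_flip) "+" else "-"
        out[[length(out) + 1L]] <- tibble(
          probe_id = probe_id, variant = srch$label, chrom = chrom,
          strand = strand,
          matches = aln$matches, mismatches = aln$mismatches,
          qgap_open = aln$qgap_open, tgap_open = aln$tgap_open,
          score = aln$matches - aln$mismatches - aln$qgap_open -
            aln$tgap_open,
          plus_start = as.integer(min(blocks$pstart)) + 1L,
          plus_end = as.integer(max(blocks$pstart + blocks$len)),
          blocks = list(blocks))
      }
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- bind_rows(out)
  # candidate clusters are disjoint per variant/chrom, but keep the best
  # record should two clusters resolve to the same span
  res |>
    group_by(.data$variant, .data$chrom, .data$plus_start,
             .data$plus_end) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$variant, .data$chrom, .data$plus_start)
}

#' Filter alignments by the cross-hybridisation thresholds
#'
#' Passing alignments have `matches >= min_matches` and
#' `score >= min_score` (the published threshold pair: 47 matches on a
#' 50-mer gives a score of exactly 44 with three substitutions). When a
#' manifest is supplied, each probe is routed to exactly one category:
#' `no_homology` (no alignment anywhere), `no_mapinfo_homology` (no
#' passing alignment covering the manifest coordinate),
#' `cross_hybridising` (at least one passing alignment beyond the
#' on-target one) or `not_cross_hybridising`.
#'
#' @param alns alignment tibble from [align_probe()] / [read_psl()].
#' @param manifest optional manifest tibble (for per-probe flags).
#' @param min_matches,min_score thresholds.
#' @return the passing alignments, with columns `passes` and (when
#'   manifest given) `is_on_target`; attribute `"probe_flags"` is a
#'   tibble `ilmn_id`, `category`, `n_offtargets` (`CH_BLAT`-style flag
#'   derivable as `category == "cross_hybridising"`).
#' @export
filter_alignments <- function(alns, manifest = NULL, min_matches = 47L,
                              min_score = 44L) {
  alns <- mutate(alns, passes = .data$matches >= min_matches &
                   .data$score >= min_score)
  if (is.null(manifest)) {
    return(filter(alns, .data$passes))
  }
  mf <- tibble(probe_id = manifest$ilmn_id, chrom_t = manifest$chrom,
               mapinfo = manifest$mapinfo)
  alns <- left_join(alns, mf, by = "probe_id")
  # on-target: the manifest coordinate maps to a query offset at or just
  # beyond the probe ends (Type II / opposite-strand designs interrogate
  # the base adjacent to the 3' terminus, outside the footprint)
  alns$is_on_target <- !is.na(alns$mapinfo) & alns$chrom_t != "chr0" &
    alns$chrom == alns$chrom_t &
    purrr::pmap_lgl(list(alns$blocks, alns$strand, alns$mapinfo),
                    function(b, s, mp) {
                      q <- query_offset_of_coord(b, s, mp)
                      !is.na(q) && q >= -2L && q <= 51L
                    })
  pass <- filter(alns, .data$passes)
  flags <- mf |>
    mutate(
      n_any = vapply(.data$probe_id, function(p)
        sum(alns$probe_id == p), integer(1)),
      n_on = vapply(.data$probe_id, function(p)
        sum(pass$probe_id == p & pass$is_on_target), integer(1)),
      n_off = vapply(.data$probe_id, function(p)
        sum(pass$probe_id == p & !pass$is_on_target), integer(1))) |>
    mutate(category = dplyr::case_when(
      .data$chrom_t == "chr0" ~ "unmapped",
      .data$n_any == 0L ~ "no_homology",
      .data$n_on == 0L ~ "no_mapinfo_homology",
      .data$n_off > 0L ~ "cross_hybridising",
      TRUE ~ "not_cross_hybridising")) |>
    select(ilmn_id = "probe_id", "category", n_offtargets = "n_off")
  out <- select(pass, -"chrom_t", -"mapinfo")
  attr(out, "probe_flags") <- flags
  out
}

# The interrogated cytosine can sit just beyond the probe footprint
# (Type II and opposite-strand designs read it by extension at the 3'
# terminus), so both walkers extrapolate along the diagonal of the
# terminal block; offsets falling in an internal gap stay NA.

query_offset_of_coord <- function(blocks, strand, coord1) {
  p0 <- coord1 - 1L
  diag_q <- function(b) {
    if (strand == "+") b$qstart + (p0 - b$pstart)
    else b$qstart + (b$pstart + b$len - 1L - p0)
  }
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    if (p0 >= b$pstart && p0 < b$pstart + b$len) return(diag_q(b))
  }
  # outside every block: extrapolate from the hull edges, NA inside a gap
  lo <- min(blocks$pstart); hi <- max(blocks$pstart + blocks$len) - 1L
  if (p0 >= lo && p0 <= hi) return(NA_integer_)
  edge <- if ((p0 < lo) == (strand == "+")) {
    blocks[which.min(blocks$qstart), ]
  } else {
    blocks[which.max(blocks$qstart + blocks$len), ]
  }
  diag_q(edge)
}

coord_of_query_offset <- function(blocks, strand, q) {
  diag_p <- function(b) {
    if (strand == "+") b$pstart + (q - b$qstart) + 1L
    else b$pstart + b$len - 1L - (q - b$qstart) + 1L
  }
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    if (q >= b$qstart && q < b$qstart + b$len) return(diag_p(b))
  }
  qlo <- min(blocks$qstart); qhi <- max(blocks$qstart + blocks$len) - 1L
  if (q >= qlo && q <= qhi) return(NA_integer_)  # internal gap: skipped
  edge <- if (q < qlo) blocks[which.min(blocks$qstart), ]
          else blocks[which.max(blocks$qstart + blocks$len), ]
  diag_p(edge)
}

#' Transpose the target nucleotide onto off-target alignments
#'
#' Computes the query offset of the interrogated nucleotide from the
#' on-target alignment blocks, then maps that offset through each
#' off-target alignment's blocks (indel-aware) to a plus-strand 1-based
#' coordinate. Off-targets whose blocks do not cover the offset (it
#' falls in a gap) are skipped and counted.
#'
#' @param on_target single-row alignment tibble covering the probe's
#'   manifest coordinate.
#' @param target_coord manifest MAPINFO (plus-strand, 1-based).
#' @param off_targets alignment tibble of the same probe's other hits.
#' @return tibble of off-target hits: `probe_id`, `variant`, `chrom`,
#'   `strand`, `coord` (plus-strand 1-based), `score`; attribute
#'   `"n_skipped"` counts offsets landing in gaps.
#' @export
transpose_target_to_offtargets <- function(on_target, target_coord,
                                           off_targets) {
  stopifnot(nrow(on_target) == 1L)
  q <- query_offset_of_coord(on_target$blocks[[1L]], on_target$strand,
                             target_coord)
  if (is.na(q)) {
    abort("target coordinate outside all on-target alignment blocks")
  }
  if (nrow(off_targets) == 0L) {
    out <- tibble(probe_id = character(), variant = character(),
                  chrom = character(), strand = character(),
                  coord = integer(), score = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  coord <- purrr::pmap_int(
    list(off_targets$blocks, off_targets$strand),
    function(b, s) coord_of_query_offset(b, s, q))
  out <- tibble(probe_id = off_targets$probe_id,
                variant = off_targets$variant,
                chrom = off_targets$chrom,
                strand = off_targets$strand,
                coord = coord,
                score = off_targets$score) |>
    filter(!is.na(.data$coord))
  attr(out, "n_skipped") <- sum(is.na(coord))
  out
}

#' Classify the genomic base at an off-target coordinate
#'
#' Reads the base from the unconverted genome in the aligned orientation
#' (minus-strand hits are complemented). Cytosines are `CpG` when the
#' next base in that orientation is G, otherwise `CpH`; other bases are
#' `nonC`. A cytosine at a contig end with no successor is flagged
#' undecidable (classified `CpH` with `undecidable = TRUE`).
#'
#' @param chrom,coord plus-strand 1-based hit coordinate(s).
#' @param genome `genome_variants` object or named character vector of
#'   plus-strand sequences.
#' @param strand `"+"` or `"-"` per hit (aligned orientation).
#' @return tibble: `base`, `dinucleotide_class`, `undecidable`.
#' @export
classify_offtarget_base <- function(chrom, coord, genome, strand = "+") {
  plus <- if (inherits(genome, "genome_variants")) genome$plus else genome
  n <- max(length(chrom), length(coord), length(strand))
  chrom <- rep_len(chrom, n); coord <- rep_len(coord, n)
  strand <- rep_len(strand, n)
  rows <- purrr::pmap(list(chrom, coord, strand), function(ch, co, st) {
    s <- plus[[ch]]
    if (co < 1L || co > nchar(s)) abort("coordinate outside genome bounds")
    if (st == "+") {
      base <- substr(s, co, co)
      succ <- if (co < nchar(s)) substr(s, co + 1L, co + 1L) else "N"
    } else {
      base <- complement_chr(substr(s, co, co))
      succ <- if (co > 1L) complement_chr(substr(s, co - 1L, co - 1L))
              else "N"
    }
    und <- base == "C" && succ == "N"
    cls <- if (base == "C") {
      if (succ == "G") "CpG" else "CpH"
    } else {
      "nonC"
    }
    tibble(base = base, dinucleotide_class = cls, undecidable = und)
  })
  bind_rows(rows)
}

#' Map all off-target sites for a manifest of probes
#'
#' Orchestrates the cross-hybridisation scan: aligns (or takes supplied
#' alignments for) each located probe, applies the match/score filter,
#' transposes the target coordinate onto off-target alignments and
#' classifies the off-target bases. Probes lacking coordinates, lacking
#' homology, or lacking homology at MAPINFO are routed to the exclusion
#' report.
#'
#' @param manifest manifest tibble (needs `allele_a_seq` probes when
#'   `alignments` is `NULL`).
#' @param variants `genome_variants` object.
#' @param alignments optional precomputed alignment tibble (e.g. from
#'   [read_psl()]); when `NULL`, probes are aligned with [align_probe()].
#' @param min_matches,min_score thresholds as in [filter_alignments()].
#' @return tibble of off-target hits with base classification (one row
#'   per off-target event): `ilmn_id`, `chrom`, `coord`, `variant`,
#'   `strand`, `score`, `base`, `dinucleotide_class`, `is_cpg`;
#'   attribute `"probe_flags"` as in [filter_alignments()].
#' @export
map_offtargets <- function(manifest, variants, alignments = NULL,
                           min_matches = 47L, min_score = 44L) {
  if (is.null(alignments)) {
    alignments <- bind_rows(purrr::map2(
      manifest$allele_a_seq, manifest$ilmn_id,
      function(seq, id) {
        # degenerate-free scan sequence: Type I allele A is already plain
        align_probe(seq, variants, min_matches = min_matches,
                    probe_id = id)
      }))
  }
  pass <- filter_alignments(alignments, manifest,
                            min_matches = min_matches,
                            min_score = min_score)
  flags <- attr(pass, "probe_flags")
  hits <- list()
  for (p in flags$ilmn_id[flags$category == "cross_hybridising"]) {
    sub <- filter(pass, .data$probe_id == p)
    on <- filter(sub, .data$is_on_target)
    on <- dplyr::slice_max(on, .data$score, n = 1L, with_ties = FALSE)
    off <- filter(sub, !.data$is_on_target)
    mp <- manifest$mapinfo[manifest$ilmn_id == p]
    tr <- transpose_target_to_offtargets(on, mp, off)
    tr <- filter(tr, .data$coord >= 1L,
                 .data$coord <= variants$lengths[.data$chrom])
    if (nrow(tr) == 0L) next
    # read each off-target in the orientation that reads the interrogated
    # base at the on-target: "+" shows the C of a cg target at MAPINFO
    # (CpG G-coordinate conventions flip it), and off-targets aligned on
    # the other strand than the on-target are flipped relative to it
    on_chrom_seq <- variants$plus[[on$chrom]]
    on_read <- if (substr(on_chrom_seq, mp, mp) == "G") "-" else "+"
    read_ori <- ifelse(tr$strand == on$strand, on_read,
                       if (on_read == "+") "-" else "+")
    cls <- classify_offtarget_base(tr$chrom, tr$coord, variants, read_ori)
    hits[[length(hits) + 1L]] <- bind_cols(
      tibble(ilmn_id = tr$probe_id, chrom = tr$chrom, coord = tr$coord,
             variant = tr$variant, strand = tr$strand, score = tr$score),
      cls) |>
      mutate(is_cpg = .data$dinucleotide_class == "CpG")
  }
  out <- if (length(hits)) bind_rows(hits) else
    tibble(ilmn_id = character(), chrom = character(), coord = integer(),
           variant = character(), strand = character(), score = integer(),
           base = character(), dinucleotide_class = character(),
           undecidable = logical(), is_cpg = logical())
  attr(out, "probe_flags") <- flags
  out
}
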