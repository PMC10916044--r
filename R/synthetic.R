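# Seeded synthetic generators: toy genomes, designed manifests, planted
# off-target homologies and matched multi-platform methylation data.
# These are first-class, tested code — every other module is testable
# against their planted truth without external downloads.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic generators. Identical config and
#' seed give byte-identical outputs. Defaults emulate the study design:
#' 18 matched samples on EPICv1/EPICv2/WGBS, near-unit platform slopes,
#' moderate array noise, 20x WGBS coverage, and sparse dropout.
#'
#' @param seed integer seed.
#' @param genome_length toy genome length (>= 200 nt).
#' @param cpg_density expected CG dinucleotides per bp.
#' @param n_probes probes in a designed manifest.
#' @param flank Forward_Sequence flank length (nt each side).
#' @param n_samples matched samples per platform.
#' @param platform_alpha,platform_slope,platform_sigma named numeric
#'   vectors (per array platform) of M-space offset, slope and noise sd.
#' @param wgbs_coverage mean per-CpG read coverage (Poisson).
#' @param detection_fail_rate per-cell array detection-p failure rate.
#' @param zero_coverage_rate per-cell WGBS zero-coverage rate.
#' @param mixture_weights weights of the latent methylation mixture
#'   (near-0, intermediate, near-1).
#' @param sample_sd sd of per-sample latent variation (M space).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 20000L,
                       cpg_density = 0.02,
                       n_probes = 64L,
                       flank = 60L,
                       n_samples = 18L,
                       platform_alpha = c(EPICv1 = 0, EPICv2 = 0),
                       platform_slope = c(EPICv1 = 1, EPICv2 = 1),
                       platform_sigma = c(EPICv1 = 0.3, EPICv2 = 0.3),
                       wgbs_coverage = 20,
                       detection_fail_rate = 0.01,
                       zero_coverage_rate = 0.01,
                       mixture_weights = c(0.4, 0.2, 0.4),
                       sample_sd = 1.5) {
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a deterministic toy genome
#'
#' Draws a random sequence, removes every accidental CG dinucleotide,
#' then plants `round(cpg_density * (length - 1))` CG sites at sampled
#' non-overlapping positions, so the realised CpG count matches the
#' request. Returns a named character vector usable wherever a FASTA is
#' accepted; write it with `Biostrings::writeXStringSet` if a file is
#' needed.
#'
#' @param length genome length in nt (>= 200).
#' @param cpg_density target CG dinucleotides per bp; 0 gives a
#'   CpG-free genome.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return named character vector of length 1.
#' @export
generate_toy_genome <- function(length = 10000L, cpg_density = 0.02,
                                seed = 1L, chrom = "chr1") {
  stopifnot(length >= 200L)
  n_cpg <- round(cpg_density * (length - 1L))
  if (n_cpg > floor((length - 10L) / 3L)) {
    abort("infeasible cpg_density for this genome length")
  }
  restore <- local_seed(seed)
  on.exit(restore())
  ch <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(ch[-length] == "C" & ch[-1L] == "G")
  ch[cg + 1L] <- "A"
  if (n_cpg > 0L) {
    # sample CG start positions spaced >= 3 apart, away from the ends
    starts <- integer(0)
    cand <- sample(seq(5L, length - 5L))
    for (p in cand) {
      if (length(starts) == n_cpg) break
      if (!any(abs(starts - p) < 3L)) starts <- c(starts, p)
    }
    if (length(starts) < n_cpg) abort("infeasible cpg_density (packing)")
    ch[starts] <- "C"
    ch[starts + 1L] <- "G"
  }
  setNames(paste(ch, collapse = ""), chrom)
}

# greedy spacing: keep each position at least min_gap after the last kept
spaced_keep <- function(pos, min_gap) {
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last > min_gap) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}

#' Positions of CpG cytosines in a genome
#' @param genome named character vector of plus-strand sequences.
#' @return tibble `chrom`, `mapinfo` (1-based C positions).
#' @export
cpg_positions <- function(genome) {
  bind_rows(purrr::imap(genome, function(s, chrom) {
    hits <- gregexpr("CG", s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(tibble(chrom = character(),
                                       mapinfo = integer()))
    tibble(chrom = chrom, mapinfo = as.integer(hits))
  }))
}

# plus-strand footprint (1-based, inclusive) of the 50-nt design window
design_footprint <- function(target_pos, flank, strand_tb, strand_co,
                             design_type) {
  b <- design_window_bounds(if (strand_tb == "T") flank else flank,
                            strand_co, design_type)
  if (strand_tb == "T") {
    # design strand index i maps to plus position target_pos - flank + i
    c(target_pos - flank + b[1L], target_pos - flank + b[2L] - 1L)
  } else {
    # design strand = revcomp of span; index i maps to
    # plus position (target_pos + 1 + flank) - i
    sort(c(target_pos + 1L + flank - b[1L],
           target_pos + 1L + flank - (b[2L] - 1L)))
  }
}

#' Design a probe against a toy genome
#'
#' Extracts the Forward_Sequence around a CpG target and runs the
#' bisulphite design engine, emitting a one-row manifest record whose
#' allele sequences [recompute_probe_sequences()] reproduces exactly.
#'
#' @param genome named character vector (plus strand).
#' @param chrom chromosome name.
#' @param target_pos 1-based position of the C of a CpG.
#' @param strand_tb,strand_co,design_type design choice.
#' @param rep_num replicate number for the IlmnID suffix.
#' @param flank Forward_Sequence flank (default 60 nt each side).
#' @param name probe name; default derives from the target position.
#' @return one-row manifest tibble (canonical columns plus
#'   `window_start`/`window_end`, the probe's plus-strand footprint).
#' @export
design_probe <- function(genome, chrom, target_pos, strand_tb, strand_co,
                         design_type, rep_num = 1L, flank = 60L,
                         name = NULL) {
  s <- genome[[chrom]]
  if (target_pos < flank + 1L || target_pos + 1L + flank > nchar(s)) {
    abort("target lacks the required flanks")
  }
  if (substr(s, target_pos, target_pos + 1L) != "CG") {
    abort("target position is not the C of a CpG")
  }
  fwd <- paste0(substr(s, target_pos - flank, target_pos - 1L),
                "[CG]",
                substr(s, target_pos + 2L, target_pos + 1L + flank))
  rec <- recompute_probe_sequences(fwd, strand_tb, strand_co, design_type)
  if (is.null(name)) name <- sprintf("cg%08d", target_pos)
  fp <- design_footprint(target_pos, flank, strand_tb, strand_co,
                         design_type)
  tibble(
    ilmn_id = compose_ilmnid(name, strand_tb, strand_co, design_type,
                             rep_num),
    name = name, target_class = "cg",
    strand_tb = strand_tb, strand_co = strand_co,
    design_type = design_type, rep_num = as.integer(rep_num),
    chrom = chrom, mapinfo = as.integer(target_pos),
    forward_sequence = fwd,
    allele_a_seq = rec$allele_a, allele_b_seq = rec$allele_b,
    next_base = rec$next_base, color_channel = rec$color_channel,
    window_start = fp[1L], window_end = fp[2L])
}

ALL_DESIGNS <- expand.grid(strand_tb = c("T", "B"),
                           strand_co = c("C", "O"),
                           design_type = c("I", "II"),
                           stringsAsFactors = FALSE)

#' Design a synthetic manifest over a toy genome
#'
#' Samples CpG targets with adequate flanks and designs probes cycling
#' through all eight (TB x CO x type) combinations. Optionally plants
#' replicate sets of each class: exact (same design, rep_num 2),
#' location (a second design type at the same CpG) and sequence-only
#' (a duplicated record under a fresh name with chr0/MAPINFO=0,
#' mirroring the unmapped sequence-replicates of the real array).
#'
#' @param genome named character vector.
#' @param n_probes base probe count.
#' @param seed integer seed.
#' @param flank flank length.
#' @param n_exact,n_location,n_seqonly replicate plantings per class.
#' @return manifest tibble (`source_dialect = "illumina"`), with planted
#'   replicate truth in attribute `"replicate_truth"`.
#' @export
design_manifest <- function(genome, n_probes = 64L, seed = 1L,
                            flank = 60L, n_exact = 0L, n_location = 0L,
                            n_seqonly = 0L) {
  restore <- local_seed(seed)
  on.exit(restore())
  cpgs <- cpg_positions(genome)
  cpgs <- filter(cpgs, .data$mapinfo > flank + 1L,
                 .data$mapinfo + 1L + flank <
                   nchar(genome[.data$chrom]))
  # keep targets far enough apart that probe windows do not overlap
  cpgs <- cpgs |>
    group_by(.data$chrom) |>
    filter(spaced_keep(.data$mapinfo, 120L)) |>
    ungroup()
  need <- n_probes + n_location
  if (nrow(cpgs) < need) abort("genome has too few designable CpGs")
  pick <- cpgs[sort(sample(nrow(cpgs), need)), ]
  rows <- purrr::map(seq_len(n_probes), function(i) {
    d <- ALL_DESIGNS[((i - 1L) %% nrow(ALL_DESIGNS)) + 1L, ]
    design_probe(genome, pick$chrom[i], pick$mapinfo[i], d$strand_tb,
                 d$strand_co, d$design_type, flank = flank)
  })
  manifest <- bind_rows(rows)
  truth <- list(exact = list(), location = list(), seqonly = list())
  # exact replicates: duplicate the first n_exact probes with rep_num 2
  if (n_exact > 0L) {
    for (i in seq_len(n_exact)) {
      dup <- manifest[i, ]
      dup$rep_num <- 2L
      dup$ilmn_id <- compose_ilmnid(dup$name, dup$strand_tb, dup$strand_co,
                                    dup$design_type, 2L)
      manifest <- bind_rows(manifest, dup)
      truth$exact[[i]] <- c(manifest$ilmn_id[i], dup$ilmn_id)
    }
  }
  # location replicates: a different design type at a fresh CpG + pair
  if (n_location > 0L) {
    for (i in seq_len(n_location)) {
      pos <- pick[n_probes + i, ]
      a <- design_probe(genome, pos$chrom, pos$mapinfo, "T", "C", "I",
                        flank = flank)
      b <- design_probe(genome, pos$chrom, pos$mapinfo, "B", "C", "II",
                        flank = flank)
      manifest <- bind_rows(manifest, a, b)
      truth$location[[i]] <- c(a$ilmn_id, b$ilmn_id)
    }
  }
  # sequence-only replicates: same sequences under a new name, unmapped
  if (n_seqonly > 0L) {
    for (i in seq_len(n_seqonly)) {
      src <- manifest[n_exact + i, ]
      dup <- src
      dup$name <- sprintf("cg9%07d", i)
      dup$ilmn_id <- compose_ilmnid(dup$name, dup$strand_tb, dup$strand_co,
                                    dup$design_type, 1L)
      dup$chrom <- "chr0"; dup$mapinfo <- 0L
      dup$window_start <- NA_integer_; dup$window_end <- NA_integer_
      manifest <- bind_rows(manifest, dup)
      truth$seqonly[[i]] <- c(src$ilmn_id, dup$ilmn_id)
    }
  }
  out <- new_manifest(manifest, "illumina", "toy")
  attr(out, "replicate_truth") <- truth
  out
}

#' Plant an off-target homolog of a probe into a toy genome
#'
#' Copies the probe's on-target plus-strand footprint (plus two bases of
#' conversion context each side) to `location`, applying
#' `n_mismatches` interior substitutions and optionally deleting
#' `n_del` bases (one internal gap), then verifies by realignment that
#' the planted locus yields exactly the expected match count. The
#' expected transposed off-target coordinate of the target nucleotide is
#' returned as truth.
#'
#' @param genome named character vector.
#' @param record one-row manifest tibble from [design_probe()].
#' @param n_mismatches interior substitutions (default 0).
#' @param n_del bases deleted at one interior point (default 0; the
#'   alignment then carries one target-gap opening).
#' @param location 1-based plus-strand start for the planted segment;
#'   must not overlap the on-target footprint.
#' @param mutate_target also substitute the transposed target base (so
#'   the off-target base is no longer a cytosine).
#' @param seed integer seed for mutation placement.
#' @return list `genome` (modified), `truth` (tibble: `probe_id`,
#'   `chrom`, `planted_start`, `expected_coord`, `expected_matches`,
#'   `expected_score`, `expected_tgap_open`).
#' @export
plant_offtarget <- function(genome, record, n_mismatches = 0L,
                            n_del = 0L, location, mutate_target = FALSE,
                            seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  chrom <- record$chrom
  s0 <- genome[[chrom]]
  pad <- 2L
  wstart <- record$window_start - pad
  wend <- record$window_end + pad
  stopifnot(wstart >= 1L, wend <= nchar(s0))
  seg0 <- strsplit(substr(s0, wstart, wend), "")[[1L]]
  seg_len0 <- length(seg0)
  if (location <= record$window_end + seg_len0 &&
      location + seg_len0 >= record$window_start - seg_len0) {
    abort("planted location overlaps the on-target site")
  }
  # offset (1-based within seg) of the target nucleotide
  toff <- record$mapinfo - wstart + 1L
  # candidate interior positions, excluding the pad, segment ends, the
  # target and its CpG partner
  interior <- setdiff(seq(pad + 4L, seg_len0 - pad - 3L),
                      c(toff - 1L, toff, toff + 1L))
  exp_matches <- 50L - n_mismatches - n_del -
    (if (mutate_target) 1L else 0L)
  exp_tgap <- if (n_del > 0L) 1L else 0L
  exp_score <- exp_matches -
    (n_mismatches + (if (mutate_target) 1L else 0L)) - exp_tgap

  # bisulphite-converted sequences are repetitive (a 3-letter alphabet),
  # so a given mutation layout can admit a better-scoring gapped
  # alignment than the intended one; sample layouts until realignment
  # confirms the planted truth is the optimum
  for (attempt in seq_len(25L)) {
    seg <- seg0
    mut_at <- integer(0)
    for (p in sample(interior)) {
      if (length(mut_at) == n_mismatches) break
      if (!any(abs(mut_at - p) < 6L)) mut_at <- c(mut_at, p)
    }
    if (length(mut_at) < n_mismatches) next
    for (p in mut_at) {
      # the complement never collapses with the original after C->T
      # conversion on either strand (unlike A<->? transitions)
      seg[p] <- switch(seg[p], A = "T", T = "A", C = "G", G = "C")
    }
    if (mutate_target) seg[toff] <- "A"
    del_at <- NA_integer_
    if (n_del > 0L) {
      cand <- setdiff(interior, unlist(lapply(mut_at, function(p)
        (p - 6L):(p + 6L))))
      cand <- setdiff(cand, (toff - n_del - 1L):(toff + 1L))
      if (!length(cand)) next
      del_at <- sample(cand, 1L)
      seg <- seg[-(del_at:(del_at + n_del - 1L))]
    }
    seg_str <- paste(seg, collapse = "")
    if (location + nchar(seg_str) - 1L > nchar(s0)) {
      abort("planted segment exceeds genome end")
    }
    s <- s0
    substr(s, location, location + nchar(seg_str) - 1L) <- seg_str
    # self-check: realign against the planted locus only; the optimum
    # there must be unique and carry exactly the planted statistics
    vr <- build_genome_variants(setNames(
      substr(s, location - 5L, location + nchar(seg_str) + 5L), chrom))
    chk <- align_probe(record$allele_a_seq, vr,
                       min_matches = min(47L, exp_matches),
                       probe_id = record$ilmn_id)
    ok <- nrow(chk) == 1L && chk$matches == exp_matches &&
      chk$score == exp_score && chk$tgap_open == exp_tgap
    if (!ok) next
    genome[[chrom]] <- s
    exp_coord <- location + toff - 1L
    if (!is.na(del_at) && del_at < toff) exp_coord <- exp_coord - n_del
    truth <- tibble(
      probe_id = record$ilmn_id, chrom = chrom,
      planted_start = as.integer(location),
      expected_coord = as.integer(exp_coord),
      expected_matches = exp_matches,
      expected_score = exp_score,
      expected_tgap_open = exp_tgap)
    return(list(genome = genome, truth = truth))
  }
  abort("planted off-target failed self-verification")
}

#' Simulate matched multi-platform methylation data
#'
#' Draws a latent methylation level per site from a bimodal-plus-
#' intermediate beta mixture (near-0, intermediate, near-1), adds
#' per-sample latent variation in M space, and observes it on each array
#' platform as `M = alpha_p + slope_p * latent + N(0, sigma_p)` with a
#' detection-p companion, and on WGBS as binomial read counts at
#' Poisson coverage transformed with [wgbs_logit()]. Detection-p
#' failures and zero-coverage cells are planted as indicator masks at
#' the configured rates.
#'
#' @param config [sim_config()] object.
#' @param sites character vector of site keys (e.g. `chrom:pos`); or an
#'   integer count.
#' @return list: `tables` (named list of [methyl_table()] tibbles,
#'   arrays in M space, WGBS in logit space), `truth` (list with the
#'   latent matrix, platform parameters, and planted dropout masks).
#' @export
simulate_methylation_dataset <- function(config, sites = 200L) {
  stopifnot(inherits(config, "sim_config"), config$n_samples >= 3L)
  restore <- local_seed(config$seed)
  on.exit(restore())
  if (is.numeric(sites)) sites <- sprintf("site_%04d", seq_len(sites))
  ns <- length(sites); np <- config$n_samples
  samples <- sprintf("S%02d", seq_len(np))
  w <- config$mixture_weights / sum(config$mixture_weights)
  comp <- sample(3L, ns, replace = TRUE, prob = w)
  base_beta <- c(rbeta(ns, 2, 20), rbeta(ns, 5, 5),
                 rbeta(ns, 20, 2))[seq_len(ns) + (comp - 1L) * ns]
  base_m <- log2(base_beta / (1 - base_beta))
  latent <- outer(base_m, rep(1, np)) +
    matrix(rnorm(ns * np, 0, config$sample_sd), ns, np)
  rownames(latent) <- sites; colnames(latent) <- samples
  long_latent <- as_tibble(latent, rownames = "site") |>
    tidyr::pivot_longer(-"site", names_to = "sample", values_to = "latent")
  tables <- list()
  det_masks <- list()
  for (p in names(config$platform_slope)) {
    m <- config$platform_alpha[[p]] +
      config$platform_slope[[p]] * latent +
      matrix(rnorm(ns * np, 0, config$platform_sigma[[p]]), ns, np)
    fail <- matrix(runif(ns * np) < config$detection_fail_rate, ns, np)
    detp <- matrix(runif(ns * np, 0, 0.04), ns, np)
    detp[fail] <- runif(sum(fail), 0.06, 1)
    tbl <- tibble(
      site = rep(sites, np), sample = rep(samples, each = ns),
      value = as.vector(m), qc = as.vector(detp))
    tables[[p]] <- methyl_table(tbl, p, space = "M",
                                qc_type = "detection_p")
    det_masks[[p]] <- fail
  }
  mu <- 2^latent / (1 + 2^latent)
  cov <- matrix(stats::rpois(ns * np, config$wgbs_coverage), ns, np)
  cov[matrix(runif(ns * np) < config$zero_coverage_rate, ns, np)] <- 0L
  meth <- matrix(rbinom(ns * np, as.vector(cov), as.vector(mu)), ns, np)
  wgbs_val <- wgbs_logit(meth, cov - meth)
  wgbs_val[cov == 0L] <- NA_real_
  tables$WGBS <- methyl_table(
    tibble(site = rep(sites, np), sample = rep(samples, each = ns),
           value = as.vector(wgbs_val), qc = as.vector(cov)),
    "WGBS", space = "logit", qc_type = "coverage")
  list(tables = tables,
       truth = list(latent = latent, mu = mu,
                    platform_alpha = config$platform_alpha,
                    platform_slope = config$platform_slope,
                    platform_sigma = config$platform_sigma,
                    detection_masks = det_masks, coverage = cov))
}
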