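# Shared fixtures, built in code at test time.

ALL_DESIGN_COMBOS <- expand.grid(tb = c("T", "B"), co = c("C", "O"),
                                 ty = c("I", "II"),
                                 stringsAsFactors = FALSE)

fixture_genome <- function(length = 6000L, density = 0.03, seed = 7L) {
  generate_toy_genome(length, density, seed = seed)
}

# designable, well-spaced CpG positions with `flank`-nt flanks
fixture_cpgs <- function(genome, flank = 60L, min_gap = 130L) {
  cp <- cpg_positions(genome)
  cp <- cp[cp$mapinfo > flank + 2L &
             cp$mapinfo + flank + 2L < nchar(genome[cp$chrom]), ]
  cp[epickit:::spaced_keep(cp$mapinfo, min_gap), ]
}

# exhaustive sliding-window edit-distance scan: the independent oracle
# for the built-in aligner. Returns clustered hit loci per search space
# in plus-strand coordinates.
oracle_edit_scan <- function(probe, variants, max_edits = 3L,
                             cluster_gap = 10L) {
  spaces <- list(c("fwd", "+"), c("fwd", "-"),
                 c("fwd_bis", "+"), c("fwd_bis", "-"),
                 c("rev_bis", "+"), c("rev_bis", "-"))
  out <- list()
  for (sp in spaces) {
    store <- sp[1L]; ori <- sp[2L]
    pat <- if (ori == "+") probe else revcomp(probe)
    for (ci in seq_along(variants$plus)) {
      chrom <- names(variants$plus)[ci]
      seqv <- as.character(variants$dna[[store]][[ci]])
      L <- nchar(seqv)
      hitpos <- integer(0)
      for (wl in (50L - max_edits):(50L + max_edits)) {
        ss <- seq_len(L - wl + 1L)
        d <- utils::adist(pat, substring(seqv, ss, ss + wl - 1L))
        hitpos <- union(hitpos, ss[as.integer(d) <= max_edits])
      }
      if (!length(hitpos)) next
      hitpos <- sort(hitpos)
      cl <- cumsum(c(TRUE, diff(hitpos) > cluster_gap))
      for (k in unique(cl)) {
        lo <- min(hitpos[cl == k]); hi <- max(hitpos[cl == k]) + 52L
        span <- if (store == "rev_bis") {
          c(max(1L, L - hi + 1L), L - lo + 1L)   # map to plus strand
        } else {
          c(lo, min(L, hi))
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          store = store, ori = ori, chrom = chrom,
          plus_lo = span[1L], plus_hi = span[2L])
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(store = character(), ori = character(),
                   chrom = character(), plus_lo = integer(),
                   plus_hi = integer())
}

# map an align_probe() row to the (store, orientation) search space
alignment_space <- function(variant, strand) {
  dplyr::case_when(
    variant == "fwd" ~ "fwd|+",
    variant == "rev" ~ "fwd|-",
    variant == "fwd_bis" & strand == "+" ~ "fwd_bis|+",
    variant == "fwd_bis" & strand == "-" ~ "fwd_bis|-",
    variant == "rev_bis" & strand == "-" ~ "rev_bis|+",
    TRUE ~ "rev_bis|-")
}

# simulated replicate set with a planted superior member
simulate_replicate_set <- function(seed, n = 18L,
                                   slopes = c(1, 0.6, 0.6),
                                   sigmas = c(0.05, 1, 1)) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n))
  latent <- rnorm(n, 0, 2)
  members <- purrr::map2(slopes, sigmas, function(b, s) {
    tibble::tibble(sample = samples, m = b * latent + rnorm(n, 0, s))
  })
  names(members) <- paste0("P", seq_along(members))
  list(members = members,
       epicv1 = tibble::tibble(sample = samples,
                               m = latent + rnorm(n, 0, 0.1)),
       wgbs = tibble::tibble(sample = samples,
                             value = latent + rnorm(n, 0, 0.3)),
       latent = latent)
}
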