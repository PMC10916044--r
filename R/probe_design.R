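# Bisulphite probe-design engine.
#
# Conventions (documented in the methods vignette):
#   * Forward_Sequence = left flank + "[XY]" + right flank, with the
#     interrogated cytosine the first bracketed base on the design strand.
#     Flank lengths are free; brackets are located, not assumed at offsets.
#   * T designs use the Forward_Sequence strand as the design strand D;
#     B designs use its reverse complement (where the CpG reappears as CG).
#   * The bisulphite-converted design strand V templates C-strand probes
#     (probe = reverse complement of a 50-nt V window); O-strand probes
#     anneal to the strand complementary to V, so the probe sequence equals
#     the V window read 5'->3'.
#   * Window placement, with t the 0-based target-C index on D:
#       Type I,  C: V[t   .. t+49]  (3' terminus covers the target base)
#       Type II, C: V[t+1 .. t+50]  (3' terminus abuts the target C)
#       Type I,  O: V[t-49 .. t  ]  (3' terminus covers the target base)
#       Type II, O: V[t-50 .. t-1]
#   * Type I: allele A = unmethylated template, allele B = methylated.
#     Type II: single allele-A probe from the degenerate template (body
#     CpG cytosines -> Y, rendered R after reverse complement).

#' Bisulphite-convert a sequence window
#'
#' Converts every cytosine outside a CpG context to thymine. CpG
#' cytosines are kept (`methylated`), converted to T (`unmethylated`), or
#' rendered as the degenerate base Y (`degenerate`, the Type II body
#' encoding; reverse-complementing yields the manifest's R). A terminal C
#' whose genomic successor lies outside the window uses `successor` to
#' decide CpG status; if unknown it is treated as non-CpG, since
#' conversion depends on the genome, not the window cut.
#'
#' @param seq character vector over A/C/G/T.
#' @param mode `"methylated"`, `"unmethylated"` or `"degenerate"`.
#' @param successor single character: the genomic base following the last
#'   base of `seq`, or `NA` if unknown.
#' @param protect optional integer vector (1-based, recycled across `seq`
#'   elements of equal length): positions treated as interrogated
#'   cytosines, i.e. converted per `mode` regardless of CpG context (used
#'   for CpH 'ch' targets).
#' @return converted character vector, lengths preserved.
#' @export
#' @examples
#' bisulphite_convert_window("ACGACCGT", "methylated")    # "ACGATCGT"
#' bisulphite_convert_window("ACGACCGT", "unmethylated")  # "ATGATTGT"
#' bisulphite_convert_window("ACGACCGT", "degenerate")    # "AYGATYGT"
bisulphite_convert_window <- function(seq,
                                      mode = c("methylated", "unmethylated",
                                               "degenerate"),
                                      successor = NA_character_,
                                      protect = integer(0)) {
  mode <- match.arg(mode)
  assert_dna(seq, c("A", "C", "G", "T"), "window")
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n == 0L) return("")
    nxt <- c(ch[-1L], if (is.na(successor)) "N" else successor)
    is_cpg_c <- ch == "C" & nxt == "G"
    if (length(protect)) is_cpg_c[protect] <- ch[protect] == "C"
    plain_c <- ch == "C" & !is_cpg_c
    ch[plain_c] <- "T"
    ch[is_cpg_c] <- switch(mode,
                           methylated = "C",
                           unmethylated = "T",
                           degenerate = "Y")
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_forward_sequence <- function(forward_sequence) {
  m <- stringr::str_match(forward_sequence,
                          "^([ACGT]*)\\[([ACGT]{2})\\]([ACGT]*)$")
  if (any(is.na(m[, 1L]))) {
    abort("forward_sequence must be FLANK[XY]FLANK over A/C/G/T")
  }
  list(left = m[, 2L], bracket = m[, 3L], right = m[, 4L])
}

# Build the design strand and locate the target cytosine (0-based).
design_strand <- function(forward_sequence, strand_tb) {
  p <- split_forward_sequence(forward_sequence)
  if (strand_tb == "T") {
    if (substr(p$bracket, 1L, 1L) != "C") {
      abort("undesignable: top-strand target is not a cytosine")
    }
    list(seq = paste0(p$left, p$bracket, p$right), t = nchar(p$left))
  } else if (strand_tb == "B") {
    if (substr(p$bracket, 2L, 2L) != "G") {
      abort("undesignable: bottom strand carries no target cytosine")
    }
    list(seq = revcomp(paste0(p$left, p$bracket, p$right)),
         t = nchar(p$right))
  } else {
    abort("unknown strand_tb; suffix required")
  }
}

design_window_bounds <- function(t, strand_co, design_type) {
  # 0-based half-open [from, to) on the design strand
  if (strand_co == "C") {
    if (design_type == "I") c(t, t + 50L) else c(t + 1L, t + 51L)
  } else if (strand_co == "O") {
    if (design_type == "I") c(t - 49L, t + 1L) else c(t - 50L, t)
  } else {
    abort("unknown strand_co; suffix required")
  }
}

probe_from_template <- function(V, from, to, strand_co) {
  w <- substr0(V, from, to)
  if (strand_co == "C") revcomp(w) else w
}

#' Recompute Allele A/B probe sequences from a manifest row
#'
#' Re-derives the 50-nt probe sequences from `forward_sequence` and the
#' decoded IlmnID suffix via the bisulphite design engine: the design
#' window on the strand implied by `(strand_tb, strand_co)` is
#' bisulphite-converted (Type I: unmethylated template gives allele A,
#' methylated gives allele B; Type II: degenerate template, allele A
#' only) and reverse-complemented into probe orientation for C-strand
#' designs. The result is comparable character-for-character with the
#' manifest `AlleleA_ProbeSeq` / `AlleleB_ProbeSeq` columns.
#'
#' @param forward_sequence manifest Forward_Sequence (bracketed target).
#' @param strand_tb,strand_co,design_type decoded suffix fields.
#' @return A list with `allele_a`, `allele_b` (`""` for Type II),
#'   `next_base` (the ddNTP incorporated at single-base extension for
#'   Type I, `""` for Type II) and `color_channel` (`"Red"`/`"Grn"`,
#'   `""` for Type II).
#' @export
recompute_probe_sequences <- function(forward_sequence, strand_tb,
                                      strand_co, design_type) {
  d <- design_strand(forward_sequence, strand_tb)
  b <- design_window_bounds(d$t, strand_co, design_type)
  # conversion needs one base of successor context beyond the window
  if (b[1L] < 0L || b[2L] + 1L > nchar(d$seq) ||
      (design_type == "I" && strand_co == "C" && d$t < 1L)) {
    abort("undesignable: forward_sequence flank too short for 50-nt window")
  }
  protect <- d$t + 1L  # interrogated cytosine, converted per-mode always
  if (design_type == "I") {
    v_un <- bisulphite_convert_window(d$seq, "unmethylated",
                                      protect = protect)
    v_me <- bisulphite_convert_window(d$seq, "methylated",
                                      protect = protect)
    allele_a <- probe_from_template(v_un, b[1L], b[2L], strand_co)
    allele_b <- probe_from_template(v_me, b[1L], b[2L], strand_co)
    if (strand_co == "C") {
      # extension reads template position t-1 (templates agree there)
      tmpl <- substr0(v_me, d$t - 1L, d$t)
      next_base <- complement_chr(tmpl)
    } else {
      # extension reads the opposite strand C of the CpG: incorporates G
      next_base <- "G"
    }
    channel <- ifelse(next_base %in% c("A", "T"), "Red", "Grn")
    list(allele_a = allele_a, allele_b = allele_b,
         next_base = next_base, color_channel = channel)
  } else {
    v_dg <- bisulphite_convert_window(d$seq, "degenerate",
                                      protect = protect)
    allele_a <- probe_from_template(v_dg, b[1L], b[2L], strand_co)
    list(allele_a = allele_a, allele_b = "",
         next_base = "", color_channel = "")
  }
}

#' Verify manifest probe sequences against the design engine
#'
#' Recomputes each probe's allele sequences from its Forward_Sequence and
#' suffix and flags exact string equality against the manifest allele
#' columns (both alleles must match for Type I). Undesignable probes
#' (short flanks, missing suffix) count as unmatched and are listed.
#'
#' @param table manifest tibble with `forward_sequence` and allele columns.
#' @return A tibble, one row per attempted probe: `ilmn_id`, `match_a`,
#'   `match_b`, `matched`, `recomputed_a`, `recomputed_b`,
#'   `first_mismatch_offset` (1-based offset of the first differing
#'   allele-A character, `NA` when matched), `note`. The overall matched
#'   fraction is attached as attribute `"fraction"`.
#' @export
verify_manifest_sequences <- function(table) {
  rows <- purrr::pmap(
    list(table$ilmn_id, table$forward_sequence, table$strand_tb,
         table$strand_co, table$design_type, table$allele_a_seq,
         table$allele_b_seq),
    function(id, fwd, tb, co, ty, a, b) {
      rec <- tryCatch(recompute_probe_sequences(fwd, tb, co, ty),
                      error = function(e) conditionMessage(e))
      if (is.character(rec)) {
        return(tibble(ilmn_id = id, match_a = FALSE, match_b = FALSE,
                      matched = FALSE, recomputed_a = NA_character_,
                      recomputed_b = NA_character_,
                      first_mismatch_offset = NA_integer_, note = rec))
      }
      ma <- identical(rec$allele_a, a)
      mb <- if (ty == "I") identical(rec$allele_b, b) else TRUE
      off <- NA_integer_
      if (!ma && !is.na(rec$allele_a) && nchar(rec$allele_a) == nchar(a)) {
        diff <- which(strsplit(rec$allele_a, "")[[1L]] !=
                        strsplit(a, "")[[1L]])
        if (length(diff)) off <- diff[1L]
      }
      tibble(ilmn_id = id, match_a = ma, match_b = mb,
             matched = ma && mb, recomputed_a = rec$allele_a,
             recomputed_b = rec$allele_b,
             first_mismatch_offset = off, note = "")
    })
  out <- bind_rows(rows)
  attr(out, "fraction") <- if (nrow(out)) mean(out$matched) else NA_real_
  out
}

#' Extension-site semantics of a probe design
#'
#' Type I probes designed to the converted (`C`) strand extend at the
#' base adjacent to the target CpG (the manifest Next_Base); Type I
#' probes on the opposite (`O`) strand extend at the C of the target CpG
#' site itself. Type II probes read the target base by single-base
#' extension, with no fixed channel.
#'
#' @param design_type `"I"` or `"II"`; @param strand_co `"C"` or `"O"`.
#' @param next_base for Type I C-strand designs, the manifest Next_Base
#'   (used to report the expected channel); optional.
#' @return A list with `site` (`"target_C"` or `"next_base"`) and
#'   `expected_channel` (`"Red"`, `"Grn"`, or `NA` for Type II).
#' @export
infer_extension_site <- function(design_type, strand_co,
                                 next_base = NA_character_) {
  if (!strand_co %in% c("C", "O")) {
    if (design_type == "II") {
      return(list(site = "target_C", expected_channel = NA_character_))
    }
    abort("infer_extension_site(): unknown strand_co")
  }
  if (design_type == "II") {
    list(site = "target_C", expected_channel = NA_character_)
  } else if (strand_co == "O") {
    # extension incorporates G opposite the CpG's opposite-strand C
    list(site = "target_C", expected_channel = "Grn")
  } else {
    ch <- if (is.na(next_base) || !nzchar(next_base)) NA_character_
          else if (next_base %in% c("A", "T")) "Red" else "Grn"
    list(site = "next_base", expected_channel = ch)
  }
}
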