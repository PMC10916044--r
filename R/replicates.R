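# Replicate-probe detection: the three replicate classes new to EPICv2.
#
#   exact         same Name and same (allele A, allele B) sequence pair
#   location      same target coordinate with >= 2 distinct sequences
#   sequence_only same sequence pair with >= 2 distinct Names
#
# Location keying ignores strand (Illumina reports the C coordinate);
# chr0 probes are excluded from location sets but can still be
# sequence_only members. Name agreement within location sets is recorded
# so both published phrasings of "location-replicate" are covered.

seq_key <- function(table) paste(table$allele_a_seq, table$allele_b_seq,
                                 sep = "|")
loc_key <- function(table) paste(table$chrom, table$mapinfo, sep = ":")

#' Detect and classify replicate probes
#'
#' Groups manifest probes into maximal replicate sets of the three
#' EPICv2 classes and emits the per-probe augmented-manifest fields.
#'
#' @param table manifest tibble.
#' @return A tibble of replicate sets: `set_id`, `replicate_class`
#'   (`exact` / `location` / `sequence_only`), `key`, `n_members`,
#'   `member_ilmn_ids` (list-column), `names_agree` (location sets only:
#'   all members share one Name). Per-probe fields are attached as
#'   attribute `"probe_fields"`: `ilmn_id`, `namerep`, `posrep`,
#'   `seqrep`, `posrep_IlmnIDs`, `seqrep_IlmnIDs`, `namerep_IlmnIDs`
#'   (semicolon-joined).
#' @export
classify_replicates <- function(table) {
  grp_sets <- function(keys, keep, class) {
    idx <- which(keep)
    sp <- split(idx, keys[idx])
    sp <- sp[lengths(sp) >= 2L]
    if (!length(sp)) {
      return(tibble(set_id = character(), replicate_class = character(),
                    key = character(), n_members = integer(),
                    member_ilmn_ids = list(), names_agree = logical()))
    }
    tibble(
      set_id = paste0(class, "_", seq_along(sp)),
      replicate_class = class,
      key = names(sp),
      n_members = lengths(sp),
      member_ilmn_ids = lapply(sp, function(i) table$ilmn_id[i]),
      names_agree = vapply(sp, function(i) {
        length(unique(table$name[i])) == 1L
      }, logical(1)))
  }

  sk <- seq_key(table)
  lk <- loc_key(table)
  located <- table$chrom != "chr0"

  # exact: same name AND same sequence pair
  ek <- paste(table$name, sk, sep = "@")
  exact <- grp_sets(ek, rep(TRUE, nrow(table)), "exact")

  # location: same coordinate with >= 2 distinct sequences
  loc_all <- split(seq_len(nrow(table))[located], lk[located])
  loc_all <- loc_all[vapply(loc_all, function(i) {
    length(i) >= 2L && length(unique(sk[i])) >= 2L
  }, logical(1))]
  location <- if (length(loc_all)) {
    tibble(
      set_id = paste0("location_", seq_along(loc_all)),
      replicate_class = "location",
      key = names(loc_all),
      n_members = lengths(loc_all),
      member_ilmn_ids = lapply(loc_all, function(i) table$ilmn_id[i]),
      names_agree = vapply(loc_all, function(i) {
        length(unique(table$name[i])) == 1L
      }, logical(1)))
  } else {
    exact[0L, ]
  }

  # sequence_only: same sequence pair with >= 2 distinct names
  seq_all <- split(seq_len(nrow(table)), sk)
  seq_all <- seq_all[vapply(seq_all, function(i) {
    length(i) >= 2L && length(unique(table$name[i])) >= 2L
  }, logical(1))]
  seqonly <- if (length(seq_all)) {
    tibble(
      set_id = paste0("sequence_only_", seq_along(seq_all)),
      replicate_class = "sequence_only",
      key = names(seq_all),
      n_members = lengths(seq_all),
      member_ilmn_ids = lapply(seq_all, function(i) table$ilmn_id[i]),
      names_agree = FALSE)
  } else {
    exact[0L, ]
  }

  sets <- bind_rows(exact, location, seqonly)

  join_others <- function(keys, keep) {
    vapply(seq_len(nrow(table)), function(i) {
      if (!keep[i]) return("")
      peers <- which(keep & keys == keys[i])
      peers <- setdiff(peers, i)
      paste(table$ilmn_id[peers], collapse = ";")
    }, character(1))
  }
  name_ids <- join_others(table$name, rep(TRUE, nrow(table)))
  pos_ids <- join_others(lk, located)
  seq_ids <- join_others(sk, rep(TRUE, nrow(table)))
  fields <- tibble(
    ilmn_id = table$ilmn_id,
    namerep = nzchar(name_ids),
    posrep = nzchar(pos_ids),
    seqrep = nzchar(seq_ids),
    namerep_IlmnIDs = name_ids,
    posrep_IlmnIDs = pos_ids,
    seqrep_IlmnIDs = seq_ids)
  attr(sets, "probe_fields") <- fields
  sets
}

#' Histogram of replicate-set sizes per class
#'
#' @param sets tibble from [classify_replicates()].
#' @return tibble with `replicate_class`, `size`, `n_sets`.
#' @export
replicate_size_histogram <- function(sets) {
  if (nrow(sets) == 0L) {
    return(tibble(replicate_class = character(), size = integer(),
                  n_sets = integer()))
  }
  sets |>
    dplyr::count(.data$replicate_class, size = .data$n_members,
                 name = "n_sets") |>
    arrange(.data$replicate_class, .data$size)
}
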