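# Cross-array-version probe matching and provenance categories.

#' Match probes between EPICv2 and an older array manifest
#'
#' Matches every EPICv2 probe (replicates treated independently) against
#' another platform's manifest by 1) probe Name, 2) reconciled cytosine
#' coordinate and 3) probe sequence (both Allele A and Allele B must
#' match). One row is emitted per (v2 probe, other probe) matching pair;
#' older-array internal replicates therefore yield duplicated
#' `other_probe_id` values, never collapsed rows.
#'
#' @param v2 EPICv2 manifest tibble.
#' @param other manifest tibble for the older platform.
#' @param platform_tag tag stored in the output (`"EPICv1"`, `"K450"`,
#'   `"K27"`).
#' @return A tibble: `v2_ilmn_id`, `other_platform`, `other_probe_id`,
#'   `matched_by_name`, `matched_by_location`, `matched_by_sequence`.
#'   Rows exist only where at least one flag is `TRUE`.
#' @export
match_probes <- function(v2, other, platform_tag) {
  a_v2 <- manifest_assembly(v2); a_ot <- manifest_assembly(other)
  if (!is.na(a_v2) && !is.na(a_ot) && a_v2 != a_ot) {
    abort(sprintf("assembly mismatch: %s vs %s", a_v2, a_ot))
  }
  has_seq <- all(c("allele_a_seq", "allele_b_seq") %in% names(other)) &&
    all(c("allele_a_seq", "allele_b_seq") %in% names(v2))
  v2k <- tibble(
    v2_ilmn_id = v2$ilmn_id,
    v2_name = v2$name,
    v2_loc = dplyr::if_else(v2$chrom == "chr0", NA_character_,
                            loc_key(v2)),
    v2_seq = if (has_seq) seq_key(v2) else
      rep(NA_character_, nrow(v2)))
  otk <- tibble(
    other_probe_id = other$ilmn_id,
    ot_name = other$name,
    ot_loc = dplyr::if_else(other$chrom == "chr0", NA_character_,
                            loc_key(other)),
    ot_seq = if (has_seq) seq_key(other) else
      rep(NA_character_, nrow(other)))
  by_name <- inner_join(v2k, otk, by = c(v2_name = "ot_name"),
                        relationship = "many-to-many")
  by_loc <- inner_join(filter(v2k, !is.na(.data$v2_loc)),
                       filter(otk, !is.na(.data$ot_loc)),
                       by = c(v2_loc = "ot_loc"),
                       relationship = "many-to-many")
  by_seq <- if (has_seq) {
    inner_join(filter(v2k, !is.na(.data$v2_seq)),
               filter(otk, !is.na(.data$ot_seq)),
               by = c(v2_seq = "ot_seq"), relationship = "many-to-many")
  } else {
    by_name[0L, ]
  }
  pairs <- distinct(bind_rows(
    select(by_name, "v2_ilmn_id", "other_probe_id"),
    select(by_loc, "v2_ilmn_id", "other_probe_id"),
    select(by_seq, "v2_ilmn_id", "other_probe_id")))
  if (nrow(pairs) == 0L) {
    return(tibble(v2_ilmn_id = character(), other_platform = character(),
                  other_probe_id = character(), matched_by_name = logical(),
                  matched_by_location = logical(),
                  matched_by_sequence = logical()))
  }
  flag <- function(tb) {
    paste(pairs$v2_ilmn_id, pairs$other_probe_id) %in%
      paste(tb$v2_ilmn_id, tb$other_probe_id)
  }
  tibble(
    v2_ilmn_id = pairs$v2_ilmn_id,
    other_platform = platform_tag,
    other_probe_id = pairs$other_probe_id,
    matched_by_name = flag(by_name),
    matched_by_location = flag(by_loc),
    matched_by_sequence = flag(by_seq)) |>
    arrange(.data$v2_ilmn_id, .data$other_probe_id)
}

#' Augmented-manifest fields from a cross-version match table
#'
#' Collapses [match_probes()] rows to one row per EPICv2 probe with
#' semicolon-joined matched probe ids and per-criterion flags, named for
#' the augmented manifest (e.g. `EPICv1probeID`, `EPICv1locmatch`,
#' `EPICv1seqmatch`).
#'
#' @param matches tibble from [match_probes()].
#' @param prefix field-name prefix (default taken from `other_platform`).
#' @return one-row-per-probe tibble keyed by `ilmn_id`.
#' @export
crossversion_fields <- function(matches, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- if (nrow(matches)) matches$other_platform[1L] else "other"
  }
  out <- matches |>
    group_by(.data$v2_ilmn_id) |>
    summarise(
      probe_id = paste(.data$other_probe_id, collapse = ";"),
      locmatch = paste(ifelse(.data$matched_by_location, "Y", "N"),
                       collapse = ";"),
      seqmatch = paste(ifelse(.data$matched_by_sequence, "Y", "N"),
                       collapse = ";"),
      .groups = "drop") |>
    rename(ilmn_id = "v2_ilmn_id")
  names(out)[-1L] <- paste0(prefix, c("probeID", "locmatch", "seqmatch"))
  out
}

#' Assign provenance categories to EPICv2 target locations
#'
#' Partitions the unique EPICv2 target locations (rs/nv probes and chr0
#' removed, locations deduplicated before counting) into `new` (EPICv2
#' only), `retained` (also on EPICv1) and `reinstated` (on 450K and/or
#' 27K but not EPICv1), and reports EPICv1 locations absent from EPICv2
#' as the `excluded` set.
#'
#' @param v2,epicv1,k450,k27 manifest tibbles (k450/k27 may be `NULL`).
#' @return A tibble with `location`, `chrom`, `mapinfo`, `category` for
#'   every unique EPICv2 location, plus attribute `"excluded"` (tibble of
#'   EPICv1-only locations) and attribute `"counts"` (named list).
#' @export
assign_provenance <- function(v2, epicv1, k450 = NULL, k27 = NULL) {
  locs <- function(tb) {
    if (is.null(tb)) return(character())
    keep <- tb$chrom != "chr0" & !(tb$target_class %in% c("rs", "nv"))
    unique(loc_key(tb)[keep])
  }
  l2 <- locs(v2); l1 <- locs(epicv1)
  lold <- union(locs(k450), locs(k27))
  category <- dplyr::case_when(
    l2 %in% l1 ~ "retained",
    l2 %in% lold ~ "reinstated",
    TRUE ~ "new")
  parts <- stringr::str_split_fixed(l2, ":", 2L)
  out <- tibble(location = l2, chrom = parts[, 1L],
                mapinfo = as.integer(parts[, 2L]), category = category)
  exc <- setdiff(l1, l2)
  eparts <- stringr::str_split_fixed(exc, ":", 2L)
  excluded <- tibble(location = exc,
                     chrom = if (length(exc)) eparts[, 1L] else character(),
                     mapinfo = if (length(exc)) as.integer(eparts[, 2L])
                               else integer())
  attr(out, "excluded") <- excluded
  attr(out, "counts") <- list(
    new = sum(category == "new"),
    retained = sum(category == "retained"),
    reinstated = sum(category == "reinstated"),
    excluded = nrow(excluded),
    total_v2 = length(l2))
  out
}
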