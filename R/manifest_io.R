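# Manifest reading/writing and IlmnID decoding.
#
# Internal coordinate convention: `mapinfo` is the 1-based position of the
# interrogated cytosine on the plus strand of the stated assembly (Illumina
# MAPINFO). SeSAMe/BED 0-based half-open intervals are converted at the
# boundary. Probes with chrom == "chr0" / mapinfo == 0 are retained in tables
# but excluded from every location-keyed operation.

CANONICAL_COLS <- c("ilmn_id", "name", "target_class", "strand_tb",
                    "strand_co", "design_type", "rep_num", "chrom", "mapinfo",
                    "forward_sequence", "allele_a_seq", "allele_b_seq",
                    "next_base", "color_channel")

ILLUMINA_HEADERS <- c(
  ilmn_id = "IlmnID", name = "Name", target_class = "Probe_Type",
  rep_num = "Rep_Num",
  strand_tb = "Strand_TB", strand_co = "Strand_CO",
  design_type = "Infinium_Design_Type", chrom = "CHR", mapinfo = "MAPINFO",
  forward_sequence = "Forward_Sequence", allele_a_seq = "AlleleA_ProbeSeq",
  allele_b_seq = "AlleleB_ProbeSeq", next_base = "Next_Base",
  color_channel = "Color_Channel")

#' Decode IlmnID probe identifiers
#'
#' EPICv2 IlmnIDs are a probe `Name` plus a four-character suffix
#' (e.g. `cg09617579_BC12`) encoding: design strand top (`T`) or bottom
#' (`B`); bisulphite-converted (`C`) or opposite (`O`) strand; Infinium
#' design type (`1`/`2`); and the replicate number of the identical probe.
#' Identifiers without a suffix (older-array dialects) decode with unknown
#' strand fields, `NA` design type and `rep_num = 1`.
#'
#' @param ilmn_id character vector of probe identifiers.
#' @return A tibble with columns `ilmn_id`, `name`, `target_class`
#'   (`cg`/`ch`/`rs`/`nv`/`control`), `strand_tb`, `strand_co`,
#'   `design_type` (`"I"`/`"II"`), `rep_num`, `has_suffix`.
#' @export
#' @examples
#' parse_ilmnid(c("cg09617579_BC12", "cg04853151_BC21", "cg00000029"))
parse_ilmnid <- function(ilmn_id) {
  if (any(is.na(ilmn_id) | !nzchar(ilmn_id))) {
    abort("parse_ilmnid(): empty or missing IlmnID")
  }
  suffix <- stringr::str_match(ilmn_id, "^(.*)_([A-Za-z0-9]{4})$")
  has_suffix_slot <- !is.na(suffix[, 3L])
  valid <- has_suffix_slot &
    grepl("^[TB][CO][12][1-9]$", suffix[, 3L])
  if (any(has_suffix_slot & !valid)) {
    abort(sprintf(
      "parse_ilmnid(): suffix not matching [TB][CO][12][1-9] in: %s",
      paste(head(ilmn_id[has_suffix_slot & !valid], 5L), collapse = ", ")))
  }
  name <- ifelse(valid, suffix[, 2L], ilmn_id)
  sfx <- ifelse(valid, suffix[, 3L], NA_character_)
  cls <- stringr::str_match(name, "^(cg|ch|rs|nv)")[, 2L]
  tibble(
    ilmn_id = ilmn_id,
    name = name,
    target_class = ifelse(is.na(cls), "control", cls),
    strand_tb = ifelse(valid, substr(sfx, 1L, 1L), "unknown"),
    strand_co = ifelse(valid, substr(sfx, 2L, 2L), "unknown"),
    design_type = dplyr::case_when(
      !valid ~ NA_character_,
      substr(sfx, 3L, 3L) == "1" ~ "I",
      TRUE ~ "II"),
    rep_num = ifelse(valid, as.integer(substr(sfx, 4L, 4L)), 1L),
    has_suffix = valid)
}

#' Compose an IlmnID from its suffix components
#'
#' Inverse of [parse_ilmnid()] for suffixed probes.
#'
#' @param name probe name (e.g. `"cg09617579"`).
#' @param strand_tb `"T"` or `"B"`; @param strand_co `"C"` or `"O"`.
#' @param design_type `"I"` or `"II"`; @param rep_num integer 1-9.
#' @return character vector of IlmnIDs.
#' @export
compose_ilmnid <- function(name, strand_tb, strand_co, design_type,
                           rep_num = 1L) {
  stopifnot(strand_tb %in% c("T", "B"), strand_co %in% c("C", "O"),
            design_type %in% c("I", "II"), rep_num %in% 1:9)
  paste0(name, "_", strand_tb, strand_co,
         ifelse(design_type == "I", "1", "2"), rep_num)
}

new_manifest <- function(tbl, dialect, assembly = "toy",
                         controls = NULL) {
  attr(tbl, "source_dialect") <- dialect
  attr(tbl, "assembly") <- assembly
  attr(tbl, "controls") <- controls
  tbl
}

#' Source dialect / assembly / controls of a manifest table
#' @param x a manifest tibble from [read_illumina_manifest()],
#'   [read_sesame_manifest()] or [design_manifest()].
#' @return a string, or for `manifest_controls()` a tibble (or `NULL`).
#' @export
manifest_dialect <- function(x) attr(x, "source_dialect") %||% "illumina"

#' @rdname manifest_dialect
#' @export
manifest_assembly <- function(x) attr(x, "assembly") %||% NA_character_

#' @rdname manifest_dialect
#' @export
manifest_controls <- function(x) attr(x, "controls")

validate_manifest <- function(tbl) {
  if (anyDuplicated(tbl$ilmn_id)) {
    abort("manifest: duplicated IlmnID")
  }
  bad <- which(xor(tbl$chrom == "chr0", tbl$mapinfo == 0L))
  if (length(bad)) {
    abort(sprintf("manifest row %d: chr0/MAPINFO=0 must co-occur", bad[1L]))
  }
  invisible(tbl)
}

#' Read an Illumina-layout manifest CSV
#'
#' Understands the Illumina section layout: optional descriptive
#' `[Heading]` lines, an `[Assay]` section with one CSV row per probe, and
#' an optional `[Controls]` section (headerless: address, control type,
#' color, description). Assay rows are decoded into the canonical probe
#' record columns; any extra manifest columns are carried through
#' unchanged. Control probes live in a separate partition (see
#' [manifest_controls()]) and are never counted among assay probes.
#'
#' @param path path to the CSV file.
#' @param include_controls parse the `[Controls]` section (default `TRUE`).
#' @return A manifest tibble (one row per assay probe) with attributes
#'   `source_dialect = "illumina"`, `assembly`, and `controls`.
#' @export
read_illumina_manifest <- function(path, include_controls = TRUE) {
  lines <- readr::read_lines(path)
  assay_at <- which(grepl("^\\[Assay\\]", lines))
  controls_at <- which(grepl("^\\[Controls\\]", lines))
  if (length(assay_at) == 0L) {
    # plain CSV without section markers: treat whole file as the assay table
    assay_at <- 0L
  } else {
    assay_at <- assay_at[1L]
  }
  assembly <- NA_character_
  if (assay_at > 0L) {
    hd <- lines[seq_len(assay_at - 1L)]
    m <- stringr::str_match(hd, "^Assembly,(.+)$")
    if (any(!is.na(m[, 2L]))) assembly <- m[which(!is.na(m[, 2L]))[1L], 2L]
  }
  assay_end <- if (length(controls_at)) controls_at[1L] - 1L else length(lines)
  assay_lines <- lines[(assay_at + 1L):assay_end]
  assay_lines <- assay_lines[nzchar(assay_lines)]
  raw <- readr::read_csv(I(assay_lines), col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required <- c("IlmnID", "Name", "Infinium_Design_Type", "CHR", "MAPINFO",
                "Forward_Sequence", "AlleleA_ProbeSeq", "AlleleB_ProbeSeq")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("manifest format error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  mapinfo <- suppressWarnings(as.integer(raw$MAPINFO))
  bad <- which(is.na(mapinfo) & !is.na(raw$MAPINFO))
  if (length(bad)) {
    abort(sprintf("manifest row %d: malformed MAPINFO '%s'",
                  bad[1L], raw$MAPINFO[bad[1L]]))
  }
  ids <- parse_ilmnid(raw$IlmnID)
  tbl <- tibble(
    ilmn_id = raw$IlmnID,
    name = raw$Name,
    target_class = ids$target_class,
    strand_tb = ids$strand_tb,
    strand_co = ids$strand_co,
    design_type = dplyr::coalesce(
      dplyr::if_else(raw$Infinium_Design_Type %in% c("I", "II"),
                     raw$Infinium_Design_Type, NA_character_),
      ids$design_type),
    rep_num = ids$rep_num,
    chrom = dplyr::coalesce(raw$CHR, "chr0"),
    mapinfo = dplyr::coalesce(mapinfo, 0L),
    forward_sequence = raw$Forward_Sequence,
    allele_a_seq = dplyr::coalesce(raw$AlleleA_ProbeSeq, ""),
    allele_b_seq = dplyr::coalesce(raw$AlleleB_ProbeSeq, ""),
    next_base = dplyr::coalesce(raw[["Next_Base"]], ""),
    color_channel = dplyr::coalesce(raw[["Color_Channel"]], ""))
  if ("Rep_Num" %in% names(raw)) {
    rn <- suppressWarnings(as.integer(raw$Rep_Num))
    tbl$rep_num <- dplyr::coalesce(rn, tbl$rep_num)
  }
  extra <- setdiff(names(raw), ILLUMINA_HEADERS)
  if (length(extra)) tbl <- bind_cols(tbl, raw[extra])
  validate_manifest(tbl)
  controls <- NULL
  if (include_controls && length(controls_at)) {
    ctl_lines <- lines[(controls_at[1L] + 1L):length(lines)]
    ctl_lines <- ctl_lines[nzchar(ctl_lines)]
    if (length(ctl_lines)) {
      controls <- readr::read_csv(
        I(ctl_lines),
        col_names = c("address", "control_type", "color", "description"),
        col_types = "cccc", progress = FALSE)
    } else {
      controls <- tibble(address = character(), control_type = character(),
                         color = character(), description = character())
    }
  }
  new_manifest(tbl, "illumina", assembly, controls)
}

#' Read a SeSAMe-style mapping manifest (tab-delimited, BED convention)
#'
#' SeSAMe manifests give each target as a two-nucleotide, 0-based half-open
#' interval (`CpG_beg`, `CpG_end`). A 1-based cytosine point (`mapinfo =
#' beg + 1`) is derived at read time so location-keyed operations share one
#' convention with Illumina tables. Accepts either a headered TSV (columns
#' `Probe_ID`, `CpG_chrm`, `CpG_beg`, `CpG_end`, optionally `strand`,
#' `Color_Channel`) or a headerless whitespace-delimited file with columns
#' in that order.
#'
#' @param path path to the manifest file.
#' @param assembly assembly tag stored on the table (default `"hg38"`).
#' @return A manifest tibble with columns `ilmn_id`, `name`, `chrom`,
#'   `beg`, `end`, `strand`, `color_channel`, `mapinfo`, plus decoded
#'   suffix fields; attribute `source_dialect = "sesame"`.
#' @export
read_sesame_manifest <- function(path, assembly = "hg38") {
  first <- readr::read_lines(path, n_max = 1L)
  headered <- length(first) && grepl("Probe_ID|CpG_chrm", first)
  if (headered) {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    pick <- function(...) {
      nm <- intersect(c(...), names(raw))
      if (length(nm)) raw[[nm[1L]]] else rep(NA_character_, nrow(raw))
    }
    probe_id <- pick("Probe_ID", "probe_id")
    chrom <- pick("CpG_chrm", "chrom", "chr")
    beg <- pick("CpG_beg", "beg", "start")
    end <- pick("CpG_end", "end")
    strand <- pick("mapping_strand", "strand")
    color <- pick("Color_Channel", "col", "color")
  } else {
    raw <- readr::read_table(
      path, col_names = FALSE,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE)
    if (nrow(raw) == 0L) {
      return(new_manifest(
        tibble(ilmn_id = character(), name = character(),
               chrom = character(), beg = integer(), end = integer(),
               strand = character(), color_channel = character(),
               mapinfo = integer()),
        "sesame", assembly))
    }
    if (ncol(raw) < 4L) abort("sesame manifest: expected >= 4 columns")
    probe_id <- raw[[1L]]; chrom <- raw[[2L]]
    beg <- raw[[3L]]; end <- raw[[4L]]
    strand <- if (ncol(raw) >= 5L) raw[[5L]] else rep("*", nrow(raw))
    color <- if (ncol(raw) >= 6L) raw[[6L]] else rep("", nrow(raw))
  }
  beg_i <- suppressWarnings(as.integer(beg))
  end_i <- suppressWarnings(as.integer(end))
  bad <- which((is.na(beg_i) & !is.na(beg)) | (is.na(end_i) & !is.na(end)))
  if (length(bad)) {
    abort(sprintf("sesame manifest row %d: non-numeric coordinates", bad[1L]))
  }
  ids <- parse_ilmnid(probe_id)
  tbl <- tibble(
    ilmn_id = probe_id, name = ids$name,
    target_class = ids$target_class,
    strand_tb = ids$strand_tb, strand_co = ids$strand_co,
    design_type = ids$design_type, rep_num = ids$rep_num,
    chrom = dplyr::coalesce(chrom, "chr0"),
    beg = dplyr::coalesce(beg_i, -1L), end = dplyr::coalesce(end_i, 0L),
    strand = dplyr::coalesce(strand, "*"),
    color_channel = dplyr::coalesce(color, ""),
    mapinfo = dplyr::coalesce(beg_i, -1L) + 1L)
  tbl$mapinfo[tbl$chrom == "chr0" | tbl$beg < 0L] <- 0L
  tbl$chrom[tbl$beg < 0L] <- "chr0"
  new_manifest(tbl, "sesame", assembly)
}

#' Compare Illumina and SeSAMe manifest coordinates
#'
#' Joins two manifests on IlmnID and tests whether each shared probe's
#' Illumina point coordinate, widened to the CpG dinucleotide
#' `[mapinfo, mapinfo + 1]`, intersects the SeSAMe two-nucleotide BED
#' range. Probes absent from either side are reported with `status`
#' `"illumina_only"` / `"sesame_only"`. Probes lacking coordinates
#' (chr0) on either side get `agrees = NA`.
#'
#' @param illumina manifest tibble (Illumina dialect).
#' @param sesame manifest tibble (SeSAMe dialect).
#' @return A tibble with one row per probe: `ilmn_id`, `status`,
#'   `chrom_illumina`, `mapinfo`, `chrom_sesame`, `sesame_beg`,
#'   `sesame_end`, `agrees`. A summary list (counts of shared, absent,
#'   located, discrepant probes) is attached as attribute `"summary"`.
#' @export
compare_manifests <- function(illumina, sesame) {
  il <- tibble(ilmn_id = illumina$ilmn_id,
               chrom_illumina = illumina$chrom,
               mapinfo = illumina$mapinfo)
  se <- tibble(ilmn_id = sesame$ilmn_id,
               chrom_sesame = sesame$chrom,
               sesame_beg = if ("beg" %in% names(sesame)) sesame$beg
                            else sesame$mapinfo - 1L,
               sesame_end = if ("end" %in% names(sesame)) sesame$end
                            else sesame$mapinfo + 1L)
  out <- dplyr::full_join(il, se, by = "ilmn_id")
  out$status <- dplyr::case_when(
    is.na(out$chrom_illumina) ~ "sesame_only",
    is.na(out$chrom_sesame) ~ "illumina_only",
    TRUE ~ "shared")
  located <- out$status == "shared" &
    out$chrom_illumina != "chr0" & out$chrom_sesame != "chr0" &
    out$sesame_beg >= 0L
  # Illumina dinucleotide [mapinfo, mapinfo+1] vs SeSAMe (beg, end] in
  # 1-based closed space: intersect iff starts/ends overlap on same chrom
  out$agrees <- NA
  out$agrees[located] <-
    out$chrom_illumina[located] == out$chrom_sesame[located] &
    pmax(out$mapinfo[located], out$sesame_beg[located] + 1L) <=
    pmin(out$mapinfo[located] + 1L, out$sesame_end[located])
  out <- as_tibble(out)
  attr(out, "summary") <- list(
    n_shared = sum(out$status == "shared"),
    n_illumina_only = sum(out$status == "illumina_only"),
    n_sesame_only = sum(out$status == "sesame_only"),
    n_located = sum(located),
    n_discrepant = sum(!out$agrees[located]))
  out
}

#' Write an augmented manifest CSV
#'
#' Writes the manifest back in Illumina section layout (`[Heading]`,
#' `[Assay]`, optional `[Controls]`), appending any annotation blocks
#' (replicate fields, cross-version matches, cross-hybridisation flags,
#' replicate verdicts) as extra columns keyed by IlmnID. Round-trips
#' through [read_illumina_manifest()].
#'
#' @param table manifest tibble.
#' @param path output path.
#' @param annotations a named list of tibbles, each with an `ilmn_id`
#'   column plus annotation fields, or a single such tibble. Keys absent
#'   from `table` trigger a warning listing the orphans.
#' @return `path`, invisibly.
#' @export
write_augmented_manifest <- function(table, path, annotations = list()) {
  if (inherits(annotations, "data.frame")) annotations <- list(annotations)
  out <- table
  for (ann in annotations) {
    stopifnot("ilmn_id" %in% names(ann))
    orphans <- setdiff(ann$ilmn_id, table$ilmn_id)
    if (length(orphans)) {
      warn(sprintf("annotation keys not in manifest: %s%s",
                   paste(head(orphans, 5L), collapse = ", "),
                   if (length(orphans) > 5L) ", ..." else ""))
      ann <- ann[ann$ilmn_id %in% table$ilmn_id, , drop = FALSE]
    }
    out <- left_join(out, ann, by = "ilmn_id")
  }
  canon <- intersect(CANONICAL_COLS, names(out))
  body <- out[c(canon, setdiff(names(out), canon))]
  nm <- names(body)
  nm[match(canon, nm)] <- unname(ILLUMINA_HEADERS[canon])
  names(body) <- nm
  hd <- c("[Heading]",
          sprintf("Descriptor File Name,%s", basename(path)),
          sprintf("Assembly,%s", manifest_assembly(table)),
          "[Assay]")
  readr::write_lines(hd, path)
  readr::write_csv(body, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  ctl <- manifest_controls(table)
  if (!is.null(ctl) && nrow(ctl)) {
    readr::write_lines("[Controls]", path, append = TRUE)
    readr::write_csv(ctl, path, append = TRUE, col_names = FALSE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Count assay probes by target class
#'
#' @param table manifest tibble.
#' @return tibble with `target_class` and `n`.
#' @export
probe_class_counts <- function(table) {
  dplyr::count(table, .data$target_class, name = "n")
}
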