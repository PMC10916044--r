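# Value transforms, cross-platform matching, row-linear consensus fits,
# RMSE-based cross-hybridisation evidence, replicate verdicts, RLM QC.
#
# All cross-platform and RMSE computations operate in M/logit space;
# beta-space input is transformed at the boundary.

#' Beta value from methylated/unmethylated intensities
#'
#' `beta = C / (C + T + 100)`: the methylated signal fraction with an
#' offset of 100 in the denominator to avoid infinite values.
#'
#' @param C,T methylated / unmethylated signal (non-negative).
#' @return beta values in `[0, 1)`.
#' @export
#' @examples
#' beta_from_intensities(100, 100) # 1/3
beta_from_intensities <- function(C, T) {
  if (any(C < 0) || any(T < 0)) abort("negative signal intensity")
  C / (C + T + 100)
}

#' M-value (logit2) from beta
#'
#' `M = log2(beta / (1 - beta))`. Exact 0/1 betas are clipped to
#' `clip` / `1 - clip` when `clip > 0`, otherwise rejected.
#'
#' @param beta beta values in `[0, 1]`.
#' @param clip clipping bound for exact 0/1 (default 0: error instead).
#' @return M values.
#' @export
m_from_beta <- function(beta, clip = 0) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta outside [0, 1]")
  }
  if (clip > 0) {
    beta <- pmin(pmax(beta, clip), 1 - clip)
  } else if (any(beta == 0 | beta == 1, na.rm = TRUE)) {
    abort("beta of exactly 0/1 needs a clipping policy (clip > 0)")
  }
  log2(beta / (1 - beta))
}

#' Inverse of [m_from_beta()]
#' @param M M-values.
#' @return beta values.
#' @export
beta_from_m <- function(M) 2^M / (1 + 2^M)

#' WGBS logit value from read counts
#'
#' `logit2((C + 0.5) / (C + T + 1)) = log2((C + 0.5) / (T + 0.5))`, the
#' half-count-smoothed logit of per-CpG methylated/unmethylated reads.
#' Sites with zero coverage in any sample are removed upstream by
#' [match_cross_platform()].
#'
#' @param C,T methylated / unmethylated read counts (non-negative).
#' @return logit2 values.
#' @export
#' @examples
#' wgbs_logit(3, 0) # log2(7)
wgbs_logit <- function(C, T) {
  if (any(C < 0) || any(T < 0)) abort("negative read counts")
  log2((C + 0.5) / (T + 0.5))
}

#' Construct a methylation measurement table
#'
#' A long tibble of per-site, per-sample measurements for one platform,
#' with a quality companion: detection p-values for arrays (`qc_type =
#' "detection_p"`) or read coverage for WGBS (`qc_type = "coverage"`).
#'
#' @param data tibble with columns `site`, `sample`, `value`, `qc`.
#' @param platform platform tag (e.g. `"EPICv2"`).
#' @param space `"beta"`, `"M"` or `"logit"`.
#' @param qc_type `"detection_p"` or `"coverage"`.
#' @return the validated tibble with attributes set.
#' @export
methyl_table <- function(data, platform, space = c("M", "beta", "logit"),
                         qc_type = c("detection_p", "coverage")) {
  space <- match.arg(space); qc_type <- match.arg(qc_type)
  stopifnot(all(c("site", "sample", "value", "qc") %in% names(data)))
  if (space == "beta" &&
      any(data$value < 0 | data$value > 1, na.rm = TRUE)) {
    abort("beta-space values outside [0, 1]")
  }
  out <- as_tibble(data)
  attr(out, "platform") <- platform
  attr(out, "space") <- space
  attr(out, "qc_type") <- qc_type
  out
}

to_m_space <- function(tbl, clip = 1e-6) {
  if (attr(tbl, "space") == "beta") {
    tbl$value <- m_from_beta(tbl$value, clip = clip)
    attr(tbl, "space") <- "M"
  }
  tbl
}

#' Match methylation tables across platforms
#'
#' Builds the full-complement sites x samples x platforms block used by
#' the consensus analysis: array sites with any detection p-value above
#' `detection_p` are dropped, WGBS sites with any zero-coverage sample
#' are dropped, and only sites present on every platform with every
#' shared sample survive. When a manifest is supplied, duplicate-location
#' probes are resolved by manifest order (the probe appearing first
#' wins) after keying array sites by coordinate.
#'
#' @param tables named list of [methyl_table()] tibbles (>= 2).
#' @param manifest optional manifest for coordinate keying of array
#'   probes: sites matching `ilmn_id` are re-keyed to `chrom:mapinfo`.
#' @param detection_p dropout threshold (default 0.05).
#' @return long tibble `site`, `platform`, `sample`, `m` (M/logit space)
#'   with attribute `"exclusions"`: tibble `site`, `platform`, `reason`.
#' @export
match_cross_platform <- function(tables, manifest = NULL,
                                 detection_p = 0.05) {
  stopifnot(length(tables) >= 2L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, attr, "", "platform")
  }
  shared_samples <- Reduce(intersect, lapply(tables, function(t)
    unique(t$sample)))
  if (!length(shared_samples)) abort("no shared samples across platforms")
  excl <- list()
  keyed <- purrr::imap(tables, function(tbl, platform) {
    tbl <- filter(tbl, .data$sample %in% shared_samples)
    if (!is.null(manifest) && any(tbl$site %in% manifest$ilmn_id)) {
      key <- tibble(site = manifest$ilmn_id,
                    coord = paste(manifest$chrom, manifest$mapinfo,
                                  sep = ":"),
                    ord = seq_len(nrow(manifest))) |>
        filter(manifest$chrom != "chr0")
      tbl <- inner_join(tbl, key, by = "site")
      # duplicate-location probes: first manifest row wins
      keep <- tbl |>
        distinct(.data$site, .data$coord, .data$ord) |>
        group_by(.data$coord) |>
        dplyr::slice_min(.data$ord, n = 1L, with_ties = FALSE) |>
        ungroup()
      dropped <- setdiff(unique(tbl$site), keep$site)
      if (length(dropped)) {
        excl[[length(excl) + 1L]] <<- tibble(
          site = dropped, platform = platform,
          reason = "duplicate_location_later_in_manifest")
      }
      tbl <- tbl |>
        filter(.data$site %in% keep$site) |>
        mutate(site = .data$coord) |>
        select(-"coord", -"ord")
    }
    qc_type <- attr(tbl, "qc_type")
    bad_sites <- tbl |>
      group_by(.data$site) |>
      summarise(bad = if (qc_type == "detection_p") {
        any(is.na(.data$value)) || any(.data$qc > detection_p) ||
          dplyr::n() < length(shared_samples)
      } else {
        any(is.na(.data$value)) || any(.data$qc == 0) ||
          dplyr::n() < length(shared_samples)
      }, .groups = "drop") |>
      filter(.data$bad)
    if (nrow(bad_sites)) {
      excl[[length(excl) + 1L]] <<- tibble(
        site = bad_sites$site, platform = platform,
        reason = if (qc_type == "detection_p") "detection_p_failure"
                 else "zero_coverage")
    }
    tbl <- anti_join(tbl, bad_sites, by = "site")
    tbl <- to_m_space(tbl)
    tibble(site = tbl$site, platform = platform, sample = tbl$sample,
           m = tbl$value)
  })
  common_sites <- Reduce(intersect, lapply(keyed, function(t)
    unique(t$site)))
  out <- bind_rows(keyed) |>
    filter(.data$site %in% common_sites) |>
    arrange(.data$site, .data$platform, .data$sample)
  attr(out, "exclusions") <- if (length(excl)) bind_rows(excl) else
    tibble(site = character(), platform = character(), reason = character())
  out
}

#' Row-linear consensus fit (sensitivity and precision per platform)
#'
#' For each site, the consensus is the across-platform mean per sample;
#' each platform's values are regressed on the consensus by ordinary
#' least squares. The slope is the platform's sensitivity to methylation
#' change at that site; precision is the residual scatter around the
#' regression line (root mean squared residual, denominator `n - 2`;
#' smaller is superior). An adaptation of the interlaboratory
#' consistency design of ASTM E691, with platforms in place of
#' laboratories. When every platform contributes to the consensus the
#' platform slopes average to 1 per site.
#'
#' @param matched long tibble from [match_cross_platform()] (columns
#'   `site`, `platform`, `sample`, `m`), or any tibble with those
#'   columns; values must be in M/logit space.
#' @param center centre the consensus before fitting (Mandel
#'   parameterisation). Changes only the intercept `alpha`, never slope
#'   or precision.
#' @return tibble of class `rowlinear_fit`: `site`, `platform`, `alpha`,
#'   `sensitivity`, `precision`, `n_samples`.
#' @export
rowlinear_fit <- function(matched, center = FALSE) {
  wide <- matched |>
    group_by(.data$site, .data$sample) |>
    mutate(consensus = mean(.data$m)) |>
    ungroup()
  fit_grp <- function(df, key) {
    n <- nrow(df)
    cm <- mean(df$consensus)
    ss <- sum((df$consensus - cm)^2)
    if (n < 3L || !is.finite(ss) || ss == 0) {
      abort(sprintf(
        "degenerate row-linear fit (n < 3 or zero consensus variance) at site %s",
        key$site))
    }
    b <- sum((df$consensus - cm) * (df$m - mean(df$m))) / ss
    r <- df$m - (mean(df$m) + b * (df$consensus - cm))
    tibble(
      alpha = if (center) mean(df$m) else mean(df$m) - b * cm,
      sensitivity = b,
      precision = sqrt(sum(r^2) / (n - 2L)),
      n_samples = n)
  }
  fits <- wide |>
    group_by(.data$site, .data$platform) |>
    dplyr::group_modify(fit_grp) |>
    ungroup()
  class(fits) <- c("rowlinear_fit", class(fits))
  fits
}

#' Paired Cohen's d
#'
#' `d = mean(x - y) / sd(x - y)` with the sample (n - 1) standard
#' deviation.
#'
#' @param x,y paired numeric vectors.
#' @return a single d value.
#' @export
paired_cohens_d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s == 0) {
    abort("paired_cohens_d undefined: zero sd of differences")
  }
  mean(d) / s
}

#' Root mean squared error between two vectors
#'
#' Pairwise-complete: pairs with a missing value in either vector are
#' dropped before `sqrt(mean((x - y)^2))`.
#'
#' @param x,y equal-length numeric vectors.
#' @return a single RMSE value.
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) abort("rmse: no complete pairs")
  sqrt(mean((x[ok] - y[ok])^2))
}

#' Empirical cross-hybridisation evidence from WGBS
#'
#' Compares a probe's array M-values against the WGBS logit methylation
#' of its on-target CpG and of each CpG off-target site. Evaluation
#' requires at least one CpG off-target and at least `min_pairs` of
#' `n_samples` matched values (array and WGBS both present); otherwise
#' the probe is `not_evaluated`. The flag is `Y` when some off-target
#' RMSE is lower than the on-target RMSE, with the minimising off-target
#' reported as the suggested alternative.
#'
#' @param probe_values tibble `sample`, `m` for the probe (M space).
#' @param on_target tibble `sample`, `value` of on-target WGBS logits.
#' @param off_targets tibble `coord`, `sample`, `value` of off-target
#'   WGBS logits (CpG off-targets only; pass zero rows if none).
#' @param min_pairs,n_samples dropout rule (defaults 12 of 18).
#' @return one-row tibble: `rmse_on_target`, `best_off_rmse`,
#'   `best_off_coordinate`, `num_offtargets`, `flag` (`Y`/`N`/
#'   `not_evaluated`).
#' @export
crosshyb_wgbs_evidence <- function(probe_values, on_target, off_targets,
                                   min_pairs = 12L, n_samples = 18L) {
  not_eval <- tibble(rmse_on_target = NA_real_, best_off_rmse = NA_real_,
                     best_off_coordinate = NA_character_,
                     num_offtargets = nrow(distinct(off_targets,
                                                    .data$coord)),
                     flag = "not_evaluated")
  if (nrow(off_targets) == 0L) return(not_eval)
  on <- inner_join(probe_values, on_target, by = "sample")
  on <- filter(on, !is.na(.data$m), !is.na(.data$value))
  if (nrow(on) < min_pairs) return(not_eval)
  offs <- off_targets |>
    inner_join(probe_values, by = "sample") |>
    filter(!is.na(.data$m), !is.na(.data$value)) |>
    group_by(.data$coord) |>
    summarise(n = dplyr::n(),
              rmse_off = sqrt(mean((.data$m - .data$value)^2)),
              .groups = "drop") |>
    filter(.data$n >= min_pairs)
  if (nrow(offs) == 0L) return(not_eval)
  r_on <- rmse(on$m, on$value)
  best <- offs[which.min(offs$rmse_off), ]
  tibble(rmse_on_target = r_on, best_off_rmse = best$rmse_off,
         best_off_coordinate = as.character(best$coord),
         num_offtargets = nrow(distinct(off_targets, .data$coord)),
         flag = if (best$rmse_off < r_on) "Y" else "N")
}

best_by <- function(values, larger_better, tie_order) {
  # index of the best value; ties broken by tie_order (smaller first)
  v <- if (larger_better) -values else values
  order(v, tie_order)[1L]
}

#' Competitive evaluation of a replicate probe set
#'
#' Adjudicates the members of one replicate set. With matched EPICv1
#' data, row-linear fits for each member and for the set mean (sample
#' means of member M-values) yield labels: `superior` (best sensitivity
#' and precision versus all members and the set mean), `inferior` (worst
#' versus all members and the set mean), otherwise `best_sensitivity` /
#' `best_precision` per axis, with `best_precision_by_group_mean` when
#' the set mean confers the best precision (the best-sensitivity member
#' is still labelled `best_sensitivity` regardless). Without EPICv1,
#' the member with the smallest RMSE against on-target WGBS is
#' `superior_by_WGBS` and the others `inferior_by_WGBS`, unless the set
#' mean outperforms all members, in which case members are relabelled
#' `superior_group_mean_WGBS`. Sets with fewer than `min_pairs` matched
#' values for every member are `insufficient`.
#'
#' @param members named list (by IlmnID, in manifest order) of tibbles
#'   `sample`, `m` (EPICv2 M-values for each member probe).
#' @param epicv1 tibble `sample`, `m` for the matched EPICv1 probe, or
#'   `NULL` if no EPICv1 target-site match exists.
#' @param wgbs tibble `sample`, `value` of on-target WGBS logits.
#' @param min_pairs,n_samples dropout rule (defaults 12 of 18).
#' @return tibble, one row per member: `probe_id`, `label`,
#'   `sensitivity`, `precision`, `rmse_wgbs`, plus set-mean columns
#'   `mean_sensitivity`, `mean_precision`, `mean_rmse_wgbs`.
#' @export
evaluate_replicate_set <- function(members, epicv1 = NULL, wgbs = NULL,
                                   min_pairs = 12L, n_samples = 18L) {
  if (length(members) < 2L) abort("not a replicate set (size < 2)")
  ids <- names(members)
  complete <- vapply(members, function(m) {
    ok <- !is.na(m$m)
    if (!is.null(epicv1)) {
      ok <- ok & m$sample %in% epicv1$sample[!is.na(epicv1$m)]
    }
    if (!is.null(wgbs)) {
      ok <- ok & m$sample %in% wgbs$sample[!is.na(wgbs$value)]
    }
    sum(ok)
  }, integer(1))
  out <- tibble(probe_id = ids, label = "insufficient",
                sensitivity = NA_real_, precision = NA_real_,
                rmse_wgbs = NA_real_, mean_sensitivity = NA_real_,
                mean_precision = NA_real_, mean_rmse_wgbs = NA_real_)
  usable <- complete >= min_pairs
  if (!any(usable)) return(out)
  # set mean: sample-wise mean M across members
  mean_tbl <- bind_rows(members) |>
    group_by(.data$sample) |>
    summarise(m = mean(.data$m, na.rm = TRUE), .groups = "drop")

  if (!is.null(epicv1)) {
    # One consensus per set (set-mean EPICv2, EPICv1, and WGBS when
    # available): fitting every member against the same consensus makes
    # the set-mean sensitivity exactly the mean of member sensitivities,
    # hence by definition intermediate of the member extremes.
    cons <- inner_join(rename(mean_tbl, m_set = "m"),
                       rename(epicv1, m_v1 = "m"), by = "sample")
    if (!is.null(wgbs)) {
      cons <- inner_join(cons, rename(wgbs, m_w = "value"), by = "sample")
      cons$consensus <- (cons$m_set + cons$m_v1 + cons$m_w) / 3
    } else {
      cons$consensus <- (cons$m_set + cons$m_v1) / 2
    }
    cons <- filter(cons, is.finite(.data$consensus))
    fit_one <- function(series) {
      df <- inner_join(series, cons[c("sample", "consensus")],
                       by = "sample")
      df <- filter(df, !is.na(.data$m))
      n <- nrow(df)
      cm <- mean(df$consensus)
      ss <- sum((df$consensus - cm)^2)
      if (n < 3L || ss == 0) {
        return(list(sensitivity = NA_real_, precision = NA_real_))
      }
      b <- sum((df$consensus - cm) * (df$m - mean(df$m))) / ss
      r <- df$m - (mean(df$m) + b * (df$consensus - cm))
      list(sensitivity = b, precision = sqrt(sum(r^2) / (n - 2L)))
    }
    fits <- purrr::map(members[usable], fit_one)
    mean_fit <- fit_one(mean_tbl)
    sens_all <- vapply(fits, `[[`, numeric(1), "sensitivity")
    prec_all <- vapply(fits, `[[`, numeric(1), "precision")
    ok <- !is.na(sens_all) & !is.na(prec_all)
    usable[which(usable)[!ok]] <- FALSE
    sens <- sens_all[ok]; prec <- prec_all[ok]
    out$sensitivity[usable] <- sens
    out$precision[usable] <- prec
    out$mean_sensitivity <- mean_fit$sensitivity
    out$mean_precision <- mean_fit$precision
    ui <- which(usable)
    ord <- seq_along(ui)  # manifest order among usable members
    if (length(ui) >= 2L) {
      ib_sens <- best_by(sens, TRUE, ord)
      ib_prec <- best_by(prec, FALSE, ord)
      is_superior <- ib_sens == ib_prec &&
        sens[ib_sens] > max(sens[-ib_sens]) &&
        sens[ib_sens] > mean_fit$sensitivity &&
        prec[ib_prec] < min(prec[-ib_prec]) &&
        prec[ib_prec] < mean_fit$precision
      lab <- rep(NA_character_, length(ui))
      if (is_superior) {
        lab[ib_sens] <- "superior"
        iw <- which(sens == min(sens) & prec == max(prec))
        if (length(iw) == 1L && iw != ib_sens &&
            sens[iw] < min(sens[-iw]) && prec[iw] > max(prec[-iw]) &&
            sens[iw] < mean_fit$sensitivity &&
            prec[iw] > mean_fit$precision) {
          lab[iw] <- "inferior"
        }
      } else if (mean_fit$precision < min(prec)) {
        lab[] <- "best_precision_by_group_mean"
        lab[ib_sens] <- "best_sensitivity"
      } else {
        lab[ib_sens] <- "best_sensitivity"
        if (ib_prec != ib_sens) lab[ib_prec] <- "best_precision"
      }
      out$label[ui] <- lab
    }
  } else if (!is.null(wgbs)) {
    rms <- vapply(members, function(m) {
      j <- inner_join(m, wgbs, by = "sample")
      j <- filter(j, !is.na(.data$m), !is.na(.data$value))
      if (nrow(j) < min_pairs) return(NA_real_)
      rmse(j$m, j$value)
    }, numeric(1))
    jm <- inner_join(mean_tbl, wgbs, by = "sample")
    jm <- filter(jm, !is.na(.data$m), !is.na(.data$value))
    mean_rms <- if (nrow(jm) >= min_pairs) rmse(jm$m, jm$value) else
      NA_real_
    out$rmse_wgbs <- rms
    out$mean_rmse_wgbs <- mean_rms
    ok <- !is.na(rms)
    if (sum(ok) >= 2L) {
      if (!is.na(mean_rms) && mean_rms < min(rms[ok])) {
        out$label[ok] <- "superior_group_mean_WGBS"
      } else {
        ib <- which(ok)[best_by(rms[ok], FALSE, seq_len(sum(ok)))]
        out$label[ok] <- "inferior_by_WGBS"
        out$label[ib] <- "superior_by_WGBS"
      }
    }
  }
  out
}

#' Relative log methylation deviations
#'
#' Subtracts, per site, the across-sample median M-value; the per-sample
#' deviation distributions are the RLM quality-control diagnostic.
#'
#' @param data tibble `site`, `sample`, `m` (M space), or a numeric
#'   matrix sites x samples.
#' @return tibble `site`, `sample`, `deviation`.
#' @export
rlm_deviations <- function(data) {
  if (is.matrix(data)) {
    data <- as_tibble(data, rownames = "site") |>
      tidyr::pivot_longer(-"site", names_to = "sample", values_to = "m")
  }
  stopifnot(length(unique(data$sample)) >= 2L)
  data |>
    group_by(.data$site) |>
    mutate(deviation = .data$m - median(.data$m, na.rm = TRUE)) |>
    ungroup() |>
    select("site", "sample", "deviation")
}

#' Choose the cleanest technical replicate
#'
#' Pre-matching helper: among technical replicate samples, picks the one
#' with the fewest probes failing the detection p-value threshold.
#'
#' @param tbl [methyl_table()] tibble with detection-p companion.
#' @param replicate_samples character vector of candidate sample keys.
#' @param detection_p threshold (default 0.05).
#' @return the chosen sample key.
#' @export
select_technical_replicate <- function(tbl, replicate_samples,
                                       detection_p = 0.05) {
  fails <- vapply(replicate_samples, function(s) {
    sum(tbl$qc[tbl$sample == s] > detection_p, na.rm = TRUE)
  }, integer(1))
  replicate_samples[which.min(fails)]
}
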