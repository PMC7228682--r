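# Group-level comparison of per-segment features across the pre-stent,
# post-stent and normal conditions.

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from explicit between-
#' and within-group sums of squares, with the F statistic referred to the
#' F distribution on `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups Named list of numeric vectors, one per group (each with at
#'   least 2 finite values).
#' @param feature_name Optional label carried into the result.
#' @return A list of class `pcg_group_comparison`: per-group `n`, `mean`,
#'   `sd`; `ss_between`, `ss_within`, `ss_total`; `df`; `F_statistic`;
#'   `p_value`.
#' @export
one_way_anova <- function(groups, feature_name = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_pcg("pcgbeam_input_error", "need at least two groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, function(g) length(g) < 2L || any(!is.finite(g)),
                 logical(1)))) {
    stop_pcg("pcgbeam_input_error",
             "every group needs >= 2 finite values")
  }
  n_i <- vapply(groups, length, integer(1))
  mean_i <- vapply(groups, mean, numeric(1))
  sd_i <- vapply(groups, stats::sd, numeric(1))
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ss_between <- sum(n_i * (mean_i - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  ss_total <- sum((all_x - grand)^2)
  k <- length(groups)
  df1 <- k - 1L
  df2 <- length(all_x) - k
  if (ss_within == 0 && ss_between == 0) {
    warning("all values identical in every group; F is 0/0, reporting p = 1")
    f_stat <- NaN
    p <- 1
  } else if (ss_within == 0) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(
    feature_name = feature_name,
    groups = names(groups),
    n = n_i, mean = mean_i, sd = sd_i,
    ss_between = ss_between, ss_within = ss_within, ss_total = ss_total,
    df = c(df1, df2), F_statistic = f_stat, p_value = p
  ), class = "pcg_group_comparison")
}

#' @export
print.pcg_group_comparison <- function(x, ...) {
  cat(sprintf("<pcg_group_comparison>%s\n",
              if (is.null(x$feature_name)) "" else
                paste0(" feature: ", x$feature_name)))
  df <- data.frame(group = x$groups, n = x$n, mean = signif(x$mean, 4),
                   sd = signif(x$sd, 4))
  print(df, row.names = FALSE)
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F_statistic, x$p_value))
  invisible(x)
}

#' Run the full study pipeline on a cohort
#'
#' For every recording: delay-and-sum beamforming with geometry-derived
#' delays, S2 referencing, extraction of 128-ms diastolic windows 100 ms
#' after S2, unit-energy normalization, 65-500 Hz order-5 Butterworth
#' filtering, and per-segment approximate-entropy and band-energy-ratio
#' features.  Features are pooled by condition (per segment by default) and
#' compared with a three-group one-way ANOVA plus pairwise two-group
#' contrasts.
#'
#' @param cohort A `pcg_cohort` from [generate_cohort()], or `NULL` to
#'   generate one from `config`.
#' @param config A [study_config()].
#' @return A list of class `pcg_study_result`: `features` (per-segment data
#'   frame), `comparisons` (per feature: the three-group ANOVA and pairwise
#'   contrasts), `significance` (logical flags at 0.05 and 0.01),
#'   `excluded` (recordings that yielded no valid segment) and `config`.
#' @export
run_study <- function(cohort = NULL, config = study_config()) {
  stopifnot(inherits(config, "pcg_study_config"))
  if (is.null(cohort)) cohort <- cohort_from_config(config)
  stopifnot(inherits(cohort, "pcg_cohort"))

  fspec <- filter_spec(order = config$filter$order,
                       band = config$filter$band,
                       mode = config$filter$mode)
  feats <- list()
  excluded <- list()
  for (rec in cohort$recordings) {
    geom <- rec$geometry
    bf <- delay_and_sum(rec, compute_delays(geom))
    s2 <- detect_s2(bf, method = config$s2_method)
    segs <- extract_diastolic_segments(
      bf, s2,
      offset_s = config$segment$offset_s,
      length_samples = config$segment$length_samples,
      max_segments = config$segment$per_recording)
    if (!length(segs$segments)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        subject_id = rec$meta$subject_id %||% NA_character_,
        condition = rec$meta$condition %||% NA_character_,
        reason = "no valid diastolic segment", stringsAsFactors = FALSE)
      next
    }
    segs <- condition_segments(segs, fspec,
                               swap_order = config$filter$before_normalize)
    feats[[length(feats) + 1L]] <- feature_block(
      segs$segments,
      m = config$apen$m, r_coefficient = config$apen$r_coefficient,
      split_hz = config$split_hz, band = config$filter$band)
  }
  features <- do.call(rbind, feats)

  pool <- function(feature) {
    conds <- intersect(c("pre_stent", "post_stent", "normal"),
                       unique(features$condition))
    vals <- lapply(conds, function(cc) {
      sub <- features[features$condition == cc, ]
      if (config$pooling == "per_subject") {
        tapply(sub[[feature]], sub$subject_id, mean)
      } else {
        sub[[feature]]
      }
    })
    names(vals) <- conds
    vals
  }

  contrast_pairs <- list(c("pre_stent", "post_stent"),
                         c("post_stent", "normal"),
                         c("pre_stent", "normal"))
  comparisons <- list()
  for (feature in c("apen", "ratio")) {
    g <- pool(feature)
    omnibus <- if (length(g) >= 2) one_way_anova(g, feature) else NULL
    pairwise <- list()
    for (pair in contrast_pairs) {
      if (all(pair %in% names(g))) {
        pairwise[[paste(pair, collapse = "_vs_")]] <-
          one_way_anova(g[pair], feature)
      }
    }
    comparisons[[feature]] <- list(omnibus = omnibus, pairwise = pairwise)
  }

  significance <- lapply(comparisons, function(cmp) {
    lapply(cmp$pairwise, function(ct) {
      c(p_0.05 = ct$p_value < 0.05, p_0.01 = ct$p_value < 0.01)
    })
  })

  structure(list(
    features = features,
    comparisons = comparisons,
    significance = significance,
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
    config = config
  ), class = "pcg_study_result")
}

#' @export
print.pcg_study_result <- function(x, ...) {
  cat("<pcg_study_result>\n")
  cat(sprintf("  %d segments from %d subject(s)\n", nrow(x$features),
              length(unique(x$features$subject_id))))
  for (feature in names(x$comparisons)) {
    cmp <- x$comparisons[[feature]]
    cat(sprintf("  %s:\n", feature))
    for (nm in names(cmp$pairwise)) {
      ct <- cmp$pairwise[[nm]]
      cat(sprintf("    %-24s p = %.3g\n", nm, ct$p_value))
    }
  }
  invisible(x)
}
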