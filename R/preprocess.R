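#' Condense a replicate set by the best-duplicate rule
#'
#' From three technical replicates, picks the pair with the smallest
#' absolute Cq difference and returns its mean; the spread is that
#' difference. This is the standard guard against a single aberrant well
#' (dust, bubble) in a triplicate. When two pairs tie on distance the pair
#' with the lower mean Cq (the stronger signal) is chosen and the result
#' is flagged as tie-broken. Undetermined replicates (`NA`) are dropped
#' before pair selection; if exactly two finite values remain they form
#' the duplicate.
#'
#' @param cqs Numeric vector of replicate Cq values (typically length 3;
#'   `NA` = undetermined).
#' @return A list with `mean`, `spread` (absolute Cq difference of the
#'   chosen pair), `n_used` (always 2), and `tie_broken` (logical).
#' @export
#' @examples
#' best_duplicate(c(10.0, 10.1, 10.5))  # mean 10.05, spread 0.1
best_duplicate <- function(cqs) {
  x <- cqs[is.finite(cqs)]
  if (length(x) < 2) {
    stop("best_duplicate needs at least 2 finite Cq values, got ",
         length(x), call. = FALSE)
  }
  if (length(x) == 2) {
    return(list(mean = mean(x), spread = abs(x[1] - x[2]), n_used = 2L,
                tie_broken = FALSE))
  }
  pairs <- utils::combn(length(x), 2)
  d <- abs(x[pairs[1, ]] - x[pairs[2, ]])
  m <- (x[pairs[1, ]] + x[pairs[2, ]]) / 2
  best_d <- min(d)
  cand <- which(d <= best_d + 1e-12)
  tie <- length(cand) > 1 && diff(range(m[cand])) > 1e-12
  pick <- cand[which.min(m[cand])]
  list(mean = m[pick], spread = d[pick], n_used = 2L, tie_broken = tie)
}

#' Condense replicates to one Cq per well group
#'
#' Collapses each (rna, kit, RT input, qPCR dilution, amplicon) group of a
#' validated Cq table to a single Cq. The default policy is the
#' best-duplicate rule ([best_duplicate()]); `mean_all` and `median_all`
#' use all finite replicates. Groups with fewer than two finite Cq values
#' cannot be condensed; they are dropped with a warning and recorded in
#' the `dropped` attribute. Control wells (RT0, RT-, gDNA) are excluded.
#'
#' Flags per group (semicolon-joined in the `flags` column):
#' `UNDETERMINED_PRESENT` when any replicate was undetermined,
#' `TIE_BROKEN` when pair selection needed the low-Cq tie-break, and
#' `HIGH_CQ` when the condensed value exceeds `high_cq` (stochastic
#' single-molecule territory; flagged, not excluded).
#'
#' @param table A validated Cq table.
#' @param policy `"best_duplicate"`, `"mean_all"` or `"median_all"`.
#' @param high_cq Cq above which a group is flagged `HIGH_CQ`.
#' @return A tibble with the group key columns plus `cq_mean`, `spread`
#'   (chosen-pair difference, or SD of all used replicates for the other
#'   policies), `n_used` and `flags`; dropped groups in `attr(, "dropped")`.
#' @export
condense <- function(table, policy = c("best_duplicate", "mean_all", "median_all"),
                     high_cq = 30) {
  table <- validate_cq_table(table)
  policy <- match.arg(policy)
  samples <- table[table$role == "sample", ]
  grouped <- dplyr::group_by(samples,
                             dplyr::across(dplyr::all_of(group_key_columns)))
  out <- dplyr::summarise(
    grouped,
    .n_finite = sum(is.finite(.data$cq)),
    .any_undet = any(!is.finite(.data$cq)),
    .cqs = list(.data$cq),
    .groups = "drop"
  )
  condense_one <- function(cqs, any_undet) {
    x <- cqs[is.finite(cqs)]
    if (policy == "best_duplicate") {
      bd <- best_duplicate(cqs)
      cq_mean <- bd$mean; spread <- bd$spread
      n_used <- bd$n_used; tie <- bd$tie_broken
    } else {
      cq_mean <- if (policy == "mean_all") mean(x) else stats::median(x)
      spread <- if (length(x) > 1) stats::sd(x) else 0
      n_used <- length(x); tie <- FALSE
    }
    flags <- c(
      if (any_undet) "UNDETERMINED_PRESENT",
      if (tie) "TIE_BROKEN",
      if (cq_mean > high_cq) "HIGH_CQ"
    )
    list(cq_mean = cq_mean, spread = spread, n_used = as.integer(n_used),
         flags = paste(flags, collapse = ";"))
  }
  ok <- out$.n_finite >= 2
  dropped <- out[!ok, group_key_columns]
  if (nrow(dropped) > 0) {
    warning(nrow(dropped), " group(s) with < 2 finite Cq values dropped",
            call. = FALSE)
  }
  kept <- out[ok, ]
  res <- Map(condense_one, kept$.cqs, kept$.any_undet)
  condensed <- tibble::as_tibble(kept[, group_key_columns])
  condensed$cq_mean <- vapply(res, `[[`, numeric(1), "cq_mean")
  condensed$spread <- vapply(res, `[[`, numeric(1), "spread")
  condensed$n_used <- vapply(res, `[[`, integer(1), "n_used")
  condensed$flags <- vapply(res, `[[`, character(1), "flags")
  attr(condensed, "dropped") <- tibble::as_tibble(dropped)
  condensed
}

#' Replicate dispersion summary
#'
#' Two dispersion measures over all sample well groups with three finite
#' replicates: the standard deviation across the triplicate, and the
#' absolute Cq difference of the best (closest) duplicate. Each is
#' reported as mean and SD across groups.
#'
#' @param table A validated Cq table.
#' @return A tibble with one row per statistic (`triplicate_sd`,
#'   `best_duplicate_spread`) and columns `mean`, `sd`, `n_groups`.
#' @export
replicate_dispersion <- function(table) {
  table <- validate_cq_table(table)
  samples <- table[table$role == "sample", ]
  grouped <- dplyr::group_by(samples,
                             dplyr::across(dplyr::all_of(group_key_columns)))
  per_group <- dplyr::summarise(
    grouped,
    n_finite = sum(is.finite(.data$cq)),
    trip_sd = stats::sd(.data$cq[is.finite(.data$cq)]),
    .cqs = list(.data$cq),
    .groups = "drop"
  )
  full <- per_group[per_group$n_finite == 3, ]
  spreads <- vapply(full$.cqs, function(cqs) best_duplicate(cqs)$spread,
                    numeric(1))
  tibble::tibble(
    statistic = c("triplicate_sd", "best_duplicate_spread"),
    mean = c(mean(full$trip_sd), mean(spreads)),
    sd = c(stats::sd(full$trip_sd), stats::sd(spreads)),
    n_groups = nrow(full)
  )
}

#' Negative-control quality check
#'
#' Flags RT0 (no-template) and RT- (no-enzyme) control wells whose Cq
#' falls below a threshold, i.e. wells with a substantial reading where
#' none is expected. Undetermined controls pass. A clean run has no flags.
#'
#' @param table A validated Cq table.
#' @param threshold_cq Controls with finite Cq below this value are
#'   flagged. Default 35: late stochastic signal above it is tolerated.
#' @return A list with `flagged` (tibble of offending control wells),
#'   `n_controls` and `pass`.
#' @export
qc_negative_controls <- function(table, threshold_cq = 35) {
  table <- validate_cq_table(table)
  stopifnot(is.numeric(threshold_cq), length(threshold_cq) == 1,
            threshold_cq > 0, threshold_cq <= 40)
  controls <- table[table$role %in% c("RT0", "RTminus"), ]
  flagged <- controls[is.finite(controls$cq) & controls$cq < threshold_cq, ]
  list(
    flagged = tibble::as_tibble(flagged),
    n_controls = nrow(controls),
    pass = nrow(flagged) == 0
  )
}
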