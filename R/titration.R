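#' Form adjacent 2-fold dilution pairs and their Cq2f values
#'
#' Cq2f is the Cq increase per 2-fold dilution of input: the Cq at the
#' lower input minus the Cq at the 2-fold higher input. Under perfect
#' dose response it equals 1 on either axis; values near 0 mean the
#' measured signal did not respond to input (saturation).
#'
#' On the qPCR axis a pair is two adjacent cDNA dilution levels at fixed
#' (rna, kit, RT input, amplicon); on the RT axis two adjacent RNA input
#' doses at fixed (rna, kit, amplicon, qPCR dilution). Inputs are
#' expressed as relative amounts so that `hi_input / lo_input = 2` on both
#' axes (on the qPCR axis the relative cDNA amount is the reciprocal of
#' the dilution factor). Pairs with a missing member are omitted; their
#' count is recorded in the `n_incomplete` attribute.
#'
#' @param condensed Condensed measurements from [condense()].
#' @param axis `"rt"` or `"qpcr"`.
#' @return A tibble of pair records: `axis`, `rna`, `kit`, `amplicon`, the
#'   fixed coordinate on the other axis (`qpcr_dilution_level` for the RT
#'   axis, `rt_input_ng` for the qPCR axis), `hi_input`, `lo_input`,
#'   `cq_hi`, `cq_lo` and `cq2f = cq_lo - cq_hi`.
#' @export
cq2f_pairs <- function(condensed, axis) {
  if (!is.character(axis) || length(axis) != 1 || !axis %in% c("rt", "qpcr")) {
    stop("unknown axis: must be \"rt\" or \"qpcr\"", call. = FALSE)
  }
  stopifnot(is.data.frame(condensed),
            all(c(group_key_columns, "cq_mean") %in% names(condensed)))

  df <- tibble::as_tibble(condensed)
  if (axis == "rt") {
    df$input <- df$rt_input_ng
    fixed <- c("rna", "kit", "amplicon", "qpcr_dilution_level")
  } else {
    df$input <- 1 / df$qpcr_dilution_level
    fixed <- c("rna", "kit", "amplicon", "rt_input_ng")
  }
  df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(fixed)),
                       dplyr::desc(.data$input))
  grouped <- dplyr::group_by(df, dplyr::across(dplyr::all_of(fixed)))
  pairs <- dplyr::reframe(
    grouped,
    hi_input = .data$input[-dplyr::n()],
    lo_input = .data$input[-1],
    cq_hi = .data$cq_mean[-dplyr::n()],
    cq_lo = .data$cq_mean[-1]
  )
  # keep only true adjacent 2-fold pairs; a missing intermediate dose
  # leaves a 4-fold gap which is never halved into synthetic pairs
  adjacent <- abs(pairs$hi_input / pairs$lo_input - 2) < 1e-9
  n_incomplete <- sum(!adjacent)
  pairs <- pairs[adjacent, ]
  pairs$cq2f <- pairs$cq_lo - pairs$cq_hi
  pairs <- tibble::as_tibble(pairs)
  pairs$axis <- axis
  out <- pairs[, c("axis", fixed, "hi_input", "lo_input", "cq_hi", "cq_lo", "cq2f")]
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Summarise Cq2f values by grouping
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator; 0 when a
#' group has a single pair) and pair count of Cq2f values, per group or
#' overall when `group_by` is empty.
#'
#' @param pairs Pair records from [cq2f_pairs()].
#' @param group_by Character vector of grouping columns (e.g.
#'   `c("amplicon", "kit")`); empty for a grand summary.
#' @return A tibble with the grouping columns plus `mean_cq2f`, `sd_cq2f`,
#'   `n_pairs`.
#' @export
summarize_cq2f <- function(pairs, group_by = character()) {
  stopifnot(is.data.frame(pairs), "cq2f" %in% names(pairs))
  if (nrow(pairs) == 0) stop("no pairs to summarise", call. = FALSE)
  unknown <- setdiff(group_by, names(pairs))
  if (length(unknown) > 0) {
    stop("unknown grouping column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grouped <- if (length(group_by) == 0) {
    dplyr::group_by(tibble::as_tibble(pairs))
  } else {
    dplyr::group_by(tibble::as_tibble(pairs),
                    dplyr::across(dplyr::all_of(group_by)))
  }
  dplyr::summarise(
    grouped,
    mean_cq2f = mean(.data$cq2f),
    sd_cq2f = if (dplyr::n() > 1) stats::sd(.data$cq2f) else 0,
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
}

#' Classify dose-response behaviour from mean Cq2f
#'
#' Labels each summary row by how its mean RT-axis Cq2f compares with the
#' ideal value of 1: `linear` at or above `linear_min`, `saturated` at or
#' below `saturated_max`, `compressed` in between. The defaults (0.75 and
#' 0.25) separate well-behaved amplicons from ones whose RT step barely
#' responds to input; both are tunable.
#'
#' @param summary A tibble from [summarize_cq2f()].
#' @param linear_min Lower bound of the `linear` label.
#' @param saturated_max Upper bound of the `saturated` label.
#' @return The summary with an added `bias` column.
#' @export
classify_bias <- function(summary, linear_min = 0.75, saturated_max = 0.25) {
  stopifnot(is.data.frame(summary), "mean_cq2f" %in% names(summary))
  if (saturated_max >= linear_min) {
    stop("thresholds must satisfy saturated_max < linear_min", call. = FALSE)
  }
  summary$bias <- dplyr::case_when(
    summary$mean_cq2f >= linear_min ~ "linear",
    summary$mean_cq2f <= saturated_max ~ "saturated",
    TRUE ~ "compressed"
  )
  summary
}
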