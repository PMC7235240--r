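match_condition <- function(condensed, condition) {
  stopifnot(is.list(condition), length(names(condition)) == length(condition))
  unknown <- setdiff(names(condition), names(condensed))
  if (length(unknown) > 0) {
    stop("condition refers to unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(condensed))
  for (col in names(condition)) {
    value <- condition[[col]]
    keep <- keep & if (is.numeric(value)) {
      is.finite(condensed[[col]]) & abs(condensed[[col]] - value) < 1e-9
    } else {
      condensed[[col]] == value
    }
  }
  keep
}

# mean condensed Cq of one amplicon under a condition; multiple reference
# amplicons average on the Cq scale (geometric mean of linear quantities)
resolve_cq <- function(condensed, amplicons, condition, label) {
  per_amplicon <- vapply(amplicons, function(a) {
    keep <- match_condition(condensed, condition) & condensed$amplicon == a
    if (!any(keep)) {
      stop("no condensed measurement for amplicon '", a, "' under ", label,
           " condition {",
           paste(names(condition), unlist(condition), sep = "=", collapse = ", "),
           "}", call. = FALSE)
    }
    mean(condensed$cq_mean[keep])
  }, numeric(1))
  mean(per_amplicon)
}

#' Relative quantification by the delta-delta-Cq method
#'
#' Computes `dCq = Cq(target) - Cq(reference)` within each condition,
#' `ddCq = dCq_a - dCq_b`, and the fold change `2^(-ddCq)` of the target
#' in condition a relative to condition b. When a condition matches
#' several condensed measurements (e.g. multiple qPCR dilutions) their Cq
#' values are averaged first; multiple reference amplicons are combined by
#' the arithmetic mean of their Cq values.
#'
#' @param condensed Condensed measurements from [condense()].
#' @param target Target amplicon name.
#' @param reference Reference amplicon name(s).
#' @param condition_a,condition_b Named lists of column filters describing
#'   the two conditions, e.g. `list(rna = "H", kit = "iScript",
#'   rt_input_ng = 600)`.
#' @return A one-row tibble: `target`, `reference`, `delta_cq_a`,
#'   `delta_cq_b`, `delta_delta_cq`, `fold_change`.
#' @export
delta_delta_cq <- function(condensed, target, reference,
                           condition_a, condition_b) {
  stopifnot(is.data.frame(condensed),
            all(c("amplicon", "cq_mean") %in% names(condensed)))
  t_a <- resolve_cq(condensed, target, condition_a, "a")
  t_b <- resolve_cq(condensed, target, condition_b, "b")
  r_a <- resolve_cq(condensed, reference, condition_a, "a")
  r_b <- resolve_cq(condensed, reference, condition_b, "b")
  dcq_a <- t_a - r_a
  dcq_b <- t_b - r_b
  ddcq <- dcq_a - dcq_b
  tibble::tibble(
    target = target,
    reference = paste(reference, collapse = "+"),
    delta_cq_a = dcq_a,
    delta_cq_b = dcq_b,
    delta_delta_cq = ddcq,
    fold_change = 2^(-ddcq)
  )
}

#' Dose-dependence of an apparent differential-expression call
#'
#' Recomputes the between-sample fold change of a target (relative to a
#' reference) separately at each RT input dose. A measurement free of
#' RT dose-response bias gives the same fold at every dose
#' (`max_discrepancy = 1`); RT saturation makes the apparent fold drift
#' with input.
#'
#' @inheritParams delta_delta_cq
#' @param condition_a,condition_b Named lists describing the two samples
#'   *without* `rt_input_ng`; the dose is supplied per row from `doses`.
#' @param doses RT input doses (ng) at which to evaluate the comparison.
#' @return A list with `results` (one [delta_delta_cq()] row per dose,
#'   with `rt_input_ng` prepended) and `max_discrepancy` (max fold divided
#'   by min fold across doses).
#' @export
apparent_de_across_doses <- function(condensed, target, reference,
                                     condition_a, condition_b, doses) {
  if (length(doses) < 2) {
    stop("need at least 2 doses to assess dose dependence", call. = FALSE)
  }
  rows <- lapply(doses, function(m) {
    res <- delta_delta_cq(
      condensed, target, reference,
      c(condition_a, list(rt_input_ng = m)),
      c(condition_b, list(rt_input_ng = m))
    )
    dplyr::bind_cols(tibble::tibble(rt_input_ng = m), res)
  })
  results <- dplyr::bind_rows(rows)
  list(
    results = results,
    max_discrepancy = max(results$fold_change) / min(results$fold_change)
  )
}

#' Cq shift caused by RNA fragmentation
#'
#' Pairs every condensed measurement of an amplicon in a fragmented RNA
#' with the measurement of its intact counterpart at the same kit, RT
#' input and qPCR dilution, and reports `dCq = Cq(fragmented) -
#' Cq(intact)` per coordinate. Positive shifts mean template loss;
#' negative shifts (as seen for structured RNAs) mean the species
#' survives fragmentation better than average.
#'
#' @param condensed Condensed measurements from [condense()].
#' @param amplicon Amplicon name.
#' @param intact_rna,fragmented_rna RNA names of the matched pair.
#' @return A list with `shifts` (per-coordinate tibble with `delta_cq`),
#'   `mean_shift`, `sd_shift` and `n`.
#' @export
fragmentation_shift <- function(condensed, amplicon, intact_rna, fragmented_rna) {
  stopifnot(is.data.frame(condensed))
  a <- condensed[condensed$amplicon == amplicon &
                   condensed$rna == fragmented_rna, ]
  b <- condensed[condensed$amplicon == amplicon &
                   condensed$rna == intact_rna, ]
  matched <- dplyr::inner_join(
    a[, c("kit", "rt_input_ng", "qpcr_dilution_level", "cq_mean")],
    b[, c("kit", "rt_input_ng", "qpcr_dilution_level", "cq_mean")],
    by = c("kit", "rt_input_ng", "qpcr_dilution_level"),
    suffix = c("_fragmented", "_intact")
  )
  if (nrow(matched) == 0) {
    stop("no matched (kit, dose, dilution) coordinates between '",
         fragmented_rna, "' and '", intact_rna, "' for amplicon '",
         amplicon, "'", call. = FALSE)
  }
  matched$delta_cq <- matched$cq_mean_fragmented - matched$cq_mean_intact
  list(
    shifts = tibble::as_tibble(matched),
    mean_shift = mean(matched$delta_cq),
    sd_shift = if (nrow(matched) > 1) stats::sd(matched$delta_cq) else 0,
    n = nrow(matched)
  )
}

#' Apparent differential expression induced by fragmentation
#'
#' Applies the delta-delta-Cq method between a fragmented RNA and its
#' intact counterpart at every matched (kit, RT input, qPCR dilution)
#' coordinate. With identical RNA in both conditions any fold away from 1
#' is an artifact of amplicon-specific fragmentation response. The
#' maximum is taken over fold magnitudes: folds below 1 are inverted
#' first, so a 0.5-fold reads as a 2-fold artifact.
#'
#' @inheritParams delta_delta_cq
#' @param intact_rna,fragmented_rna RNA names of the matched pair.
#' @return A list with `results` (per-coordinate folds; condition a =
#'   fragmented, condition b = intact) and `max_fold` (maximum fold
#'   magnitude after inversion).
#' @export
fragmentation_de_artifact <- function(condensed, target, reference,
                                      intact_rna, fragmented_rna) {
  stopifnot(is.data.frame(condensed))
  relevant <- condensed$amplicon %in% c(target, reference) &
    condensed$rna %in% c(intact_rna, fragmented_rna)
  coords <- dplyr::distinct(
    condensed[relevant, c("kit", "rt_input_ng", "qpcr_dilution_level")]
  )
  rows <- list()
  for (i in seq_len(nrow(coords))) {
    coord <- as.list(coords[i, ])
    res <- tryCatch(
      delta_delta_cq(
        condensed, target, reference,
        c(list(rna = fragmented_rna), coord),
        c(list(rna = intact_rna), coord)
      ),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <- dplyr::bind_cols(tibble::as_tibble(coord), res)
    }
  }
  if (length(rows) == 0) {
    stop("no matched coordinates with both amplicons present for '",
         fragmented_rna, "' vs '", intact_rna, "'", call. = FALSE)
  }
  results <- dplyr::bind_rows(rows)
  magnitudes <- pmax(results$fold_change, 1 / results$fold_change)
  list(results = results, max_fold = max(magnitudes))
}
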