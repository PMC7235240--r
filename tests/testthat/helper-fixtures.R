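# Shared fixtures built in code.

# A deliberately tiny design: 2 RNAs (one fragmented), 2 kits, 2 doses,
# 2 dilutions, 2 amplicons, triplicates.
mini_design <- function(replicates = 3, controls = c("RT0", "RTminus")) {
  design_grid(
    rnas = tibble::tibble(
      rna = c("T", "Tf"),
      integrity = c("intact", "fragmented"),
      matched_intact = c(NA, "T")
    ),
    kits = c("iScript", "Transcriptor"),
    rt_inputs_ng = c(200, 100),
    qpcr_dilution_levels = c(1, 2),
    amplicons = c("eEF1A1", "U1"),
    replicates = replicates,
    controls = controls
  )
}

# Hand-rolled condensed table: one row per well group with given Cq values.
make_condensed <- function(df) {
  defaults <- tibble::tibble(
    rna = "A", kit = "k", rt_input_ng = 100, qpcr_dilution_level = 1,
    amplicon = "x", cq_mean = 20, spread = 0, n_used = 2L, flags = ""
  )
  out <- df
  for (col in names(defaults)) {
    if (!col %in% names(out)) out[[col]] <- defaults[[col]]
  }
  tibble::as_tibble(out)
}

# Brute-force oracle for best-duplicate condensation: enumerate the three
# pairs explicitly, independent of the implementation's combn-based path.
oracle_best_duplicate <- function(x) {
  stopifnot(length(x) == 3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  d <- sapply(pairs, function(p) abs(x[p[1]] - x[p[2]]))
  m <- sapply(pairs, function(p) mean(x[p]))
  best <- which(abs(d - min(d)) < 1e-12)
  i <- best[which.min(m[best])]
  list(mean = m[i], spread = d[i])
}

# Brute-force oracle for dilution-pair counting: scan all ordered pairs of
# distinct well groups and keep those matching on every coordinate except
# the named axis, where inputs must differ exactly 2-fold.
oracle_count_pairs <- function(design, axis) {
  groups <- unique(enumerate_wells(design)[
    enumerate_wells(design)$role == "sample",
    c("rna", "kit", "rt_input_ng", "qpcr_dilution_level", "amplicon")
  ])
  n <- 0L
  for (i in seq_len(nrow(groups))) {
    for (j in seq_len(nrow(groups))) {
      if (i == j) next
      g <- groups[i, ]; h <- groups[j, ]
      same <- g$rna == h$rna && g$kit == h$kit && g$amplicon == h$amplicon
      if (!same) next
      if (axis == "rt") {
        if (g$qpcr_dilution_level == h$qpcr_dilution_level &&
            abs(g$rt_input_ng / h$rt_input_ng - 2) < 1e-9) n <- n + 1L
      } else {
        if (g$rt_input_ng == h$rt_input_ng &&
            abs(h$qpcr_dilution_level / g$qpcr_dilution_level - 2) < 1e-9) n <- n + 1L
      }
    }
  }
  n  # ordered scan counts each unordered pair exactly once (hi -> lo)
}
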