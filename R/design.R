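#' Built-in amplicon registry
#'
#' Metadata for the eight qPCR amplicons used by the built-in titration
#' designs: four coding amplicons (eEF1A1 exon-exon, its intronic eEFint,
#' OAZ1, MVP) and four non-coding ones (18S and 5.8S rRNA, U1 snRNA, Alu).
#' Primer sequences are carried as opaque metadata strings; amplicon length
#' is the cDNA product size in bp (for Alu, the lower end of its 90-93 bp
#' range).
#'
#' @return A tibble with columns `amplicon`, `category` (one of
#'   `coding-exonic`, `coding-intronic`, `ncRNA`, `repeat`),
#'   `amplicon_length_bp`, `primer_fwd`, `primer_rev`, `notes`.
#' @export
#' @examples
#' amplicon_registry()
amplicon_registry <- function() {
  tibble::tribble(
    ~amplicon, ~category,         ~amplicon_length_bp, ~primer_fwd,             ~primer_rev,             ~notes,
    "eEF1A1",  "coding-exonic",   79L, "GGCATCGACAAAAGAACCATC", "CCAGGCATACTTGAAGGAG",    "exon-exon junction; empirically strong reference",
    "eEFint",  "coding-intronic", 79L, "TGGTTGCTTCTGTAACCCAAA", "CAGCCCTTAATTGGCAGTTT",   "intron of eEF1A1; low abundance",
    "OAZ1",    "coding-exonic",   80L, "GCTCCTAAGCCTGCACAGC",   "GACCCGGGTTACTACAGCAG",   "exon-exon junction",
    "MVP",     "coding-exonic",   76L, "AGGCCAAGCTAAAAGCACAG",  "AGCTCTCGGACCTTCTGGAC",   "MVP/LRP; low abundance",
    "18S",     "ncRNA",           75L, "CTGGATACCGCAGCTAGGAA",  "ATCATGGCCTCAGTTCCGAA",   "18S rRNA",
    "5.8S",    "ncRNA",          102L, "GGTGGATCACTCGGCTCGT",   "GCAAGTGCGTTCGAAGTGTC",   "5.8S rRNA",
    "U1",      "ncRNA",          101L, "CCATGATCACGAAGGTGGTT",  "TATGCAGTCGAGTTTCCCACAT", "U1 snRNA; highly structured",
    "Alu",     "repeat",          90L, "CATGGTGAAACCCCGTCTCT",  "AGCCTCAGCCTCCCGAGTAG",   "multi-locus repeat; proposed total-RNA proxy"
  )
}

validate_rna_table <- function(rnas) {
  stopifnot(is.data.frame(rnas))
  required <- c("rna", "integrity")
  missing <- setdiff(required, names(rnas))
  if (length(missing) > 0) {
    stop("RNA table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"matched_intact" %in% names(rnas)) rnas$matched_intact <- NA_character_
  if (!"source" %in% names(rnas)) rnas$source <- NA_character_
  if (anyDuplicated(rnas$rna)) stop("duplicate RNA names", call. = FALSE)
  bad <- !rnas$integrity %in% c("intact", "fragmented")
  if (any(bad)) {
    stop("RNA integrity must be 'intact' or 'fragmented': ",
         paste(rnas$rna[bad], collapse = ", "), call. = FALSE)
  }
  frag <- rnas$integrity == "fragmented"
  ok <- rnas$matched_intact[frag] %in% rnas$rna[rnas$integrity == "intact"]
  if (any(!ok)) {
    stop("fragmented RNA(s) without a matched intact counterpart: ",
         paste(rnas$rna[frag][!ok], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(rnas[, c("rna", "source", "integrity", "matched_intact")])
}

check_twofold <- function(x, what, tol = 1e-9) {
  if (length(x) < 1 || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be a non-empty vector of positive values", call. = FALSE)
  }
  if (length(x) > 1) {
    r <- x[-length(x)] / x[-1]
    if (any(abs(r - 2) > tol)) {
      stop(what, " must be a descending 2-fold series, got: ",
           paste(x, collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' Construct a nested titration design grid
#'
#' A design grid is the cross of RNAs, RT kits, RT input masses, qPCR
#' dilution levels, amplicons and replicates, plus the negative controls
#' carried along each RT (RT0, water instead of RNA; RT-, enzyme omitted).
#' Both titration axes must be descending 2-fold series: the RT axis in ng
#' of total RNA into the RT reaction, the qPCR axis as relative dilution
#' factors of the resulting cDNA (1 = least diluted).
#'
#' @param rnas Data frame with columns `rna`, `integrity` (`intact` or
#'   `fragmented`), and optionally `matched_intact` (required for fragmented
#'   RNAs) and `source`.
#' @param kits Character vector of RT kit names.
#' @param rt_inputs_ng Descending 2-fold series of RNA masses (ng).
#' @param qpcr_dilution_levels Descending-input 2-fold series of relative
#'   cDNA dilution factors, e.g. `c(1, 2, 4)`.
#' @param amplicons Data frame as returned by [amplicon_registry()], or a
#'   character vector of names to select from the built-in registry.
#' @param replicates Number of technical qPCR replicates per well group.
#' @param controls Which negative controls the design carries; subset of
#'   `c("RT0", "RTminus")`.
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(rnas, kits, rt_inputs_ng, qpcr_dilution_levels,
                        amplicons = amplicon_registry(), replicates = 3,
                        controls = c("RT0", "RTminus")) {
  rnas <- validate_rna_table(rnas)
  if (is.character(amplicons)) {
    reg <- amplicon_registry()
    unknown <- setdiff(amplicons, reg$amplicon)
    if (length(unknown) > 0) {
      stop("unknown amplicon(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    amplicons <- reg[match(amplicons, reg$amplicon), ]
  }
  stopifnot(is.data.frame(amplicons))
  if (nrow(amplicons) == 0) stop("amplicon list must not be empty", call. = FALSE)
  if (!"amplicon" %in% names(amplicons)) {
    stop("amplicon table needs an 'amplicon' column", call. = FALSE)
  }
  if (anyDuplicated(amplicons$amplicon)) stop("duplicate amplicon names", call. = FALSE)
  if ("amplicon_length_bp" %in% names(amplicons) &&
      any(amplicons$amplicon_length_bp <= 0, na.rm = TRUE)) {
    stop("amplicon_length_bp must be positive", call. = FALSE)
  }
  if (length(kits) == 0 || anyDuplicated(kits)) {
    stop("kits must be a non-empty vector of unique names", call. = FALSE)
  }
  check_twofold(rt_inputs_ng, "rt_inputs_ng")
  # dilution factors ascend (1, 2, 4) but cDNA *input* descends 2-fold
  check_twofold(rev(qpcr_dilution_levels), "qpcr_dilution_levels (reversed)")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  controls <- if (length(controls) == 0) character(0) else {
    match.arg(controls, c("RT0", "RTminus"), several.ok = TRUE)
  }

  structure(
    list(
      rnas = rnas,
      kits = as.character(kits),
      rt_inputs_ng = as.numeric(rt_inputs_ng),
      qpcr_dilution_levels = as.numeric(qpcr_dilution_levels),
      amplicons = tibble::as_tibble(amplicons),
      replicates = replicates,
      controls = controls
    ),
    class = "design_grid"
  )
}

#' @export
print.design_grid <- function(x, ...) {
  cat("Nested RT/qPCR titration design\n")
  cat("  RNAs:        ", paste(x$rnas$rna, collapse = ", "), "\n")
  cat("  kits:        ", paste(x$kits, collapse = ", "), "\n")
  cat("  RT inputs:   ", paste(x$rt_inputs_ng, collapse = ", "), "ng\n")
  cat("  qPCR levels: ", paste(x$qpcr_dilution_levels, collapse = ", "), "\n")
  cat("  amplicons:   ", paste(x$amplicons$amplicon, collapse = ", "), "\n")
  cat("  replicates:  ", x$replicates, "\n")
  cat("  controls:    ", paste(x$controls, collapse = ", "), "\n")
  n <- nrow(x$rnas) * length(x$kits) * length(x$rt_inputs_ng) *
    length(x$qpcr_dilution_levels) * nrow(x$amplicons) * x$replicates
  cat("  sample wells:", n, "\n")
  invisible(x)
}

#' Built-in titration designs
#'
#' Two preset nested titration experiments:
#' * `exp1`: three RNAs (H, T and chemically fragmented Tf) x three RT kits
#'   (iScript, Transcriptor, SuperScript-IV) x four RT inputs (600, 300,
#'   150, 75 ng) x eight amplicons x three qPCR dilutions x triplicates.
#' * `exp2`: six RNAs (H, T, U and their fragmented counterparts Hf, Tf,
#'   Uf) x one kit (SuperScript-II with library-prep style fragmentation) x
#'   the same doses, amplicons, dilutions and replicates.
#'
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @return A [design_grid()].
#' @export
#' @examples
#' builtin_design("exp1")
builtin_design <- function(experiment_id = c("exp1", "exp2")) {
  if (!is.character(experiment_id) || length(experiment_id) != 1 ||
      !experiment_id %in% c("exp1", "exp2")) {
    stop("unknown experiment_id: ",
         paste(deparse(substitute(experiment_id)), collapse = ""),
         " (expected \"exp1\" or \"exp2\")", call. = FALSE)
  }
  if (experiment_id == "exp1") {
    rnas <- tibble::tibble(
      rna = c("H", "T", "Tf"),
      source = c("Hs578T total RNA", "T-47D total RNA",
                 "T-47D total RNA, chemically fragmented"),
      integrity = c("intact", "intact", "fragmented"),
      matched_intact = c(NA, NA, "T")
    )
    kits <- c("iScript", "Transcriptor", "SuperScript-IV")
  } else {
    rnas <- tibble::tibble(
      rna = c("H", "T", "U", "Hf", "Tf", "Uf"),
      source = c("Hs578T total RNA", "T-47D total RNA",
                 "commercial human reference total RNA",
                 "Hs578T, library-prep fragmented",
                 "T-47D, library-prep fragmented",
                 "reference RNA, library-prep fragmented"),
      integrity = c("intact", "intact", "intact",
                    "fragmented", "fragmented", "fragmented"),
      matched_intact = c(NA, NA, NA, "H", "T", "U")
    )
    kits <- "SuperScript-II"
  }
  design_grid(
    rnas = rnas,
    kits = kits,
    rt_inputs_ng = c(600, 300, 150, 75),
    qpcr_dilution_levels = c(1, 2, 4),
    amplicons = amplicon_registry(),
    replicates = 3
  )
}

#' Enumerate the wells of a design
#'
#' Produces one descriptor row per sample well (rna x kit x RT input x
#' qPCR dilution x amplicon x replicate) plus one row per control well
#' (per kit x amplicon x replicate, with no RT input and the least-diluted
#' qPCR level). No Cq values are attached. The output order is
#' deterministic: sorted by the full key tuple.
#'
#' @param design A [design_grid()].
#' @return A tibble with columns `rna`, `kit`, `rt_input_ng`,
#'   `qpcr_dilution_level`, `amplicon`, `replicate`, `role`.
#' @export
enumerate_wells <- function(design) {
  stopifnot(inherits(design, "design_grid"))
  samples <- tidyr::expand_grid(
    rna = design$rnas$rna,
    kit = design$kits,
    rt_input_ng = design$rt_inputs_ng,
    qpcr_dilution_level = design$qpcr_dilution_levels,
    amplicon = design$amplicons$amplicon,
    replicate = seq_len(design$replicates)
  )
  samples$role <- "sample"
  if (length(design$controls) > 0) {
    ctrl <- tidyr::expand_grid(
      rna = NA_character_,
      kit = design$kits,
      rt_input_ng = NA_real_,
      qpcr_dilution_level = min(design$qpcr_dilution_levels),
      amplicon = design$amplicons$amplicon,
      replicate = seq_len(design$replicates),
      role = design$controls
    )
    samples <- dplyr::bind_rows(samples, ctrl)
  }
  dplyr::arrange(samples, .data$role, .data$rna, .data$kit,
                 dplyr::desc(.data$rt_input_ng), .data$qpcr_dilution_level,
                 .data$amplicon, .data$replicate)
}

#' Count adjacent 2-fold dilution pairs in a design
#'
#' Counts the adjacent 2-fold pairs available on one titration axis after
#' replicates are condensed to a single value per well group. On the qPCR
#' axis every (rna, kit, RT input, amplicon) combination contributes
#' `length(qpcr_dilution_levels) - 1` pairs; on the RT axis every
#' (rna, kit, amplicon, qPCR dilution) combination contributes
#' `length(rt_inputs_ng) - 1` pairs. Control wells never pair.
#'
#' @param design A [design_grid()].
#' @param axis `"rt"` or `"qpcr"`.
#' @return Integer pair count.
#' @export
#' @examples
#' count_dilution_pairs(builtin_design("exp1"), "qpcr")  # 576
#' count_dilution_pairs(builtin_design("exp1"), "rt")    # 648
count_dilution_pairs <- function(design, axis) {
  stopifnot(inherits(design, "design_grid"))
  if (!is.character(axis) || length(axis) != 1 || !axis %in% c("rt", "qpcr")) {
    stop("unknown axis: must be \"rt\" or \"qpcr\"", call. = FALSE)
  }
  n_rna <- nrow(design$rnas)
  n_kit <- length(design$kits)
  n_amp <- nrow(design$amplicons)
  n_dose <- length(design$rt_inputs_ng)
  n_dil <- length(design$qpcr_dilution_levels)
  if (axis == "qpcr") {
    n_rna * n_kit * n_dose * n_amp * (n_dil - 1L)
  } else {
    n_rna * n_kit * n_amp * n_dil * (n_dose - 1L)
  }
}

#' Write a design to a YAML config
#'
#' @param design A [design_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_grid"))
  obj <- list(
    rnas = lapply(seq_len(nrow(design$rnas)), function(i) {
      r <- as.list(design$rnas[i, ])
      r[!vapply(r, is.na, logical(1))]
    }),
    kits = as.list(design$kits),
    rt_inputs_ng = as.list(design$rt_inputs_ng),
    qpcr_dilution_levels = as.list(design$qpcr_dilution_levels),
    amplicons = lapply(seq_len(nrow(design$amplicons)), function(i) {
      as.list(design$amplicons[i, ])
    }),
    replicates = design$replicates,
    controls = as.list(design$controls)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a design from a YAML config
#'
#' Accepts either a full config written by [write_design()] or the name of
#' a built-in preset (`exp1`, `exp2`) given as `preset: exp1`.
#'
#' @param path Path to a YAML design config.
#' @return A [design_grid()].
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$preset)) return(builtin_design(obj$preset))
  required <- c("rnas", "kits", "rt_inputs_ng", "qpcr_dilution_levels")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop("design config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rnas <- dplyr::bind_rows(lapply(obj$rnas, tibble::as_tibble))
  amplicons <- if (is.null(obj$amplicons)) {
    amplicon_registry()
  } else if (is.character(obj$amplicons) ||
             all(vapply(obj$amplicons, is.character, logical(1)))) {
    unlist(obj$amplicons)
  } else {
    dplyr::bind_rows(lapply(obj$amplicons, tibble::as_tibble))
  }
  design_grid(
    rnas = rnas,
    kits = unlist(obj$kits),
    rt_inputs_ng = unlist(obj$rt_inputs_ng),
    qpcr_dilution_levels = unlist(obj$qpcr_dilution_levels),
    amplicons = amplicons,
    replicates = if (is.null(obj$replicates)) 3 else obj$replicates,
    controls = if (is.null(obj$controls)) c("RT0", "RTminus") else unlist(obj$controls)
  )
}
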