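#' Consolidated titration QC report
#'
#' Runs the full diagnostic pipeline on a validated Cq table: replicate
#' dispersion, negative-control QC, per-amplicon x kit dose-response
#' summaries with bias labels on both titration axes, optional
#' delta-delta-Cq dose-dependence recipes, and fragmentation shifts for
#' every matched intact/fragmented RNA pair in the design. The report
#' `status` is nonzero when any RT-axis amplicon x kit group is labelled
#' saturated, or any recipe's fold change drifts across doses by more
#' than `max_fold_bound` — the gate for "is this assay safe for
#' delta-delta-Cq?".
#'
#' @param table A validated Cq table.
#' @param design The [design_grid()] the table should conform to.
#' @param policy Replicate condensation policy (see [condense()]).
#' @param nc_threshold Negative-control flag threshold (Cq).
#' @param linear_min,saturated_max Bias classification thresholds (see
#'   [classify_bias()]).
#' @param high_cq High-Cq flag threshold (see [condense()]).
#' @param de_recipes List of recipes, each a list with `target`,
#'   `reference`, `condition_a`, `condition_b` (named filter lists
#'   without `rt_input_ng`) and optional `doses` (default: all design
#'   doses).
#' @param max_fold_bound Maximum tolerated dose discrepancy of a recipe's
#'   fold change. The default 1.5 confines reference-normalised calls to
#'   minor fluctuations (1.5-fold is a delta-Cq of 0.58).
#' @return An object of class `cq2f_report`: a list with elements
#'   `validation`, `dispersion`, `negative_controls`, `titration`
#'   (grand + grouped summaries for both axes), `dose_dependence`,
#'   `fragmentation`, `status` (0 = clean) and `failures` (character).
#' @export
qc_report <- function(table, design, policy = "best_duplicate",
                      nc_threshold = 35, linear_min = 0.75,
                      saturated_max = 0.25, high_cq = 30,
                      de_recipes = list(), max_fold_bound = 1.5) {
  table <- validate_cq_table(table)
  validation <- validate_against_design(table, design)
  if (nrow(validation$missing) > 0) {
    stop("table is incomplete against the design: ",
         nrow(validation$missing), " well group(s) missing", call. = FALSE)
  }
  dispersion <- replicate_dispersion(table)
  nc <- qc_negative_controls(table, nc_threshold)
  condensed <- condense(table, policy = policy, high_cq = high_cq)

  titration <- list()
  failures <- character()
  for (axis in c("rt", "qpcr")) {
    pairs <- cq2f_pairs(condensed, axis)
    grand <- summarize_cq2f(pairs)
    by_group <- summarize_cq2f(pairs, group_by = c("amplicon", "kit"))
    if (axis == "rt") {
      by_group <- classify_bias(by_group, linear_min, saturated_max)
      sat <- by_group[by_group$bias == "saturated", ]
      if (nrow(sat) > 0) {
        failures <- c(failures, paste0(
          "saturated RT dose-response: ",
          paste(sat$amplicon, sat$kit, sep = "/", collapse = ", ")
        ))
      }
    }
    titration[[axis]] <- list(grand = grand, by_amplicon_kit = by_group,
                              n_pairs = nrow(pairs))
  }

  dose_dependence <- lapply(de_recipes, function(recipe) {
    doses <- if (is.null(recipe$doses)) design$rt_inputs_ng else recipe$doses
    res <- apparent_de_across_doses(condensed, recipe$target, recipe$reference,
                                    recipe$condition_a, recipe$condition_b,
                                    doses)
    res$recipe <- recipe
    res
  })
  for (res in dose_dependence) {
    if (res$max_discrepancy > max_fold_bound) {
      failures <- c(failures, paste0(
        "dose-dependent apparent DE for ", res$recipe$target, " vs ",
        res$recipe$reference, ": max discrepancy ",
        format(res$max_discrepancy, digits = 3), "-fold"
      ))
    }
  }

  frag_pairs <- design$rnas[design$rnas$integrity == "fragmented" &
                              !is.na(design$rnas$matched_intact), ]
  fragmentation <- if (nrow(frag_pairs) == 0) NULL else {
    rows <- list()
    for (i in seq_len(nrow(frag_pairs))) {
      for (a in design$amplicons$amplicon) {
        sh <- tryCatch(
          fragmentation_shift(condensed, a, frag_pairs$matched_intact[i],
                              frag_pairs$rna[i]),
          error = function(e) NULL
        )
        if (!is.null(sh)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            amplicon = a,
            intact_rna = frag_pairs$matched_intact[i],
            fragmented_rna = frag_pairs$rna[i],
            mean_shift = sh$mean_shift, sd_shift = sh$sd_shift, n = sh$n
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  if (!nc$pass) {
    failures <- c(failures, paste0(nrow(nc$flagged),
                                   " negative-control well(s) with substantial readings"))
  }

  structure(
    list(
      validation = validation,
      dispersion = dispersion,
      negative_controls = nc,
      condensed = condensed,
      titration = titration,
      dose_dependence = dose_dependence,
      fragmentation = fragmentation,
      failures = failures,
      status = as.integer(length(failures) > 0)
    ),
    class = "cq2f_report"
  )
}

#' @export
print.cq2f_report <- function(x, ...) {
  cat("== Nested titration QC report ==\n\n")
  cat("[replicate dispersion]\n")
  print(x$dispersion)
  cat("\n[negative controls] ", x$negative_controls$n_controls, "wells,",
      nrow(x$negative_controls$flagged), "flagged ->",
      if (x$negative_controls$pass) "PASS" else "FAIL", "\n")
  for (axis in names(x$titration)) {
    g <- x$titration[[axis]]$grand
    cat("\n[", axis, " axis] grand Cq2f ",
        sprintf("%.2f +/- %.2f (n = %d)", g$mean_cq2f, g$sd_cq2f, g$n_pairs),
        "\n", sep = "")
    print(x$titration[[axis]]$by_amplicon_kit, n = Inf)
  }
  if (length(x$dose_dependence) > 0) {
    cat("\n[dose dependence of apparent DE]\n")
    for (res in x$dose_dependence) {
      cat("  ", res$recipe$target, " vs ", res$recipe$reference,
          ": max discrepancy ", sprintf("%.2f", res$max_discrepancy),
          "-fold\n", sep = "")
    }
  }
  if (!is.null(x$fragmentation)) {
    cat("\n[fragmentation shifts]\n")
    print(x$fragmentation, n = Inf)
  }
  cat("\nstatus:", x$status,
      if (x$status == 0) "(clean)" else
        paste0("(", paste(x$failures, collapse = "; "), ")"), "\n")
  invisible(x)
}

report_to_list <- function(report) {
  list(
    dispersion = as.list(tidyr::pivot_wider(
      report$dispersion[, c("statistic", "mean", "sd")],
      names_from = "statistic", values_from = c("mean", "sd")
    )),
    negative_controls = list(
      n_controls = report$negative_controls$n_controls,
      n_flagged = nrow(report$negative_controls$flagged),
      pass = report$negative_controls$pass
    ),
    titration = lapply(report$titration, function(ax) {
      list(grand = as.list(ax$grand),
           by_amplicon_kit = unname(split(
             ax$by_amplicon_kit,
             seq_len(nrow(ax$by_amplicon_kit))
           ) |> lapply(as.list)))
    }),
    dose_dependence = lapply(report$dose_dependence, function(res) {
      list(target = res$recipe$target,
           reference = res$recipe$reference,
           max_discrepancy = res$max_discrepancy,
           per_dose = unname(split(res$results, seq_len(nrow(res$results))) |>
                               lapply(as.list)))
    }),
    fragmentation = if (is.null(report$fragmentation)) NULL else {
      unname(split(report$fragmentation,
                   seq_len(nrow(report$fragmentation))) |> lapply(as.list))
    },
    failures = report$failures,
    status = report$status
  )
}

#' Write a QC report to disk
#'
#' Emits a machine-readable `report.json` carrying every number the
#' human-readable summary shows, CSVs of the per-group summaries, and a
#' plain-text `summary.txt` (the [print()] rendering).
#'
#' @param report A [qc_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cq2f_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$condensed, file.path(dir, "condensed.csv"),
                   progress = FALSE)
  for (axis in names(report$titration)) {
    readr::write_csv(report$titration[[axis]]$by_amplicon_kit,
                     file.path(dir, paste0("cq2f_", axis, "_by_amplicon_kit.csv")),
                     progress = FALSE)
  }
  if (!is.null(report$fragmentation)) {
    readr::write_csv(report$fragmentation,
                     file.path(dir, "fragmentation_shifts.csv"),
                     progress = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

resolve_design <- function(x) {
  if (inherits(x, "design_grid")) return(x)
  if (is.character(x) && x %in% c("exp1", "exp2")) return(builtin_design(x))
  if (is.character(x) && file.exists(x)) return(read_design(x))
  stop("cannot resolve design: ", x, call. = FALSE)
}

resolve_params <- function(x, seed = NULL) {
  p <- if (inherits(x, "generative_params")) {
    x
  } else if (is.character(x) && x %in% c("ideal", "paperlike")) {
    preset_params(x)
  } else if (is.character(x) && file.exists(x)) {
    read_params(x)
  } else {
    stop("cannot resolve simulator parameters: ", x, call. = FALSE)
  }
  if (!is.null(seed)) p$seed <- as.integer(seed)
  p
}

#' Simulate a titration table from a run config
#'
#' Thin driver around [simulate_cq_table()]: resolves the design and
#' parameter presets or files named in the config, writes the canonical
#' long CSV and a sidecar YAML echoing the exact parameters and seed
#' used.
#'
#' @param config A list (or YAML file path) with fields `design` (preset
#'   name, design file or object), `params` (preset name, file or
#'   object), optional `seed`, and `out` (CSV path).
#' @return The simulated table, invisibly.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  design <- resolve_design(config$design)
  params <- resolve_params(config$params, seed = config$seed)
  table <- simulate_cq_table(design, params)
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), recursive = TRUE, showWarnings = FALSE)
    write_cq_table(table, config$out)
    write_params(params, paste0(config$out, ".params.yaml"))
  }
  invisible(table)
}

#' Run the consolidated QC report from a run config
#'
#' @param config A list (or YAML file path) with fields `input` (CSV path
#'   or table), `design`, and optionally `policy`, `nc_threshold`,
#'   `linear_min`, `saturated_max`, `high_cq`, `recipes`,
#'   `max_fold_bound`, `out` (directory for [write_report()]).
#' @return The [qc_report()] object, invisibly; its `status` element is
#'   the intended process exit code.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  table <- if (is.data.frame(config$input)) {
    validate_cq_table(config$input)
  } else {
    read_cq_table(config$input)
  }
  design <- resolve_design(config$design)
  arg <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  report <- qc_report(
    table, design,
    policy = arg("policy", "best_duplicate"),
    nc_threshold = arg("nc_threshold", 35),
    linear_min = arg("linear_min", 0.75),
    saturated_max = arg("saturated_max", 0.25),
    high_cq = arg("high_cq", 30),
    de_recipes = arg("recipes", list()),
    max_fold_bound = arg("max_fold_bound", 1.5)
  )
  if (!is.null(config$out)) write_report(report, config$out)
  invisible(report)
}
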