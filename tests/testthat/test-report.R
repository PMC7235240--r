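test_that("an ideal experiment yields a clean report", {
  design <- mini_design()
  table <- simulate_cq_table(design, preset_params("ideal"))
  report <- qc_report(table, design)
  expect_s3_class(report, "cq2f_report")
  expect_equal(report$status, 0L)
  expect_length(report$failures, 0)
  expect_true(all(report$titration$rt$by_amplicon_kit$bias == "linear"))
  expect_equal(report$titration$rt$grand$mean_cq2f, 1)
  expect_equal(report$titration$qpcr$grand$mean_cq2f, 1)
  expect_true(report$negative_controls$pass)
})

test_that("a saturated experiment fails the report gate with named groups", {
  design <- builtin_design("exp1")
  table <- simulate_cq_table(design, preset_params("paperlike"), seed = 2)
  report <- qc_report(table, design)
  expect_equal(report$status, 1L)
  expect_true(any(grepl("saturated RT dose-response", report$failures)))
  expect_true(any(grepl("U1/iScript", report$failures)))
  sat <- report$titration$rt$by_amplicon_kit
  expect_gte(sum(sat$bias == "saturated"), 1)
})

test_that("dose-dependence recipes can trip the report gate", {
  design <- mini_design()
  table <- simulate_cq_table(design, preset_params("ideal"))
  recipe <- list(target = "U1", reference = "eEF1A1",
                 condition_a = list(rna = "T", kit = "iScript"),
                 condition_b = list(rna = "T", kit = "Transcriptor"))
  clean <- qc_report(table, design, de_recipes = list(recipe))
  expect_equal(clean$status, 0L)
  expect_equal(clean$dose_dependence[[1]]$max_discrepancy, 1.0)

  # inject a dose-dependent skew into one condition's target measurements
  skewed <- table
  pick <- skewed$role == "sample" & skewed$amplicon == "U1" &
    skewed$kit == "iScript" & skewed$rna == "T" & skewed$rt_input_ng == 100
  skewed$cq[pick] <- skewed$cq[pick] + 1
  rep2 <- qc_report(skewed, design, de_recipes = list(recipe))
  expect_gt(rep2$dose_dependence[[1]]$max_discrepancy, 1.5)
  expect_equal(rep2$status, 1L)
  expect_true(any(grepl("dose-dependent apparent DE", rep2$failures)))
})

test_that("incomplete tables abort the report with a named cause", {
  design <- mini_design()
  table <- simulate_cq_table(design, preset_params("ideal"))
  crippled <- table[!(table$role == "sample" & table$amplicon == "U1" &
                        table$rna == "T" &
                        table$kit == "iScript" & table$rt_input_ng == 200 &
                        table$qpcr_dilution_level == 1), ]
  expect_error(qc_report(crippled, design), "incomplete")
})

test_that("fragmentation shifts appear only when matched RNAs exist", {
  design <- mini_design()
  table <- simulate_cq_table(design, preset_params("paperlike"))
  report <- qc_report(table, design)
  expect_false(is.null(report$fragmentation))
  expect_setequal(unique(report$fragmentation$fragmented_rna), "Tf")

  intact_only <- design_grid(
    rnas = tibble::tibble(rna = "T", integrity = "intact",
                          matched_intact = NA_character_),
    kits = "iScript", rt_inputs_ng = c(200, 100),
    qpcr_dilution_levels = c(1, 2), amplicons = c("eEF1A1", "U1")
  )
  t2 <- simulate_cq_table(intact_only, preset_params("paperlike"))
  expect_null(qc_report(t2, intact_only)$fragmentation)
})

test_that("simulate and report drivers are reproducible end to end", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "a.csv")
  out2 <- file.path(dir, "b.csv")
  cfg <- list(design = "exp2", params = "paperlike", seed = 4, out = out1)
  run_simulate(cfg)
  run_simulate(within(cfg, out <- out2))
  expect_identical(readLines(out1), readLines(out2))
  expect_true(file.exists(paste0(out1, ".params.yaml")))

  table <- read_cq_table(out1)
  expect_true(validate_against_design(table, builtin_design("exp2"))$pass)

  rep_dir1 <- file.path(dir, "rep1")
  rep_dir2 <- file.path(dir, "rep2")
  r1 <- run_report(list(input = out1, design = "exp2", out = rep_dir1))
  r2 <- run_report(list(input = out1, design = "exp2", out = rep_dir2))
  expect_identical(readLines(file.path(rep_dir1, "report.json")),
                   readLines(file.path(rep_dir2, "report.json")))
  expect_equal(r1$status, r2$status)
})

test_that("the machine-readable report carries the printed numbers", {
  design <- mini_design()
  table <- simulate_cq_table(design, preset_params("paperlike"))
  report <- qc_report(table, design)
  dir <- withr::local_tempdir()
  write_report(report, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$titration$rt$grand$mean_cq2f,
               report$titration$rt$grand$mean_cq2f)
  expect_equal(js$titration$qpcr$grand$n_pairs,
               report$titration$qpcr$grand$n_pairs)
  expect_equal(js$status, report$status)
  expect_equal(length(js$fragmentation), nrow(report$fragmentation))
  txt <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("grand Cq2f", txt)))
})
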