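two_condition_condensed <- function(cq_target_a, cq_target_b,
                                    cq_ref_a, cq_ref_b) {
  make_condensed(tibble::tibble(
    rna = rep(c("a", "b"), each = 2),
    amplicon = rep(c("tgt", "ref"), 2),
    cq_mean = c(cq_target_a, cq_ref_a, cq_target_b, cq_ref_b)
  ))
}

test_that("delta-delta-Cq follows the standard formula and orientation", {
  cond <- two_condition_condensed(25, 26, 20, 20)
  res <- delta_delta_cq(cond, "tgt", "ref", list(rna = "a"), list(rna = "b"))
  expect_equal(res$delta_cq_a, 5)
  expect_equal(res$delta_cq_b, 6)
  expect_equal(res$delta_delta_cq, -1)
  expect_equal(res$fold_change, 2.0)
  expect_equal(res$fold_change, 2^(-res$delta_delta_cq), tolerance = 1e-12)

  same <- two_condition_condensed(25, 25, 20, 20)
  expect_equal(delta_delta_cq(same, "tgt", "ref", list(rna = "a"),
                              list(rna = "b"))$fold_change, 1.0)
  # self-normalisation is always fold 1
  expect_equal(delta_delta_cq(cond, "ref", "ref", list(rna = "a"),
                              list(rna = "b"))$fold_change, 1.0)
  expect_error(
    delta_delta_cq(cond, "tgt", "ref", list(rna = "zz"), list(rna = "b")),
    "no condensed measurement"
  )
})

test_that("multiple references combine by arithmetic Cq mean", {
  cond <- make_condensed(tibble::tibble(
    rna = rep(c("a", "b"), each = 3),
    amplicon = rep(c("tgt", "r1", "r2"), 2),
    cq_mean = c(25, 18, 22, 25, 19, 23)
  ))
  res <- delta_delta_cq(cond, "tgt", c("r1", "r2"),
                        list(rna = "a"), list(rna = "b"))
  expect_equal(res$delta_cq_a, 25 - 20)
  expect_equal(res$delta_cq_b, 25 - 21)
})

test_that("fold changes are reciprocal and plate-offset invariant", {
  set.seed(99)
  for (i in 1:50) {
    cq <- runif(4, 15, 30)
    cond <- two_condition_condensed(cq[1], cq[2], cq[3], cq[4])
    ab <- delta_delta_cq(cond, "tgt", "ref", list(rna = "a"), list(rna = "b"))
    ba <- delta_delta_cq(cond, "tgt", "ref", list(rna = "b"), list(rna = "a"))
    expect_equal(ab$fold_change * ba$fold_change, 1, tolerance = 1e-9)

    shifted <- cond
    shifted$cq_mean <- shifted$cq_mean + runif(1, -5, 5)
    ab2 <- delta_delta_cq(shifted, "tgt", "ref", list(rna = "a"),
                          list(rna = "b"))
    expect_equal(ab2$delta_delta_cq, ab$delta_delta_cq, tolerance = 1e-9)
  }
})

test_that("dose dependence of apparent DE is quantified across RT inputs", {
  # ideal data: between-sample fold identical at every dose
  design <- mini_design()
  condensed <- condense(simulate_cq_table(design, preset_params("ideal")))
  res <- apparent_de_across_doses(condensed, "U1", "eEF1A1",
                                  list(rna = "T", kit = "iScript"),
                                  list(rna = "T", kit = "Transcriptor"),
                                  design$rt_inputs_ng)
  expect_equal(res$max_discrepancy, 1.0)

  # hand-built: folds 1.0 at 600 ng and 2.0 at 75 ng
  cond <- make_condensed(tibble::tibble(
    rna = rep(c("a", "b"), each = 4),
    rt_input_ng = rep(c(600, 600, 75, 75), 2),
    amplicon = rep(c("tgt", "ref"), 4),
    cq_mean = c(25, 20, 24, 20, 25, 20, 25, 20)
  ))
  res2 <- apparent_de_across_doses(cond, "tgt", "ref", list(rna = "a"),
                                   list(rna = "b"), c(600, 75))
  expect_equal(sort(res2$results$fold_change), c(1.0, 2.0))
  expect_equal(res2$max_discrepancy, 2.0)

  expect_error(
    apparent_de_across_doses(cond, "tgt", "ref", list(rna = "a"),
                             list(rna = "b"), 600),
    "at least 2 doses"
  )
})

test_that("fragmentation shifts are matched-coordinate Cq differences", {
  base <- make_condensed(tidyr::expand_grid(
    rna = c("T", "Tf"), kit = "k", rt_input_ng = c(600, 300),
    qpcr_dilution_level = c(1, 2), amplicon = "eEF1A1"
  ))
  base$cq_mean <- 20
  expect_equal(fragmentation_shift(base, "eEF1A1", "T", "Tf")$mean_shift, 0)

  base$cq_mean[base$rna == "Tf"] <- 22
  sh <- fragmentation_shift(base, "eEF1A1", "T", "Tf")
  expect_equal(sh$mean_shift, 2.0)
  expect_equal(sh$sd_shift, 0.0)
  expect_equal(sh$n, 4)

  expect_error(fragmentation_shift(base, "eEF1A1", "T", "Xf"),
               "no matched")
})

test_that("noiseless simulation ties the shift to the survival factor", {
  design <- mini_design()
  params <- preset_params("ideal")
  params$s["eEF1A1"] <- 0.25
  params$sigma <- 0
  condensed <- condense(simulate_cq_table(design, params))
  sh <- fragmentation_shift(condensed, "eEF1A1", "T", "Tf")
  expect_equal(sh$mean_shift, -log2(0.25), tolerance = 1e-12)  # = 2
})

test_that("fragmentation-induced apparent DE inverts sub-unity folds", {
  grid <- tidyr::expand_grid(
    rna = c("T", "Tf"), kit = "k", rt_input_ng = c(600, 300),
    qpcr_dilution_level = 1, amplicon = c("tgt", "ref")
  )
  base <- make_condensed(grid)
  base$cq_mean <- 20
  # identical shifts in target and reference cancel
  base$cq_mean[base$rna == "Tf"] <- 21
  res <- fragmentation_de_artifact(base, "tgt", "ref", "T", "Tf")
  expect_true(all(res$results$fold_change == 1))
  expect_equal(res$max_fold, 1.0)

  # target +1, reference +2: fold = 2^(-(1 - 2)) = 2
  base$cq_mean <- 20
  base$cq_mean[base$rna == "Tf" & base$amplicon == "tgt"] <- 21
  base$cq_mean[base$rna == "Tf" & base$amplicon == "ref"] <- 22
  res2 <- fragmentation_de_artifact(base, "tgt", "ref", "T", "Tf")
  expect_equal(unique(res2$results$fold_change), 2.0)

  # target +0.5, reference -0.5: fold 0.5, reported magnitude 2
  base$cq_mean <- 20
  base$cq_mean[base$rna == "Tf" & base$amplicon == "tgt"] <- 20.5
  base$cq_mean[base$rna == "Tf" & base$amplicon == "ref"] <- 19.5
  res3 <- fragmentation_de_artifact(base, "tgt", "ref", "T", "Tf")
  expect_equal(unique(res3$results$fold_change), 0.5)
  expect_equal(res3$max_fold, 2.0)
})
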