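test_that("expected Cq has the ideal-dilution limits", {
  p <- preset_params("ideal")
  cq1 <- expected_cq(p, "U1", "T", "iScript", M = 300, d = 1)
  # halving cDNA input (doubling d) raises Cq by exactly 1
  expect_equal(expected_cq(p, "U1", "T", "iScript", M = 300, d = 2) - cq1, 1)
  # halving RNA input raises Cq by exactly 1 when the RT never saturates
  expect_equal(expected_cq(p, "U1", "T", "iScript", M = 150, d = 1) - cq1, 1)
  expect_error(expected_cq(p, "GAPDH", "T", "iScript", 300, 1),
               "no parameters")
})

test_that("closed-form RT-axis Cq2f matches the well-level model", {
  expect_equal(expected_cq2f_rt(300, Inf), 1)
  expect_equal(expected_cq2f_rt(300, 300), 1 + log2(2 / 3))  # ~0.415
  expect_lt(expected_cq2f_rt(1e9, 1), 1e-6)                  # full saturation

  p <- preset_params("ideal")
  for (K in c(20, 150, 300, 1500, Inf)) {
    p$K[] <- K
    for (M in c(75, 150, 300)) {
      cq2f <- expected_cq(p, "U1", "T", "iScript", M, 1) -
        expected_cq(p, "U1", "T", "iScript", 2 * M, 1)
      expect_equal(cq2f, expected_cq2f_rt(M, K), tolerance = 1e-12)
    }
  }
})

test_that("expected Cq decreases in input and Cq2f decreases in M/K", {
  p <- preset_params("paperlike")
  M <- c(75, 150, 300, 600)
  cqs <- sapply(M, function(m) expected_cq(p, "MVP", "H", "iScript", m, 1))
  expect_true(all(diff(cqs) < 0))
  ds <- c(4, 2, 1)  # increasing cDNA input
  cqd <- sapply(ds, function(d) expected_cq(p, "MVP", "H", "iScript", 300, d))
  expect_true(all(diff(cqd) < 0))
  ratio <- 10^seq(-3, 3, length.out = 50)
  vals <- expected_cq2f_rt(ratio, 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("simulation is seed-deterministic and design-complete", {
  design <- mini_design()
  params <- preset_params("paperlike")
  t1 <- simulate_cq_table(design, params, seed = 5)
  t2 <- simulate_cq_table(design, params, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_cq_table(design, params, seed = 6)
  expect_false(identical(t1, t3))
  expect_true(validate_against_design(t1, design)$pass)
  # control wells are emitted undetermined
  expect_true(all(is.na(t1$cq[t1$role != "sample"])))

  bad <- design_grid(
    tibble::tibble(rna = "Z", integrity = "intact",
                   matched_intact = NA_character_),
    kits = "iScript", rt_inputs_ng = c(600, 300),
    qpcr_dilution_levels = c(1, 2), amplicons = "U1"
  )
  expect_error(simulate_cq_table(bad, params), "cover RNA 'Z'")
})

test_that("noisy RT-axis Cq2f means track the closed form", {
  design <- builtin_design("exp1")
  params <- preset_params("ideal")
  params$sigma <- 0.1
  params$K[] <- 300
  condensed <- condense(simulate_cq_table(design, params, seed = 21))
  pairs <- cq2f_pairs(condensed, "rt")
  expected <- mean(expected_cq2f_rt(c(75, 150, 300), 300))
  n <- nrow(pairs)
  expect_equal(mean(pairs$cq2f), expected,
               tolerance = 3 * params$sigma / sqrt(n) / expected)
})

test_that("the saturation constant is recoverable from Cq2f data", {
  Ms <- c(75, 150, 300)
  noiseless <- data.frame(lo_input = Ms, cq2f = expected_cq2f_rt(Ms, 300))
  fit <- fit_saturation(noiseless)
  expect_true(fit$saturation_detected)
  expect_lt(abs(fit$K - 300) / 300, 1e-6)
  expect_lt(fit$residual_norm, 1e-6)

  flat <- data.frame(lo_input = Ms, cq2f = c(1, 1, 1))
  fit0 <- fit_saturation(flat)
  expect_identical(fit0$K, Inf)
  expect_false(fit0$saturation_detected)

  expect_error(fit_saturation(data.frame(lo_input = c(75, 75),
                                         cq2f = c(0.5, 0.6))),
               "distinct dose pairs")
})

test_that("noisy recovery of K stays within 15% in at least 90% of runs", {
  Ms <- rep(c(75, 150, 300), each = 24)
  truth <- 150
  mu <- expected_cq2f_rt(Ms, truth)
  hits <- 0L
  for (i in 1:200) {
    set.seed(5000 + i)
    obs <- data.frame(lo_input = Ms, cq2f = mu + rnorm(length(Ms), 0, 0.05))
    fit <- fit_saturation(obs)
    if (is.finite(fit$K) && abs(fit$K - truth) / truth <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 180L)
})

test_that("the paperlike preset shows the kit-swapped saturation signature", {
  design <- builtin_design("exp1")
  condensed <- condense(simulate_cq_table(design, preset_params("paperlike"),
                                          seed = 2))
  summary <- classify_bias(
    summarize_cq2f(cq2f_pairs(condensed, "rt"), c("amplicon", "kit"))
  )
  label <- function(a, k) summary$bias[summary$amplicon == a & summary$kit == k]
  # each kit saturates one of the two small structural RNAs, not the other
  expect_equal(label("U1", "iScript"), "saturated")
  expect_false(label("5.8S", "iScript") == "saturated")
  expect_equal(label("5.8S", "Transcriptor"), "saturated")
  expect_false(label("U1", "Transcriptor") == "saturated")
  # the repeat amplicon responds consistently under both kits
  expect_equal(label("Alu", "iScript"), label("Alu", "Transcriptor"))
  expect_false(label("Alu", "iScript") == "saturated")
})
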