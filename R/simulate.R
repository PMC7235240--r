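#' Generative parameters for the Cq simulator
#'
#' The simulator's noiseless model of one well is
#' `T = alpha[a, r] * s[a]^frag * M / (1 + M / K[a, k])` and
#' `Cq = beta[k] - log(T / d) / log(1 + E)`, where `M` is the RNA mass
#' into the RT (ng), `d` the relative qPCR dilution factor and `frag`
#' 1 for fragmented RNA, else 0. The hyperbolic term makes RT capture
#' saturate in total RNA input with half-saturation constant `K`;
#' `K = Inf` recovers the ideal `-1 Cq per input doubling` behaviour.
#'
#' @param alpha Numeric matrix of relative template abundance per ng,
#'   amplicons in rows, RNAs in columns (dimnames required). Fragmented
#'   RNAs use the abundance of their column (typically set equal to the
#'   matched intact RNA) times the survival factor.
#' @param K Numeric matrix of RT saturation constants (ng), amplicons in
#'   rows, kits in columns; `Inf` = no saturation.
#' @param beta Named numeric vector of kit-level Cq intercepts (Cq at unit
#'   effective template in an undiluted reaction).
#' @param s Named numeric vector of fragmentation survival factors per
#'   amplicon; values above 1 model structure-protected species.
#' @param efficiency qPCR efficiency per cycle, in (0, 1]; 1 = perfect
#'   doubling.
#' @param sigma Replicate noise SD in Cq units.
#' @param seed Default RNG seed used by [simulate_cq_table()].
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(alpha, K, beta, s, efficiency = 1,
                              sigma = 0.19, seed = 1L) {
  stopifnot(is.matrix(alpha), is.matrix(K),
            !is.null(dimnames(alpha)), !is.null(dimnames(K)))
  if (any(alpha <= 0) || any(!is.finite(alpha))) {
    stop("alpha must be finite and positive", call. = FALSE)
  }
  if (any(K <= 0)) stop("K must be positive (Inf allowed)", call. = FALSE)
  if (is.null(names(beta)) || any(!is.finite(beta))) {
    stop("beta must be a named finite vector", call. = FALSE)
  }
  if (is.null(names(s)) || any(s <= 0) || any(!is.finite(s))) {
    stop("s must be a named vector of positive finite survivals", call. = FALSE)
  }
  stopifnot(length(efficiency) == 1, efficiency > 0, efficiency <= 1,
            length(sigma) == 1, sigma >= 0)
  structure(
    list(alpha = alpha, K = K, beta = beta, s = s,
         efficiency = efficiency, sigma = sigma, seed = as.integer(seed)),
    class = "generative_params"
  )
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Cq simulator parameters\n")
  cat("  amplicons: ", paste(rownames(x$alpha), collapse = ", "), "\n")
  cat("  RNAs:      ", paste(colnames(x$alpha), collapse = ", "), "\n")
  cat("  kits:      ", paste(colnames(x$K), collapse = ", "), "\n")
  cat("  efficiency:", x$efficiency, "  sigma:", x$sigma, " seed:", x$seed, "\n")
  invisible(x)
}

#' Noiseless expected Cq of one well
#'
#' @param params A [generative_params()] object.
#' @param amplicon,rna,kit Coordinate names (must be covered by the
#'   parameter matrices).
#' @param M RNA mass into the RT reaction (ng), > 0.
#' @param d Relative qPCR dilution factor, >= 1.
#' @param fragmented Apply the amplicon's fragmentation survival factor?
#' @return The deterministic Cq value.
#' @export
expected_cq <- function(params, amplicon, rna, kit, M, d, fragmented = FALSE) {
  stopifnot(inherits(params, "generative_params"), M > 0, d >= 1)
  if (!amplicon %in% rownames(params$alpha)) {
    stop("no parameters for amplicon '", amplicon, "'", call. = FALSE)
  }
  if (!rna %in% colnames(params$alpha)) {
    stop("no parameters for RNA '", rna, "'", call. = FALSE)
  }
  if (!kit %in% colnames(params$K) || !kit %in% names(params$beta)) {
    stop("no parameters for kit '", kit, "'", call. = FALSE)
  }
  surv <- if (fragmented) params$s[[amplicon]] else 1
  template <- params$alpha[amplicon, rna] * surv * M /
    (1 + M / params$K[amplicon, kit])
  if (!is.finite(template) || template <= 0) {
    stop("non-positive effective template for (", amplicon, ", ", rna, ", ",
         kit, ")", call. = FALSE)
  }
  params$beta[[kit]] - log(template / d) / log(1 + params$efficiency)
}

#' Closed-form RT-axis Cq2f under hyperbolic saturation
#'
#' For the adjacent dose pair (M, 2M) the model predicts
#' `Cq2f = 1 + log2((1 + M/K) / (1 + 2M/K))`: 1 when `K = Inf`, falling
#' towards 0 as `M/K` grows.
#'
#' @param M Lower dose of the pair (ng).
#' @param K Saturation constant (ng); `Inf` allowed.
#' @return Cq2f value in (0, 1].
#' @export
#' @examples
#' expected_cq2f_rt(300, Inf)  # 1
#' expected_cq2f_rt(300, 300)  # ~0.415
expected_cq2f_rt <- function(M, K) {
  stopifnot(all(M > 0), all(K > 0))
  n <- max(length(M), length(K))
  M <- rep_len(M, n)
  K <- rep_len(K, n)
  out <- 1 + log2((1 + M / K) / (1 + 2 * M / K))
  out[is.infinite(K)] <- 1
  out
}

#' Simulate a full titration experiment
#'
#' Generates one well per design slot with `Cq = expected_cq + N(0,
#' sigma^2)` noise, independent per well. Fragmented RNAs (by design
#' integrity) apply the amplicon survival factor. Control wells (RT0,
#' RT-) and any Cq beyond the 40-cycle detection horizon are emitted as
#' undetermined (`NA`). The same seed always produces the identical
#' table.
#'
#' @param design A [design_grid()].
#' @param params A [generative_params()] object covering every amplicon,
#'   RNA and kit in the design.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A validated Cq table (tibble).
#' @export
simulate_cq_table <- function(design, params, seed = params$seed) {
  stopifnot(inherits(design, "design_grid"),
            inherits(params, "generative_params"))
  for (a in design$amplicons$amplicon) {
    if (!a %in% rownames(params$alpha) || !a %in% rownames(params$K) ||
        !a %in% names(params$s)) {
      stop("params do not cover amplicon '", a, "'", call. = FALSE)
    }
  }
  for (r in design$rnas$rna) {
    if (!r %in% colnames(params$alpha)) {
      stop("params do not cover RNA '", r, "'", call. = FALSE)
    }
  }
  for (k in design$kits) {
    if (!k %in% colnames(params$K) || !k %in% names(params$beta)) {
      stop("params do not cover kit '", k, "'", call. = FALSE)
    }
  }
  wells <- enumerate_wells(design)
  fragmented <- stats::setNames(design$rnas$integrity == "fragmented",
                                design$rnas$rna)
  is_sample <- wells$role == "sample"
  mu <- rep(NA_real_, nrow(wells))
  idx <- which(is_sample)
  mu[idx] <- vapply(idx, function(i) {
    expected_cq(params, wells$amplicon[i], wells$rna[i], wells$kit[i],
                wells$rt_input_ng[i], wells$qpcr_dilution_level[i],
                fragmented = fragmented[[wells$rna[i]]])
  }, numeric(1))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  cq <- mu + stats::rnorm(nrow(wells), 0, params$sigma)
  cq[!is_sample] <- NA_real_
  cq[is.finite(cq) & cq > 40] <- NA_real_  # beyond the 40-cycle horizon
  if (any(is.finite(cq) & cq <= 0)) {
    stop("simulated Cq <= 0; parameters put template abundance beyond ",
         "the dynamic range of a 40-cycle run", call. = FALSE)
  }
  wells$cq <- cq
  validate_cq_table(wells[, cq_columns])
}

#' Fit the saturation constant from RT-axis Cq2f values
#'
#' Least-squares fit of [expected_cq2f_rt()] to observed RT-axis Cq2f
#' values for one amplicon x kit, over the lower doses of the pairs. The
#' fit is in `u = 1/K` (so "no saturation" is the interior-boundary value
#' `u = 0`); when the optimum lies at the boundary or the fitted `K`
#' exceeds `k_max`, `K = Inf` is reported with `saturation_detected =
#' FALSE`.
#'
#' @param pairs RT-axis pair records from [cq2f_pairs()] (or any data
#'   frame with columns `lo_input` and `cq2f`) for a single amplicon x
#'   kit.
#' @param k_max Largest K considered distinguishable from Inf (ng).
#' @return A list with `K`, `residual_norm` (RMS residual),
#'   `saturation_detected` and `n`.
#' @export
fit_saturation <- function(pairs, k_max = 1e6) {
  stopifnot(is.data.frame(pairs),
            all(c("lo_input", "cq2f") %in% names(pairs)))
  M <- pairs$lo_input
  y <- pairs$cq2f
  if (length(M) < 2 || length(unique(M)) < 2) {
    stop("need Cq2f observations at >= 2 distinct dose pairs", call. = FALSE)
  }
  sse <- function(u) sum((y - expected_cq2f_rt(M, 1 / u))^2)
  sse0 <- sum((y - 1)^2)
  # coarse log-spaced scan to bracket the optimum, then golden-section polish
  u_grid <- 10^seq(log10(1 / k_max), log10(100 / min(M)), length.out = 400)
  vals <- vapply(u_grid, sse, numeric(1))
  i <- which.min(vals)
  if (sse0 <= vals[i] + 1e-15) {
    return(list(K = Inf, residual_norm = sqrt(sse0 / length(y)),
                saturation_detected = FALSE, n = length(y)))
  }
  lower <- if (i == 1) 0 else u_grid[i - 1]
  upper <- if (i == length(u_grid)) u_grid[i] * 10 else u_grid[i + 1]
  opt <- stats::optimize(sse, c(lower, upper), tol = 1e-14)
  u_hat <- opt$minimum
  if (u_hat <= 1 / k_max || sse0 <= opt$objective) {
    return(list(K = Inf, residual_norm = sqrt(sse0 / length(y)),
                saturation_detected = FALSE, n = length(y)))
  }
  list(K = 1 / u_hat, residual_norm = sqrt(opt$objective / length(y)),
       saturation_detected = TRUE, n = length(y))
}
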