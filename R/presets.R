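preset_amplicons <- function() amplicon_registry()$amplicon
preset_rnas <- function() c("H", "T", "U", "Tf", "Hf", "Uf")
preset_kits <- function() {
  c("iScript", "Transcriptor", "SuperScript-IV", "SuperScript-II")
}

# Baseline Cq per amplicon at 600 ng, undiluted, no saturation: a rough
# abundance ladder from rRNA (very low Cq) down to intronic signal.
preset_base_cq <- function() {
  c("eEF1A1" = 15, "eEFint" = 28, "OAZ1" = 20, "MVP" = 26,
    "18S" = 8, "5.8S" = 14, "U1" = 20, "Alu" = 12)
}

#' Shipped simulator parameter presets
#'
#' Two presets covering both built-in designs:
#' * `ideal`: no RT saturation (`K = Inf`), neutral fragmentation
#'   survival (`s = 1`), perfect qPCR efficiency and zero noise — every
#'   titration axis responds with exactly 1 Cq per input doubling.
#' * `paperlike`: illustrative, hand-chosen (not fitted) saturation
#'   constants and survival factors that reproduce the qualitative
#'   failure modes seen in real nested titrations: kit-swapped
#'   saturation of 5.8S vs U1 (each kit linear-ish for one and saturated
#'   for the other, Alu moderately compressed under both), early
#'   saturation of MVP under iScript, strong fragmentation loss of
#'   eEF1A1/eEFint versus apparent protection of the structured U1, and
#'   replicate noise of 0.19 Cq.
#'
#' @param name `"ideal"` or `"paperlike"`.
#' @param seed Default seed stored in the parameters.
#' @return A [generative_params()] object covering every RNA, kit and
#'   amplicon of the built-in designs.
#' @export
#' @examples
#' preset_params("ideal")
preset_params <- function(name = c("ideal", "paperlike"), seed = 1L) {
  name <- match.arg(name)
  amps <- preset_amplicons()
  rnas <- preset_rnas()
  kits <- preset_kits()
  beta <- stats::setNames(c(36, 36.3, 35.8, 36.1), kits)
  base_cq <- preset_base_cq()
  alpha <- matrix(2^(beta[["iScript"]] - base_cq[amps]) / 600,
                  nrow = length(amps), ncol = length(rnas),
                  dimnames = list(amps, rnas))
  # one genuine biological difference: OAZ1 is 2-fold lower in T than H
  alpha["OAZ1", c("T", "Tf")] <- alpha["OAZ1", c("T", "Tf")] / 2

  if (name == "ideal") {
    K <- matrix(Inf, length(amps), length(kits), dimnames = list(amps, kits))
    s <- stats::setNames(rep(1, length(amps)), amps)
    return(generative_params(alpha, K, beta, s, efficiency = 1, sigma = 0,
                             seed = seed))
  }

  # Saturation constants (ng of total RNA at half-saturation), columns =
  # kits. Small K = early saturation; the 5.8S/U1 columns swap between
  # the first two kits.
  K <- rbind(
    #           iScript  Transcriptor  SS-IV  SS-II
    "eEF1A1" = c(221.6,   943.0,       150,   1359.3),
    "eEFint" = c(263.9,   329.7,       150,    943.0),
    "OAZ1"   = c(361.1,   415.4,       150,    943.0),
    "MVP"    = c( 57.6,   531.2,       150,    695.0),
    "18S"    = c(136.5,   170.5,       150,    531.2),
    "5.8S"   = c(170.5,    13.7,       150,     27.8),
    "U1"     = c( 27.8,   275.8,       150,     33.1),
    "Alu"    = c(415.4,   622.0,       150,    830.0)
  )
  dimnames(K) <- list(amps, kits)
  # Fragmentation survival: coding amplicons lose template (long exposed
  # transcripts fragment within the amplicon), the structured U1 snRNA
  # is protected and *gains* relative signal.
  s <- c("eEF1A1" = 0.25, "eEFint" = 0.31, "OAZ1" = 0.50, "MVP" = 0.52,
         "18S" = 0.60, "5.8S" = 0.70, "U1" = 1.60, "Alu" = 0.55)
  generative_params(alpha, K, beta, s[amps], efficiency = 1, sigma = 0.19,
                    seed = seed)
}

#' Read simulator parameters from a YAML config
#'
#' The config mirrors the [generative_params()] fields: `alpha` and `K`
#' as named row maps (amplicon -> named values), `beta` and `s` as named
#' maps, plus scalar `efficiency`, `sigma`, `seed`. A `preset:` key loads
#' a shipped preset instead.
#'
#' @param path YAML file path.
#' @return A [generative_params()] object.
#' @export
read_params <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$preset)) {
    return(preset_params(obj$preset,
                         seed = if (is.null(obj$seed)) 1L else obj$seed))
  }
  to_matrix <- function(rows) {
    cols <- names(rows[[1]])
    m <- do.call(rbind, lapply(rows, function(r) unlist(r)[cols]))
    dimnames(m) <- list(names(rows), cols)
    m
  }
  generative_params(
    alpha = to_matrix(obj$alpha),
    K = to_matrix(lapply(obj$K, function(r) {
      lapply(r, function(v) if (identical(v, "Inf") || identical(v, ".inf")) Inf else v)
    })),
    beta = unlist(obj$beta),
    s = unlist(obj$s),
    efficiency = if (is.null(obj$efficiency)) 1 else obj$efficiency,
    sigma = if (is.null(obj$sigma)) 0.19 else obj$sigma,
    seed = if (is.null(obj$seed)) 1L else obj$seed
  )
}

#' Write simulator parameters to a YAML config
#'
#' @param params A [generative_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "generative_params"))
  row_map <- function(m, inf_as_string = FALSE) {
    out <- lapply(rownames(m), function(a) {
      v <- as.list(m[a, ])
      if (inf_as_string) v <- lapply(v, function(x) if (is.infinite(x)) "Inf" else x)
      v
    })
    stats::setNames(out, rownames(m))
  }
  yaml::write_yaml(list(
    alpha = row_map(params$alpha),
    K = row_map(params$K, inf_as_string = TRUE),
    beta = as.list(params$beta),
    s = as.list(params$s),
    efficiency = params$efficiency,
    sigma = params$sigma,
    seed = params$seed
  ), path)
  invisible(path)
}
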