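#' Simulate a qPCR Ct table
#'
#' Generates cycle-threshold values carrying a log-copy-number signal:
#' `Ct(marker) = c0 - log_efficiency(copies) + Normal(0, noise_sd)`, with the
#' two single-copy reference genes ALS and CPS included at 1 copy. A marker
#' with 0 copies does not amplify and is recorded as `NA` (distinct from a
#' low copy number).
#'
#' @param copy_truth Named numeric vector of marker copy numbers (may be 0).
#' @param efficiency Per-cycle amplification factor in (1, 2]; 2 is perfect
#'   doubling.
#' @param noise_sd Gaussian noise on Ct, in cycles (>= 0).
#' @param seed Integer seed.
#' @param c0 Baseline Ct of a single-copy target (cycles).
#' @param sample_id Sample label.
#' @param replicates Number of technical replicates.
#' @return data.frame with `sample`, `replicate`, `marker`, `ct` (NA when the
#'   marker does not amplify).
#' @export
simulate_qpcr <- function(copy_truth, efficiency = 2, noise_sd = 0, seed = 1L,
                          c0 = 25, sample_id = "sample1", replicates = 1L) {
  if (any(copy_truth < 0)) stop("copy numbers must be >= 0")
  if (!(efficiency > 1 && efficiency <= 2))
    stop("efficiency must be in (1, 2]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(copy_truth)) || any(names(copy_truth) == ""))
    stop("copy_truth must be a named vector")
  copies <- c(ALS = 1, CPS = 1, copy_truth)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
      ct <- c0 - log(copies, base = efficiency) +
        rnorm(length(copies), 0, noise_sd)
      ct[copies == 0] <- NA_real_
      data.frame(sample = sample_id, replicate = rep,
                 marker = names(copies), ct = unname(ct),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
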