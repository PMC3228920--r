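#' Beta-galactosidase activity in Miller units
#'
#' Computed as `abs420 / (vol_ul * time_min * od600)`. The classical
#' convention multiplies by 1000; set `classic = TRUE` for that scaling.
#'
#' @param abs420 absorbance at 420 nm (vectorized).
#' @param vol_ul assay volume in microliters.
#' @param time_min incubation time in minutes.
#' @param od600 culture density.
#' @param classic multiply by 1000 (default FALSE).
#' @return Miller units.
#' @export
miller_units <- function(abs420, vol_ul, time_min, od600, classic = FALSE) {
  if (any(vol_ul <= 0) || any(time_min <= 0) || any(od600 <= 0)) {
    stop("vol_ul, time_min and od600 must be positive")
  }
  u <- abs420 / (vol_ul * time_min * od600)
  if (classic) u <- u * 1000
  u
}

#' Repression ratio of reporter activity with the repressor present vs absent
#'
#' The ratio of mean activities, repressed (wild type) over derepressed
#' (repressor deletion); ~1 means no repression, much less than 1 strong
#' repression. The standard deviation is first-order error propagation of
#' the two replicate SDs:
#' `sd = ratio * sqrt((sd_r/mean_r)^2 + (sd_d/mean_d)^2)`
#' (0 for a replicate group of size 1, and 0 when the repressed mean is 0).
#'
#' @param repressed,derepressed numeric vectors of replicate Miller units.
#' @return list with `ratio` and `sd`.
#' @export
repression_ratio <- function(repressed, derepressed) {
  if (length(repressed) < 1L || length(derepressed) < 1L) {
    stop("need at least one replicate per condition")
  }
  mr <- mean(repressed); md <- mean(derepressed)
  if (md == 0) stop("derepressed mean activity is zero")
  ratio <- mr / md
  sdr <- if (length(repressed) > 1L) stats::sd(repressed) else 0
  sdd <- if (length(derepressed) > 1L) stats::sd(derepressed) else 0
  sd <- if (mr == 0) 0 else abs(ratio) * sqrt((sdr / mr)^2 + (sdd / md)^2)
  list(ratio = ratio, sd = sd)
}

#' Repression ratios from a replicate measurement table
#'
#' @param df data.frame with columns `sample`, `condition`
#'   (`repressed`/`derepressed`), `abs420`, `vol_ul`, `time_min`, `od600`.
#' @param classic passed to [miller_units()].
#' @return data.frame with `sample`, `ratio`, `sd`.
#' @export
assay_table <- function(df, classic = FALSE) {
  need <- c("sample", "condition", "abs420", "vol_ul", "time_min", "od600")
  if (!all(need %in% names(df))) {
    stop("assay table needs columns ", paste(need, collapse = ", "))
  }
  df$units <- miller_units(df$abs420, df$vol_ul, df$time_min, df$od600,
                           classic = classic)
  res <- lapply(split(df, df$sample), function(s) {
    rr <- repression_ratio(s$units[s$condition == "repressed"],
                           s$units[s$condition == "derepressed"])
    data.frame(sample = s$sample[1L], ratio = rr$ratio, sd = rr$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
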