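#' Extract a site plus flanking context from its upstream region
#'
#' Operator boxes are under direct selection while flanking DNA drifts, so
#' conservation is judged on the site span extended by a short flank on each
#' side (default 8 bp), truncated at the region edges and never padded.
#'
#' @param region_seq the upstream-region sequence the site was called in.
#' @param site one row of a [call_sites()]/[scan_genome()] table (needs
#'   `region_start`, `region_end`, 0-based half-open).
#' @param flank flank width in bp (default 8).
#' @return DNA string.
#' @export
extract_site_context <- function(region_seq, site, flank = 8L) {
  lo <- max(0L, site$region_start - flank)
  hi <- min(nchar(region_seq), site$region_end + flank)
  substr(region_seq, lo + 1L, hi)
}

#' Ungapped percent identity between two DNA sequences
#'
#' Equal lengths: column-wise identity end to end. Unequal lengths: the
#' shorter sequence slides along the longer at every ungapped offset and the
#' best match count is used; the denominator is always the shorter length,
#' so edge-truncated contexts are not penalized.
#'
#' @param query,reference nonempty DNA strings.
#' @return percent identity in \[0, 100\].
#' @export
percent_identity <- function(query, reference) {
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("percent_identity: empty sequence")
  }
  a <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  ns <- length(a); nl <- length(b)
  best <- 0L
  for (off in 0:(nl - ns)) {
    best <- max(best, sum(a == b[(off + 1L):(off + ns)]))
  }
  100 * best / ns
}

#' Conservation tier from percent identity
#'
#' Strong conservation at >= 70% identity, weak at >= 60%, divergent below.
#'
#' @param identity percent identity in \[0, 100\].
#' @return factor with levels strong, weak, divergent.
#' @export
conservation_tier <- function(identity) {
  cut(identity, breaks = c(-Inf, 60, 70, Inf), right = FALSE,
      labels = c("divergent", "weak", "strong"))
}

#' Classify cross-species conservation of site regions against a reference
#'
#' @param contexts data.frame with columns `species_id`, `family`,
#'   `context` (site + flank sequence from [extract_site_context()]).
#' @param reference_species the species identities are measured against.
#' @return data.frame with one row per (species, family) pair of the input:
#'   `species_id`, `family`, `identity`, `tier` (`not_evaluable` when the
#'   reference lacks the family).
#' @export
classify_conservation <- function(contexts, reference_species) {
  ref <- contexts[contexts$species_id == reference_species, , drop = FALSE]
  refseq <- ref$context[match(contexts$family, ref$family)]
  identity <- rep(NA_real_, nrow(contexts))
  tier <- rep("not_evaluable", nrow(contexts))
  ok <- !is.na(refseq)
  identity[ok] <- mapply(percent_identity, contexts$context[ok], refseq[ok])
  tier[ok] <- as.character(conservation_tier(identity[ok]))
  data.frame(species_id = contexts$species_id, family = contexts$family,
             identity = identity, tier = tier, stringsAsFactors = FALSE)
}
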