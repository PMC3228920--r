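#' Score every 8-bp window of an upstream region and keep box hits
#'
#' All offsets `0 .. L-8` are scored against the matrix; windows scoring at
#' least `tau_box` are returned in offset order. Only the forward strand of
#' the (already strand-oriented) region is scanned: the symmetrized matrix
#' gives every window exactly the score of its reverse complement, so a
#' second pass would duplicate every hit.
#'
#' @param region an `upstream_region` (or any list with a `sequence` field),
#'   or a plain DNA string.
#' @param iwm an `iwm` object.
#' @param thresholds list from [scan_thresholds()].
#' @return data.frame with columns `offset` (0-based window start within the
#'   region), `sequence`, `score`.
#' @export
scan_boxes <- function(region, iwm, thresholds = scan_thresholds(iwm)) {
  seq <- if (is.character(region)) region else region$sequence
  L <- nchar(seq)
  empty <- data.frame(offset = integer(), sequence = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < 8L) return(empty)
  enc <- encode_dna(seq)
  full <- expand_bits(iwm)
  n <- L - 7L
  scores <- numeric(n)
  for (p in 1:8) scores <- scores + full[cbind(enc[p:(p + n - 1L)], p)]
  keep <- which(scores >= thresholds$tau_box)
  if (length(keep) == 0L) return(empty)
  data.frame(offset = keep - 1L,
             sequence = substring(seq, keep, keep + 7L),
             score = scores[keep], stringsAsFactors = FALSE)
}

#' Assemble tandem sites from box hits
#'
#' Hits are chained into maximal runs of abutting, in-phase boxes
#' (successive offsets differing by exactly 8 bp, or up to
#' `8 + spacing_tolerance`). A run of at least two boxes becomes a site call
#' iff its summed score reaches `tau_site`; single boxes are discarded
#' because functional repression needs two or more adjacent repressor
#' dimers. When two candidate runs overlap (out-of-phase), the run with the
#' higher total is kept, ties broken leftmost.
#'
#' @param hits data.frame from [scan_boxes()], sorted by offset.
#' @param thresholds list with `tau_site` (and `tau_box`, already applied).
#' @param spacing_tolerance extra bp allowed between consecutive box starts
#'   beyond the exact 8 (default 0).
#' @return data.frame with one row per site: `region_start`, `region_end`
#'   (0-based half-open span over all boxes), `n_boxes`, `box_offsets`,
#'   `box_seqs`, `box_scores` (comma-joined), `total_score`.
#' @export
call_sites <- function(hits, thresholds, spacing_tolerance = 0L) {
  empty <- data.frame(region_start = integer(), region_end = integer(),
                      n_boxes = integer(), box_offsets = character(),
                      box_seqs = character(), box_scores = character(),
                      total_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  if (is.unsorted(hits$offset, strictly = TRUE)) {
    stop("box hits must be sorted by strictly increasing offset")
  }
  # chain each hit to the nearest hit starting 8 .. 8+tolerance bp later;
  # an out-of-phase hit in between does not break the chain
  n <- nrow(hits)
  nxt <- rep(NA_integer_, n)
  has_pred <- logical(n)
  for (i in seq_len(n)) {
    ok <- which(hits$offset >= hits$offset[i] + 8L &
                hits$offset <= hits$offset[i] + 8L + spacing_tolerance &
                !has_pred)
    if (length(ok) > 0L) {
      nxt[i] <- ok[1L]
      has_pred[ok[1L]] <- TRUE
    }
  }
  runs <- lapply(which(!has_pred), function(s) {
    ix <- s
    while (!is.na(nxt[ix[length(ix)]])) ix <- c(ix, nxt[ix[length(ix)]])
    ix
  })
  cand <- lapply(runs, function(ix) {
    if (length(ix) < 2L) return(NULL)
    total <- sum(hits$score[ix])
    if (total < thresholds$tau_site) return(NULL)
    data.frame(
      region_start = hits$offset[ix[1L]],
      region_end = hits$offset[ix[length(ix)]] + 8L,
      n_boxes = length(ix),
      box_offsets = paste(hits$offset[ix], collapse = ","),
      box_seqs = paste(hits$sequence[ix], collapse = ","),
      box_scores = paste(sprintf("%.2f", hits$score[ix]), collapse = ","),
      total_score = total, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # resolve overlapping candidate runs: best total first, leftmost on ties
  cand <- cand[order(-cand$total_score, cand$region_start), , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    clash <- kept & cand$region_start < cand$region_end[i] &
      cand$region_end > cand$region_start[i]
    if (!any(clash)) kept[i] <- TRUE
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$region_start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Scan a whole genome's gene upstream regions for tandem metbox sites
#'
#' Runs [extract_upstream()], [scan_boxes()] and [call_sites()] for every
#' annotated gene and translates site spans to forward-strand genomic
#' coordinates. A physically identical genomic site reachable from two
#' divergently transcribed genes is reported once per gene, flagged
#' `shared = TRUE`.
#'
#' @param genome named character vector from [read_genome()].
#' @param genes data.frame from [read_annotations()].
#' @param iwm an `iwm` object.
#' @param thresholds list from [scan_thresholds()].
#' @param window upstream window length in bp (default 400).
#' @param spacing_tolerance passed to [call_sites()].
#' @return data.frame with one row per (gene, site): `gene_id`, `contig_id`,
#'   `strand`, `genomic_start`, `genomic_end` (1-based inclusive, forward
#'   strand), `region_start`, `region_end`, `n_boxes`, `box_offsets`,
#'   `box_seqs`, `box_scores`, `total_score`, `dist_to_start` (bp between
#'   site end and the start codon), `shared`.
#' @export
scan_genome <- function(genome, genes, iwm,
                        thresholds = scan_thresholds(iwm), window = 400L,
                        spacing_tolerance = 0L) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    region <- suppressWarnings(extract_upstream(genome, gene, window))
    sites <- call_sites(scan_boxes(region, iwm, thresholds), thresholds,
                        spacing_tolerance)
    if (nrow(sites) == 0L) next
    g <- t(mapply(function(rs, re) region_to_genomic(region, rs, re),
                  sites$region_start, sites$region_end))
    out[[i]] <- data.frame(
      gene_id = gene$gene_id, contig_id = gene$contig_id,
      strand = gene$strand,
      genomic_start = unname(g[, 1L]), genomic_end = unname(g[, 2L]),
      sites,
      dist_to_start = nchar(region$sequence) - sites$region_end,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), contig_id = character(),
                      strand = character(), genomic_start = integer(),
                      genomic_end = integer(), region_start = integer(),
                      region_end = integer(), n_boxes = integer(),
                      box_offsets = character(), box_seqs = character(),
                      box_scores = character(), total_score = numeric(),
                      dist_to_start = integer(), shared = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(out$contig_id, out$genomic_start, out$genomic_end)
  out$shared <- key %in% key[duplicated(key)]
  rownames(out) <- NULL
  out
}

#' Write site calls to BED6 / detailed TSV
#'
#' BED uses 0-based half-open coordinates, name = gene_id and
#' score = total bits x 10, rounded. The TSV keeps 1-based inclusive
#' coordinates and the per-box detail.
#'
#' @param sites data.frame from [scan_genome()].
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$contig_id, sites$genomic_start - 1L,
                    sites$genomic_end, sites$gene_id,
                    round(sites$total_score * 10), sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
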