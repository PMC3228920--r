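# Base alphabet used throughout: A,C,G,T plus N (index 5).
DNA_BASES <- c("A", "C", "G", "T")
# complement index: A<->T, C<->G, N->N
COMP_IDX <- c(4L, 3L, 2L, 1L, 5L)

encode_dna <- function(x) {
  i <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
  i[is.na(i)] <- 5L
  i
}

decode_dna <- function(i) paste(c(DNA_BASES, "N")[i], collapse = "")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper; `N` maps to `N`.
#'
#' @param x a character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split 8-bp boxes into symmetrized 4-bp half-sites
#'
#' A metbox is bound by a repressor homodimer, so its two halves are related
#' by reverse complementation. Each 8-bp box therefore contributes two
#' half-sites to the matrix: its first four bases, and the reverse complement
#' of its last four bases.
#'
#' @param boxes character vector of 8-base DNA words (A/C/G/T only).
#' @return character vector of 4-base half-sites, length `2 * length(boxes)`,
#'   ordered first-halves then second-halves per box (interleaved by box).
#' @export
#' @examples
#' symmetrize_boxes("AGACGTCT")  # perfect palindrome: both halves "AGAC"
symmetrize_boxes <- function(boxes) {
  if (length(boxes) == 0L) return(character())
  boxes <- toupper(boxes)
  bad <- nchar(boxes) != 8L | grepl("[^ACGT]", boxes)
  if (any(bad)) {
    stop("boxes must be 8 bp of A/C/G/T; offending box(es): ",
         paste(boxes[bad], collapse = ", "))
  }
  first <- substr(boxes, 1L, 4L)
  second <- revcomp(substr(boxes, 5L, 8L))
  as.vector(rbind(first, second))
}

#' Build an information weight matrix from half-sites or a counts table
#'
#' Tallies base counts per half-site position and converts them to
#' information weights \eqn{R_{iw}(b, l) = \mu + \log_2 f(b, l)}, where
#' \eqn{f(b, l)} is the count of base \eqn{b} at position \eqn{l} divided by
#' the total number of half-sites \eqn{N}. Any zero count is replaced by
#' `pseudocount` before taking frequencies; the denominator stays \eqn{N}.
#' With `mu_bits = 2` (the default, \eqn{\log_2 4}) a uniformly distributed
#' position scores 0 bits.
#'
#' @param half_sites character vector of 4-base half-sites; ignored when
#'   `counts` is given.
#' @param counts optional 4x4 integer matrix (rows A,C,G,T; columns half-site
#'   positions 1-4) with equal column sums.
#' @param mu_bits additive constant \eqn{\mu} in bits (default 2).
#' @param pseudocount replacement for zero counts (default 1).
#' @return an object of class `iwm` with elements `counts`, `n_observations`,
#'   `mu_bits`, `pseudocount`, `bits` (4x4 weight matrix in bits).
#' @export
build_iwm <- function(half_sites = NULL, counts = NULL, mu_bits = 2,
                      pseudocount = 1) {
  if (is.null(counts)) {
    if (is.null(half_sites) || length(half_sites) == 0L) {
      stop("no half-sites and no counts supplied (n_observations = 0)")
    }
    half_sites <- toupper(half_sites)
    bad <- nchar(half_sites) != 4L | grepl("[^ACGT]", half_sites)
    if (any(bad)) stop("half-sites must be 4 bp of A/C/G/T")
    m <- do.call(rbind, strsplit(half_sites, "", fixed = TRUE))
    counts <- sapply(1:4, function(p) {
      tabulate(match(m[, p], DNA_BASES), nbins = 4L)
    })
    dimnames(counts) <- list(DNA_BASES, NULL)
  } else {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(4L, 4L))) stop("counts must be 4x4")
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
    if (length(unique(colSums(counts))) != 1L) {
      stop("counts columns must have equal sums")
    }
    rownames(counts) <- DNA_BASES
  }
  n_obs <- sum(counts[, 1L])
  if (n_obs == 0L) stop("n_observations = 0")
  adj <- counts
  adj[adj == 0L] <- pseudocount
  bits <- mu_bits + log2(adj / n_obs)
  dimnames(bits) <- dimnames(counts)
  structure(list(counts = counts, n_observations = n_obs,
                 mu_bits = mu_bits, pseudocount = pseudocount, bits = bits),
            class = "iwm")
}

#' @export
print.iwm <- function(x, ...) {
  cat("Information weight matrix (", x$n_observations, " half-sites, mu = ",
      x$mu_bits, " bits, pseudocount = ", x$pseudocount, ")\n", sep = "")
  cat("Counts:\n"); print(x$counts)
  cat("Weights (bits):\n"); print(round(x$bits, 2))
  cat("Consensus:", iwm_consensus(x), "; full-site score",
      round(consensus_score(x), 2), "bits\n")
  invisible(x)
}

#' Per-position base frequencies of a matrix
#'
#' Zero counts are pseudocount-adjusted as in [build_iwm()], then columns are
#' renormalized to sum to one. Used both by the synthetic-site sampler and as
#' the metric space for matrix-recovery comparisons.
#'
#' @param iwm an `iwm` object.
#' @return 4x4 matrix of frequencies, columns summing to 1.
#' @export
iwm_frequencies <- function(iwm) {
  adj <- iwm$counts
  adj[adj == 0L] <- iwm$pseudocount
  sweep(adj, 2, colSums(adj), "/")
}

# 5x8 full-site weight table: columns 1-4 are the half matrix, columns 5-8
# mirror the complemented base at position 9-p (palindromic pairing); row 5
# scores N as the worst weight in its column (conservative, never wildcard).
expand_bits <- function(iwm) {
  b <- iwm$bits
  full <- matrix(0, nrow = 5L, ncol = 8L)
  full[1:4, 1:4] <- b
  for (p in 5:8) full[1:4, p] <- b[COMP_IDX[1:4], 9L - p]
  full[5L, ] <- apply(full[1:4, , drop = FALSE], 2, min)
  full
}

#' Consensus sequence of the matrix (highest-weight base per position)
#' @param iwm an `iwm` object.
#' @return the 8-bp consensus word.
#' @export
iwm_consensus <- function(iwm) {
  half <- apply(iwm$bits, 2, which.max)
  decode_dna(c(half, COMP_IDX[rev(half)]))
}

#' Bit score of the consensus (best possible) full site
#'
#' Twice the sum over half-site positions of the maximal base weight; by
#' construction this equals the maximum of [score_window()] over all
#' \eqn{4^8} windows.
#'
#' @param iwm an `iwm` object.
#' @return score in bits.
#' @export
consensus_score <- function(iwm) {
  2 * sum(apply(iwm$bits, 2, max))
}

#' Default scan thresholds derived from the consensus score
#'
#' A single box must score at least one quarter of the consensus full-site
#' score; a whole (multi-box) site must score at least the consensus score.
#'
#' @param iwm an `iwm` object.
#' @param tau_box,tau_site optional overrides in bits.
#' @return list with `tau_box` and `tau_site`.
#' @export
scan_thresholds <- function(iwm, tau_box = NULL, tau_site = NULL) {
  cs <- consensus_score(iwm)
  list(tau_box = if (is.null(tau_box)) cs / 4 else tau_box,
       tau_site = if (is.null(tau_site)) cs else tau_site)
}

#' Score 8-bp windows against the matrix
#'
#' The score of a window is the sum over its eight positions of the weight of
#' the observed base; positions 5-8 use the half-matrix weight of the
#' complemented base at the mirrored position, so scores are exactly
#' strand-symmetric: `score_window(m, w) == score_window(m, revcomp(w))`.
#' `N` scores the most negative weight at its position.
#'
#' @param iwm an `iwm` object.
#' @param windows character vector of 8-base words (A/C/G/T/N).
#' @return numeric vector of scores in bits.
#' @export
score_window <- function(iwm, windows) {
  if (any(nchar(windows) != 8L)) stop("windows must be 8 bp")
  full <- expand_bits(iwm)
  vapply(windows, function(w) {
    idx <- encode_dna(w)
    sum(full[cbind(idx, 1:8)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read / write a matrix as TSV
#'
#' The TSV mirrors the matrix layout: rows A,C,G,T, columns
#' `count_1..count_4` and (on write) `bits_1..bits_4` for half-site positions
#' 1(8) to 4(5). Reading uses the count columns and rebuilds the weights.
#'
#' @param path file path.
#' @param mu_bits,pseudocount passed to [build_iwm()].
#' @return for `read_iwm`, an `iwm` object.
#' @export
read_iwm <- function(path, mu_bits = 2, pseudocount = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("base", paste0("count_", 1:4)) %in% names(df))) {
    stop("matrix TSV needs columns base, count_1..count_4")
  }
  cnt <- as.matrix(df[match(DNA_BASES, df$base), paste0("count_", 1:4)])
  dimnames(cnt) <- list(DNA_BASES, NULL)
  build_iwm(counts = cnt, mu_bits = mu_bits, pseudocount = pseudocount)
}

#' @rdname read_iwm
#' @param iwm an `iwm` object to serialize.
#' @export
write_iwm <- function(iwm, path) {
  df <- data.frame(base = DNA_BASES, iwm$counts, round(iwm$bits, 2))
  names(df) <- c("base", paste0("count_", 1:4), paste0("bits_", 1:4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The MetJ metbox matrix bundled with the package
#'
#' Base counts over 832 pooled gammaproteobacterial half-metboxes, the final
#' matrix of the two-stage bootstrap; the package's default matrix for
#' scanning and for planting synthetic sites.
#'
#' @param mu_bits,pseudocount passed to [build_iwm()].
#' @return an `iwm` object.
#' @export
metj_matrix <- function(mu_bits = 2, pseudocount = 1) {
  read_iwm(system.file("extdata", "metj_iwm_counts.tsv", package = "metboxr"),
           mu_bits = mu_bits, pseudocount = pseudocount)
}
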