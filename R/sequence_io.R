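#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased; any character outside A/C/G/T (including IUPAC
#' ambiguity codes) becomes `N`. Gzipped files are handled transparently.
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate contig identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Read gene annotations from GFF3 or a tab-separated gene table
#'
#' GFF3 (`.gff`/`.gff3`, optionally gzipped) is parsed with
#' `rtracklayer::import` and filtered to `CDS`/`gene` features. The TSV
#' alternative has columns `contig_id`, `strand`, `start`, `end`, `gene_id`
#' and optionally `name`, `product`. Coordinates are 1-based inclusive in
#' both formats.
#'
#' @param path annotation file.
#' @return data.frame with columns `gene_id`, `contig_id`, `strand`,
#'   `start`, `end`, `name`, `product`, sorted by contig then start.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
    if (length(gr) == 0L) stop("no CDS/gene features in ", path)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    if (all(is.na(ids)) && !is.null(gr$locus_tag)) ids <- gr$locus_tag
    if (all(is.na(ids))) ids <- paste0("gene_", seq_along(gr))
    df <- data.frame(
      gene_id = ids,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_,
      product = if (!is.null(gr$product)) as.character(gr$product)
                else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig_id", "strand", "start", "end", "gene_id")
    if (!all(need %in% names(df))) {
      stop("gene table needs columns ", paste(need, collapse = ", "))
    }
    if (is.null(df$name)) df$name <- NA_character_
    if (is.null(df$product)) df$product <- NA_character_
    df <- df[, c("gene_id", "contig_id", "strand", "start", "end",
                 "name", "product")]
  }
  validate_genes(df, path)
}

validate_genes <- function(df, src = "gene table") {
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop(src, ": unknown strand at record ", which(bad_strand)[1L],
         " ('", df$strand[which(bad_strand)[1L]], "')")
  }
  bad_coord <- df$start > df$end | df$start < 1L
  if (any(bad_coord)) {
    stop(src, ": start > end (or start < 1) at record ",
         which(bad_coord)[1L])
  }
  if (anyDuplicated(df$gene_id)) {
    stop(src, ": duplicate gene_id ",
         df$gene_id[duplicated(df$gene_id)][1L])
  }
  df[order(df$contig_id, df$start), , drop = FALSE]
}

#' Extract the upstream region of a gene
#'
#' For a plus-strand gene the window is the forward-strand slice
#' `[start - window, start - 1]`; for a minus-strand gene it is the reverse
#' complement of `[end + 1, end + window]`. Windows are truncated at contig
#' boundaries, never padded, and are deliberately NOT clipped at neighboring
#' genes (annotation may be wrong; real shared operators between divergent
#' gene pairs must stay visible from both genes). In the returned sequence
#' position 1 is the base farthest from the start codon and the last base
#' abuts it.
#'
#' @param genome named character vector from [read_genome()].
#' @param gene one-row data.frame (or list) with `gene_id`, `contig_id`,
#'   `strand`, `start`, `end`.
#' @param window window length in bp (default 400).
#' @return list of class `upstream_region` with `gene_id`, `contig_id`,
#'   `strand`, `sequence`, and forward-strand 1-based inclusive
#'   `genomic_start`, `genomic_end` (`genomic_end = genomic_start - 1` for an
#'   empty window).
#' @export
extract_upstream <- function(genome, gene, window = 400L) {
  if (!gene$contig_id %in% names(genome)) {
    stop("contig not in genome: ", gene$contig_id)
  }
  contig <- genome[[gene$contig_id]]
  L <- nchar(contig)
  if (gene$strand == "+") {
    gs <- max(1L, gene$start - window)
    ge <- gene$start - 1L
  } else {
    gs <- gene$end + 1L
    ge <- min(L, gene$end + window)
  }
  if (ge < gs) {
    warning("zero-length upstream window for gene ", gene$gene_id)
    seq <- ""
    gs <- if (gene$strand == "+") gene$start else gene$end + 1L
    ge <- gs - 1L
  } else {
    seq <- substr(contig, gs, ge)
    if (gene$strand == "-") seq <- revcomp(seq)
  }
  structure(list(gene_id = gene$gene_id, contig_id = gene$contig_id,
                 strand = gene$strand, sequence = seq,
                 genomic_start = gs, genomic_end = ge),
            class = "upstream_region")
}

# Map a 0-based half-open offset interval inside an upstream region back to
# forward-strand 1-based inclusive genomic coordinates.
region_to_genomic <- function(region, rs, re) {
  if (region$strand == "+") {
    c(start = region$genomic_start + rs, end = region$genomic_start + re - 1L)
  } else {
    c(start = region$genomic_end - re + 1L, end = region$genomic_end - rs)
  }
}
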