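#' Configuration for the synthetic cohort generator
#'
#' The generator emulates what the genome-wide scan consumes: bacterial
#' contigs of i.i.d. background composition, annotated genes on both strands,
#' and tandem arrays of 8-bp boxes planted in upstream windows with known
#' coordinates. `fidelity` is the per-base probability of drawing from the
#' matrix frequency model instead of uniform; planted sites sit so that the
#' distance from site end to the start codon is binomially distributed with
#' mode ~75 bp (the typical operator placement), or uniform over feasible
#' offsets when `site_offset = "uniform"`.
#'
#' @param n_species number of species.
#' @param genes_per_species genes per (single-contig) species genome.
#' @param upstream_len upstream window length in bp (default 400).
#' @param gc_fraction background GC content.
#' @param boxes_per_site k, number of abutting boxes per planted site
#'   (>= 2).
#' @param planting_fraction fraction of genes receiving a planted site.
#' @param fidelity per-base probability of sampling from matrix frequencies.
#' @param site_offset `"near_start"` (default, mode ~75 bp from the start
#'   codon) or `"uniform"`.
#' @param gene_len gene body length in bp.
#' @param seed RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 5L, genes_per_species = 50L,
                             upstream_len = 400L, gc_fraction = 0.5,
                             boxes_per_site = 2L, planting_fraction = 0.5,
                             fidelity = 1.0, site_offset = "near_start",
                             gene_len = 120L, seed = 1L) {
  stopifnot(boxes_per_site >= 2L, boxes_per_site <= 5L,
            gc_fraction >= 0, gc_fraction <= 1,
            planting_fraction >= 0, planting_fraction <= 1,
            fidelity >= 0, fidelity <= 1)
  if (upstream_len < 8L * boxes_per_site) {
    stop("upstream_len must be >= 8 * boxes_per_site")
  }
  structure(list(n_species = n_species,
                 genes_per_species = genes_per_species,
                 upstream_len = upstream_len, gc_fraction = gc_fraction,
                 boxes_per_site = boxes_per_site,
                 planting_fraction = planting_fraction,
                 fidelity = fidelity, site_offset = site_offset,
                 gene_len = gene_len, seed = seed),
            class = "synthetic_config")
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Sample 8-bp boxes from a matrix frequency model
#'
#' Each half-site position is drawn from the matrix's per-position base
#' frequencies with probability `fidelity`, else uniformly; the second half
#' of the box is the reverse complement of an independently drawn half-site,
#' so the palindromic statistics of the matrix are preserved. At fidelity 1
#' the modal draw is the consensus box.
#'
#' @param iwm an `iwm` object.
#' @param fidelity per-base probability in \[0, 1\].
#' @param n number of boxes.
#' @return character vector of 8-bp words.
#' @export
sample_box <- function(iwm, fidelity = 1.0, n = 1L) {
  freq <- iwm_frequencies(iwm)
  draw_half <- function() {
    vapply(1:4, function(p) {
      if (stats::runif(1) < fidelity) {
        sample.int(4L, 1L, prob = freq[, p])
      } else sample.int(4L, 1L)
    }, integer(1))
  }
  vapply(seq_len(n), function(i) {
    h1 <- draw_half()
    h2 <- draw_half()
    decode_dna(c(h1, COMP_IDX[rev(h2)]))
  }, character(1))
}

#' Generate a synthetic multi-species cohort with planted sites
#'
#' Each species is one contig of tiled gene units (alternating strands);
#' planted genes receive `boxes_per_site` abutting boxes from [sample_box()]
#' in their upstream window. Species are assigned one per genus by default
#' and cycled through five order labels; gene `j` of every species belongs
#' to ortholog family `fam<j>`, giving a complete ortholog map. The truth
#' table records, per planted site, the gene, forward-strand genomic
#' coordinates, box sequences (in upstream orientation), and the realized
#' per-box/total scores under the planting matrix.
#'
#' @param config a [synthetic_config()].
#' @param iwm planting matrix (default [metj_matrix()]).
#' @return list with `genomes` (named list of named character vectors),
#'   `genes` (named list of annotation data.frames), `species` (data.frame
#'   `species_id`, `genus`, `order_label`), `ortholog_map` (data.frame
#'   `species_id`, `gene_id`, `family`), `truth` (data.frame), `config`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            iwm = metj_matrix()) {
  set.seed(config$seed)
  orders <- c("Ent", "Pas", "Vib", "Aer", "Alt")
  up <- config$upstream_len
  gl <- config$gene_len
  unit <- up + gl
  k <- config$boxes_per_site
  sl <- 8L * k
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(config$n_species)),
    genus = sprintf("genus%02d", seq_len(config$n_species)),
    order_label = orders[(seq_len(config$n_species) - 1L) %% 5L + 1L],
    stringsAsFactors = FALSE)
  genomes <- list(); genes <- list(); truth <- list(); map <- list()
  for (s in seq_len(config$n_species)) {
    sp <- species$species_id[s]
    ng <- config$genes_per_species
    n_plant <- round(config$planting_fraction * ng)
    planted <- sort(sample.int(ng, n_plant))
    units <- character(ng)
    gdf <- data.frame(gene_id = sprintf("%s_g%03d", sp, seq_len(ng)),
                      contig_id = paste0(sp, "_c1"),
                      strand = ifelse(seq_len(ng) %% 2L == 1L, "+", "-"),
                      start = NA_integer_, end = NA_integer_,
                      name = NA_character_, product = NA_character_,
                      stringsAsFactors = FALSE)
    for (g in seq_len(ng)) {
      u0 <- (g - 1L) * unit  # 0-based unit start on the contig
      up_seq <- random_dna(up, config$gc_fraction)
      body <- random_dna(gl, config$gc_fraction)
      if (g %in% planted) {
        boxes <- sample_box(iwm, config$fidelity, n = k)
        d <- plant_distance(config, sl)
        rs <- up - d - sl  # 0-based offset of site start in oriented window
        substr(up_seq, rs + 1L, rs + sl) <- paste(boxes, collapse = "")
        scores <- score_window(iwm, boxes)
        truth[[length(truth) + 1L]] <- data.frame(
          species_id = sp, gene_id = gdf$gene_id[g],
          contig_id = gdf$contig_id[g], strand = gdf$strand[g],
          region_start = rs, region_end = rs + sl,
          unit0 = u0, n_boxes = k,
          box_seqs = paste(boxes, collapse = ","),
          box_scores = paste(sprintf("%.4f", scores), collapse = ","),
          total_score = sum(scores), stringsAsFactors = FALSE)
      }
      if (gdf$strand[g] == "+") {
        units[g] <- paste0(up_seq, body)
        gdf$start[g] <- u0 + up + 1L
        gdf$end[g] <- u0 + unit
      } else {
        units[g] <- paste0(body, revcomp(up_seq))
        gdf$start[g] <- u0 + 1L
        gdf$end[g] <- u0 + gl
      }
    }
    contig <- paste(units, collapse = "")
    genomes[[sp]] <- stats::setNames(contig, paste0(sp, "_c1"))
    genes[[sp]] <- gdf
    map[[s]] <- data.frame(species_id = sp, gene_id = gdf$gene_id,
                           family = sprintf("fam%03d", seq_len(ng)),
                           stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species_id = character(), gene_id = character(),
               contig_id = character(), strand = character(),
               region_start = integer(), region_end = integer(),
               unit0 = integer(), n_boxes = integer(),
               box_seqs = character(), box_scores = character(),
               total_score = numeric(), stringsAsFactors = FALSE)
  # forward-strand genomic coordinates of planted sites
  if (nrow(truth) > 0L) {
    plus <- truth$strand == "+"
    truth$genomic_start <- ifelse(
      plus, truth$unit0 + truth$region_start + 1L,
      truth$unit0 + gl + (up - truth$region_end) + 1L)
    truth$genomic_end <- truth$genomic_start + (truth$region_end -
      truth$region_start) - 1L
    truth$unit0 <- NULL
  } else truth$genomic_start <- truth$genomic_end <- integer()
  list(genomes = genomes, genes = genes, species = species,
       ortholog_map = do.call(rbind, map), truth = truth, config = config)
}

plant_distance <- function(config, site_len) {
  dmax <- config$upstream_len - site_len
  if (identical(config$site_offset, "uniform")) {
    sample.int(dmax + 1L, 1L) - 1L
  } else {
    # bounded, mode ~75 bp from the start codon
    min(dmax, 8L + stats::rbinom(1L, 134L, 0.5))
  }
}

#' A divergent gene pair sharing one planted site
#'
#' Two genes transcribed away from each other with a single tandem
#' consensus-box site in the shared intergenic region; the truth table lists
#' both gene associations for the same genomic span. Used to exercise the
#' shared-site flag.
#'
#' @param iwm planting matrix.
#' @param intergenic length of the shared region (default 200, >= 16).
#' @return list with `genome`, `genes`, `truth`.
#' @export
divergent_pair_fixture <- function(iwm = metj_matrix(), intergenic = 200L) {
  cons <- iwm_consensus(iwm)
  site <- paste0(cons, cons)
  mid <- random_dna(intergenic)
  rs <- (intergenic - 16L) %/% 2L
  substr(mid, rs + 1L, rs + 16L) <- site
  ga <- random_dna(60L); gb <- random_dna(60L)
  contig <- paste0(ga, mid, gb)
  genes <- data.frame(
    gene_id = c("gA", "gB"), contig_id = "c1", strand = c("-", "+"),
    start = c(1L, 60L + intergenic + 1L),
    end = c(60L, 60L + intergenic + 60L),
    name = NA_character_, product = NA_character_, stringsAsFactors = FALSE)
  gstart <- 60L + rs + 1L
  truth <- data.frame(
    gene_id = c("gA", "gB"), contig_id = "c1",
    genomic_start = gstart, genomic_end = gstart + 15L,
    box_seqs = paste(cons, cons, sep = ","),
    total_score = 2 * consensus_score(iwm),  # two consensus boxes
    stringsAsFactors = FALSE)
  list(genome = stats::setNames(contig, "c1"), genes = genes, truth = truth)
}

#' Scan every species of a cohort
#'
#' @param cohort from [generate_cohort()].
#' @param iwm scan matrix.
#' @param thresholds from [scan_thresholds()].
#' @param spacing_tolerance passed through.
#' @return [scan_genome()] table with a `species_id` column.
#' @export
scan_cohort <- function(cohort, iwm, thresholds = scan_thresholds(iwm),
                        spacing_tolerance = 0L) {
  out <- lapply(cohort$species$species_id, function(sp) {
    s <- scan_genome(cohort$genomes[[sp]], cohort$genes[[sp]], iwm,
                     thresholds, window = cohort$config$upstream_len,
                     spacing_tolerance = spacing_tolerance)
    if (nrow(s)) cbind(species_id = sp, s, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(species_id = character(),
                                      gene_id = character(),
                                      genomic_start = integer(),
                                      genomic_end = integer(),
                                      total_score = numeric(),
                                      stringsAsFactors = FALSE)
  out
}

#' Recovery of planted sites by a scan
#'
#' A truth site is *detectable* when every planted box meets `tau_box` and
#' the total meets `tau_site`; no scanner can recover a sub-threshold
#' planting, so `recall` (the scanner-correctness number) is computed over
#' detectable sites, while `recall_all` divides by all plantings and
#' reflects the statistical power of the threshold rule at the planting
#' fidelity. Recovery requires the exact gene and exact genomic span.
#'
#' @param sites from [scan_cohort()].
#' @param truth the cohort's truth table.
#' @param thresholds the thresholds used for the scan.
#' @return list with `recall`, `recall_all`, `n_truth`, `n_detectable`,
#'   `n_recovered`, `n_false_positive` (called sites matching no planting).
#' @export
evaluate_recovery <- function(sites, truth, thresholds) {
  box_scores <- lapply(strsplit(truth$box_scores, ","), as.numeric)
  detectable <- vapply(box_scores, function(s) all(s >= thresholds$tau_box),
                       logical(1)) & truth$total_score >= thresholds$tau_site
  tkey <- paste(truth$species_id, truth$gene_id, truth$genomic_start,
                truth$genomic_end)
  skey <- paste(sites$species_id, sites$gene_id, sites$genomic_start,
                sites$genomic_end)
  recovered <- tkey %in% skey
  list(recall = if (any(detectable)) mean(recovered[detectable]) else NA_real_,
       recall_all = if (nrow(truth)) mean(recovered) else NA_real_,
       n_truth = nrow(truth), n_detectable = sum(detectable),
       n_recovered = sum(recovered),
       n_false_positive = sum(!skey %in% tkey))
}

#' Write a cohort to disk as FASTA + TSV + BED truth + JSON sidecar
#'
#' @param cohort from [generate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in cohort$species$species_id) {
    ss <- Biostrings::DNAStringSet(cohort$genomes[[sp]])
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(sp, ".fa")))
    utils::write.table(cohort$genes[[sp]],
                       file.path(dir, paste0(sp, "_genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$species, file.path(dir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$ortholog_map,
                     file.path(dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cohort$truth)) {
    bed <- data.frame(cohort$truth$contig_id,
                      cohort$truth$genomic_start - 1L,
                      cohort$truth$genomic_end,
                      paste(cohort$truth$species_id, cohort$truth$gene_id,
                            sep = ":"),
                      round(cohort$truth$total_score * 10),
                      cohort$truth$strand)
    utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `genomes`, `genes`, `species`, `ortholog_map`, `truth`
#'   (if present) and `config`.
#' @export
read_cohort <- function(dir) {
  species <- utils::read.delim(file.path(dir, "species.tsv"),
                               stringsAsFactors = FALSE)
  genomes <- list(); genes <- list()
  for (sp in species$species_id) {
    genomes[[sp]] <- read_genome(file.path(dir, paste0(sp, ".fa")))
    genes[[sp]] <- read_annotations(file.path(dir, paste0(sp, "_genes.tsv")))
  }
  cfgf <- file.path(dir, "config.json")
  config <- if (file.exists(cfgf)) jsonlite::read_json(cfgf,
    simplifyVector = TRUE) else list(upstream_len = 400L)
  tf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tf)) utils::read.delim(tf,
    stringsAsFactors = FALSE) else NULL
  list(genomes = genomes, genes = genes, species = species,
       ortholog_map = utils::read.delim(file.path(dir, "ortholog_map.tsv"),
                                        stringsAsFactors = FALSE),
       truth = truth, config = config)
}
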