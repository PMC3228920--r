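#' Pick one representative species per genus
#'
#' Genera differ wildly in how many sequenced members they have; pooling
#' binding sites from every species would overweight the densely sequenced
#' genera, so matrix refinement queries one species per genus.
#'
#' @param species data.frame with `species_id` and `genus`.
#' @param policy `"lexicographic"` (deterministic default: smallest
#'   `species_id` wins within each genus).
#' @return subset of `species`, one row per genus, ordered by genus.
#' @export
select_representatives <- function(species, policy = "lexicographic") {
  if (nrow(species) == 0L) return(species)
  if (!identical(policy, "lexicographic")) {
    stop("unknown representative policy: ", policy)
  }
  picks <- vapply(split(species$species_id, species$genus),
                  function(x) sort(x)[1L], character(1))
  out <- species[match(picks, species$species_id), , drop = FALSE]
  out[order(out$genus), , drop = FALSE]
}

#' Collect half-sites from a preliminary scan of candidate operators
#'
#' The seed matrix (built from experimentally known operators) is scanned,
#' with its own consensus-derived thresholds, over the upstream regions of
#' genes already believed to belong to the regulon; every box inside every
#' passing tandem site is decomposed into its two symmetrized half-sites and
#' pooled. These high-confidence half-sites are the raw material for the
#' refined final matrix.
#'
#' @param seed_iwm the seed `iwm`.
#' @param regions list of `upstream_region` objects (or DNA strings).
#' @param thresholds defaults to the seed matrix's own thresholds.
#' @param spacing_tolerance passed to [call_sites()].
#' @return character vector of 4-bp half-sites.
#' @export
preliminary_collect <- function(seed_iwm, regions,
                                thresholds = scan_thresholds(seed_iwm),
                                spacing_tolerance = 0L) {
  boxes <- unlist(lapply(regions, function(r) {
    sites <- call_sites(scan_boxes(r, seed_iwm, thresholds), thresholds,
                        spacing_tolerance)
    if (nrow(sites) == 0L) return(character())
    unlist(strsplit(sites$box_seqs, ","))
  }))
  if (length(boxes) == 0L) {
    stop("preliminary scan found no passing sites; cannot build final matrix")
  }
  symmetrize_boxes(boxes)
}

#' Two-stage bootstrap discovery of the regulon
#'
#' Stage 1 builds the seed matrix from known boxes; stage 2 scans candidate
#' operators in one representative species per genus and pools the
#' half-sites of passing sites; stage 3 builds the final matrix from that
#' pool; stage 4 scans every gene of every species with the final matrix's
#' thresholds; stage 5 tallies regulon membership per family and order.
#' Fully deterministic given its inputs.
#'
#' @param seed_boxes character vector of known 8-bp boxes.
#' @param cohort list with `genomes`, `genes`, `species`, `ortholog_map`
#'   (as produced by [generate_cohort()] or [read_cohort()]).
#' @param config optional list: `window` (default 400 or the cohort's
#'   upstream length), `mu_bits`, `pseudocount`, `spacing_tolerance`,
#'   `candidate_families` (default: every family in the ortholog map),
#'   `representative_policy`, `tau_box`/`tau_site` overrides for stage 4.
#' @return list with `seed_matrix`, `final_matrix`, `half_site_pool`,
#'   `sites` (stage-4 calls with `species_id`), `summary`
#'   (a [summarize_regulon()] table), and `log` (per-stage counts).
#' @export
discover <- function(seed_boxes, cohort, config = list()) {
  cfg <- utils::modifyList(list(
    window = if (!is.null(cohort$config$upstream_len))
      cohort$config$upstream_len else 400L,
    mu_bits = 2, pseudocount = 1, spacing_tolerance = 0L,
    candidate_families = unique(cohort$ortholog_map$family),
    representative_policy = "lexicographic",
    tau_box = NULL, tau_site = NULL), config)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("discover stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed_iwm <- stage("seed_matrix", build_iwm(symmetrize_boxes(seed_boxes),
    mu_bits = cfg$mu_bits, pseudocount = cfg$pseudocount))
  log$seed_boxes <- length(seed_boxes)

  reps <- stage("representatives",
                select_representatives(cohort$species,
                                       cfg$representative_policy))
  cand <- cohort$ortholog_map[
    cohort$ortholog_map$family %in% cfg$candidate_families &
    cohort$ortholog_map$species_id %in% reps$species_id, , drop = FALSE]
  regions <- stage("candidate_regions", lapply(seq_len(nrow(cand)),
    function(i) {
      sp <- cand$species_id[i]
      gene <- cohort$genes[[sp]][
        cohort$genes[[sp]]$gene_id == cand$gene_id[i], ]
      suppressWarnings(extract_upstream(cohort$genomes[[sp]], gene,
                                        cfg$window))
    }))
  log$representatives <- nrow(reps)
  log$candidate_regions <- length(regions)

  pool <- stage("preliminary_collect",
                preliminary_collect(seed_iwm, regions,
                  spacing_tolerance = cfg$spacing_tolerance))
  log$half_sites_pooled <- length(pool)

  final_iwm <- stage("final_matrix", build_iwm(pool, mu_bits = cfg$mu_bits,
    pseudocount = cfg$pseudocount))
  thr <- scan_thresholds(final_iwm, tau_box = cfg$tau_box,
                         tau_site = cfg$tau_site)

  sites <- stage("genome_scan",
                 scan_cohort(cohort, final_iwm, thr,
                             spacing_tolerance = cfg$spacing_tolerance))
  log$sites_called <- nrow(sites)

  summary <- stage("summarize",
                   summarize_regulon(sites, cohort$ortholog_map,
                                     cohort$species))
  list(seed_matrix = seed_iwm, final_matrix = final_iwm,
       half_site_pool = pool, sites = sites, thresholds = thr,
       summary = summary, log = log)
}

#' Regulon membership counts per gene family and taxonomic order
#'
#' For each family and order: how many species of the order carry the gene
#' at all (from the ortholog map), and how many of those carry at least one
#' called tandem site upstream of it.
#'
#' @param sites site table with `species_id` and `gene_id` (e.g. from
#'   [scan_cohort()] or `discover()$sites`).
#' @param ortholog_map data.frame `species_id`, `gene_id`, `family`.
#' @param species data.frame `species_id`, `order_label`.
#' @return data.frame `family`, `order_label`, `species_with_gene`,
#'   `species_with_metboxes`. Genes with sites but no family are tallied as
#'   family `"unassigned"` with a warning.
#' @export
summarize_regulon <- function(sites, ortholog_map, species) {
  map <- ortholog_map
  skey <- paste(sites$species_id, sites$gene_id)
  mkey <- paste(map$species_id, map$gene_id)
  miss <- !skey %in% mkey
  if (any(miss)) {
    warning(sum(miss), " site gene(s) missing from the ortholog map; ",
            "tallied as family 'unassigned'")
    map <- rbind(map, data.frame(species_id = sites$species_id[miss],
                                 gene_id = sites$gene_id[miss],
                                 family = "unassigned",
                                 stringsAsFactors = FALSE))
    mkey <- paste(map$species_id, map$gene_id)
  }
  map$order_label <- species$order_label[match(map$species_id,
                                               species$species_id)]
  map$has_site <- mkey %in% skey
  grp <- split(map, list(map$family, map$order_label), drop = TRUE)
  agg <- do.call(rbind, lapply(grp, function(g) {
    data.frame(family = g$family[1L], order_label = g$order_label[1L],
               species_with_gene = length(unique(g$species_id)),
               species_with_metboxes = length(unique(
                 g$species_id[g$has_site])),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$family, agg$order_label), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
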