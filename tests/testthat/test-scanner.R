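m_thr <- function() {
  m <- metj_matrix()
  list(m = m, thr = scan_thresholds(m))
}

test_that("scan_boxes scores every offset and keeps threshold passers", {
  x <- m_thr()
  h <- scan_boxes("TTTTAGACGTCTTTTT", x$m, x$thr)
  expect_equal(h$offset, 4L)
  expect_equal(h$sequence, "AGACGTCT")
  expect_equal(round(h$score, 2), 12.58)

  expect_equal(nrow(scan_boxes(strrep("A", 50), x$m, x$thr)), 0L)
  expect_equal(nrow(scan_boxes("TTTTTTT", x$m, x$thr)), 0L)
})

test_that("call_sites chains abutting boxes and enforces both thresholds", {
  x <- m_thr()
  h <- scan_boxes("TTTTAGACGTCTAGACGTCTTTTT", x$m, x$thr)
  expect_equal(h$offset, c(4L, 12L))
  s <- call_sites(h, x$thr)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$region_start, s$region_end), c(4L, 20L))
  expect_equal(s$n_boxes, 2L)
  expect_equal(round(s$total_score, 2), 25.17)

  # a single box is never a site
  one <- data.frame(offset = 4L, sequence = "AGACGTCT",
                    score = 12.58, stringsAsFactors = FALSE)
  expect_equal(nrow(call_sites(one, x$thr)), 0L)

  # adjacency passes but the summed score fails tau_site
  weak <- data.frame(offset = c(4L, 12L), sequence = "NNNNNNNN",
                     score = c(3.2, 3.3), stringsAsFactors = FALSE)
  expect_equal(nrow(call_sites(weak, x$thr)), 0L)

  expect_error(call_sites(weak[c(2, 1), ], x$thr), "sorted")
})

test_that("in-phase boxes chain across an intervening out-of-phase hit", {
  x <- m_thr()
  h <- data.frame(offset = c(4L, 9L, 12L), sequence = "AGACGTCT",
                  score = c(10, 4, 10), stringsAsFactors = FALSE)
  s <- call_sites(h, x$thr)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$region_start, s$region_end), c(4L, 20L))
  expect_equal(s$total_score, 20)
})

test_that("overlapping out-of-phase runs keep the higher total, ties left", {
  thr <- list(tau_box = 0, tau_site = 10)
  h <- data.frame(offset = c(0L, 4L, 8L, 12L), sequence = "AGACGTCT",
                  score = c(6, 7, 6, 7), stringsAsFactors = FALSE)
  s <- call_sites(h, thr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$region_start, 4L)  # 14 > 12
  h2 <- data.frame(offset = c(0L, 4L, 8L, 12L), sequence = "AGACGTCT",
                   score = 6, stringsAsFactors = FALSE)
  s2 <- call_sites(h2, thr)
  expect_equal(s2$region_start, 0L)  # tie broken leftmost
})

test_that("spacing tolerance admits slightly separated boxes", {
  thr <- list(tau_box = 0, tau_site = 10)
  h <- data.frame(offset = c(0L, 10L), sequence = "AGACGTCT",
                  score = c(8, 8), stringsAsFactors = FALSE)
  expect_equal(nrow(call_sites(h, thr)), 0L)
  expect_equal(nrow(call_sites(h, thr, spacing_tolerance = 2L)), 1L)
})

test_that("scan_boxes agrees with the naive rescan oracle", {
  x <- m_thr()
  set.seed(31)
  for (i in seq_len(30)) {
    region <- random_region(400)
    got <- scan_boxes(region, x$m, x$thr)
    scores <- vapply(1:393, function(o) {
      oracle_score(substr(region, o, o + 7L), x$m)
    }, numeric(1))
    keep <- which(scores >= x$thr$tau_box)
    expect_equal(got$offset, keep - 1L)
    expect_equal(got$score, scores[keep], tolerance = 1e-12)
  }
})

test_that("scanning the reverse complement mirrors hits exactly", {
  x <- m_thr()
  set.seed(32)
  for (i in seq_len(20)) {
    region <- random_region(200)
    # plant one consensus pair so there is something to find
    substr(region, 51, 66) <- strrep(iwm_consensus(x$m), 2)
    fwd <- scan_boxes(region, x$m, x$thr)
    rev <- scan_boxes(revcomp(region), x$m, x$thr)
    expect_equal(sort(200L - 8L - rev$offset), sort(fwd$offset))
    expect_equal(sort(rev$score), sort(fwd$score), tolerance = 1e-12)
  }
})

test_that("raising either threshold never increases the site count", {
  x <- m_thr()
  set.seed(33)
  region <- paste0(random_region(60), strrep(iwm_consensus(x$m), 3),
                   random_region(60), strrep(iwm_consensus(x$m), 2),
                   random_region(40))
  base_hits <- scan_boxes(region, x$m, list(tau_box = 0, tau_site = 0))
  n_sites <- function(tb, ts) {
    thr <- list(tau_box = tb, tau_site = ts)
    nrow(call_sites(scan_boxes(region, x$m, thr), thr))
  }
  prev <- Inf
  for (tb in c(-5, 0, 3.15, 6, 13)) {
    cur <- n_sites(tb, 12.58)
    expect_lte(cur, prev)
    prev <- cur
  }
  prev <- Inf
  for (ts in c(0, 12.58, 25, 38, 60)) {
    cur <- n_sites(3.15, ts)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("scan_genome attributes planted sites to the right gene", {
  x <- m_thr()
  set.seed(34)
  co <- generate_cohort(synthetic_config(n_species = 1L,
                                         genes_per_species = 6L,
                                         planting_fraction = 0.5,
                                         seed = 7L))
  sp <- co$species$species_id[1]
  sites <- scan_genome(co$genomes[[sp]], co$genes[[sp]], metj_matrix())
  expect_true(all(c("genomic_start", "genomic_end", "dist_to_start",
                    "shared") %in% names(sites)))
  # every truth site that clears both thresholds must be called for its gene
  thr <- x$thr
  bs <- lapply(strsplit(co$truth$box_scores, ","), as.numeric)
  det <- vapply(bs, function(s) all(s >= thr$tau_box), logical(1)) &
    co$truth$total_score >= thr$tau_site
  for (i in which(det)) {
    hit <- sites[sites$gene_id == co$truth$gene_id[i] &
                 sites$genomic_start <= co$truth$genomic_start[i] &
                 sites$genomic_end >= co$truth$genomic_end[i], ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("a shared intergenic site is reported once per divergent gene", {
  set.seed(35)
  fx <- divergent_pair_fixture()
  sites <- scan_genome(fx$genome, fx$genes, metj_matrix())
  both <- sites[sites$genomic_start == fx$truth$genomic_start[1], ]
  expect_setequal(both$gene_id, c("gA", "gB"))
  expect_true(all(both$shared))
  expect_equal(unique(both$genomic_end), fx$truth$genomic_end[1])
})

test_that("site writers emit BED6 and detailed TSV", {
  set.seed(36)
  fx <- divergent_pair_fixture()
  sites <- scan_genome(fx$genome, fx$genes, metj_matrix())
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sites_bed(sites, bed)
  write_sites_tsv(sites, tsv)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(ncol(b), 6L)
  expect_equal(b$V2, sites$genomic_start - 1L)  # 0-based half-open
  expect_equal(b$V3, sites$genomic_end)
  t <- utils::read.delim(tsv)
  expect_equal(t$total_score, sites$total_score, tolerance = 1e-6)
})
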