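test_that("select_representatives keeps one lexicographic pick per genus", {
  sp <- data.frame(species_id = c("b_sp", "a_sp", "c_sp"),
                   genus = c("G1", "G1", "G2"),
                   order_label = "Ent", stringsAsFactors = FALSE)
  reps <- select_representatives(sp)
  expect_equal(reps$species_id, c("a_sp", "c_sp"))
  expect_equal(nrow(select_representatives(sp[0, ])), 0L)
  expect_error(select_representatives(sp, policy = "random"), "policy")
})

test_that("preliminary_collect pools two half-sites per box of each site", {
  m <- metj_matrix()
  cons <- iwm_consensus(m)
  # deterministic low-scoring background so exactly the planted pair passes
  regions <- replicate(10, paste0(strrep("C", 40), strrep(cons, 2),
                                  strrep("C", 64)))
  pool <- preliminary_collect(m, as.list(regions))
  expect_length(pool, 40L)  # 10 regions x 2 boxes x 2 halves
  expect_true(all(nchar(pool) == 4L))

  set.seed(41)
  bg <- replicate(5, random_region(120))
  expect_error(preliminary_collect(m, as.list(bg)), "no passing sites")
})

small_cohort <- function(seed = 42L, n_species = 3L, genes = 15L,
                         fidelity = 1.0) {
  generate_cohort(synthetic_config(n_species = n_species,
                                   genes_per_species = genes,
                                   planting_fraction = 0.4,
                                   fidelity = fidelity, seed = seed))
}

seed_boxes_from <- function(m, n = 40L) sample_box(m, 1.0, n = n)

test_that("discover runs all five stages and reports per-stage counts", {
  m <- metj_matrix()
  set.seed(43)
  co <- small_cohort()
  res <- discover(seed_boxes_from(m), co)
  expect_s3_class(res$final_matrix, "iwm")
  expect_equal(res$log$seed_boxes, 40L)
  expect_equal(res$log$representatives, 3L)
  expect_equal(res$log$half_sites_pooled, length(res$half_site_pool))
  expect_gt(res$log$sites_called, 0L)
  expect_true(all(c("family", "order_label", "species_with_gene",
                    "species_with_metboxes") %in% names(res$summary)))
  expect_true(all(res$summary$species_with_metboxes <=
                  res$summary$species_with_gene))
  # stage errors carry the stage name
  expect_error(discover(seed_boxes_from(m),
    within(co, genomes <- lapply(genomes, function(g) {
      chartr("ACGT", "TTTT", g)
    }))), "preliminary_collect")
})

test_that("discover is deterministic given identical inputs", {
  m <- metj_matrix()
  set.seed(44)
  co <- small_cohort()
  seeds <- seed_boxes_from(m)
  r1 <- discover(seeds, co)
  r2 <- discover(seeds, co)
  expect_identical(r1$final_matrix$counts, r2$final_matrix$counts)
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$summary, r2$summary)
})

test_that("duplicating a species within a genus leaves the pool unchanged", {
  m <- metj_matrix()
  set.seed(45)
  co <- small_cohort()
  seeds <- seed_boxes_from(m)
  p1 <- discover(seeds, co)$half_site_pool

  co2 <- co
  sp1 <- co$species$species_id[1]
  dup <- "zz_dup"
  co2$species <- rbind(co2$species,
                       data.frame(species_id = dup,
                                  genus = co$species$genus[1],
                                  order_label = co$species$order_label[1]))
  co2$genomes[[dup]] <- stats::setNames(unname(co$genomes[[sp1]]),
                                        paste0(dup, "_c1"))
  g <- co$genes[[sp1]]
  g$contig_id <- paste0(dup, "_c1")
  g$gene_id <- sub(sp1, dup, g$gene_id)
  co2$genes[[dup]] <- g
  co2$ortholog_map <- rbind(co2$ortholog_map,
    data.frame(species_id = dup, gene_id = g$gene_id,
               family = co$ortholog_map$family[
                 co$ortholog_map$species_id == sp1]))
  p2 <- discover(seeds, co2)$half_site_pool
  expect_identical(sort(p1), sort(p2))
})

test_that("bootstrap from a corrupted seed moves toward the truth matrix", {
  m <- metj_matrix()
  f_true <- iwm_frequencies(m)
  set.seed(46)
  improved <- vapply(seq_len(5), function(rep) {
    co <- small_cohort(seed = 460L + rep)
    seeds <- sample_box(m, 1.0, n = 48L)
    corrupt <- sample.int(48L, 10L)  # ~20% randomized
    seeds[corrupt] <- vapply(corrupt, function(i) random_region(8),
                             character(1))
    res <- discover(seeds, co)
    err_seed <- max(abs(iwm_frequencies(res$seed_matrix) - f_true))
    err_final <- max(abs(iwm_frequencies(res$final_matrix) - f_true))
    err_final < err_seed
  }, logical(1))
  expect_gte(mean(improved), 0.8)
})

test_that("summarize_regulon tallies species with gene vs with sites", {
  species <- data.frame(species_id = c("s1", "s2"), genus = c("g1", "g2"),
                        order_label = "Ent", stringsAsFactors = FALSE)
  map <- data.frame(species_id = c("s1", "s2"),
                    gene_id = c("s1_gA", "s2_gA"),
                    family = "metA", stringsAsFactors = FALSE)
  sites <- data.frame(species_id = "s1", gene_id = "s1_gA",
                      stringsAsFactors = FALSE)
  sm <- summarize_regulon(sites, map, species)
  expect_equal(sm$species_with_gene, 2L)
  expect_equal(sm$species_with_metboxes, 1L)

  # a site on a gene missing from the map lands in 'unassigned'
  orphan <- data.frame(species_id = "s2", gene_id = "s2_gX",
                       stringsAsFactors = FALSE)
  expect_warning(sm2 <- summarize_regulon(rbind(sites, orphan), map,
                                          species), "unassigned")
  expect_true("unassigned" %in% sm2$family)
})

test_that("summary counts match the generator's truth bookkeeping", {
  m <- metj_matrix()
  thr <- scan_thresholds(m)
  set.seed(47)
  co <- small_cohort(seed = 48L)
  sites <- scan_cohort(co, m, thr)
  sm <- summarize_regulon(sites, co$ortholog_map, co$species)
  # per family/order, the count of species with called sites can never
  # exceed the species carrying the gene, and matches a direct tally
  fam_of <- function(sp, gid) co$ortholog_map$family[
    co$ortholog_map$species_id == sp & co$ortholog_map$gene_id == gid]
  direct <- table(vapply(seq_len(nrow(sites)), function(i) {
    paste(fam_of(sites$species_id[i], sites$gene_id[i]),
          co$species$order_label[co$species$species_id ==
                                 sites$species_id[i]])
  }, character(1)))
  for (key in names(direct)) {
    parts <- strsplit(key, " ")[[1]]
    row <- sm[sm$family == parts[1] & sm$order_label == parts[2], ]
    expect_gte(row$species_with_metboxes, 1L)
  }
})
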