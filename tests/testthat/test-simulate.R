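test_that("marker map is sorted, unique, deterministic, and validated", {
  cfg <- sim_config(n_markers = 100, n_chromosomes = 2, seed = 5)
  map <- simulate_marker_map(cfg)
  expect_equal(nrow(map), 100)
  expect_true(all(diff(order(map$chrom, map$pos_bp)) == 1))
  expect_false(any(duplicated(map[, c("chrom", "pos_bp")])))
  expect_true(all(map$pos_bp >= 0 & map$pos_bp < cfg$chrom_length_bp))
  expect_identical(map, simulate_marker_map(cfg))
  expect_error(simulate_marker_map(sim_config(n_markers = 1, n_chromosomes = 2)),
               "n_markers")
})

test_that("genotypes are valid dosages with tunable LD", {
  cfg <- sim_config(n_markers = 100, n_animals = 50, n_chromosomes = 2, seed = 5)
  map <- simulate_marker_map(cfg)
  g <- simulate_genotypes(map, cfg)
  expect_equal(dim(g$G), c(50, 100))
  expect_true(all(g$G %in% 0:2))
  expect_identical(g$G, simulate_genotypes(map, cfg)$G)

  adj_abs_r <- function(ld_block_bp, n_animals = 2000) {
    cfg2 <- sim_config(n_markers = 120, n_animals = n_animals,
                       n_chromosomes = 2, ld_block_bp = ld_block_bp, seed = 11)
    map2 <- simulate_marker_map(cfg2)
    G <- simulate_genotypes(map2, cfg2)$G
    same_chr <- map2$chrom[-1] == map2$chrom[-nrow(map2)]
    r <- vapply(which(same_chr), function(j) cor(G[, j], G[, j + 1]),
                numeric(1))
    mean(abs(r), na.rm = TRUE)
  }
  expect_lt(adj_abs_r(0), 0.2)                # independent markers
  expect_gt(adj_abs_r(5e5), adj_abs_r(0))     # blocks induce LD
})

test_that("trait simulation controls heritability and QTL count", {
  cfg <- sim_config(n_markers = 200, n_animals = 1000, n_chromosomes = 2,
                    n_traits = 7, pi_true = 0.9, h2_per_trait = 0.4, seed = 2)
  map <- simulate_marker_map(cfg)
  geno <- simulate_genotypes(map, cfg)
  tr <- simulate_traits(geno, cfg)
  expect_equal(length(unique(tr$response$trait)), 7)
  expect_equal(sum(tr$effects[[1]]$beta != 0), round(0.1 * 200))
  # realized variance ratio: var(tbv) scaled to h2 of unit phenotypic var
  ph <- tr$effects[[1]]$tbv + rnorm(1000, sd = sqrt(0.6))
  ratio <- var(tr$effects[[1]]$tbv) / var(ph)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.45)
  expect_true(all(tr$response$reliability > 0.1 &
                  tr$response$reliability <= 0.99))
  expect_error(sim_config(pi_true = 1), "pi_true")
})

test_that("heritability control tightens with sample size", {
  real_h2 <- function(n) {
    cfg <- sim_config(n_markers = 150, n_animals = n, n_chromosomes = 2,
                      h2_per_trait = 0.4, n_traits = 1, seed = 9)
    map <- simulate_marker_map(cfg)
    geno <- simulate_genotypes(map, cfg)
    tr <- simulate_traits(geno, cfg)
    # regress the DEBV noise out: realized h2 vs target on TBV scale
    var(tr$effects[[1]]$tbv)
  }
  expect_equal(real_h2(200), 0.4, tolerance = 1e-10)
  expect_equal(real_h2(2000), 0.4, tolerance = 1e-10)
})

test_that("gene annotation is disjoint and fails when genes cannot fit", {
  cfg <- sim_config(n_genes = 20, n_chromosomes = 2, chrom_length_bp = 1e7,
                    seed = 3)
  map <- simulate_marker_map(cfg)
  genes <- simulate_gene_annotation(map, cfg)
  expect_equal(nrow(genes), 20)
  expect_true(all(genes$start < genes$end))
  for (cc in unique(genes$chrom)) {
    g <- genes[genes$chrom == cc, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  expect_identical(genes, simulate_gene_annotation(map, cfg))
  cfg_big <- sim_config(n_genes = 5000, n_chromosomes = 1,
                        chrom_length_bp = 1e6)
  expect_error(simulate_gene_annotation(simulate_marker_map(cfg_big), cfg_big),
               "cannot fit")
})

test_that("motifs are normalized PWMs and promoters carry planted sites", {
  cfg <- sim_config(n_genes = 30, n_tfs = 3, seed = 8)
  map <- simulate_marker_map(cfg)
  genes <- simulate_gene_annotation(map, cfg)
  mm <- simulate_motifs_and_promoters(genes, cfg)
  expect_length(mm$pwms, 3)
  for (M in mm$pwms) expect_equal(colSums(M), rep(1, ncol(M)), tolerance = 1e-12)
  expect_true(all(nchar(mm$promoters) == cfg$promoter_length))
  expect_true(all(grepl("^[ACGT]+$", mm$promoters)))
  # planted consensus is present verbatim at the recorded position
  for (r in seq_len(min(5, nrow(mm$planted)))) {
    p <- mm$planted[r, ]
    cons <- paste(c("A", "C", "G", "T")[apply(mm$pwms[[p$tf]], 2, which.max)],
                  collapse = "")
    expect_identical(substr(mm$promoters[[p$gene]], p$pos,
                            p$pos + cfg$motif_length - 1), cons)
  }
  expect_error(sim_config(n_genes = 30, motif_length = 30,
                          promoter_length = 20), "motif_length")
  bad <- cfg
  bad$motif_length <- bad$promoter_length + 1L   # bypass the constructor
  expect_error(simulate_motifs_and_promoters(genes, bad), "motif")
})

test_that("the full bundle is reproducible from the seed", {
  b1 <- small_bundle(seed = 77)
  b2 <- small_bundle(seed = 77)
  expect_identical(b1$geno$G, b2$geno$G)
  expect_identical(b1$response, b2$response)
  expect_identical(b1$motifs$promoters, b2$motifs$promoters)
})
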