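#' Simulation configuration
#'
#' Bundles every parameter of the data simulator and validates it. Defaults
#' describe a desk-scale analogue of a dense-SNP pig GWAS: a multi-chromosome
#' genome, LD-structured genotypes, a point-mass mixture of QTL effects
#' (fraction `pi_true` of markers with zero effect), seven traits with the
#' heritabilities typical of growth, production and reproduction traits, and
#' promoters carrying planted transcription-factor binding sites.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_markers total number of SNP markers across the genome.
#' @param n_animals number of genotyped animals.
#' @param n_traits number of traits.
#' @param pi_true fraction of markers with zero true effect, in (0,1).
#' @param h2_per_trait per-trait heritability, each in (0,1); recycled to
#'   `n_traits`.
#' @param ld_block_bp length of an LD block in bp; markers within a block
#'   share a latent haplotype signal. `0` makes markers independent.
#' @param maf_range interval within (0, 0.5] from which per-marker allele
#'   frequencies are drawn.
#' @param n_genes number of annotated genes.
#' @param n_tfs number of transcription factors (taken from the gene set).
#' @param motif_length PWM length in bp.
#' @param promoter_length promoter (upstream flank) length in bp.
#' @param seed integer RNG seed; the same config reproduces identical data.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       chrom_length_bp = 2e7,
                       n_markers = 1500L,
                       n_animals = 300L,
                       n_traits = 7L,
                       pi_true = 0.99,
                       h2_per_trait = c(0.36, 0.42, 0.35, 0.42, 0.11, 0.10, 0.08),
                       ld_block_bp = 5e5,
                       maf_range = c(0.05, 0.5),
                       n_genes = 150L,
                       n_tfs = 8L,
                       motif_length = 8L,
                       promoter_length = 2000L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_markers = as.integer(n_markers),
    n_animals = as.integer(n_animals),
    n_traits = as.integer(n_traits),
    pi_true = pi_true,
    h2_per_trait = rep_len(h2_per_trait, n_traits),
    ld_block_bp = as.numeric(ld_block_bp),
    maf_range = maf_range,
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    motif_length = as.integer(motif_length),
    promoter_length = as.integer(promoter_length),
    seed = as.integer(seed)
  )
  counts <- c("n_chromosomes", "n_markers", "n_animals", "n_traits",
              "n_genes", "n_tfs", "motif_length", "promoter_length")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("sim_config: '", nm, "' must be a positive count")
  }
  if (cfg$chrom_length_bp <= 0) stop("sim_config: chrom_length_bp must be positive")
  if (cfg$ld_block_bp < 0) stop("sim_config: ld_block_bp must be >= 0")
  if (!(cfg$pi_true > 0 && cfg$pi_true < 1))
    stop("sim_config: pi_true must lie in (0,1)")
  if (any(cfg$h2_per_trait <= 0 | cfg$h2_per_trait >= 1))
    stop("sim_config: every h2 must lie in (0,1)")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("sim_config: maf_range must be an ordered interval within (0, 0.5]")
  if (cfg$motif_length >= cfg$promoter_length)
    stop("sim_config: motif_length must be smaller than promoter_length")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a marker map
#'
#' Places `n_markers` SNPs uniformly at random on `n_chromosomes` chromosomes
#' of equal length, at least one marker per chromosome, with unique positions
#' within a chromosome, sorted by (chromosome, position).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `marker_id`, `chrom` (integer), `pos_bp`.
#' @export
simulate_marker_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_markers < cfg$n_chromosomes)
    stop("simulate_marker_map: need at least one marker per chromosome ",
         "(n_markers < n_chromosomes)")
  set.seed(cfg$seed + 101L)
  base <- cfg$n_markers %/% cfg$n_chromosomes
  per_chrom <- rep(base, cfg$n_chromosomes)
  extra <- cfg$n_markers - base * cfg$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(seq_len(cfg$n_chromosomes), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(cfg$chrom_length_bp, k, replace = FALSE)) - 1
  }))
  map <- data.frame(
    marker_id = sprintf("SNP%05d", seq_len(cfg$n_markers)),
    chrom = chrom,
    pos_bp = as.numeric(pos),
    stringsAsFactors = FALSE
  )
  map
}

#' Simulate LD-structured genotype dosages
#'
#' Generates 0/1/2 allele dosages. Each marker has an allele frequency drawn
#' uniformly from `maf_range`. Markers falling in the same `ld_block_bp`
#' window of a chromosome share a latent per-gamete haplotype indicator: the
#' allele is drawn from an elevated frequency when the latent indicator is 1
#' and a depressed one when it is 0, which gives adjacent markers within a
#' block positive dosage correlation while preserving the marginal allele
#' frequency. `ld_block_bp = 0` gives independent markers.
#'
#' @param map marker map from [simulate_marker_map()].
#' @param cfg a [sim_config()].
#' @return list with `G` (n_animals x n_markers integer matrix, columns named
#'   by marker id), `allele_freq`, and `animal_id`.
#' @export
simulate_genotypes <- function(map, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(map) > 0)
  set.seed(cfg$seed + 202L)
  m <- nrow(map)
  n <- cfg$n_animals
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # block index: unique per (chrom, floor(pos/ld_block_bp)); 0 => no blocks
  if (cfg$ld_block_bp > 0) {
    block <- paste(map$chrom, floor(map$pos_bp / cfg$ld_block_bp), sep = "_")
  } else {
    block <- as.character(seq_len(m))
  }
  block <- match(block, unique(block))
  n_block <- max(block)
  # mixture frequencies: marginal stays p, latent split controls LD strength
  d <- 0.9 * pmin(p, 1 - p)
  q1 <- p + d
  q0 <- p - d
  G <- matrix(0L, n, m)
  for (gamete in 1:2) {
    z_block <- matrix(runif(n * n_block) < 0.5, n, n_block)
    z <- z_block[, block, drop = FALSE]
    freq <- matrix(rep(q0, each = n), n, m)
    freq[z] <- rep(q1, each = n)[z]
    G <- G + (matrix(runif(n * m), n, m) < freq)
  }
  storage.mode(G) <- "integer"
  colnames(G) <- map$marker_id
  animal_id <- sprintf("A%05d", seq_len(n))
  rownames(G) <- animal_id
  list(G = G, allele_freq = p, animal_id = animal_id)
}

#' Simulate trait architectures and deregressed responses
#'
#' For each trait, draws a QTL set of size `round((1 - pi_true) * n_markers)`
#' with standard-normal effects, scales effects so the true breeding values
#' explain `h2` of a unit phenotypic variance, and builds a deregressed
#' EBV-style response: true breeding value plus noise whose variance is
#' consistent with a per-animal reliability drawn uniformly in (0.1, 0.99].
#'
#' @param geno output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `effects` (list per trait: `beta`, `qtl_idx`, `tbv`),
#'   and `response`, a long-format data.frame
#'   (`animal_id`, `trait`, `debv`, `reliability`).
#' @export
simulate_traits <- function(geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(geno$G) > 0)
  if (any(cfg$h2_per_trait <= 0 | cfg$h2_per_trait >= 1))
    stop("simulate_traits: h2 must lie in (0,1)")
  if (cfg$pi_true >= 1) stop("simulate_traits: pi_true must be < 1")
  set.seed(cfg$seed + 303L)
  G <- geno$G
  n <- nrow(G); m <- ncol(G)
  Zc <- scale(G, center = TRUE, scale = FALSE)
  n_qtl <- max(1L, round((1 - cfg$pi_true) * m))
  trait_names <- default_trait_names(cfg$n_traits)
  effects <- vector("list", cfg$n_traits)
  names(effects) <- trait_names
  resp <- vector("list", cfg$n_traits)
  for (t in seq_len(cfg$n_traits)) {
    h2 <- cfg$h2_per_trait[t]
    qtl <- sort(sample.int(m, n_qtl))
    beta <- numeric(m)
    beta[qtl] <- rnorm(n_qtl)
    tbv0 <- as.vector(Zc %*% beta)
    s <- sqrt(h2 / var(tbv0))
    beta <- beta * s
    tbv <- tbv0 * s                       # var(tbv) == h2 exactly
    rel <- runif(n, 0.1, 0.99)
    debv <- tbv + rnorm(n, sd = sqrt(var(tbv) * (1 - rel) / rel))
    effects[[t]] <- list(beta = beta, qtl_idx = qtl, tbv = tbv)
    resp[[t]] <- data.frame(
      animal_id = geno$animal_id,
      trait = trait_names[t],
      debv = debv,
      reliability = rel,
      stringsAsFactors = FALSE
    )
  }
  list(effects = effects, response = do.call(rbind, resp))
}

default_trait_names <- function(k) {
  base <- c("BFAT", "ADG", "DAYS", "PCL", "LTTNB", "LTNBA", "WEI")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, sprintf("TRAIT%02d", seq_len(k - length(base))))
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping gene intervals across the genome,
#' proportionally to chromosome count, with random strand. Coordinates are
#' 1-based inclusive.
#'
#' @param map marker map (defines the chromosome set).
#' @param cfg a [sim_config()].
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_annotation <- function(map, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(map) > 0)
  set.seed(cfg$seed + 404L)
  n_chr <- cfg$n_chromosomes
  base <- cfg$n_genes %/% n_chr
  per_chrom <- rep(base, n_chr)
  extra <- cfg$n_genes - base * n_chr
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  out <- vector("list", n_chr)
  gid <- 0L
  for (cc in seq_len(n_chr)) {
    k <- per_chrom[cc]
    if (k == 0L) next
    len <- round(runif(k, 5e3, 5e4))
    slack <- cfg$chrom_length_bp - sum(len) - k  # >=1bp gap between genes
    if (slack < 0)
      stop("simulate_gene_annotation: genes cannot fit in the genome; ",
           "reduce n_genes or enlarge chrom_length_bp")
    gaps <- floor(slack * diff(c(0, sort(runif(k)), 1)))
    start <- cumsum(gaps[seq_len(k)] + 1) + cumsum(c(0, len[-k]))
    out[[cc]] <- data.frame(
      gene_id = sprintf("G%04d", gid + seq_len(k)),
      chrom = cc,
      start = start,
      end = start + len - 1,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE
    )
    gid <- gid + k
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  genes
}

#' Simulate PWMs and promoters with planted binding sites
#'
#' Builds one informative PWM per transcription factor (a dominant base with
#' probability 0.85 per position) and one random ACGT promoter per gene.
#' For each TF, a random subset of genes receives the motif consensus planted
#' at a random promoter position; the planted truth is returned so scans can
#' be validated. The first `n_tfs` genes of the annotation act as the TFs.
#'
#' @param genes gene annotation from [simulate_gene_annotation()].
#' @param cfg a [sim_config()].
#' @param target_prob probability that a gene is a planted target of a TF.
#' @return list with `pwms` (named list of 4 x L probability matrices, rows
#'   A,C,G,T), `promoters` (named character vector), `tf_list` (TF gene ids)
#'   and `planted` (data.frame `tf`, `gene`, `pos`).
#' @export
simulate_motifs_and_promoters <- function(genes, cfg, target_prob = 0.15) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$motif_length >= cfg$promoter_length)
    stop("simulate_motifs_and_promoters: motif longer than promoter")
  if (cfg$n_tfs > nrow(genes))
    stop("simulate_motifs_and_promoters: n_tfs exceeds n_genes")
  set.seed(cfg$seed + 505L)
  bases <- c("A", "C", "G", "T")
  L <- cfg$motif_length
  tf_list <- genes$gene_id[seq_len(cfg$n_tfs)]
  pwms <- lapply(seq_len(cfg$n_tfs), function(i) {
    dom <- sample.int(4, L, replace = TRUE)
    M <- matrix(0.05, 4, L, dimnames = list(bases, NULL))
    M[cbind(dom, seq_len(L))] <- 0.85
    M
  })
  names(pwms) <- tf_list
  n_gene <- nrow(genes)
  promoters <- vapply(seq_len(n_gene), function(i) {
    paste(sample(bases, cfg$promoter_length, replace = TRUE), collapse = "")
  }, character(1))
  names(promoters) <- genes$gene_id
  planted <- list()
  for (tf in tf_list) {
    consensus <- paste(bases[apply(pwms[[tf]], 2, which.max)], collapse = "")
    hit <- which(runif(n_gene) < target_prob)
    for (g in hit) {
      pos <- sample.int(cfg$promoter_length - L + 1, 1)
      substr(promoters[g], pos, pos + L - 1) <- consensus
      planted[[length(planted) + 1L]] <- data.frame(
        tf = tf, gene = genes$gene_id[g], pos = pos,
        stringsAsFactors = FALSE
      )
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(tf = character(), gene = character(), pos = integer())
  list(pwms = pwms, promoters = promoters, tf_list = tf_list,
       planted = planted)
}

#' Simulate a complete input bundle
#'
#' Runs every simulator stage with a shared configuration and returns the
#' bundle the pipeline consumes.
#'
#' @param cfg a [sim_config()].
#' @return list: `cfg`, `map`, `geno`, `truth` (effects), `response`,
#'   `genes`, `motifs` (pwms/promoters/tf_list/planted).
#' @export
simulate_all <- function(cfg = sim_config()) {
  map <- simulate_marker_map(cfg)
  geno <- simulate_genotypes(map, cfg)
  tr <- simulate_traits(geno, cfg)
  genes <- simulate_gene_annotation(map, cfg)
  motifs <- simulate_motifs_and_promoters(genes, cfg)
  list(cfg = cfg, map = map, geno = geno, truth = tr$effects,
       response = tr$response, genes = genes, motifs = motifs)
}
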