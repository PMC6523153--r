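#' Annotate SNPs with their nearest gene
#'
#' For each marker, finds the nearest gene on the same chromosome by
#' interval distance in bp: 0 if the SNP lies inside the gene (genic), else
#' the gap to the closest gene boundary. Ties are broken in favour of the
#' gene with the smaller start coordinate. SNPs on chromosomes without genes
#' get `NA` gene and distance.
#'
#' @param map marker map (`marker_id`, `chrom`, `pos_bp`).
#' @param genes gene annotation (`gene_id`, `chrom`, `start`, `end`),
#'   1-based inclusive coordinates.
#' @return data.frame `marker_id`, `gene_id`, `distance_bp`, `region_class`
#'   (`"genic"`/`"intergenic"`, `NA` when unannotated).
#' @export
annotate_nearest_gene <- function(map, genes) {
  n <- nrow(map)
  gene_id <- rep(NA_character_, n)
  dist_bp <- rep(NA_real_, n)
  for (cc in unique(map$chrom)) {
    gi <- which(genes$chrom == cc)
    if (!length(gi)) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    si <- which(map$chrom == cc)
    for (k in si) {
      p <- map$pos_bp[k]
      d <- pmax(0, g$start - p, p - g$end)
      best <- which(d == min(d))[1]  # genes sorted by start => tie rule
      gene_id[k] <- g$gene_id[best]
      dist_bp[k] <- d[best]
    }
  }
  data.frame(
    marker_id = map$marker_id,
    gene_id = gene_id,
    distance_bp = dist_bp,
    region_class = ifelse(is.na(dist_bp), NA_character_,
                          ifelse(dist_bp == 0, "genic", "intergenic")),
    stringsAsFactors = FALSE
  )
}

#' Select the SNP rows of an association weight matrix
#'
#' Applies the three AWM construction rules to per-trait GWAS results:
#' \enumerate{
#'   \item keep SNPs significant (`bf >= bf_min`) for the key trait, or for
#'     at least two traits;
#'   \item distance filter against the nearest gene. `mode = "literal"`
#'     keeps SNPs with `d_min <= distance <= d_max` (eliminating those
#'     closer than `d_min` or farther than `d_max`); `mode = "proximal"`
#'     keeps SNPs within `d_min` of a gene. The two conventions coexist in
#'     the AWM literature; see the package vignette;
#'   \item one SNP per gene, ranked by the number of significant traits,
#'     then the key-trait Bayes factor, then the lower genomic coordinate.
#' }
#' Surviving SNPs without a gene assignment are retained as their own rows
#' when `keep_unannotated` is `TRUE`.
#'
#' @param gwas named list (one element per trait) of [snp_significance()]
#'   tables; all tables must share the same marker set.
#' @param links nearest-gene table from [annotate_nearest_gene()].
#' @param key_trait name of the key trait (must be in `names(gwas)`).
#' @param bf_min Bayes-factor significance cutoff (default 3.2).
#' @param d_min lower distance bound in bp (default 2500).
#' @param d_max upper distance bound in bp (default 1.5 Mb).
#' @param mode `"literal"` or `"proximal"` distance rule.
#' @param keep_unannotated retain surviving unannotated SNPs as rows.
#' @return data.frame `row_id`, `marker_id`, `gene_id`, `distance_bp`,
#'   `n_sig_traits`, `bf_key`, `chrom`, `pos_bp`.
#' @export
select_awm_rows <- function(gwas, links, key_trait, bf_min = 3.2,
                            d_min = 2500, d_max = 1.5e6,
                            mode = c("literal", "proximal"),
                            keep_unannotated = TRUE) {
  mode <- match.arg(mode)
  if (!key_trait %in% names(gwas))
    stop("select_awm_rows: key trait '", key_trait, "' not in GWAS results")
  ids <- gwas[[1]]$marker_id
  bf_mat <- vapply(gwas, function(g) g$bf[match(ids, g$marker_id)],
                   numeric(length(ids)))
  sig <- bf_mat >= bf_min
  n_sig <- rowSums(sig)
  keep1 <- sig[, key_trait] | n_sig >= 2

  li <- match(ids, links$marker_id)
  d <- links$distance_bp[li]
  gene <- links$gene_id[li]
  keep2 <- if (mode == "literal") !is.na(d) & d >= d_min & d <= d_max
           else !is.na(d) & d <= d_min
  if (keep_unannotated) keep2 <- keep2 | is.na(d)

  keep <- keep1 & keep2
  if (!any(keep)) {
    return(data.frame(row_id = character(), marker_id = character(),
                      gene_id = character(), distance_bp = numeric(),
                      n_sig_traits = integer(), bf_key = numeric(),
                      chrom = gwas[[1]]$chrom[0], pos_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  sel <- data.frame(
    marker_id = ids[keep],
    gene_id = gene[keep],
    distance_bp = d[keep],
    n_sig_traits = n_sig[keep],
    bf_key = bf_mat[keep, key_trait],
    chrom = gwas[[key_trait]]$chrom[match(ids[keep], gwas[[key_trait]]$marker_id)],
    pos_bp = gwas[[key_trait]]$pos_bp[match(ids[keep], gwas[[key_trait]]$marker_id)],
    stringsAsFactors = FALSE
  )
  # one representative SNP per gene
  key <- ifelse(is.na(sel$gene_id), paste0("snp:", sel$marker_id), sel$gene_id)
  ord <- order(key, -sel$n_sig_traits, -sel$bf_key, sel$chrom, sel$pos_bp)
  sel <- sel[ord, , drop = FALSE]
  key <- key[ord]
  sel <- sel[!duplicated(key), , drop = FALSE]
  sel$row_id <- ifelse(is.na(sel$gene_id), sel$marker_id, sel$gene_id)
  rownames(sel) <- NULL
  sel[, c("row_id", "marker_id", "gene_id", "distance_bp", "n_sig_traits",
          "bf_key", "chrom", "pos_bp")]
}

#' Build the z-normalised association weight matrix
#'
#' Assembles the genes-by-traits matrix of additive effects for the selected
#' representative SNPs and standardises every trait column to mean 0 and
#' sample (n-1) standard deviation 1.
#'
#' @param rows selection from [select_awm_rows()] (>= 3 rows).
#' @param gwas the same named list of [snp_significance()] tables.
#' @return object of class `"awm"`: list with `M` (row_id x trait matrix of
#'   z-scores) and `provenance` (the `rows` table with per-trait BFs).
#' @export
zscore_matrix <- function(rows, gwas) {
  if (nrow(rows) < 3) stop("zscore_matrix: need at least 3 rows")
  eff <- vapply(gwas, function(g) g$effect[match(rows$marker_id, g$marker_id)],
                numeric(nrow(rows)))
  bf <- vapply(gwas, function(g) g$bf[match(rows$marker_id, g$marker_id)],
               numeric(nrow(rows)))
  colnames(bf) <- paste0("bf_", names(gwas))
  sds <- apply(eff, 2, stats::sd)
  if (any(sds == 0))
    stop("zscore_matrix: constant effect column for trait(s): ",
         paste(names(gwas)[sds == 0], collapse = ", "))
  M <- scale(eff)
  dimnames(M) <- list(rows$row_id, names(gwas))
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  structure(list(M = M, provenance = cbind(rows, bf)), class = "awm")
}

#' @export
print.awm <- function(x, ...) {
  cat("Association weight matrix:", nrow(x$M), "rows (",
      sum(!is.na(x$provenance$gene_id)), "genes,",
      sum(is.na(x$provenance$gene_id)), "bare SNPs ) x",
      ncol(x$M), "traits\n")
  invisible(x)
}

#' Build an association weight matrix in one call
#'
#' Convenience wrapper: nearest-gene annotation, row selection and
#' z-normalisation.
#'
#' @inheritParams select_awm_rows
#' @param map marker map.
#' @param genes gene annotation.
#' @param ... passed to [select_awm_rows()].
#' @return an `"awm"` object, see [zscore_matrix()].
#' @export
build_awm <- function(gwas, map, genes, key_trait, ...) {
  links <- annotate_nearest_gene(map, genes)
  rows <- select_awm_rows(gwas, links, key_trait, ...)
  zscore_matrix(rows, gwas)
}
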