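#' @name bfawm-io
#' @title Readers and writers for the pipeline's file dialects
#'
#' @description
#' Plain-text formats: marker map TSV (`marker_id`, `chrom`, `pos_bp`),
#' genotype TSV (first column `animal_id`, one 0/1/2 column per marker),
#' response TSV (`animal_id`, `trait`, `debv`, `reliability`\[, `weight`\]),
#' gene annotation BED (0-based half-open on disk, 1-based inclusive in
#' memory), promoter FASTA, MEME minimal motif files, and one-symbol-per-line
#' TF lists. Readers validate and report the offending file/line on error.
NULL

#' @rdname bfawm-io
#' @param map,path,geno,records,genes,promoters,pwms,tf_list objects/paths.
#' @export
write_marker_map <- function(map, path) {
  data.table::fwrite(map[, c("marker_id", "chrom", "pos_bp")], path,
                     sep = "\t")
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_marker_map <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(m)))
    stop("read_marker_map: ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (any(m$pos_bp < 0)) {
    bad <- which(m$pos_bp < 0)[1]
    stop("read_marker_map: ", path, " line ", bad + 1, ": negative position")
  }
  m[order(m$chrom, m$pos_bp), need, drop = FALSE]
}

#' @rdname bfawm-io
#' @export
write_genotypes <- function(geno, path) {
  G <- if (is.list(geno) && !is.null(geno$G)) geno$G else geno
  dt <- data.table::data.table(animal_id = rownames(G))
  dt <- cbind(dt, data.table::as.data.table(G))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_genotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "animal_id")
    stop("read_genotypes: ", path, ": first column must be animal_id")
  ids <- dt$animal_id
  G <- as.matrix(dt[, -1])
  bad <- which(!(is.na(G) | G %in% c(0, 1, 2)))
  if (length(bad)) {
    rr <- ((bad[1] - 1) %% nrow(G)) + 1
    stop("read_genotypes: ", path, " line ", rr + 1,
         ": dosage outside {0,1,2}")
  }
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  G
}

#' @rdname bfawm-io
#' @export
write_response <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_response <- function(path) {
  r <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("animal_id", "trait", "debv", "reliability")
  if (!all(need %in% names(r)))
    stop("read_response: ", path, " must have columns ",
         paste(need, collapse = ", "))
  bad <- which(r$reliability < 0 | r$reliability > 1)
  if (length(bad))
    stop("read_response: ", path, " line ", bad[1] + 1,
         ": reliability outside [0,1]")
  r
}

#' @rdname bfawm-io
#' @export
write_gene_annotation <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = genes$start - 1L,  # to 0-based half-open
                    end = genes$end,
                    name = genes$gene_id,
                    score = 0L,
                    strand = genes$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_gene_annotation <- function(path) {
  bed <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(bed) < 4)
    stop("read_gene_annotation: ", path, ": need at least 4 BED columns")
  bad <- which(bed[[3]] <= bed[[2]])
  if (length(bad))
    stop("read_gene_annotation: ", path, " line ", bad[1],
         ": end <= start")
  data.frame(gene_id = as.character(bed[[4]]),
             chrom = bed[[1]],
             start = bed[[2]] + 1L,            # to 1-based inclusive
             end = bed[[3]],
             strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
             stringsAsFactors = FALSE)
}

#' @rdname bfawm-io
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname bfawm-io
#' @param background background base frequencies written in the header.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.6g C %.6g G %.6g T %.6g", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (nm in names(pwms)) {
    M <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(M)), con)
    for (i in seq_len(ncol(M)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         M[1, i], M[2, i], M[3, i], M[4, i]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("read_meme: ", path, ": no MOTIF blocks found")
  pwms <- list()
  for (k in motif_at) {
    nm <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[k])), "\\s+")[[1]][1]
    hdr <- k + which(grepl("letter-probability matrix", lines[(k + 1):length(lines)]))[1]
    if (is.na(hdr)) stop("read_meme: ", path, " line ", k,
                         ": MOTIF without probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    M <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]),
                  numeric(4)))
    if (anyNA(M)) stop("read_meme: ", path, ": malformed matrix for motif ", nm)
    M <- t(M)                               # to 4 x L
    rownames(M) <- c("A", "C", "G", "T")
    pwms[[nm]] <- M
  }
  pwms
}

#' @rdname bfawm-io
#' @export
write_tf_list <- function(tf_list, path) {
  writeLines(tf_list, path)
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' @rdname bfawm-io
#' @param awm an `"awm"` object.
#' @export
write_awm <- function(awm, path) {
  dt <- data.table::data.table(row_id = rownames(awm$M))
  dt <- cbind(dt, data.table::as.data.table(awm$M))
  data.table::fwrite(dt, path, sep = "\t")
  prov_path <- sub("(\\.[^.]*)?$", "_provenance.tsv", path)
  data.table::fwrite(awm$provenance, prov_path, sep = "\t")
  invisible(path)
}

#' @rdname bfawm-io
#' @export
read_awm <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  M <- as.matrix(dt[, -1])
  rownames(M) <- dt$row_id
  M
}

#' @rdname bfawm-io
#' @param net a `"coassoc_network"`.
#' @export
write_edges <- function(net, path) {
  sif <- data.frame(a = net$edges$a, type = "co", b = net$edges$b,
                    weight = net$edges$weight)
  data.table::fwrite(sif, path, sep = "\t")
  invisible(path)
}

# Serialize BF columns with an "inf" sentinel so TSVs round-trip.
format_bf <- function(bf) ifelse(is.infinite(bf), "inf", format(bf, digits = 10))

parse_bf <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "inf"] <- Inf
  out
}

#' Read and validate a complete input bundle
#'
#' Parses every pipeline input from files written in the package's dialects
#' and cross-checks consistency (markers of the genotype matrix present in
#' the map, promoters named by genes).
#'
#' @param paths named list: `map`, `genotypes`, `response`, `genes`,
#'   `promoters`, `motifs`, `tf_list`.
#' @return bundle list (`map`, `geno`, `response`, `genes`, `motifs`).
#' @export
read_inputs <- function(paths) {
  for (nm in c("map", "genotypes", "response", "genes", "promoters",
               "motifs", "tf_list"))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("read_inputs: missing file for '", nm, "': ", paths[[nm]])
  map <- read_marker_map(paths$map)
  G <- read_genotypes(paths$genotypes)
  if (!all(colnames(G) %in% map$marker_id))
    stop("read_inputs: genotype columns missing from the marker map")
  response <- read_response(paths$response)
  genes <- read_gene_annotation(paths$genes)
  promoters <- read_promoters(paths$promoters)
  pwms <- read_meme(paths$motifs)
  tf_list <- read_tf_list(paths$tf_list)
  list(map = map,
       geno = list(G = G, animal_id = rownames(G)),
       response = response,
       genes = genes,
       motifs = list(pwms = pwms, promoters = promoters, tf_list = tf_list))
}

#' Write a simulated bundle to a directory
#'
#' Serialises a [simulate_all()] bundle into the pipeline's file dialects.
#'
#' @param bundle a [simulate_all()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_inputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    map = file.path(dir, "marker_map.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    response = file.path(dir, "response.tsv"),
    genes = file.path(dir, "genes.bed"),
    promoters = file.path(dir, "promoters.fasta"),
    motifs = file.path(dir, "motifs.meme"),
    tf_list = file.path(dir, "tf_list.txt")
  )
  write_marker_map(bundle$map, paths$map)
  write_genotypes(bundle$geno, paths$genotypes)
  write_response(bundle$response, paths$response)
  write_gene_annotation(bundle$genes, paths$genes)
  write_promoters(bundle$motifs$promoters, paths$promoters)
  write_meme(bundle$motifs$pwms, paths$motifs)
  write_tf_list(bundle$motifs$tf_list, paths$tf_list)
  invisible(paths)
}
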