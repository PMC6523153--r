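# Hand-built 12-SNP x 7-trait fixture with known Bayes factors, distances
# and gene assignments, plus the hand-enumerated expected row sets for both
# distance-filter modes (key trait T1, bf_min 3.2, d_min 2500, d_max 1.5e6).
make_awm_fixture <- function(seed = 101) {
  set.seed(seed)
  traits <- paste0("T", 1:7)
  ids <- sprintf("s%02d", 1:12)
  SIG <- 10; NS <- 1
  bf <- matrix(NS, 12, 7, dimnames = list(ids, traits))
  bf["s01", "T1"] <- SIG                      # key only
  bf["s02", c("T2", "T3")] <- SIG             # two non-key
  bf["s03", "T4"] <- SIG                      # one non-key -> fails rule 1
  # s04: none                                 -> fails rule 1
  bf["s05", "T1"] <- SIG                      # key, genic (d = 0)
  bf["s06", c("T1", "T2", "T3")] <- 50        # 3 sig traits, shares gB
  bf["s07", "T1"] <- 80                       # higher key BF, 1 sig trait
  bf["s08", c("T1", "T5")] <- SIG             # too far (d = 2e6)
  bf["s09", "T1"] <- SIG                      # unannotated SNP
  bf["s10", c("T5", "T6")] <- SIG             # d = 2500 boundary
  bf["s11", "T1"] <- SIG                      # d = 1.5e6 boundary
  bf["s12", "T1"] <- SIG                      # d = 100, proximal only
  links <- data.frame(
    marker_id = ids,
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB", "gC", NA,
                "gC", "gD", "gE"),
    distance_bp = c(3000, 1000, 4000, 4000, 0, 5000, 6000, 2e6, NA,
                    2500, 1.5e6, 100),
    stringsAsFactors = FALSE
  )
  gwas <- lapply(traits, function(tr) {
    data.frame(marker_id = ids, chrom = 1, pos_bp = seq_len(12) * 1e5,
               effect = round(rnorm(12), 3), model_freq = 0.5,
               bf = bf[, tr], stringsAsFactors = FALSE)
  })
  names(gwas) <- traits
  list(gwas = gwas, links = links,
       expected_literal = c(gA = "s01", gB = "s06", s09 = "s09",
                            gC = "s10", gD = "s11"),
       expected_proximal = c(gA = "s02", gB = "s05", s09 = "s09",
                             gC = "s10", gE = "s12"))
}
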