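test_that("FASTA + variant table load round-trips, including the empty case", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ENH1 chr7:101-140(+)",
               "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"), fa)
  lib <- load_library(fa, NULL)
  expect_s3_class(lib, "cre_library")
  expect_equal(nrow(lib$cres), 1)
  expect_equal(nrow(lib$variants), 0)
  expect_equal(lib$cres$start, 101L)
  expect_equal(lib$cres$end, 140L)

  tab <- tempfile(fileext = ".tsv")
  write.table(data.frame(cre_id = "ENH1", position = 103, ref = "G",
                         alt = "A"),
              tab, sep = "\t", row.names = FALSE, quote = FALSE)
  lib2 <- load_library(fa, tab)
  expect_equal(nrow(lib2$variants), 1)
  expect_equal(lib2$variants$variant_id, "ENH1:103:G>A")
})

test_that("validation rejects ref mismatches naming the position, and missing CREs", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ENH1 chr7:101-140(+)",
               "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"), fa)
  tab <- tempfile(fileext = ".tsv")
  write.table(data.frame(cre_id = "ENH1", position = 103, ref = "T",
                         alt = "A"),
              tab, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_library(fa, tab), "103")
  write.table(data.frame(cre_id = "NOPE", position = 103, ref = "G",
                         alt = "A"),
              tab, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_library(fa, tab), "NOPE")
})

test_that("allele application handles SNVs, deletions, and insertions", {
  cre <- list(cre_id = "X", start = 1L, end = 4L, sequence = "ACGT")
  snv <- list(variant_id = "s", position = 2L, ref = "C", alt = "G")
  expect_equal(apply_variant(cre, snv)$dna, "AGGT")

  cre5 <- list(cre_id = "X", start = 1L, end = 5L, sequence = "ACGTA")
  del <- list(variant_id = "d", position = 2L, ref = "CGT", alt = "C")
  expect_equal(apply_variant(cre5, del)$dna, "ACA")

  ins <- list(variant_id = "i", position = 2L, ref = "C", alt = "CTT")
  expect_equal(apply_variant(cre, ins)$dna, "ACTTGT")

  oob <- list(variant_id = "o", position = 9L, ref = "A", alt = "G")
  expect_error(apply_variant(cre, oob), "out of bounds")
})

test_that("SNV application is reversible and indels shift length by alt-ref", {
  lib <- tiny_library()
  for (i in seq_len(nrow(lib$variants))) {
    v <- lib$variants[i, ]
    cre <- lib$cres[match(v$cre_id, lib$cres$cre_id), ]
    res <- apply_variant(cre, v)
    expect_equal(nchar(res$dna) - nchar(cre$sequence),
                 nchar(v$alt) - nchar(v$ref))
    if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
      back <- v
      back$ref <- v$alt
      back$alt <- v$ref
      cre2 <- cre
      cre2$sequence <- res$dna
      expect_equal(apply_variant(cre2, back)$dna, cre$sequence)
    }
  }
})

test_that("library sequences contain exactly one reference per CRE", {
  lib <- tiny_library()
  seqs <- library_sequences(lib)
  refs <- grep(":ref$", seqs$seq_id, value = TRUE)
  expect_equal(sort(refs), sort(paste0(lib$cres$cre_id, ":ref")))
  expect_equal(nrow(seqs), nrow(lib$cres) + nrow(lib$variants))
})

test_that("variant classification partitions input by type and frequency", {
  variants <- data.frame(
    variant_id = paste0("v", 1:4),
    ref = c("A", "C", "G", "GT"), alt = c("G", "T", "A", "G"),
    af_afr = c(0.022, 0.001, NA, NA),
    af_eur = c(0.003, 0.0005, NA, 0.3),
    stringsAsFactors = FALSE)
  cl <- classify_variants(variants, common_threshold = 0.01)
  expect_equal(unname(cl$counts["SNV"]), 3)
  expect_equal(unname(cl$counts["indel"]), 1)
  # AF 2.2% in one population exceeds the 1% threshold
  expect_equal(cl$table$freq_class[1], "common")
  expect_equal(cl$table$freq_class[2], "rare")
  expect_equal(cl$table$freq_class[3], "unknown")
  expect_equal(sum(cl$counts[c("common", "rare", "unknown")]), 4)
  expect_equal(sum(cl$counts[c("SNV", "indel")]), 4)
})

test_that("a study-scale variant table loads with every record validated", {
  cfg <- sim_config(n_cres = 6, cre_length = 400,
                    n_variants_per_cre = 203, barcodes_per_variant = 1,
                    seed = 3)
  gen <- generate_library(cfg)
  fa <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(
    sprintf(">%s %s:%d-%d(%s)", gen$library$cres$cre_id,
            gen$library$cres$chrom, gen$library$cres$start,
            gen$library$cres$end, gen$library$cres$strand),
    gen$library$cres$sequence)), fa)
  tab <- tempfile(fileext = ".tsv")
  v <- gen$library$variants[seq_len(1214), ]
  write.table(v[, c("cre_id", "chrom", "position", "ref", "alt")], tab,
              sep = "\t", row.names = FALSE, quote = FALSE)
  lib <- load_library(fa, tab)
  expect_equal(nrow(lib$variants), 1214)
  expect_equal(nrow(lib$cres), 6)
})

test_that("VCF records map POS/REF/ALT onto the variant table identically", {
  lib <- tiny_library()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr7\t103\t.\tG\tA\t.\t.\tCRE=ENH1",
               "chr7\t505\t.\tC\tT\t.\t.\t."), vcf)
  v <- read_variants_vcf(vcf, lib$cres)
  expect_equal(v$position, c(103L, 505L))
  expect_equal(v$cre_id, c("ENH1", "ENH2"))
  lib2 <- cre_library(lib$cres, v)
  expect_equal(nrow(lib2$variants), 2)
})

test_that("haplotype alleles realise all member variants on one sequence", {
  lib <- tiny_library()
  defs <- data.frame(haplotype_id = "hapA",
                     variant_ids = paste(lib$variants$variant_id[1:2],
                                         collapse = ","))
  lib2 <- add_haplotypes(lib, defs)
  hap_dna <- lib2$extras$dna[1]
  # SNV at offset 3 (G>A) and deletion at offsets 11-12 (GT>G)
  expect_equal(hap_dna,
               paste0("ACATACGTACG", substr(lib$cres$sequence[1], 13, 40)))
  expect_error(add_haplotypes(lib, data.frame(haplotype_id = "bad",
                                              variant_ids = "nope")),
               "nope")
})
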