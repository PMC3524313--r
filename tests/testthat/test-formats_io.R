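test_that("GMT reader dedups genes, rejects malformed lines and duplicate names", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tdesc\tC\tD"), f)
  expect_warning(gmt <- read_gmt(f), "duplicate genes")
  expect_identical(gmt$sets$S1, c("A", "B"))
  expect_identical(gmt$sets$S2, c("C", "D"))

  writeLines(character(0), f)
  empty <- read_gmt(f)
  expect_s3_class(empty, "gene_set_collection")
  expect_length(empty, 0)

  writeLines("S1\tonlydesc", f)
  expect_error(read_gmt(f), "line 1")

  writeLines(c("S1\td\tA\tB", "S1\td\tC\tD"), f)
  expect_error(read_gmt(f), "duplicate gene set name")
})

test_that("GMT round-trips and tolerates CRLF line endings", {
  col <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("C", "D", "E")),
                             provenance = c(S1 = "x", S2 = "y"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, f)
  back <- read_gmt(f)
  expect_identical(back$sets, col$sets)

  crlf <- withr::local_tempfile(fileext = ".gmt")
  con <- file(crlf, "wb")
  writeLines(readLines(f), con, sep = "\r\n")
  close(con)
  expect_identical(read_gmt(crlf)$sets, col$sets)
})

test_that("PLINK text reader counts minor alleles and handles missing calls", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  # SNP1: AA AA AG GG (G minor -> 0,0,1,2); SNP2: one missing call
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), map)
  writeLines(c("F1 I1 0 0 1 2 A A A A",
               "F2 I2 0 0 1 2 A A 0 0",
               "F3 I3 0 0 1 1 A G A C",
               "F4 I4 0 0 1 1 G G A A"), ped)
  st <- read_plink_text(ped, map)
  expect_equal(unname(st$dosage["rs1", ]), c(0, 0, 1, 2))
  expect_true(is.na(st$dosage["rs2", "I2"]))
  expect_identical(st$phenotype, c("case", "case", "control", "control"))
  expect_equal(st$pos, c(100, 200))
})

test_that("PLINK reader breaks MAF ties lexicographically and validates input", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1\trs1\t0\t100", map)
  # equal counts of C and T: minor must be C (lexicographically smaller)
  writeLines(c("F1 I1 0 0 1 2 C T", "F2 I2 0 0 1 1 T C"), ped)
  expect_message(st <- read_plink_text(ped, map), "tie")
  expect_equal(unname(st$dosage[1, ]), c(1, 1))

  writeLines(c("F1 I1 0 0 1 2 X T", "F2 I2 0 0 1 1 T T"), ped)
  expect_error(read_plink_text(ped, map), "allele codes")

  writeLines(c("F1 I1 0 0 1 2 C T C T"), ped)  # too many fields for 1 SNP
  expect_error(read_plink_text(ped, map), "PED/MAP mismatch")
})

test_that("genotype study round-trips through PED/MAP", {
  set.seed(42)
  d <- matrix(rbinom(60, 2, 0.3), nrow = 6)
  d[1, 2] <- NA
  st <- toy_study(d, 5, 5)
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_plink_text(st, ped, map)
  back <- read_plink_text(ped, map)
  expect_equal(unname(back$dosage), unname(st$dosage))
  expect_identical(back$phenotype, st$phenotype)
  expect_equal(back$pos, st$pos)
})

test_that("BED reader applies the 0-based to 1-based conversion and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tG1", f)
  g <- read_gene_bed(f)
  expect_equal(g$start, 1000)
  expect_equal(g$end, 2000)

  writeLines("chr1\t500\t500\tG1", f)
  expect_error(read_gene_bed(f), "zero-length")

  writeLines("chr1\t100\t200", f)
  expect_error(read_gene_bed(f), "column 4")

  writeLines(c("chr1\t0\t10\tG1", "chr1\t20\t30\tG1"), f)
  expect_error(read_gene_bed(f), "duplicate gene id")

  write_gene_bed(data.frame(gene = "G1", chrom = "chr1", start = 1000,
                            end = 2000), f)
  expect_equal(readLines(f), "chr1\t999\t2000\tG1")
})

test_that("expression reader round-trips and reports bad cells precisely", {
  st <- expression_study(c("g1", "g2"), matrix(c(1.5, 2, 3, 4.25), 2),
                         c("A", "B"), c("case", "control"))
  m <- withr::local_tempfile(fileext = ".tsv")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression(st, m, p)
  back <- read_expression(m, p)
  expect_equal(unname(back$values), unname(st$values))
  expect_identical(back$phenotype, st$phenotype)

  writeLines(c("gene\tA\tB", "g1\t1\tx", "g2\t3\t4"), m)
  expect_error(read_expression(m, p), "row 2.*sample B")

  writeLines(c("gene\tA\tB", "g1\t1\t2", "g1\t3\t4"), m)
  dup <- read_expression(m, p)  # duplicate gene rows preserved
  expect_identical(dup$gene_ids, c("g1", "g1"))

  writeLines(c("sample\tphenotype", "A\tcase"), p)
  expect_error(read_expression(m, p), "missing from phenotype")
})

test_that("results table writer is sorted, formatted, and byte-deterministic", {
  res <- data.frame(set = c("b", "a", "c"), size = c(3L, 2L, 4L),
                    score = c(0.5, 0.25, 1.5), nes = c(1.2, NaN, 0.8),
                    p = c(0.02, 0.02, 0.001), fdr = c(0.1, 0.1, NA))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, f1)
  lines <- readLines(f1)
  expect_equal(lines[1], "set\tsize\tscore\tnes\tp\tfdr")
  expect_match(lines[2], "^c\t")          # smallest p first
  expect_match(lines[3], "^a\t")          # p tie broken by name
  expect_match(lines[3], "\tNA\t")        # NaN nes serialized as NA
  write_results_table(res[c(3, 1, 2), ], f2)  # row order must not matter
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  write_results_table(res[0, ], f1)
  expect_equal(readLines(f1), "set\tsize\tscore\tnes\tp\tfdr")
})
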