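# genomics_io: annotation and aberration parsing, scope resolution.

annotationFixture <- function() {
  readGeneAnnotation(fixturePath("gene_annotation.tsv"), "tsv")
}

test_that("BED rows parse into 1-based GRanges with chr stripped", {
  p <- writeTemp("chr13\t48303748\t48481890\tRB1", ".bed")
  gr <- readGeneAnnotation(p, "bed")
  expect_s4_class(gr, "GRanges")
  expect_equal(gr$gene, "RB1")
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "13")
  expect_equal(GenomicRanges::start(gr), 48303749)  # 0-based BED converted
  expect_equal(GenomicRanges::end(gr), 48481890)
})

test_that("empty annotation files yield empty annotations", {
  expect_length(readGeneAnnotation(writeTemp(character(), ".bed"), "bed"), 0)
  expect_length(
    readGeneAnnotation(writeTemp("gene\tchrom\tstart\tend\tcytoband"), "tsv"),
    0)
})

test_that("duplicated gene symbols are rejected", {
  p <- writeTemp(c("gene\tchrom\tstart\tend\tcytoband",
                   "TP53\t17\t100\t200\t17p13.1",
                   "TP53\t17\t300\t400\t17p13.1"))
  expect_error(readGeneAnnotation(p, "tsv"), "TP53")
})

test_that("malformed rows raise errors naming the line", {
  p <- writeTemp(c("gene\tchrom\tstart\tend\tcytoband",
                   "TP53\t17\t100\t200\t17p13.1",
                   "RB1\t13\toops\t300\t13q14.2"))
  expect_error(readGeneAnnotation(p, "tsv"), "line 3")
  pb <- writeTemp(c("13\t100\t200\tRB1", "13\t100"), ".bed")
  expect_error(readGeneAnnotation(pb, "bed"), "line 2")
})

test_that("start > end intervals are rejected", {
  p <- writeTemp(c("gene\tchrom\tstart\tend\tcytoband",
                   "TP53\t17\t500\t200\t17p13.1"))
  expect_error(readGeneAnnotation(p, "tsv"), "start > end")
})

test_that("unknown formats are rejected", {
  expect_error(readGeneAnnotation(tempfile(), "vcf"))
})

test_that("karyotype-style cytoband scopes parse", {
  s <- parseCytobandScope("del(7)(q22q36)")
  expect_equal(s, list(chrom = "7", band_from = "q22", band_to = "q36"))
  s1 <- parseCytobandScope("del(17)(p13.1)")
  expect_equal(s1$band_from, s1$band_to)
  expect_equal(s1$band_from, "p13.1")
  expect_error(parseCytobandScope("nonsense"), "cannot parse")
})

test_that("packaged aberration tables read with invariants enforced", {
  for (i in 1:4) {
    ab <- readAberrations(fixturePath(sprintf("patient%d_aberrations.tsv", i)))
    expect_s3_class(ab, "AberrationSet")
    expect_gt(nrow(ab), 0)
    expect_true(all(ab$zygosity %in%
                      c("heterozygous", "homozygous", "unspecified")))
  }
})

abHeader <- "kind\tscope_type\tchrom\tstart\tend\tband_from\tband_to\tgene\tzygosity"

test_that("aberration parsing errors name the offending line", {
  bad <- writeTemp(c(abHeader,
                     "copy_banana\tgene\t\t\t\t\t\tTP53\thomozygous"))
  expect_error(readAberrations(bad), "copy_banana")
  badScope <- writeTemp(c(abHeader,
                          "monosomy\tgene\t\t\t\t\t\tTP53\tunspecified"))
  expect_error(readAberrations(badScope), "whole_chromosome")
  badMut <- writeTemp(c(abHeader,
                        "mutation_lof\twhole_chromosome\t13\t\t\t\t\t\t"))
  expect_error(readAberrations(badMut), "gene scope")
})

test_that("blank zygosity defaults to unspecified; karyotype rows expand", {
  p <- writeTemp(c(abHeader,
                   "copy_loss\tkaryotype\tdel(7)(q22q36)\t\t\t\t\t\t"))
  ab <- readAberrations(p)
  expect_equal(ab$zygosity, "unspecified")
  expect_equal(ab$scope_type, "cytoband_range")
  expect_equal(ab$chrom, "7")
  expect_equal(ab$band_from, "q22")
  expect_equal(ab$band_to, "q36")
})

test_that("direction mapping is exhaustive over the seven kinds", {
  expect_equal(
    aberrationDirection(c("copy_gain", "copy_loss", "monosomy", "trisomy",
                          "translocation_amplification", "mutation_gof",
                          "mutation_lof")),
    c("up", "down", "down", "up", "up", "up", "down"))
  expect_error(aberrationDirection("inversion"), "unrecognized")
})

test_that("whole-chromosome loss resolves every annotated gene on 13", {
  ann <- annotationFixture()
  p <- writeTemp(c(abHeader,
                   "monosomy\twhole_chromosome\t13\t\t\t\t\t\theterozygous"))
  res <- resolveGenes(readAberrations(p), ann)
  expect_true(all(c("RB1", "FOXO1") %in% res$gene))
  expect_true(all(res$change == "down"))
})

test_that("cytoband loss at 17p13.1 resolves TP53 down", {
  ann <- annotationFixture()
  p <- writeTemp(c(abHeader,
                   "copy_loss\tkaryotype\tdel(17)(p13.1)\t\t\t\t\t\thomozygous"))
  res <- resolveGenes(readAberrations(p), ann)
  expect_true("TP53" %in% res$gene)
  expect_true(all(res$change == "down"))
})

test_that("intervals use any-overlap and nest monotonically", {
  ann <- annotationFixture()
  tp53 <- ann["TP53"]
  lo <- GenomicRanges::start(tp53)
  hi <- GenomicRanges::end(tp53)
  mk <- function(s, e) {
    readAberrations(writeTemp(c(abHeader,
      sprintf("copy_loss\tinterval\t17\t%d\t%d\t\t\t\tunspecified", s, e))))
  }
  # one-bp overlap at the gene edge still counts
  expect_true("TP53" %in% resolveGenes(mk(lo - 10, lo), ann)$gene)
  # a gap before the gene does not
  expect_false("TP53" %in% resolveGenes(mk(lo - 10, lo - 1), ann)$gene)
  # containment: genes(J) subset of genes(I) for J inside I
  inner <- resolveGenes(mk(lo, hi), ann)$gene
  outer <- resolveGenes(mk(lo - 1e6, hi + 1e6), ann)$gene
  expect_true(all(inner %in% outer))
})

test_that("interval overlapping no gene resolves to nothing", {
  ann <- annotationFixture()
  p <- writeTemp(c(abHeader,
                   "copy_loss\tinterval\t17\t1\t2\t\t\t\tunspecified"))
  expect_equal(nrow(resolveGenes(readAberrations(p), ann)), 0)
})

test_that("unknown cytobands error at resolve time, not parse time", {
  ann <- annotationFixture()
  p <- writeTemp(c(abHeader,
                   "copy_loss\tkaryotype\tdel(17)(q99)\t\t\t\t\t\t"))
  ab <- readAberrations(p)   # parse succeeds
  expect_error(resolveGenes(ab, ann), "q99")
})

test_that("resolution is deterministic and row-order independent", {
  ann <- annotationFixture()
  ab <- readAberrations(fixturePath("patient4_aberrations.tsv"))
  a <- resolveGenes(ab, ann)
  b <- resolveGenes(ab[rev(seq_len(nrow(ab))), ], ann)
  key <- function(x) sort(paste(x$gene, x$change))
  expect_identical(key(a), key(b))
  expect_identical(a, resolveGenes(ab, ann))
})

test_that("translocation amplification with gene scope resolves up", {
  ann <- annotationFixture()
  p <- writeTemp(c(abHeader,
    "translocation_amplification\tgene\t\t\t\t\t\tCCND1\tunspecified",
    "translocation_amplification\tgene\t\t\t\t\t\tAKT1\tunspecified"))
  res <- resolveGenes(readAberrations(p), ann)
  expect_setequal(res$gene, c("CCND1", "AKT1"))
  expect_true(all(res$change == "up"))
})
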