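test_that("table dialect parses printed gene orders with strand marks", {
  s <- parse_structure("cox1 *cox3 ls1 *ls3 *cytb *ls5 ls4 (L)", "table1")
  expect_length(s$chrs, 1L)
  ch <- s$chrs[[1]]
  expect_false(ch$circular)
  expect_equal(ch$id, c("cox1", "cox3", "ls1", "ls3", "cytb", "ls5", "ls4"))
  expect_equal(ch$sign, c(1L, -1L, 1L, -1L, -1L, -1L, 1L))
})

test_that("grimm dialect parses circular chromosomes and headers", {
  s <- parse_structure(">toy\ng1 g2 @")
  expect_equal(s$name, "toy")
  expect_true(s$chrs[[1]]$circular)
  expect_length(s$chrs[[1]]$id, 2L)
})

test_that("circular equality is rotation and reversal invariant", {
  s1 <- parse_structure(">x\ng1 g2 g3 @")
  s2 <- parse_structure(">x\ng2 g3 g1 @")
  s3 <- parse_structure(">x\n-g3 -g2 -g1 @")
  expect_true(structures_equal(s1, s2))
  expect_true(structures_equal(s1, s3))
  lin <- parse_structure(">x\ng1 -g2 $")
  rev <- parse_structure(">x\ng2 -g1 $")
  expect_true(structures_equal(lin, rev))
})

test_that("canonicalization is idempotent and writing is deterministic", {
  s <- parse_structure(">x\n-g2 g1 @\ng4 -g3 $")
  c1 <- canonical_structure(s)
  expect_identical(write_structure(c1), write_structure(canonical_structure(c1)))
  expect_identical(write_structure(parse_structure(">x\ng2 g1 @")),
                   write_structure(parse_structure(">x\ng1 g2 @")))
})

test_that("write/parse round-trips all printed mitochondrial rows", {
  rows <- read_table1()
  expect_length(rows, 18L)
  for (s in rows) {
    for (d in c("grimm", "table1")) {
      back <- parse_structure(write_structure(s, d), d)
      expect_true(structures_equal(s, back), info = s$name)
    }
  }
  ## Babesia bovis keeps its 8 tokens and 5 strand marks
  bb <- rows[["Babesia_bovis"]]
  expect_length(bb$chrs[[1]]$id, 8L)
  expect_equal(sum(bb$chrs[[1]]$sign < 0), 5L)
  ## canonical text may emit the reversed reading, which flips the strand
  ## marks of the 8 tokens (5 on one strand, 3 on the other)
  expect_true(length(gregexpr("\\*", write_structure(bb, "table1"))[[1]]) %in% c(3L, 5L))
})

test_that("malformed input is rejected with positional diagnostics", {
  expect_error(parse_structure(">x\ng1 g2"), "end with")
  expect_error(parse_structure(">x\ng1 g1 $"), "duplicate")
  expect_error(chrom_structure(list(chromosome(c("a", "a")))), "duplicate")
  expect_error(chromosome(character(0)), "at least one")
})

test_that("adjacency view and reconstruction are inverse", {
  for (txt in list(">x\ng1 -g2 g3 $", ">x\ng1 g2 @\n-g3 $", ">x\ng1 @")) {
    s <- parse_structure(txt)
    back <- adjset_to_structure(as_adjset(s))
    expect_true(structures_equal(s, back), info = txt)
  }
})

test_that("paralog indices parse and render with dot notation", {
  s <- parse_structure(">x\ncox1.1 -cox1.2 g $")
  expect_equal(gene_family(structure_genes(s)), c("cox1", "cox1", "g"))
  expect_equal(gene_paralog(structure_genes(s)), c(1L, 2L, NA_integer_))
})
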