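test_that("construct names parse into ordered mutation specs", {
  expect_equal(nrow(parse_construct_name("WT")), 0)

  one <- parse_construct_name("T85A")
  expect_equal(one$wt, "T")
  expect_equal(one$pos, 85L)
  expect_equal(one$new, "A")

  three <- parse_construct_name("H53A/G54H/T85A")
  expect_equal(three$pos, c(53L, 54L, 85L))
  expect_equal(three$wt, c("H", "G", "T"))
  expect_equal(three$new, c("A", "H", "A"))

  expect_error(parse_construct_name("T85"), "malformed")
  expect_error(parse_construct_name("85A"), "malformed")
  expect_error(parse_construct_name("T85T"), "identical")
})

test_that("apply_mutations honours offsets and validates residues", {
  loopB <- "SGGHINPTVTFSLCLLGREPWRKFP"
  expect_equal(apply_mutations(loopB, parse_construct_name("T85A"),
                               offset = 77),
               "SGGHINPAVTFSLCLLGREPWRKFP")

  loopA <- "HILSGGSHGMFLTV"
  expect_equal(apply_mutations(loopA, parse_construct_name("H53A/G54H"),
                               offset = 45),
               "HILSGGSAHMFLTV")

  # empty spec list is the identity
  expect_equal(apply_mutations(loopB, parse_construct_name("WT")), loopB)

  # wild-type mismatch reports expected vs found
  expect_error(apply_mutations(loopB, parse_construct_name("A85T"),
                               offset = 77), "expected A, found T")
  expect_error(apply_mutations(loopB, parse_construct_name("T85A")),
               "out of range")

  # protein_sequence objects round-trip through the same path
  ps <- protein_sequence("loopB", loopB)
  out <- apply_mutations(ps, parse_construct_name("T85A"), offset = 77)
  expect_s3_class(out, "protein_sequence")
  expect_equal(out$residues, "SGGHINPAVTFSLCLLGREPWRKFP")
})

test_that("mutation application is an involution", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    seq0 <- paste(sample(alphabet, 30, replace = TRUE), collapse = "")
    pos <- sample(30, 3)
    chars <- strsplit(seq0, "")[[1]]
    specs <- data.frame(wt = chars[pos], pos = pos,
                        new = vapply(chars[pos], function(c)
                          sample(setdiff(alphabet, c), 1), ""))
    mut <- apply_mutations(seq0, specs)
    inverse <- data.frame(wt = specs$new, pos = specs$pos, new = specs$wt)
    expect_identical(apply_mutations(mut, inverse), seq0)
  }
})

test_that("NPA-box scanning finds and classifies motifs", {
  m1 <- find_np_motifs("SGGHINPTVT")
  expect_equal(m1$start, 6L)
  expect_equal(m1$triplet, "NPT")
  expect_false(m1$canonical)

  m2 <- find_np_motifs("AVNPARDLGP")
  expect_equal(m2$start, 3L)
  expect_equal(m2$triplet, "NPA")
  expect_true(m2$canonical)

  expect_equal(nrow(find_np_motifs("ACDEFG")), 0)

  # positions are stable under suffix extension
  base <- find_np_motifs("SGGHINPTVT")
  ext <- find_np_motifs(paste0("SGGHINPTVT", "KLMWYR"))
  expect_equal(base$start, ext$start[seq_len(nrow(base))])
})

test_that("packaged mutant fragments all derive from the WT fragments", {
  rep <- verify_table2()
  expect_true(attr(rep, "all_pass"))
  expect_equal(length(unique(rep$construct)), 15)  # all mutant rows
  expect_true(all(rep$pass))

  # the WT first box is the NPT variant; T85A restores canonical NPA
  fx <- table2_constructs()
  wt_b <- fx$fragments$loop_B[fx$fragments$construct == "WT"]
  t85a_b <- fx$fragments$loop_B[fx$fragments$construct == "T85A"]
  expect_equal(find_np_motifs(wt_b)$triplet[1], "NPT")
  expect_equal(find_np_motifs(t85a_b)$triplet[1], "NPA")

  # corrupting a stored row is caught and named
  fx$fragments$loop_B[fx$fragments$construct == "T85A"] <-
    sub("AVT", "AVA", t85a_b)
  rep2 <- verify_table2(fx)
  expect_false(attr(rep2, "all_pass"))
  bad <- rep2[!rep2$pass, ]
  expect_equal(unique(bad$construct), "T85A")
  expect_equal(unique(bad$loop), "B")
})

test_that("FASTA round trip preserves ids and residues", {
  skip_if_not_installed("Biostrings")
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  seqs <- list(protein_sequence("a", "MKTLV"),
               protein_sequence("b", "NPAWY"))
  write_fasta(seqs, tmp)
  back <- read_fasta(tmp)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$b$residues, "NPAWY")
})
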