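test_that("choose_codon picks the top usage codon with stated tie-break", {
  usage <- codon_usage_table()
  # leucine: TTG is the most frequent yeast codon
  expect_identical(choose_codon("L", "GCT", usage), "TTG")

  # explicit tie: lexicographically first wins
  tied <- tibble::tibble(aa = c("K", "K"), codon = c("AAG", "AAA"),
                         fraction = c(0.5, 0.5))
  expect_identical(choose_codon("K", "GCT", tied), "AAA")

  # null mutation forbidden
  expect_error(choose_codon("A", "GCT", usage), "null mutation")
})

test_that("melting temperature matches the frozen independent oracle", {
  # expected values from a second nearest-neighbor implementation
  # (same unified parameter set, 50 mM Na+, CT 0.5 uM), frozen
  cases <- list(
    c("ACGTACGTGGCCAACGTGCA", 62.7153),
    c("ATATATATATATATATATAT", 27.2845),
    c("GGGGCCCCGGGGCCCCGGGG", 76.1099),
    c("AGCTTCAGGACCTTAGC", 50.7543)
  )
  for (cs in cases) {
    expect_equal(melting_temperature(cs[1], na_conc = 0.05),
                 as.numeric(cs[2]), tolerance = 1e-3)
  }

  # duplex symmetry: reverse complement has the same Tm
  s <- "ACGTACGTGGCCAACGTGCA"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  expect_equal(melting_temperature(s), melting_temperature(rc),
               tolerance = 1e-9)

  expect_error(melting_temperature("ACGTAC"), "shorter than 8")
  expect_error(melting_temperature("ACGTACGN"), "non-ACGT")

  # appending G/C never lowers Tm on these fixtures
  for (base in c("AGCTTCAGGACCTTAGC", "ACGTACGTGGCCAACGTGCA")) {
    grown <- base
    for (i in 1:10) {
      longer <- paste0(grown, "G")
      expect_gte(melting_temperature(longer), melting_temperature(grown))
      grown <- longer
    }
  }
})

test_that("designed oligos round-trip through in-silico application", {
  ref <- make_reference(60, seed = 11)
  d <- toy_design(ref, n_positions = 3)
  oligos <- design_oligos(d, ref$cds)
  expect_identical(sum(oligos$pool == "single"),
                   nrow(enumerate_singles(d)))
  doubles <- enumerate_doubles(d)
  expect_identical(sum(oligos$pool == "double"),
                   sum(doubles$pool == "proximal"))

  ref_aa <- strsplit(ref$protein, "")[[1]]
  for (i in seq_len(nrow(oligos))) {
    mut <- apply_oligo(oligos[i, ], ref$cds)
    expect_identical(nchar(mut), nchar(ref$cds))
    p <- strsplit(translate_cds(mut), "")[[1]]
    subs <- parse_variant(oligos$variant[i])
    expect_identical(which(p != ref_aa), sort(subs$position))
    expect_identical(p[subs$position],
                     subs$aa[order(subs$position)])
  }
  # arms meet their Tm floor and are exact reference substrings
  params <- oligo_params()
  expect_true(all(oligos$arm5_tm >= params$min_arm_tm))
  expect_true(all(oligos$arm3_tm >= params$min_arm_tm))
  for (i in seq_len(nrow(oligos))) {
    arm5 <- substr(oligos$sequence[i], 1, oligos$arm5_len[i])
    expect_true(grepl(arm5, ref$cds, fixed = TRUE))
  }
})

test_that("proximal double oligos carry the intervening reference", {
  ref <- make_reference(40, seed = 3)
  protein <- strsplit(ref$protein, "")[[1]]
  pos <- c(18L, 21L)
  sub_aa <- vapply(pos, function(p) {
    setdiff(standard_aa(), c(protein[p], "C", "P"))[1]
  }, character(1))
  v <- format_variant(protein[pos], pos, sub_aa)
  o <- design_oligo(v, ref$cds)
  expect_identical(o$pool, "double")
  core <- substr(o$sequence, o$arm5_len + 1,
                 nchar(o$sequence) - o$arm3_len)
  # middle codons (19, 20) untouched
  expect_identical(substr(core, 4, 9), substr(ref$cds, 3 * 19 - 2, 3 * 20))
})

test_that("arm boundary violations are explicit errors", {
  ref <- make_reference(60, seed = 5)
  protein <- strsplit(ref$protein, "")[[1]]
  aa1 <- setdiff(standard_aa(), c(protein[1], "C", "P"))[1]
  expect_error(design_oligo(paste0(protein[1], 1, aa1), ref$cds),
               "5' arm runs past")
  # wild-type mismatch guard
  wrong_wt <- setdiff(standard_aa(), protein[30])[1]
  expect_error(design_oligo(paste0(wrong_wt, 30, "G"), ref$cds),
               "reference mismatch")
})

test_that("apply_oligo enforces arm uniqueness and identity edits", {
  ref <- make_reference(50, seed = 21)
  # a wild-type "oligo" (core = reference span) is an identity edit
  o <- list(sequence = substr(ref$cds, 31, 90), arm5_len = 20L,
            arm3_len = 20L)
  expect_identical(apply_oligo(o, ref$cds), ref$cds)

  # engineered repeat: arm occurring twice is ambiguous
  rep_ref <- paste0(ref$cds, substr(ref$cds, 31, 50))
  expect_error(apply_oligo(o, rep_ref), "ambiguous")

  o2 <- list(sequence = "AAACCCGGGTTTACGTACGT", arm5_len = 10L,
             arm3_len = 10L)
  expect_error(apply_oligo(o2, ref$cds), "not found")
})

test_that("export_pools writes one FASTA and manifest per pool", {
  ref <- make_reference(60, seed = 13)
  d <- tiny_design(c(20, 23, 40), strsplit(ref$protein, "")[[1]][c(20, 23, 40)],
                   list(c("D", "E"), c("D", "E", "G"), c("D", "E")))
  oligos <- design_oligos(d, ref$cds)
  dir <- tempfile()
  files <- export_pools(oligos, dir)
  single_fa <- Biostrings::readDNAStringSet(
    files$fasta[files$pool == "single"])
  expect_length(single_fa, 7)
  double_fa <- Biostrings::readDNAStringSet(
    files$fasta[files$pool == "double"])
  expect_length(double_fa, 6) # 2x3 proximal pairs at positions 20/23
  manifest <- readr::read_tsv(files$manifest[files$pool == "single"],
                              show_col_types = FALSE)
  expect_identical(nrow(manifest), 7L)

  expect_error(export_pools(rbind(oligos, oligos[1, ]), tempfile()),
               "duplicate")
  expect_message(
    export_pools(oligos[oligos$pool == "single", ], tempfile()),
    "empty")
})
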