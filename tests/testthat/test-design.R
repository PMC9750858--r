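test_that("default allele sets exclude wild type and global exclusions", {
  d <- build_allele_sets(data.frame(position = 59, wt = "K"))
  expect_length(d$alleles[[1]], 17) # 20 - wt - C - P
  expect_false(any(c("K", "C", "P") %in% d$alleles[[1]]))

  # wt already in the exclusion set: only one extra letter removed
  d2 <- build_allele_sets(data.frame(position = 10, wt = "C"))
  expect_length(d2$alleles[[1]], 18)
})

test_that("stability filtering and overrides shape allele sets", {
  stab <- data.frame(position = 62,
                     aa = c("A", "D", "E", "F", "G", "H"),
                     ddg = c(0.5, 1.2, 0.1, 5.0, 3.1, 0.9))
  d <- build_allele_sets(data.frame(position = 62, wt = "I"),
                         stability = stab, ddg_threshold = 1.5)
  # hand filter: F (5.0) and G (3.1) dropped, the other 13 defaults kept
  expect_false(any(c("F", "G") %in% d$alleles[[1]]))
  expect_true(all(c("A", "D", "E", "H") %in% d$alleles[[1]]))
  expect_length(d$alleles[[1]], 15)

  d2 <- build_allele_sets(data.frame(position = 62, wt = "I"),
                          overrides = list(`62` = c("V", "L", "M", "A")))
  expect_identical(d2$alleles[[1]], c("A", "L", "M", "V"))
  expect_error(
    build_allele_sets(data.frame(position = 62, wt = "I"),
                      overrides = list(`62` = c("I", "V"))),
    "wild type")
  expect_error(
    build_allele_sets(data.frame(position = 62, wt = "I"),
                      overrides = list(`99` = "V")),
    "unknown position")
  expect_error(
    build_allele_sets(data.frame(position = c(10, 10), wt = c("A", "A"))),
    "strictly increasing")
})

test_that("pocket-scale enumeration reproduces the published combinatorics", {
  # 25 contact positions, all 19 non-wt substitutions allowed
  pos25 <- data.frame(position = seq(51, 75), wt = rep("A", 25))
  d25 <- build_allele_sets(pos25, global_exclusions = character(0))
  expect_identical(nrow(enumerate_singles(d25)), 475L)
  expect_identical(nrow(enumerate_doubles(d25)), 108300L)

  # 19 retained positions
  pos19 <- data.frame(position = seq(51, 69), wt = rep("A", 19))
  d19 <- build_allele_sets(pos19, global_exclusions = character(0))
  expect_identical(nrow(enumerate_singles(d19)), 361L)
})

test_that("enumeration matches a brute-force oracle on small designs", {
  withr::with_seed(42, {
    for (trial in 1:5) {
      n_pos <- sample(2:5, 1)
      positions <- sort(sample(10:60, n_pos))
      wt <- sample(standard_aa(), n_pos, replace = TRUE)
      sets <- lapply(seq_len(n_pos), function(i) {
        sort(sample(setdiff(standard_aa(), wt[i]), sample(1:6, 1)))
      })
      d <- tiny_design(positions, wt, sets)
      oracle <- brute_force_variants(positions, sets)

      singles <- enumerate_singles(d)
      expect_identical(nrow(singles), nrow(oracle$singles))
      expect_setequal(paste0(singles$position, singles$aa),
                      paste0(oracle$singles$position, oracle$singles$aa))

      doubles <- enumerate_doubles(d)
      expect_identical(nrow(doubles), nrow(oracle$doubles))
      expect_setequal(
        paste(doubles$position1, doubles$aa1, doubles$position2,
              doubles$aa2),
        paste(oracle$doubles$p1, oracle$doubles$aa1, oracle$doubles$p2,
              oracle$doubles$aa2))

      # count identities
      sizes <- lengths(sets)
      expect_identical(nrow(singles), as.integer(sum(sizes)))
      expect_identical(nrow(doubles),
                       as.integer((sum(sizes)^2 - sum(sizes^2)) / 2))
    }
  })
})

test_that("degenerate designs enumerate cleanly", {
  d1 <- tiny_design(10, "A", list(character(0)))
  expect_identical(nrow(enumerate_singles(d1)), 0L)
  expect_identical(nrow(enumerate_doubles(d1)), 0L)
  rep <- library_report(d1)
  expect_identical(rep$n_total, 0L)
})

test_that("proximity partition follows the strict window rule", {
  d <- tiny_design(c(10, 15, 30), c("A", "A", "A"),
                   list("V", "V", "V"), window = 8)
  doubles <- enumerate_doubles(d)
  part <- partition_by_proximity(doubles, window = 8)
  expect_identical(part$pool[part$position1 == 10 & part$position2 == 15],
                   "proximal")
  expect_identical(part$pool[part$position2 == 30], c("distal", "distal"))

  # boundary: separation exactly 8 is distal ("at least eight apart")
  d8 <- tiny_design(c(10, 18), c("A", "A"), list("V", "V"), window = 8)
  expect_identical(enumerate_doubles(d8)$pool, "distal")
  d7 <- tiny_design(c(10, 17), c("A", "A"), list("V", "V"), window = 8)
  expect_identical(enumerate_doubles(d7)$pool, "proximal")

  # window 0: nothing is proximal
  expect_true(all(partition_by_proximity(doubles, 0)$pool == "distal"))

  # a partition: pools are disjoint and exhaustive, order-invariant
  shuffled <- part[rev(seq_len(nrow(part))), ]
  repart <- partition_by_proximity(shuffled, 8)
  expect_identical(sum(repart$pool == "proximal") +
                     sum(repart$pool == "distal"), nrow(part))
  expect_identical(sort(repart$variant[repart$pool == "proximal"]),
                   sort(part$variant[part$pool == "proximal"]))

  expect_error(
    partition_by_proximity(enumerate_singles(d), 8), "double")
})

test_that("library_report totals are internally consistent", {
  d <- tiny_design(c(5, 12, 40), c("A", "G", "T"),
                   list(c("V", "L"), c("V", "L"), c("V", "L", "M")))
  rep <- library_report(d)
  expect_identical(rep$n_singles, 7L)
  expect_identical(rep$n_doubles, 16L)
  expect_identical(rep$n_total, 23L)
  expect_identical(rep$n_singles + rep$n_doubles, rep$n_total)
  expect_identical(rep$n_proximal + rep$n_distal, rep$n_doubles)
  expect_identical(glance(d), rep)
})

test_that("enumeration order is stable across runs", {
  d <- tiny_design(c(3, 9, 20), c("A", "A", "A"),
                   list(c("V", "W"), c("D", "E"), c("F", "G")))
  f1 <- tempfile(); f2 <- tempfile()
  write_variants(enumerate_doubles(d), f1)
  write_variants(enumerate_doubles(d), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contact_positions agrees with a distance oracle", {
  # 5 residues whose CA atoms sit at chosen distances from a single
  # ligand atom at the origin
  dists <- c(2.9, 4.4, 4.5, 6.0, 9.1)
  prot <- data.frame(resno = 1:5, x = dists, y = 0, z = 0)
  lig <- data.frame(x = 0, y = 0, z = 0)
  pdb <- write_tiny_pdb(tempfile(fileext = ".pdb"), prot, lig)

  hits <- contact_positions(pdb, "LIG", cutoff = 4.5)
  expect_identical(hits, c(1L, 2L, 3L)) # boundary 4.5 inclusive

  expect_identical(contact_positions(pdb, "LIG", cutoff = 3.0), 1L)
  expect_identical(contact_positions(pdb, "LIG", cutoff = 2.8), integer(0))

  # brute-force oracle over all atom pairs
  cutoff <- 5.5
  oracle <- prot$resno[sqrt(prot$x^2 + prot$y^2 + prot$z^2) <= cutoff]
  expect_identical(contact_positions(pdb, "LIG", cutoff = cutoff),
                   as.integer(oracle))

  # atom order must not matter
  prot_shuf <- prot[c(4, 1, 5, 3, 2), ]
  pdb2 <- write_tiny_pdb(tempfile(fileext = ".pdb"), prot_shuf, lig)
  expect_identical(contact_positions(pdb2, "LIG", cutoff = 4.5),
                   c(1L, 2L, 3L))

  expect_error(contact_positions(pdb, "ABA", cutoff = 4.5),
               "ligand not found")
  expect_identical(contact_positions(pdb, "LIG", cutoff = 4.5, offset = 58L),
                   c(59L, 60L, 61L))
})
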