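# Reference mapping, residue calling, family classification, star MSA,
# conservation profiles.

make_ref <- function(seed = 41, len = 125) {
  set.seed(seed)
  chars <- sample(aa_alphabet(), len, replace = TRUE,
                  prob = blosum62_background())
  chars[c(42, 46, 50, 69, 92, 96, 100, 119)] <-
    c("Y", "E", "S", "C", "F", "F", "M", "W")
  list(id = "ref", residues = paste(chars, collapse = ""))
}

test_that("mapping the reference onto itself is the identity", {
  ref <- make_ref()
  rm <- map_to_reference(ref, ref)
  expect_true(rm$reliable)
  expect_equal(paste(rm$mapping, collapse = ""), ref$residues)
  cl <- call_residues(rm, ref)
  expect_equal(unname(cl$residues_at[c("42", "46", "69")]),
               c("Y", "E", "C"))
  expect_length(cl$substitution_labels, 0)
  expect_true(cl$functional)
})

test_that("deletions shift and insertions are absorbed", {
  ref <- make_ref()
  chars <- strsplit(ref$residues, "")[[1]]
  # delete reference position 10: it maps to a gap, the rest still map
  del <- list(id = "del10", residues = paste(chars[-10], collapse = ""))
  rm <- map_to_reference(del, ref)
  expect_equal(rm$mapping[10], "-")
  expect_equal(rm$mapping[-10], chars[-10])
  # 3-residue insertion after position 20: all reference positions map to
  # their own residues; the insertion is recorded, not mapped
  ins <- list(id = "ins20", residues = paste(c(chars[1:20], "W", "W", "W",
                                               chars[21:125]), collapse = ""))
  rm2 <- map_to_reference(ins, ref)
  expect_equal(rm2$mapping, chars)
  expect_equal(sum(nchar(rm2$insertions)), 3)
})

test_that("substitution labels and the Cys69 rule drive the calls", {
  ref <- make_ref()
  chars <- strsplit(ref$residues, "")[[1]]
  v <- chars; v[42] <- "F"
  cl <- call_residues(map_to_reference(
    list(id = "y42f", residues = paste(v, collapse = "")), ref), ref)
  expect_equal(cl$substitution_labels, "Y42F")
  expect_true(cl$functional)  # position 42 does not affect the flag
  w <- chars; w[69] <- "S"
  cl2 <- call_residues(map_to_reference(
    list(id = "c69s", residues = paste(w, collapse = "")), ref), ref)
  expect_true("C69S" %in% cl2$substitution_labels)
  expect_false(cl2$functional)
  # gap at 69 is labelled with the gap marker and kills the flag
  z <- chars[-69]
  cl3 <- call_residues(map_to_reference(
    list(id = "del69", residues = paste(z, collapse = "")), ref), ref)
  expect_true("C69-" %in% cl3$substitution_labels)
  expect_false(cl3$functional)
  expect_error(call_residues(map_to_reference(ref, ref), ref, positions = 999),
               "outside")
})

test_that("family classification counts members and substitution rates", {
  ref <- make_ref()
  chars <- strsplit(ref$residues, "")[[1]]
  mk <- function(id, at = NULL, to = NULL) {
    v <- chars
    if (!is.null(at)) v[at] <- to
    setNames(paste(v, collapse = ""), id)
  }
  seqs <- c(mk("a"), mk("b"), mk("c", 69, "S"), mk("d", 69, "A"),
            mk("e", 69, "G"), mk("f", 42, "F"), mk("g", 46, "Q"),
            mk("h"), mk("i"), mk("j"))
  calls <- call_residues_many(seqs, ref)
  fam <- classify_family(calls)
  expect_equal(fam$member_fraction, 0.7)
  expect_equal(sort(fam$members), c("a", "b", "f", "g", "h", "i", "j"))
  expect_equal(fam$triad_fraction, 0.5)
  expect_equal(unname(fam$label_counts[["Y42F"]]), 1)
  expect_false(fam$y42_e46_cooccurrence)
  # a functional double 42+46 substitution is detected when present
  seqs2 <- c(seqs, mk("k", c(42, 46), c("F", "Q")))
  fam2 <- classify_family(call_residues_many(seqs2, ref))
  expect_true(fam2$y42_e46_cooccurrence)
})

test_that("planted substitution rates are recovered within 3 binomial SE", {
  cfg <- synth_config(seed = 42)
  fam <- generate_family(cfg, "A", 500)
  ref <- list(id = "ref", residues = fam$residues[1])
  # read positions directly (no indels in the generator)
  y42f <- mean(substr(fam$residues, 42, 42) == "F")
  e46q <- mean(substr(fam$residues, 46, 46) == "Q")
  se <- function(p) sqrt(p * (1 - p) / 500)
  expect_lt(abs(y42f - 0.10), 3 * se(0.10))
  expect_lt(abs(e46q - 0.05), 3 * se(0.05))
  # and through the full mapping/calling route on a subsample
  sub <- fam[1:100, ]
  refrec <- generate_dataset(synth_config(seed = 42,
                                          genomes_per_phylum = c(PA = 2),
                                          pyp_prevalence = c(PA = 1),
                                          n_decoy_families = 0))$reference
  calls <- call_residues_many(setNames(sub$residues, sub$id), refrec)
  got_y42f <- mean(vapply(calls, function(cl)
    "Y42F" %in% cl$substitution_labels, TRUE))
  expect_lt(abs(got_y42f - mean(substr(sub$residues, 42, 42) == "F")), 1e-12)
})

test_that("star MSA obeys the merge rule and the stacking oracle", {
  ref <- make_ref()
  chars <- strsplit(ref$residues, "")[[1]]
  # indel-free sequences stack directly: no insert columns
  set.seed(43)
  muts <- lapply(1:4, function(i) {
    v <- chars; v[sample(125, 10)] <- sample(aa_alphabet(), 10, TRUE); v
  })
  seqs <- setNames(vapply(muts, paste, "", collapse = ""), paste0("s", 1:4))
  msa <- star_msa(seqs, ref)
  expect_equal(ncol(msa$rows), 125)
  expect_true(all(msa$is_ref_column))
  expect_equal(unname(msa_strings(msa)[-1]), unname(seqs))
  # one insertion -> exactly one insert column with a reference gap
  ins <- c(seqs, one = paste(c(chars[1:60], "W", chars[61:125]), collapse = ""))
  msa2 <- star_msa(ins, ref)
  expect_equal(ncol(msa2$rows), 126)
  expect_equal(sum(!msa2$is_ref_column), 1)
  icol <- which(!msa2$is_ref_column)
  expect_equal(unname(msa2$rows[1, icol]), "-")
  expect_equal(unname(msa2$rows["one", icol]), "W")
  # nested indels: width equals the hand-merged construction, where each
  # insertion slot takes the longest insertion over all rows
  nest <- c(seqs,
            i2 = paste(c(chars[1:60], "WW", chars[61:125]), collapse = ""),
            i3 = paste(c(chars[1:60], "WWF", chars[61:125]), collapse = ""))
  msa3 <- star_msa(nest, ref)
  expect_equal(ncol(msa3$rows), 125 + 3)
  expect_equal(substr(msa_strings(msa3)[["i2"]], 61, 63), "WW-")
})

test_that("conservation profiles are normalized and track planted motifs", {
  ref <- make_ref()
  chars <- strsplit(ref$residues, "")[[1]]
  g1a <- chars; g1b <- chars; g1b[50] <- "A"
  seqs <- setNames(c(paste(g1a, collapse = ""), paste(g1b, collapse = "")),
                   c("r1", "r2"))
  msa <- star_msa(seqs, ref)
  prof <- conservation_profile(msa, c(r1 = "G", r2 = "G"))
  expect_true(all(abs(colSums(prof$G) - 1) < 1e-12))
  expect_equal(prof$G["C", "69"], 1)
  expect_equal(prof$G["S", "50"], 0.5)
  expect_equal(prof$G["A", "50"], 0.5)
  expect_error(conservation_profile(msa, c(r1 = "G", zz = "H")), "empty group")
  # clade-C generator: Met100 conservation ~ 1 (motif is restored after
  # mutation, so only unplanted drift at other positions varies)
  cfg <- synth_config(seed = 44, substitution_rates = c(Y42F = 0)[0])
  fam <- generate_family(cfg, "C", 30)
  refrec <- list(id = "ref", residues = fam$residues[1])
  msaC <- star_msa(setNames(fam$residues, fam$id), refrec)
  profC <- conservation_profile(msaC,
                                setNames(rep("C", nrow(fam)), fam$id))
  expect_equal(profC$C["M", "100"], 1)
})

test_that("unreliable maps are excluded from the star MSA with a warning", {
  ref <- make_ref()
  junk <- paste(rep("P", 30), collapse = "")
  expect_false(map_to_reference(list(id = "junk", residues = junk),
                                ref)$reliable)
  seqs <- c(ok = ref$residues, junk = junk)
  expect_warning(msa <- star_msa(seqs, ref), "unreliable")
  expect_equal(msa$ids, c("ref", "ok"))
})
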