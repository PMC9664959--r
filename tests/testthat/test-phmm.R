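# Profile HMM: construction, scoring against path enumeration, cutoffs,
# iteration, serialization.

msa_from_strings <- function(strings, ref_free = TRUE) {
  # build a star_msa-shaped object directly from gapped rows
  rows <- do.call(rbind, strsplit(strings, ""))
  rownames(rows) <- names(strings)
  is_ref <- rep(TRUE, ncol(rows))
  structure(list(ids = names(strings), rows = rows,
                 is_ref_column = is_ref,
                 ref_position = seq_len(ncol(rows))),
            class = "star_msa")
}

test_that("build_hmm turns counts into normalized emissions/transitions", {
  msa <- msa_from_strings(c(a = "ACD", b = "ACD", c = "ACD", d = "ACD"))
  h <- build_hmm(msa, pseudocount_weight = 0)
  expect_equal(h$n_match, 3)
  expect_equal(unname(h$emissions_match[1, "A"]), 1)
  expect_equal(unname(h$emissions_match[2, "C"]), 1)
  expect_equal(unname(h$transitions[2, "MM"]), 1)  # interior M->M
  expect_equal(unname(h$transitions[1, "MM"]), 1)  # begin -> M1
  # occupancy rule: 3 residues + 1 gap = 0.75 >= 0.5 -> match state
  msa2 <- msa_from_strings(c(a = "AC", b = "AC", c = "AC", d = "A-"))
  h2 <- build_hmm(msa2, match_occupancy = 0.5, pseudocount_weight = 0)
  expect_equal(h2$n_match, 2)
  # pseudocount formula: column (C, C), w = 1, uniform background
  h3 <- build_hmm(msa_from_strings(c(a = "C", b = "C")), pseudocount_weight = 1)
  bgC <- blosum62_background()[["C"]]
  expect_equal(unname(h3$emissions_match[1, "C"]), (2 + bgC) / (2 + 1))
  # all-gap occupancy failure
  expect_error(build_hmm(msa_from_strings(c(a = "-", b = "-"))),
               "zero match columns")
  # normalization invariants
  for (h in list(build_hmm(msa, pseudocount_weight = 1), h2, h3)) {
    expect_true(all(abs(rowSums(h$emissions_match) - 1) < 1e-12))
    expect_true(all(abs(rowSums(h$emissions_insert) - 1) < 1e-12))
    for (k in 0:h$n_match) {
      tr <- h$transitions[k + 1, ]
      expect_equal(unname(sum(tr[c("MM", "MI", "MD")])), 1)
      expect_equal(unname(sum(tr[c("IM", "II")])), 1)
      if (k >= 1) expect_equal(unname(sum(tr[c("DM", "DD")])), 1)
    }
  }
})

test_that("viterbi and forward match brute-force path enumeration", {
  set.seed(51)
  for (case in 1:60) {
    h <- random_small_hmm(sample(1:3, 1))
    seq <- random_aa_seq(sample(1:4, 1))
    enum <- enum_hmm_paths(h, seq)
    bg <- bg_prob(h, seq)
    fwd <- hmm_forward(h, seq)
    vit <- hmm_viterbi(h, seq)$bit_score
    expect_equal(2^fwd * bg, enum$total, tolerance = 1e-9)
    expect_equal(2^vit * bg, enum$best, tolerance = 1e-9)
    expect_gte(fwd + 1e-12, vit)
  }
})

test_that("degenerate single-path models score identically both ways", {
  msa <- msa_from_strings(c(a = "W", b = "W"))
  h <- build_hmm(msa, pseudocount_weight = 0)
  expect_equal(hmm_forward(h, "W"), hmm_viterbi(h, "W")$bit_score)
  # consensus of a sharply peaked model scores positive
  msa2 <- msa_from_strings(c(a = "WCDY", b = "WCDY", c = "WCDY"))
  h2 <- build_hmm(msa2, pseudocount_weight = 0)
  expect_gt(hmm_viterbi(h2, "WCDY")$bit_score, 0)
  expect_equal(hmm_viterbi(h2, "WCDY")$path, c("M1", "M2", "M3", "M4"))
  expect_error(hmm_viterbi(h2, ""), "empty")
})

test_that("search scores every sequence and respects cutoffs", {
  msa <- msa_from_strings(c(a = "WCDY", b = "WCDY", c = "WCDY"))
  h <- build_hmm(msa)
  db <- c(hit1 = "WCDY", hit2 = "WCDF", far = "AAAA")
  all <- hmm_search(h, db, cutoff = "none")
  expect_equal(nrow(all), 3)
  expect_equal(all$sequence_id[1], "hit1")  # sorted by score desc
  scores <- setNames(all$bit_score, all$sequence_id)
  h <- set_cutoffs(h, scores, c(hit1 = TRUE, hit2 = TRUE, far = FALSE),
                   training_ids = c("hit1", "hit2"))
  ga <- hmm_search(h, db, cutoff = "GA")
  expect_true(all(c("hit1", "hit2") %in% ga$sequence_id))
  expect_false("far" %in% ga$sequence_id)
  expect_equal(nrow(hmm_search(h, db[0], "none")), 0)
})

test_that("cutoff rules follow the Cys69-conservation construction", {
  h <- random_small_hmm(2)
  sc <- c(f1 = 50, f2 = 60, n1 = 20)
  fun <- c(f1 = TRUE, f2 = TRUE, n1 = FALSE)
  h2 <- set_cutoffs(h, sc, fun)
  expect_equal(unname(h2$cutoffs), c(35, 50, 20))  # GA, TC, NC
  # no non-functional sequences: NC = 0, GA = TC/2
  h3 <- set_cutoffs(h, c(f1 = 50, f2 = 60), c(f1 = TRUE, f2 = TRUE))
  expect_equal(unname(h3$cutoffs), c(25, 50, 0))
  # all functional with equal scores
  h4 <- set_cutoffs(h, c(f1 = 7, f2 = 7), c(f1 = TRUE, f2 = TRUE))
  expect_equal(unname(h4$cutoffs[["TC"]]), 7)
  expect_equal(unname(h4$cutoffs[["NC"]]), 0)
  # overlap collapses onto TC with a warning, preserving NC <= GA <= TC
  expect_warning(h5 <- set_cutoffs(h, c(f = 10, n = 30),
                                   c(f = TRUE, n = FALSE)), "overlap")
  co <- h5$cutoffs
  expect_true(co[["NC"]] <= co[["GA"]] && co[["GA"]] <= co[["TC"]])
  expect_error(set_cutoffs(h, c(n1 = 5), c(n1 = FALSE)), "no functional")
})

test_that("cutoff ordering holds on random score/flag configurations", {
  set.seed(52)
  h <- random_small_hmm(2)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    sc <- setNames(round(rnorm(n, 50, 30), 2), paste0("s", 1:n))
    fun <- setNames(runif(n) < 0.6, names(sc))
    if (!any(fun)) fun[1] <- TRUE
    h2 <- suppressWarnings(set_cutoffs(h, sc, fun))
    co <- h2$cutoffs
    expect_true(co[["NC"]] <= co[["GA"]] && co[["GA"]] <= co[["TC"]])
  }
})

test_that("iteration reaches a fixed point on a seeds-only database", {
  set.seed(53)
  cfg <- synth_config(seed = 53, substitution_rates = c(Y42F = 0)[0])
  fam <- generate_family(cfg, "A", 10)
  ref <- list(id = "ref", residues = fam$residues[1])
  seeds <- setNames(fam$residues, fam$id)
  it <- iterate_build(seeds, seeds, ref, max_rounds = 4)
  expect_true(it$converged)
  expect_setequal(it$hits, names(seeds))
  expect_lte(it$n_rounds, 3)
  # max_rounds 1 runs exactly one build/search cycle
  it1 <- iterate_build(seeds, seeds, ref, max_rounds = 1)
  expect_equal(it1$n_rounds, 1)
})

test_that("the model serialization round-trips exactly", {
  msa <- msa_from_strings(c(a = "WCDY", b = "WCDY", c = "WCD-"))
  h <- build_hmm(msa)
  h <- set_cutoffs(h, c(a = 10, b = 12), c(a = TRUE, b = TRUE))
  p1 <- tempfile(); p2 <- tempfile()
  write_hmm(h, p1)
  back <- read_hmm(p1)
  expect_equal(back$n_match, h$n_match)
  expect_equal(back$cutoffs, h$cutoffs, tolerance = 1e-6)
  write_hmm(back, p2)
  expect_equal(readLines(p1), readLines(p2))  # byte-stable rewrite
})
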