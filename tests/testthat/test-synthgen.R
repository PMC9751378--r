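# The planted-truth simulator itself.

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_organelle_pair(91, plastome_len = 20000, mito_len = 30000,
                               ir_len = 4000, n_transfers = 4)
  b <- simulate_organelle_pair(91, plastome_len = 20000, mito_len = 30000,
                               ir_len = 4000, n_transfers = 4)
  expect_identical(a$plastome$sequence, b$plastome$sequence)
  expect_identical(a$mitogenome$sequence, b$mitogenome$sequence)
  expect_identical(a$truth$planted_transfers, b$truth$planted_transfers)
})

test_that("planted features lie inside their genomes and are consistent", {
  sim <- simulate_organelle_pair(92)
  tr <- sim$truth$planted_transfers
  Lp <- genome_length(sim$plastome); Lm <- genome_length(sim$mitogenome)
  expect_true(all(tr$p_start >= 0 & tr$p_end <= Lp))
  expect_true(all(tr$m_start >= 0 & tr$m_end <= Lm))
  expect_equal(tr$p_end - tr$p_start, tr$length)
  expect_equal(tr$m_end - tr$m_start, tr$length)
  # planted copies really sit at the recorded identity
  for (i in seq_len(nrow(tr))) {
    a <- strsplit(substr(sim$plastome$sequence, tr$p_start[i] + 1, tr$p_end[i]), "")[[1]]
    b <- strsplit(substr(sim$mitogenome$sequence, tr$m_start[i] + 1, tr$m_end[i]), "")[[1]]
    expect_equal(mean(a == b), tr$identity[i], tolerance = 1 / tr$length[i])
  }
  # the planted IR really is a reverse complement
  ir <- sim$truth$planted_ir
  a <- substr(sim$plastome$sequence, ir$a[1] + 1, ir$a[2])
  b <- substr(sim$plastome$sequence, ir$b[1] + 1, ir$b[2])
  expect_identical(b, rc_str(a))
})

test_that("planted SSRs and repeats are recovered by the scanners", {
  sim <- simulate_organelle_pair(93, plastome_len = 15000, mito_len = 40000,
                                 ir_len = 3000, n_transfers = 3,
                                 transfer_len_range = c(150, 800),
                                 n_ssrs = 5, n_repeats = 3)
  ssrs <- find_ssrs(sim$mitogenome)
  tr_ssr <- sim$truth$planted_ssrs
  for (i in seq_len(nrow(tr_ssr))) {
    hit <- ssrs$motif == tr_ssr$motif[i] & ssrs$start == tr_ssr$start[i] &
      ssrs$n_repeats == tr_ssr$n_repeats[i]
    expect_true(any(hit), info = paste("ssr", i))
  }
  reps <- find_dispersed_repeats(sim$mitogenome)
  tr_rep <- sim$truth$planted_repeats
  for (i in seq_len(nrow(tr_rep))) {
    hit <- reps$rtype == tr_rep$rtype[i] &
      reps$a_start <= tr_rep$a_start[i] & reps$a_end >= tr_rep$a_end[i] &
      reps$b_start <= tr_rep$b_start[i] & reps$b_end >= tr_rep$b_end[i]
    expect_true(any(hit), info = paste("repeat", i))
  }
})

test_that("with no transfers planted the search finds nothing", {
  for (seed in 1:3) {
    sim <- simulate_organelle_pair(seed + 900, plastome_len = 15000,
                                   mito_len = 20000, n_transfers = 0,
                                   ir_len = 3000, n_ssrs = 0, n_repeats = 0,
                                   n_trnas = 0, n_cds = 0)
    red <- collapse_inverted_repeat(sim$plastome)
    expect_equal(nrow(homology_search(red$genome, sim$mitogenome)), 0L)
  }
})

test_that("an infeasible packing budget errors informatively", {
  expect_error(
    simulate_organelle_pair(94, plastome_len = 12000, mito_len = 10000,
                            n_transfers = 30,
                            transfer_len_range = c(900, 1000)),
    "packing")
})

test_that("pileups at efficiency 1 and zero error have alt_count == depth", {
  set.seed(95)
  g <- organelle_genome("m1", random_seq(5000), "linear", "mitogenome")
  sp <- simulate_pileup(g, n_sites = 10, efficiency = 1, depth = 30,
                        error_rate = 0, seed = 96)
  expect_true(all(sp$truth$alt_count == 30L))
  f <- withr::local_tempfile(); writeLines(sp$lines, f)
  sites <- call_editing_sites(read_pileup(f), g)
  expect_equal(sort(sites$pos), sort(sp$truth$pos))
  expect_true(all(sites$efficiency == 1))
})

test_that("a site planted next to an indel is present but never called", {
  set.seed(97)
  g <- organelle_genome("m1", random_seq(20000), "linear", "mitogenome")
  sp <- simulate_pileup(g, n_sites = 5, efficiency = 0.8,
                        n_near_indel = 4, seed = 98)
  f <- withr::local_tempfile(); writeLines(sp$lines, f)
  p <- read_pileup(f)
  near <- sp$truth[sp$truth$category == "near_indel", ]
  expect_true(all(near$pos %in% p$pos))              # present in the pileup
  sites <- call_editing_sites(p, g)
  expect_false(any(near$pos %in% sites$pos))         # absent from the calls
})

test_that("mean recovered efficiency at depth 30 is within +/- 0.02", {
  set.seed(99)
  g <- organelle_genome("m1", random_seq(60000), "linear", "mitogenome")
  sp <- simulate_pileup(g, n_sites = 1000, efficiency = 0.5, depth = 30,
                        seed = 100)
  f <- withr::local_tempfile(); writeLines(sp$lines, f)
  sites <- call_editing_sites(read_pileup(f), g)
  expect_gt(nrow(sites), 900)
  expect_lt(abs(mean(sites$efficiency) - 0.5), 0.02)
})

test_that("alignment columns are built exactly to the requested classes", {
  sa <- simulate_alignment(6, 300, class_mix = c(invariant = 1), seed = 101)
  s <- classify_sites(sa$alignment)
  expect_equal(s$variable_sites, 0L)
  expect_equal(s$invariant_sites, 300L)
  sa2 <- simulate_alignment(6, 200,
                            class_mix = c(invariant = 0.75, singleton2 = 0.25),
                            seed = 102)
  s2 <- classify_sites(sa2$alignment)
  expect_equal(unname(s2$singleton_sites["two"]), 50L)
  # a general mix is reproduced exactly
  sa3 <- simulate_alignment(7, 500, seed = 103)
  s3 <- classify_sites(sa3$alignment)
  want <- sa3$truth$counts
  expect_equal(s3$invariant_sites, unname(want["invariant"]))
  expect_equal(unname(s3$singleton_sites[c("two", "three", "four")]),
               unname(want[c("singleton2", "singleton3", "singleton4")]))
  expect_equal(unname(s3$informative_sites[c("two", "three", "four")]),
               unname(want[c("informative2", "informative3", "informative4")]))
  expect_equal(s3$gap_or_missing_sites, unname(want["gap"]))
  expect_error(simulate_alignment(3, 100,
                                  class_mix = c(informative2 = 0.5)), "taxa")
})

test_that("truth tables reload byte-identically", {
  sim <- simulate_organelle_pair(104, plastome_len = 15000, mito_len = 20000,
                                 ir_len = 3000, n_transfers = 3)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_truth_table(sim$truth, f1)
  back <- read_truth_table(f1)
  write_truth_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$planted_transfers$m_start,
               sim$truth$planted_transfers$m_start)
})
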