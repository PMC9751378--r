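# RNA-editing site calling, filters, efficiency and tissue summaries.

mk_pileup_df <- function(pos, ref, nC = 0L, nT = 0L, q = 30,
                         indel_dist = Inf, genome_id = "m1") {
  depth <- nC + nT
  data.frame(genome_id = genome_id, pos = pos, ref_base = ref,
             nA = 0L, nC = nC, nG = 0L, nT = nT, nN = 0L, depth = depth,
             qA = NA_real_, qC = ifelse(nC > 0, q, NA_real_),
             qG = NA_real_, qT = ifelse(nT > 0, q, NA_real_),
             mean_quality = q, n_del = 0L, has_indel = FALSE,
             distance_to_nearest_indel = indel_dist,
             stringsAsFactors = FALSE)
}

mito <- function(len = 200) {
  set.seed(61)
  organelle_genome("m1", random_seq(len), "linear", "mitogenome")
}

test_that("a C site with T evidence at depth 10 is emitted with efficiency 0.6", {
  g <- mito()
  p <- mk_pileup_df(5L, "C", nC = 4L, nT = 6L)
  s <- call_editing_sites(p, g)
  expect_equal(nrow(s), 1L)
  expect_equal(s$edit_type, "C>T")
  expect_equal(s$efficiency, 0.6)
})

test_that("each documented filter excludes its counterexample", {
  g <- mito()
  # depth 9 on a mitogenome
  expect_equal(nrow(call_editing_sites(mk_pileup_df(5L, "C", 3L, 6L), g)), 0L)
  # quality 9 on the variant reads
  expect_equal(nrow(call_editing_sites(
    mk_pileup_df(5L, "C", 4L, 6L, q = 9), g)), 0L)
  # 3 bp from an indel
  expect_equal(nrow(call_editing_sites(
    mk_pileup_df(5L, "C", 4L, 6L, indel_dist = 3), g)), 0L)
  # exactly 5 bp away is still excluded; 6 passes
  expect_equal(nrow(call_editing_sites(
    mk_pileup_df(5L, "C", 4L, 6L, indel_dist = 5), g)), 0L)
  expect_equal(nrow(call_editing_sites(
    mk_pileup_df(5L, "C", 4L, 6L, indel_dist = 6), g)), 1L)
  # singleton variant evidence
  expect_equal(nrow(call_editing_sites(mk_pileup_df(5L, "C", 11L, 1L), g)), 0L)
  # plastome threshold is 20
  pg <- organelle_genome("m1", strrep("ACGT", 50), "linear", "plastome")
  expect_equal(nrow(call_editing_sites(mk_pileup_df(5L, "C", 13L, 6L), pg)), 0L)
  expect_equal(nrow(call_editing_sites(mk_pileup_df(5L, "C", 14L, 6L), pg)), 1L)
})

test_that("T>C sites are called and non-editing changes are not", {
  g <- mito()
  p <- rbind(mk_pileup_df(5L, "T", nC = 12L, nT = 18L),
             mk_pileup_df(9L, "G", nC = 0L, nT = 30L),     # G>T: not an edit type
             mk_pileup_df(12L, "A", nC = 30L, nT = 0L))    # A>C: not an edit type
  s <- call_editing_sites(p, g)
  expect_equal(nrow(s), 1L)
  expect_equal(s$edit_type, "T>C")
  expect_equal(s$efficiency, 0.4)
})

test_that("raising the depth threshold never adds sites", {
  g <- organelle_genome("m1", strrep("CT", 10000), "linear", "mitogenome")
  sp <- simulate_pileup(g, n_sites = 200, efficiency = runif(200, 0.1, 0.9),
                        seed = 62)
  f <- withr::local_tempfile(); writeLines(sp$lines, f)
  p <- read_pileup(f)
  n_prev <- Inf
  for (thr in c(5, 10, 20, 31)) {
    n <- nrow(call_editing_sites(p, g, config = orgdyn_config(edit_min_depth_mito = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_equal(n_prev, 0L)   # threshold above the simulated depth
})

test_that("simulated pileups round-trip: exactly the passing sites emerge", {
  set.seed(63)
  g <- organelle_genome("m1", random_seq(30000), "linear", "mitogenome")
  sp <- simulate_pileup(g, n_sites = 60, efficiency = runif(60, 0.2, 0.9),
                        n_low_depth = 5, n_low_quality = 5, n_near_indel = 5,
                        seed = 64, path = withr::local_tempfile())
  p <- read_pileup(sp$path)
  # decoded counts equal the generator's emitted counts at every site
  tr <- sp$truth
  m <- match(tr$pos, p$pos)
  expect_false(anyNA(m))
  alt_decoded <- ifelse(tr$alt_base == "T", p$nT[m], p$nC[m])
  expect_equal(alt_decoded, tr$alt_count)
  expect_equal(p$depth[m], tr$depth)
  sites <- call_editing_sites(p, g, tissue = "root")
  expect_setequal(sites$pos, tr$pos[tr$expected_pass])
  m2 <- match(sites$pos, tr$pos)
  expect_equal(sites$alt_count, tr$alt_count[m2])
  expect_equal(sites$efficiency, tr$alt_count[m2] / tr$depth[m2])
})

test_that("site location uses exonic CDS intervals only", {
  ft <- rbind(feat_row("c1", "CDS", "+", 100L, 160L, 1L),
              feat_row("c1", "CDS", "+", 200L, 260L, 2L))
  s <- structure(data.frame(genome_id = "m1", pos = c(120L, 180L, 300L),
                            ref_base = "C", alt_base = "T", edit_type = "C>T",
                            depth = 30L, alt_count = 10L, efficiency = 1 / 3,
                            location = NA_character_, tissue = "t"),
                 class = c("editing_sites", "data.frame"))
  out <- classify_site_location(s, ft)
  expect_equal(out$location, c("cds", "non-cds", "non-cds"))
  # randomized positions against a brute-force membership test
  set.seed(65)
  pos <- sample(0:400, 100)
  s2 <- s[rep(1, 100), ]; s2$pos <- pos
  out2 <- classify_site_location(s2, ft)
  want <- ifelse((pos >= 100 & pos < 160) | (pos >= 200 & pos < 260),
                 "cds", "non-cds")
  expect_equal(out2$location, want)
})

test_that("efficiency bins use a lower-closed top bin", {
  b <- bin_efficiency(c(0.85, 0.8, 1.0, 0.15, 0.2, 0.79999))
  expect_equal(unname(b$counts), c(1L, 1L, 0L, 1L, 3L))
  set.seed(66)
  eff <- runif(500)
  bb <- bin_efficiency(eff)
  naive <- c(sum(eff < 0.2), sum(eff >= 0.2 & eff < 0.4),
             sum(eff >= 0.4 & eff < 0.6), sum(eff >= 0.6 & eff < 0.8),
             sum(eff >= 0.8))
  expect_equal(unname(bb$counts), naive)
})

test_that("tissue summaries aggregate counts, types and contributions", {
  one <- data.frame(genome_id = "m1", pos = 1:10, ref_base = "C",
                    alt_base = "T", edit_type = "C>T", depth = 30L,
                    alt_count = 15L, efficiency = 0.5, location = "cds",
                    tissue = "root")
  ts1 <- tissue_summary(one)
  expect_equal(ts1$per_tissue$pct_ct, 100)
  expect_equal(ts1$per_tissue$n_sites, 10L)
  two <- rbind(one[rep(1, 225), ],
               transform(one[rep(1, 160), ], tissue = "stem"))
  ts2 <- tissue_summary(two)
  contrib <- ts2$contributions
  expect_equal(round(contrib$pct_of_genome[contrib$tissue == "root"], 1), 58.4)
  expect_equal(round(contrib$pct_of_genome[contrib$tissue == "stem"], 1), 41.6)
})
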