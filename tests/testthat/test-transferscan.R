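# Homology search, IR collapsing, transfer detection, windows, hotspots
# and synteny.

lin_genome <- function(seq, kind = "mitogenome", id = "g") {
  organelle_genome(id, seq, "linear", kind)
}

test_that("two identical sequences give one full-length same-strand fragment", {
  set.seed(41)
  s <- random_seq(300)
  fr <- homology_search(lin_genome(s, id = "a"), lin_genome(s, id = "b"))
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$q_start, 0L); expect_equal(fr$q_end, 300L)
  expect_equal(fr$s_start, 0L); expect_equal(fr$s_end, 300L)
  expect_equal(fr$identity, 1)
  expect_equal(fr$strand, "same")
})

test_that("a planted 600-bp segment at ~90% identity is recovered", {
  for (seed in 1:3) {
    set.seed(seed + 400)
    host <- random_seq(50000)
    donor <- random_seq(5000)
    seg <- substr(donor, 2001, 2600)
    ch <- strsplit(seg, "")[[1]]
    mut <- sample(600, 60)
    for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    substr(host, 20001, 20600) <- paste0(ch, collapse = "")
    fr <- homology_search(lin_genome(donor, id = "d"),
                          lin_genome(host, id = "h"))
    expect_equal(nrow(fr), 1L)
    ov_q <- min(fr$q_end, 2600) - max(fr$q_start, 2000)
    ov_s <- min(fr$s_end, 20600) - max(fr$s_start, 20000)
    expect_gte(ov_q / max(fr$q_end - fr$q_start, 600), 0.95)
    expect_gte(ov_s / max(fr$s_end - fr$s_start, 600), 0.95)
    expect_gte(fr$identity, 0.85)
  }
})

test_that("independent random sequences yield no fragment", {
  for (seed in 1:3) {
    set.seed(seed + 500)
    a <- lin_genome(random_seq(10000), id = "a")
    b <- lin_genome(random_seq(10000), id = "b")
    expect_equal(nrow(homology_search(a, b)), 0L)
  }
})

test_that("search is symmetric in its arguments", {
  set.seed(42)
  a <- random_seq(20000); b <- random_seq(30000)
  seg <- substr(a, 5001, 6200)
  substr(b, 10001, 11200) <- seg
  seg2 <- substr(a, 12001, 12500)
  substr(b, 20001, 20500) <- rc_str(seg2)
  ga <- lin_genome(a, id = "a"); gb <- lin_genome(b, id = "b")
  f1 <- homology_search(ga, gb)
  f2 <- homology_search(gb, ga)
  expect_equal(nrow(f1), nrow(f2))
  k1 <- with(f1, sort(paste(strand, q_start, q_end, s_start, s_end)))
  k2 <- with(f2, sort(paste(strand, s_start, s_end, q_start, q_end)))
  expect_equal(k1, k2)
})

test_that("lowering the identity cutoff never loses recovered bases", {
  set.seed(43)
  pl <- random_seq(20000); mt <- random_seq(30000)
  for (i in 1:4) {
    seg <- substr(pl, 1 + 3000 * i, 3000 * i + 800)
    ch <- strsplit(seg, "")[[1]]
    mut <- sample(800, 120)                           # 85% identity
    for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    substr(mt, 1 + 5000 * i, 5000 * i + 800) <- paste0(ch, collapse = "")
  }
  g1 <- lin_genome(pl, "plastome", "p"); g2 <- lin_genome(mt, id = "m")
  bp <- vapply(c(0.95, 0.9, 0.85, 0.8), function(idmin) {
    fr <- homology_search(g1, g2, orgdyn_config(homology_min_identity = idmin))
    sum(merge_intervals(fr, "subject")$end -
          merge_intervals(fr, "subject")$start)
  }, 0)
  expect_true(all(diff(bp) >= 0))
})

test_that("interval merging coalesces overlaps and matches the mask oracle", {
  m <- merge_intervals(data.frame(start = c(100L, 300L), end = c(400L, 700L)))
  expect_equal(m, data.frame(start = 100L, end = 700L))
  m2 <- merge_intervals(data.frame(start = c(0L, 500L), end = c(100L, 600L)))
  expect_equal(nrow(m2), 2L)
  # bookended intervals coalesce
  m3 <- merge_intervals(data.frame(start = c(0L, 100L), end = c(100L, 150L)))
  expect_equal(m3, data.frame(start = 0L, end = 150L))
  set.seed(44)
  iv <- data.frame(start = sample(0:5000, 200, replace = TRUE))
  iv$end <- iv$start + sample(1:300, 200, replace = TRUE)
  mm <- merge_intervals(iv)
  expect_equal(sum(mm$end - mm$start), mask_union_bp(iv, 6000))
  expect_true(all(mm$start[-1] > mm$end[-nrow(mm)]))
})

test_that("IR collapsing excises the second copy and tolerates SNPs", {
  set.seed(45)
  pl <- random_seq(30000)
  ir <- substr(pl, 2001, 7000)                        # 5-kb IR
  irrc <- rc_str(ir)
  ch <- strsplit(irrc, "")[[1]]
  for (p in sample(5000, 2)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  substr(pl, 20001, 25000) <- paste0(ch, collapse = "")
  g <- lin_genome(pl, "plastome", "p")
  red <- collapse_inverted_repeat(g)
  expect_lte(abs(red$removed_bp - 5000L), 10L)
  expect_lte(abs(genome_length(red$genome) - 25000L), 10L)
  expect_gte(red$ir_removed[1], 19900L)               # second occurrence excised
  # genome without an IR is returned unchanged
  set.seed(46)
  g2 <- lin_genome(random_seq(20000), "plastome", "p2")
  red2 <- collapse_inverted_repeat(g2)
  expect_identical(red2$genome$sequence, g2$sequence)
  expect_null(red2$ir_removed)
})

test_that("transfer detection recovers planted fragments and merges sides", {
  sim <- simulate_organelle_pair(47)
  red <- collapse_inverted_repeat(sim$plastome)
  ts <- detect_transfers(red$genome, sim$mitogenome)
  tr <- sim$truth$planted_transfers
  expect_equal(ts$mitogenome_count, nrow(tr))
  expect_equal(ts$plastome_count,
               nrow(merge_intervals(data.frame(start = tr$p_start_reduced,
                                               end = tr$p_end_reduced))))
  ov <- 0
  for (i in seq_len(nrow(ts$mitogenome_intervals)))
    for (j in seq_len(nrow(tr)))
      ov <- ov + max(0, min(ts$mitogenome_intervals$end[i], tr$m_end[j]) -
                       max(ts$mitogenome_intervals$start[i], tr$m_start[j]))
  expect_gte(ov / sum(tr$m_end - tr$m_start), 0.95)
  # totals equal per-base union of the fragments (mask oracle)
  iv <- data.frame(start = ts$fragments$s_start, end = ts$fragments$s_end)
  expect_equal(ts$mitogenome_total_bp,
               mask_union_bp(iv, genome_length(sim$mitogenome)))
})

test_that("no homology gives an empty transfer set", {
  set.seed(48)
  pl <- lin_genome(random_seq(12000), "plastome", "p")
  mt <- lin_genome(random_seq(15000), id = "m")
  ts <- detect_transfers(pl, mt)
  expect_equal(ts$plastome_count, 0L)
  expect_equal(ts$mitogenome_total_bp, 0L)
})

test_that("fragment length bins use the printed inclusive bounds", {
  iv <- data.frame(start = c(0, 1000, 2000, 3000),
                   end = c(150, 1250, 2600, 4500))
  expect_equal(unname(bin_fragment_lengths(iv)), c(1L, 1L, 0L, 1L, 1L))
  expect_equal(sum(bin_fragment_lengths(iv[0, ])), 0L)
  expect_error(bin_fragment_lengths(data.frame(start = 0, end = 50)), "100")
  # boundary membership
  iv2 <- data.frame(start = 0, end = c(200, 201, 500, 501, 1000, 1001))
  expect_equal(unname(bin_fragment_lengths(iv2)), c(1L, 1L, 1L, 2L, 1L))
})

test_that("fragment content classification uses the 50% exonic-base rule", {
  ft <- rbind(feat_row("c1", "CDS", "+", 1000L, 2000L),
              feat_row("t1", "tRNA", "+", 5000L, 5075L))
  inside <- classify_fragment_content(data.frame(start = 1200L, end = 1400L), ft)
  expect_equal(inside$label, "cds")
  out <- classify_fragment_content(data.frame(start = 3000L, end = 3500L), ft)
  expect_equal(out$label, "non-cds")
  part <- classify_fragment_content(data.frame(start = 1700L, end = 2200L), ft)
  expect_equal(part$coding_fraction, 0.6)
  expect_equal(part$label, "cds")
})

test_that("window profiles attribute transferred bases per base", {
  prof <- window_transfer_profile(data.frame(start = 1000L, end = 3500L),
                                  20000L, 5000L)
  expect_equal(prof$value[1], 2500L)
  expect_equal(sum(prof$value), 2500L)
  prof2 <- window_transfer_profile(data.frame(start = 3000L, end = 8000L),
                                   20000L, 5000L)
  expect_equal(prof2$value[1:2], c(2000L, 3000L))
  # conservation + mask oracle on random interval sets
  set.seed(49)
  for (r in 1:3) {
    iv <- data.frame(start = sample(0:18000, 40, replace = TRUE))
    iv$end <- pmin(iv$start + sample(50:2000, 40, replace = TRUE), 20000L)
    mg <- merge_intervals(iv)
    p <- window_transfer_profile(mg, 20000L, 5000L)
    expect_equal(p$value, mask_window_sums(iv, 20000L, 5000L))
    expect_equal(sum(p$value), sum(mg$end - mg$start))
  }
})

test_that("hotspot calling is strictly greater than the threshold", {
  prof <- structure(data.frame(start = c(0L, 5000L), end = c(5000L, 10000L),
                               value = c(2500L, 2000L)),
                    class = c("window_profile", "data.frame"))
  hs <- call_hotspots(prof, 2000)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$value, 2500L)
})

test_that("hotspot tRNA flags need only one overlapping base", {
  ft <- rbind(feat_row("t1", "tRNA", "+", 1000L, 1075L),
              feat_row("t2", "tRNA", "+", 4995L, 5070L))
  hs <- data.frame(start = c(0L, 5000L, 10000L), end = c(5000L, 10000L, 15000L),
                   value = c(2500L, 2500L, 2500L))
  out <- annotate_hotspot_trnas(hs, ft)
  expect_equal(out$trna, c(TRUE, TRUE, FALSE))   # 5-bp edge overlap flags t2
  expect_equal(attr(out, "fraction"), 2 / 3)
})

test_that("self synteny drops the trivial diagonal; rotations are recovered", {
  set.seed(50)
  g <- lin_genome(random_seq(12000), id = "s")
  sy <- synteny_blocks(g, g, self_mode = TRUE)
  expect_equal(nrow(sy$blocks), 0L)
  # exact copy under a circular rotation: blocks jointly cover >= 99%
  s <- random_seq(30000)
  rot <- paste0(substr(s, 10001, 30000), substr(s, 1, 10000))
  ga <- lin_genome(s, id = "a"); gb <- lin_genome(rot, id = "b")
  sy2 <- synteny_blocks(ga, gb)
  cov <- merge_intervals(sy2$blocks[, c("a_start", "a_end")] |>
                           setNames(c("start", "end")))
  expect_gte(sum(cov$end - cov$start) / 30000, 0.99)
  # planted shared 8-kb block -> exactly one display block
  set.seed(51)
  x <- random_seq(40000); y <- random_seq(40000)
  blk <- substr(x, 15001, 23000)
  substr(y, 5001, 13000) <- blk
  sy3 <- synteny_blocks(lin_genome(x, id = "x"), lin_genome(y, id = "y"))
  expect_equal(nrow(sy3$display), 1L)
  expect_gte(sy3$display$length, 8000 * 0.99)
})

test_that("circos link files carry 1-based inclusive coordinates", {
  blocks <- data.frame(genome_a = "a", genome_b = "b", a_start = 0L,
                       a_end = 100L, b_start = 50L, b_end = 150L,
                       orientation = "+", length = 100L, identity = 1)
  f <- withr::local_tempfile()
  write_circos_links(blocks, f)
  expect_equal(readLines(f), "a 1 100 b 51 150")
})
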