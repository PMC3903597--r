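test_that("find_tir_pairs recovers a planted inverted-repeat pair", {
  set.seed(21)
  tir <- random_seq(150)
  tir_r <- mutate_at(tir, sample(150, 12))       # 92% identity
  win <- paste0(random_seq(300), tir, random_seq(2400),
                mulescan:::revcomp(tir_r), random_seq(300))
  pairs <- find_tir_pairs(win)
  expect_gte(nrow(pairs), 1)
  best <- pairs[1, ]
  expect_lt(abs(best$left_start - 301), 8)
  expect_lt(abs(best$right_end - (300 + 150 + 2400 + 150)), 8)
  expect_lt(abs(best$identity - 0.92), 0.02)
})

test_that("direct repeats and sub-2kb spans yield no TIR pairs", {
  set.seed(22)
  rep150 <- random_seq(150)
  direct <- paste0(random_seq(300), rep150, random_seq(2400), rep150,
                   random_seq(300))
  expect_identical(nrow(find_tir_pairs(direct)), 0L)
  tir <- random_seq(150)
  close_pair <- paste0(random_seq(2000), tir, random_seq(1000),
                       mulescan:::revcomp(tir), random_seq(2000))
  expect_identical(nrow(find_tir_pairs(close_pair)), 0L)  # span < 2 kb
})

test_that("find_tir_pairs agrees with a brute-force search on small windows", {
  set.seed(23)
  tlen <- 120L
  tir <- random_seq(tlen)
  tir_r <- mutate_at(tir, sample(tlen, 8))
  win <- paste0(random_seq(250), tir, random_seq(2200),
                mulescan:::revcomp(tir_r), random_seq(250))
  n <- nchar(win)
  # brute force: ungapped identity of every (left start, right end) placement
  subj <- Biostrings::DNAString(win)
  best <- c(i = NA, j = NA, id = 0)
  for (i in seq_len(n - 2000L)) {
    L <- substr(win, i, i + tlen - 1L)
    rs <- seq(i + 2000L - tlen, n - tlen + 1L)
    rs <- rs[rs >= 1 & rs + tlen - 1L <= n]
    if (!length(rs)) next
    ned <- Biostrings::neditStartingAt(Biostrings::DNAString(mulescan:::revcomp(L)),
                                       subj, starting.at = rs)
    k <- which.min(ned)
    id <- 1 - ned[k] / tlen
    if (id > best["id"]) best <- c(i = i, j = rs[k] + tlen - 1L, id = id)
  }
  pairs <- find_tir_pairs(win)
  expect_gte(nrow(pairs), 1)
  expect_lt(abs(pairs$left_start[1] - best["i"]), 10)
  expect_lt(abs(pairs$right_end[1] - best["j"]), 10)
  # gapped vs ungapped identity definitions differ slightly at the edges
  expect_lt(abs(pairs$identity[1] - best["id"]), 0.05)
})

test_that("translated scan finds exact back-translations and frameshift halves", {
  prot <- ref_fix$protein
  set.seed(24)
  cds <- mulescan:::with_seed(31, mulescan:::back_translate(prot))
  g <- c(chr = paste0(random_seq(2000), cds, random_seq(2000)))
  hits <- translated_homology_scan(g, c(q = prot))
  expect_gte(nrow(hits), 1)
  expect_lte(abs(hits$start[which.max(hits$score)] - 2001L), 3L)
  # a 1-nt deletion splits the signal across two frames
  cds_fs <- paste0(substr(cds, 1, 1200), substr(cds, 1202, nchar(cds)))
  g2 <- c(chr = paste0(random_seq(2000), cds_fs, random_seq(2000)))
  hits2 <- translated_homology_scan(g2, c(q = prot))
  expect_gte(nrow(hits2), 2)
  expect_gte(length(unique(hits2$frame)), 2)
})

test_that("translated scan is quiet on i.i.d. background", {
  zero <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    g <- c(bg = random_seq(100000))
    if (nrow(translated_homology_scan(g, c(q = ref_fix$protein))) == 0)
      zero <- zero + 1L
  }
  expect_gte(zero, 9L)
})

test_that("element calling recovers planted elements with validated structure", {
  truth_spans <- t(sapply(small_sim$truth, function(x) x$span))
  matched <- mapply(function(s, e)
    any(abs(truth_spans[, 1] - s) <= 20 & abs(truth_spans[, 2] - e) <= 20),
    small_calls$start, small_calls$end)
  expect_gte(sum(matched) / nrow(truth_spans), 0.95)   # recall
  expect_gte(mean(matched), 0.95)                      # precision
  # every emitted call re-validates the three structural criteria
  for (i in seq_len(nrow(small_calls))) {
    cl <- small_calls[i, ]
    expect_gt(cl$tir_identity, 0.75)
    span <- cl$end - cl$start + 1L
    expect_true(span >= 2000 && span <= 30000)
    g <- small_sim$genome[[cl$seq_id]]
    expect_true(validate_tsd(substr(g, cl$start - cl$tsd_len, cl$start - 1L),
                             substr(g, cl$end + 1L, cl$end + cl$tsd_len))$valid)
  }
})

test_that("a scrambled TSD or low-identity TIR pair blocks the call", {
  cfg <- sim_config(seed = 31, genome_len = 40000, n_elements = 1)
  sim <- simulate_genome(cfg)
  tr <- sim$truth[[1]]
  g <- sim$genome[[1]]
  # scramble the right TSD copy
  set.seed(32)
  broken <- paste0(substr(g, 1, tr$span[2]), random_seq(nchar(tr$tsd)),
                   substr(g, tr$span[2] + nchar(tr$tsd) + 1L, nchar(g)))
  hits <- translated_homology_scan(c(chr = broken), c(q = sim$ref$protein))
  expect_identical(nrow(call_candidate_elements(c(chr = broken), hits)), 0L)
  # degrade the right TIR below 75% identity
  tir_len <- tr$tirR[2] - tr$tirR[1] + 1L
  bad_tir <- mutate_at(substr(g, tr$tirR[1], tr$tirR[2]),
                       sample(tir_len, round(0.4 * tir_len)))
  g2 <- paste0(substr(g, 1, tr$tirR[1] - 1L), bad_tir,
               substr(g, tr$tirR[2] + 1L, nchar(g)))
  hits2 <- translated_homology_scan(c(chr = g2), c(q = sim$ref$protein))
  expect_identical(nrow(call_candidate_elements(c(chr = g2), hits2)), 0L)
})

test_that("discovery is strand-symmetric", {
  g <- small_sim$genome
  g_rc <- c(synth_chr1 = mulescan:::revcomp(g[[1]]))
  hits_rc <- translated_homology_scan(g_rc, c(tpase = small_sim$ref$protein))
  calls_rc <- call_candidate_elements(g_rc, hits_rc)
  expect_identical(nrow(calls_rc), nrow(small_calls))
  n <- nchar(g[[1]])
  mirrored <- data.frame(start = sort(n - calls_rc$end + 1L),
                         end = sort(n - calls_rc$start + 1L))
  expect_true(all(abs(mirrored$start - sort(small_calls$start)) <= 5))
  expect_true(all(abs(mirrored$end - sort(small_calls$end)) <= 5))
})

test_that("representative clustering collapses near-identical elements", {
  set.seed(25)
  a <- random_seq(3000)
  b <- mutate_at(a, sample(3000, 30))       # 99% identical to a
  c_ <- random_seq(3000)                    # unrelated
  reps <- cluster_representatives(c(e1 = a, e2 = b, e3 = c_))
  expect_identical(length(reps), 2L)
  expect_identical(cluster_representatives(c(x = a, y = a)), "x")
  d <- mutate_at(a, sample(3000, 900))      # ~70% identity: kept apart
  expect_identical(length(cluster_representatives(c(e1 = a, e4 = d))), 2L)
  # a large near-clonal family collapses to a small representative set
  fam <- stats::setNames(
    c(lapply(1:12, function(i) mutate_at(a, sample(3000, 15))), list(c_)),
    sprintf("m%02d", 1:13))
  fam <- vapply(fam, identity, "")
  expect_lt(length(cluster_representatives(fam)), 13L)
})

test_that("size profile bins stripped lengths as 2-3.5 / 3.5-8 / >8 kb", {
  sp <- size_profile(c(3000, 4000, 9000, 2200))
  expect_identical(sp$count, c(2L, 1L, 1L))
  expect_equal(sum(sp$fraction), 1)
  expect_warning(sp2 <- size_profile(c(1500, 5000)), "under 2 kb")
  expect_identical(sp2$count[1], 1L)
})
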