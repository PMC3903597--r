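test_that("indel counting treats a gap run as one event and is symmetric", {
  set.seed(71)
  a <- random_seq(2000)
  st <- align_count_indels(a, a)
  expect_identical(st$n_indels, 0L)
  expect_identical(st$indel_len_total, 0L)
  expect_equal(st$identity, 1)
  expect_identical(st$aligned_cols, 2000L)
  # one 10-bp insertion: one indel of length 10, identity still 1
  b <- paste0(substr(a, 1, 1000), random_seq(10), substr(a, 1001, 2000))
  st2 <- align_count_indels(a, b)
  expect_identical(st2$n_indels, 1L)
  expect_identical(st2$indel_len_total, 10L)
  expect_equal(st2$identity, 1)
  # symmetry of every statistic
  c_ <- mutate_at(b, sample(2010, 20))
  expect_identical(align_count_indels(a, c_), align_count_indels(c_, a))
  expect_error(align_count_indels(random_seq(100), a), "200")
})

test_that("estimated indel counts track the planted rate", {
  set.seed(72)
  errs <- replicate(40, {
    base <- random_seq(3000)
    m <- mutate_homolog(base, 0.01, 2)
    st <- align_count_indels(base, m$seq)
    st$n_indels - m$truth$n_indels
  })
  # mean estimated count within 10% of the mean planted count (~6 per pair)
  expect_lt(abs(mean(errs)) / 6, 0.10)
})

test_that("NIK and LIK normalize by summed element length", {
  nl <- compute_nik_lik(3, 30, 2000, 2000)
  expect_equal(nl$NIK, 0.75)
  expect_equal(nl$LIK, 7.5)
  expect_equal(compute_nik_lik(0, 0, 1000, 3000)$NIK, 0)
  expect_error(compute_nik_lik(1, 5, 0, 0), "zero")
})

test_that("best-homolog pairing keeps longest-alignment partners above 95% identity", {
  set.seed(73)
  a <- random_seq(2500)
  fam <- c(e1 = a,
           e2 = mutate_at(a, sample(2500, 25)),     # 99% to e1
           e3 = mutate_at(a, sample(2500, 50)))     # ~98%
  pairs <- best_homolog_pairs(fam)
  expect_true(all(pairs$identity > 0.95))
  expect_true(all(pairs$id_a < pairs$id_b))          # unordered, unique
  # an element whose only relative is at ~90% identity is excluded
  far <- c(x1 = a, x2 = mutate_at(a, sample(2500, 250)))
  expect_identical(nrow(best_homolog_pairs(far)), 0L)
  expect_error(best_homolog_pairs(c(only = a)), "two elements")
})

test_that("Ks is zero for identical CDS and matches NG86 closed forms", {
  set.seed(74)
  cds <- mulescan:::with_seed(74, mulescan:::back_translate(ref_fix$protein,
                                                            add_stop = FALSE))
  cds100 <- substr(cds, 1, 300)
  expect_equal(compute_ks(cds100, cds100), 0)
  # single synonymous third-position change in 100 codons: hand oracle
  mut <- cds100
  pos <- 150                                    # third position of codon 50
  old <- substr(mut, pos, pos)
  gc <- Biostrings::GENETIC_CODE
  for (b in setdiff(c("A", "C", "G", "T"), old)) {
    cand <- mut; substr(cand, pos, pos) <- b
    if (gc[[substr(cand, 148, 150)]] == gc[[substr(cds100, 148, 150)]]) {
      mut <- cand; break
    }
  }
  expect_false(identical(mut, cds100))
  expect_equal(compute_ks(cds100, mut), ng86_oracle(cds100, mut), tolerance = 1e-9)
})

test_that("Ks equals the exhaustive site-counting oracle on random toy pairs", {
  set.seed(75)
  for (rep in 1:5) {
    prot <- paste(sample(setdiff(mulescan:::AA20, "M"), 80, replace = TRUE),
                  collapse = "")
    a <- mulescan:::back_translate(paste0("M", prot), add_stop = FALSE)
    b <- a
    idx <- sample(nchar(b), 6)
    b <- mutate_at(b, idx)
    ks_a <- compute_ks(a, b)
    ks_b <- ng86_oracle(a, b)
    if (is.na(ks_a)) expect_true(is.na(ks_b))
    else expect_equal(ks_a, ks_b, tolerance = 1e-6)
  }
  expect_true(is.na(compute_ks(substr(ref_fix$protein, 1, 60),
                               substr(ref_fix$protein, 1, 60))))  # < 30 codons usable
})

test_that("Ks increases monotonically with the substitution scale", {
  set.seed(76)
  cds <- mulescan:::back_translate(ref_fix$protein, add_stop = FALSE)
  ks <- vapply(c(5, 15, 30, 60, 100), function(k) {
    m <- mutate_at(cds, sample(nchar(cds), k))
    compute_ks(cds, m)
  }, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("binning by identity assigns pairs to printed ranges", {
  ps <- data.frame(identity = c(0.955, 0.968, 0.995, 1.0),
                   NIK = c(2.5, 1.5, 0.6, 0), LIK = c(80, 60, 20, 0))
  b <- bin_pairs(ps)
  expect_identical(b$n, c(1L, 1L, 0L, 0L, 2L))
  expect_equal(b$mean_NIK[1], 2.5)
  expect_true(is.na(b$mean_NIK[3]))
  # all-identical pairs collapse into the (99,100] bin with NIK 0
  same <- data.frame(identity = rep(1, 4), NIK = 0, LIK = 0)
  b2 <- bin_pairs(same)
  expect_identical(b2$n[5], 4L)
  expect_equal(b2$mean_NIK[5], 0)
  # duplicating the pair set leaves bin means unchanged
  b3 <- bin_pairs(rbind(ps, ps))
  expect_equal(b3$mean_NIK, b$mean_NIK)
})

test_that("doubling the simulated indel rate doubles mean NIK", {
  set.seed(77)
  mean_nik <- function(rate, n = 40) {
    mean(replicate(n, {
      base <- random_seq(3000)
      m <- mutate_homolog(base, 0.005, rate)
      st <- align_count_indels(base, m$seq)
      compute_nik_lik(st$n_indels, st$indel_len_total, 3000, nchar(m$seq))$NIK
    }))
  }
  r1 <- mean_nik(1.5); r2 <- mean_nik(3)
  expect_lt(abs(r2 / r1 - 2), 0.3)
})
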